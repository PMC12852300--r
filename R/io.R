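#' Parse a stoichiometry string
#'
#' Accepts strings like `"aISU + 7.59143·FM -> ISU"`; coefficients are
#' attached with `·` or `*` (a bare name means coefficient 1), terms are
#' joined with `+`, and the arrow may be `->` or the UTF-8 arrow.
#' An empty right-hand side denotes a dilution-style sink.
#'
#' @param s the stoichiometry string.
#' @return list with named numeric vectors `reactants` and `products`.
#' @export
parse_reaction_string <- function(s) {
  s <- gsub("→", "->", s)
  sides <- strsplit(s, "->", fixed = TRUE)[[1]]
  if (length(sides) < 1 || length(sides) > 2)
    stop("cannot parse stoichiometry string: ", s)
  parse_side <- function(side) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      parts <- strsplit(term, "[·*]")[[1]]
      parts <- trimws(parts)
      if (length(parts) == 1) {
        out[parts] <- sum(out[parts], 1, na.rm = TRUE)
      } else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient in term: ", term)
        out[parts[2]] <- sum(out[parts[2]], coef, na.rm = TRUE)
      } else stop("cannot parse term: ", term)
    }
    out
  }
  list(reactants = parse_side(sides[1]),
       products = if (length(sides) == 2) parse_side(sides[2]) else numeric(0))
}

#' @rdname parse_reaction_string
#' @param rxn a [reaction()].
#' @return `format_reaction_string` returns the canonical string form.
#' @export
format_reaction_string <- function(rxn) {
  fmt <- function(coefs) {
    if (!length(coefs)) return("")
    paste(ifelse(coefs == 1, names(coefs),
                 paste0(sprintf("%.10g", coefs), "·", names(coefs))),
          collapse = " + ")
  }
  paste(fmt(rxn$reactants), "->", fmt(rxn$products))
}

#' Write a model bundle
#'
#' Serializes a network to a directory: `components.tsv` (name,
#' compartment, role, conc_uM, carbon, per-center iron columns),
#' `reactions.tsv` (id, kind, location, stoichiometry string, catalyst
#' list, invented flag; dilution reactions omitted since they regenerate)
#' and `morphology.json`.
#'
#' @param network a `bp_network`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(network$components, file.path(dir, "components.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  non_dil <- Filter(Negate(is_dilution), network$reactions)
  rdf <- data.frame(
    id = vapply(non_dil, `[[`, "", "id"),
    kind = vapply(non_dil, `[[`, "", "kinetics"),
    location = vapply(non_dil, `[[`, "", "location"),
    stoichiometry = vapply(non_dil, format_reaction_string, ""),
    catalysts = vapply(non_dil, function(r)
      paste(r$catalysts, collapse = ","), ""),
    invented = vapply(non_dil, function(r) r$invented, TRUE),
    stringsAsFactors = FALSE)
  utils::write.table(rdf, file.path(dir, "reactions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  m <- network$morphology
  jsonlite::write_json(list(
    V_cell = m$V_cell, alpha_cell = m$alpha_cell,
    fractions = as.list(unclass(m$fractions)),
    bilayer_thickness_um = m$bilayer_thickness_um,
    mito_inner_to_outer_area_ratio = m$mito_inner_to_outer_area_ratio,
    nuclear_membrane_layers = m$nuclear_membrane_layers,
    er_membrane_fraction = m$er_membrane_fraction,
    pl_molecule_volume = m$pl_molecule_volume,
    mito_cylinder_radius_um = m$mito_cylinder_radius_um
  ), file.path(dir, "morphology.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a model bundle
#'
#' @param dir directory written by [write_model()].
#' @return a validated `bp_network`.
#' @export
read_model <- function(dir) {
  comp <- utils::read.table(file.path(dir, "components.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  rdf <- utils::read.table(file.path(dir, "reactions.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  mj <- jsonlite::read_json(file.path(dir, "morphology.json"),
                            simplifyVector = TRUE)
  morph <- cell_morphology(
    V_cell = mj$V_cell, alpha_cell = mj$alpha_cell,
    fractions = unlist(mj$fractions),
    bilayer_thickness_um = mj$bilayer_thickness_um,
    mito_inner_to_outer_area_ratio = mj$mito_inner_to_outer_area_ratio,
    nuclear_membrane_layers = mj$nuclear_membrane_layers,
    er_membrane_fraction = mj$er_membrane_fraction,
    pl_molecule_volume = mj$pl_molecule_volume,
    mito_cylinder_radius_um = mj$mito_cylinder_radius_um)
  rxns <- lapply(seq_len(nrow(rdf)), function(i) {
    st <- parse_reaction_string(rdf$stoichiometry[i])
    cats <- rdf$catalysts[i]
    cats <- if (is.na(cats) || !nzchar(cats)) character(0) else
      trimws(strsplit(cats, ",")[[1]])
    reaction(rdf$id[i], st$reactants, st$products, catalysts = cats,
             kinetics = rdf$kind[i], location = rdf$location[i],
             invented = isTRUE(rdf$invented[i]))
  })
  reaction_network(comp, rxns, morph)
}

#' Load a full-model stoichiometric or basic-pathways matrix from CSV
#'
#' Reads a plain CSV export (first row reaction/pathway ids, first column
#' component/reaction ids) of the published full-model matrices and
#' validates its structure: the S matrix must be 80 x 169 with a diagonal
#' strictly-negative dilution block in its last 80 columns; the W matrix
#' must be 169 x 89 and entirely nonnegative.  Set `dims = NULL` to skip
#' the dimension check (e.g. for reduced models in the same layout).
#'
#' @param path CSV file path.
#' @param kind `"S"` or `"W"`.
#' @param dims expected `c(rows, cols)`; defaults to the published
#'   dimensions.
#' @return the validated numeric matrix.
#' @export
load_si_matrix <- function(path, kind = c("S", "W"), dims = "published") {
  kind <- match.arg(kind)
  M <- read_matrix_csv(path)
  if (identical(dims, "published"))
    dims <- if (kind == "S") c(80L, 169L) else c(169L, 89L)
  if (!is.null(dims) && !all(dim(M) == dims))
    stop(sprintf("%s matrix must be %d x %d, got %d x %d",
                 kind, dims[1], dims[2], nrow(M), ncol(M)))
  if (kind == "S") {
    m <- nrow(M)
    D <- M[, seq.int(ncol(M) - m + 1L, ncol(M)), drop = FALSE]
    off <- D; diag(off) <- 0
    if (any(off != 0) || any(diag(D) >= 0))
      stop("S matrix lacks the diagonal negative dilution block")
  } else {
    if (any(M < 0)) stop("W matrix must be nonnegative")
    if (any(rowSums(M != 0) == 0) || any(colSums(M != 0) == 0))
      stop("W matrix has an all-zero row or column")
  }
  M
}
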