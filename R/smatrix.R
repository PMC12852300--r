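#' Build the volume-scaled stoichiometric matrix
#'
#' Every reaction rate is cytosol-referenced: the rate is the time
#' derivative of the extent of reaction per cytosolic volume, whatever
#' compartment the chemistry occurs in.  Consequently the matrix entry for
#' component i (home compartment k) in reaction j is the signed
#' stoichiometric coefficient multiplied by the volume ratio
#' \eqn{V_{cyt}/V_k = f_c/f_k}; cytosolic components carry the plain
#' coefficient.  Nutrients are boundary species and get no row.  The
#' dilution column of component i has the single entry \eqn{-f_c/f_k} in
#' row i, so the dilution block is diagonal and strictly negative and the
#' matrix has the (S0 | -D) structure.
#'
#' @param network a validated [reaction_network()].
#' @return an object of class `bp_smatrix`: list with `matrix`,
#'   `component_index`, `reaction_index`, `r` (non-dilution reaction
#'   count) and `m` (component count).
#' @export
build_smatrix <- function(network) {
  comp <- network$components
  f <- network$morphology$fractions
  rows <- internal_components(network)
  m <- length(rows)
  scale_of <- function(name) {
    k <- comp$compartment[match(name, comp$name)]
    f[["c"]] / f[[k]]
  }
  row_scale <- vapply(rows, scale_of, numeric(1))

  rxns <- network$reactions
  n <- length(rxns)
  r <- sum(!vapply(rxns, is_dilution, TRUE))
  ids <- vapply(rxns, `[[`, "", "id")
  S <- matrix(0, m, n, dimnames = list(rows, ids))
  for (j in seq_len(n)) {
    rxn <- rxns[[j]]
    add_entries <- function(coefs, sign) {
      for (nm in names(coefs)) {
        i <- match(nm, rows)
        if (is.na(i)) next  # nutrient: boundary species, no row
        entry <- sign * coefs[[nm]] * row_scale[[i]]
        if (S[i, j] != 0)
          warning(rxn$id, ": duplicate entry for ", nm, "; coefficients summed")
        S[i, j] <<- S[i, j] + entry
      }
    }
    add_entries(rxn$reactants, -1)
    add_entries(rxn$products, +1)
  }
  structure(list(matrix = S, component_index = rows, reaction_index = ids,
                 r = r, m = m), class = "bp_smatrix")
}

#' @export
print.bp_smatrix <- function(x, ...) {
  cat("Stoichiometric matrix:", x$m, "components x",
      length(x$reaction_index), "reactions (", x$r, "non-dilution )\n")
  invisible(x)
}

#' Validate the structure of a stoichiometric matrix
#'
#' Checks the diagonal strictly-negative dilution block, computes the
#' numerical rank (expected full row rank m for an (S0 | -D) system) and
#' the nullity n - m.  Structural violations are reported, not thrown.
#'
#' @param S a `bp_smatrix`.
#' @param tol singular-value tolerance for the rank computation.
#' @return list with `ok`, `rank`, `nullity`, `full_rank` and `problems`.
#' @export
validate_structure <- function(S, tol = 1e-10) {
  M <- S$matrix
  n <- ncol(M)
  problems <- character(0)
  dil_cols <- seq.int(S$r + 1L, n)
  if (length(dil_cols) != S$m) {
    problems <- c(problems, sprintf(
      "dilution block is %d x %d, expected square of size m = %d",
      S$m, length(dil_cols), S$m))
  } else {
    D <- M[, dil_cols, drop = FALSE]
    offdiag <- D; diag(offdiag) <- 0
    if (any(offdiag != 0))
      problems <- c(problems, "dilution block has off-diagonal entries")
    if (any(diag(D) >= 0))
      problems <- c(problems, "dilution block diagonal is not strictly negative")
  }
  sv <- svd(M, nu = 0, nv = 0)$d
  rank <- sum(sv > tol * max(sv, 1))
  if (rank != S$m)
    problems <- c(problems, sprintf("rank %d != m = %d", rank, S$m))
  list(ok = length(problems) == 0, rank = rank, nullity = n - rank,
       full_rank = rank == S$m, problems = problems)
}

#' Diagonal of the dilution block (positive values)
#' @param S a `bp_smatrix`.
#' @return numeric vector of length m, named by component.
#' @export
dilution_diagonal <- function(S) {
  dil <- S$matrix[, seq.int(S$r + 1L, ncol(S$matrix)), drop = FALSE]
  stats::setNames(-diag(dil), S$component_index)
}

#' Write / read a matrix CSV
#'
#' First row holds reaction ids, first column component ids, cells the
#' matrix entries at full double precision; read and write round-trip
#' bit-exactly for canonical formatting.
#'
#' @param M numeric matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_csv <- function(M, path) {
  df <- data.frame(component = rownames(M),
                   matrix(sprintf("%.17g", M), nrow(M), ncol(M)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("component", colnames(M))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_matrix_csv
#' @return `read_matrix_csv` returns the numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df[[1]]
  M
}
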