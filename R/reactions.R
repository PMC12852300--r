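KINETICS_KINDS <- c("mass_action", "michaelis_menten", "transport_ratio",
                    "dilution")
COMPONENT_ROLES <- c("nutrient", "waste", "protein_group", "metabolite",
                     "iron_pool")

#' Define a model component
#'
#' @param name component identifier.
#' @param compartment compartment id (`c`, `m`, `n`, `v`, `e`).
#' @param role one of nutrient, waste, protein_group, metabolite,
#'   iron_pool.
#' @param conc_uM wild-type steady-state cellular concentration (uM); may
#'   be `NA` when concentrations are derived later from steady-state
#'   dilution rates.
#' @param carbon carbons per molecule.
#' @param iron an [iron_profile()]; default no iron.
#' @return one-row data.frame in the canonical component-table layout.
#' @export
component <- function(name, compartment, role = "metabolite",
                      conc_uM = NA_real_, carbon = 0,
                      iron = iron_profile()) {
  role <- match.arg(role, COMPONENT_ROLES)
  if (carbon < 0) stop("carbon_count must be >= 0")
  if (!is.na(conc_uM) && conc_uM < 0) stop("concentration must be >= 0")
  p <- unclass(iron)
  data.frame(name = name, compartment = compartment, role = role,
             conc_uM = conc_uM, carbon = carbon,
             fe_FH = p[["FH"]], fe_FO = p[["FO"]], fe_FF = p[["FF"]],
             fe_F2 = p[["F2"]], fe_F3 = p[["F3"]], fe_F4 = p[["F4"]],
             stringsAsFactors = FALSE)
}

#' Define a reaction
#'
#' Reactions are irreversible; reactants and products carry strictly
#' positive stoichiometric coefficients.  Catalysts modulate the rate law
#' but never enter the stoichiometry or element balance.  A dilution
#' reaction has exactly one reactant, no products and no catalysts.
#'
#' @param id reaction identifier; by convention prefixed by category
#'   (AC activity, B biosynthesis, M metallation, T transfer,
#'   U unmetallation, D dilution).
#' @param reactants named numeric vector of coefficients (> 0).
#' @param products named numeric vector of coefficients (> 0); empty for
#'   dilution.
#' @param catalysts character vector of component names.
#' @param kinetics one of mass_action, michaelis_menten, transport_ratio,
#'   dilution.
#' @param location compartment id or interface label (metadata only).
#' @param invented flag for closure reactions not taken from curated
#'   stoichiometry.
#' @return an object of class `bp_reaction`.
#' @export
reaction <- function(id, reactants, products = numeric(0),
                     catalysts = character(0),
                     kinetics = "michaelis_menten", location = "c",
                     invented = FALSE) {
  kinetics <- match.arg(kinetics, KINETICS_KINDS)
  reactants <- unlist(reactants)
  products <- unlist(products)
  if (!length(reactants) || is.null(names(reactants)))
    stop(id, ": reactants must be a named vector")
  if (length(products) && is.null(names(products)))
    stop(id, ": products must be named")
  if (any(c(reactants, products) <= 0))
    stop(id, ": stoichiometric coefficients must be strictly positive")
  if (kinetics == "dilution" &&
      (length(reactants) != 1 || length(products) || length(catalysts)))
    stop(id, ": a dilution reaction has one reactant, no products, no catalysts")
  # a catalyst may coincide with a product (autocatalysis, e.g. DNA
  # catalyzing its own replication) but never with a reactant
  both <- intersect(catalysts, names(reactants))
  if (length(both))
    stop(id, ": catalysts must not be consumed: ",
         paste(both, collapse = ", "))
  structure(list(id = id, reactants = reactants, products = products,
                 catalysts = as.character(catalysts), kinetics = kinetics,
                 location = location, invented = isTRUE(invented)),
            class = "bp_reaction")
}

#' @export
print.bp_reaction <- function(x, ...) {
  cat(x$id, ": ", format_reaction_string(x), "\n", sep = "")
  invisible(x)
}

is_dilution <- function(rxn) rxn$kinetics == "dilution"

#' Element balance of a reaction
#'
#' Residuals (products minus reactants, in atoms per reaction event) for
#' iron and carbon.  Catalysts are excluded.  A balanced reaction returns
#' residuals of magnitude below the stated tolerance; printed model
#' coefficients carry 6-7 significant figures, so the default tolerance is
#' 1e-4 atoms.
#'
#' @param rxn a [reaction()] (non-dilution).
#' @param components component table as built by [component()] rows.
#' @return named vector `c(Fe, C)` of residuals.
#' @export
element_balance <- function(rxn, components) {
  if (is_dilution(rxn)) stop("element balance is not defined for dilution reactions")
  content <- function(names) {
    idx <- match(names, components$name)
    if (anyNA(idx))
      stop(rxn$id, ": unknown component(s): ",
           paste(names[is.na(idx)], collapse = ", "))
    fe <- components$fe_FH[idx] * 1 + components$fe_FO[idx] * 1 +
      components$fe_FF[idx] * 2 + components$fe_F2[idx] * 2 +
      components$fe_F3[idx] * 3 + components$fe_F4[idx] * 4
    cbind(Fe = fe, C = components$carbon[idx])
  }
  r <- content(names(rxn$reactants))
  p <- if (length(rxn$products)) content(names(rxn$products)) else
    matrix(0, 0, 2, dimnames = list(NULL, c("Fe", "C")))
  res <- colSums(p * rxn$products) - colSums(r * rxn$reactants)
  c(Fe = unname(res["Fe"]), C = unname(res["C"]))
}

#' Assemble a reaction network
#'
#' Validates names, compartments and element balance, and auto-generates a
#' dilution reaction `D<name>` for every non-nutrient component that lacks
#' one.  Reactions are stored with all non-dilution reactions first, then
#' dilution reactions in component order, which gives the stoichiometric
#' matrix its (S0 | -D) block structure without permutation bookkeeping.
#'
#' @param components component table (rows from [component()]).
#' @param reactions list of [reaction()]s (dilutions optional).
#' @param morphology a [cell_morphology()].
#' @param balance_tol element-balance tolerance in atoms per event.
#' @param auto_dilution generate missing dilution reactions?
#' @return an object of class `bp_network`.
#' @export
reaction_network <- function(components, reactions, morphology,
                             balance_tol = 1e-4, auto_dilution = TRUE) {
  if (anyDuplicated(components$name))
    stop("duplicate component names: ",
         paste(unique(components$name[duplicated(components$name)]),
               collapse = ", "))
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad_comp <- setdiff(components$compartment, names(morphology$fractions))
  if (length(bad_comp))
    stop("component compartment(s) missing from morphology: ",
         paste(bad_comp, collapse = ", "))
  known <- components$name
  for (rxn in reactions) {
    used <- c(names(rxn$reactants), names(rxn$products), rxn$catalysts)
    missing <- setdiff(used, known)
    if (length(missing))
      stop(rxn$id, ": unknown component(s): ", paste(missing, collapse = ", "))
  }

  non_dil <- Filter(Negate(is_dilution), reactions)
  dil <- Filter(is_dilution, reactions)

  # element balance for every non-dilution reaction
  for (rxn in non_dil) {
    res <- element_balance(rxn, components)
    if (any(abs(res) > balance_tol))
      stop(rxn$id, ": element balance violated (Fe ", format(res["Fe"]),
           ", C ", format(res["C"]), ")")
  }

  internal <- components$name[components$role != "nutrient"]
  dil_targets <- vapply(dil, function(r) names(r$reactants), "")
  if (length(dil_targets) && anyDuplicated(dil_targets))
    stop("component(s) with more than one dilution reaction: ",
         paste(unique(dil_targets[duplicated(dil_targets)]), collapse = ", "))
  extra <- setdiff(dil_targets, internal)
  if (length(extra))
    stop("dilution reactions for nutrient/unknown components: ",
         paste(extra, collapse = ", "))
  if (auto_dilution) {
    for (nm in setdiff(internal, dil_targets)) {
      dil <- c(dil, list(reaction(paste0("D", nm), stats::setNames(1, nm),
                                  kinetics = "dilution",
                                  location = components$compartment[
                                    match(nm, components$name)])))
    }
  }
  # dilutions in component order
  dil_targets <- vapply(dil, function(r) names(r$reactants), "")
  dil <- dil[order(match(dil_targets, components$name))]

  net <- structure(list(components = components,
                        reactions = c(non_dil, dil),
                        morphology = morphology),
                   class = "bp_network")
  net
}

#' @export
print.bp_network <- function(x, ...) {
  nd <- sum(!vapply(x$reactions, is_dilution, TRUE))
  cat("Reaction network:", nrow(x$components), "components (",
      sum(x$components$role == "nutrient"), "nutrients ),",
      length(x$reactions), "reactions (", nd, "non-dilution )\n")
  invisible(x)
}

#' Internal (state) components of a network
#'
#' Components other than nutrients; these are the rows of the
#' stoichiometric matrix and the state variables of the ODE system.
#' @param network a `bp_network`.
#' @return character vector of names.
#' @export
internal_components <- function(network) {
  network$components$name[network$components$role != "nutrient"]
}

network_reaction <- function(network, id) {
  for (r in network$reactions) if (r$id == id) return(r)
  stop("no reaction with id ", id)
}

#' Iron profile table of a network
#'
#' @param network a `bp_network`.
#' @return named list of iron profiles, one per component.
#' @export
network_iron_profiles <- function(network) {
  comp <- network$components
  out <- lapply(seq_len(nrow(comp)), function(i)
    iron_profile(FH = comp$fe_FH[i], FO = comp$fe_FO[i], FF = comp$fe_FF[i],
                 F2 = comp$fe_F2[i], F3 = comp$fe_F3[i], F4 = comp$fe_F4[i]))
  names(out) <- comp$name
  out
}
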