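#' Logistic regulation factor
#'
#' `lf(x) = 2 / (1 + exp(-steepness * (x - 1)))`, a factor in (0, 2) that
#' equals 1 at `x = 1`.  Regulation multiplies a rate by
#' `lf(2 - [C](t)/[C]_ss)`, which is neutral (factor 1) at the reference
#' steady state, damps the rate towards 0 when the sensed component rises
#' above twice its reference, and boosts it towards 2 when the component
#' is depleted.
#'
#' @param x dimensionless argument.
#' @param steepness slope parameter (default 5).
#' @return factor in (0, 2).
#' @export
logistic <- function(x, steepness = 5) {
  2 / (1 + exp(-steepness * (x - 1)))
}

#' Regulation rule
#'
#' @param reaction_id regulated reaction.
#' @param sensed component whose normalized concentration is sensed.
#' @param reference steady-state concentration of the sensed component
#'   (local uM); must be > 0.
#' @param steepness logistic steepness.
#' @return object of class `bp_regulation`.
#' @export
regulation_rule <- function(reaction_id, sensed, reference,
                            steepness = 5) {
  if (reference <= 0) stop("sensed reference must be > 0")
  structure(list(reaction_id = reaction_id, sensed = sensed,
                 reference = reference, steepness = steepness),
            class = "bp_regulation")
}

#' Build a rate law for one reaction
#'
#' Rate-law construction rules:
#' \itemize{
#'   \item \strong{michaelis_menten}: product over substrates of
#'     `[S] / (K_M + [S])` with `K_M` equated to the wild-type local
#'     concentration of the substrate (so each term is 1/2 at reference),
#'     times a first-order normalized factor `[E]/[E]_w` per catalyst,
#'     times `k_rxn`.
#'   \item \strong{mass_action}: `k_rxn` times the product of normalized
#'     first-order substrate factors `[S]/[S]_w`.
#'   \item \strong{transport_ratio}: `k_rxn * ([donor]/[receiver] - 1)`
#'     on local concentrations; may go negative dynamically (net reverse
#'     flow) and is passed through unclamped.
#'   \item \strong{dilution}: `alpha_cell * [C]_local * f_k / f_c`
#'     (cytosol-referenced, so the -f_c/f_k matrix entry reproduces
#'     `d[C]_local/dt = -alpha [C]_local`).
#' }
#'
#' @param rxn a [reaction()].
#' @param U_ss_local named wild-type local concentrations (uM) covering
#'   all substrates and catalysts (nutrients at their medium
#'   concentration).
#' @param morphology the network's [cell_morphology()] (needed for
#'   dilution and compartment referencing).
#' @param component_compartments named map component -> compartment id.
#' @param transport_pair optional `c(donor, receiver)` override; by
#'   default the single reactant is the donor and the single product the
#'   receiver.
#' @return an object of class `bp_ratelaw` with `k` unset (NA).
#' @export
build_rate_law <- function(rxn, U_ss_local, morphology,
                           component_compartments = NULL,
                           transport_pair = NULL) {
  ref_of <- function(nm) {
    v <- U_ss_local[[nm]]
    if (is.null(v) || is.na(v))
      stop(rxn$id, ": no steady-state concentration for ", nm)
    if (v <= 0)
      stop(rxn$id, ": zero reference concentration for ", nm)
    v
  }
  law <- list(id = rxn$id, kind = rxn$kinetics, k = NA_real_,
              substrates = NULL, catalysts = NULL, transport = NULL,
              dilution_scale = NA_real_, target = NA_character_,
              regulation = list())
  if (rxn$kinetics == "dilution") {
    nm <- names(rxn$reactants)
    law$target <- nm
    f <- morphology$fractions
    k_comp <- component_compartments[[nm]]
    law$dilution_scale <- morphology$alpha_cell * f[[k_comp]] / f[["c"]]
  } else if (rxn$kinetics == "transport_ratio") {
    pair <- transport_pair
    if (is.null(pair)) {
      if (length(rxn$reactants) != 1 || length(rxn$products) != 1)
        stop(rxn$id, ": transport law needs a single donor and receiver")
      pair <- c(names(rxn$reactants), names(rxn$products))
    }
    law$transport <- list(donor = pair[[1]], receiver = pair[[2]],
                          ratio_w = ref_of(pair[[1]]) / ref_of(pair[[2]]))
  } else {
    subs <- names(rxn$reactants)
    law$substrates <- data.frame(
      component = subs,
      K_M = vapply(subs, ref_of, numeric(1)),
      ref = vapply(subs, ref_of, numeric(1)),
      stringsAsFactors = FALSE)
    if (length(rxn$catalysts))
      law$catalysts <- data.frame(
        component = rxn$catalysts,
        ref = vapply(rxn$catalysts, ref_of, numeric(1)),
        stringsAsFactors = FALSE)
  }
  structure(law, class = "bp_ratelaw")
}

# evaluate the concentration-dependent part of a law (k = 1), without
# regulation
law_kernel <- function(law, U_local) {
  get_c <- function(nm) {
    v <- U_local[[nm]]
    if (is.null(v)) stop(law$id, ": missing concentration for ", nm)
    v
  }
  switch(law$kind,
    dilution = law$dilution_scale * get_c(law$target),
    transport_ratio = {
      get_c(law$transport$donor) / get_c(law$transport$receiver) - 1
    },
    michaelis_menten = {
      term <- 1
      s <- law$substrates
      for (i in seq_len(NROW(s))) {
        x <- get_c(s$component[i])
        term <- term * x / (s$K_M[i] + x)
      }
      cats <- law$catalysts
      for (i in seq_len(NROW(cats)))
        term <- term * get_c(cats$component[i]) / cats$ref[i]
      term
    },
    mass_action = {
      term <- 1
      s <- law$substrates
      for (i in seq_len(NROW(s)))
        term <- term * get_c(s$component[i]) / s$ref[i]
      term
    },
    stop("unknown law kind ", law$kind))
}

#' Calibrate the rate constant of a law
#'
#' Sets `k_rxn = R_ss / kernel(U_ss)` where the kernel is the law
#' evaluated with `k = 1` at the wild-type state.  For a Michaelis-Menten
#' law with s substrates (each term 1/2 at reference) this gives
#' `k = R_ss * 2^s`; for a transport law, `k = R_ss / (ratio_w - 1)`.
#' A reaction with `R_ss = 0` gets `k = 0` and the law is inert.
#'
#' @param law a `bp_ratelaw`.
#' @param R_ss steady-state rate (>= 0, cytosol-referenced uM/min).
#' @param U_ss_local wild-type local concentrations.
#' @return the law with `k` set.
#' @export
calibrate_rate_constant <- function(law, R_ss, U_ss_local) {
  if (R_ss < 0) stop(law$id, ": steady rate must be >= 0")
  if (law$kind == "dilution") { law$k <- 1; return(law) }
  if (R_ss == 0) { law$k <- 0; return(law) }
  kern <- law_kernel(law, U_ss_local)
  if (abs(kern) < .Machine$double.eps * 100)
    stop(law$id, ": law evaluates to 0 at the reference state; ",
         "cannot calibrate a nonzero rate (transport with unit ",
         "wild-type ratio, or a zero reference)")
  law$k <- R_ss / kern
  law
}

#' Attach regulation rules to a law
#'
#' The rate is multiplied by the product of
#' `lf(2 - [C_i](t)/[C_i]_ss)` over the rules; at the reference state
#' each factor is 1 so calibration is unchanged.
#'
#' @param law a `bp_ratelaw`.
#' @param rules list of [regulation_rule()]s (those targeting other
#'   reactions are ignored).
#' @return the regulated law.
#' @export
apply_regulation <- function(law, rules) {
  mine <- Filter(function(r) r$reaction_id == law$id, rules)
  law$regulation <- c(law$regulation, mine)
  law
}

regulation_factor <- function(law, U_local) {
  fac <- 1
  for (rule in law$regulation) {
    x <- U_local[[rule$sensed]]
    if (is.null(x)) stop(law$id, ": missing sensed component ", rule$sensed)
    fac <- fac * logistic(2 - x / rule$reference, rule$steepness)
  }
  fac
}

#' Evaluate a calibrated rate law
#'
#' @param law a calibrated `bp_ratelaw`.
#' @param U_local named local concentrations (uM), nutrients included.
#' @param t time (min); present for interface symmetry, the laws are
#'   autonomous.
#' @return the reaction rate (uM/min, cytosol-referenced).  Nonnegative
#'   for all kinds except `transport_ratio`, which passes negative net
#'   flow through.
#' @export
evaluate_rate <- function(law, U_local, t = 0) {
  if (is.na(law$k)) stop(law$id, ": rate constant not calibrated")
  law$k * law_kernel(law, U_local) * regulation_factor(law, U_local)
}

#' Build and calibrate rate laws for a whole network
#'
#' @param network a `bp_network`.
#' @param R_ss named steady-state rate vector over all reactions (from
#'   [build_steady_state()]).
#' @param U_ss_local named wild-type local concentrations, nutrients
#'   included.
#' @param regulation list of [regulation_rule()]s.
#' @param k_overrides named numeric vector of rate-constant overrides
#'   (e.g. to reactivate a zero-rate reaction).
#' @return named list of calibrated `bp_ratelaw`s.
#' @export
build_kinetics <- function(network, R_ss, U_ss_local,
                           regulation = list(), k_overrides = numeric(0)) {
  comp_map <- stats::setNames(network$components$compartment,
                              network$components$name)
  laws <- lapply(network$reactions, function(rxn) {
    law <- build_rate_law(rxn, U_ss_local, network$morphology, comp_map)
    law <- calibrate_rate_constant(law, R_ss[[rxn$id]], U_ss_local)
    apply_regulation(law, regulation)
  })
  names(laws) <- vapply(network$reactions, `[[`, "", "id")
  for (id in names(k_overrides)) laws[[id]]$k <- k_overrides[[id]]
  laws
}
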