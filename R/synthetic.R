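#' Specification for a synthetic network
#'
#' @param n_components internal components (>= 2).
#' @param n_nutrients boundary nutrient species feeding the network.
#' @param n_destinations components with no outgoing reactions (pure
#'   sinks fed by conversion chains).
#' @param extra_reactions additional random cross-links beyond the
#'   spanning set of production reactions.
#' @param n_compartments number of compartments used (2-5; cytosol
#'   always included).
#' @param seed integer seed fixing all sampling.
#' @param alpha_cell growth rate (1/min).
#' @return object of class `bp_synthetic_spec`.
#' @export
synthetic_spec <- function(n_components = 8, n_nutrients = 1,
                           n_destinations = 2, extra_reactions = 2,
                           n_compartments = 2, seed = 1,
                           alpha_cell = 0.003333) {
  if (n_components < 2) stop("need at least 2 components")
  if (n_destinations >= n_components)
    stop("more destinations than non-nutrient components")
  if (n_nutrients < 1) stop("need at least 1 nutrient")
  if (n_compartments < 2 || n_compartments > 5)
    stop("n_compartments must be in 2..5 (fractional volumes are strictly below 1)")
  structure(list(n_components = n_components, n_nutrients = n_nutrients,
                 n_destinations = n_destinations,
                 extra_reactions = extra_reactions,
                 n_compartments = n_compartments, seed = seed,
                 alpha_cell = alpha_cell),
            class = "bp_synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic network with a known positive steady state
#'
#' Emulates the structure of the growth-dilution cell models: a
#' compartmentalized, carbon-balanced network of irreversible conversion
#' reactions flowing from nutrient imports to destination components,
#' with one dilution pseudo-reaction per component, so the stoichiometric
#' matrix has the (S0 | -D) form and full row rank.  Reaction rates are
#' built constructively: each component passes at most 70% of its inflow
#' on to downstream reactions and dilutes the rest, so every non-dilution
#' rate and every net production is strictly positive (a strictly
#' positive steady-state rate vector exists by construction).
#' Steady-state concentrations follow from the dilution balance
#' `[C_i] = d_i * f_c / alpha`.  The same seed reproduces the network
#' exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (a `bp_network`), `rates` (the known
#'   strictly positive non-dilution steady rates), `U_ss` (cellular uM)
#'   and `spec`.
#' @export
synthetic_network <- function(spec) {
  with_seed(spec$seed, {
    m <- spec$n_components
    comp_ids <- c("c", "m", "v", "n", "e")[seq_len(spec$n_compartments)]
    # cytosol gets the largest share
    fr <- sort(stats::runif(spec$n_compartments, 0.5, 1.5), decreasing = TRUE)
    fr <- fr / sum(fr)
    names(fr) <- comp_ids
    morph <- cell_morphology(alpha_cell = spec$alpha_cell, fractions = fr)

    nut_names <- sprintf("NUT%02d", seq_len(spec$n_nutrients))
    int_names <- sprintf("X%02d", seq_len(m))
    carbon <- c(stats::setNames(sample(1:5, spec$n_nutrients, TRUE), nut_names),
                stats::setNames(sample(1:20, m, TRUE), int_names))
    compartment <- c(stats::setNames(rep("c", spec$n_nutrients), nut_names),
                     stats::setNames(sample(comp_ids, m, TRUE), int_names))
    n_dest <- spec$n_destinations
    dest <- int_names[seq.int(m - n_dest + 1L, m)]

    rxns <- list()
    add <- function(id, from, to, kinetics = "mass_action") {
      coef <- carbon[[from]] / carbon[[to]]
      rxns[[length(rxns) + 1L]] <<- reaction(
        id, stats::setNames(1, from), stats::setNames(coef, to),
        kinetics = kinetics,
        location = compartment[[to]])
    }
    # imports: each nutrient feeds a random early component
    early <- int_names[seq_len(max(1L, m - n_dest))]
    for (i in seq_len(spec$n_nutrients))
      add(sprintf("IMP%02d", i), nut_names[i],
          early[sample.int(length(early), 1)])
    # spanning production: every component receives from an earlier one
    fed <- unique(vapply(rxns, function(r) names(r$products), ""))
    for (j in seq_len(m)) {
      nm <- int_names[j]
      if (nm %in% fed) next
      src <- if (j == 1) nut_names[sample.int(spec$n_nutrients, 1)] else
        int_names[sample.int(j - 1L, 1)]
      add(sprintf("CNV%02d", length(rxns)), src, nm)
      fed <- c(fed, nm)
    }
    # extra cross-links between non-destination components and anything
    for (e in seq_len(spec$extra_reactions)) {
      from <- sample(setdiff(int_names, dest), 1)
      to <- sample(setdiff(int_names, from), 1)
      add(sprintf("XTR%02d", e), from, to)
    }

    # constructive rates: topological sweep over the acyclic core; any
    # cycle introduced by cross-links is handled by iterating to a fixed
    # point of the 70%-pass-through rule
    ids <- vapply(rxns, `[[`, "", "id")
    inflow <- stats::setNames(rep(0, m), int_names)
    rates <- stats::setNames(rep(0, length(rxns)), ids)
    for (i in seq_along(rxns)) {
      # every nutrient-fed reaction is an import, whatever made it
      if (names(rxns[[i]]$reactants) %in% nut_names)
        rates[i] <- stats::runif(1, 0.5, 2)
    }
    # per-component pass-through shares, fixed before iterating; the
    # fixed-point map is then linear with spectral radius <= 0.7
    shares <- lapply(int_names, function(nm) {
      out <- which(vapply(rxns, function(r)
        names(r$reactants) == nm, TRUE))
      if (!length(out)) return(NULL)
      sh <- stats::runif(length(out), 0.5, 1.5)
      list(out = out, share = 0.7 * sh / sum(sh))
    })
    names(shares) <- int_names
    for (it in seq_len(200)) {
      inflow[] <- 0
      for (i in seq_along(rxns)) {
        pr <- rxns[[i]]$products
        inflow[names(pr)] <- inflow[names(pr)] + pr * rates[i]
      }
      new_rates <- rates
      for (nm in int_names) {
        sh <- shares[[nm]]
        if (is.null(sh)) next
        new_rates[sh$out] <- sh$share * inflow[[nm]]
      }
      if (max(abs(new_rates - rates)) < 1e-13 * max(1, max(rates))) {
        rates <- new_rates; break
      }
      rates <- new_rates
    }
    # final inflow/outflow bookkeeping
    inflow[] <- 0
    outflow <- stats::setNames(rep(0, m), int_names)
    for (i in seq_along(rxns)) {
      pr <- rxns[[i]]$products
      inflow[names(pr)] <- inflow[names(pr)] + pr * rates[i]
      re <- names(rxns[[i]]$reactants)
      if (re %in% int_names)
        outflow[re] <- outflow[re] + rates[i] * rxns[[i]]$reactants
    }
    d <- inflow - outflow
    if (any(d <= 0) || any(rates <= 0))
      stop("synthetic construction failed to keep flows positive")
    conc <- d * fr[["c"]] / spec$alpha_cell

    comps <- do.call(rbind, c(
      lapply(nut_names, function(nm)
        component(nm, "c", "nutrient", 100, carbon[[nm]])),
      lapply(int_names, function(nm)
        component(nm, compartment[[nm]],
                  if (nm %in% dest) "waste" else "metabolite",
                  conc[[nm]], carbon[[nm]]))))
    network <- reaction_network(comps, rxns, morph)
    list(network = network, rates = rates,
         U_ss = stats::setNames(as.numeric(conc), int_names), spec = spec)
  })
}
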