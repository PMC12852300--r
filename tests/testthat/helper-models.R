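# shared fixtures, built once per test run

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

get_fixture_network <- function() cached("net", fixture_core_model)

get_fixture_model <- function(regulated = TRUE) {
  cached(if (regulated) "fx_reg" else "fx_unreg",
         function() fixture_model(regulated = regulated))
}

# two-compartment morphology used by the toy networks
toy_morphology <- function(alpha = 0.01)
  cell_morphology(V_cell = 1e-14, alpha_cell = alpha,
                  fractions = c(c = 0.7, m = 0.3))

# single component fed by an import; x' = k - alpha * x in local units
toy_single_network <- function(x_ss = 10, alpha = 0.01) {
  comps <- rbind(component("NUT", "c", "nutrient", 100, 1),
                 component("X", "c", "metabolite", x_ss * 0.7, 1))
  rxns <- list(reaction("IMP", c(NUT = 1), c(X = 1),
                        kinetics = "mass_action"))
  reaction_network(comps, rxns, toy_morphology(alpha))
}

toy_single_model <- function(x_ss = 10, alpha = 0.01) {
  net <- toy_single_network(x_ss, alpha)
  S <- build_smatrix(net)
  basis <- make_nonnegative_basis(build_null_basis_G(S), S)
  ss <- build_steady_state(net, basis,
                           rate_assignment(dilution_rate_assignment(net)),
                           S = S)
  U_local <- network_local_concentrations(net)
  laws <- build_kinetics(net, ss$R_cell, U_local)
  assemble_system(net, S, laws, U_local["X"], U_local["NUT"])
}

# two-component chain A -> B with both diluted; 4 reactions in all
toy_chain_network <- function() {
  comps <- rbind(component("NUT", "c", "nutrient", 100, 2),
                 component("A", "c", "metabolite", 50, 2),
                 component("B", "m", "metabolite", 20, 2))
  rxns <- list(reaction("IMP", c(NUT = 1), c(A = 1), kinetics = "mass_action"),
               reaction("CNV", c(A = 1), c(B = 1), kinetics = "mass_action",
                        location = "m"))
  reaction_network(comps, rxns, toy_morphology())
}

# mutual autocatalysis: both syntheses catalyzed by both products, so the
# production terms are quadratic in the state and a positive perturbation
# outruns the linear dilution
toy_blowup_model <- function() {
  comps <- rbind(component("NUT", "c", "nutrient", 100, 1),
                 component("A", "c", "metabolite", 7, 1),
                 component("B", "c", "metabolite", 7, 1))
  rxns <- list(
    reaction("BA", c(NUT = 1), c(A = 1), catalysts = c("A", "B")),
    reaction("BB", c(NUT = 1), c(B = 1), catalysts = c("A", "B")))
  net <- reaction_network(comps, rxns, toy_morphology(alpha = 0.1))
  S <- build_smatrix(net)
  basis <- make_nonnegative_basis(build_null_basis_G(S), S)
  ss <- build_steady_state(net, basis,
                           rate_assignment(dilution_rate_assignment(net)),
                           S = S)
  U_local <- network_local_concentrations(net)
  laws <- build_kinetics(net, ss$R_cell, U_local)
  assemble_system(net, S, laws, U_local[c("A", "B")], U_local["NUT"])
}

# brute-force extreme-ray enumeration for small stoichiometric matrices:
# a ray is a sign-definite one-dimensional null space of a column subset,
# kept when its support is minimal
enumerate_extreme_rays <- function(M, tol = 1e-9) {
  n <- ncol(M)
  rays <- list()
  supports <- list()
  for (size in seq_len(n)) {
    for (J in utils::combn(n, size, simplify = FALSE)) {
      # a support containing a known ray's support cannot be minimal
      if (length(supports) &&
          any(vapply(supports, function(s) all(s %in% J), TRUE))) next
      A <- M[, J, drop = FALSE]
      sv <- svd(A, nu = 0, nv = ncol(A))
      rk <- sum(sv$d > tol * max(sv$d, 1))
      if (size - rk != 1L) next
      v <- sv$v[, size]
      if (sum(v) < 0) v <- -v
      if (min(v) < tol * max(v)) next  # not sign-definite on this support
      ray <- numeric(n); ray[J] <- v
      rays[[length(rays) + 1L]] <- ray / max(ray)
      supports[[length(supports) + 1L]] <- J
    }
  }
  rays
}

# is v a nonnegative combination of the columns of B?
in_cone <- function(B, v, tol = 1e-7) {
  cs <- sqrt(colSums(B^2)); cs[cs == 0] <- 1
  fit <- pracma::lsqnonneg(sweep(B, 2, cs, "/"), v)
  sqrt(fit$resid.norm) < tol * max(1, sqrt(sum(v^2)))
}
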