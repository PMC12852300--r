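test_that("the algebraic null basis is (I ; D^-1 S0) and annihilates S", {
  # one component X: import at unit rate forces dilution 1/d
  net <- toy_single_network()
  S <- build_smatrix(net)
  G <- build_null_basis_G(S)
  d <- unname(dilution_diagonal(S))
  expect_equal(dim(G), c(2, 1))
  expect_equal(unname(G[, 1]), c(1, 1 / d))
  expect_lt(max(abs(S$matrix %*% G)), 1e-12)

  net2 <- get_fixture_network()
  S2 <- build_smatrix(net2)
  G2 <- build_null_basis_G(S2)
  expect_equal(dim(G2), c(ncol(S2$matrix), S2$r))
  expect_lt(max(abs(S2$matrix %*% G2)), 1e-10)
})

test_that("the nonnegative basis satisfies its contract on the fixture", {
  fx <- get_fixture_model()
  W <- fx$basis$W
  S <- fx$S
  expect_true(all(W >= 0))
  expect_lt(max(abs(S$matrix %*% W)), 1e-8 * max(1, max(W)))
  expect_equal(qr(sweep(W, 2, apply(W, 2, max), "/"), tol = 1e-10)$rank,
               ncol(W))
  expect_true(all(rowSums(W != 0) >= 1))
  expect_true(all(colSums(W != 0) >= 1))
  # each column of G reconstructs from W (span preservation)
  G <- build_null_basis_G(S)
  cn <- sqrt(colSums(W^2))
  qrW <- qr(sweep(W, 2, cn, "/"), LAPACK = TRUE)
  for (j in seq(1, ncol(G), by = 7)) {
    cf <- qr.coef(qrW, G[, j])
    expect_lt(sqrt(sum((sweep(W, 2, cn, "/") %*% cf - G[, j])^2)),
              1e-6 * max(1, sqrt(sum(G[, j]^2))))
  }
})

test_that("an already-nonnegative basis passes through up to scaling", {
  # two parallel imports: every G column is already a nonnegative
  # import-to-dilution flow
  comps <- rbind(component("NUT", "c", "nutrient", 100, 1),
                 component("A", "c", "metabolite", 50, 1),
                 component("B", "m", "metabolite", 20, 1))
  rxns <- list(reaction("IMPA", c(NUT = 1), c(A = 1), kinetics = "mass_action"),
               reaction("IMPB", c(NUT = 1), c(B = 1), kinetics = "mass_action",
                        location = "m"))
  net <- reaction_network(comps, rxns, toy_morphology())
  S <- build_smatrix(net)
  G <- build_null_basis_G(S)
  expect_true(all(G >= 0))
  basis <- make_nonnegative_basis(G, S)
  for (j in seq_len(ncol(G))) {
    nz <- G[, j] != 0
    ratio <- basis$W[nz, j] / G[nz, j]
    expect_equal(max(ratio), min(ratio))  # same column up to one scalar
    expect_true(all(basis$W[!nz, j] == 0))
  }
})

test_that("basis columns match brute-force extreme rays on small networks", {
  set.seed(21)
  n_checked <- 0
  for (sd in 1:8) {
    g <- synthetic_network(synthetic_spec(
      n_components = 3, n_nutrients = 1, n_destinations = 1,
      extra_reactions = sd %% 2, n_compartments = 2, seed = sd))
    S <- build_smatrix(g$network)
    if (ncol(S$matrix) > 8) next
    basis <- make_nonnegative_basis(build_null_basis_G(S), S)
    rays <- enumerate_extreme_rays(S$matrix)
    expect_gte(length(rays), ncol(basis$W))
    R <- do.call(cbind, rays)
    for (j in seq_len(ncol(basis$W)))
      expect_true(in_cone(R, basis$W[, j]))
    for (k in seq_along(rays))
      expect_true(in_cone(basis$W, rays[[k]]))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 4)
})

test_that("singleton statistics read the sparsity pattern", {
  s_id <- singleton_stats(diag(3))
  expect_equal(s_id$singleton_row_count, 3)
  expect_equal(s_id$deficient_column_count, 0)
  expect_equal(s_id$sparsity, 2 / 3)
  s_ones <- singleton_stats(matrix(1, 3, 3))
  expect_equal(s_ones$singleton_row_count, 0)
  expect_equal(s_ones$deficient_column_count, 3)
  expect_equal(s_ones$singleton_row_rank, 0)
})

test_that("weights solve from singleton rows and the reduced system", {
  # identity basis: weights are the assigned rates themselves
  net <- toy_chain_network()
  S <- build_smatrix(net)
  basis <- make_nonnegative_basis(build_null_basis_G(S), S)
  ind <- select_independent_set(basis)
  R <- compose_rates(basis, c(2, 3))
  cw <- solve_weights(basis, rate_assignment(R[ind]))
  expect_equal(unname(cw), c(2, 3), tolerance = 1e-10)
  # column with singleton row entry 2 and rate 6 gives weight 3
  basis2 <- basis
  basis2$W <- basis$W %*% diag(c(0.5, 1))
  basis2$singleton_rows <- singleton_stats(basis2$W)$singleton_map
  R2 <- compose_rates(basis2, c(3, 1))
  cw2 <- solve_weights(basis2, rate_assignment(R2[ind]))
  expect_equal(unname(cw2), c(3, 1), tolerance = 1e-10)
})

test_that("solve_weights rejects infeasible and underdetermined input", {
  net <- toy_chain_network()
  S <- build_smatrix(net)
  basis <- make_nonnegative_basis(build_null_basis_G(S), S)
  ind <- select_independent_set(basis)
  R <- compose_rates(basis, c(2, 3))
  expect_error(solve_weights(basis, rate_assignment(R[ind][1])), "exactly r")
  mk_basis <- function(W, ids) {
    st <- singleton_stats(W)
    structure(list(W = W, reaction_index = ids,
                   singleton_rows = st$singleton_map,
                   deficient_columns = st$deficient_columns,
                   sparsity = st$sparsity, provenance = "constructed"),
              class = "bp_basis")
  }
  # duplicated independent rows leave a singular reduced system
  Wdup <- matrix(c(1, 1, 1, 1, 1, 0), 3, 2)
  bdup <- mk_basis(Wdup, c("R1", "R2", "R3"))
  expect_error(solve_weights(bdup, rate_assignment(c(R1 = 1, R2 = 2))),
               "insufficient")
  # a singleton weight that forces a negative companion weight
  Wneg <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  bneg <- mk_basis(Wneg, c("R1", "R2", "R3"))
  expect_error(solve_weights(bneg, rate_assignment(c(R2 = 1, R3 = 5))),
               "negative weight")
})

test_that("compose and decompose round-trip and respect the null space", {
  fx <- get_fixture_model()
  basis <- fx$basis; S <- fx$S
  r <- ncol(basis$W)
  expect_equal(unname(compose_rates(basis, rep(0, r))), rep(0, nrow(basis$W)))
  e3 <- replace(rep(0, r), 3, 1)
  expect_equal(unname(compose_rates(basis, e3)), unname(basis$W[, 3]))
  set.seed(31)
  for (i in 1:5) {
    cstar <- runif(r, 0, 2)
    R <- compose_rates(basis, cstar)
    expect_true(all(R >= 0))
    expect_lt(max(abs(S$matrix %*% R)), 1e-8 * max(1, max(R)))
    dec <- decompose_rates(basis, R)
    expect_lt(dec$residual, 1e-8 * max(1, max(R)))
    expect_lt(max(abs(R - compose_rates(basis, pmax(dec$C_BP, 0)))),
              1e-6 * max(1, max(R)))
  }
  dec0 <- decompose_rates(basis, rep(0, nrow(basis$W)))
  expect_equal(unname(dec0$C_BP), rep(0, r))
  expect_error(compose_rates(basis, replace(rep(0, r), 1, -1)), ">= 0")
})

test_that("scaling all assigned rates scales weights and rates linearly", {
  g <- synthetic_network(synthetic_spec(seed = 12))
  S <- build_smatrix(g$network)
  basis <- make_nonnegative_basis(build_null_basis_G(S), S)
  ind <- select_independent_set(basis)
  set.seed(4)
  cstar <- runif(ncol(basis$W), 0.1, 2)
  R <- compose_rates(basis, cstar)
  lambda <- 3.7
  c1 <- solve_weights(basis, rate_assignment(R[ind]))
  c2 <- solve_weights(basis, rate_assignment(lambda * R[ind]))
  expect_equal(unname(c2), unname(lambda * c1), tolerance = 1e-9)
})

test_that("pathways classify into nutrient-to-destination flows and cycles", {
  net <- toy_chain_network()
  S <- build_smatrix(net)
  basis <- make_nonnegative_basis(build_null_basis_G(S), S)
  # the column through CNV runs IMP -> CNV -> dilution of B: a pure
  # import-to-dilution chain with a single destination
  jc <- which(basis$reaction_index == "CNV")
  cl <- classify_pathway(setNames(basis$W[, 2], basis$reaction_index), net)
  expect_false(cl$cyclic)
  expect_equal(cl$nutrients_consumed, "NUT")
  # fixture: a pure futile loop is cyclic
  fx <- get_fixture_model()
  w <- setNames(numeric(nrow(fx$basis$W)), fx$basis$reaction_index)
  w[c("MAAFT", "UAFT")] <- 1
  cl2 <- classify_pathway(w, fx$network)
  expect_true(cl2$cyclic)
  # a biosynthesis pathway consumes nutrients and reaches a destination
  jb <- which(colSums(fx$basis$W[c("BAPOL"), , drop = FALSE] > 0) > 0)[1]
  cl3 <- classify_pathway(jb, fx$network, basis = fx$basis)
  expect_gt(length(cl3$nutrients_consumed), 0)
  expect_gt(length(cl3$destinations) + length(cl3$intermediates_diluted), 0)
})

test_that("the fixture steady state solves with nonnegative weights", {
  fx <- get_fixture_model()
  ss <- fx$steady
  expect_true(all(ss$C_BP >= 0))
  expect_true(all(ss$R_cell >= 0))
  expect_lt(max(abs(fx$S$matrix %*% ss$R_cell)),
            1e-8 * max(1, max(ss$R_cell)))
  expect_lt(max(abs(compose_rates(fx$basis, ss$C_BP) - ss$R_cell)), 1e-8)
  # the iron-replete zero set stays off
  expect_equal(unname(ss$R_cell[c("ACFT5", "UAFT")]), c(0, 0))
  # dilution rates reproduce the assignment exactly
  dil <- dilution_rate_assignment(fx$network)
  expect_lt(max(abs(ss$R_cell[names(dil)] - dil)), 1e-8 * max(1, max(dil)))
})

test_that("all independent rates zero gives the zero steady state", {
  net <- toy_chain_network()
  S <- build_smatrix(net)
  basis <- make_nonnegative_basis(build_null_basis_G(S), S)
  ind <- select_independent_set(basis)
  cw <- solve_weights(basis, rate_assignment(setNames(rep(0, length(ind)), ind)))
  expect_equal(unname(cw), rep(0, ncol(basis$W)))
})
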