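test_that("the logistic factor is neutral at 1 and saturates at 0 and 2", {
  expect_equal(logistic(1), 1)
  expect_equal(logistic(1e6), 2)
  expect_equal(logistic(-1e6), 0)
  # regulation argument at steady state: lf(2 - 1) = 1
  expect_equal(logistic(2 - 1), 1)
  expect_equal(logistic(0), 2 / (1 + exp(5)))
  expect_equal(logistic(2), 2 / (1 + exp(-5)))
})

test_that("rate-law kinds evaluate by their construction rules", {
  morph <- toy_morphology()
  U <- c(A = 10, B = 4, E = 2, X = 5, O2 = 8, O2M = 8)
  cmap <- c(A = "c", B = "c", E = "c", X = "m", O2 = "c", O2M = "m")
  mm <- build_rate_law(
    reaction("R1", c(A = 1, B = 1), c(X = 1), catalysts = "E"),
    U, morph, cmap)
  mm$k <- 1
  # each substrate term is 1/2 at reference, catalyst term 1
  expect_equal(evaluate_rate(mm, U), 0.25)
  expect_equal(evaluate_rate(mm, replace(U, "E", 4)), 0.5)  # linear catalyst
  sat <- replace(U, c("A", "B"), c(1e9, 1e9))
  expect_equal(evaluate_rate(mm, sat), 1, tolerance = 1e-6)
  ma <- build_rate_law(
    reaction("R2", c(A = 1), c(X = 1), kinetics = "mass_action"),
    U, morph, cmap)
  ma$k <- 3
  expect_equal(evaluate_rate(ma, replace(U, "A", 20)), 6)
  tr <- build_rate_law(
    reaction("TO2", c(O2 = 1), c(O2M = 1), kinetics = "transport_ratio"),
    U, morph, cmap)
  tr$k <- 2
  expect_equal(evaluate_rate(tr, U), 0)        # equal concentrations
  expect_equal(evaluate_rate(tr, replace(U, "O2", 16)), 2)
  expect_lt(evaluate_rate(tr, replace(U, "O2", 4)), 0)  # reverse flow passes
  dil <- build_rate_law(
    reaction("DX", c(X = 1), kinetics = "dilution"), U, morph, cmap)
  dil$k <- 1
  expect_equal(evaluate_rate(dil, U),
               morph$alpha_cell * 5 * morph$fractions[["m"]] /
                 morph$fractions[["c"]])
  expect_error(build_rate_law(
    reaction("R3", c(A = 1), c(X = 1)), replace(U, "A", 0), morph, cmap),
    "zero reference")
})

test_that("calibration inverts the kernel: two substrates give k = 4 R_ss", {
  morph <- toy_morphology()
  U <- c(A = 10, B = 4, E = 2, X = 5)
  cmap <- c(A = "c", B = "c", E = "c", X = "c")
  mm <- build_rate_law(
    reaction("R1", c(A = 1, B = 1), c(X = 1), catalysts = "E"),
    U, morph, cmap)
  mm <- calibrate_rate_constant(mm, R_ss = 1, U)
  expect_equal(mm$k, 4)
  # zero substrates, purely catalytic
  cat0 <- build_rate_law(reaction("R4", c(E = 1), c(X = 1),
                                  kinetics = "mass_action"), U, morph, cmap)
  cat0 <- calibrate_rate_constant(cat0, 2.5, U)
  expect_equal(evaluate_rate(cat0, U), 2.5)
  # transport with wild-type ratio 2: k = R_ss / (2 - 1)
  U2 <- c(O2 = 8, O2M = 4)
  tr <- build_rate_law(reaction("T", c(O2 = 1), c(O2M = 1),
                                kinetics = "transport_ratio"),
                       U2, morph, c(O2 = "c", O2M = "m"))
  tr <- calibrate_rate_constant(tr, 3, U2)
  expect_equal(tr$k, 3)
  # transport with unit wild-type ratio cannot carry a nonzero rate
  U3 <- c(O2 = 8, O2M = 8)
  tr3 <- build_rate_law(reaction("T3", c(O2 = 1), c(O2M = 1),
                                 kinetics = "transport_ratio"),
                        U3, morph, c(O2 = "c", O2M = "m"))
  expect_error(calibrate_rate_constant(tr3, 1, U3), "cannot calibrate")
  # zero steady rate gives an inert law
  tr0 <- calibrate_rate_constant(tr3, 0, U3)
  expect_equal(tr0$k, 0)
})

test_that("every calibrated fixture law returns its steady rate at U_ss", {
  fx <- get_fixture_model()
  U_local <- network_local_concentrations(fx$network)
  for (id in names(fx$laws)) {
    r_hat <- evaluate_rate(fx$laws[[id]], U_local)
    expect_equal(r_hat, unname(fx$steady$R_cell[[id]]), tolerance = 1e-10)
  }
})

test_that("calibration scales linearly in the target rate", {
  morph <- toy_morphology()
  U <- c(A = 10, E = 2, X = 5)
  cmap <- c(A = "c", E = "c", X = "c")
  law <- build_rate_law(reaction("R", c(A = 1), c(X = 1), catalysts = "E"),
                        U, morph, cmap)
  k1 <- calibrate_rate_constant(law, 1.3, U)$k
  k2 <- calibrate_rate_constant(law, 3.9, U)$k
  expect_equal(k2, 3 * k1)
})

test_that("Michaelis-Menten rates are nondecreasing in every concentration", {
  morph <- toy_morphology()
  U <- c(A = 10, B = 4, E = 2, X = 5)
  cmap <- c(A = "c", B = "c", E = "c", X = "c")
  law <- build_rate_law(
    reaction("R1", c(A = 1, B = 1), c(X = 1), catalysts = "E"),
    U, morph, cmap)
  law <- calibrate_rate_constant(law, 1, U)
  set.seed(8)
  for (nm in c("A", "B", "E")) {
    vals <- sort(runif(10, 0.01, 100))
    rates <- vapply(vals, function(v)
      evaluate_rate(law, replace(U, nm, v)), numeric(1))
    expect_true(all(diff(rates) >= -1e-12))
  }
})

test_that("regulation multiplies in and is neutral at the reference", {
  morph <- toy_morphology()
  U <- c(A = 10, X = 5, FMx = 3, HEMEx = 1)
  cmap <- c(A = "c", X = "c", FMx = "c", HEMEx = "c")
  law <- build_rate_law(reaction("R", c(A = 1), c(X = 1)), U, morph, cmap)
  law <- calibrate_rate_constant(law, 2, U)
  rules <- list(regulation_rule("R", "FMx", 3), regulation_rule("R", "HEMEx", 1),
                regulation_rule("OTHER", "A", 10))
  reg <- apply_regulation(law, rules)
  expect_equal(length(reg$regulation), 2)  # rules for other reactions ignored
  expect_equal(evaluate_rate(reg, U), 2)   # neutral at reference
  # both sensed components at twice reference: lf(0)^2
  U2 <- replace(U, c("FMx", "HEMEx"), c(6, 2))
  expect_equal(evaluate_rate(reg, U2), 2 * (2 / (1 + exp(5)))^2)
  # sensed component depleted: factor lf(2) = 2/(1+e^-5), up-regulated
  U3 <- replace(U, c("FMx"), 0)
  expect_equal(evaluate_rate(reg, U3), 2 * (2 / (1 + exp(-5))))
  expect_error(regulation_rule("R", "FMx", 0), "> 0")
})

test_that("regulated and unregulated fixtures agree exactly at U_ss", {
  fx_r <- get_fixture_model(TRUE)
  fx_u <- get_fixture_model(FALSE)
  U <- fx_r$model$U_ss
  rhs_r <- cellbp:::model_rhs(fx_r$model, U)
  rhs_u <- cellbp:::model_rhs(fx_u$model, U)
  expect_equal(rhs_r, rhs_u)
})
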