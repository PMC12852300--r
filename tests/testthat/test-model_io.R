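test_that("stoichiometry strings parse with middle-dot, star and arrows", {
  st <- parse_reaction_string("aISU + 7.59143·FM -> ISU")
  expect_equal(st$reactants, c(aISU = 1, FM = 7.59143))
  expect_equal(st$products, c(ISU = 1))
  st2 <- parse_reaction_string("2*AA + 5*ATP → NUCM + 5*ADP")
  expect_equal(st2$reactants, c(AA = 2, ATP = 5))
  expect_equal(st2$products, c(NUCM = 1, ADP = 5))
  st3 <- parse_reaction_string("X ->")
  expect_equal(length(st3$products), 0)
  expect_error(parse_reaction_string("A -> B -> C"), "parse")
})

test_that("format and parse are inverse for the fixture reactions", {
  net <- get_fixture_network()
  for (rxn in net$reactions) {
    if (rxn$kinetics == "dilution") next
    st <- parse_reaction_string(format_reaction_string(rxn))
    expect_equal(st$reactants[sort(names(st$reactants))],
                 rxn$reactants[sort(names(rxn$reactants))])
  }
})

test_that("model bundles round-trip through the canonical directory format", {
  net <- get_fixture_network()
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  write_model(net, d1)
  net2 <- read_model(d1)
  expect_equal(net2$components, net$components)
  expect_equal(length(net2$reactions), length(net$reactions))
  expect_equal(net2$morphology$fractions, net$morphology$fractions)
  write_model(net2, d2)
  for (f in c("components.tsv", "reactions.tsv", "morphology.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("published-format matrices validate dimensions and structure", {
  # synthetic stand-ins with the documented shapes
  set.seed(40)
  m <- 80; n <- 169; r <- n - m
  S0 <- matrix(0, m, n - m)
  for (j in seq_len(r)) S0[sample.int(m, 2), j] <- c(-1, 1)
  Sfull <- cbind(S0, -diag(runif(m, 0.5, 6)))
  dimnames(Sfull) <- list(sprintf("C%03d", 1:m), sprintf("R%03d", 1:n))
  fS <- tempfile(fileext = ".csv")
  write_matrix_csv(Sfull, fS)
  M <- load_si_matrix(fS, "S")
  expect_equal(dim(M), c(80L, 169L))
  Wfake <- matrix(runif(169 * 89), 169, 89)
  dimnames(Wfake) <- list(sprintf("R%03d", 1:169), sprintf("BP%02d", 1:89))
  fW <- tempfile(fileext = ".csv")
  write_matrix_csv(Wfake, fW)
  expect_equal(dim(load_si_matrix(fW, "W")), c(169L, 89L))
  # transposed or negative files are rejected
  fT <- tempfile(fileext = ".csv")
  write_matrix_csv(t(Sfull), fT)
  expect_error(load_si_matrix(fT, "S"), "must be 80 x 169")
  Wneg <- Wfake; Wneg[1, 1] <- -1
  fN <- tempfile(fileext = ".csv")
  write_matrix_csv(Wneg, fN)
  expect_error(load_si_matrix(fN, "W"), "nonnegative")
  # reduced models pass with dims = NULL
  net <- get_fixture_network()
  S <- build_smatrix(net)
  fR <- tempfile(fileext = ".csv")
  write_matrix_csv(S$matrix, fR)
  expect_silent(load_si_matrix(fR, "S", dims = NULL))
})

test_that("the fixture model carries the printed coefficients", {
  net <- get_fixture_network()
  rx <- function(id) {
    for (r in net$reactions) if (r$id == id) return(r)
    NULL
  }
  expect_equal(rx("MAISU")$reactants[["FM"]], 7.59143)
  expect_equal(rx("MAISA")$reactants[["ISU"]], 0.9416092)
  expect_equal(rx("MAISA")$reactants[["NAHM"]], 1.787040)
  expect_equal(rx("ACETC")$products[["ROSM"]], 0.05)
  expect_equal(rx("AATM")$reactants[["aGRX"]], 1.538601)
  expect_equal(rx("MAHEM")$reactants[["FM"]], 7.054408)
  expect_equal(rx("MAAFT")$reactants[["GRX"]], 0.3459033)
  expect_equal(rx("BACAC")$products[["ACAC"]], 0.2)
  expect_equal(rx("BAACIA")$reactants[["AA"]], 4667.9)
  expect_equal(rx("BAACIA")$reactants[["ATP"]], 14003.7)
  expect_equal(rx("MAPOL")$reactants[["CIA"]], 1.6447644)
  expect_equal(rx("MACIA")$reactants[["NAH"]], 4.7078421)
  expect_equal(rx("MALYS")$reactants[["ISA"]], 0.3725193)
  # the iron-sensor group's transient cluster count falls out of the
  # transfer-chain arithmetic
  comp <- net$components
  expect_equal(comp$fe_F2[comp$name == "AFT"], 0.85334, tolerance = 1e-5)
  # every component in exactly one dilution reaction, nutrients in none
  dil_targets <- vapply(Filter(function(r) r$kinetics == "dilution",
                               net$reactions),
                        function(r) names(r$reactants), "")
  expect_setequal(dil_targets, internal_components(net))
})

test_that("synthetic generation is reproducible and structurally sound", {
  g1 <- synthetic_network(synthetic_spec(seed = 5))
  g2 <- synthetic_network(synthetic_spec(seed = 5))
  expect_identical(g1$rates, g2$rates)
  expect_identical(g1$U_ss, g2$U_ss)
  d1 <- file.path(tempdir(), "syn1"); d2 <- file.path(tempdir(), "syn2")
  write_model(g1$network, d1); write_model(g2$network, d2)
  for (f in c("components.tsv", "reactions.tsv", "morphology.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  g3 <- synthetic_network(synthetic_spec(seed = 6))
  expect_false(identical(g1$rates, g3$rates))
  S <- build_smatrix(g1$network)
  v <- validate_structure(S)
  expect_true(v$full_rank)
  expect_equal(v$nullity, S$r)
  expect_true(all(g1$rates > 0))
  expect_true(all(g1$U_ss > 0))
  expect_error(synthetic_spec(n_components = 3, n_destinations = 5),
               "destinations")
})
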