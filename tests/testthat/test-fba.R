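test_that("a 1:1 linear chain converts its full uptake into biomass", {
  ch <- make_linear_chain(3, 10)
  pr <- build_problem(ch$model,
                      scenario("chain", open_exchanges = c(EX_A = 10),
                               biomass = "BIO"))
  sol <- maximize_flux(pr)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-6)
  expect_true(all(sol$fluxes >= pr$lb - 1e-9 & sol$fluxes <= pr$ub + 1e-9))

  # a 2:1 middle step halves the achievable biomass
  ch2 <- make_linear_chain(5, 10, step_coefficient = 2)
  pr2 <- build_problem(ch2$model,
                       scenario("chain", open_exchanges = c(EX_A = 10),
                                biomass = "BIO"))
  expect_equal(maximize_flux(pr2)$objective_value, 5, tolerance = 1e-9)
  expect_equal(ch2$optimum, 5)
})

test_that("with every exchange closed a loop-free network only rests", {
  ch <- make_linear_chain(4, 10)
  pr <- build_problem(ch$model, scenario("closed", biomass = "BIO"))
  sol <- maximize_flux(pr)
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  fva <- flux_variability(pr)
  expect_true(all(abs(fva$min) < 1e-7))
  expect_true(all(abs(fva$max) < 1e-7))
})

test_that("a basis caps the combined uptake of several exchanges", {
  # two substrate pools feeding the same intermediate
  met <- data.frame(id = c("A_e", "B_e", "M_c"),
                    compartment = c("e", "e", "c"))
  rxn <- data.frame(id = c("EX_A", "EX_B", "T_A", "T_B", "BIO"),
                    lower = c(-1000, -1000, 0, 0, 0), upper = 1000,
                    kind = c("exchange", "exchange", "transport",
                             "transport", "biomass"))
  S <- matrix(0, 3, 5, dimnames = list(met$id, rxn$id))
  S["A_e", "EX_A"] <- -1; S["B_e", "EX_B"] <- -1
  S["A_e", "T_A"] <- -1; S["M_c", "T_A"] <- 1
  S["B_e", "T_B"] <- -1; S["M_c", "T_B"] <- 1
  S["M_c", "BIO"] <- -1
  m <- metabolic_model(met, rxn, S, biomass = c(default = "BIO"))

  sc <- scenario("basis", biomass = "BIO",
                 basis = list(exchanges = c("EX_A", "EX_B"), amount = 100))
  sol <- maximize_flux(build_problem(m, sc))
  expect_equal(sol$objective_value, 100, tolerance = 1e-6)
  # uptake really is shared, not per-exchange
  expect_equal(-(sol$fluxes[["EX_A"]] + sol$fluxes[["EX_B"]]), 100,
               tolerance = 1e-6)
})

test_that("scenario configuration errors name the offending id", {
  ch <- make_linear_chain(3, 10)
  expect_error(build_problem(ch$model,
                             scenario("bad", open_exchanges = c(NOPE = 1),
                                      biomass = "BIO")), "NOPE")
  expect_error(build_problem(ch$model,
                             scenario("bad", open_exchanges = c(R1 = 1),
                                      biomass = "BIO")), "non-exchange")
  expect_error(build_problem(ch$model,
                             scenario("bad", biomass = "NOPE")), "NOPE")
})

test_that("knockouts never help, and emptying the network zeroes growth", {
  ch <- make_linear_chain(4, 10)
  pr <- build_problem(ch$model,
                      scenario("chain", open_exchanges = c(EX_A = 10),
                               biomass = "BIO"))
  wt <- maximize_flux(pr)$objective_value
  expect_equal(maximize_flux(apply_knockout(pr, character(0)))$objective_value,
               wt)
  expect_equal(maximize_flux(apply_knockout(pr, "R2"))$objective_value, 0)

  set.seed(21)
  for (s in 1:8) {
    toy <- make_random_toy(sample(4:8, 1), seed = s)
    pr <- toy_problem(toy)
    base <- maximize_flux(pr)$objective_value
    victim <- sample(toy$reactions$id, 2)
    mutant <- maximize_flux(apply_knockout(pr, victim))$objective_value
    expect_lte(mutant, base + 1e-8)
  }
})

test_that("infeasible problems report their status instead of throwing", {
  met <- data.frame(id = "A_c", compartment = "c")
  # forced production with nowhere to go
  rxn <- data.frame(id = c("SRC", "SNK"), lower = c(5, 0), upper = c(10, 0),
                    kind = "metabolic")
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A_c", rxn$id))
  m <- metabolic_model(met, rxn, S)
  sol <- maximize_flux(as_problem(m, "SRC"))
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("the simplex agrees with exhaustive vertex enumeration", {
  for (s in 1:12) {
    toy <- make_random_toy(3 + (s %% 6), seed = 100 + s)
    pr <- toy_problem(toy)
    got <- maximize_flux(pr)
    obj <- as.numeric(toy$reactions$id == attr(toy, "objective"))
    want <- brute_force_fba(toy$stoich, toy$reactions$lower,
                            toy$reactions$upper, obj)
    expect_equal(got$status, want$status)
    expect_equal(got$objective_value, want$objective, tolerance = 1e-6)
  }
})

test_that("cobrapy reproduces the optimum from our written SBML", {
  # independent cross-check through a second implementation: write the
  # light-constrained mini phototroph and a chain, solve both with COBRA
  run_cobra <- function(model, objective) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(model, path)
    py <- sprintf(
      "import warnings; warnings.filterwarnings('ignore')\nimport cobra\nm = cobra.io.read_sbml_model(%s)\nm.objective = %s\nprint('%%.9f' %% m.optimize().objective_value)",
      shQuote(path), shQuote(objective))
    out <- suppressWarnings(
      system2("python", c("-c", shQuote(py)), stdout = TRUE, stderr = NULL))
    as.numeric(out[length(out)])
  }

  pl <- build_problem(mini$model, mini$scenarios$light, mini$diurnal_sets)
  m <- mini$model
  m$reactions$lower <- unname(pl$lb)
  m$reactions$upper <- unname(pl$ub)
  expect_equal(run_cobra(m, "BIO_L"),
               maximize_flux(pl)$objective_value, tolerance = 1e-6)

  ch <- make_linear_chain(4, 7)
  pc <- build_problem(ch$model,
                      scenario("chain", open_exchanges = c(EX_A = 7),
                               biomass = "BIO"))
  mc <- ch$model
  mc$reactions$lower <- unname(pc$lb)
  mc$reactions$upper <- unname(pc$ub)
  expect_equal(run_cobra(mc, "BIO"), 7, tolerance = 1e-6)
})
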