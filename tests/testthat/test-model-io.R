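test_that("model construction enforces the structural invariants", {
  met <- data.frame(id = c("A_c", "B_c"), compartment = "c")
  rxn <- data.frame(id = c("R1", "R1"), lower = 0, upper = 10)
  S <- matrix(c(-1, 1, -1, 1), 2, 2, dimnames = list(met$id, c("R1", "R1")))
  expect_error(metabolic_model(met, rxn, S), "duplicate reaction")

  rxn2 <- data.frame(id = c("R1", "R2"), lower = c(0, 5), upper = c(10, 1))
  colnames(S) <- rxn2$id
  expect_error(metabolic_model(met, rxn2, S), "lower bound exceeds")

  rxn3 <- data.frame(id = c("R1", "R2"), lower = 0, upper = 10)
  S3 <- S; S3[, 2] <- 0
  colnames(S3) <- rxn3$id
  expect_error(metabolic_model(met, rxn3, S3), "empty stoichiometry")

  # infinite bounds are normalised to the big-M convention
  rxn4 <- data.frame(id = c("R1", "R2"), lower = c(-Inf, 0),
                     upper = c(Inf, 10))
  colnames(S) <- rxn4$id
  m <- metabolic_model(met, rxn4, S)
  expect_equal(m$reactions$lower[1], -1000)
  expect_equal(m$reactions$upper[1], 1000)

  # exchange reactions must touch exactly one metabolite
  rxn5 <- data.frame(id = c("R1", "EX"), lower = 0, upper = 10,
                     kind = c("metabolic", "exchange"))
  colnames(S) <- rxn5$id
  expect_error(metabolic_model(met, rxn5, S), "exactly one metabolite")
})

test_that("compare_models partitions ids and is symmetric", {
  a <- make_linear_chain(3)$model
  b <- make_mini_phototroph()$model

  self <- compare_models(a, a)
  expect_length(self$reactions$unique_to_a, 0)
  expect_length(self$reactions$unique_to_b, 0)
  expect_setequal(self$reactions$shared, a$reactions$id)

  ab <- compare_models(a, b)
  ba <- compare_models(b, a)
  expect_identical(ab$reactions$shared, ba$reactions$shared)
  expect_identical(ab$reactions$unique_to_a, ba$reactions$unique_to_b)
  expect_identical(ab$metabolites$unique_to_b, ba$metabolites$unique_to_a)
  # partition identity: |shared| + |unique_to_a| = |reactions of a|
  expect_equal(length(ab$reactions$shared) + length(ab$reactions$unique_to_a),
               nrow(a$reactions))
  # these two fixtures are disjoint by construction
  expect_length(ab$reactions$shared, 0)
  expect_length(ab$metabolites$shared, 0)

  tmp <- withr::local_tempfile()
  paths <- write_comparison(ab, tmp)
  expect_true(all(file.exists(paths)))
  got <- jsonlite::read_json(paths[2])
  expect_equal(length(got$reactions$unique_to_a), nrow(a$reactions))
})

test_that("SBML write/read round-trips every structural field", {
  for (fix in list(make_linear_chain(4, 7), mini)) {
    m <- fix$model
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    m2 <- read_sbml(path)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_identical(m2$metabolites$id, m$metabolites$id)
    expect_equal(m2$stoich, m$stoich)
    expect_equal(m2$reactions$lower, m$reactions$lower)
    expect_equal(m2$reactions$upper, m$reactions$upper)
    expect_identical(m2$reactions$kind, m$reactions$kind)
    expect_identical(vapply(m2$gprs, format_gpr, character(1)),
                     vapply(m$gprs, format_gpr, character(1)))
    expect_identical(m2$metabolites$formula, m$metabolites$formula)
    expect_identical(m2$metabolites$charge, m$metabolites$charge)
    expect_identical(m2$biomass, m$biomass)
    expect_setequal(m2$compartments, m$compartments)
  }
})

test_that("GPR strings with unknown-gene terms survive the round trip", {
  m <- mini$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(format_gpr(m2$gprs$GLYD), "gGd or unknown")
  expect_identical(format_gpr(m2$gprs$OXPP), "gOx1 and gOx2")
  # the unknown leaf still rescues the reaction after re-reading
  expect_true(gpr_is_active(m2$gprs$GLYD, "gGd"))
})

test_that("an empty model writes to a valid minimal document and back", {
  empty <- metabolic_model(
    data.frame(id = character(0), compartment = character(0)),
    data.frame(id = character(0), lower = numeric(0), upper = numeric(0)),
    matrix(0, 0, 0), compartments = "c")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(empty, path)
  m2 <- read_sbml(path)
  expect_equal(nrow(m2$reactions), 0)
  expect_equal(nrow(m2$metabolites), 0)
})

test_that("legacy Level 2 encodings are read: kinetic-law bounds and notes", {
  l2 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="legacy">
  <listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>
  <listOfSpecies>
   <species id="A_e" compartment="e" boundaryCondition="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>FORMULA: C3H4O3</p><p>CHARGE: -1</p></body></notes>
   </species>
   <species id="A_c" compartment="c"/>
   <species id="A_b" compartment="e" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_A" reversible="true">
    <listOfReactants><speciesReference species="A_e"/></listOfReactants>
    <listOfProducts><speciesReference species="A_b"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="-5"/>
      <parameter id="UPPER_BOUND" value="999"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="T_A" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: (g1 and g2) or g3</p></body></notes>
    <listOfReactants><speciesReference species="A_e"/></listOfReactants>
    <listOfProducts><speciesReference species="A_c" stoichiometry="2"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  m <- read_sbml(path)
  # boundary species dropped; EX_A touches only A_e and is an exchange
  expect_false("A_b" %in% m$metabolites$id)
  expect_equal(m$reactions$kind[m$reactions$id == "EX_A"], "exchange")
  expect_equal(m$reactions$lower[m$reactions$id == "EX_A"], -5)
  expect_equal(m$reactions$upper[m$reactions$id == "EX_A"], 999)
  # irreversible reaction without explicit bounds gets [0, big]
  expect_equal(m$reactions$lower[m$reactions$id == "T_A"], 0)
  expect_identical(format_gpr(m$gprs$T_A), "(g1 and g2) or g3")
  expect_identical(m$metabolites$formula[m$metabolites$id == "A_e"],
                   "C3H4O3")
  expect_equal(m$metabolites$charge[m$metabolites$id == "A_e"], -1L)
  expect_equal(m$stoich["A_c", "T_A"], 2)
})

test_that("unreadable or structurally broken SBML raises a useful error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed>", path)
  expect_error(read_sbml(path))
  writeLines('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core">
    <model id="m"><listOfReactions><reaction id="R_empty">
    </reaction></listOfReactions></model></sbml>', path)
  expect_error(read_sbml(path), "R_empty")
})

test_that("tabular import parses equation strings", {
  rx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tgpr",
               "EX_A\tA_e ->\t",
               "T_A\tA_e <-> A_c\t",
               "R1\t2 A_c + B_c -> C_c\tg1 or g2"), rx)
  mt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tcompartment\tformula\tcharge",
               "A_e\tsubstrate\te\tC6H12O6\t0"), mt)
  m <- read_model_table(rx, mt)
  expect_equal(m$stoich["A_c", "R1"], -2)
  expect_equal(m$stoich["C_c", "R1"], 1)
  expect_equal(m$reactions$lower[m$reactions$id == "T_A"], -1000)
  expect_equal(m$reactions$lower[m$reactions$id == "R1"], 0)
  expect_identical(format_gpr(m$gprs$R1), "g1 or g2")
  expect_identical(m$metabolites$formula[m$metabolites$id == "A_e"],
                   "C6H12O6")
  # compartment inferred from the _x suffix when not listed
  expect_equal(m$metabolites$compartment[m$metabolites$id == "B_c"], "c")
})
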