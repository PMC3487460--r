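test_that("the 10% screen recovers the planted essential set exactly", {
  calls <- single_gene_deletions(mini$model, mini$scenarios$light,
                                 diurnal_sets = mini$diurnal_sets)
  expect_setequal(calls$gene, mini$model$genes)
  ng <- calls$gene[calls$in_silico == "NG"]
  expect_setequal(ng, mini$truth$essential_genes_light)

  # independent route: brute-force every knockout with truth-table GPR
  # evaluation and compare growth gene by gene
  pl <- build_problem(mini$model, mini$scenarios$light, mini$diurnal_sets)
  wt <- maximize_flux(pl)$objective_value
  for (g in mini$model$genes) {
    off <- mini$model$reactions$id[!vapply(mini$model$gprs, gpr_is_active,
                                           logical(1), g)]
    mut <- maximize_flux(apply_knockout(pl, off))
    grow <- if (mut$status == "optimal") mut$objective_value else 0
    expect_equal(calls$mutant_growth[calls$gene == g], grow,
                 tolerance = 1e-8)
    expect_identical(calls$in_silico[calls$gene == g],
                     if (grow >= 0.1 * wt) "G" else "NG")
  }
})

test_that("isozyme partners are dispensable one at a time", {
  calls <- single_gene_deletions(mini$model, mini$scenarios$light,
                                 genes = mini$truth$isozyme_pair,
                                 diurnal_sets = mini$diurnal_sets)
  expect_true(all(calls$in_silico == "G"))
  # and both members of the AND complex are individually lethal
  calls2 <- single_gene_deletions(mini$model, mini$scenarios$light,
                                  genes = mini$truth$and_complex,
                                  diurnal_sets = mini$diurnal_sets)
  expect_true(all(calls2$in_silico == "NG"))
})

test_that("raising the threshold never flips NG back to G", {
  thresholds <- c(0.01, 0.1, 0.5, 0.9)
  prev_ng <- character(0)
  for (th in thresholds) {
    calls <- single_gene_deletions(mini$model, mini$scenarios$light,
                                   threshold_fraction = th,
                                   diurnal_sets = mini$diurnal_sets)
    ng <- calls$gene[calls$in_silico == "NG"]
    expect_true(all(prev_ng %in% ng))
    prev_ng <- ng
  }
})

test_that("a gene outside every GPR is growth-neutral", {
  calls <- suppressWarnings(
    single_gene_deletions(mini$model, mini$scenarios$light,
                          genes = "ghost_gene",
                          diurnal_sets = mini$diurnal_sets))
  expect_identical(calls$in_silico, "G")
  expect_equal(calls$mutant_growth, calls$wild_type_growth)
})

test_that("classification and summary follow the four-way definitions", {
  calls <- data.frame(
    gene = paste0("g", 1:5),
    wild_type_growth = 1,
    mutant_growth = c(1, 0, 0, 1, 0.5),
    in_silico = c("G", "NG", "NG", "G", "G"),
    stringsAsFactors = FALSE)
  invivo <- c(g1 = "G", g2 = "NG", g3 = "G", g4 = "NG")
  cl <- classify_essentiality(calls, invivo)
  expect_identical(cl$category,
                   c("GG", "NGNG", "NGG", "GNG", "unclassified"))
  s <- summarize_screen(cl)
  expect_equal(unname(s$counts[c("GG", "GNG", "NGG", "NGNG")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(s$specificity, 1 / 2)
  expect_equal(s$sensitivity, 1 / 2)

  expect_error(classify_essentiality(calls, c(g1 = "G", g1 = "NG")),
               "duplicate")
  expect_error(classify_essentiality(calls, c(g1 = "yes")), "verdicts")
})

test_that("a zero denominator yields an undefined metric, not zero", {
  calls <- data.frame(gene = c("a", "b"), wild_type_growth = 1,
                      mutant_growth = c(0, 0), in_silico = c("NG", "NG"),
                      stringsAsFactors = FALSE)
  cl <- classify_essentiality(calls, c(a = "NG", b = "NG"))
  s <- summarize_screen(cl)
  expect_true(is.na(s$specificity))   # no in vivo viable mutants at all
  expect_equal(s$sensitivity, 1)
})

test_that("random screens summarise to hand-counted ratios", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 20
    calls <- data.frame(
      gene = paste0("g", 1:n), wild_type_growth = 1,
      mutant_growth = stats::runif(n),
      in_silico = sample(c("G", "NG"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    invivo <- stats::setNames(sample(c("G", "NG"), n, replace = TRUE),
                              calls$gene)
    s <- summarize_screen(classify_essentiality(calls, invivo))
    gg <- sum(calls$in_silico == "G" & invivo == "G")
    ngg <- sum(calls$in_silico == "NG" & invivo == "G")
    ngng <- sum(calls$in_silico == "NG" & invivo == "NG")
    gng <- sum(calls$in_silico == "G" & invivo == "NG")
    expect_equal(s$specificity, gg / (gg + ngg))
    expect_equal(s$sensitivity, ngng / (ngng + gng))
  }
})

test_that("viability tables drop incompletely segregated mutants", {
  path <- system.file("extdata", "synthetic_mini_phototroph_viability.tsv",
                      package = "cyanoflux")
  invivo <- read_viability_table(path)
  expect_length(invivo, 10)            # the incomplete gNif row is gone
  expect_identical(unname(invivo["gNif"]), "G")
  expect_identical(unname(invivo["gCfx"]), "NG")
})
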