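test_that("formula parsing handles multi-letter elements and repeats", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6),
               ignore_attr = TRUE)
  f <- parse_formula("Fe2S2H")
  expect_equal(f[["Fe"]], 2)
  expect_equal(f[["H"]], 1)
  expect_null(parse_formula(NA))
  expect_error(parse_formula("C6H12-"), "unparseable")
})

test_that("balance linting flags exactly what is wrong", {
  # 2 H + O -> H2O, correct formulas
  met <- data.frame(id = c("H_c", "O_c", "H2O_c"), compartment = "c",
                    formula = c("H", "O", "H2O"), charge = c(0, 0, 0))
  rxn <- data.frame(id = "W", lower = 0, upper = 10, kind = "metabolic")
  S <- matrix(c(-2, -1, 1), 3, 1, dimnames = list(met$id, "W"))
  m <- metabolic_model(met, rxn, S)
  rep <- check_balance(m)
  expect_identical(rep$status, "balanced")

  # perturbing the product charge by +1 shows up as charge imbalance +1
  met$charge[3] <- 1
  rep2 <- check_balance(metabolic_model(met, rxn, S))
  expect_identical(rep2$status, "imbalanced")
  expect_equal(rep2$charge_imbalance, 1)
  expect_identical(rep2$element_imbalance, "")

  # unparseable formulas are skipped with a reason, never passed silently
  met$formula[1] <- "not/a/formula"
  rep3 <- check_balance(metabolic_model(met, rxn, S))
  expect_identical(rep3$status, "skipped")
  expect_match(rep3$reason, "unparseable")
})

test_that("exchange and biomass reactions are skipped by design", {
  rep <- check_balance(mini$model)
  kinds <- mini$model$reactions$kind
  expect_true(all(rep$status[kinds == "exchange"] == "skipped"))
  expect_true(all(rep$status[kinds == "biomass"] == "skipped"))
  expect_false(any(rep$status == "imbalanced"))
})

test_that("planted hydrogen imbalances are recovered exactly", {
  for (s in 1:10) {
    ch <- make_linear_chain(4 + (s %% 3), 10)
    planted <- plant_defect(ch$model, "imbalance", seed = s)
    rep <- check_balance(planted$model)
    flagged <- rep$reaction_id[rep$status == "imbalanced"]
    expect_identical(flagged, planted$truth$imbalanced)
    expect_match(rep$element_imbalance[rep$status == "imbalanced"], "H:")
  }
})

test_that("dead ends and their dependents are blocked; clean chains are not", {
  ch <- make_linear_chain(4, 10)
  expect_length(find_blocked_metabolites(ch$model), 0)

  # a produced-but-never-consumed side metabolite is a classic dead end
  m <- ch$model
  met <- rbind(m$metabolites,
               data.frame(id = "X_c", name = "X_c", compartment = "c",
                          formula = NA, charge = NA))
  rxn <- rbind(m$reactions,
               data.frame(id = "SIDE", name = "SIDE", lower = 0,
                          upper = 1000, gpr = "", kind = "metabolic"))
  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  S[rownames(m$stoich), colnames(m$stoich)] <- m$stoich
  S["M1_c", "SIDE"] <- -1; S["X_c", "SIDE"] <- 1
  m2 <- metabolic_model(met, rxn, S, biomass = m$biomass)
  expect_identical(find_blocked_metabolites(m2), "X_c")
})

test_that("severing a pathway step blocks the whole linear pathway", {
  # deleting the sole consumer of any chain intermediate stops all
  # steady-state flux: everything upstream loses its consumer chain and
  # everything downstream loses its producer, so every metabolite blocks
  for (s in 1:6) {
    ch <- make_linear_chain(4 + (s %% 3), 10)
    planted <- plant_defect(ch$model, "gap", seed = s)
    blocked <- find_blocked_metabolites(planted$model)
    expect_setequal(blocked, planted$model$metabolites$id)
    expect_true(planted$truth$orphaned %in% blocked)
  }
})

test_that("a branch gap blocks only the branch", {
  ch <- make_linear_chain(3, 10)
  m <- ch$model
  met <- rbind(m$metabolites,
               data.frame(id = c("X_c", "B_e"), name = c("X_c", "B_e"),
                          compartment = c("c", "e"), formula = NA,
                          charge = NA))
  rxn <- rbind(m$reactions,
               data.frame(id = c("RB1", "TB", "EX_B"),
                          name = c("RB1", "TB", "EX_B"),
                          lower = 0, upper = 1000, gpr = "",
                          kind = c("metabolic", "transport", "exchange")))
  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  S[rownames(m$stoich), colnames(m$stoich)] <- m$stoich
  S["M1_c", "RB1"] <- -1; S["X_c", "RB1"] <- 1
  S["X_c", "TB"] <- -1; S["B_e", "TB"] <- 1
  S["B_e", "EX_B"] <- -1
  branched <- metabolic_model(met, rxn, S, biomass = m$biomass)
  expect_length(find_blocked_metabolites(branched), 0)

  # drop the sole consumer of the branch intermediate: only X_c blocks
  # (B_e keeps its secreting exchange but loses all production, so it
  # blocks too — derived by hand from the topology)
  keep <- setdiff(branched$reactions$id, "TB")
  cut <- metabolic_model(met, rxn[rxn$id %in% keep, ],
                         S[, keep], biomass = m$biomass)
  expect_setequal(find_blocked_metabolites(cut), c("X_c", "B_e"))
})

test_that("gap-fill proposals are minimal and actually unblock the target", {
  ch <- make_linear_chain(4, 10)
  planted <- plant_defect(ch$model, "gap", seed = 7)
  target <- planted$truth$orphaned
  props <- propose_gapfill(planted$model, ch$model, target)
  expect_length(props, 1)
  expect_identical(props[[1]], planted$truth$deleted)
  # applying the proposal removes the target from the blocked set
  healed <- cyanoflux:::add_reactions_from(planted$model, ch$model,
                                           props[[1]])
  expect_false(target %in% find_blocked_metabolites(healed))

  # an already-producible target needs nothing
  expect_length(propose_gapfill(ch$model, mini$model, "M1_c"), 0)

  # no solution within the size limit: empty list, message logged
  # (the phototroph pool shares no metabolites with the chain, so no
  # single addition can reconnect the orphan)
  expect_message(
    none <- propose_gapfill(planted$model, mini$model, target,
                            max_additions = 1),
    "no gap-fill")
  expect_length(none, 0)
})

test_that("planted two-reaction cycles are found and grouped", {
  for (s in 1:8) {
    ch <- make_linear_chain(4 + (s %% 3), 10)
    expect_length(detect_infeasible_loops(ch$model)$members, 0)
    planted <- plant_defect(ch$model, "loop", seed = s)
    rep <- detect_infeasible_loops(planted$model)
    expect_setequal(rep$members, planted$truth$loop)
    expect_length(rep$groups, 1)
    # the witness is a genuine internal cycle: S v = 0, v != 0,
    # zero exchange flux
    w <- rep$witnesses[[1]]
    expect_lt(max(abs(planted$model$stoich %*% w)), 1e-6)
    expect_gt(max(abs(w)), 1e-6)
    ex <- planted$model$reactions$id[
      planted$model$reactions$kind == "exchange"]
    expect_true(all(abs(w[ex]) < 1e-9))
  }
})

test_that("making one duplicate irreversible resolves the cycle", {
  ch <- make_linear_chain(4, 10)
  planted <- plant_defect(ch$model, "loop", seed = 2)
  m <- planted$model
  dup <- grep("_revdup$", planted$truth$loop, value = TRUE)
  # restrict the duplicate's direction (the suggested repair) and re-run
  m$reactions$upper[m$reactions$id == dup] <- 0
  expect_length(detect_infeasible_loops(m)$members, 0)
})

test_that("the loop report is invariant under scaling all bounds", {
  planted <- plant_defect(make_linear_chain(5, 10)$model, "loop", seed = 4)
  base <- detect_infeasible_loops(planted$model)
  scaled <- planted$model
  scaled$reactions$lower <- scaled$reactions$lower * 7
  scaled$reactions$upper <- scaled$reactions$upper * 7
  rep <- detect_infeasible_loops(scaled)
  expect_identical(rep$members, base$members)
})

test_that("loop-forming proposals are rejected, fresh exchanges accepted", {
  ch <- make_linear_chain(4, 10)
  planted <- plant_defect(ch$model, "gap", seed = 7)
  target <- planted$truth$orphaned

  # pool: the honest repair, a reverse duplicate (cycle bait), and an
  # exchange on the orphaned metabolite
  pool_met <- planted$model$metabolites
  honest <- ch$model$reactions[ch$model$reactions$id ==
                                 planted$truth$deleted, , drop = FALSE]
  revdup_src <- planted$model$reactions$id[
    planted$model$reactions$kind == "metabolic"][1]
  j <- match(revdup_src, planted$model$reactions$id)
  pool_rxn <- rbind(
    honest,
    data.frame(id = "BAIT", name = "BAIT", lower = 0, upper = 1000,
               gpr = "", kind = "metabolic"),
    data.frame(id = "EX_new", name = "EX_new", lower = 0, upper = 1000,
               gpr = "", kind = "exchange"))
  S <- matrix(0, nrow(pool_met), 3,
              dimnames = list(pool_met$id, pool_rxn$id))
  S[rownames(ch$model$stoich), 1] <-
    ch$model$stoich[, planted$truth$deleted]
  S[, "BAIT"] <- -planted$model$stoich[, j]
  S[target, "EX_new"] <- -1
  pool <- metabolic_model(pool_met, pool_rxn, S)

  verdict <- filter_proposals_by_loops(
    planted$model, list(planted$truth$deleted, "BAIT", "EX_new"), pool)
  expect_identical(verdict$accepted,
                   list(planted$truth$deleted, "EX_new"))
  expect_identical(verdict$rejected, list("BAIT"))
})
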