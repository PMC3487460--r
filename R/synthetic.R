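# Synthetic networks with known ground truth. Everything the pipeline can
# do — FBA/FVA, diurnal phases, knockouts, balance linting, gap and loop
# detection — is exercisable on these fixtures with no external files.

# run `code` under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Linear-chain toy model with a known optimum
#'
#' `A_e -> M1_c -> ... -> Mk_c -> biomass`, all coefficients 1, so the
#' maximum biomass flux equals the uptake bound. Metabolites carry the
#' one-carbon formula `CH2O` so the chain is fully balance-checkable.
#'
#' @param length number of internal metabolites (>= 2).
#' @param uptake uptake bound on the substrate exchange.
#' @param step_coefficient substrate coefficient of the middle chain step
#'   (`step_coefficient` units in, one unit out), so the analytic optimum
#'   is `uptake / step_coefficient`.
#' @return list(model, optimum) where `optimum` is the analytic maximum
#'   biomass flux.
#' @export
make_linear_chain <- function(length = 3, uptake = 10,
                              step_coefficient = 1) {
  stopifnot(length >= 2, step_coefficient > 0)
  mids <- paste0("M", seq_len(length), "_c")
  # a non-unit step makes the 1:1 carbon bookkeeping wrong, so formulas
  # are only attached when every step conserves the one-carbon unit
  met <- data.frame(id = c("A_e", mids),
                    compartment = c("e", rep("c", length)),
                    formula = if (step_coefficient == 1) "CH2O"
                              else NA_character_,
                    charge = if (step_coefficient == 1) 0L else NA_integer_,
                    stringsAsFactors = FALSE)
  rids <- c("EX_A", "T_A", paste0("R", seq_len(length - 1)), "BIO")
  rxn <- data.frame(id = rids,
                    lower = c(-uptake, rep(0, length + 1)),
                    upper = 1000,
                    kind = c("exchange", "transport",
                             rep("metabolic", length - 1), "biomass"),
                    gpr = "", stringsAsFactors = FALSE)
  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  S["A_e", "EX_A"] <- -1
  S["A_e", "T_A"] <- -1; S[mids[1], "T_A"] <- 1
  mid_step <- max(1L, (length - 1L) %/% 2L)
  for (i in seq_len(length - 1)) {
    S[mids[i], paste0("R", i)] <- if (i == mid_step) -step_coefficient else -1
    S[mids[i + 1], paste0("R", i)] <- 1
  }
  S[mids[length], "BIO"] <- -1
  model <- metabolic_model(met, rxn, S, biomass = c(default = "BIO"),
                           id = sprintf("chain%d", length))
  list(model = model, optimum = uptake / step_coefficient)
}

#' Mini phototroph fixture with diurnal ground truth
#'
#' A ~20-reaction cyanobacterium in miniature: photon, CO2, O2, water,
#' glycogen and H2 exchanges; light reactions producing ATP; an
#' NADPH-producing oxidative route; carbon fixation into a one-carbon
#' unit `fc_c` (CH2O); glycogen synthesis/degradation; respiration; a
#' nitrogenase-style H2 reaction with an ATP cost; and separate light and
#' dark biomass equations. GPRs plant one essential carbon-fixation gene,
#' an essential transport gene, a two-gene AND complex (both essential),
#' an isozyme OR pair (individually dispensable) and an `unknown`-gene OR
#' rescue.
#'
#' Topology is fixed; `seed` is accepted for interface symmetry with the
#' random generators and does not alter the model. The returned ground
#' truth holds analytic optima derived by hand from the stoichiometry:
#' light biomass `U/10` at CO2 uptake `U`; carbon fixation at least `35 b`
#' at biomass `b`; dark biomass `8 G / 19` at glycogen uptake `G`;
#' subjective-dark H2 `9 G` (3 NADPH per carbon oxidised, 2 NADPH per H2);
#' and the planted essential gene set for the light condition.
#'
#' @param seed unused; present for generator-interface symmetry.
#' @param co2_uptake,glycogen_uptake scenario uptake bounds `U` and `G`.
#' @return list(model, scenarios, diurnal_sets, truth).
#' @export
make_mini_phototroph <- function(seed = 1, co2_uptake = 10,
                                 glycogen_uptake = 5) {
  met <- data.frame(
    id = c("photon_e", "co2_e", "o2_e", "h2o_e", "h2_e", "glyc_e",
           "photon_c", "co2_c", "o2_c", "h2o_c", "h2_c", "glyc_c",
           "fc_c", "atp_c", "nadph_c"),
    compartment = c(rep("e", 6), rep("c", 9)),
    formula = c(NA, "CO2", "O2", "H2O", "H2", "C6H12O6",
                NA, "CO2", "O2", "H2O", "H2", "C6H12O6",
                "CH2O", NA, NA),
    charge = c(NA, 0, 0, 0, 0, 0, NA, 0, 0, 0, 0, 0, 0, NA, NA),
    stringsAsFactors = FALSE)

  rxn <- data.frame(
    id = c("EX_photon", "EX_co2", "EX_o2", "EX_h2o", "EX_h2", "EX_glyc",
           "PHOTt", "CO2t", "O2t", "H2Ot", "H2t", "GLYCt",
           "LIGHT", "CFX", "OXPP", "RESP", "GLYS", "GLYD", "NIT",
           "BIO_L", "BIO_D"),
    lower = c(-1000, -1000, -1000, -1000, 0, -1000,
              0, -1000, -1000, -1000, 0, 0,
              0, 0, 0, 0, 0, 0, 0, 0, 0),
    upper = c(0, 1000, 1000, 1000, 1000, 1000,
              1000, 1000, 1000, 1000, 1000, 1000,
              1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000),
    kind = c(rep("exchange", 6), rep("transport", 6),
             rep("metabolic", 7), "biomass", "biomass"),
    gpr = c(rep("", 6),
            "", "gCt", "", "", "", "gGt",
            "", "gCfx", "gOx1 and gOx2", "gResp", "gGs1 or gGs2",
            "gGd or unknown", "gNif", "", ""),
    stringsAsFactors = FALSE)

  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  ex <- function(m, r) S[m, r] <<- -1
  ex("photon_e", "EX_photon"); ex("co2_e", "EX_co2"); ex("o2_e", "EX_o2")
  ex("h2o_e", "EX_h2o"); ex("h2_e", "EX_h2"); ex("glyc_e", "EX_glyc")
  tr <- function(a, b, r) { S[a, r] <<- -1; S[b, r] <<- 1 }
  tr("photon_e", "photon_c", "PHOTt")
  tr("co2_e", "co2_c", "CO2t")
  tr("o2_e", "o2_c", "O2t")
  tr("h2o_e", "h2o_c", "H2Ot")
  tr("h2_c", "h2_e", "H2t")
  tr("glyc_e", "glyc_c", "GLYCt")
  # photophosphorylation: photons -> ATP (energy only; no mass)
  S[c("photon_c", "atp_c"), "LIGHT"] <- c(-1, 2)
  # carbon fixation: CO2 + 2 NADPH + 3 ATP -> CH2O unit
  S[c("co2_c", "nadph_c", "atp_c", "fc_c"), "CFX"] <- c(-1, -2, -3, 1)
  # oxidative pentose-phosphate-style NADPH source
  S[c("fc_c", "o2_c", "co2_c", "h2o_c", "nadph_c"), "OXPP"] <-
    c(-1, -1, 1, 1, 3)
  # respiration: CH2O + O2 -> CO2 + H2O + 4 ATP
  S[c("fc_c", "o2_c", "co2_c", "h2o_c", "atp_c"), "RESP"] <-
    c(-1, -1, 1, 1, 4)
  S[c("fc_c", "atp_c", "glyc_c"), "GLYS"] <- c(-6, -1, 1)
  S[c("glyc_c", "fc_c"), "GLYD"] <- c(-1, 6)
  # nitrogenase-style H2 evolution with ATP cost
  S[c("atp_c", "nadph_c", "h2_c"), "NIT"] <- c(-4, -2, 1)
  S[c("fc_c", "atp_c", "nadph_c"), "BIO_L"] <- c(-10, -20, -5)
  S[c("fc_c", "atp_c"), "BIO_D"] <- c(-8, -25)

  model <- metabolic_model(met, rxn, S,
                           biomass = c(light = "BIO_L", dark = "BIO_D"),
                           id = "mini_phototroph")

  diurnal_sets <- list(storage_uptake = "GLYCt",
                       co2_uptake = "CO2t",
                       light = c("PHOTt", "LIGHT"),
                       carbon_fixation = "CFX")
  scenarios <- list(
    light = scenario("photoautotrophic-light",
                     open_exchanges = c(EX_photon = 1000,
                                        EX_co2 = co2_uptake,
                                        EX_o2 = 1000, EX_h2o = 1000),
                     biomass = "BIO_L", phase = "light"),
    dark = scenario("dark-heterotrophic",
                    open_exchanges = c(EX_glyc = glycogen_uptake,
                                       EX_o2 = 1000, EX_h2o = 1000),
                    biomass = "BIO_D", phase = "dark"),
    subjective_dark = scenario("subjective-dark",
                               open_exchanges = c(EX_photon = 1000,
                                                  EX_glyc = glycogen_uptake,
                                                  EX_o2 = 1000,
                                                  EX_h2o = 1000),
                               biomass = "BIO_D",
                               phase = "subjective-dark"))
  truth <- list(
    light_biomass_max = co2_uptake / 10,
    light_yield_per_co2 = 1 / 10,
    min_carbon_fixed_per_biomass = 35,
    dark_biomass_max = 8 * glycogen_uptake / 19,
    h2_max_subjective_dark = 9 * glycogen_uptake,
    h2_yield_per_glycogen = 9,
    essential_genes_light = c("gCfx", "gCt", "gOx1", "gOx2"),
    isozyme_pair = c("gGs1", "gGs2"),
    and_complex = c("gOx1", "gOx2"),
    unknown_rescued_gene = "gGd")

  list(model = model, scenarios = scenarios, diurnal_sets = diurnal_sets,
       truth = truth)
}

#' Random small flux network (for oracle cross-checks)
#'
#' Generates a feasible bounded network of at most 8 reactions: one uptake
#' and one secretion exchange plus random internal reactions over a small
#' metabolite set, coefficients in 1..2, a random subset of reactions
#' reversible. The zero flux vector is always feasible, so maximisation
#' problems are never infeasible; optima are checked against the
#' brute-force enumeration oracle.
#'
#' @param n_reactions total reaction count (3..8).
#' @param seed integer seed; the same seed reproduces the model bit for
#'   bit.
#' @return A `metabolic_model` with a `"objective"` attribute naming a
#'   random objective reaction.
#' @export
make_random_toy <- function(n_reactions = 6, seed = 1) {
  stopifnot(n_reactions >= 3, n_reactions <= 8)
  with_local_seed(seed, {
    n_int <- n_reactions - 2L
    n_met <- max(2L, n_int)
    mids <- paste0("X", seq_len(n_met), "_c")
    met <- data.frame(id = mids, compartment = "c",
                      formula = NA_character_, charge = NA_integer_,
                      stringsAsFactors = FALSE)
    rids <- c("EX_in", "EX_out", paste0("R", seq_len(n_int)))
    S <- matrix(0, n_met, n_reactions, dimnames = list(mids, rids))
    S[1, "EX_in"] <- -1
    S[n_met, "EX_out"] <- -1
    for (j in seq_len(n_int)) {
      k <- if (n_met >= 3) sample(2:3, 1) else 2L
      mets <- sample(n_met, k)
      coef <- sample(1:2, k, replace = TRUE)
      sgn <- c(-1, 1, sample(c(-1, 1), k - 2, replace = TRUE))
      S[mets, paste0("R", j)] <- coef * sgn
    }
    rev_int <- stats::runif(n_int) < 0.4
    rxn <- data.frame(
      id = rids,
      lower = c(-10, 0, ifelse(rev_int, -10, 0)),
      upper = c(0, 10, rep(10, n_int)),
      kind = c("exchange", "exchange", rep("metabolic", n_int)),
      gpr = "", stringsAsFactors = FALSE)
    model <- metabolic_model(met, rxn, S, id = sprintf("toy_s%d", seed))
    attr(model, "objective") <- sample(rids, 1)
    model
  })
}

#' Plant a known defect into a model
#'
#' * `"loop"` — adds a reversed duplicate of a random internal reaction,
#'   creating a two-reaction thermodynamically infeasible cycle; truth
#'   records the pair.
#' * `"gap"` — deletes the sole consumer of a random eligible internal
#'   metabolite, orphaning it; truth records the orphaned metabolite and
#'   the deleted reaction.
#' * `"imbalance"` — adds one hydrogen to the formula of a random
#'   metabolite that participates in exactly one balance-checkable
#'   reaction, so exactly that reaction becomes elementally imbalanced;
#'   truth records the reaction.
#'
#' @param model a `metabolic_model` without the defect at the insertion
#'   site.
#' @param kind `"loop"`, `"gap"` or `"imbalance"`.
#' @param seed integer seed selecting the site.
#' @return list(model, truth) where `truth` names the affected ids.
#' @export
plant_defect <- function(model, kind = c("loop", "gap", "imbalance"),
                         seed = 1) {
  kind <- match.arg(kind)
  with_local_seed(seed, switch(kind,
    loop = plant_loop(model),
    gap = plant_gap(model),
    imbalance = plant_imbalance(model)))
}

plant_loop <- function(model) {
  internal <- which(!model$reactions$kind %in% c("exchange", "biomass"))
  if (!length(internal)) stop("no eligible site for a loop")
  j <- sample(internal, 1)
  orig <- model$reactions$id[j]
  dup <- paste0(orig, "_revdup")
  rxn <- model$reactions[j, , drop = FALSE]
  rxn$id <- dup
  rxn$name <- dup
  rxn$lower <- 0; rxn$upper <- model$big
  met <- model$metabolites
  reactions <- rbind(model$reactions, rxn)
  S <- cbind(model$stoich, -model$stoich[, j])
  colnames(S)[ncol(S)] <- dup
  m2 <- metabolic_model(met, reactions, S, biomass = model$biomass,
                        compartments = model$compartments,
                        id = model$id, big = model$big)
  list(model = m2, truth = list(loop = sort(c(orig, dup))))
}

plant_gap <- function(model) {
  S <- model$stoich
  consumers <- lapply(seq_len(nrow(S)), function(i)
    which(S[i, ] < 0 & model$reactions$kind != "exchange"))
  producers <- vapply(seq_len(nrow(S)), function(i)
    sum(S[i, ] > 0), integer(1))
  eligible <- which(lengths(consumers) == 1 & producers >= 1 &
                      model$metabolites$compartment != "e")
  if (!length(eligible)) stop("no eligible site for a gap")
  i <- if (length(eligible) == 1) eligible else sample(eligible, 1)
  victim <- model$reactions$id[consumers[[i]]]
  keep <- setdiff(model$reactions$id, victim)
  m2 <- metabolic_model(model$metabolites,
                        model$reactions[model$reactions$id %in% keep, ,
                                        drop = FALSE],
                        S[, keep, drop = FALSE],
                        biomass = model$biomass[
                          model$biomass %in% keep],
                        compartments = model$compartments,
                        id = model$id, big = model$big)
  list(model = m2, truth = list(orphaned = model$metabolites$id[i],
                                deleted = victim))
}

plant_imbalance <- function(model) {
  bal <- check_balance(model)
  checkable <- bal$reaction_id[bal$status == "balanced"]
  S <- model$stoich
  in_checkable <- vapply(seq_len(nrow(S)), function(i)
    sum(S[i, checkable, drop = FALSE] != 0), integer(1))
  eligible <- which(in_checkable == 1 & !is.na(model$metabolites$formula))
  if (!length(eligible)) stop("no eligible site for an imbalance")
  i <- if (length(eligible) == 1) eligible else sample(eligible, 1)
  target_rxn <- checkable[colSums(
    S[i, checkable, drop = FALSE] != 0) > 0]
  f <- parse_formula(model$metabolites$formula[i])
  f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0) + 1
  model$metabolites$formula[i] <-
    paste0(names(f), ifelse(f == 1, "", f), collapse = "")
  list(model = model,
       truth = list(imbalanced = target_rxn,
                    metabolite = model$metabolites$id[i]))
}
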