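#' Define a growth scenario
#'
#' A scenario names a growth condition: which exchange reactions are open
#' for uptake (and to what extent), an optional shared substrate basis
#' (e.g. 100 mmol of CO2 plus bicarbonate, constrained jointly), the
#' biomass reaction for the condition, a diurnal phase, and any regulatory
#' shutdown list (reactions forced to zero under the condition, e.g.
#' dark-phase inactivated enzymes or the aerobic cyclase restriction).
#'
#' @param label free-text condition label (`"photoautotrophic"`, `"light"`,
#'   `"dark"`, ...).
#' @param open_exchanges named numeric vector: exchange reaction id ->
#'   maximum uptake (positive number; uptake is the negative flux
#'   direction of an exchange).
#' @param biomass biomass reaction id for this condition.
#' @param objective reaction id to optimise; defaults to `biomass`.
#' @param basis optional `list(exchanges = <ids>, amount = <total uptake>)`
#'   constraining the combined uptake of several exchanges (the
#'   "100 mmol CO2 + H2CO3" style basis).
#' @param phase one of `"none"`, `"light"`, `"dark"`, `"subjective-dark"`.
#' @param shutdown reaction ids fixed to zero flux under this condition.
#' @return A `scenario` object.
#' @export
scenario <- function(label, open_exchanges = numeric(), biomass = NULL,
                     objective = biomass, basis = NULL,
                     phase = c("none", "light", "dark", "subjective-dark"),
                     shutdown = character()) {
  phase <- match.arg(phase)
  if (!is.null(basis)) {
    stopifnot(is.list(basis), !is.null(basis$exchanges),
              is.numeric(basis$amount), basis$amount >= 0)
  }
  structure(list(label = label, open_exchanges = open_exchanges,
                 biomass = biomass, objective = objective, basis = basis,
                 phase = phase, shutdown = shutdown),
            class = "scenario")
}

#' Build the steady-state flux problem for a model under a scenario
#'
#' Produces one mass-balance equality per metabolite and one bounded flux
#' variable per reaction. All exchange reactions are closed to uptake
#' (secretion stays open), then the scenario's listed exchanges are opened
#' to their stated uptake bounds; shutdown reactions are pinned to zero; a
#' basis adds a joint uptake cap over its exchanges; a diurnal phase applies
#' the light/dark regulatory constraints via [apply_diurnal()].
#'
#' @param model a `metabolic_model`.
#' @param scen a [scenario()].
#' @param diurnal_sets diurnal reaction sets (see [apply_diurnal()]);
#'   required when `scen$phase != "none"`.
#' @return A `flux_problem`.
#' @export
build_problem <- function(model, scen, diurnal_sets = NULL) {
  validate_model(model)
  rid <- model$reactions$id
  lb <- stats::setNames(model$reactions$lower, rid)
  ub <- stats::setNames(model$reactions$upper, rid)

  is_ex <- model$reactions$kind == "exchange"
  lb[is_ex] <- pmax(lb[is_ex], 0)            # uptake closed by default

  if (length(scen$open_exchanges)) {
    idx <- rxn_index(model, names(scen$open_exchanges), "exchange")
    not_ex <- !is_ex[idx]
    if (any(not_ex))
      stop("open_exchanges names non-exchange reaction(s): ",
           paste(names(scen$open_exchanges)[not_ex], collapse = ", "))
    lb[idx] <- -abs(unname(scen$open_exchanges))
  }
  if (length(scen$shutdown)) {
    idx <- rxn_index(model, scen$shutdown, "shutdown")
    lb[idx] <- 0; ub[idx] <- 0
  }

  extra <- NULL
  if (!is.null(scen$basis)) {
    idx <- rxn_index(model, scen$basis$exchanges, "basis exchange")
    lb[idx] <- pmin(lb[idx], -scen$basis$amount)
    row <- stats::setNames(numeric(length(rid)), rid)
    row[idx] <- -1                             # total uptake = -sum(v)
    extra <- list(A = matrix(row, nrow = 1, dimnames = list(NULL, rid)),
                  rhs = scen$basis$amount, dir = "<=")
  }
  objective <- scen$objective
  if (!is.null(objective)) rxn_index(model, objective, "objective")
  if (!is.null(scen$biomass)) rxn_index(model, scen$biomass, "biomass")

  prob <- structure(list(model = model, lb = lb, ub = ub, extra = extra,
                         objective = objective, scenario = scen),
                    class = "flux_problem")
  if (scen$phase != "none") {
    if (is.null(diurnal_sets))
      stop("scenario has phase '", scen$phase,
           "' but no diurnal_sets were supplied")
    prob <- apply_diurnal(prob, scen$phase, diurnal_sets)
  }
  prob
}

#' Wrap a model as a flux problem with its bounds as stored
#'
#' Unlike [build_problem()], no exchange is closed and no scenario
#' constraint is applied: the problem is the model verbatim. Useful for
#' raw networks whose bounds already encode the condition of interest.
#'
#' @param model a `metabolic_model`.
#' @param objective optional objective reaction id.
#' @return A `flux_problem`.
#' @export
as_problem <- function(model, objective = NULL) {
  validate_model(model)
  if (!is.null(objective)) rxn_index(model, objective, "objective")
  structure(list(model = model,
                 lb = stats::setNames(model$reactions$lower,
                                      model$reactions$id),
                 ub = stats::setNames(model$reactions$upper,
                                      model$reactions$id),
                 extra = NULL, objective = objective,
                 scenario = scenario("as-is")),
            class = "flux_problem")
}

#' Apply diurnal (light/dark) regulatory constraints
#'
#' The reaction sets follow the convention that every listed transport is
#' written with uptake as its positive direction. In the light phase the
#' organism photosynthesises and stores carbon, so uptake of stored carbon
#' (glycogen/glycerol transport) is forced to zero while light and
#' carbon-fixation reactions stay unconstrained. In the dark phase the
#' light reactions and carbon fixation are forced to zero and CO2 uptake
#' is disabled (flux clamped <= 0, release still allowed) while stored
#' carbon may be consumed. `"subjective-dark"` applies the dark constraints
#' but leaves the light reactions active (stored glycogen as the carbon
#' source while light energy is still harvested).
#'
#' @param problem a `flux_problem`.
#' @param phase `"light"`, `"dark"` or `"subjective-dark"`.
#' @param sets list with character elements `storage_uptake` (glycogen /
#'   glycerol uptake transports), `co2_uptake` (CO2 uptake transports),
#'   `light` (photon-driven reactions) and `carbon_fixation`.
#' @return The constrained `flux_problem`.
#' @export
apply_diurnal <- function(problem, phase = c("light", "dark",
                                             "subjective-dark"), sets) {
  phase <- match.arg(phase)
  model <- problem$model
  for (nm in c("storage_uptake", "co2_uptake", "light", "carbon_fixation"))
    if (length(sets[[nm]])) rxn_index(model, sets[[nm]], nm)

  clamp_zero <- function(ids) {
    problem$lb[ids] <<- 0
    problem$ub[ids] <<- 0
  }
  forbid_positive <- function(ids) {        # uptake-positive convention
    problem$ub[ids] <<- pmin(problem$ub[ids], 0)
    problem$lb[ids] <<- pmin(problem$lb[ids], problem$ub[ids])
  }

  if (phase == "light") {
    forbid_positive(sets$storage_uptake)
  } else {
    clamp_zero(sets$carbon_fixation)
    forbid_positive(sets$co2_uptake)
    if (phase == "dark") clamp_zero(sets$light)
  }
  problem
}

#' Disable a set of reactions (gene-knockout constraint)
#'
#' Pins the bounds of every listed reaction to `[0, 0]`, the linear
#' constraint representing loss of the catalysing gene product(s). Compose
#' with [reactions_disabled_by()] to go from knocked genes to reactions.
#'
#' @param problem a `flux_problem`.
#' @param disabled reaction ids to pin to zero.
#' @return The constrained `flux_problem`.
#' @export
apply_knockout <- function(problem, disabled) {
  if (length(disabled)) {
    rxn_index(problem$model, disabled, "knockout")
    problem$lb[disabled] <- 0
    problem$ub[disabled] <- 0
  }
  problem
}

# internal: solve the problem for an arbitrary objective vector
problem_solve <- function(problem, obj, maximize = TRUE) {
  solve_lp(obj, problem$model$stoich, problem$lb, problem$ub,
           extra = problem$extra, maximize = maximize)
}

obj_vector <- function(problem, objective) {
  rid <- problem$model$reactions$id
  j <- rxn_index(problem$model, objective, "objective")
  obj <- numeric(length(rid))
  obj[j] <- 1
  obj
}

#' Maximise an objective flux (flux balance analysis)
#'
#' Solves the steady-state LP and returns one optimal vertex solution.
#' Because alternate optima are ubiquitous in genome-scale models the
#' returned flux vector is *a* solution, never *the* solution; use
#' [flux_variability()] for statements about individual reactions.
#'
#' @param problem a `flux_problem`.
#' @param objective reaction id to maximise; defaults to the problem's
#'   scenario objective.
#' @return A `flux_distribution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"maxiter"`), `objective_value`, `fluxes` (named
#'   vector) and `residual` (the steady-state infinity-norm residual).
#' @export
maximize_flux <- function(problem, objective = NULL) {
  objective <- objective %||% problem$objective
  if (is.null(objective)) stop("no objective reaction given")
  res <- problem_solve(problem, obj_vector(problem, objective))
  dist <- structure(list(status = res$status,
                         objective = objective,
                         objective_value = res$objective,
                         fluxes = res$fluxes,
                         residual = NA_real_),
                    class = "flux_distribution")
  if (res$status == "optimal") {
    dist$residual <- max(abs(problem$model$stoich %*% res$fluxes))
    if (dist$residual > 1e-6)
      warning("steady-state residual ", format(dist$residual),
              " exceeds 1e-6")
  }
  dist
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status: ", x$status, sep = "")
  if (x$status == "optimal")
    cat("  ", x$objective, " = ", format(x$objective_value),
        "  (|S v|_inf = ", format(x$residual), ")", sep = "")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve the biomass floor; errors name the floor and achievable maximum
resolve_floor <- function(problem, biomass_floor, floor_fraction) {
  objective <- problem$objective
  if (is.null(objective))
    stop("flux variability needs a problem objective to floor")
  wt <- maximize_flux(problem, objective)
  if (wt$status != "optimal")
    stop("problem is ", wt$status, "; cannot establish a biomass floor")
  opt <- wt$objective_value
  floor <- if (is.null(biomass_floor)) floor_fraction * opt else biomass_floor
  if (floor > opt + 1e-6)
    stop("biomass floor ", format(floor),
         " is infeasible; achievable maximum is ", format(opt))
  floor
}

#' Flux variability analysis under a biomass floor
#'
#' For each requested reaction, minimises and maximises its flux over the
#' steady-state region with the objective (biomass) flux held at or above
#' a floor. The floor defaults to `floor_fraction` (default 1, i.e. 100%)
#' of the problem optimum, matching the max-biomass convention used for
#' comparing predicted ranges against carbon-labelling flux measurements.
#'
#' @param problem a `flux_problem` with an objective.
#' @param reactions reaction ids to scan; default all.
#' @param biomass_floor explicit floor value (overrides `floor_fraction`).
#' @param floor_fraction fraction of the optimum used as floor.
#' @param witnesses if `TRUE`, attach the optimal flux vectors achieving
#'   each extreme as attribute `"witnesses"` (used by loop detection).
#' @return data.frame with columns `reaction_id`, `min`, `max`, `floor`.
#' @export
flux_variability <- function(problem, reactions = NULL, biomass_floor = NULL,
                             floor_fraction = 1, witnesses = FALSE) {
  model <- problem$model
  reactions <- reactions %||% model$reactions$id
  rxn_index(model, reactions)
  floor <- resolve_floor(problem, biomass_floor, floor_fraction)
  # a floor is just a tightened lower bound on the objective flux
  problem$lb[problem$objective] <-
    max(problem$lb[problem$objective], floor - 1e-9 * max(1, abs(floor)))

  wit <- if (witnesses) vector("list", 2L * length(reactions))
  vmin <- vmax <- numeric(length(reactions))
  for (i in seq_along(reactions)) {
    obj <- obj_vector(problem, reactions[i])
    lo <- problem_solve(problem, obj, maximize = FALSE)
    hi <- problem_solve(problem, obj, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for ", reactions[i], " returned ",
           lo$status, "/", hi$status)
    vmin[i] <- lo$objective; vmax[i] <- hi$objective
    if (witnesses) {
      wit[[2L * i - 1L]] <- lo$fluxes
      wit[[2L * i]] <- hi$fluxes
    }
  }
  out <- data.frame(reaction_id = reactions, min = vmin, max = vmax,
                    floor = floor, stringsAsFactors = FALSE)
  if (witnesses) attr(out, "witnesses") <- wit
  out
}

#' Flux variability after pinning reactions to measured ranges
#'
#' Tightens the bounds of the pinned reactions to the supplied intervals
#' (intersected with the existing bounds) and re-runs
#' [flux_variability()] on the target reactions — the operation used to
#' test whether experimentally measured ranges (e.g. for transaldolase)
#' collapse the predicted ranges of neighbouring reactions.
#'
#' @param problem a `flux_problem` with an objective.
#' @param pin named list of `c(lo, hi)` intervals keyed by reaction id.
#' @param targets reaction ids to scan.
#' @inheritParams flux_variability
#' @return As [flux_variability()].
#' @export
restricted_fva <- function(problem, pin, targets, biomass_floor = NULL,
                           floor_fraction = 1) {
  for (id in names(pin)) {
    rxn_index(problem$model, id, "pinned")
    iv <- pin[[id]]
    problem$lb[id] <- max(problem$lb[id], iv[1])
    problem$ub[id] <- min(problem$ub[id], iv[2])
    if (problem$lb[id] > problem$ub[id])
      stop("pinning ", id, " to [", iv[1], ", ", iv[2],
           "] empties its bound interval")
  }
  flux_variability(problem, targets, biomass_floor, floor_fraction)
}

#' Maximum theoretical product yield under a scenario
#'
#' Maximises the product flux — after fixing biomass at its scenario
#' optimum when `fix_biomass = TRUE` ("under maximum biomass production")
#' — and divides by the basis consumption. The denominator is, in order of
#' preference: the flux of `denominator` (e.g. the RuBisCO carboxylation
#' reaction for "per mole carbon fixed" yields), else the total uptake
#' through the scenario's basis exchanges, else the total uptake through
#' the scenario's open exchanges.
#'
#' @param model a `metabolic_model`.
#' @param scen a [scenario()].
#' @param product reaction id whose flux is the product output.
#' @param denominator optional reaction id measured at the product optimum
#'   whose (absolute) flux is the yield denominator.
#' @param fix_biomass fix biomass at its maximum before maximising product?
#' @param diurnal_sets passed to [build_problem()].
#' @return Yield as a numeric scalar (mole product / mole basis), with
#'   attributes `product_flux`, `denominator_flux` and — when the product
#'   is unreachable — `diagnostic`, naming the first blocked precursor of
#'   the product reaction.
#' @export
compute_yield <- function(model, scen, product, denominator = NULL,
                          fix_biomass = TRUE, diurnal_sets = NULL) {
  problem <- build_problem(model, scen, diurnal_sets)
  rxn_index(model, product, "product")
  if (fix_biomass) {
    if (is.null(scen$biomass))
      stop("fix_biomass = TRUE but the scenario has no biomass reaction")
    wt <- maximize_flux(problem, scen$biomass)
    if (wt$status != "optimal")
      stop("wild-type problem is ", wt$status, " under scenario '",
           scen$label, "'")
    opt <- wt$objective_value
    problem$lb[scen$biomass] <- max(problem$lb[scen$biomass],
                                    opt - 1e-9 * max(1, abs(opt)))
  }
  best <- maximize_flux(problem, product)
  if (best$status != "optimal")
    stop("product optimisation is ", best$status)
  p <- best$objective_value

  if (p <= 1e-9) {
    diag <- first_blocked_precursor(model, problem, product)
    out <- 0
    attr(out, "product_flux") <- 0
    attr(out, "denominator_flux") <- NA_real_
    attr(out, "diagnostic") <- diag
    return(out)
  }

  den <- if (!is.null(denominator)) {
    abs(best$fluxes[[denominator]])
  } else if (!is.null(scen$basis)) {
    sum(pmax(-best$fluxes[scen$basis$exchanges], 0))
  } else if (length(scen$open_exchanges)) {
    sum(pmax(-best$fluxes[names(scen$open_exchanges)], 0))
  } else stop("no denominator: supply `denominator` or a scenario basis")
  if (den <= 1e-9)
    stop("yield denominator is zero at the product optimum")

  out <- p / den
  attr(out, "product_flux") <- p
  attr(out, "denominator_flux") <- den
  out
}

# name the first substrate of `product` that cannot be produced at steady
# state under the problem's constraints (diagnostic for zero yields)
first_blocked_precursor <- function(model, problem, product) {
  col <- model$stoich[, product]
  substrates <- rownames(model$stoich)[col < 0]
  for (m in substrates) {
    if (metabolite_max_drain(model, problem, m) <= 1e-9)
      return(m)
  }
  NA_character_
}

# maximum steady-state production (drain) of one metabolite
metabolite_max_drain <- function(model, problem, met) {
  i <- met_index(model, met)
  S2 <- cbind(model$stoich, drain = 0)
  S2[i, ncol(S2)] <- -1
  colnames(S2)[ncol(S2)] <- ".drain"
  extra <- problem$extra
  if (!is.null(extra)) extra$A <- cbind(extra$A, 0)
  obj <- c(numeric(ncol(model$stoich)), 1)
  res <- solve_lp(obj, S2, c(problem$lb, 0), c(problem$ub, model$big),
                  extra = extra, maximize = TRUE)
  if (res$status != "optimal") 0 else res$objective
}
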