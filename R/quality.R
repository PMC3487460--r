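# Model quality control: elemental/charge balance linting, blocked
# metabolites, gap-fill proposals, and thermodynamically infeasible loops.

#' Parse a Hill-style chemical formula
#'
#' `"C6H12O6"` -> `c(C = 6, H = 12, O = 6)`. Two-letter elements
#' (`Fe`, `Mg`, ...) and repeated elements (counts summed) are handled.
#'
#' @param formula formula string; `NA`/`""` return `NULL`.
#' @return Named numeric vector of element counts, or `NULL`.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("unparseable formula: '", formula, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", parts))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

#' Elemental and charge balance report
#'
#' For every metabolic and transport reaction whose participants all have
#' a parseable formula and a charge, computes the per-element and charge
#' net imbalance (sum of coefficient x count). Exchange, demand-style and
#' biomass reactions are skipped by design (they are net producers or
#' consumers by construction), as are reactions touching metabolites with
#' unknown formula or charge — skips are reported with their reason, never
#' silently passed.
#'
#' @param model a `metabolic_model`.
#' @return data.frame with columns `reaction_id`, `status` (`"balanced"`,
#'   `"imbalanced"`, `"skipped"`), `reason`, `element_imbalance` (compact
#'   `"H:+1"` style summary) and `charge_imbalance`.
#' @export
check_balance <- function(model) {
  if (!nrow(model$reactions))
    return(data.frame(reaction_id = character(0), status = character(0),
                      reason = character(0),
                      element_imbalance = character(0),
                      charge_imbalance = numeric(0),
                      stringsAsFactors = FALSE))
  S <- model$stoich
  met <- model$metabolites
  formulas <- lapply(met$formula, function(f)
    tryCatch(parse_formula(f), error = function(e) NA))
  unparseable <- vapply(formulas, function(x)
    length(x) == 1 && is.na(x[1]) && !is.null(x), logical(1))
  has_formula <- !vapply(formulas, is.null, logical(1)) & !unparseable
  has_charge <- !is.na(met$charge)

  rows <- lapply(seq_len(nrow(model$reactions)), function(j) {
    rid <- model$reactions$id[j]
    kind <- model$reactions$kind[j]
    out <- data.frame(reaction_id = rid, status = "balanced", reason = "",
                      element_imbalance = "", charge_imbalance = 0,
                      stringsAsFactors = FALSE)
    if (kind %in% c("exchange", "biomass")) {
      out$status <- "skipped"; out$reason <- paste0(kind, " reaction")
      out$charge_imbalance <- NA_real_
      return(out)
    }
    part <- which(S[, j] != 0)
    if (any(unparseable[part])) {
      out$status <- "skipped"
      out$reason <- paste0("unparseable formula: ",
                           paste(met$id[part][unparseable[part]],
                                 collapse = ", "))
      out$charge_imbalance <- NA_real_
      return(out)
    }
    if (any(!has_formula[part]) || any(!has_charge[part])) {
      unk <- part[!has_formula[part] | !has_charge[part]]
      out$status <- "skipped"
      out$reason <- paste0("unknown formula/charge: ",
                           paste(met$id[unk], collapse = ", "))
      out$charge_imbalance <- NA_real_
      return(out)
    }
    net <- numeric(0)
    for (i in part) {
      f <- formulas[[i]]
      for (e in names(f)) net[e] <- (net[e] %||na% 0) + S[i, j] * f[[e]]
    }
    net <- net[abs(net) > 1e-9]
    qnet <- sum(S[part, j] * met$charge[part])
    if (length(net) || abs(qnet) > 1e-9) {
      out$status <- "imbalanced"
      out$element_imbalance <- paste(sprintf("%s:%+g", names(net), net),
                                     collapse = ",")
      out$charge_imbalance <- qnet
    }
    out
  })
  do.call(rbind, rows)
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Detect blocked metabolites
#'
#' A metabolite is blocked when no steady-state flux distribution under
#' the scenario's exchanges produces it through any incident reaction: for
#' every reaction consuming or creating it, the flux range over the
#' steady-state region (computed by plain LP, no integer variables) never
#' runs in the producing direction. This recovers the same blocked set as
#' the classic binary-variable connectivity formulation: a dead-end with
#' producers but no consumers is blocked because mass balance forces its
#' producers to zero, and anything exclusively downstream of a blocked
#' metabolite is blocked in turn.
#'
#' @param model a `metabolic_model`.
#' @param scen optional [scenario()]; by default every exchange is opened
#'   to uptake at the model's big-M (the most permissive condition, so
#'   anything blocked here is structurally blocked).
#' @param tol production below this is considered zero.
#' @return Character vector of blocked metabolite ids.
#' @export
find_blocked_metabolites <- function(model, scen = NULL, tol = 1e-6) {
  if (is.null(scen)) {
    ex <- model$reactions$id[model$reactions$kind == "exchange"]
    scen <- scenario("all-open",
                     open_exchanges = stats::setNames(
                       rep(model$big, length(ex)), ex))
  }
  problem <- build_problem(model, scen)
  rid <- model$reactions$id
  vmax <- vmin <- stats::setNames(numeric(length(rid)), rid)
  for (j in seq_along(rid)) {
    obj <- numeric(length(rid)); obj[j] <- 1
    hi <- problem_solve(problem, obj, maximize = TRUE)
    lo <- problem_solve(problem, obj, maximize = FALSE)
    vmax[j] <- if (hi$status == "optimal") hi$objective else 0
    vmin[j] <- if (lo$status == "optimal") lo$objective else 0
  }
  S <- model$stoich
  producible <- vapply(seq_len(nrow(S)), function(i) {
    any(S[i, ] > 0 & vmax > tol) || any(S[i, ] < 0 & vmin < -tol)
  }, logical(1))
  model$metabolites$id[!producible]
}

#' Propose minimal gap-filling reaction additions
#'
#' Searches the user-supplied universal reaction pool for
#' minimal-cardinality addition sets that make the target metabolite
#' producible, by iterative deepening over subset size (1, then 2, ...
#' up to `max_additions`). All minimal sets are returned, ordered
#' lexicographically by reaction id. Literature corroboration of a
#' proposal — the decisive step in curation — is out of scope here; pair
#' with [filter_proposals_by_loops()] to discard proposals that create
#' thermodynamically infeasible cycles.
#'
#' @param model a `metabolic_model` in which `target` is blocked.
#' @param universal a `metabolic_model` acting as the candidate pool
#'   (e.g. the union of two related reconstructions); only reactions
#'   absent from `model` are candidates.
#' @param target blocked metabolite id.
#' @param max_additions largest addition-set size to consider.
#' @param scen optional scenario, as in [find_blocked_metabolites()].
#' @return List of character vectors (reaction ids from the pool); empty
#'   when no solution exists within `max_additions`.
#' @export
propose_gapfill <- function(model, universal, target, max_additions = 2,
                            scen = NULL) {
  met_index(model, target)
  candidates <- sort(setdiff(universal$reactions$id, model$reactions$id))
  if (target %in% find_blocked_metabolites(model, scen)) {
    for (size in seq_len(max_additions)) {
      sets <- utils::combn(candidates, size, simplify = FALSE)
      hits <- Filter(function(s) {
        m2 <- add_reactions_from(model, universal, s)
        !(target %in% find_blocked_metabolites(m2, scen))
      }, sets)
      if (length(hits)) return(hits)
    }
    message("no gap-fill for '", target, "' within ", max_additions,
            " additions from a pool of ", length(candidates))
    return(list())
  }
  list()    # already producible: nothing to add
}

# graft reactions (and any new metabolites they use) from `pool` into `model`
add_reactions_from <- function(model, pool, rxn_ids) {
  jdx <- rxn_index(pool, rxn_ids, "pool reaction")
  sub <- pool$stoich[, jdx, drop = FALSE]
  used <- rownames(sub)[rowSums(abs(sub)) > 0]
  new_mets <- setdiff(used, model$metabolites$id)
  met <- rbind(model$metabolites,
               pool$metabolites[match(new_mets, pool$metabolites$id), ,
                                drop = FALSE])
  rxn <- rbind(model$reactions, pool$reactions[jdx, , drop = FALSE])
  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  if (nrow(model$stoich))
    S[rownames(model$stoich), colnames(model$stoich)] <- model$stoich
  S[used, rxn_ids] <- sub[used, , drop = FALSE]
  metabolic_model(met, rxn, S, biomass = model$biomass,
                  compartments = union(model$compartments,
                                       pool$compartments),
                  id = model$id, big = model$big)
}

#' Detect thermodynamically infeasible loops
#'
#' Closes every exchange reaction and runs flux variability over the
#' internal reactions. Any internal reaction still able to carry flux at
#' the big-M scale sustains a cycle with zero net exchange — flux that
#' would be unbounded were the bounds not capped. Members are grouped by
#' the shared support of the witness flux vectors (each witness satisfies
#' `S v = 0`, `v != 0`, zero exchange flux).
#'
#' @param model a `metabolic_model`.
#' @param threshold_fraction fraction of the model's largest bound
#'   magnitude above which a flux is considered "at the big-M scale"
#'   (default 0.5).
#' @return A `loop_report`: list with `members` (flagged reaction ids),
#'   `groups` (list of id vectors) and `witnesses` (one flux vector per
#'   group).
#' @export
detect_infeasible_loops <- function(model, threshold_fraction = 0.5) {
  is_ex <- model$reactions$kind == "exchange"
  internal <- model$reactions$id[!is_ex]
  empty <- structure(list(members = character(0), groups = list(),
                          witnesses = list()), class = "loop_report")
  if (!length(internal)) return(empty)

  closed <- model
  closed$reactions$lower[is_ex] <- 0
  closed$reactions$upper[is_ex] <- 0
  bigM <- max(abs(c(closed$reactions$lower[!is_ex],
                    closed$reactions$upper[!is_ex])), 1e-12)
  thr <- threshold_fraction * bigM

  prob <- structure(list(
    model = closed,
    lb = stats::setNames(closed$reactions$lower, closed$reactions$id),
    ub = stats::setNames(closed$reactions$upper, closed$reactions$id),
    extra = NULL, objective = NULL,
    scenario = scenario("closed")), class = "flux_problem")

  members <- character(0)
  wits <- list()
  for (id in internal) {
    obj <- obj_vector(prob, id)
    hi <- problem_solve(prob, obj, maximize = TRUE)
    lo <- problem_solve(prob, obj, maximize = FALSE)
    if (hi$status == "optimal" && hi$objective > thr) {
      members <- c(members, id); wits <- c(wits, list(hi$fluxes))
    } else if (lo$status == "optimal" && lo$objective < -thr) {
      members <- c(members, id); wits <- c(wits, list(lo$fluxes))
    }
  }
  if (!length(members)) return(empty)

  # union-find over shared witness support
  parent <- stats::setNames(members, members)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (w in wits) {
    supp <- intersect(names(w)[abs(w) > 1e-6], members)
    if (length(supp) > 1)
      for (s in supp[-1]) parent[[find(s)]] <- find(supp[1])
  }
  roots <- vapply(members, find, character(1))
  groups <- split(members, roots)
  names(groups) <- NULL
  group_wits <- lapply(groups, function(g) {
    wits[[match(g[1], members)]]
  })
  structure(list(members = sort(members), groups = groups,
                 witnesses = group_wits), class = "loop_report")
}

#' @export
print.loop_report <- function(x, ...) {
  cat("<loop_report> ", length(x$members), " reaction(s) in ",
      length(x$groups), " group(s)\n", sep = "")
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Split gap-fill proposals by whether they create infeasible loops
#'
#' A proposal is rejected iff applying it strictly enlarges the set of
#' loop-member reactions relative to the unmodified model — mirroring the
#' curation rule that reconnection hypotheses generating thermodynamically
#' infeasible cycles are excluded.
#'
#' @param model a `metabolic_model`.
#' @param proposals list of reaction-id vectors from [propose_gapfill()].
#' @param universal the pool model the proposals draw from.
#' @return list(accepted, rejected), each a list of proposals.
#' @export
filter_proposals_by_loops <- function(model, proposals, universal) {
  base <- detect_infeasible_loops(model)$members
  verdict <- vapply(proposals, function(p) {
    m2 <- add_reactions_from(model, universal, p)
    after <- detect_infeasible_loops(m2)$members
    length(setdiff(after, base)) > 0
  }, logical(1))
  list(accepted = proposals[!verdict], rejected = proposals[verdict])
}
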