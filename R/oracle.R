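# Exhaustive reference optimiser for tiny networks.
#
# For LPs of the form  opt c'v, S v = 0, lb <= v <= ub  with finite bounds,
# every optimum is attained at a basic solution: pick r = rank(S) basic
# variables, fix each remaining variable at one of its bounds, and solve
# the square system. Enumerating all (basis, bound-pattern) combinations
# visits every vertex of the polytope. This is exponential and only
# sensible for <= ~10 reactions; it exists as an independent check on the
# simplex path, sharing no code with it.

#' Brute-force flux optimum by basic-solution enumeration
#'
#' @param S stoichiometric matrix (metabolites x reactions).
#' @param lb,ub finite bound vectors.
#' @param obj objective vector.
#' @param maximize direction.
#' @param tol feasibility tolerance for bound checks.
#' @return list(objective, fluxes, status) where status is `"optimal"` or
#'   `"infeasible"`.
#' @export
brute_force_fba <- function(S, lb, ub, obj, maximize = TRUE, tol = 1e-8) {
  n <- ncol(S)
  if (n > 12) stop("brute-force enumeration is limited to <= 12 reactions")
  # reduce to an independent row set
  qrS <- qr(t(S))
  r <- qrS$rank
  Sr <- S[qrS$pivot[seq_len(r)], , drop = FALSE]

  best <- NULL
  bases <- if (r == 0) list(integer(0)) else utils::combn(n, r, simplify = FALSE)
  for (B in bases) {
    NB <- setdiff(seq_len(n), B)
    SB <- Sr[, B, drop = FALSE]
    if (r > 0 && abs(det(SB)) < 1e-10) next
    k <- length(NB)
    for (pat in seq_len(2^k) - 1L) {
      at_ub <- as.logical(bitwAnd(pat, 2^(seq_len(k) - 1L)))
      vNB <- ifelse(at_ub, ub[NB], lb[NB])
      v <- numeric(n)
      v[NB] <- vNB
      if (r > 0) {
        rhs <- -Sr[, NB, drop = FALSE] %*% vNB
        v[B] <- solve(SB, rhs)
      }
      if (any(v < lb - tol) || any(v > ub + tol)) next
      z <- sum(obj * v)
      if (is.null(best) ||
          (maximize && z > best$objective) ||
          (!maximize && z < best$objective)) {
        best <- list(objective = z, fluxes = v, status = "optimal")
      }
    }
  }
  if (is.null(best)) list(objective = NA_real_, fluxes = NULL,
                          status = "infeasible")
  else best
}

#' Brute-force flux variability by basic-solution enumeration
#'
#' Per-reaction minima and maxima over the steady-state polytope, with an
#' optional floor on one reaction's flux (the biomass floor is a bound
#' tightening, so the enumeration is unchanged).
#'
#' @inheritParams brute_force_fba
#' @param reactions column indices or names to scan (default all).
#' @param floor_reaction,floor optional reaction whose lower bound is
#'   raised to `floor` before scanning.
#' @return data.frame(reaction_id, min, max).
#' @export
brute_force_fva <- function(S, lb, ub, reactions = NULL,
                            floor_reaction = NULL, floor = NULL,
                            tol = 1e-8) {
  n <- ncol(S)
  ids <- colnames(S) %||% as.character(seq_len(n))
  reactions <- reactions %||% ids
  if (!is.null(floor_reaction)) {
    j <- if (is.character(floor_reaction)) match(floor_reaction, ids)
         else floor_reaction
    lb[j] <- max(lb[j], floor)
  }
  res <- lapply(reactions, function(rn) {
    j <- if (is.character(rn)) match(rn, ids) else rn
    obj <- numeric(n); obj[j] <- 1
    lo <- brute_force_fba(S, lb, ub, obj, maximize = FALSE, tol = tol)
    hi <- brute_force_fba(S, lb, ub, obj, maximize = TRUE, tol = tol)
    c(lo$objective, hi$objective)
  })
  data.frame(reaction_id = as.character(reactions),
             min = vapply(res, `[`, numeric(1), 1),
             max = vapply(res, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}
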