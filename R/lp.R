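# Linear-programming layer.
#
# All flux LPs in this package share one shape:
#   optimise  c'v   subject to  S v = 0,  lb <= v <= ub,  A_extra v <=/>= rhs
# with finite bounds (infinities were normalised to big-M at model build).
# The solver is a dense two-phase primal simplex over bounded variables
# with Bland's anti-cycling rule: inequality rows get slack variables,
# phase 1 drives artificial variables to zero (their residual certifies
# infeasibility), phase 2 optimises with the artificials pinned at zero.
# Problems here are small (tens of reactions), so the basis inverse is
# recomputed per pivot rather than updated.

solve_lp <- function(obj, S, lb, ub, extra = NULL, maximize = TRUE,
                     tol = 1e-9) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n, ncol(S) == n)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_, fluxes = NULL))

  A <- S
  b <- rep(0, nrow(S))
  l <- lb; u <- ub
  cost <- if (maximize) obj else -obj

  if (!is.null(extra) && length(extra$rhs)) {
    # slack per inequality row: A v + s = rhs with s >= 0 (<=) or s <= 0 (>=)
    k <- length(extra$rhs)
    A <- rbind(A, extra$A)
    A <- cbind(A, rbind(matrix(0, nrow(S), k), diag(k)))
    b <- c(b, extra$rhs)
    span <- as.vector(abs(extra$A) %*% pmax(abs(lb), abs(ub))) +
      abs(extra$rhs) + 1
    sl <- ifelse(extra$dir == "<=", 0, -span)
    su <- ifelse(extra$dir == "<=", span, 0)
    l <- c(l, sl); u <- c(u, su)
    cost <- c(cost, rep(0, k))
  }

  res <- simplex_bounded(cost, A, b, l, u, tol = tol)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, fluxes = NULL))
  v <- res$x[seq_len(n)]
  zval <- sum(obj * v)
  list(status = "optimal", objective = zval,
       fluxes = stats::setNames(v, colnames(S)))
}

# maximise c'x subject to A x = b, l <= x <= u  (finite l, u)
simplex_bounded <- function(cost, A, b, l, u, tol = 1e-9,
                            max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {                       # pure bound problem
    x <- ifelse(cost > 0, u, ifelse(cost < 0, l, pmin(pmax(0, l), u)))
    return(list(status = "optimal", x = x, objective = sum(cost * x)))
  }

  # start: structural variables at their smallest-magnitude bound
  x <- ifelse(abs(l) <= abs(u), l, u)
  at_upper <- abs(l) > abs(u)

  resid <- b - as.vector(A %*% x)
  asign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(asign, m))
  xa <- abs(resid)
  lfull <- c(l, rep(0, m))
  ufull <- c(u, rep(Inf, m))
  xfull <- c(x, xa)
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)

  phase1 <- c(rep(0, n), rep(-1, m))   # maximise -(sum of artificials)
  st <- simplex_core(phase1, Afull, lfull, ufull, xfull, at_upper, basis,
                     tol, max_iter)
  if (st$status != "optimal") return(list(status = st$status))
  if (sum(st$x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible"))

  # pin artificials to zero and optimise the real objective
  ufull <- c(u, rep(0, m))
  st$x[n + seq_len(m)] <- 0
  st2 <- simplex_core(c(cost, rep(0, m)), Afull, lfull, ufull, st$x,
                      st$at_upper, st$basis, tol, max_iter)
  if (st2$status != "optimal") return(list(status = st2$status))
  list(status = "optimal", x = st2$x[seq_len(n)],
       objective = sum(cost * st2$x[seq_len(n)]))
}

simplex_core <- function(cost, A, l, u, x, at_upper, basis, tol,
                         max_iter) {
  m <- nrow(A); N <- ncol(A)
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) return(list(status = "singular"))
    y <- drop(cost[basis] %*% Binv)
    nonbasic <- setdiff(seq_len(N), basis)
    d <- cost[nonbasic] - drop(y %*% A[, nonbasic, drop = FALSE])

    # entering: improve the maximisation; Bland = smallest index eligible
    up <- at_upper[nonbasic]
    eligible <- (!up & d > tol & u[nonbasic] > l[nonbasic]) |
                (up & d < -tol)
    if (!any(eligible)) {
      return(list(status = "optimal", x = x, basis = basis,
                  at_upper = at_upper))
    }
    q <- nonbasic[eligible][which.min(nonbasic[eligible])]
    dirn <- if (at_upper[q]) -1 else 1       # entering moves off its bound

    w <- drop(Binv %*% A[, q]) * dirn        # x_B changes by -w * t
    t_enter <- u[q] - l[q]                   # bound-to-bound flip
    t_best <- t_enter; leave <- 0L           # 0 = bound flip
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (w[i] > tol) {                      # basic decreases toward l
        ti <- (x[bi] - l[bi]) / w[i]
        if (ti < t_best - tol ||
            (ti < t_best + tol && leave != 0L && bi < basis[leave])) {
          t_best <- ti; leave <- i
        }
      } else if (w[i] < -tol) {              # basic increases toward u
        if (is.finite(u[bi])) {
          ti <- (u[bi] - x[bi]) / (-w[i])
          if (ti < t_best - tol ||
              (ti < t_best + tol && leave != 0L && bi < basis[leave])) {
            t_best <- ti; leave <- i
          }
        }
      }
    }
    if (!is.finite(t_best)) return(list(status = "unbounded"))
    t_best <- max(t_best, 0)

    x[q] <- x[q] + dirn * t_best
    x[basis] <- x[basis] - w * t_best
    if (leave == 0L) {                       # entering flipped bounds
      at_upper[q] <- !at_upper[q]
    } else {
      bi <- basis[leave]
      # leaving variable rests on the bound it hit
      hit_lower <- w[leave] > 0
      x[bi] <- if (hit_lower) l[bi] else u[bi]
      at_upper[bi] <- !hit_lower
      basis[leave] <- q
    }
  }
  list(status = "maxiter")
}
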