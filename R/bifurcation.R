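## Codimension-one bifurcation analysis of equilibria of a smooth vector
## field: multistart Newton, natural-parameter continuation with warm
## starts, Hopf / saddle-node detection by eigenvalue-crossing bracketing
## and bisection refinement. Generic over the field, with a specialised
## reduced-space path for the neocortical subsystem.

num_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h * max(1, abs(x[j]))
    J[, j] <- (f(x + e) - f(x - e)) / (2 * e[j])
  }
  J
}

newton_root <- function(f, x0, jac = NULL, tol = 1e-10, maxit = 50) {
  x <- x0
  for (i in seq_len(maxit)) {
    fx <- f(x)
    if (!all(is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    J <- if (is.null(jac)) num_jacobian(f, x) else jac(x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    # damped update guards against overshoot far from the root
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- f(xn)
      if (all(is.finite(fn)) && (max(abs(fn)) < max(abs(fx)) || lam < 1 / 64)) break
      lam <- lam / 2
    }
    x <- xn
  }
  if (max(abs(f(x))) < tol * 100) x else NULL
}

dedup_rows <- function(X, tol) {
  if (is.null(X) || nrow(X) <= 1) return(X)
  keep <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(X) - 1)) {
    if (!keep[i]) next
    for (j in seq(i + 1, nrow(X)))
      if (keep[j] && max(abs(X[i, ] - X[j, ])) < tol) keep[j] <- FALSE
  }
  X[keep, , drop = FALSE]
}

#' Find equilibria of a vector field
#'
#' Newton iteration from a set of starting points, deduplicated at a
#' tolerance; each converged root is returned with the eigenvalues of the
#' (numerically estimated, unless supplied) Jacobian and a stability flag
#' (all real parts negative at tolerance 1e-8).
#'
#' @param field function mapping a state vector to its derivative; may carry
#'   attributes `jac` (analytic Jacobian function) and `eig` (function
#'   returning the eigenvalues governing stability, when these differ from
#'   the eigenvalues of `jac`, as for a reduced equilibrium map).
#' @param starts matrix of starting points (one per row), or a vector of
#'   starts for a one-dimensional field.
#' @param jac optional Jacobian function (overrides the attribute).
#' @param tol Newton residual tolerance. @param dedup_tol root
#'   deduplication tolerance.
#' @return list of equilibria, each a list with `x`, `eigenvalues`,
#'   `stable`. Empty (with a warning) if no start converges.
#' @export
#' @examples
#' eq <- find_equilibria(function(x) 1 - x^2, starts = c(-2, 0, 2))
#' sort(sapply(eq, function(e) e$x))      # -1, 1
find_equilibria <- function(field, starts, jac = NULL, tol = 1e-10,
                            dedup_tol = 1e-6) {
  if (is.null(jac)) jac <- attr(field, "jac")
  eigf <- attr(field, "eig")
  if (is.null(dim(starts))) starts <- matrix(starts, ncol = 1)
  X <- NULL
  for (i in seq_len(nrow(starts))) {
    x <- newton_root(field, starts[i, ], jac = jac, tol = tol)
    if (!is.null(x)) X <- rbind(X, x)
  }
  if (is.null(X)) {
    warning("no Newton start converged; returning no equilibria")
    return(list())
  }
  X <- dedup_rows(X, dedup_tol)
  lapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    ev <- if (!is.null(eigf)) eigf(x)
          else eigen(if (is.null(jac)) num_jacobian(field, x) else jac(x),
                     only.values = TRUE)$values
    list(x = x, eigenvalues = ev, stable = all(Re(ev) < 1e-8))
  })
}

# leading real parts used for crossing detection: among complex pairs
# (Hopf) and among numerically real eigenvalues (fold)
crossing_measures <- function(ev, im_tol = 1e-6) {
  cplx <- ev[abs(Im(ev)) > im_tol]
  real <- ev[abs(Im(ev)) <= im_tol]
  c(hopf = if (length(cplx)) max(Re(cplx)) else -Inf,
    fold = if (length(real)) max(Re(real)) else -Inf)
}

#' Sweep a parameter and locate codim-1 bifurcations
#'
#' Natural-parameter continuation of every equilibrium branch of a family of
#' vector fields over a parameter grid, with warm-started Newton plus
#' multistart re-seeding at every value. A Hopf bifurcation is flagged where
#' the real part of the leading complex-conjugate eigenvalue pair changes
#' sign along a branch and refined by bisection to `refine_tol`; a
#' saddle-node where the leading real eigenvalue changes sign, or where a
#' branch terminates between grid values (fold, reported with the bracketing
#' interval).
#'
#' @param make_field function(parameter) returning the field (with optional
#'   `jac`/`eig` attributes, see [find_equilibria()]).
#' @param values increasing parameter grid.
#' @param starts multistart points (matrix, one per row; or vector for 1-D).
#' @param refine_tol bisection tolerance on the parameter.
#' @param link_tol maximum per-component state jump linking equilibria
#'   across consecutive values into one branch.
#' @return list with `branch` (data.frame: `value`, `branch` id, `norm`,
#'   `x1`, `leading` real part, `stable`) and `points` (list of bifurcation
#'   points with `kind`, `value`, `x`, `bracket`).
#' @export
#' @examples
#' # saddle-node normal form xdot = mu - x^2: fold at mu = 0
#' sw <- sweep_bifurcations(function(mu) function(x) mu - x^2,
#'                          values = seq(-0.3, 0.3, by = 0.02),
#'                          starts = c(-1, 0, 1))
#' round(sw$points[[1]]$value, 3)
sweep_bifurcations <- function(make_field, values, starts, refine_tol = 1e-5,
                               link_tol = 0.2) {
  if (is.null(dim(starts))) starts <- matrix(starts, ncol = 1)
  solve_at <- function(par, warm = NULL) {
    f <- make_field(par)
    suppressWarnings(find_equilibria(f, rbind(warm, starts)))
  }
  eq_prev <- solve_at(values[1])
  next_id <- 1L; ids <- integer(0)
  if (length(eq_prev)) { ids <- seq_along(eq_prev); next_id <- length(eq_prev) + 1L }
  rows <- list(); points <- list()
  push_rows <- function(par, eqs, ids) {
    for (i in seq_along(eqs)) {
      e <- eqs[[i]]
      rows[[length(rows) + 1]] <<- data.frame(
        value = par, branch = ids[i], norm = sqrt(sum(e$x^2)),
        x1 = e$x[1], leading = max(Re(e$eigenvalues)), stable = e$stable)
    }
  }
  push_rows(values[1], eq_prev, ids)
  measure_at <- function(par, warm, kind) {
    eqs <- solve_at(par, warm = matrix(warm, nrow = 1))
    if (!length(eqs)) return(NA_real_)
    d <- vapply(eqs, function(e) max(abs(e$x - warm)), 0)
    e <- eqs[[which.min(d)]]
    crossing_measures(e$eigenvalues)[[kind]]
  }
  refine <- function(lo, hi, warm, kind) {
    s_lo <- sign(measure_at(lo, warm, kind))
    while (abs(hi - lo) > refine_tol) {
      mid <- (lo + hi) / 2
      m <- measure_at(mid, warm, kind)
      if (!is.finite(m)) break
      if (sign(m) == s_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (kv in seq_along(values)[-1]) {
    par <- values[kv]
    warm <- if (length(eq_prev))
      do.call(rbind, lapply(eq_prev, function(e) e$x)) else NULL
    eqs <- solve_at(par, warm = warm)
    new_ids <- integer(length(eqs))
    used <- rep(FALSE, length(eq_prev))
    for (i in seq_along(eqs)) {
      if (length(eq_prev)) {
        d <- vapply(eq_prev, function(e) max(abs(e$x - eqs[[i]]$x)), 0)
        jbest <- which.min(d)
        if (length(jbest) && d[jbest] < link_tol && !used[jbest]) {
          new_ids[i] <- ids[jbest]; used[jbest] <- TRUE
          m0 <- crossing_measures(eq_prev[[jbest]]$eigenvalues)
          m1 <- crossing_measures(eqs[[i]]$eigenvalues)
          for (kind in c("hopf", "fold")) {
            if (is.finite(m0[[kind]]) && is.finite(m1[[kind]]) &&
                sign(m0[[kind]]) != sign(m1[[kind]]) && sign(m0[[kind]]) != 0) {
              pstar <- refine(values[kv - 1], par, eq_prev[[jbest]]$x, kind)
              points[[length(points) + 1]] <- list(
                kind = if (kind == "hopf") "Hopf" else "saddle-node",
                value = pstar, x = eqs[[i]]$x,
                bracket = c(values[kv - 1], par))
            }
          }
        }
      }
      if (new_ids[i] == 0L) {
        new_ids[i] <- next_id; next_id <- next_id + 1L
        # a branch born between grid values: refine the fold by bisection on
        # the existence of a nearby root (approached from the absent side).
        # Only a genuine appearance counts: no equilibrium near the new root
        # at the previous value (otherwise it is a duplicate, not a fold).
        if (length(eq_prev)) {
          dprev <- vapply(eq_prev, function(e) max(abs(e$x - eqs[[i]]$x)), 0)
          if (min(dprev) < link_tol) next
        }
        lo <- values[kv - 1]; hi <- par
        xw <- eqs[[i]]$x
        while (abs(hi - lo) > refine_tol) {
          mid <- (lo + hi) / 2
          eqs_m <- solve_at(mid, warm = matrix(xw, nrow = 1))
          near <- FALSE
          if (length(eqs_m)) {
            d <- vapply(eqs_m, function(e) max(abs(e$x - xw)), 0)
            if (min(d) < link_tol) { near <- TRUE; xw <- eqs_m[[which.min(d)]]$x }
          }
          if (near) hi <- mid else lo <- mid
        }
        points[[length(points) + 1]] <- list(
          kind = "saddle-node", value = (lo + hi) / 2,
          x = eqs[[i]]$x, bracket = c(values[kv - 1], par))
      }
    }
    if (length(eq_prev)) {
      for (j in which(!used)) {
        # branch terminated between grid values: refine the fold location by
        # bisection on the existence of a nearby root
        xlost <- eq_prev[[j]]$x
        lo <- values[kv - 1]; hi <- par
        xw <- xlost
        while (abs(hi - lo) > refine_tol) {
          mid <- (lo + hi) / 2
          eqs_m <- solve_at(mid, warm = matrix(xw, nrow = 1))
          near <- FALSE
          if (length(eqs_m)) {
            d <- vapply(eqs_m, function(e) max(abs(e$x - xw)), 0)
            if (min(d) < link_tol) { near <- TRUE; xw <- eqs_m[[which.min(d)]]$x }
          }
          if (near) lo <- mid else hi <- mid
        }
        points[[length(points) + 1]] <- list(
          kind = "saddle-node", value = (lo + hi) / 2,
          x = xlost, bracket = c(values[kv - 1], par))
      }
    }
    push_rows(par, eqs, new_ids)
    eq_prev <- eqs; ids <- new_ids
  }
  if (length(points) > 1) {
    keep <- rep(TRUE, length(points))
    step <- max(abs(diff(values)))
    for (i in seq_along(points)) {
      if (!keep[i]) next
      for (j in seq_along(points)) {
        if (j <= i || !keep[j]) next
        if (points[[i]]$kind == points[[j]]$kind &&
            abs(points[[i]]$value - points[[j]]$value) < 2 * step)
          keep[j] <- FALSE
      }
    }
    points <- points[keep]
  }
  list(branch = do.call(rbind, rows), points = points)
}

# default multistart grid for the reduced neocortical equilibrium map:
# constant activation fractions of each mass between silence and saturation
ncx_starts <- function(params, levels = seq(0, 1, by = 0.2)) {
  sp <- params$subpopulations
  nm <- subpop_names()[1:7]
  ymax <- vapply(nm, function(n) sp[[n]]$W / sp[[n]]$w, 0) * 2 * params$sigmoid$e0
  t(vapply(levels, function(a) a * ymax, numeric(7)))
}

#' Equilibria of the neocortical subsystem
#'
#' Solves the reduced fixed-point equations of the seven neocortical masses
#' (at equilibrium every PSP derivative pair vanishes, leaving seven
#' equations in the PSP components) with an analytic Jacobian, then
#' classifies stability from the full 14-dimensional linearisation.
#'
#' @param params model parameters. @param y6 constant thalamic relay PSP
#'   (mV). @param kappa STD factor on TC->PYR. @param extra_starts optional
#'   matrix of additional 7-dimensional starting points.
#' @return list of equilibria with `y` (PSP components), `x` (full
#'   14-dimensional state), `eigenvalues`, `stable`.
#' @export
ncx_equilibria <- function(params = default_params(), y6 = 0.26, kappa = 1,
                           extra_starts = NULL) {
  red <- ncx_reduced(params, y6, kappa)
  f <- red$F
  attr(f, "jac") <- red$J
  attr(f, "eig") <- function(y) eigen(red$full_jacobian(y),
                                      only.values = TRUE)$values
  eqs <- suppressWarnings(
    find_equilibria(f, rbind(ncx_starts(params), extra_starts)))
  lapply(eqs, function(e)
    list(y = e$x, x = c(e$x, numeric(7)), eigenvalues = e$eigenvalues,
         stable = e$stable))
}

#' Sweep the neocortical subsystem
#'
#' [sweep_bifurcations()] applied to the neocortical compartment with either
#' the thalamic relay PSP `y6` or the STD factor `kappa` as the bifurcation
#' parameter, the other held fixed. Newton runs in the reduced 7-dimensional
#' PSP space; stability and crossings use the full 14-dimensional
#' linearisation.
#'
#' @param params model parameters. @param param `"y6"` or `"kappa"`.
#' @param values parameter grid. @param y6,kappa value of the non-swept
#'   parameter. @param refine_tol bisection tolerance.
#' @return as [sweep_bifurcations()]; `x1` is the pyramidal PSP.
#' @export
ncx_sweep <- function(params = default_params(), param = c("y6", "kappa"),
                      values, y6 = 0.26, kappa = 1, refine_tol = 1e-5) {
  param <- match.arg(param)
  make_field <- function(v) {
    red <- if (param == "y6") ncx_reduced(params, v, kappa)
           else ncx_reduced(params, y6, v)
    f <- red$F
    attr(f, "jac") <- red$J
    attr(f, "eig") <- function(y) eigen(red$full_jacobian(y),
                                        only.values = TRUE)$values
    f
  }
  sweep_bifurcations(make_field, values, ncx_starts(params),
                     refine_tol = refine_tol, link_tol = 0.05)
}

#' Characterise periodic orbits by direct simulation
#'
#' For each parameter value, integrates the noise-free neocortical subsystem
#' (via \pkg{deSolve}) from one or more initial conditions, discards a
#' transient, and tests for a periodic attractor by peak detection on the
#' pyramidal PSP: if a sustained oscillation is present, the orbit's min/max
#' amplitude and period are recorded; otherwise the entry is marked absent.
#' Supplying both a near-rest and a strongly excited initial condition
#' probes bistability between an equilibrium and a spike-wave orbit.
#'
#' @param params model parameters. @param param `"y6"` or `"kappa"`.
#' @param values parameter values. @param y6,kappa the non-swept parameter.
#' @param inits list of 14-dimensional initial conditions.
#' @param t_trans,t_obs transient and observation horizons (s).
#' @return data.frame: `value`, `init` (index), `periodic`, `ymin`, `ymax`,
#'   `period` (s; NA when no periodic attractor is reached).
#' @export
orbit_branch <- function(params = default_params(), param = c("y6", "kappa"),
                         values, y6 = 0.26, kappa = 1, inits = NULL,
                         t_trans = 20, t_obs = 10) {
  param <- match.arg(param)
  if (is.null(inits))
    inits <- list(rep(0, 14), c(rep(0.05, 7), rep(0, 7)))
  rows <- list()
  for (v in values) {
    f <- if (param == "y6") ncx_field(params, y6 = v, kappa = kappa)
         else ncx_field(params, y6 = y6, kappa = v)
    dfun <- function(t, y, parms) list(f(y))
    for (ii in seq_along(inits)) {
      sol <- deSolve::ode(y = inits[[ii]],
                          times = seq(0, t_trans + t_obs, by = 1e-3),
                          func = dfun, parms = NULL, method = "lsoda",
                          rtol = 1e-8, atol = 1e-8)
      y0 <- sol[sol[, 1] >= t_trans, 2] # pyramidal PSP
      amp <- diff(range(y0))
      if (amp < 1e-4) {
        rows[[length(rows) + 1]] <- data.frame(
          value = v, init = ii, periodic = FALSE,
          ymin = NA_real_, ymax = NA_real_, period = NA_real_)
      } else {
        pk <- which(diff(sign(diff(y0))) == -2) + 1
        pk <- pk[y0[pk] > min(y0) + 0.5 * amp]
        per <- if (length(pk) >= 3) stats::median(diff(pk)) * 1e-3 else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          value = v, init = ii, periodic = TRUE,
          ymin = min(y0), ymax = max(y0), period = per)
      }
    }
  }
  do.call(rbind, rows)
}
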