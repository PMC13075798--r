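## ------------------------------------------------------------------
## Periodic orbits by single shooting.  The monodromy matrix comes from
## integrating the variational equations alongside the orbit (compiled
## for the single column; generic R path for other systems).

## flow map and monodromy over time T from y0 at parameter lam
flow_mono <- function(model, y0, lam, T, tol = 1e-10) {
  n <- model$n
  if (isTRUE(model$compiled_var)) {
    parms <- c(model$cparms(lam), n)   # last slot: number of tangent columns
    init <- c(y0, as.vector(diag(n)))
    out <- deSolve::ode(init, c(0, T), func = "lanmm_derivs_var",
                        parms = parms, dllname = "lanmm",
                        initfunc = "lanmm_initmod_var", method = "lsoda",
                        rtol = tol, atol = tol * 1e-2, maxsteps = 500000)
  } else {
    f <- function(t, y, p) {
      yy <- y[seq_len(n)]
      Phi <- matrix(y[-seq_len(n)], n, n)
      list(c(model$f(yy, lam), as.vector(model$jac(yy, lam) %*% Phi)))
    }
    out <- deSolve::ode(c(y0, as.vector(diag(n))), c(0, T), f, NULL,
                        method = "lsoda", rtol = tol, atol = tol * 1e-2,
                        maxsteps = 500000)
  }
  if (!all(is.finite(out[nrow(out), -1]))) stop("variational flow blew up")
  yT <- out[nrow(out), 2:(n + 1)]
  M <- matrix(out[nrow(out), (n + 2):(n + n * n + 1)], n, n)
  list(yT = unname(yT), M = M)
}

flow_only <- function(model, y0, lam, times, tol = 1e-10) {
  if (!is.null(model$c_derivs)) {
    out <- deSolve::ode(y0, times, func = model$c_derivs,
                        parms = model$cparms(lam), dllname = "lanmm",
                        initfunc = model$c_init, method = "lsoda",
                        rtol = tol, atol = tol * 1e-2, maxsteps = 500000)
  } else {
    f <- function(t, y, p) list(model$f(y, lam))
    out <- deSolve::ode(y0, times, f, NULL, method = "lsoda",
                        rtol = tol, atol = tol * 1e-2, maxsteps = 500000)
  }
  if (!all(is.finite(out[nrow(out), -1]))) stop("flow blew up")
  out
}

## augment a cmodel with the compiled fast path for the single column
cmodel_single_fast <- function(params, vary = "phi_e1") {
  m <- cmodel_single(params, vary)
  m$cparms <- function(lam) {
    params$inputs[[vary]] <- lam
    as_parm_vector(params)
  }
  m$c_derivs <- "lanmm_derivs"
  m$c_init <- "lanmm_initmod"
  m$compiled_var <- TRUE
  m
}

## orbit metrics: amplitude of both observables over one period
orbit_amplitude <- function(model, y0, lam, T, nsamp = 400) {
  out <- flow_only(model, y0, lam, seq(0, T, length.out = nsamp))
  y <- out[, -1, drop = FALSE]
  obs <- t(apply(y, 1, function(yy) model$observe(yy, lam)))
  c(amp1 = diff(range(obs[, 1])), amp2 = diff(range(obs[, 2])))
}

## Newton solve of the shooting system at fixed parameter:
## unknowns (x0, T); equations flow_T(x0) - x0 = 0 plus the Poincare
## phase condition <f(x_ref), x0 - x_ref> = 0.
shoot_newton <- function(model, x0, T, lam, x_ref = x0,
                         f_ref = model$f(x_ref, lam),
                         tol = 1e-9, maxit = 25) {
  n <- model$n
  for (it in seq_len(maxit)) {
    fm <- flow_mono(model, x0, lam, T)
    res <- c(fm$yT - x0, sum(f_ref * (x0 - x_ref)))
    if (max(abs(res)) < tol)
      return(list(x0 = x0, T = T, M = fm$M, ok = TRUE,
                  res = max(abs(res))))
    A <- rbind(cbind(fm$M - diag(n), model$f(fm$yT, lam)),
               c(f_ref, 0))
    d <- tryCatch(solve(A, res), error = function(e) NULL)
    if (is.null(d) || !all(is.finite(d))) break
    ## damped update; period must stay positive
    sc <- 1
    if (T - sc * d[n + 1] <= 0) sc <- 0.5 * T / abs(d[n + 1])
    x0 <- x0 - sc * d[seq_len(n)]
    T <- T - sc * d[n + 1]
  }
  list(x0 = x0, T = T, ok = FALSE, res = NA_real_)
}

make_cycle <- function(model, sol, lam, params = NULL) {
  mult <- eigen(sol$M, only.values = TRUE)$values
  triv <- which.min(abs(mult - 1))
  nontriv <- mult[-triv]
  amp <- orbit_amplitude(model, sol$x0, lam, sol$T)
  structure(list(
    param = lam, vary = model$vary, anchor_state = sol$x0,
    period = sol$T, floquet_multipliers = mult,
    trivial_multiplier = mult[triv],
    stable = all(Mod(nontriv) < 1 + 1e-4),
    amplitude = amp, residual = sol$res, params = params
  ), class = "lanmm_cycle")
}

#' Locate a periodic orbit by single shooting
#'
#' Newton solve of the shooting system (return map minus identity, plus
#' a Poincare phase condition anchored at the initial guess), with the
#' monodromy matrix obtained by integrating the variational equations
#' along the orbit.  Floquet multipliers are its eigenvalues; one
#' multiplier is always 1 for an autonomous flow and is excluded from
#' the stability test.
#'
#' @param params a [lanmm_params()] object at the operating point.
#' @param guess_state state near the orbit (e.g. a simulation sample).
#' @param guess_period approximate period, s.
#' @param vary name of the parameter recorded with the orbit.
#' @param model internal: alternative system interface.
#' @return an object of class \code{lanmm_cycle}: \code{anchor_state},
#'   \code{period} (s), \code{floquet_multipliers} (complex),
#'   \code{stable}, \code{amplitude} (peak-to-peak of both observables,
#'   mV), \code{param}.
#' @export
find_cycle <- function(params, guess_state, guess_period,
                       vary = "phi_e1", model = NULL) {
  if (is.null(model)) model <- cmodel_single_fast(params, vary)
  lam <- params$inputs[[vary]]
  sol <- shoot_newton(model, guess_state, guess_period, lam)
  if (!sol$ok)
    stop("shooting Newton did not converge to a periodic orbit")
  if (sol$T < 1e-4 || sqrt(sum(model$f(sol$x0, lam)^2)) < 1e-8)
    stop("converged to an equilibrium, not a periodic orbit")
  make_cycle(model, sol, lam, params)
}

#' @export
print.lanmm_cycle <- function(x, ...) {
  cat(sprintf(
    "Periodic orbit at %s = %g: period %.5f s (%.2f Hz), %s\n",
    x$vary, x$param, x$period, 1 / x$period,
    if (x$stable) "stable" else "unstable"))
  cat(sprintf("  amplitude vP1 %.3f mV, vP2 %.3f mV; |trivial mult - 1| = %.2g\n",
              x$amplitude[1], x$amplitude[2],
              abs(x$trivial_multiplier - 1)))
  invisible(x)
}

#' Seed a periodic orbit from simulation
#'
#' Convenience wrapper: simulates at the operating point, estimates the
#' period from zero crossings of the centered deep-pyramidal potential,
#' and polishes by shooting.
#'
#' @inheritParams find_cycle
#' @param t_transient,t_record probe simulation windows, s.
#' @export
cycle_from_simulation <- function(params, vary = "phi_e1",
                                  t_transient = 15, t_record = 10) {
  ts <- simulate_lanmm(params, solver_settings(t_transient = t_transient,
                                               t_record = t_record))
  per <- estimate_period(ts$vP1, attr(ts, "sample_rate"))
  if (is.na(per)) stop("no oscillation found at this operating point")
  find_cycle(params, attr(ts, "final_state"), per, vary = vary)
}

## corrector for the 12-dimensional (x0, T, lam) continuation system;
## d flow / d lam by finite differences (one extra orbit integration)
cycle_correct <- function(model, u, u_prev, tang, h, w, f_prev,
                          tol = 1e-8, maxit = 10) {
  n <- model$n
  ug <- u_prev + h * tang
  for (it in seq_len(maxit)) {
    x0 <- ug[seq_len(n)]; T <- ug[n + 1]; lam <- ug[n + 2]
    if (T <= 0) return(NULL)
    fm <- tryCatch(flow_mono(model, x0, lam, T), error = function(e) NULL)
    if (is.null(fm)) return(NULL)
    res <- c(fm$yT - x0,
             sum(f_prev * (x0 - u_prev[seq_len(n)])),
             sum(w^2 * (ug - u_prev) * tang) - h)
    if (max(abs(res[seq_len(n + 1)])) < tol && abs(res[n + 2]) < tol)
      return(list(u = ug, M = fm$M, iters = it))
    dlam <- 1e-4 * max(1, abs(lam))
    yT2 <- tryCatch(flow_only(model, x0, lam + dlam, c(0, T))[2, -1],
                    error = function(e) NULL)
    if (is.null(yT2)) return(NULL)
    dflam <- (yT2 - fm$yT) / dlam
    A <- rbind(cbind(fm$M - diag(n), model$f(fm$yT, lam), dflam),
               c(f_prev, 0, 0),
               w^2 * tang)
    d <- tryCatch(solve(A, res), error = function(e) NULL)
    if (is.null(d) || !all(is.finite(d))) return(NULL)
    ug <- ug - d
  }
  NULL
}

#' Continue a branch of periodic orbits
#'
#' Pseudo-arclength continuation of the shooting system in one
#' parameter.  Unstable cycles are tracked through folds (this is what
#' makes the method necessary: simulation cannot converge to repelling
#' orbits).  Period, observable amplitudes and Floquet multipliers are
#' recorded at every accepted point.
#'
#' @param start a [find_cycle()] result.
#' @param range parameter interval to cover (continuation starts at
#'   \code{start$param} and first proceeds toward \code{range[2]}).
#' @param step,max_step,min_step arclength step control (rate units).
#' @param state_weight,period_weight weights of the state and period
#'   components relative to the parameter in the arclength norm.
#' @param max_points safety bound.
#' @param model internal system interface override.
#' @return a \code{lanmm_cycle_branch}: data frame with columns
#'   \code{param}, \code{period}, \code{freq}, \code{amp_vP1},
#'   \code{amp_vP2}, \code{stable}, \code{max_nontrivial_mod},
#'   \code{tangent_param}; attributes \code{anchors}, \code{multipliers}.
#' @export
continue_cycles <- function(start, range, step = 1, max_step = 5,
                            min_step = 1e-5, state_weight = 20,
                            period_weight = 50, max_points = 3000,
                            model = NULL) {
  stopifnot(inherits(start, "lanmm_cycle"))
  if (is.null(model)) model <- cmodel_single_fast(start$params, start$vary)
  n <- model$n
  w <- c(rep(state_weight, n), period_weight, 1)
  u <- c(start$anchor_state, start$period, start$param)
  ## initial tangent: nudge the parameter, re-solve, take the secant
  dlam <- 0.05 * diff(range(range)) / 100 + 1e-3
  dir0 <- sign(range[2] - start$param + 1e-12)
  lam1 <- start$param + dir0 * dlam
  s1 <- shoot_newton(model, start$anchor_state, start$period, lam1,
                     x_ref = start$anchor_state,
                     f_ref = model$f(start$anchor_state, start$param))
  if (!s1$ok) stop("could not establish the continuation direction")
  tang <- c(s1$x0 - start$anchor_state, s1$T - start$period,
            lam1 - start$param)
  tang <- tang / sqrt(sum(w^2 * tang^2))

  pts <- list()
  add_pt <- function(u, M) {
    mult <- eigen(M, only.values = TRUE)$values
    amp <- orbit_amplitude(model, u[seq_len(n)], u[n + 2], u[n + 1])
    pts[[length(pts) + 1]] <<- list(u = u, mult = mult, amp = amp,
                                    tl = tang[n + 2])
  }
  fm0 <- flow_mono(model, u[seq_len(n)], u[n + 2], u[n + 1])
  add_pt(u, fm0$M)

  h <- step
  fail_stop <- FALSE
  repeat {
    lam <- u[n + 2]
    if (lam > max(range) || lam < min(range) ||
        length(pts) >= max_points) break
    f_prev <- model$f(u[seq_len(n)], lam)
    ok <- NULL
    while (is.null(ok)) {
      ok <- cycle_correct(model, u, u, tang, h, w, f_prev)
      if (is.null(ok)) {
        h <- h / 2
        if (h < min_step) { fail_stop <- TRUE; break }
      }
    }
    if (fail_stop) {
      warning("cycle branch lost at parameter = ", signif(lam, 6),
              " (minimum step reached)")
      break
    }
    tang_new <- ok$u - u
    tang <- tang_new / sqrt(sum(w^2 * tang_new^2))
    u <- ok$u
    add_pt(u, ok$M)
    ## stop if the orbit has collapsed onto an equilibrium
    if (pts[[length(pts)]]$amp[1] < 1e-6 &&
        pts[[length(pts)]]$amp[2] < 1e-6) break
    if (ok$iters <= 3) h <- min(h * 1.4, max_step)
  }

  df <- data.frame(
    param = vapply(pts, function(z) z$u[n + 2], numeric(1)),
    period = vapply(pts, function(z) z$u[n + 1], numeric(1)),
    amp_vP1 = vapply(pts, function(z) unname(z$amp[1]), numeric(1)),
    amp_vP2 = vapply(pts, function(z) unname(z$amp[2]), numeric(1)),
    tangent_param = vapply(pts, `[[`, numeric(1), "tl")
  )
  df$freq <- 1 / df$period
  mods <- lapply(pts, function(z) {
    m <- z$mult
    m[-which.min(abs(m - 1))]
  })
  df$max_nontrivial_mod <- vapply(mods, function(m) max(Mod(m)), numeric(1))
  df$stable <- df$max_nontrivial_mod < 1 + 1e-4
  structure(df, class = c("lanmm_cycle_branch", "data.frame"),
            anchors = t(vapply(pts, function(z) z$u[seq_len(n)],
                               numeric(n))),
            multipliers = lapply(pts, `[[`, "mult"),
            model = model, vary = model$vary,
            weights = w)
}

#' @export
print.lanmm_cycle_branch <- function(x, ...) {
  cat(sprintf(
    "Cycle branch in %s: %d orbits over [%.4g, %.4g], periods %.4g-%.4g s\n",
    attr(x, "vary"), nrow(x), min(x$param), max(x$param),
    min(x$period), max(x$period)))
  invisible(x)
}

#' @export
plot.lanmm_cycle_branch <- function(x, channel = "amp_vP1", ...) {
  graphics::plot(x$param, x[[channel]], type = "n",
                 xlab = attr(x, "vary"), ylab = channel, ...)
  graphics::points(x$param[x$stable], x[[channel]][x$stable],
                   pch = 16, cex = 0.35)
  graphics::points(x$param[!x$stable], x[[channel]][!x$stable],
                   pch = 1, cex = 0.35, col = "grey60")
  invisible(x)
}

## nontrivial multipliers of a recorded branch point
nontrivial_mults <- function(mult) mult[-which.min(abs(mult - 1))]

## extremum of a quadratic through three consecutive values (unit grid)
parabola_extremum <- function(v) {
  a <- (v[1] - 2 * v[2] + v[3]) / 2
  b <- (v[3] - v[1]) / 2
  if (abs(a) < 1e-12) return(v[2])
  s <- -b / (2 * a)
  s <- max(-1, min(1, s))
  v[2] + b * s + a * s^2
}

#' Detect bifurcations of periodic orbits along a cycle branch
#'
#' Scans consecutive branch points for: folds of limit cycles (FLC),
#' where the branch reverses direction in the parameter (a real
#' multiplier crossing +1); torus bifurcations (TR), where a complex
#' Floquet pair crosses the unit circle; and period doublings (PD),
#' where a real multiplier crosses -1.  FLC locations are taken at the
#' geometric parameter fold; TR and PD are refined by bisection between
#' the bracketing points.
#'
#' @param branch a [continue_cycles()] result.
#' @param refine bisection-refine TR/PD detections.
#' @return data frame with columns \code{kind} (\code{"FLC"},
#'   \code{"torus"}, \code{"period_doubling"}), \code{param},
#'   \code{diagnostic} (multiplier modulus or real part at detection).
#' @export
detect_cycle_bifurcations <- function(branch, refine = TRUE) {
  mults <- attr(branch, "multipliers")
  model <- attr(branch, "model")
  w <- attr(branch, "weights")
  anchors <- attr(branch, "anchors")
  n <- model$n
  out <- list()
  tl <- branch$tangent_param
  ## complex-pair modulus test and real-negative multiplier test
  tr_test <- vapply(mults, function(m) {
    mm <- nontrivial_mults(m)
    ## genuine rotating pair: exclude real-axis collisions at folds (+1)
    ## and period doublings (-1)
    cc <- mm[abs(Arg(mm)) > 0.1 & abs(abs(Arg(mm)) - pi) > 0.1]
    if (!length(cc)) -Inf else max(Mod(cc)) - 1
  }, numeric(1))
  pd_test <- vapply(mults, function(m) {
    mm <- nontrivial_mults(m)
    rr <- Re(mm[abs(Im(mm)) < 1e-6 & Re(mm) < 0])
    if (!length(rr)) Inf else min(rr) + 1
  }, numeric(1))
  for (i in seq_len(nrow(branch) - 1)) {
    if (sign(tl[i]) != sign(tl[i + 1]) && tl[i] != 0) {
      ## geometric fold: parabolic extremum of param over the three
      ## points straddling the tangent reversal
      idx <- if (i > 1) (i - 1):(i + 1) else i:(i + 2)
      out[[length(out) + 1]] <- list(
        kind = "FLC", param = parabola_extremum(branch$param[idx]),
        diagnostic = branch$max_nontrivial_mod[i])
    }
    for (spec in list(list(v = tr_test, kind = "torus"),
                      list(v = pd_test, kind = "period_doubling"))) {
      v <- spec$v
      if (is.finite(v[i]) && is.finite(v[i + 1]) &&
          sign(v[i]) != sign(v[i + 1]) && v[i] != 0) {
        par_est <- branch$param[i] +
          (branch$param[i + 1] - branch$param[i]) *
          abs(v[i]) / (abs(v[i]) + abs(v[i + 1]))
        if (refine) {
          ref <- tryCatch(
            refine_cycle_event(model, branch, i, spec$kind, w),
            error = function(e) NULL)
          if (!is.null(ref)) par_est <- ref
        }
        out[[length(out) + 1]] <- list(kind = spec$kind, param = par_est,
                                       diagnostic = v[i + 1] + 1)
      }
    }
  }
  if (!length(out))
    return(data.frame(kind = character(), param = numeric(),
                      diagnostic = numeric()))
  df <- data.frame(kind = vapply(out, `[[`, character(1), "kind"),
                   param = vapply(out, `[[`, numeric(1), "param"),
                   diagnostic = vapply(out, `[[`, numeric(1), "diagnostic"))
  df[order(df$param), , drop = FALSE]
}

## bisection along the secant between branch points i and i+1 on the
## relevant multiplier test function
refine_cycle_event <- function(model, branch, i, kind, w, iters = 20) {
  n <- model$n
  anchors <- attr(branch, "anchors")
  u_a <- c(anchors[i, ], branch$period[i], branch$param[i])
  u_b <- c(anchors[i + 1, ], branch$period[i + 1], branch$param[i + 1])
  dir <- u_b - u_a
  nz <- sqrt(sum(w^2 * dir^2))
  tang <- dir / nz
  f_prev <- model$f(u_a[seq_len(n)], u_a[n + 2])
  testf <- function(M) {
    mm <- nontrivial_mults(eigen(M, only.values = TRUE)$values)
    if (kind == "torus") {
      cc <- mm[abs(Arg(mm)) > 0.1 & abs(abs(Arg(mm)) - pi) > 0.1]
      if (!length(cc)) return(-Inf)
      max(Mod(cc)) - 1
    } else {
      rr <- Re(mm[abs(Im(mm)) < 1e-6 & Re(mm) < 0])
      if (!length(rr)) return(Inf)
      min(rr) + 1
    }
  }
  fm_a <- flow_mono(model, u_a[seq_len(n)], u_a[n + 2], u_a[n + 1])
  f_a <- testf(fm_a$M)
  lo <- 0; hi <- nz; best <- NA_real_
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cor <- cycle_correct(model, u_a, u_a, tang, mid, w, f_prev)
    if (is.null(cor)) return(NULL)
    f_m <- testf(cor$M)
    best <- cor$u[n + 2]
    if (is.finite(f_m) && sign(f_m) == sign(f_a)) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-7 * nz) break
  }
  best
}

#' Export a cycle branch as CSV
#'
#' @param branch a [continue_cycles()] result.
#' @param path output CSV path.
#' @param bifurcations optional [detect_cycle_bifurcations()] result,
#'   written as \code{<path>.bif.json}.
#' @return \code{path}, invisibly.
#' @export
write_cycle_branch_csv <- function(branch, path, bifurcations = NULL) {
  df <- as.data.frame(branch)[, c("param", "period", "freq", "amp_vP1",
                                  "amp_vP2", "stable",
                                  "max_nontrivial_mod")]
  names(df)[1] <- attr(branch, "vary")
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(bifurcations))
    jsonlite::write_json(as.data.frame(bifurcations),
                         paste0(path, ".bif.json"), digits = NA,
                         pretty = TRUE)
  invisible(path)
}
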