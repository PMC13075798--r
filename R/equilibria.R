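## ------------------------------------------------------------------
## Generic autonomous-system interface used by the continuation code.
## A "cmodel" bundles the vector field, analytic Jacobian and parameter
## derivative for one free parameter, so the same machinery serves the
## 10-dimensional single column and the 20-dimensional two-column model.

cmodel_single <- function(params, vary = "phi_e1") {
  force(params); force(vary)
  setp <- function(lam) {
    params$inputs[[vary]] <- lam
    params
  }
  list(
    n = 10,
    f    = function(y, lam) lanmm_rhs(y, setp(lam)),
    jac  = function(y, lam) lanmm_jacobian(y, setp(lam)),
    dfdp = function(y, lam) lanmm_dfdp(y, setp(lam), vary),
    observe = function(y, lam) lanmm_observables(y, setp(lam)),
    setp = setp, vary = vary
  )
}

## damped Newton for f(y) = 0 with analytic Jacobian
newton_solve <- function(f, jac, y, tol = 1e-11, maxit = 50) {
  for (i in seq_len(maxit)) {
    fv <- f(y)
    if (max(abs(fv)) < tol) return(list(y = y, ok = TRUE, res = max(abs(fv))))
    step <- tryCatch(solve(jac(y), fv), error = function(e) NULL)
    if (is.null(step)) return(list(y = y, ok = FALSE, res = max(abs(fv))))
    lam <- 1
    f0 <- sum(fv^2)
    repeat {
      yn <- y - lam * step
      fn <- f(yn)
      if (all(is.finite(fn)) && sum(fn^2) < f0 || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- yn
  }
  list(y = y, ok = max(abs(f(y))) < 1e-9, res = max(abs(f(y))))
}

#' Locate an equilibrium of the laminar model
#'
#' Damped-Newton solve of the stationarity condition with the analytic
#' Jacobian, starting from \code{guess}.  Stability is read off the
#' Jacobian eigenvalues at the solution.
#'
#' @param params a [lanmm_params()] object (inputs fixed).
#' @param guess starting state; the zero state by default.
#' @param tol residual tolerance (max-norm of the vector field).
#' @return an object of class \code{lanmm_equilibrium}: list with
#'   \code{state}, \code{eigenvalues} (10 complex), \code{stable},
#'   \code{residual}, \code{phi_e1}, \code{phi_e2}.
#' @export
find_equilibrium <- function(params, guess = rep(0, 10), tol = 1e-11) {
  sol <- newton_solve(function(y) lanmm_rhs(y, params),
                      function(y) lanmm_jacobian(y, params), guess, tol)
  if (!sol$ok)
    stop("Newton did not converge to an equilibrium (residual ",
         signif(sol$res, 3), ")")
  ev <- eigen(lanmm_jacobian(sol$y, params), only.values = TRUE)$values
  structure(list(state = sol$y, eigenvalues = ev,
                 stable = all(Re(ev) < 0), residual = sol$res,
                 phi_e1 = params$inputs$phi_e1,
                 phi_e2 = params$inputs$phi_e2),
            class = "lanmm_equilibrium")
}

#' @export
print.lanmm_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium at (phi_e1 = %g, phi_e2 = %g): %s, max Re(lambda) = %.4g\n",
              x$phi_e1, x$phi_e2, if (x$stable) "stable" else "unstable",
              max(Re(x$eigenvalues))))
  invisible(x)
}

## one weighted pseudo-arclength corrector step; returns NULL on failure
pals_correct <- function(model, y, lam, t_y, t_l, h, ws, wp,
                         tol = 1e-10, maxit = 12) {
  yg <- y + h * t_y
  lg <- lam + h * t_l
  for (it in seq_len(maxit)) {
    fv <- model$f(yg, lg)
    g <- ws^2 * sum((yg - y) * t_y) + wp^2 * (lg - lam) * t_l - h
    if (all(is.finite(fv)) && max(abs(fv)) < tol && abs(g) < tol) {
      ## guard against corrector convergence onto a different branch:
      ## the accepted point must stay near the predictor
      dist <- sqrt(ws^2 * sum((yg - y - h * t_y)^2) +
                     wp^2 * (lg - lam - h * t_l)^2)
      if (dist > 3 * h + 1e-3) return(NULL)
      return(list(y = yg, lam = lg, iters = it))
    }
    A <- rbind(cbind(model$jac(yg, lg), model$dfdp(yg, lg)),
               c(ws^2 * t_y, wp^2 * t_l))
    d <- tryCatch(solve(A, c(fv, g)), error = function(e) NULL)
    if (is.null(d) || !all(is.finite(d))) return(NULL)
    yg <- yg - d[seq_len(model$n)]
    lg <- lg - d[model$n + 1]
  }
  NULL
}

#' Continue an equilibrium branch in one input parameter
#'
#' Secant-predictor, pseudo-arclength Newton-corrector continuation of
#' the equilibrium curve, with weighted arclength so that S-shaped
#' branches are traversed through their folds rather than jumped.  The
#' step adapts on corrector iteration count.  Eigenvalues of the dense
#' Jacobian are attached at every accepted point.
#'
#' @param params a [lanmm_params()] object; the non-varied input stays
#'   at its value in \code{params}.
#' @param vary which input rate to vary (\code{"phi_e1"} or
#'   \code{"phi_e2"}).
#' @param range length-2 parameter interval to cover.  Continuation
#'   starts from an equilibrium at \code{range[1]} and stops when the
#'   branch leaves \code{[range[1] - slack, range[2]]}.
#' @param step initial arclength step (rate units).
#' @param max_step,min_step step bounds; the step doubles after easy
#'   corrector solves and halves on failure.
#' @param state_weight weight of state components relative to the
#'   parameter in the arclength norm.
#' @param guess starting state guess at \code{range[1]}.
#' @param max_points safety bound on branch length.
#' @param model internal: an alternative system interface (used by the
#'   two-column model); overrides \code{params}/\code{vary}.
#' @param slack how far outside \code{range} a folded branch may run
#'   before continuation stops.
#' @param start parameter value of the starting equilibrium (defaults
#'   to \code{range[1]}).
#' @param direction +1 to move initially toward larger parameter
#'   values, -1 toward smaller (used to pick up disconnected upper
#'   branches from the high end of the range).
#' @return a \code{lanmm_eq_branch}: data frame with columns
#'   \code{param} (the varied rate), \code{vP1}, \code{vP2},
#'   \code{stable}, \code{max_re} (leading eigenvalue real part),
#'   \code{tangent_param}; attributes \code{states} (matrix),
#'   \code{eigenvalues} (list), \code{vary}, \code{model},
#'   \code{params}.
#' @export
continue_equilibria <- function(params, vary = "phi_e1",
                                range = c(0, 600), step = 0.5,
                                max_step = 4, min_step = 1e-4,
                                state_weight = 20, guess = rep(0, 10),
                                max_points = 20000, model = NULL,
                                slack = 200, start = range[1],
                                direction = 1) {
  if (is.null(model)) model <- cmodel_single(params, vary)
  ws <- state_weight; wp <- 1
  lam <- start
  sol <- newton_solve(function(y) model$f(y, lam),
                      function(y) model$jac(y, lam), guess)
  if (!sol$ok) stop("no converged starting equilibrium at ", lam)
  y <- sol$y

  t_y <- tryCatch(-solve(model$jac(y, lam), model$dfdp(y, lam)),
                  error = function(e) rep(0, model$n))
  t_l <- 1
  nz <- sqrt(ws^2 * sum(t_y^2) + wp^2 * t_l^2)
  t_y <- direction * t_y / nz; t_l <- direction * t_l / nz

  pts <- vector("list", 512)
  np <- 0
  h <- step
  repeat {
    ev <- eigen(model$jac(y, lam), only.values = TRUE)$values
    obs <- model$observe(y, lam)
    np <- np + 1
    if (np > length(pts)) pts <- c(pts, vector("list", length(pts)))
    pts[[np]] <- list(lam = lam, y = y, ev = ev, tl = t_l, obs = obs,
                      res = max(abs(model$f(y, lam))))
    if (lam > range[2] + slack * (direction < 0) ||
        lam < range[1] - slack || np >= max_points) break
    ok <- NULL
    while (is.null(ok)) {
      ok <- pals_correct(model, y, lam, t_y, t_l, h, ws, wp)
      if (is.null(ok)) {
        h <- h / 2
        if (h < min_step)
          stop("corrector failed repeatedly at parameter = ", signif(lam, 6))
      }
    }
    nt_y <- ok$y - y; nt_l <- ok$lam - lam
    nz <- sqrt(ws^2 * sum(nt_y^2) + wp^2 * nt_l^2)
    t_y <- nt_y / nz; t_l <- nt_l / nz
    y <- ok$y; lam <- ok$lam
    if (ok$iters <= 4) h <- min(h * 1.4, max_step)
  }
  pts <- pts[seq_len(np)]
  df <- data.frame(
    param = vapply(pts, `[[`, numeric(1), "lam"),
    vP1 = vapply(pts, function(z) z$obs[[1]], numeric(1)),
    vP2 = vapply(pts, function(z) z$obs[[2]], numeric(1)),
    max_re = vapply(pts, function(z) max(Re(z$ev)), numeric(1)),
    tangent_param = vapply(pts, `[[`, numeric(1), "tl"),
    residual = vapply(pts, `[[`, numeric(1), "res")
  )
  df$stable <- df$max_re < 0
  structure(df, class = c("lanmm_eq_branch", "data.frame"),
            states = t(vapply(pts, `[[`, numeric(model$n), "y")),
            eigenvalues = lapply(pts, `[[`, "ev"),
            vary = model$vary, model = model, params = params,
            state_weight = state_weight)
}

#' @export
print.lanmm_eq_branch <- function(x, ...) {
  bif <- attr(x, "bifurcations")
  cat(sprintf("Equilibrium branch in %s: %d points over [%.4g, %.4g], %d stable\n",
              attr(x, "vary"), nrow(x), min(x$param), max(x$param),
              sum(x$stable)))
  if (!is.null(bif) && nrow(bif) > 0) {
    cat("Detected bifurcations:\n")
    for (i in seq_len(nrow(bif)))
      cat(sprintf("  %-6s at %s = %.4f\n", bif$kind[i], attr(x, "vary"),
                  bif$param[i]))
  }
  invisible(x)
}

#' @export
plot.lanmm_eq_branch <- function(x, channel = "vP1", ...) {
  v <- x[[channel]]
  graphics::plot(x$param, v, type = "n", xlab = attr(x, "vary"),
                 ylab = paste(channel, "(mV)"), ...)
  graphics::points(x$param[x$stable], v[x$stable], pch = 16, cex = 0.3)
  graphics::points(x$param[!x$stable], v[!x$stable], pch = 1, cex = 0.3,
                   col = "grey60")
  invisible(x)
}

## bisection refinement along the secant between two accepted branch
## points; testfun maps (y, lam, eigenvalues) to a signed scalar
refine_on_segment <- function(model, p_a, p_b, testfun, ws, wp = 1,
                              iters = 45) {
  dir_y <- p_b$y - p_a$y
  dir_l <- p_b$lam - p_a$lam
  nz <- sqrt(ws^2 * sum(dir_y^2) + wp^2 * dir_l^2)
  t_y <- dir_y / nz; t_l <- dir_l / nz
  f_a <- testfun(p_a$y, p_a$lam, p_a$ev)
  lo <- 0; hi <- nz
  point <- p_a
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cor <- pals_correct(model, p_a$y, p_a$lam, t_y, t_l, mid, ws, wp)
    if (is.null(cor)) break
    ev <- eigen(model$jac(cor$y, cor$lam), only.values = TRUE)$values
    f_m <- testfun(cor$y, cor$lam, ev)
    point <- list(y = cor$y, lam = cor$lam, ev = ev)
    if (sign(f_m) == sign(f_a)) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-9 * max(1, abs(p_a$lam))) break
  }
  point
}

branch_points <- function(branch) {
  states <- attr(branch, "states")
  evs <- attr(branch, "eigenvalues")
  lapply(seq_len(nrow(branch)), function(i)
    list(y = states[i, ], lam = branch$param[i], ev = evs[[i]],
         tl = branch$tangent_param[i]))
}

## test functions: fold = tangent parameter component (sign change across
## the fold); hopf = real part of the k-th complex eigenvalue pair
## (ranked by real part).  Per-pair tracking is essential: a pair can
## cross the axis while another pair is already unstable, which a
## max-real-part test would never see.
hopf_testval <- function(ev, min_im = 1) {
  cv <- ev[abs(Im(ev)) > min_im]
  if (!length(cv)) return(-Inf)
  max(Re(cv))
}

## real parts of the complex pairs, decreasing (one entry per pair)
pair_re <- function(ev, min_im = 1) {
  sort(Re(ev[Im(ev) > min_im]), decreasing = TRUE)
}

hopf_testval_k <- function(ev, k, min_im = 1) {
  pr <- pair_re(ev, min_im)
  if (length(pr) < k) return(-Inf)
  pr[k]
}

#' Detect fold and Hopf bifurcations along an equilibrium branch
#'
#' Folds are located where the branch tangent reverses its parameter
#' component (a real eigenvalue crossing zero); Hopf points where the
#' leading complex-conjugate eigenvalue pair crosses the imaginary axis
#' with nonzero frequency.  Each detection is refined by bisection along
#' the branch segment that brackets it.  Hopf criticality is decided by
#' a probe simulation just past the point (a stable small-amplitude
#' cycle marks a supercritical Hopf).
#'
#' @param branch a [continue_equilibria()] result.
#' @param refine bisection-refine each detection (default \code{TRUE}).
#' @param classify_hopf probe Hopf criticality by simulation (only
#'   available for the single-column model).
#' @return a data frame with columns \code{kind} (\code{"fold"},
#'   \code{"hopf_super"}, \code{"hopf_sub"} or \code{"hopf"}),
#'   \code{param}, \code{frequency} (Hz, Hopf only), \code{diagnostic}
#'   (eigenvalue real part at detection) and the refined \code{state}
#'   rows in attribute \code{states}.
#' @export
detect_codim1 <- function(branch, refine = TRUE, classify_hopf = TRUE) {
  model <- attr(branch, "model")
  ws <- attr(branch, "state_weight")
  pts <- branch_points(branch)
  n <- length(pts)
  out <- list()
  if (n >= 3) {
    tl <- branch$tangent_param
    npair_max <- max(vapply(pts, function(z) length(pair_re(z$ev)),
                            integer(1)))
    for (i in seq_len(n - 1)) {
      if (sign(tl[i]) != sign(tl[i + 1]) && tl[i] != 0) {
        ## fold: bisection on the tangent parameter component requires
        ## tangent info; bracket using corrector steps and the secant
        ## parameter extremum instead
        pt <- if (refine)
          refine_fold(model, pts[[i]], pts[[i + 1]], ws) else
            pts[[if (abs(tl[i]) < abs(tl[i + 1])) i else i + 1]]
        out[[length(out) + 1]] <-
          list(kind = "fold", param = pt$lam, frequency = NA_real_,
               diagnostic = min(abs(Re(pt$ev))), state = pt$y)
      }
      for (k in seq_len(npair_max)) {
        v_a <- hopf_testval_k(pts[[i]]$ev, k)
        v_b <- hopf_testval_k(pts[[i + 1]]$ev, k)
        if (!is.finite(v_a) || !is.finite(v_b) ||
            sign(v_a) == sign(v_b) || v_a == 0) next
        pt <- if (refine)
          refine_on_segment(model, pts[[i]], pts[[i + 1]],
                            function(y, lam, ev) hopf_testval_k(ev, k),
                            ws)
        else pts[[i]]
        vk <- hopf_testval_k(pt$ev, k)
        cv <- pt$ev[Im(pt$ev) > 1]
        cv <- cv[order(-Re(cv))]
        freq <- if (length(cv) >= k) Im(cv[k]) / (2 * pi) else NA_real_
        ## a genuine Hopf refines onto the imaginary axis with nonzero
        ## frequency; eigenvalue-pair collisions at folds do not
        genuine <- !refine || (is.finite(vk) && abs(vk) < 0.1 &&
                                 is.finite(freq) && freq > 0.2)
        dup <- any(vapply(out, function(z)
          z$kind == "hopf" && abs(z$param - pt$lam) < 1e-3, logical(1)))
        if (genuine && !dup)
          out[[length(out) + 1]] <-
            list(kind = "hopf", param = pt$lam, frequency = freq,
                 diagnostic = vk, state = pt$y)
      }
    }
  }
  if (!length(out))
    return(data.frame(kind = character(), param = numeric(),
                      frequency = numeric(), diagnostic = numeric()))
  df <- data.frame(
    kind = vapply(out, `[[`, character(1), "kind"),
    param = vapply(out, `[[`, numeric(1), "param"),
    frequency = vapply(out, `[[`, numeric(1), "frequency"),
    diagnostic = vapply(out, `[[`, numeric(1), "diagnostic")
  )
  states <- t(vapply(out, `[[`, numeric(model$n), "state"))
  if (classify_hopf && !is.null(attr(branch, "params")) &&
      model$n == 10) {
    for (i in which(df$kind == "hopf")) {
      crit <- tryCatch(
        hopf_criticality(attr(branch, "params"), attr(branch, "vary"),
                         df$param[i], states[i, ]),
        error = function(e) "hopf")
      df$kind[i] <- crit
    }
  }
  ord <- order(df$param)
  df <- df[ord, , drop = FALSE]
  attr(df, "states") <- states[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

## locate a fold by bisection on the sign of the tangent parameter
## component, tracked via successive corrector steps from p_a
refine_fold <- function(model, p_a, p_b, ws, wp = 1, iters = 45) {
  dir_y <- p_b$y - p_a$y; dir_l <- p_b$lam - p_a$lam
  nz <- sqrt(ws^2 * sum(dir_y^2) + wp^2 * dir_l^2)
  t_y <- dir_y / nz; t_l <- dir_l / nz
  lo <- 0; hi <- nz
  best <- p_a
  lam_prev <- p_a$lam
  s_prev <- 0
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cor <- pals_correct(model, p_a$y, p_a$lam, t_y, t_l, mid, ws, wp)
    if (is.null(cor)) break
    ## local tangent parameter component via the bordered system
    J <- model$jac(cor$y, cor$lam)
    A <- rbind(cbind(J, model$dfdp(cor$y, cor$lam)), c(ws^2 * t_y, wp^2 * t_l))
    tv <- tryCatch(solve(A, c(rep(0, model$n), 1)), error = function(e) NULL)
    if (is.null(tv)) break
    dl <- tv[model$n + 1]
    ev <- eigen(J, only.values = TRUE)$values
    best <- list(y = cor$y, lam = cor$lam, ev = ev)
    ## before the fold the branch still moves in the original direction
    if (sign(dl) == sign(p_b$lam - p_a$lam) || dl == 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-10 * nz) break
  }
  best
}

## decide Hopf criticality empirically: simulate just past the point on
## the unstable side and look for a small-amplitude saturated cycle
hopf_criticality <- function(params, vary, lam_h, state_h,
                             delta = 8, t_probe = 15) {
  amp_at <- function(lam) {
    p <- params
    p$inputs[[vary]] <- lam
    eq <- tryCatch(find_equilibrium(p, guess = state_h),
                   error = function(e) NULL)
    y0 <- if (is.null(eq)) state_h else eq$state
    if (!is.null(eq) && eq$stable) return(NA_real_)  # wrong side
    y0 <- y0 + 1e-3
    ts <- simulate_lanmm(p, solver_settings(t_transient = t_probe,
                                            t_record = 3), init = y0)
    diff(range(ts$vP1))
  }
  a_hi <- amp_at(lam_h + delta)
  a_lo <- amp_at(lam_h - delta)
  side <- if (is.na(a_hi)) -1 else if (is.na(a_lo)) 1 else
    if (a_hi < a_lo) 1 else -1
  a1 <- if (side > 0) a_hi else a_lo
  if (is.na(a1)) return("hopf")
  a2 <- amp_at(lam_h + side * delta / 4)
  if (is.na(a2)) return("hopf")
  ## supercritical amplitude shrinks ~ sqrt(offset): expect a2/a1 ~ 1/2
  if (a2 < 0.75 * a1) "hopf_super" else "hopf_sub"
}

#' Classify a fold as a saddle-node on an invariant circle (SNIC)
#'
#' Simulates just past the fold, on the side where the colliding
#' equilibria have vanished.  If a stable large-amplitude periodic orbit
#' exists there and its period grows as the offset shrinks (the period
#' diverges approaching the bifurcation), the fold is relabeled SNIC.
#'
#' @param fold one row of a [detect_codim1()] result with
#'   \code{kind == "fold"} (pass the data frame row and its state via
#'   \code{state}), or simply the fold parameter value.
#' @param params the [lanmm_params()] used for the branch.
#' @param vary the varied input name.
#' @param delta parameter offset past the fold for the probe runs.
#' @param state fold state (optional, speeds up the equilibrium check).
#' @param probe_fn optional probe override: a function of the signed
#'   parameter offset returning \code{list(period, amp)} for the
#'   attractor found there (used to apply the same classification to
#'   systems other than the laminar model).
#' @return a list with \code{kind} (\code{"SNIC"} or \code{"fold"}),
#'   \code{param}, and the probe periods \code{period_far},
#'   \code{period_near} (s).
#' @export
classify_snic <- function(fold, params = NULL, vary = "phi_e1", delta = 4,
                          state = NULL, probe_fn = NULL) {
  lam_f <- if (is.list(fold) || is.data.frame(fold)) fold$param else fold
  ## find the side on which no nearby equilibrium survives
  side <- NA
  if (!is.null(state) && !is.null(params)) {
    for (s in c(1, -1)) {
      p <- params
      p$inputs[[vary]] <- lam_f + s * delta
      eq <- tryCatch(find_equilibrium(p, guess = state),
                     error = function(e) NULL)
      gone <- is.null(eq) || sqrt(sum((eq$state - state)^2)) >
        10 * sqrt(sum(state^2) + 1e-6)
      if (gone) { side <- s; break }
    }
  }
  if (is.na(side)) side <- 1
  probe <- if (!is.null(probe_fn)) function(off) probe_fn(side * off) else
    function(off) {
      p <- params
      p$inputs[[vary]] <- lam_f + side * off
      ts <- simulate_lanmm(p, solver_settings(t_transient = 10,
                                              t_record = 20))
      per <- estimate_period(ts$vP1, attr(ts, "sample_rate"))
      list(period = per, amp = diff(range(ts$vP1)))
    }
  far <- probe(delta)
  near <- probe(delta / 4)
  is_snic <- !is.na(far$period) && !is.na(near$period) &&
    far$amp > 1 && near$amp > 1 && near$period > far$period
  list(kind = if (is_snic) "SNIC" else "fold", param = lam_f,
       period_far = far$period, period_near = near$period)
}

## median period from upward crossings of the mid-range level (robust
## against secondary humps that re-cross the mean within one cycle)
estimate_period <- function(x, fs) {
  if (diff(range(x)) < 1e-6) return(NA_real_)
  x <- x - (max(x) + min(x)) / 2
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  if (length(up) < 3) return(NA_real_)
  stats::median(diff(up)) / fs
}

## fold + Hopf detections over a range, merging an upward continuation
## from range[1] with a downward one from range[2] (the S-shaped curve
## can leave the window before reconnecting to the upper branch)
equilibrium_bifurcations <- function(params, vary = "phi_e1",
                                     range = c(0, 600), model = NULL,
                                     guess = NULL, ...) {
  if (is.null(model)) model <- cmodel_single(params, vary)
  if (is.null(guess)) guess <- rep(0, model$n)
  bif <- NULL
  for (dir in c(1, -1)) {
    br <- tryCatch(
      continue_equilibria(params, vary = vary, range = range,
                          model = model, guess = guess,
                          start = if (dir > 0) range[1] else range[2],
                          direction = dir, ...),
      error = function(e) NULL)
    if (is.null(br)) next
    b <- detect_codim1(br, classify_hopf = FALSE)
    if (is.null(bif)) bif <- b
    else for (i in seq_len(nrow(b))) {
      dup <- any(bif$kind == b$kind[i] & abs(bif$param - b$param[i]) < 0.5)
      if (!dup) bif <- rbind(bif, b[i, ])
    }
  }
  if (is.null(bif))
    return(data.frame(kind = character(), param = numeric(),
                      frequency = numeric(), diagnostic = numeric()))
  bif[order(bif$param), , drop = FALSE]
}

#' Trace a bifurcation locus across the two-input plane
#'
#' Runs the one-parameter detection in \code{phi_e1} for each value of
#' \code{phi_e2} on a grid and collects the matching bifurcation points
#' into a locus.  Where several candidates of the requested kind exist,
#' the one closest in \code{phi_e1} to the previous grid row is kept, so
#' a single locus is followed; grid rows where the bifurcation has left
#' the range are omitted.
#'
#' @param params base parameter set.
#' @param kind \code{"fold"} or \code{"hopf"} (matches any Hopf
#'   criticality label); for \code{"hopf"} use \code{which_hopf} to pick
#'   the first or second crossing when no previous row guides matching.
#' @param grid_phi2 sequence of \code{phi_e2} values.
#' @param range_phi1 continuation range in \code{phi_e1}.
#' @param which_hopf 1 or 2: which Hopf (ordered by \code{phi_e1}) to
#'   seed the locus with.
#' @param freq_range optional \code{c(lo, hi)} Hz: restrict Hopf
#'   candidates to this eigenfrequency window, so that the slow-rhythm
#'   and gamma Hopf loci are followed separately even when they sweep
#'   past each other.
#' @param ... passed to [continue_equilibria()].
#' @return data frame with columns \code{phi_e2}, \code{phi_e1},
#'   \code{kind}, \code{frequency}.
#' @export
trace_locus_2param <- function(params, kind = c("fold", "hopf"),
                               grid_phi2, range_phi1 = c(0, 600),
                               which_hopf = 1, freq_range = NULL, ...) {
  kind <- match.arg(kind)
  rows <- list()
  prev <- NA_real_
  for (p2 in grid_phi2) {
    p <- params
    p$inputs$phi_e2 <- p2
    bif <- equilibrium_bifurcations(p, vary = "phi_e1",
                                    range = range_phi1, ...)
    cand <- if (kind == "fold") bif[bif$kind == "fold", , drop = FALSE]
      else bif[grepl("hopf", bif$kind), , drop = FALSE]
    if (kind == "hopf" && !is.null(freq_range))
      cand <- cand[!is.na(cand$frequency) &
                     cand$frequency >= freq_range[1] &
                     cand$frequency <= freq_range[2], , drop = FALSE]
    cand <- cand[cand$param >= range_phi1[1] & cand$param <= range_phi1[2], ,
                 drop = FALSE]
    if (!nrow(cand)) next
    pick <- if (is.na(prev)) min(which_hopf, nrow(cand)) else
      which.min(abs(cand$param - prev))
    rows[[length(rows) + 1]] <- data.frame(
      phi_e2 = p2, phi_e1 = cand$param[pick], kind = kind,
      frequency = cand$frequency[pick])
    prev <- cand$param[pick]
  }
  if (!length(rows))
    return(data.frame(phi_e2 = numeric(), phi_e1 = numeric(),
                      kind = character(), frequency = numeric()))
  do.call(rbind, rows)
}

#' Export an equilibrium branch as CSV, bifurcations as JSON
#'
#' @param branch a [continue_equilibria()] result.
#' @param path output CSV path; if bifurcations were computed, pass them
#'   via \code{bifurcations} to also write \code{<path>.bif.json}.
#' @param bifurcations optional [detect_codim1()] result.
#' @return \code{path}, invisibly.
#' @export
write_branch_csv <- function(branch, path, bifurcations = NULL) {
  df <- as.data.frame(branch)[, c("param", "vP1", "vP2", "stable", "max_re")]
  names(df)[1] <- attr(branch, "vary")
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(bifurcations))
    jsonlite::write_json(as.data.frame(bifurcations),
                         paste0(path, ".bif.json"), digits = NA,
                         pretty = TRUE)
  invisible(path)
}
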