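#' Solver settings for deterministic integration
#'
#' Defaults resolve 40 Hz gamma with 25 samples per cycle and, after the
#' transient, give 0.02 Hz spectral resolution over the recorded window.
#'
#' @param rel_tol,abs_tol relative/absolute integration tolerances.
#' @param sample_rate output sampling rate, 1/s (at least twice the
#'   highest analyzed frequency).
#' @param t_transient initial stretch discarded before recording, s.
#' @param t_record recorded duration after the transient, s.
#' @param max_step maximum internal step, s.
#' @return a list of class \code{lanmm_settings}.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                            sample_rate = 1000, t_transient = 10,
                            t_record = 50, max_step = Inf) {
  stopifnot(sample_rate > 0, t_transient >= 0, t_record > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 sample_rate = sample_rate, t_transient = t_transient,
                 t_record = t_record, max_step = max_step),
            class = "lanmm_settings")
}

## low-level adaptive integration on a uniform grid (compiled rhs)
integrate_raw <- function(params, times, init, settings,
                          func = "lanmm_derivs", initfunc = "lanmm_initmod",
                          parms = as_parm_vector(params)) {
  out <- deSolve::ode(
    y = init, times = times, func = func, parms = parms,
    dllname = "lanmm", initfunc = initfunc, method = "lsoda",
    rtol = settings$rel_tol, atol = settings$abs_tol,
    hmax = if (is.finite(settings$max_step)) settings$max_step else NULL,
    maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0 || !all(is.finite(out[nrow(out), -1])))
    stop("integration failed or trajectory blew up")
  out
}

#' Simulate the laminar model
#'
#' Adaptive high-order integration (lsoda on the compiled vector field),
#' with an initial transient discarded and the pyramidal observables
#' sampled on a uniform grid.  Deterministic: identical inputs give
#' bit-identical output.
#'
#' @param params a [lanmm_params()] object (its \code{inputs} carry the
#'   operating point).
#' @param settings a [solver_settings()] object.
#' @param init initial state (length 10); default the zero state.
#' @param keep_states if \code{TRUE}, retain the full state trajectory
#'   in the \code{states} attribute.
#' @return a \code{lanmm_ts}: a data frame with columns \code{t},
#'   \code{vP1}, \code{vP2} (uniform grid at \code{sample_rate}), with
#'   the parameters, settings and final state attached as attributes.
#' @examples
#' \donttest{
#' ts <- simulate_lanmm(lanmm_params(phi_e1 = 250),
#'                      solver_settings(t_transient = 5, t_record = 5))
#' }
#' @export
simulate_lanmm <- function(params, settings = solver_settings(),
                           init = rep(0, 10), keep_states = FALSE) {
  stopifnot(inherits(params, "lanmm_params"), all(is.finite(init)),
            length(init) == 10)
  dt <- 1 / settings$sample_rate
  t_end <- settings$t_transient + settings$t_record
  times <- seq(0, t_end, by = dt)
  out <- integrate_raw(params, times, init, settings)
  keep <- out[, 1] >= settings$t_transient - 1e-12
  y <- out[keep, -1, drop = FALSE]
  C <- unname(params$connectivity)
  ts <- data.frame(
    t = out[keep, 1] - settings$t_transient,
    vP1 = C[1] * y[, 2] + C[2] * y[, 3] + C[11] * y[, 4],
    vP2 = C[6] * y[, 4] + C[7] * y[, 5] + C[12] * y[, 1]
  )
  structure(ts, class = c("lanmm_ts", "data.frame"),
            params = params, settings = settings,
            sample_rate = settings$sample_rate,
            final_state = unname(y[nrow(y), ]),
            states = if (keep_states) unname(y) else NULL)
}

#' Response to a brief input pulse
#'
#' Initializes the column at its resting fixed point with both inputs
#' off, raises both input rates to \code{pulse_rate} for
#' \code{pulse_width} seconds, and records the relaxation back to rest.
#' The superficial population responds faster and more strongly than the
#' deep one, then both decay through damped oscillations.
#'
#' @inheritParams simulate_lanmm
#' @param pulse_width pulse duration, s.
#' @param pulse_rate input rate during the pulse, 1/s.
#' @param t_record relaxation window recorded after pulse onset, s.
#' @return a \code{lanmm_ts} (DC not removed; see [remove_dc()]).
#' @export
pulse_response <- function(params = lanmm_params(), pulse_width = 1e-3,
                           pulse_rate = 200, t_record = 2,
                           settings = solver_settings()) {
  p0 <- params
  p0$inputs$phi_e1 <- 0
  p0$inputs$phi_e2 <- 0
  eq <- find_equilibrium(p0)
  if (!eq$stable)
    stop("no stable fixed point at zero input; pulse protocol undefined")
  dt <- 1 / settings$sample_rate
  if (pulse_width <= 0) {
    times <- seq(0, t_record, by = dt)
    y <- matrix(eq$state, nrow = length(times), ncol = 10, byrow = TRUE)
    tgrid <- times
  } else {
    pp <- p0
    pp$inputs$phi_e1 <- pulse_rate
    pp$inputs$phi_e2 <- pulse_rate
    tp <- seq(0, pulse_width, length.out = 21)
    o1 <- integrate_raw(pp, tp, eq$state, settings)
    y1 <- o1[nrow(o1), -1]
    t2 <- seq(pulse_width, t_record, by = dt)
    o2 <- integrate_raw(p0, t2, y1, settings)
    y <- o2[, -1, drop = FALSE]
    tgrid <- o2[, 1]
  }
  C <- unname(params$connectivity)
  ts <- data.frame(
    t = tgrid,
    vP1 = C[1] * y[, 2] + C[2] * y[, 3] + C[11] * y[, 4],
    vP2 = C[6] * y[, 4] + C[7] * y[, 5] + C[12] * y[, 1]
  )
  structure(ts, class = c("lanmm_ts", "data.frame"),
            params = p0, settings = settings,
            sample_rate = settings$sample_rate,
            baseline = lanmm_observables(eq$state, params),
            final_state = unname(y[nrow(y), ]))
}

#' Remove the DC component of a recorded time series
#'
#' Subtracts the mean of each observable channel, centering the signals
#' at v = 0; range widths are unchanged.
#'
#' @param ts a \code{lanmm_ts}.
#' @return the same object with zero-mean \code{vP1}, \code{vP2}.
#' @export
remove_dc <- function(ts) {
  stopifnot(inherits(ts, "lanmm_ts"), nrow(ts) > 0)
  for (ch in c("vP1", "vP2")) ts[[ch]] <- ts[[ch]] - mean(ts[[ch]])
  ts
}

#' @export
print.lanmm_ts <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "LaNMM time series: %d samples at %g 1/s (%.3g s), phi_e1 = %g, phi_e2 = %g\n",
    nrow(x), attr(x, "sample_rate"), nrow(x) / attr(x, "sample_rate"),
    p$inputs$phi_e1, p$inputs$phi_e2))
  cat(sprintf("  vP1 in [%.3f, %.3f] mV, vP2 in [%.3f, %.3f] mV\n",
              min(x$vP1), max(x$vP1), min(x$vP2), max(x$vP2)))
  invisible(x)
}

#' @export
plot.lanmm_ts <- function(x, window = NULL, ...) {
  idx <- if (is.null(window)) seq_len(nrow(x)) else
    which(x$t >= window[1] & x$t <= window[2])
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t[idx], x$vP1[idx], type = "l", xlab = "time (s)",
                 ylab = "vP1 (mV)", ...)
  graphics::plot(x$t[idx], x$vP2[idx], type = "l", xlab = "time (s)",
                 ylab = "vP2 (mV)", ...)
  invisible(x)
}

#' Export a time series as CSV with a JSON sidecar
#'
#' Writes columns \code{t, vP1, vP2} and a \code{<path>.json} sidecar
#' recording the full parameter set and solver settings.
#'
#' @param ts a \code{lanmm_ts}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts)[, c("t", "vP1", "vP2")], path,
                   row.names = FALSE)
  meta <- list(params = params_as_list(attr(ts, "params")),
               settings = unclass(attr(ts, "settings")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
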