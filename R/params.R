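#' Standard parameter set of the laminar neural mass model
#'
#' Constructs the full parameterization of the five-population laminar
#' model: synaptic kernels (AMPA, slow GABA, fast GABA), per-population
#' sigmoid thresholds, the thirteen synaptic contact counts and the two
#' external input rates.  Defaults are the standard values of the model;
#' any field can be overridden by name.
#'
#' @param phi_e1 external input rate to the deep pyramidal population P1
#'   (1/s, nonnegative).
#' @param phi_e2 external input rate to the superficial pyramidal
#'   population P2 (1/s, nonnegative).
#' @param ... named overrides.  Connectivity constants are addressed as
#'   \code{C1} ... \code{C13} (e.g. \code{C7 = 300} weakens the PV to P2
#'   synapse); kernel fields as \code{A_AMPA}, \code{a_AMPA},
#'   \code{A_GABA_slow}, \code{a_GABA_slow}, \code{A_GABA_fast},
#'   \code{a_GABA_fast}; sigmoid fields as \code{v0}, \code{v0_P2},
#'   \code{phi0}, \code{r}.
#'
#' @return An object of class \code{lanmm_params}: a list with elements
#'   \code{kernels} (each with gain \code{A} in mV and rate \code{a} in
#'   1/s), \code{sigmoid} (\code{v0}, \code{v0_P2} in mV, \code{phi0} in
#'   1/s, \code{r} in 1/mV), \code{connectivity} (named numeric,
#'   \code{C1}..\code{C13}) and \code{inputs} (\code{phi_e1},
#'   \code{phi_e2} in 1/s).
#'
#' @examples
#' p <- lanmm_params(phi_e1 = 200, phi_e2 = 90)
#' p$connectivity[["C7"]]
#' @export
lanmm_params <- function(phi_e1 = 0, phi_e2 = 0, ...) {
  p <- list(
    kernels = list(
      AMPA      = list(A = 3.25, a = 100, label = "AMPA"),
      GABA_slow = list(A = -22,  a = 50,  label = "GABA_slow"),
      GABA_fast = list(A = -30,  a = 220, label = "GABA_fast")
    ),
    sigmoid = list(v0 = 6, v0_P2 = 1, phi0 = 2.5, r = 0.56),
    connectivity = c(
      C1 = 108, C2 = 33.7, C3 = 1, C4 = 135, C5 = 33.75, C6 = 70,
      C7 = 550, C8 = 1, C9 = 200, C10 = 100, C11 = 80, C12 = 200, C13 = 30
    ),
    inputs = list(phi_e1 = phi_e1, phi_e2 = phi_e2)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    val <- dots[[nm]]
    if (nm %in% names(p$connectivity)) {
      p$connectivity[[nm]] <- val
    } else if (nm %in% names(p$sigmoid)) {
      p$sigmoid[[nm]] <- val
    } else if (nm %in% c("phi_e1", "phi_e2")) {
      p$inputs[[nm]] <- val
    } else if (grepl("^(A|a)_", nm)) {
      field <- substr(nm, 1, 1)
      kn <- sub("^(A|a)_", "", nm)
      if (!kn %in% names(p$kernels))
        stop("unknown kernel in override: ", nm)
      p$kernels[[kn]][[field]] <- val
    } else {
      stop("unknown parameter override: ", nm)
    }
  }
  validate_lanmm_params(p)
  class(p) <- "lanmm_params"
  p
}

validate_lanmm_params <- function(p) {
  stopifnot(
    p$kernels$AMPA$A > 0,
    p$kernels$GABA_slow$A < 0,
    p$kernels$GABA_fast$A < 0,
    all(vapply(p$kernels, function(k) k$a > 0, logical(1))),
    p$sigmoid$phi0 > 0, p$sigmoid$r > 0,
    all(p$connectivity >= 0), length(p$connectivity) == 13,
    p$inputs$phi_e1 >= 0, p$inputs$phi_e2 >= 0
  )
  invisible(p)
}

#' @export
print.lanmm_params <- function(x, ...) {
  cat("Laminar neural mass model parameters\n")
  for (k in x$kernels)
    cat(sprintf("  %-10s A = %7.2f mV   a = %5.0f 1/s\n", k$label, k$A, k$a))
  cat(sprintf("  sigmoid    v0 = %g mV (P2: %g mV), phi0 = %g 1/s, r = %g 1/mV\n",
              x$sigmoid$v0, x$sigmoid$v0_P2, x$sigmoid$phi0, x$sigmoid$r))
  cat("  connectivity:",
      paste(names(x$connectivity), x$connectivity, sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  inputs     phi_e1 = %g 1/s, phi_e2 = %g 1/s\n",
              x$inputs$phi_e1, x$inputs$phi_e2))
  invisible(x)
}

## Pack parameters into the flat vector layout expected by the C code.
## Order must match src/lanmm.c.
as_parm_vector <- function(p) {
  c(p$kernels$AMPA$A, p$kernels$AMPA$a,
    p$kernels$GABA_slow$A, p$kernels$GABA_slow$a,
    p$kernels$GABA_fast$A, p$kernels$GABA_fast$a,
    unname(p$connectivity),
    p$sigmoid$v0, p$sigmoid$v0_P2, p$sigmoid$phi0, p$sigmoid$r,
    p$inputs$phi_e1, p$inputs$phi_e2)
}

#' Read and write parameter sets as JSON
#'
#' A parameter set serializes to a structured JSON file and reads back
#' bit-exactly.  The canonical standard set ships with the package as
#' \code{system.file("extdata", "table1.json", package = "lanmm")}.
#'
#' @param p an object returned by [lanmm_params()].
#' @param path file path.
#' @return \code{read_lanmm_params} returns a \code{lanmm_params} object;
#'   \code{write_lanmm_params} returns \code{path} invisibly.
#' @export
write_lanmm_params <- function(p, path) {
  stopifnot(inherits(p, "lanmm_params"))
  jsonlite::write_json(params_as_list(p), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

## JSON-friendly representation (named vectors become keyed objects)
params_as_list <- function(p) {
  x <- unclass(p)
  x$connectivity <- as.list(p$connectivity)
  x
}

#' @rdname write_lanmm_params
#' @export
read_lanmm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lanmm_params()
  for (kn in names(p$kernels)) {
    p$kernels[[kn]]$A <- as.numeric(x$kernels[[kn]]$A)
    p$kernels[[kn]]$a <- as.numeric(x$kernels[[kn]]$a)
  }
  p$sigmoid <- lapply(x$sigmoid, as.numeric)
  cv <- unlist(x$connectivity)
  p$connectivity[names(cv)] <- as.numeric(cv)
  p$inputs <- lapply(x$inputs, as.numeric)
  validate_lanmm_params(p)
  p
}
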