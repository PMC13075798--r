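#' Run an experiment from a configuration list or file
#'
#' Dispatches one of the package's experiment kinds from a declarative
#' configuration: \code{"simulate"}, \code{"pulse"}, \code{"branch"},
#' \code{"cycles"}, \code{"map"}, \code{"pac"}, \code{"pvscan"},
#' \code{"twocol"} or \code{"fixtures"}.  Model parameter overrides use
#' dotted keys onto the standard set (e.g. \code{"connectivity.C7"});
#' unknown keys are rejected.  Results, the fully resolved
#' configuration and a manifest with content hashes are written under
#' \code{out_dir}.
#'
#' @param config a named list, or path to a JSON (or YAML, if the yaml
#'   package is installed) configuration file.  Recognized fields:
#'   \code{kind}, \code{phi_e1}, \code{phi_e2}, \code{overrides}
#'   (named list of dotted keys), \code{settings} (fields of
#'   [solver_settings()]), \code{out_dir}, plus kind-specific fields
#'   (\code{vary}, \code{range}, \code{phase_band}, \code{amp_band},
#'   \code{grid1}, \code{grid2}, \code{metric}, \code{c7_values},
#'   \code{phi}, \code{depths}).
#' @return invisibly, a list with the result object and the manifest.
#' @export
lanmm_run <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package needed for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$kind))
  kinds <- c("simulate", "pulse", "branch", "cycles", "map", "pac",
             "pvscan", "twocol", "fixtures")
  kind <- match.arg(config$kind, kinds)
  known <- c("kind", "phi_e1", "phi_e2", "overrides", "settings",
             "out_dir", "vary", "range", "phase_band", "amp_band",
             "grid1", "grid2", "metric", "c7_values", "phi", "depths",
             "seed")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))

  params <- lanmm_params(phi_e1 = config$phi_e1 %||% 0,
                         phi_e2 = config$phi_e2 %||% 0)
  for (key in names(config$overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    leaf <- parts[length(parts)]
    val <- config$overrides[[key]]
    params <- do.call(lanmm_params,
                      c(list(phi_e1 = params$inputs$phi_e1,
                             phi_e2 = params$inputs$phi_e2),
                        stats::setNames(list(val), leaf)))
  }
  settings <- do.call(solver_settings, config$settings %||% list())

  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  files <- character(0)
  result <- switch(kind,
    simulate = {
      ts <- simulate_lanmm(params, settings)
      f <- file.path(out_dir, "timeseries.csv")
      write_timeseries_csv(ts, f)
      files <- c(f, paste0(f, ".json"))
      ts
    },
    pulse = {
      ts <- pulse_response(params, settings = settings)
      f <- file.path(out_dir, "pulse.csv")
      write_timeseries_csv(ts, f)
      files <- c(f, paste0(f, ".json"))
      ts
    },
    branch = {
      br <- continue_equilibria(params, vary = config$vary %||% "phi_e1",
                                range = config$range %||% c(0, 600))
      bif <- detect_codim1(br)
      f <- file.path(out_dir, "branch.csv")
      write_branch_csv(br, f, bif)
      files <- c(f, paste0(f, ".bif.json"))
      list(branch = br, bifurcations = bif)
    },
    cycles = {
      cyc <- cycle_from_simulation(params, vary = config$vary %||% "phi_e1")
      br <- continue_cycles(cyc, range = config$range %||% c(100, 200))
      bif <- detect_cycle_bifurcations(br)
      f <- file.path(out_dir, "cycles.csv")
      write_cycle_branch_csv(br, f, bif)
      files <- c(f, paste0(f, ".bif.json"))
      list(branch = br, bifurcations = bif)
    },
    map = {
      g1 <- config$grid1 %||% seq(0, 600, length.out = 16)
      g2 <- config$grid2 %||% seq(0, 400, length.out = 16)
      mp <- if ((config$metric %||% "freq") == "regime")
        regime_map(params, g1, g2) else frequency_map(params, g1, g2)
      f <- file.path(out_dir, "map.csv")
      utils::write.csv(as.data.frame(mp), f, row.names = FALSE)
      files <- f
      mp
    },
    pac = {
      ts <- simulate_lanmm(params, settings)
      res <- pac_mi(remove_dc(ts),
                    phase_band = config$phase_band %||% c(4, 8),
                    amp_band = config$amp_band %||% c(30, 100))
      f <- file.path(out_dir, "pac.json")
      jsonlite::write_json(res[c("mi", "n_bins", "phase_band",
                                 "amp_band")],
                           f, auto_unbox = TRUE, digits = NA)
      files <- f
      res
    },
    pvscan = {
      sc <- pv_scan(params, c7_values = config$c7_values %||%
                      c(550, 300, 150, 75))
      f1 <- file.path(out_dir, "pv_loci.csv")
      f2 <- file.path(out_dir, "pv_coexistence.csv")
      utils::write.csv(sc$loci, f1, row.names = FALSE)
      utils::write.csv(sc$coexistence, f2, row.names = FALSE)
      files <- c(f1, f2)
      sc
    },
    twocol = {
      tp <- two_column_params(params, phi = config$phi %||% 125)
      ts <- simulate_two_column(tp, settings)
      f <- file.path(out_dir, "twocol.csv")
      utils::write.csv(as.data.frame(ts), f, row.names = FALSE)
      files <- f
      ts
    },
    fixtures = {
      depths <- config$depths %||% c(0, 0.5, 1)
      fl <- character(0)
      for (d in depths) {
        sg <- synthetic_pac_signal(coupling_depth = d,
                                   seed = config$seed %||% 12345)
        f <- file.path(out_dir, sprintf("pac_depth_%03d.csv",
                                        round(100 * d)))
        utils::write.csv(as.data.frame(sg), f, row.names = FALSE)
        fl <- c(fl, f)
      }
      files <- fl
      depths
    })

  resolved <- list(kind = kind, params = params_as_list(params),
                   settings = unclass(settings), config = config)
  cfg_file <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(resolved, cfg_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- data.frame(file = basename(c(files, cfg_file)),
                         md5 = unname(tools::md5sum(c(files, cfg_file))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(list(result = result, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
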