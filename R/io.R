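# Configuration-driven runs and file I/O ---------------------------------
#
# The package is used from R; run_config() binds the modules into
# reproducible, seeded runs driven by a plain list (or JSON file) and
# writes CSV/JSON outputs with a provenance record, so a whole analysis
# can be replayed from one config.

#' Write a dose-response curve as CSV
#'
#' Columns: egf_ng_per_ml, readout, readout_normalized.
#'
#' @param curve a [dose_response()].
#' @param path output file.
#' @export
write_dose_response <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response CSV back
#'
#' @param path file written by [write_dose_response()].
#' @param kind readout kind.
#' @export
read_dose_response <- function(path, kind = "Ub") {
  d <- utils::read.csv(path)
  out <- dose_response(d$egf_ng_per_ml, d$readout, kind = kind)
  out
}

#' Write a species-level state dump as CSV
#'
#' @param state an \code{mpmb_state} or \code{eam_state}.
#' @param path output file.
#' @export
write_state <- function(state, path) {
  utils::write.csv(data.frame(species = names(state$x),
                              abundance = unname(state$x)),
                   path, row.names = FALSE)
  invisible(path)
}

.run_status <- c(ok = 0L, config_error = 1L, model_error = 2L, io_error = 3L)

#' Run a configured analysis
#'
#' @param config named list (or path to a JSON file) with elements
#'   \code{command} ("simulate", "regimes", "generate", "fit",
#'   "sensitivity", "scan"), \code{model} ("mpm", "mpmb", "eam"),
#'   optional \code{scenario}, \code{mutant}, \code{profile},
#'   \code{doses} (list from/to/n), \code{seed}, \code{rtol},
#'   \code{atol}, \code{params} (overrides), and \code{outdir}.
#' @return invisibly a list with \code{status} (0 = success; distinct
#'   codes for configuration, model and IO failures), \code{outputs}
#'   (paths written) and \code{result}.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(jsonlite::read_json(config, simplifyVector = TRUE),
                       error = function(e) e)
    if (inherits(config, "error")) {
      message("config error: ", conditionMessage(config))
      return(invisible(list(status = .run_status[["config_error"]],
                            outputs = character(0))))
    }
  }
  out <- tryCatch(.run_config_impl(config),
                  ubithresh_config_error = function(e) {
                    message("config error: ", conditionMessage(e))
                    list(status = .run_status[["config_error"]],
                         outputs = character(0))
                  },
                  error = function(e) {
                    message("model error: ", conditionMessage(e))
                    list(status = .run_status[["model_error"]],
                         outputs = character(0))
                  })
  invisible(out)
}

.config_stop <- function(...) {
  stop(structure(class = c("ubithresh_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.run_config_impl <- function(config) {
  cmd <- config$command
  valid <- c("simulate", "regimes", "generate", "fit", "sensitivity", "scan")
  if (is.null(cmd) || !cmd %in% valid) {
    .config_stop("unknown command '", cmd, "' (valid: ",
                 paste(valid, collapse = ", "), ")")
  }
  outdir <- config$outdir %||% tempfile("ubithresh_run_")
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    return(list(status = .run_status[["io_error"]], outputs = character(0)))
  }
  seed <- as.integer(config$seed %||% 1L)
  doses <- if (!is.null(config$doses)) {
    do.call(default_dose_grid, lapply(config$doses, as.numeric))
  } else default_dose_grid()
  mutant <- config$mutant %||% "3yplus"
  if (!mutant %in% .mpmb_mutants()) {
    .config_stop("unknown mutant '", mutant, "' (valid: ",
                 paste(.mpmb_mutants(), collapse = ", "), ")")
  }
  scen_names <- c("hela_default", "egfr_kd", "nih_phy", "nih_mov",
                  "nih_hov", "cbl_oe_x100", "l834r")
  scenario <- config$scenario %||% "hela_default"
  if (!scenario %in% scen_names) {
    .config_stop("unknown scenario '", scenario, "' (valid: ",
                 paste(scen_names, collapse = ", "), ")")
  }
  outputs <- character(0)
  result <- NULL
  provenance <- list(package = "ubithresh",
                     version = as.character(utils::packageVersion("ubithresh")),
                     seed = seed, config = config,
                     dose_grid = doses)
  if (cmd == "simulate") {
    model <- config$model %||% "mpmb"
    if (model == "mpm") {
      params <- .apply_overrides(mpm_params(), config$params)
      curve <- mpm_dose_response(params, doses)
    } else if (model == "mpmb") {
      params <- apply_scenario(
        apply_profile(.apply_overrides(mpmb_params(), config$params),
                      config$profile %||% "hela"),
        eam_scenario(scenario))
      curve <- mpmb_dose_response(params, doses, mutant, "Ub")
    } else if (model == "eam") {
      params <- apply_scenario(
        apply_profile(.apply_overrides(eam_params(), config$params),
                      config$profile %||% "hela"),
        eam_scenario(scenario))
      curve <- eam_dose_response(params, doses, mutant, "Ub")
    } else .config_stop("unknown model '", model, "'")
    f <- file.path(outdir, paste0("dose_response_", model, ".csv"))
    write_dose_response(curve, f)
    outputs <- c(outputs, f)
    provenance$x_t <- as.numeric(threshold_xt(curve))
    result <- curve
  } else if (cmd == "regimes") {
    res <- lapply(c("free", "saturated"), function(rg) {
      scan <- regime_rate_scan(rg, n_runs = config$n_runs %||% 1000L,
                               seed = seed)
      f <- file.path(outdir, paste0("regime_", rg, ".csv"))
      utils::write.csv(scan, f, row.names = FALSE)
      outputs <<- c(outputs, f)
      scan
    })
    names(res) <- c("free", "saturated")
    result <- res
  } else if (cmd == "generate") {
    cfg <- generator_config(doses = doses,
                            replicates = as.integer(config$replicates %||% 3L),
                            cv = as.numeric(config$cv %||% 0.10),
                            seed = seed)
    ds <- generate_dose_response(cfg)
    f <- file.path(outdir, "synthetic_dataset.csv")
    utils::write.csv(as.data.frame(ds), f, row.names = FALSE)
    ft <- file.path(outdir, "synthetic_truth.json")
    jsonlite::write_json(attr(ds, "truth"), ft, auto_unbox = TRUE)
    outputs <- c(outputs, f, ft)
    result <- ds
  } else if (cmd == "fit") {
    cfg <- generator_config(seed = seed,
                            cv = as.numeric(config$cv %||% 0.10))
    ds <- generate_dose_response(cfg)
    problem <- default_mpmb_fit_problem(ds, seed = seed)
    fit <- fit_parameters(problem,
                          sa_control = config$sa_control %||% list())
    f <- file.path(outdir, "fit_result.json")
    jsonlite::write_json(list(par = as.list(fit$par),
                              objective = fit$objective,
                              non_identifiable = fit$non_identifiable),
                         f, auto_unbox = TRUE, digits = NA)
    ftr <- file.path(outdir, "fit_trace.csv")
    utils::write.csv(fit$trace, ftr, row.names = FALSE)
    outputs <- c(outputs, f, ftr)
    result <- fit
  } else if (cmd == "sensitivity") {
    params <- apply_profile(.apply_overrides(eam_params(), config$params),
                            config$profile %||% "hela")
    screen <- sensitivity_screen(
      function(p) eam_threshold(p),
      params,
      param_names = config$param_names %||%
        c("k_kin", "k_ptp", "r_total", "k_dim_on", "k_egf_on"))
    f <- file.path(outdir, "sensitivity_xt.csv")
    utils::write.csv(screen, f, row.names = FALSE)
    outputs <- c(outputs, f)
    result <- screen
  } else if (cmd == "scan") {
    params <- apply_profile(.apply_overrides(eam_params(), config$params),
                            config$profile %||% "hela")
    surf <- dose_receptor_surface(params)
    f <- file.path(outdir, "dose_receptor_surface.csv")
    utils::write.csv(surf, f, row.names = FALSE)
    outputs <- c(outputs, f)
    result <- surf
  }
  pf <- file.path(outdir, "provenance.json")
  jsonlite::write_json(provenance, pf, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, pf)
  list(status = .run_status[["ok"]], outputs = outputs, result = result,
       outdir = outdir)
}

.apply_overrides <- function(params, overrides) {
  if (is.null(overrides)) return(params)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) {
    .config_stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
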