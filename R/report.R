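## End-to-end matrix-analysis workflow and report I/O (the pipeline surface
## behind the command-line wrapper in exec/asymkin).

REPORT_SCHEMA_VERSION <- "1.0"

#' Analysis configuration
#'
#' @param seed integer seed forwarded to every stochastic stage (mandatory;
#'   there is no silent default randomness in the workflow).
#' @param mode matrix-fit mode, `"global"` or `"per_curve"`.
#' @param weights weighting scheme, see [fit_options()].
#' @param n_starts optimizer starts per fit.
#' @param lb_tol Lineweaver-Burk intercept agreement tolerance.
#' @param bootstrap_B bootstrap resamples for the donor-saturation
#'   uncertainty (0 disables the bootstrap stage).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(seed, mode = "global", weights = "auto",
                            n_starts = 8, lb_tol = 0.05, bootstrap_B = 0) {
  check_scalar(seed, "seed")
  mode <- match.arg(mode, c("global", "per_curve"))
  structure(list(seed = as.integer(seed), mode = mode, weights = weights,
                 n_starts = n_starts, lb_tol = lb_tol,
                 bootstrap_B = bootstrap_B),
            class = "analysis_config")
}

dataset_digest <- function(dataset) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(as.data.frame(dataset), f, version = 2)
  unname(tools::md5sum(f))
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           value = NULL,
                                           reason = conditionMessage(e)))
  if (!res$ok) {
    report$stages[[name]] <- list(status = "failed", reason = res$reason)
    report$failed <- c(report$failed, name)
  }
  list(report = report, value = res$value, ok = res$ok)
}

#' Run the full matrix-kinetics analysis
#'
#' Executes the pipeline on an assay dataset: global (or per-curve) matrix
#' fit, donor-saturation hyperbola, Hill-coefficient profile with unit-h
#' crossing, Lineweaver-Burk classification, and model selection on the
#' highest-donor acceptor titration. Stage failures are recorded in the
#' report with partial results preserved; the run is deterministic given the
#' configuration seed.
#'
#' @param dataset a `kinetic_dataset` spanning >= 3 donor and >= 5 acceptor
#'   levels.
#' @param config an [analysis_config()].
#' @return an `analysis_report` list (JSON-serializable); see
#'   [write_report()].
#' @export
run_matrix_analysis <- function(dataset, config) {
  stopifnot(inherits(config, "analysis_config"))
  dataset <- kinetic_dataset(as.data.frame(dataset))
  opts <- fit_options(n_starts = config$n_starts, seed = config$seed,
                      weights = config$weights)
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    software = paste0("asymkin ",
                      as.character(utils::packageVersion("asymkin"))),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = list(rows = nrow(dataset), digest = dataset_digest(dataset)),
    options = unclass(config),
    stages = list(),
    failed = character(0)
  )

  st <- run_stage(report, "matrix_fit",
                  global_matrix_fit(dataset, opts, mode = config$mode))
  report <- st$report; mf <- st$value
  if (st$ok) {
    report$stages$matrix_fit <- list(
      status = "ok", mode = mf$mode,
      shared = as.list(mf$shared), shared_se = as.list(mf$shared_se),
      vmax_table = mf$vmax_table, rss = mf$rss, n_obs = mf$n_obs,
      flags = mf$flags)
    if (is.null(mf$donor_saturation)) {
      report$stages$donor_saturation <-
        list(status = "failed",
             reason = paste(grep("donor saturation", mf$flags, value = TRUE),
                            collapse = "; "))
      report$failed <- c(report$failed, "donor_saturation")
    } else {
      ds_fit <- mf$donor_saturation
      boot <- NULL
      if (config$bootstrap_B > 0) {
        boot <- bootstrap_ci(ds_fit, config$bootstrap_B, config$seed)
        boot <- boot$intervals
      }
      report$stages$donor_saturation <- list(
        status = "ok", estimates = as.list(ds_fit$estimates),
        se = as.list(ds_fit$se), flags = ds_fit$flags,
        bootstrap = boot)
    }
    if (is.null(mf$h_profile) || nrow(mf$h_profile) < 2) {
      report$stages$h_profile <- list(status = "failed",
                                      reason = "insufficient donor titrations")
      report$failed <- c(report$failed, "h_profile")
    } else {
      report$stages$h_profile <- list(
        status = "ok", profile = mf$h_profile,
        unit_h_crossing_uM = if (is.null(mf$unit_h)) NULL else mf$unit_h,
        unit_h_reason = if (is.null(mf$unit_h)) "no crossing of h = 1"
        else NULL)
    }
  }

  st <- run_stage(report, "lineweaver_burk",
                  lineweaver_burk_classify(dataset, tol = config$lb_tol))
  report <- st$report
  if (st$ok) {
    report$stages$lineweaver_burk <- list(
      status = "ok", pattern = st$value$pattern, lines = st$value$lines,
      tol = st$value$tol)
  }

  top_u <- max(dataset$donor_uM)
  st <- run_stage(report, "model_selection",
                  model_select(dataset[dataset$donor_uM == top_u, ], opts))
  report <- st$report
  if (st$ok) {
    report$stages$model_selection <- list(
      status = "ok", donor_uM = top_u, selected = st$value$selected,
      ranking = st$value$ranking)
  }

  class(report) <- c("analysis_report", "list")
  report
}

#' Write an analysis report as JSON
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read an analysis report from JSON
#'
#' @param path path written by [write_report()].
#' @return an `analysis_report` list.
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(r) <- c("analysis_report", "list")
  r
}

#' Render an analysis report as a text table
#'
#' @param report an `analysis_report` (or a path to a report JSON).
#' @return character vector of lines, invisibly; printed to the console.
#' @export
render_report <- function(report) {
  if (is.character(report)) report <- read_report(report)
  ln <- c(sprintf("Matrix kinetics analysis (%s, seed %d)",
                  report$software, as.integer(report$seed)),
          sprintf("input: %d rows, md5 %s", report$input$rows,
                  report$input$digest),
          "")
  s <- report$stages
  fmt <- function(x, d = 4) formatC(as.numeric(x), digits = d, format = "g")
  if (!is.null(s$matrix_fit) && identical(s$matrix_fit$status, "ok")) {
    ln <- c(ln, sprintf("Shared acceptor parameters (%s fit):",
                        s$matrix_fit$mode),
            sprintf("  K_S = %s uM   n = %s   x = %s",
                    fmt(s$matrix_fit$shared$K_S),
                    fmt(s$matrix_fit$shared$n), fmt(s$matrix_fit$shared$x)),
            "  v_max per donor level:")
    vt <- as.data.frame(s$matrix_fit$vmax_table)
    ln <- c(ln, sprintf("    U = %6s uM   v_max = %s", fmt(vt$U),
                        fmt(vt$v_max)))
  }
  if (!is.null(s$donor_saturation) &&
        identical(s$donor_saturation$status, "ok")) {
    ln <- c(ln, sprintf("Donor saturation: v_max_inf = %s, K_D = %s uM",
                        fmt(s$donor_saturation$estimates$v_max_inf, 5),
                        fmt(s$donor_saturation$estimates$K_D)))
  }
  if (!is.null(s$h_profile) && identical(s$h_profile$status, "ok")) {
    u <- s$h_profile$unit_h_crossing_uM
    ln <- c(ln, sprintf("Unit Hill coefficient (h = 1) at %s uM acceptor",
                        if (is.null(u)) "no" else fmt(u)))
  }
  if (!is.null(s$lineweaver_burk) &&
        identical(s$lineweaver_burk$status, "ok")) {
    ln <- c(ln, sprintf("Lineweaver-Burk pattern: %s",
                        s$lineweaver_burk$pattern))
  }
  if (!is.null(s$model_selection) &&
        identical(s$model_selection$status, "ok")) {
    ln <- c(ln, sprintf("Model selection (U = %s uM): %s",
                        fmt(s$model_selection$donor_uM),
                        s$model_selection$selected))
  }
  if (length(report$failed) > 0) {
    ln <- c(ln, "", paste("failed stages:",
                          paste(unique(report$failed), collapse = ", ")))
  }
  cat(ln, sep = "\n")
  invisible(ln)
}

#' Export mechanism simulations as CSV files
#'
#' Writes a steady-state acceptor scan and/or a progress-curve time series
#' for a mechanism parameterization, in tidy CSV form.
#'
#' @param params a `mechanism_params` object.
#' @param out_dir output directory (created if missing).
#' @param scan_A acceptor grid for the steady-state scan (`NULL` skips it).
#' @param donor_uM,effector_uM clamped donor/effector concentrations.
#' @param protocol optional [assay_protocol()] for a progress simulation.
#' @return character vector of files written.
#' @export
simulate_to_csv <- function(params, out_dir, scan_A = c(5, 10, 25, 50, 100),
                            donor_uM = 100, effector_uM = 0,
                            protocol = NULL) {
  stopifnot(inherits(params, "mechanism_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(scan_A)) {
    scan <- rate_substrate_scan(params, scan_A, donor_uM, effector_uM)
    f <- file.path(out_dir, "steady_state_scan.csv")
    write.csv(scan, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(protocol)) {
    sim <- simulate_progress(params, protocol)
    long <- data.frame(
      time_min = rep(sim$time, length(ALL_SPECIES)),
      species = rep(ALL_SPECIES, each = nrow(sim)),
      concentration_uM = unlist(sim[ALL_SPECIES], use.names = FALSE))
    f <- file.path(out_dir, "progress_curve.csv")
    write.csv(long, f, row.names = FALSE)
    written <- c(written, f)
  }
  written
}
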