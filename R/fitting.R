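## Weighted nonlinear least-squares machinery for the matrix-kinetics
## workflow. All fits run in log10 parameter space (every parameter is
## positive) through minpack.lm::nls.lm, with seeded multi-start.

PAR_BOUNDS <- list(
  rate = c(1e-6, 1e6),   # v_max-type parameters, nmol/min/mg
  conc = c(1e-3, 1e5),   # K-type parameters, uM
  hill = c(0.1, 6)       # Hill coefficients
)

#' Fitting options
#'
#' @param n_starts number of optimizer starts (>= 1); the first start is a
#'   data-driven heuristic, the rest are seeded log-uniform draws within the
#'   parameter bounds.
#' @param seed integer seed making the multi-start draws reproducible.
#' @param weights `"auto"` (1/variance from replicates when every
#'   concentration has >= 3 replicates with positive spread, else unit
#'   weights), `"unit"`, or `"invvar"`.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param maxfev maximum residual evaluations per start.
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 8, seed = 1, weights = "auto",
                        ftol = 1e-10, ptol = 1e-10, maxfev = 10000) {
  stop_if(n_starts < 1, "n_starts must be >= 1")
  weights <- match.arg(weights, c("auto", "unit", "invvar"))
  structure(list(n_starts = n_starts, seed = seed, weights = weights,
                 ftol = ftol, ptol = ptol, maxfev = maxfev),
            class = "fit_options")
}

## observation weights from replicate spread at each concentration combination
obs_weights <- function(conc_key, rate, scheme) {
  if (scheme == "unit") return(rep(1, length(rate)))
  v <- tapply(rate, conc_key, var)
  nrep <- tapply(rate, conc_key, length)
  usable <- all(nrep >= 3) && all(v > 0)
  if (scheme == "auto" && !usable) return(rep(1, length(rate)))
  stop_if(scheme == "invvar" && !usable,
          "1/variance weights need >= 3 replicates with positive spread ",
          "at every concentration")
  1 / v[as.character(conc_key)]
}

## multi-start Levenberg-Marquardt in log10 space
lm_multistart <- function(resid_fn, start, lower, upper, options) {
  p <- length(start)
  nms <- names(start)
  starts <- list(pmin(pmax(start, lower), upper))
  if (options$n_starts > 1) {
    draws <- with_local_seed(options$seed, {
      matrix(runif((options$n_starts - 1) * p), ncol = p)
    })
    for (i in seq_len(options$n_starts - 1)) {
      s <- 10^(log10(lower) + draws[i, ] * (log10(upper) - log10(lower)))
      starts[[i + 1]] <- setNames(s, nms)
    }
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = options$ftol, ptol = options$ptol,
                                     maxfev = options$maxfev, maxiter = 1000)
  best <- NULL
  start_rss <- rep(NA_real_, length(starts))
  start_est <- matrix(NA_real_, length(starts), p,
                      dimnames = list(NULL, nms))
  for (i in seq_along(starts)) {
    # exploratory starts may exhaust their iteration budget; that is not a
    # user-facing condition, the best start is what counts
    fit <- tryCatch(
      withCallingHandlers(
        minpack.lm::nls.lm(par = log10(starts[[i]]),
                           fn = function(th) resid_fn(setNames(10^th, nms)),
                           lower = log10(lower), upper = log10(upper),
                           control = ctrl),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit)) next
    start_rss[i] <- fit$deviance
    start_est[i, ] <- 10^fit$par
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  stop_if(is.null(best), "non-convergence: all optimizer starts failed")
  list(estimates = setNames(10^best$par, nms), rss = best$deviance,
       info = best$info, niter = best$niter,
       start_rss = start_rss, start_est = start_est)
}

## standard errors via numerical Jacobian of the residual at the optimum
fit_se <- function(resid_fn, est, rss, n_obs) {
  p <- length(est)
  if (n_obs <= p) return(setNames(rep(NA_real_, p), names(est)))
  J <- matrix(NA_real_, n_obs, p)
  for (j in seq_len(p)) {
    h <- abs(est[j]) * 1e-6
    up <- est; up[j] <- up[j] + h
    dn <- est; dn[j] <- dn[j] - h
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * h)
  }
  sigma2 <- rss / (n_obs - p)
  se <- tryCatch(sqrt(diag(solve(crossprod(J))) * sigma2),
                 error = function(e) rep(NA_real_, p))
  setNames(se, names(est))
}

## AICc with k = p + 1 (residual variance). A relative floor on the RSS keeps
## noise-free (interpolating) fits comparable: exact ties resolve by parsimony.
aicc_score <- function(rss, n, p, yscale) {
  k <- p + 1
  rss <- max(rss, n * (1e-10 * yscale)^2)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 0.5)
}

## assemble a kin_fit object; `refit` re-estimates from new responses
## (single start at the base estimate) and is used by the bootstrap
new_kin_fit <- function(model, lmfit, resid_fn, n_obs, weights_used, fitted,
                        residuals, yscale, refit, flags = character(0)) {
  est <- lmfit$estimates
  ok <- is.finite(lmfit$start_rss)
  disp <- if (sum(ok) > 1) {
    rel <- apply(lmfit$start_est[ok, , drop = FALSE], 1,
                 function(r) max(abs(r - est) / pmax(est, 1e-300)))
    stats::median(rel)
  } else NA_real_
  structure(list(
    model = model,
    estimates = est,
    se = fit_se(resid_fn, est, lmfit$rss, n_obs),
    rss = lmfit$rss,
    n_obs = n_obs,
    n_par = length(est),
    aicc = aicc_score(lmfit$rss, n_obs, length(est), yscale),
    convergence = list(info = lmfit$info, iterations = lmfit$niter,
                       start_rss = lmfit$start_rss,
                       multistart_dispersion = disp),
    weights = weights_used,
    fitted = fitted,
    residuals = residuals,
    refit = refit,
    flags = flags
  ), class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("<kin_fit>", x$model, "\n")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(tab, digits = 4)
  cat(sprintf("RSS %.6g on %d observations; AICc %.4g\n",
              x$rss, x$n_obs, x$aicc))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

## shared core for the single-curve fits
fit_curve_core <- function(model, S, rate, model_fn, start, lower, upper,
                           options, flags = character(0)) {
  w <- obs_weights(S, rate, options$weights)
  sw <- sqrt(w)
  resid_fn <- function(par) sw * (model_fn(par, S) - rate)
  lmfit <- lm_multistart(resid_fn, start, lower, upper, options)
  fitted <- model_fn(lmfit$estimates, S)
  refit <- function(rate_new, opts = options) {
    rf <- function(par) sw * (model_fn(par, S) - rate_new)
    l2 <- lm_multistart(rf, lmfit$estimates, lower, upper,
                        fit_options(n_starts = 1, seed = opts$seed,
                                    ftol = opts$ftol, ptol = opts$ptol,
                                    maxfev = opts$maxfev))
    l2$estimates
  }
  new_kin_fit(model, lmfit, resid_fn, length(rate),
              if (all(w == 1)) "unit" else "invvar",
              fitted, rate - fitted, sqrt(mean(rate^2)), refit, flags)
}

## pull acceptor/donor slices out of a kinetic_dataset or plain data.frame
slice_cols <- function(dataset, conc_col) {
  stop_if(!is.data.frame(dataset), "dataset must be a data.frame")
  stop_if(!all(c(conc_col, "rate_nmol_min_mg") %in% names(dataset)),
          "dataset needs columns ", conc_col, " and rate_nmol_min_mg")
  list(S = dataset[[conc_col]], rate = dataset$rate_nmol_min_mg)
}

#' Fit the asymmetric-cooperativity acceptor rate law to a titration
#'
#' Weighted least squares of the two-Hill-coefficient law (see
#' [acceptor_rate()]) on an acceptor titration at a fixed donor level.
#' Multi-start Levenberg-Marquardt in log10 parameter space; deterministic
#' given `options$seed`.
#'
#' @param dataset a `kinetic_dataset` slice (single donor level) or any
#'   data.frame with columns `acceptor_uM` and `rate_nmol_min_mg`.
#' @param options a [fit_options()] list.
#' @return a `kin_fit` with estimates `v_max`, `K_S`, `n`, `x`.
#' @export
fit_acceptor_curve <- function(dataset, options = fit_options()) {
  d <- slice_cols(dataset, "acceptor_uM")
  stop_if(length(unique(d$S)) < 5,
          "insufficient support: need >= 5 distinct acceptor concentrations")
  stop_if(all(d$rate == 0), "all rates are zero")
  start <- c(v_max = 3 * max(d$rate), K_S = stats::median(unique(d$S)),
             n = 1, x = 2)
  lower <- c(PAR_BOUNDS$rate[1], PAR_BOUNDS$conc[1],
             PAR_BOUNDS$hill[1], PAR_BOUNDS$hill[1])
  upper <- c(PAR_BOUNDS$rate[2], PAR_BOUNDS$conc[2],
             PAR_BOUNDS$hill[2], PAR_BOUNDS$hill[2])
  fit_curve_core("acceptor_asymmetric", d$S, d$rate,
                 function(par, S) acceptor_rate(
                   acceptor_params(par["v_max"], par["K_S"],
                                   par["n"], par["x"]), S),
                 start, lower, upper, options)
}

#' Fit the donor Hill law to a titration
#'
#' @param dataset a `kinetic_dataset` slice (single acceptor level) or any
#'   data.frame with columns `donor_uM` and `rate_nmol_min_mg`.
#' @param options a [fit_options()] list.
#' @param fix_h optionally fix the Hill coefficient (e.g. `fix_h = 1` for a
#'   Michaelis-Menten fit).
#' @return a `kin_fit` with estimates `v_max`, `K_U` (and `h` unless fixed).
#' @export
fit_donor_curve <- function(dataset, options = fit_options(), fix_h = NULL) {
  d <- slice_cols(dataset, "donor_uM")
  stop_if(length(unique(d$S)) < 4,
          "insufficient support: need >= 4 distinct donor concentrations")
  stop_if(all(d$rate == 0), "all rates are zero")
  grp <- tapply(d$rate, d$S, mean)
  stop_if(stats::var(grp) == 0,
          "unidentifiable: rates do not vary with donor concentration")
  if (is.null(fix_h)) {
    start <- c(v_max = 1.5 * max(d$rate), K_U = stats::median(unique(d$S)),
               h = 1)
    lower <- c(PAR_BOUNDS$rate[1], PAR_BOUNDS$conc[1], PAR_BOUNDS$hill[1])
    upper <- c(PAR_BOUNDS$rate[2], PAR_BOUNDS$conc[2], PAR_BOUNDS$hill[2])
    fit_curve_core("donor_hill", d$S, d$rate,
                   function(par, S) donor_rate(
                     donor_params(par["v_max"], par["K_U"], par["h"]), S),
                   start, lower, upper, options)
  } else {
    check_scalar(fix_h, "fix_h", lower = 0, strict = TRUE)
    start <- c(v_max = 1.5 * max(d$rate), K_U = stats::median(unique(d$S)))
    fit_curve_core("donor_hill_fixed_h", d$S, d$rate,
                   function(par, S) donor_rate(
                     donor_params(par["v_max"], par["K_U"], fix_h), S),
                   start,
                   c(PAR_BOUNDS$rate[1], PAR_BOUNDS$conc[1]),
                   c(PAR_BOUNDS$rate[2], PAR_BOUNDS$conc[2]), options)
  }
}

#' Fit the classical one-site law (Michaelis-Menten or substrate inhibition)
#'
#' @param dataset data.frame with columns `acceptor_uM`, `rate_nmol_min_mg`.
#' @param inhibition if `TRUE` fit `K_i` as well; otherwise the
#'   Michaelis-Menten reduction (`K_i = Inf`).
#' @param options a [fit_options()] list.
#' @return a `kin_fit`.
#' @export
fit_classic_curve <- function(dataset, inhibition = FALSE,
                              options = fit_options()) {
  d <- slice_cols(dataset, "acceptor_uM")
  stop_if(length(unique(d$S)) < (if (inhibition) 4 else 3),
          "insufficient support for the classical model")
  stop_if(all(d$rate == 0), "all rates are zero")
  if (inhibition) {
    start <- c(v_max = 3 * max(d$rate), K_m = stats::median(unique(d$S)),
               K_i = max(d$S))
    fit_curve_core("classic_si", d$S, d$rate,
                   function(par, S) classic_rate(
                     classic_params(par["v_max"], par["K_m"], par["K_i"]), S),
                   start,
                   c(PAR_BOUNDS$rate[1], PAR_BOUNDS$conc[1],
                     PAR_BOUNDS$conc[1]),
                   c(PAR_BOUNDS$rate[2], PAR_BOUNDS$conc[2],
                     PAR_BOUNDS$conc[2]), options)
  } else {
    start <- c(v_max = 1.5 * max(d$rate), K_m = stats::median(unique(d$S)))
    fit_curve_core("michaelis_menten", d$S, d$rate,
                   function(par, S) classic_rate(
                     classic_params(par["v_max"], par["K_m"], Inf), S),
                   start,
                   c(PAR_BOUNDS$rate[1], PAR_BOUNDS$conc[1]),
                   c(PAR_BOUNDS$rate[2], PAR_BOUNDS$conc[2]), options)
  }
}

#' Fit the donor-saturation hyperbola to a v_max(U) table
#'
#' @param vmax_table data.frame with columns `U` (donor, uM) and `v_max`.
#' @param options a [fit_options()] list.
#' @return a `kin_fit` with estimates `v_max_inf` and `K_D`. Flags:
#'   `"non-saturating"` when the fitted `K_D` exceeds the largest donor level
#'   (wide confidence interval expected), `"K_D at lower boundary"` for
#'   degenerate (constant) input.
#' @export
fit_donor_saturation <- function(vmax_table, options = fit_options()) {
  stop_if(!is.data.frame(vmax_table) ||
            !all(c("U", "v_max") %in% names(vmax_table)),
          "vmax_table needs columns U and v_max")
  U <- vmax_table$U; v <- vmax_table$v_max
  stop_if(length(unique(U)) < 3, "need >= 3 distinct donor levels")
  start <- c(v_max_inf = 1.5 * max(v), K_D = stats::median(unique(U)))
  fit <- fit_curve_core("donor_saturation", U, v,
                        function(par, S) donor_saturation(
                          donor_saturation_params(par["v_max_inf"],
                                                  par["K_D"]), S),
                        start,
                        c(PAR_BOUNDS$rate[1], PAR_BOUNDS$conc[1]),
                        c(PAR_BOUNDS$rate[2], PAR_BOUNDS$conc[2]), options)
  flags <- character(0)
  if (fit$estimates["K_D"] > max(U)) flags <- c(flags, "non-saturating")
  if (fit$estimates["K_D"] <= PAR_BOUNDS$conc[1] * 1.0001)
    flags <- c(flags, "K_D at lower boundary")
  fit$flags <- flags
  fit
}

#' Locate the unit-Hill-coefficient crossing of an h(S) profile
#'
#' Interpolates the (log S, h) profile linearly and returns the acceptor
#' concentration at which h crosses 1 (the point at which the donor titration
#' is exactly hyperbolic). An exact grid hit is returned as-is; `NULL` when
#' the profile never crosses 1.
#'
#' @param h_profile data.frame with columns `S` (strictly increasing, uM)
#'   and `h`.
#' @return crossing concentration (uM) or `NULL`.
#' @export
find_unit_hill <- function(h_profile) {
  stop_if(!is.data.frame(h_profile) ||
            !all(c("S", "h") %in% names(h_profile)),
          "h_profile needs columns S and h")
  stop_if(nrow(h_profile) < 2, "need >= 2 profile points")
  S <- h_profile$S; h <- h_profile$h
  stop_if(is.unsorted(S, strictly = TRUE), "profile must be sorted by S")
  check_conc(S, "S")
  hit <- which(h == 1)
  if (length(hit) > 0) return(S[hit[1]])
  d <- h - 1
  cross <- which(d[-length(d)] * d[-1] < 0)
  if (length(cross) == 0) return(NULL)
  i <- cross[1]
  frac <- (1 - h[i]) / (h[i + 1] - h[i])
  exp(log(S[i]) + frac * (log(S[i + 1]) - log(S[i])))
}

#' Classify the inhibition pattern from double-reciprocal line fits
#'
#' Fits straight lines in Lineweaver-Burk coordinates (1/rate vs 1/donor),
#' one per acceptor level, and classifies the intersection locus: a common
#' y-intercept is competitive, a common x-intercept non-competitive, parallel
#' lines uncompetitive, anything else mixed. Agreement is judged by relative
#' spread within `tol`.
#'
#' @param dataset a `kinetic_dataset` (or data.frame) with donor titrations
#'   at >= 2 acceptor levels, >= 3 donor concentrations each, all rates > 0.
#' @param tol relative agreement tolerance for the intercept/slope loci.
#' @return a list with elements `pattern` (one of "competitive",
#'   "non-competitive", "uncompetitive", "mixed") and `lines` (one row per
#'   acceptor level: slope, intercepts).
#' @export
lineweaver_burk_classify <- function(dataset, tol = 0.05) {
  stop_if(!all(c("acceptor_uM", "donor_uM", "rate_nmol_min_mg") %in%
                 names(dataset)),
          "dataset needs acceptor_uM, donor_uM and rate_nmol_min_mg")
  stop_if(any(dataset$rate_nmol_min_mg <= 0),
          "zero rates cannot be used on a reciprocal plot")
  levels_a <- sort(unique(dataset$acceptor_uM))
  stop_if(length(levels_a) < 2, "need >= 2 acceptor levels")
  lines <- do.call(rbind, lapply(levels_a, function(a) {
    d <- dataset[dataset$acceptor_uM == a, ]
    stop_if(length(unique(d$donor_uM)) < 3,
            "need >= 3 donor concentrations at acceptor ", a, " uM")
    fit <- lm(I(1 / d$rate_nmol_min_mg) ~ I(1 / d$donor_uM))
    b <- unname(coef(fit))
    data.frame(acceptor_uM = a, slope = b[2], y_intercept = b[1],
               x_intercept = -b[1] / b[2])
  }))
  agree <- function(v) {
    (max(v) - min(v)) <= tol * max(mean(abs(v)), 1e-300)
  }
  pattern <- if (agree(lines$y_intercept)) "competitive"
  else if (agree(lines$x_intercept)) "non-competitive"
  else if (agree(lines$slope)) "uncompetitive"
  else "mixed"
  list(pattern = pattern, lines = lines, tol = tol)
}

#' Rank candidate rate laws on an acceptor titration
#'
#' Fits Michaelis-Menten (2 parameters), the classical single-site substrate
#' inhibition law (3), and the asymmetric-cooperativity law (4) to the same
#' slice and ranks them by AICc. Models within 2 AICc units of the best are
#' treated as ties, resolved toward fewer parameters.
#'
#' @param dataset acceptor titration slice (see [fit_acceptor_curve()]).
#' @param options a [fit_options()] list.
#' @return list with `ranking` (data.frame: model, n_par, rss, aicc, daicc),
#'   `fits` (named list of `kin_fit`), and `selected` (model name).
#' @export
model_select <- function(dataset, options = fit_options()) {
  fits <- list(
    michaelis_menten = fit_classic_curve(dataset, FALSE, options),
    classic_si = fit_classic_curve(dataset, TRUE, options),
    acceptor_asymmetric = fit_acceptor_curve(dataset, options)
  )
  ranking <- data.frame(
    model = names(fits),
    n_par = vapply(fits, function(f) f$n_par, integer(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1))
  )
  ranking$daicc <- ranking$aicc - min(ranking$aicc)
  ranking <- ranking[order(ranking$aicc), ]
  rownames(ranking) <- NULL
  tied <- ranking[ranking$daicc < 2, ]
  selected <- tied$model[order(tied$n_par, tied$aicc)][1]
  list(ranking = ranking, fits = fits, selected = selected)
}

#' Residual-resampling bootstrap intervals for a fitted curve
#'
#' Resamples residuals with replacement, refits from the base estimate, and
#' reports percentile (2.5/97.5%) intervals per parameter. Identical seeds
#' give identical intervals.
#'
#' @param fit a `kin_fit`.
#' @param B number of bootstrap resamples (>= 1).
#' @param seed integer seed.
#' @return list with `intervals` (data.frame: parameter, lower, upper),
#'   `estimates` (B x p matrix of resample estimates), `B`, `seed`.
#' @export
bootstrap_ci <- function(fit, B, seed = 1) {
  stopifnot(inherits(fit, "kin_fit"))
  stop_if(!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B),
          "B must be a positive integer")
  est <- with_local_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      y_star <- fit$fitted + sample(fit$residuals, replace = TRUE)
      fit$refit(pmax(y_star, 0))
    }, numeric(fit$n_par)))
  })
  colnames(est) <- names(fit$estimates)
  q <- apply(est, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  list(intervals = data.frame(parameter = colnames(est),
                              lower = q[1, ], upper = q[2, ],
                              row.names = NULL),
       estimates = est, B = B, seed = seed)
}

#' Global fit of the concentration matrix
#'
#' The default global mode fits the acceptor law to every donor level jointly
#' with `K_S`, `n` and `x` shared and a free `v_max` per donor level (the
#' paper-design assumption that acceptor cooperativity is independent of the
#' donor amount); per-curve mode fits each donor level separately and reports
#' the agreement of the shared parameters across levels. Both modes then fit
#' the donor-saturation hyperbola to the v_max(U) table, profile the donor
#' Hill coefficient h against acceptor concentration, and locate the unit-h
#' crossing.
#'
#' @param dataset a `kinetic_dataset` spanning >= 3 donor levels with a valid
#'   acceptor titration (>= 5 distinct acceptor concentrations) each.
#' @param options a [fit_options()] list.
#' @param mode `"global"` (shared-parameter fit, default) or `"per_curve"`.
#' @return an object of class `matrix_fit`: shared estimates with
#'   uncertainties, `vmax_table`, `donor_saturation` fit, `h_profile`,
#'   `unit_h` crossing, per-curve results and agreement report (per-curve
#'   mode), and `flags` for skipped donor levels or failed stages.
#' @export
global_matrix_fit <- function(dataset, options = fit_options(),
                              mode = c("global", "per_curve")) {
  mode <- match.arg(mode)
  stop_if(!all(c("acceptor_uM", "donor_uM", "rate_nmol_min_mg") %in%
                 names(dataset)),
          "dataset needs acceptor_uM, donor_uM and rate_nmol_min_mg")
  flags <- character(0)
  donor_levels <- sort(unique(dataset$donor_uM))
  valid <- donor_levels[vapply(donor_levels, function(u) {
    length(unique(dataset$acceptor_uM[dataset$donor_uM == u])) >= 5
  }, logical(1))]
  skipped <- setdiff(donor_levels, valid)
  if (length(skipped) > 0)
    flags <- c(flags, paste0("donor level(s) without a full acceptor ",
                             "titration skipped: ",
                             paste(skipped, collapse = ", "), " uM"))
  stop_if(length(valid) < 1, "no donor level has a full acceptor titration")
  if (length(valid) < 3)
    flags <- c(flags, paste0("only ", length(valid), " donor level(s) with ",
                             "full titrations; shared-parameter fit is ",
                             "intended for >= 3"))
  d <- dataset[dataset$donor_uM %in% valid, ]
  lev <- match(d$donor_uM, valid)

  if (mode == "global") {
    nlev <- length(valid)
    vnames <- paste0("v_max_", seq_len(nlev))
    key <- interaction(d$acceptor_uM, d$donor_uM, drop = TRUE)
    w <- obs_weights(key, d$rate_nmol_min_mg, options$weights)
    sw <- sqrt(w)
    model_fn <- function(par) {
      r <- d$acceptor_uM / par["K_S"]
      rn <- r^par["n"]
      frac <- rn / (1 + rn + r^par["x"])
      frac[d$acceptor_uM == 0] <- 0
      unname(par[vnames][lev]) * frac
    }
    resid_fn <- function(par) sw * (model_fn(par) - d$rate_nmol_min_mg)
    vstart <- vapply(seq_len(nlev), function(i) {
      3 * max(d$rate_nmol_min_mg[lev == i])
    }, numeric(1))
    start <- c(setNames(vstart, vnames),
               K_S = stats::median(unique(d$acceptor_uM)), n = 1, x = 2)
    lower <- c(rep(PAR_BOUNDS$rate[1], nlev), PAR_BOUNDS$conc[1],
               PAR_BOUNDS$hill[1], PAR_BOUNDS$hill[1])
    upper <- c(rep(PAR_BOUNDS$rate[2], nlev), PAR_BOUNDS$conc[2],
               PAR_BOUNDS$hill[2], PAR_BOUNDS$hill[2])
    lmfit <- lm_multistart(resid_fn, start, lower, upper, options)
    se <- fit_se(function(p) resid_fn(p), lmfit$estimates, lmfit$rss,
                 nrow(d))
    shared <- lmfit$estimates[c("K_S", "n", "x")]
    shared_se <- se[c("K_S", "n", "x")]
    vmax_table <- data.frame(U = valid,
                             v_max = unname(lmfit$estimates[vnames]),
                             se = unname(se[vnames]))
    per_curve <- NULL
    agreement <- NULL
    rss <- lmfit$rss
  } else {
    per_curve <- lapply(valid, function(u) {
      fit_acceptor_curve(d[d$donor_uM == u, ], options)
    })
    names(per_curve) <- paste0("U_", valid)
    ests <- t(vapply(per_curve, function(f) f$estimates, numeric(4)))
    agreement <- data.frame(
      parameter = c("K_S", "n", "x"),
      min = apply(ests[, c("K_S", "n", "x"), drop = FALSE], 2, min),
      max = apply(ests[, c("K_S", "n", "x"), drop = FALSE], 2, max),
      cv = apply(ests[, c("K_S", "n", "x"), drop = FALSE], 2,
                 function(v) sd(v) / mean(v)),
      row.names = NULL)
    shared <- apply(ests[, c("K_S", "n", "x"), drop = FALSE], 2, median)
    shared_se <- setNames(rep(NA_real_, 3), c("K_S", "n", "x"))
    vmax_table <- data.frame(U = valid, v_max = unname(ests[, "v_max"]),
                             se = vapply(per_curve,
                                         function(f) unname(f$se["v_max"]),
                                         numeric(1)))
    rss <- sum(vapply(per_curve, function(f) f$rss, numeric(1)))
  }

  donor_sat <- tryCatch(fit_donor_saturation(vmax_table, options),
                        error = function(e) {
                          flags <<- c(flags, paste("donor saturation stage:",
                                                   conditionMessage(e)))
                          NULL
                        })

  acceptor_levels <- sort(unique(d$acceptor_uM))
  h_rows <- lapply(acceptor_levels, function(a) {
    slice <- d[d$acceptor_uM == a, ]
    if (length(unique(slice$donor_uM)) < 4) return(NULL)
    f <- tryCatch(fit_donor_curve(slice, options), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(S = a, h = unname(f$estimates["h"]),
               K_U = unname(f$estimates["K_U"]),
               v_max = unname(f$estimates["v_max"]))
  })
  h_profile <- do.call(rbind, h_rows)
  unit_h <- if (!is.null(h_profile) && nrow(h_profile) >= 2) {
    find_unit_hill(h_profile)
  } else {
    flags <- c(flags, "h profile unavailable (needs >= 2 acceptor levels ",
               "with donor titrations)")
    NULL
  }

  structure(list(mode = mode, shared = shared, shared_se = shared_se,
                 vmax_table = vmax_table, donor_saturation = donor_sat,
                 h_profile = h_profile, unit_h = unit_h, rss = rss,
                 n_obs = nrow(d), per_curve = per_curve,
                 agreement = agreement, donor_levels = valid,
                 flags = flags),
            class = "matrix_fit")
}

#' @export
print.matrix_fit <- function(x, ...) {
  cat("<matrix_fit>", x$mode, "mode;", length(x$donor_levels),
      "donor levels;", x$n_obs, "observations\n")
  cat("shared: K_S =", format(x$shared["K_S"], digits = 4),
      "uM, n =", format(x$shared["n"], digits = 3),
      ", x =", format(x$shared["x"], digits = 3), "\n")
  if (!is.null(x$donor_saturation)) {
    e <- x$donor_saturation$estimates
    cat("donor saturation: v_max_inf =", format(e["v_max_inf"], digits = 5),
        ", K_D =", format(e["K_D"], digits = 4), "uM\n")
  }
  if (!is.null(x$unit_h))
    cat("unit Hill coefficient at", format(x$unit_h, digits = 4),
        "uM acceptor\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
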