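## Synthetic assay datasets with the statistical structure of the matrix
## kinetics experiments: a 5 x 5 acceptor x donor grid, five technical
## replicates, multiplicative replicate noise truncated at zero.

#' Noise model for synthetic rates
#'
#' @param type `"multiplicative"` (normal, relative scale `cv`) or
#'   `"additive"` (normal, absolute scale `sd`). Rates are truncated at 0.
#' @param cv coefficient of variation (multiplicative type).
#' @param sd standard deviation in rate units (additive type).
#' @param seed integer seed; all generation is deterministic given the seed.
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(type = c("multiplicative", "additive"), cv = 0.08,
                        sd = 0, seed = 1) {
  type <- match.arg(type)
  check_scalar(cv, "cv", lower = 0)
  check_scalar(sd, "sd", lower = 0)
  check_scalar(seed, "seed")
  structure(list(type = type, cv = cv, sd = sd, seed = seed),
            class = "noise_model")
}

apply_noise <- function(v, noise) {
  z <- rnorm(length(v))
  out <- if (noise$type == "multiplicative") v * (1 + noise$cv * z)
  else v + noise$sd * z
  pmax(out, 0)
}

#' Assay design: concentration grids and replication
#'
#' Defaults reproduce the matrix design: acceptor and donor grids of
#' 5, 10, 25, 50 and 100 uM with five technical replicates per cell.
#'
#' @param acceptor_grid acceptor concentrations, uM (sorted, non-negative).
#' @param donor_grid donor concentrations, uM.
#' @param effector_name effector label carried into every row ("" = none).
#' @param effector_grid effector concentrations, uM.
#' @param replicates technical replicates per concentration cell (>= 1).
#' @return a list of class `assay_design`.
#' @export
assay_design <- function(acceptor_grid = c(5, 10, 25, 50, 100),
                         donor_grid = c(5, 10, 25, 50, 100),
                         effector_name = "", effector_grid = 0,
                         replicates = 5) {
  for (g in list(acceptor_grid, donor_grid, effector_grid)) {
    stop_if(length(g) == 0, "grids must be non-empty")
    check_conc(g, "grid")
    stop_if(is.unsorted(g), "grids must be sorted ascending")
  }
  stop_if(!is.character(effector_name) || length(effector_name) != 1L,
          "effector_name must be a single string")
  check_scalar(replicates, "replicates", lower = 1)
  stop_if(replicates != round(replicates), "replicates must be an integer")
  structure(list(acceptor_grid = acceptor_grid, donor_grid = donor_grid,
                 effector_name = effector_name,
                 effector_grid = effector_grid,
                 replicates = as.integer(replicates)),
            class = "assay_design")
}

#' Generating truth for the matrix design
#'
#' Shared acceptor-law parameters plus the donor-saturation hyperbola that
#' sets the per-donor-level v_max. Defaults take the magnitudes of the
#' reported fits (K_S = 20 uM, n = 1, x = 2, v_max_inf = 1157 nmol/min/mg,
#' K_D = 19 uM); they are demo/recovery-test fixtures, not a re-derivation of
#' assay data.
#'
#' @param K_S,n,x shared acceptor-law parameters.
#' @param v_max_inf,K_D donor-saturation hyperbola.
#' @return a list of class `matrix_truth`.
#' @export
matrix_truth <- function(K_S = 20, n = 1, x = 2, v_max_inf = 1157,
                         K_D = 19) {
  sat <- donor_saturation_params(v_max_inf, K_D)
  check_scalar(K_S, "K_S", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 0, strict = TRUE)
  check_scalar(x, "x", lower = 0, strict = TRUE)
  structure(list(K_S = K_S, n = n, x = x, saturation = sat),
            class = "matrix_truth")
}

#' Generate a synthetic concentration-matrix dataset
#'
#' One row per (acceptor, donor, replicate) combination; the noise-free rate
#' is the acceptor law evaluated with `v_max` set by the donor-saturation
#' hyperbola at that donor level. The generating parameters and seed are
#' attached as the `truth` attribute for recovery tests.
#'
#' @param truth a [matrix_truth()] object.
#' @param design an [assay_design()] object.
#' @param noise a [noise_model()] object.
#' @return a `kinetic_dataset` with `truth` attribute.
#' @export
generate_matrix_dataset <- function(truth = matrix_truth(),
                                    design = assay_design(),
                                    noise = noise_model()) {
  stopifnot(inherits(truth, "matrix_truth"), inherits(design, "assay_design"),
            inherits(noise, "noise_model"))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      acceptor_uM = design$acceptor_grid,
                      donor_uM = design$donor_grid)
  vmax_u <- donor_saturation(truth$saturation, grid$donor_uM)
  v <- vapply(seq_len(nrow(grid)), function(i) {
    acceptor_rate(acceptor_params(vmax_u[i], truth$K_S, truth$n, truth$x),
                  grid$acceptor_uM[i])
  }, numeric(1))
  rate <- with_local_seed(noise$seed, apply_noise(v, noise))
  ds <- kinetic_dataset(data.frame(
    acceptor_uM = grid$acceptor_uM, donor_uM = grid$donor_uM,
    effector_name = design$effector_name,
    effector_uM = 0, replicate = grid$replicate,
    rate_nmol_min_mg = rate))
  attr(ds, "truth") <- list(K_S = truth$K_S, n = truth$n, x = truth$x,
                            v_max_inf = truth$saturation$v_max_inf,
                            K_D = truth$saturation$K_D,
                            noise = unclass(noise))
  ds
}

#' Generate an effector dose-response dataset
#'
#' Emulates the reactivation experiment: fixed (inhibitory) acceptor and
#' donor concentrations, increasing effector. The noise-free curve comes
#' either from the mechanism simulator ([steady_state_rate()]) or from a
#' user-supplied empirical curve `function(C) -> rate`.
#'
#' @param truth a `mechanism_params` object or a function of the effector
#'   concentration returning a rate.
#' @param design an [assay_design()] with single-value acceptor and donor
#'   grids and the effector grid of interest.
#' @param noise a [noise_model()].
#' @param rate_scale factor converting simulator turnover (1/min) to the
#'   reported specific rate; ignored for empirical curves.
#' @return a `kinetic_dataset` with `truth` attribute.
#' @export
generate_effector_dataset <- function(truth = reference_mechanism(),
                                      design, noise = noise_model(),
                                      rate_scale = 1) {
  stopifnot(inherits(design, "assay_design"), inherits(noise, "noise_model"))
  stop_if(length(design$acceptor_grid) != 1 || length(design$donor_grid) != 1,
          "effector design needs single fixed acceptor and donor levels")
  A <- design$acceptor_grid; D <- design$donor_grid
  curve_fn <- if (is.function(truth)) truth
  else {
    stopifnot(inherits(truth, "mechanism_params"))
    function(C) rate_scale * steady_state_rate(truth, A, D, C)[["glucoside"]]
  }
  v_by_c <- vapply(design$effector_grid, curve_fn, numeric(1))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      effector_uM = design$effector_grid)
  rate <- with_local_seed(noise$seed,
                          apply_noise(v_by_c[match(grid$effector_uM,
                                                   design$effector_grid)],
                                      noise))
  ds <- kinetic_dataset(data.frame(
    acceptor_uM = A, donor_uM = D,
    effector_name = design$effector_name,
    effector_uM = grid$effector_uM, replicate = grid$replicate,
    rate_nmol_min_mg = rate))
  attr(ds, "truth") <- list(effector_grid = design$effector_grid,
                            noise_free = v_by_c, noise = unclass(noise))
  ds
}

#' Generate a glucohydrolase suppression dataset (no acceptor)
#'
#' Donor-only glucose-release rates versus effector concentration; the
#' noise-free curve is the mechanism's hydrolase flux, monotone
#' non-increasing in the effector.
#'
#' @param params a `mechanism_params` object.
#' @param donor_uM fixed donor concentration, uM.
#' @param effector_grid effector concentrations, uM (sorted).
#' @param noise a [noise_model()].
#' @param effector_name label for the effector column.
#' @param replicates technical replicates.
#' @param rate_scale turnover-to-rate factor as in
#'   [generate_effector_dataset()].
#' @return a `kinetic_dataset` (rates are glucose release).
#' @export
generate_hydrolase_dataset <- function(params = reference_mechanism(),
                                       donor_uM = 100,
                                       effector_grid = c(0, 10, 25, 50, 100),
                                       noise = noise_model(),
                                       effector_name = "effector",
                                       replicates = 5, rate_scale = 1) {
  stopifnot(inherits(params, "mechanism_params"),
            inherits(noise, "noise_model"))
  check_conc(effector_grid, "effector_grid")
  stop_if(is.unsorted(effector_grid), "effector_grid must be sorted")
  check_scalar(donor_uM, "donor_uM", lower = 0)
  hyd <- hydrolase_dose_response(params, donor_uM, effector_grid)
  v_by_c <- rate_scale * hyd$glucose
  grid <- expand.grid(replicate = seq_len(replicates),
                      effector_uM = effector_grid)
  rate <- with_local_seed(noise$seed,
                          apply_noise(v_by_c[match(grid$effector_uM,
                                                   effector_grid)], noise))
  ds <- kinetic_dataset(data.frame(
    acceptor_uM = 0, donor_uM = donor_uM, effector_name = effector_name,
    effector_uM = grid$effector_uM, replicate = grid$replicate,
    rate_nmol_min_mg = rate))
  attr(ds, "truth") <- list(effector_grid = effector_grid,
                            noise_free = v_by_c, noise = unclass(noise))
  ds
}

#' Simulate progress curves for a set of protocols
#'
#' Runs [simulate_progress()] for each protocol and stacks the results in a
#' tidy table (protocol, time, species, concentration), optionally adding
#' measurement noise to the concentrations.
#'
#' @param params a `mechanism_params` object.
#' @param protocols named list of [assay_protocol()] objects.
#' @param times optional shared output time grid.
#' @param noise optional [noise_model()]; `NULL` for noise-free output.
#' @return a data.frame with columns `protocol`, `time_min`, `species`,
#'   `concentration_uM`.
#' @export
generate_progress_dataset <- function(params, protocols, times = NULL,
                                      noise = NULL) {
  stop_if(!is.list(protocols) || length(protocols) == 0 ||
            is.null(names(protocols)) || any(names(protocols) == ""),
          "protocols must be a non-empty named list")
  out <- do.call(rbind, lapply(names(protocols), function(nm) {
    sim <- simulate_progress(params, protocols[[nm]], times = times)
    long <- data.frame(
      protocol = nm,
      time_min = rep(sim$time, length(ALL_SPECIES)),
      species = rep(ALL_SPECIES, each = nrow(sim)),
      concentration_uM = unlist(sim[ALL_SPECIES], use.names = FALSE))
    long
  }))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    out$concentration_uM <- with_local_seed(
      noise$seed, apply_noise(out$concentration_uM, noise))
  }
  rownames(out) <- NULL
  out
}
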