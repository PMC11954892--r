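acceptor_slice <- function(params, grid = c(5, 10, 25, 50, 100, 200, 500),
                           reps = 1, cv = 0, seed = 1) {
  truth <- acceptor_rate(params, rep(grid, each = reps))
  rate <- if (cv > 0) {
    withr::with_seed(seed, pmax(truth * (1 + cv * rnorm(length(truth))), 0))
  } else truth
  data.frame(acceptor_uM = rep(grid, each = reps),
             rate_nmol_min_mg = rate)
}

test_that("acceptor fit recovers generating parameters from noise-free data", {
  p <- acceptor_params(1157, 20, 1, 2)
  fit <- fit_acceptor_curve(acceptor_slice(p))
  expect_rel_equal(fit$estimates,
                   c(v_max = 1157, K_S = 20, n = 1, x = 2), 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$n_obs, 7)
})

test_that("acceptor fit input validation", {
  p <- acceptor_params(1157, 20, 1, 2)
  expect_error(fit_acceptor_curve(acceptor_slice(p, grid = c(5, 10, 25))),
               "insufficient support")
  d <- acceptor_slice(p); d$rate_nmol_min_mg <- 0
  expect_error(fit_acceptor_curve(d), "zero")
})

test_that("acceptor fit is deterministic given the seed and robust to noise", {
  p <- acceptor_params(1157, 20, 1, 2)
  d <- acceptor_slice(p, grid = c(5, 10, 25, 50, 100), reps = 5, cv = 0.05,
                      seed = 3)
  f1 <- fit_acceptor_curve(d, fit_options(seed = 9))
  f2 <- fit_acceptor_curve(d, fit_options(seed = 9))
  expect_identical(f1$estimates, f2$estimates)
  expect_rel_equal(f1$estimates["K_S"], 20, 0.35)
})

test_that("donor fit: noise-free recovery, fixed-h reduction, degeneracies", {
  p <- donor_params(800, 19, 1.3)
  grid <- c(2, 5, 10, 19, 40, 80, 160)
  d <- data.frame(donor_uM = grid, rate_nmol_min_mg = donor_rate(p, grid))
  fit <- fit_donor_curve(d)
  expect_rel_equal(fit$estimates, c(v_max = 800, K_U = 19, h = 1.3), 1e-6)

  # h fixed at 1 is exactly the Michaelis-Menten fit of the same data
  mm_truth <- classic_params(500, 25, Inf)
  d_mm <- data.frame(donor_uM = grid,
                     rate_nmol_min_mg = classic_rate(mm_truth, grid))
  f_hill <- fit_donor_curve(d_mm, fix_h = 1)
  d_mm2 <- data.frame(acceptor_uM = grid,
                      rate_nmol_min_mg = d_mm$rate_nmol_min_mg)
  f_mm <- fit_classic_curve(d_mm2, inhibition = FALSE)
  expect_rel_equal(unname(f_hill$estimates), unname(f_mm$estimates), 1e-6)

  d_flat <- data.frame(donor_uM = grid, rate_nmol_min_mg = rep(7, 7))
  expect_error(fit_donor_curve(d_flat), "unidentifiable")
  expect_error(fit_donor_curve(d[1:3, ]), "insufficient support")
})

test_that("donor-saturation fit: exact recovery, degeneracies, flags", {
  U <- c(5, 10, 25, 50, 100)
  tab <- data.frame(U = U, v_max = donor_saturation(
    donor_saturation_params(1157, 19), U))
  fit <- fit_donor_saturation(tab)
  expect_rel_equal(fit$estimates, c(v_max_inf = 1157, K_D = 19), 1e-8)
  expect_length(fit$flags, 0)

  flat <- data.frame(U = U, v_max = rep(300, 5))
  fit_flat <- fit_donor_saturation(flat)
  expect_true("K_D at lower boundary" %in% fit_flat$flags)

  expect_error(fit_donor_saturation(tab[1:2, ]), ">= 3")

  # barely-saturating data: K_D beyond the measured range is flagged
  far <- data.frame(U = U, v_max = donor_saturation(
    donor_saturation_params(2000, 400), U))
  expect_true("non-saturating" %in% fit_donor_saturation(far)$flags)
})

test_that("unit-Hill crossing is located by log-linear interpolation", {
  prof <- data.frame(S = c(5, 10, 25, 50), h = c(0.8, 0.95, 1.1, 1.4))
  # hand interpolation: log S* = log 10 + (1/3)(log 25 - log 10)
  expect_equal(find_unit_hill(prof), 10 * 2.5^(1 / 3), tolerance = 1e-12)
  expect_equal(round(find_unit_hill(prof), 1), 13.6)

  expect_null(find_unit_hill(data.frame(S = c(5, 50), h = c(1.2, 1.2))))
  expect_identical(find_unit_hill(data.frame(S = c(5, 20, 50),
                                             h = c(0.9, 1, 1.3))), 20)
  expect_error(find_unit_hill(data.frame(S = c(10, 5), h = c(1, 2))),
               "sorted")
})

test_that("Lineweaver-Burk patterns follow the textbook constructions", {
  U <- c(5, 10, 20, 50, 100)
  make <- function(vmaxes, kms) {
    do.call(rbind, Map(function(v, k, a) {
      data.frame(acceptor_uM = a, donor_uM = U,
                 rate_nmol_min_mg = classic_rate(classic_params(v, k), U))
    }, vmaxes, kms, seq_along(vmaxes)))
  }
  # same K_m, v_max varies with the acceptor level -> non-competitive
  expect_identical(
    lineweaver_burk_classify(make(c(100, 70, 40), c(20, 20, 20)))$pattern,
    "non-competitive")
  # same v_max, K_m varies -> competitive
  expect_identical(
    lineweaver_burk_classify(make(c(100, 100, 100), c(10, 20, 40)))$pattern,
    "competitive")
  # identical slopes, distinct intercepts -> uncompetitive
  # (v_max and K_m scaled together keep K_m/v_max constant)
  expect_identical(
    lineweaver_burk_classify(make(c(100, 50), c(20, 10)))$pattern,
    "uncompetitive")
  # none of the loci agree -> mixed
  expect_identical(
    lineweaver_burk_classify(make(c(100, 40), c(10, 35)))$pattern,
    "mixed")
  bad <- make(c(100, 50), c(20, 10)); bad$rate_nmol_min_mg[3] <- 0
  expect_error(lineweaver_burk_classify(bad), "reciprocal")
})

test_that("model selection prefers parsimony on ties and finds the true
           model under noise", {
  # noise-free MM data: all models interpolate; MM wins by parsimony
  mm <- classic_params(900, 15, Inf)
  grid <- c(2, 5, 10, 25, 50, 100, 250)
  d <- data.frame(acceptor_uM = grid,
                  rate_nmol_min_mg = classic_rate(mm, grid))
  sel <- model_select(d)
  expect_identical(sel$selected, "michaelis_menten")
  expect_identical(sel$ranking$model[1], "michaelis_menten")

  # with n = 1 and x = 2 the asymmetric law collapses algebraically onto the
  # classical single-site SI law (K_m = K_i = K_S), so the 3-parameter model
  # is the correct parsimonious selection for such data
  p12 <- acceptor_params(1157, 20, 1, 2)
  S <- c(0.5, 5, 20, 80, 300)
  expect_equal(acceptor_rate(p12, S),
               classic_rate(classic_params(1157, 20, 20), S),
               tolerance = 1e-14)
  d12 <- acceptor_slice(p12, grid = c(5, 10, 25, 50, 100), reps = 5,
                        cv = 0.05, seed = 1)
  expect_identical(model_select(d12)$selected, "classic_si")

  # genuinely asymmetric data (x = 3 falls outside the classical family):
  # the asymmetric law should be selected in >= 90% of seeded repetitions
  p <- acceptor_params(1157, 20, 1, 3)
  wins <- sum(vapply(1:100, function(s) {
    d <- acceptor_slice(p, grid = c(5, 10, 25, 50, 100), reps = 5,
                        cv = 0.05, seed = s)
    model_select(d, fit_options(seed = s))$selected == "acceptor_asymmetric"
  }, logical(1)))
  expect_gte(wins, 90)
})

test_that("bootstrap intervals are seeded, degenerate at B = 1, and cover", {
  p <- acceptor_params(1157, 20, 1, 2)
  d <- acceptor_slice(p, grid = c(5, 10, 25, 50, 100), reps = 5, cv = 0.05,
                      seed = 2)
  fit <- fit_acceptor_curve(d)
  b1 <- bootstrap_ci(fit, B = 50, seed = 4)
  b2 <- bootstrap_ci(fit, B = 50, seed = 4)
  expect_identical(b1$intervals, b2$intervals)

  b_single <- bootstrap_ci(fit, B = 1, seed = 4)
  expect_equal(b_single$intervals$lower, b_single$intervals$upper)
  expect_error(bootstrap_ci(fit, B = 0), "positive integer")
})

test_that("bootstrap 95% intervals cover the generating K_S at roughly
           nominal rate", {
  p <- acceptor_params(1157, 20, 1, 2)
  covered <- vapply(1:120, function(s) {
    d <- acceptor_slice(p, grid = c(5, 10, 25, 50, 100), reps = 5,
                        cv = 0.05, seed = 1000 + s)
    fit <- fit_acceptor_curve(d, fit_options(n_starts = 2, seed = s))
    ci <- bootstrap_ci(fit, B = 99, seed = s)
    k <- ci$intervals[ci$intervals$parameter == "K_S", ]
    k$lower <= 20 && 20 <= k$upper
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
})

test_that("global matrix fit: noise-free recovery and v_max monotonicity", {
  ds <- generate_matrix_dataset(noise = noise_model(cv = 0, seed = 1))
  mf <- global_matrix_fit(ds)
  expect_rel_equal(mf$shared, c(K_S = 20, n = 1, x = 2), 1e-4)
  expect_rel_equal(mf$donor_saturation$estimates,
                   c(v_max_inf = 1157, K_D = 19), 1e-4)
  expect_true(all(diff(mf$vmax_table$v_max) > 0))
  expect_length(mf$flags, 0)
})

test_that("global matrix fit flags a missing donor level and gaps", {
  ds <- generate_matrix_dataset(noise = noise_model(cv = 0, seed = 1))
  # cripple one donor level to a 2-point titration
  keep <- !(ds$donor_uM == 50 & ds$acceptor_uM > 10)
  mf <- global_matrix_fit(kinetic_dataset(as.data.frame(ds)[keep, ]))
  expect_true(any(grepl("skipped", mf$flags)))
  expect_identical(mf$donor_levels, c(5, 10, 25, 100))
  expect_rel_equal(mf$shared["K_S"], 20, 1e-4)
})

test_that("per-curve mode reports cross-level agreement of shared
           parameters", {
  ds <- generate_matrix_dataset(noise = noise_model(cv = 0, seed = 1))
  mf <- global_matrix_fit(ds, mode = "per_curve")
  expect_length(mf$per_curve, 5)
  expect_true(all(mf$agreement$cv < 1e-4))
  expect_rel_equal(mf$shared["K_S"], 20, 1e-4)
})

test_that("weighting scheme does not move noise-free fits", {
  ds <- generate_matrix_dataset(noise = noise_model(cv = 0, seed = 1))
  f_unit <- global_matrix_fit(ds, fit_options(weights = "unit"))
  f_auto <- global_matrix_fit(ds, fit_options(weights = "auto"))
  expect_rel_equal(f_unit$shared, f_auto$shared, 1e-6)
})

test_that("global RSS is no worse than vmax-only per-level refits at the
           shared optimum", {
  ds <- generate_matrix_dataset(noise = noise_model(cv = 0.08, seed = 5))
  mf <- global_matrix_fit(ds, fit_options(weights = "unit"))
  sh <- mf$shared
  rss_constrained <- sum(vapply(mf$donor_levels, function(u) {
    d <- ds[ds$donor_uM == u, ]
    vfit <- optimize(function(v) {
      sum((acceptor_rate(acceptor_params(v, sh["K_S"], sh["n"], sh["x"]),
                         d$acceptor_uM) - d$rate_nmol_min_mg)^2)
    }, c(1, 1e5))
    vfit$objective
  }, numeric(1)))
  expect_lte(mf$rss, rss_constrained * (1 + 1e-8))
})
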