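test_that("nothing reacts without ligands; enzyme is conserved", {
  p <- reference_mechanism()
  prot <- assay_protocol(data.frame(time = numeric(0),
                                    species = character(0),
                                    amount = numeric(0)),
                         duration = 10)
  sim <- simulate_progress(p, prot)
  for (sp in setdiff(names(sim), "time")) {
    expect_equal(sim[[sp]], rep(sim[[sp]][1], nrow(sim)), tolerance = 1e-10)
  }
  enz <- rowSums(sim[, c("E", "EA", "ED", "Tnp", "Tp", "EC", "EDC", "EP")])
  expect_true(all(abs(enz - p$E_tot) < 1e-6 * p$E_tot))
})

test_that("closed system conserves the donor moiety", {
  p <- reference_mechanism(E_tot = 0.5)
  prot <- assay_protocol(data.frame(time = c(0, 0),
                                    species = c("A", "D"),
                                    amount = c(20, 10)),
                         duration = 30, clamp = character(0))
  sim <- simulate_progress(p, prot)
  donor_total <- sim$D + sim$ED + sim$Tnp + sim$Tp + sim$EDC +
    sim$glucoside + sim$glucose
  expect_true(all(abs(donor_total - 10) < 1e-6 * 10))
  # product forms and donor is depleted
  expect_gt(sim$glucoside[nrow(sim)], 0)
  expect_lt(sim$D[nrow(sim)], 10)
})

test_that("initial product formation is linear in total enzyme", {
  prot <- assay_protocol(data.frame(time = c(0, 0), species = c("A", "D"),
                                    amount = c(20, 50)),
                         duration = 0.02)
  rate_for <- function(E_tot) {
    sim <- simulate_progress(reference_mechanism(E_tot = E_tot), prot,
                             times = seq(0, 0.02, length.out = 21))
    (sim$glucoside[21] - sim$glucoside[1]) / 0.02
  }
  expect_rel_equal(rate_for(0.02), 2 * rate_for(0.01), 1e-3)
})

test_that("steady-state flux edge cases", {
  p <- reference_mechanism()
  p0 <- p; p0$k_cat <- 0
  expect_equal(steady_state_rate(p0, 50, 50)[["glucoside"]], 0)
  # hydrolase-only regime: donor without acceptor releases glucose only
  fx <- steady_state_rate(p, 0, 100)
  expect_identical(fx[["glucoside"]], 0)
  expect_gt(fx[["glucose"]], 0)
})

test_that("ODE steady state matches the rapid-equilibrium oracle when
           binding is much faster than catalysis", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_fast_binding_mechanism(sep = 1e4)
    A <- 10^runif(1, 0, 2); D <- 10^runif(1, 0, 2); C <- 10^runif(1, 0, 1.5)
    ss <- steady_state_rate(p, A, D, C)
    re <- rapid_equilibrium_rate(p, A, D, C)
    expect_rel_equal(ss[["glucoside"]], re[["glucoside"]], 0.01)
    expect_rel_equal(ss[["glucose"]], re[["glucose"]], 0.01)
  }
})

test_that("rapid-equilibrium fractions match brute-force enumeration", {
  # all dissociation constants equal and A = D = K: every reachable species
  # has an equal Boltzmann weight; enumerate the partition sum directly
  K <- 10
  p <- mechanism_params(kon_EA = 5, koff_EA = 5 * K, kon_ED = 5,
                        koff_ED = 5 * K, kon_Tnp = 5, koff_Tnp = 5 * K,
                        kon_Tp = 5, koff_Tp = 5 * K,
                        k_cat = 1e-3, k_hyd = 1e-4)
  weights <- c(E = 1, EA = K / K, ED = K / K,
               Tnp = (K / K) * (K / K), Tp = (K / K) * (K / K))
  fractions <- weights / sum(weights)
  re <- rapid_equilibrium_rate(p, A = K, D = K)
  expect_equal(re[["glucoside"]], 1e-3 * fractions["Tp"],
               ignore_attr = TRUE)
  expect_equal(re[["glucose"]], 1e-4 * fractions["ED"], ignore_attr = TRUE)
  # no acceptor -> no productive ternary complex
  expect_identical(rapid_equilibrium_rate(p, 0, K)[["glucoside"]], 0)
})

test_that("rapid-equilibrium oracle rejects singular partitions", {
  p <- mechanism_params(kon_EA = 5, koff_EA = 0, k_cat = 1)
  expect_error(rapid_equilibrium_rate(p, 10, 10), "singular")
})

test_that("substrate inhibition needs the acceptor-first branch", {
  p <- reference_mechanism()
  grid <- c(5, 10, 25, 50, 100)
  scan <- rate_substrate_scan(p, grid, D = 100)
  expect_lt(scan$glucoside[length(grid)], max(scan$glucoside))

  p_ord <- p; p_ord$kon_EA <- 0  # ordered mechanism: donor must bind first
  scan_ord <- rate_substrate_scan(p_ord, c(grid, 500), D = 100)
  expect_true(all(diff(scan_ord$glucoside) >= -1e-9))

  expect_identical(rate_substrate_scan(p, 0, D = 100)$glucoside, 0)
})

test_that("a competitive placeholder effector relieves substrate inhibition", {
  p <- reference_mechanism()
  v_at <- function(a) steady_state_rate(p, a, 100)[["glucoside"]]
  opt <- optimize(v_at, c(3, 60), maximum = TRUE)$maximum
  a_high <- 5 * opt
  grid_c <- c(0, 10, 20, 40, 60, 100, 200, 500, 5000)
  dr <- effector_dose_response(p, a_high, 100, grid_c)
  expect_equal(dr$glucoside[1], v_at(a_high), tolerance = 1e-9)
  # reactivation by >= 1.5x with an interior dose-response maximum
  expect_gte(max(dr$glucoside) / dr$glucoside[1], 1.5)
  i_max <- which.max(dr$glucoside)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(grid_c))
  # saturating effector outcompetes the acceptor everywhere
  expect_lt(dr$glucoside[length(grid_c)], dr$glucoside[1])
})

test_that("effector suppresses the glucohydrolase side activity", {
  p <- reference_mechanism()
  grid_c <- c(0, 5, 10, 25, 50, 100, 250, 1000)
  hyd <- hydrolase_dose_response(p, 100, grid_c)
  expect_true(all(diff(hyd$glucose) <= 1e-12))
  expect_lt(hyd$glucose[length(grid_c)], hyd$glucose[1])

  # no effector binding to the enzyme -> flat curve
  p_flat <- p
  p_flat$kon_EC <- 0; p_flat$kon_EDC_D <- 0; p_flat$kon_EDC_C <- 0
  hyd_flat <- hydrolase_dose_response(p_flat, 100, grid_c)
  expect_rel_equal(hyd_flat$glucose, rep(hyd_flat$glucose[1], nrow(hyd_flat)),
                   1e-8)

  # hydrolase flux matches the oracle once hydrolysis is a slow perturbation
  p_slow <- p; p_slow$k_hyd <- 1e-3; p_slow$k_cat <- 1e-3
  p_slow$k_np2p <- 1e-4; p_slow$k_p2np <- 1e-5
  expect_rel_equal(steady_state_rate(p_slow, 0, 100)[["glucose"]],
                   rapid_equilibrium_rate(p_slow, 0, 100)[["glucose"]],
                   0.01)
})

test_that("hydrolase suppression is monotone for random effector-coupled
           parameterizations", {
  set.seed(55)
  for (i in 1:5) {
    p <- random_fast_binding_mechanism(sep = 100)
    hyd <- hydrolase_dose_response(p, D = 20, C_grid = c(0, 5, 20, 80, 320))
    expect_true(all(diff(hyd$glucose) <= 1e-9 * hyd$glucose[1]))
  }
})

test_that("pre-incubation order produces hysteresis under slow
           interconversion and none under fast", {
  p <- reference_mechanism()
  rates <- hysteresis_protocol(p, list(
    acceptor_first = preincubation_protocol("A", t_pre = 15),
    donor_first = preincubation_protocol("D", t_pre = 15),
    effector_first = preincubation_protocol("C", t_pre = 15)))
  expect_lt(rates[["acceptor_first"]], rates[["donor_first"]])
  expect_lt(rates[["acceptor_first"]], rates[["effector_first"]])

  # zero pre-incubation: identical protocols, identical rates
  both <- assay_protocol(data.frame(time = c(0, 0), species = c("A", "D"),
                                    amount = c(100, 100)), duration = 2)
  r0 <- hysteresis_protocol(p, list(a = both, b = both))
  expect_identical(r0[["a"]], r0[["b"]])

  # fast interconversion washes the order dependence out (< 1%)
  p_fast <- p; p_fast$k_np2p <- 5000; p_fast$k_p2np <- 500
  rf <- hysteresis_protocol(p_fast, list(
    acceptor_first = preincubation_protocol("A", t_pre = 15),
    donor_first = preincubation_protocol("D", t_pre = 15)))
  expect_lt(abs(rf[["acceptor_first"]] - rf[["donor_first"]]) /
              rf[["donor_first"]], 0.01)
})

test_that("protocol validation", {
  expect_error(assay_protocol(data.frame(time = c(1, 0), species = c("A", "D"),
                                         amount = c(1, 1)), 10),
               "non-decreasing")
  expect_error(assay_protocol(data.frame(time = 0, species = "A",
                                         amount = -5), 10),
               "non-negative")
  expect_error(assay_protocol(data.frame(time = 0, species = "glucose",
                                         amount = 5), 10),
               "species")
  expect_error(mechanism_params(kon_EA = -1), "non-negative")
  expect_error(mechanism_params(bogus = 1), "unknown")
})
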