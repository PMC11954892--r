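# Shared fixtures for the suite; everything is generated in code.

# a mechanism draw with random affinities, a thermodynamically consistent
# effector cycle, and binding rates >= `sep`-fold faster than catalysis
random_fast_binding_mechanism <- function(sep = 1e4) {
  K <- 10^runif(8, 0, 2)        # dissociation constants, 1..100 uM
  kon <- 10^runif(8, 0.5, 1.5)  # association constants, ~3..30 /uM/min
  # indices: 1 EA, 2 ED, 3 Tnp, 4 Tp, 5 EC, 6 EDC_D, 7 EDC_C, 8 EP
  # cycle consistency: K_EC * K_EDC_D = K_ED * K_EDC_C
  K[7] <- K[5] * K[6] / K[2]
  koff <- kon * K
  slow <- min(kon * 1, koff) / sep  # ligands used are >= 1 uM in tests
  mechanism_params(
    kon_EA = kon[1], koff_EA = koff[1], kon_ED = kon[2], koff_ED = koff[2],
    kon_Tnp = kon[3], koff_Tnp = koff[3], kon_Tp = kon[4], koff_Tp = koff[4],
    kon_EC = kon[5], koff_EC = koff[5],
    kon_EDC_D = kon[6], koff_EDC_D = koff[6],
    kon_EDC_C = kon[7], koff_EDC_C = koff[7],
    kon_EP = kon[8], koff_EP = koff[8],
    k_np2p = 0.1 * slow, k_p2np = 0.01 * slow,
    k_cat = slow, k_hyd = 0.3 * slow
  )
}

# pre-incubation protocols differing only in which ligand sits with the
# enzyme first; every protocol ends with the same assay composition
preincubation_protocol <- function(first, t_pre = 15, A = 100, D = 100,
                                   C = 60, run = 2) {
  amounts <- c(A = A, D = D, C = C)
  others <- setdiff(names(amounts), first)
  ev <- data.frame(time = c(0, t_pre, t_pre),
                   species = c(first, others),
                   amount = unname(c(amounts[first], amounts[others])))
  assay_protocol(ev, duration = t_pre + run)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)),
            rel_tol)
}
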