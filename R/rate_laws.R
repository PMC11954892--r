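## ---- internal validation helpers ------------------------------------------

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, allow_inf = FALSE,
                         strict = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L, name, " must be a numeric scalar")
  stop_if(is.na(x), name, " must not be NA")
  stop_if(!allow_inf && !is.finite(x), name, " must be finite")
  if (strict) {
    stop_if(x <= lower, name, " must be > ", lower)
  } else {
    stop_if(x < lower, name, " must be >= ", lower)
  }
  invisible(x)
}

check_conc <- function(x, name = deparse(substitute(x))) {
  stop_if(!is.numeric(x) || length(x) < 1L, name, " must be numeric")
  stop_if(anyNA(x) || any(!is.finite(x)), name, " must be finite")
  stop_if(any(x < 0), name, " must be non-negative")
  invisible(x)
}

## ---- parameter constructors ------------------------------------------------

#' Acceptor rate-law parameters (two Hill coefficients)
#'
#' Parameters of the asymmetric-cooperativity acceptor rate law
#' \deqn{v(S) = v_{max} \frac{(S/K_S)^n}{1 + (S/K_S)^n + (S/K_S)^x}}
#' where `n` is the Hill coefficient of the productive binding order and `x`
#' that of the non-productive order. When `x > n` the law exhibits substrate
#' inhibition (a single interior rate maximum); when `n = x` it reduces to a
#' saturating Hill curve (Michaelis-Menten-like for n = 1).
#'
#' @param v_max maximal rate, nmol/min/mg (>= 0).
#' @param K_S half-saturation constant shared by both branches, uM (> 0).
#' @param n Hill coefficient of the productive branch (> 0).
#' @param x Hill coefficient of the non-productive branch (> 0).
#' @return an object of class `acceptor_params`.
#' @seealso [acceptor_rate()], [optimum_acceptor()]
#' @export
#' @examples
#' p <- acceptor_params(v_max = 1157, K_S = 20, n = 1, x = 2)
#' acceptor_rate(p, c(5, 10, 25, 50, 100))
acceptor_params <- function(v_max, K_S, n, x) {
  check_scalar(v_max, "v_max", lower = 0)
  check_scalar(K_S, "K_S", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 0, strict = TRUE)
  check_scalar(x, "x", lower = 0, strict = TRUE)
  structure(list(v_max = v_max, K_S = K_S, n = n, x = x),
            class = "acceptor_params")
}

#' Donor rate-law parameters (single Hill coefficient)
#'
#' Parameters of the donor saturation law
#' \deqn{v(U) = v_{max} \frac{U^h}{K_U^h + U^h}}
#' For the donor the cooperativity of the two binding orders is identical
#' (symmetric), so a single Hill coefficient `h` suffices; `h = 1` recovers
#' the Michaelis-Menten hyperbola with `K_m = K_U`.
#'
#' @param v_max maximal rate, nmol/min/mg (>= 0).
#' @param K_U half-saturation constant, uM (> 0).
#' @param h Hill coefficient (> 0).
#' @return an object of class `donor_params`.
#' @export
donor_params <- function(v_max, K_U, h) {
  check_scalar(v_max, "v_max", lower = 0)
  check_scalar(K_U, "K_U", lower = 0, strict = TRUE)
  check_scalar(h, "h", lower = 0, strict = TRUE)
  structure(list(v_max = v_max, K_U = K_U, h = h), class = "donor_params")
}

#' Donor saturation (v_max vs donor) hyperbola parameters
#'
#' The per-donor-level maximal rates of the acceptor law follow a hyperbola
#' \deqn{v_{max}(U) = v_{max,\infty} \frac{U}{K_D + U}} whose dissociation
#' constant `K_D` is the donor affinity and whose asymptote `v_max_inf` is the
#' maximal rate that would be reached were there no substrate inhibition.
#'
#' @param v_max_inf asymptotic maximal rate, nmol/min/mg (>= 0).
#' @param K_D donor dissociation constant, uM (> 0).
#' @return an object of class `donor_saturation_params`.
#' @export
donor_saturation_params <- function(v_max_inf, K_D) {
  check_scalar(v_max_inf, "v_max_inf", lower = 0)
  check_scalar(K_D, "K_D", lower = 0, strict = TRUE)
  structure(list(v_max_inf = v_max_inf, K_D = K_D),
            class = "donor_saturation_params")
}

#' Classical one-site kinetic parameters (Michaelis-Menten / substrate inhibition)
#'
#' Comparison baseline: \deqn{v(S) = v_{max} \frac{S}{K_m + S + S^2/K_i}}
#' `K_i = Inf` is the explicit "no inhibition" marker and reduces the law to
#' Michaelis-Menten.
#'
#' @param v_max maximal rate (>= 0).
#' @param K_m Michaelis constant, uM (> 0).
#' @param K_i substrate-inhibition constant, uM (> 0), or `Inf` for none.
#' @return an object of class `classic_params`.
#' @export
classic_params <- function(v_max, K_m, K_i = Inf) {
  check_scalar(v_max, "v_max", lower = 0)
  check_scalar(K_m, "K_m", lower = 0, strict = TRUE)
  check_scalar(K_i, "K_i", lower = 0, strict = TRUE, allow_inf = TRUE)
  structure(list(v_max = v_max, K_m = K_m, K_i = K_i),
            class = "classic_params")
}

## ---- rate laws -------------------------------------------------------------

#' Steady-state rate of the acceptor titration (asymmetric cooperativity)
#'
#' Evaluates the two-Hill-coefficient acceptor rate law (see
#' [acceptor_params()]). The algebraic form lives only here, so an alternative
#' parameterization can be substituted without touching callers.
#'
#' @param params an `acceptor_params` object.
#' @param S acceptor concentration(s), uM (>= 0); vectorized.
#' @return rate(s), nmol/min/mg.
#' @export
acceptor_rate <- function(params, S) {
  stopifnot(inherits(params, "acceptor_params"))
  check_conc(S, "S")
  r <- S / params$K_S
  rn <- r^params$n
  v <- params$v_max * rn / (1 + rn + r^params$x)
  v[S == 0] <- 0  # r^n with n<1 at r=0 is still 0, but guard 0^0
  v
}

#' Steady-state rate of the donor titration (Hill law)
#'
#' @param params a `donor_params` object.
#' @param U donor concentration(s), uM (>= 0); vectorized.
#' @return rate(s), nmol/min/mg.
#' @export
donor_rate <- function(params, U) {
  stopifnot(inherits(params, "donor_params"))
  check_conc(U, "U")
  uh <- U^params$h
  v <- params$v_max * uh / (params$K_U^params$h + uh)
  v[U == 0] <- 0
  v
}

#' Classical Michaelis-Menten / single-site substrate-inhibition rate
#'
#' @param params a `classic_params` object (`K_i = Inf` means no inhibition).
#' @param S substrate concentration(s), uM (>= 0); vectorized.
#' @return rate(s).
#' @export
classic_rate <- function(params, S) {
  stopifnot(inherits(params, "classic_params"))
  check_conc(S, "S")
  inhib <- if (is.finite(params$K_i)) S^2 / params$K_i else 0
  params$v_max * S / (params$K_m + S + inhib)
}

#' Donor saturation hyperbola v_max(U)
#'
#' @param params a `donor_saturation_params` object.
#' @param U donor concentration(s), uM (>= 0); vectorized.
#' @return maximal rate(s) at each donor level.
#' @export
donor_saturation <- function(params, U) {
  stopifnot(inherits(params, "donor_saturation_params"))
  check_conc(U, "U")
  params$v_max_inf * U / (params$K_D + U)
}

#' Allosteric descriptor algebra
#'
#' Links the Hill description of a titration to the conformer population
#' shift of a monomeric allosteric enzyme. With activated-to-basal conformer
#' ratio L = \[E'\]/\[E\] the fractional response is v/v_max = aL/(1 + aL),
#' and comparison with the Hill equation gives
#' \deqn{\alpha L = (S/K_S)^n, \qquad \alpha = (S/K_S)^{n-1}.}
#' The allosteric intrinsic efficacy \eqn{\alpha} is therefore 1 whenever
#' n = 1 (no allosteric effect) or S = K_S.
#'
#' @param S ligand concentration, uM (>= 0).
#' @param K_S half-saturation constant, uM (> 0).
#' @param n Hill coefficient (> 0).
#' @return a list of class `allosteric_state` with elements `L` (conformer
#'   ratio), `alpha` (intrinsic efficacy), `alphaL` and `response`
#'   (fractional activity v/v_max).
#' @export
#' @examples
#' allosteric_descriptor(S = 20, K_S = 20, n = 2)$response  # 0.5
allosteric_descriptor <- function(S, K_S, n) {
  check_scalar(S, "S", lower = 0)
  check_scalar(K_S, "K_S", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 0, strict = TRUE)
  r <- S / K_S
  alphaL <- r^n
  # alpha = r^(n-1); r = 0, n = 1 gives 0^0, defined as 1 (no allosteric effect)
  alpha <- if (r == 0 && n == 1) 1 else r^(n - 1)
  L <- r  # alphaL / alpha
  structure(list(L = L, alpha = alpha, alphaL = alphaL,
                 response = alphaL / (1 + alphaL)),
            class = "allosteric_state")
}

#' Acceptor concentration of maximal rate
#'
#' The two-Hill-coefficient law has a single interior maximum iff `x > n`, at
#' the closed-form stationary point \eqn{S^* = K_S (n/(x-n))^{1/x}} (root of
#' n + (n - x) r^x = 0). For `x <= n` the curve is monotone non-decreasing and
#' no optimum exists.
#'
#' @param params an `acceptor_params` object.
#' @return the optimal acceptor concentration (uM), or `NULL` when the curve
#'   is monotone.
#' @export
optimum_acceptor <- function(params) {
  stopifnot(inherits(params, "acceptor_params"))
  if (params$x <= params$n) return(NULL)
  params$K_S * (params$n / (params$x - params$n))^(1 / params$x)
}
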