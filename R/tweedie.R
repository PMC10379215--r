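#' Tweedie parameter set
#'
#' Container for the Tweedie parameterization `TW(mu, phi, p)` with power
#' index restricted to the compound Poisson-Gamma range `1 < p < 2`. The
#' derived field `theta = log((p - 1) / (2 - p))` is the unconstrained scale
#' on which the power index is sampled.
#'
#' @param mu mean, `> 0`.
#' @param phi dispersion, `> 0`; the variance is `phi * mu^p`.
#' @param p power index in `(1, 2)`.
#' @return An object of class `tweedie_params`.
#' @export
tweedie_params <- function(mu, phi, p) {
  stopifnot(is.numeric(mu), is.numeric(phi), is.numeric(p))
  if (any(mu <= 0)) stop("`mu` must be positive")
  if (any(phi <= 0)) stop("`phi` must be positive")
  if (any(p <= 1 | p >= 2)) stop("`p` must lie strictly in (1, 2)")
  structure(list(mu = mu, phi = phi, p = p, theta = log((p - 1) / (2 - p))),
            class = "tweedie_params")
}

#' Compound Poisson-Gamma parameter set
#'
#' Parameters of `C = sum_{i<=T} X_i` with `T ~ Poisson(lam)` and
#' `X_i ~ Gamma(shape = alpha, scale = gamma)`.
#'
#' @param lam Poisson rate, `> 0`.
#' @param alpha Gamma shape, `> 0`.
#' @param gamma Gamma scale, `> 0`.
#' @return An object of class `cpg_params`.
#' @export
cpg_params <- function(lam, alpha, gamma) {
  stopifnot(is.numeric(lam), is.numeric(alpha), is.numeric(gamma))
  if (any(lam <= 0) || any(alpha <= 0) || any(gamma <= 0))
    stop("all compound Poisson-Gamma parameters must be positive")
  structure(list(lam = lam, alpha = alpha, gamma = gamma),
            class = "cpg_params")
}

#' Convert Tweedie parameters to compound Poisson-Gamma parameters
#'
#' The two parameterizations are in bijection for `1 < p < 2`:
#' `lam = mu^(2-p) / (phi (2-p))`, `alpha = (2-p)/(p-1)`,
#' `gamma = phi (p-1) mu^(p-1)`.
#'
#' @param tw a [tweedie_params] object.
#' @return A [cpg_params] object.
#' @export
tweedie_to_cpg <- function(tw) {
  stopifnot(inherits(tw, "tweedie_params"))
  with(tw, cpg_params(lam = mu^(2 - p) / (phi * (2 - p)),
                      alpha = (2 - p) / (p - 1),
                      gamma = phi * (p - 1) * mu^(p - 1)))
}

#' Convert compound Poisson-Gamma parameters to Tweedie parameters
#'
#' Inverse of [tweedie_to_cpg()]: `mu = lam alpha gamma`,
#' `p = (2 + alpha)/(1 + alpha)`, `phi = lam^(1-p) (alpha gamma)^(2-p) / (2-p)`.
#'
#' @param cpg a [cpg_params] object.
#' @return A [tweedie_params] object.
#' @export
cpg_to_tweedie <- function(cpg) {
  stopifnot(inherits(cpg, "cpg_params"))
  with(cpg, {
    p <- (2 + alpha) / (1 + alpha)
    tweedie_params(mu = lam * alpha * gamma,
                   phi = lam^(1 - p) * (alpha * gamma)^(2 - p) / (2 - p),
                   p = p)
  })
}

# internal variant avoiding the construction overhead inside hot loops
.theta_to_p <- function(theta) 1 + stats::plogis(theta)

#' Joint log density of a score and its latent count
#'
#' Log of `p(c, t | lam, alpha, gamma)`: the CPG point mass `exp(-lam)` at
#' `(c = 0, t = 0)` and, for `t >= 1`, the product of the `Gamma(t alpha,
#' gamma)` density at `c` and the `Poisson(lam)` mass at `t`. Evaluation is
#' entirely in log space.
#'
#' @param c nonnegative score(s).
#' @param t latent count(s); `t = 0` iff `c = 0`, otherwise `t >= 1`.
#' @param cpg a [cpg_params] object (scalar parameters, recycled).
#' @return Numeric vector of log densities.
#' @export
cpg_joint_logpdf <- function(c, t, cpg) {
  stopifnot(inherits(cpg, "cpg_params"))
  n <- length(c)
  if (length(t) != n) stop("`c` and `t` must have equal length")
  bad <- (c == 0) != (t == 0) | c < 0 | t < 0
  if (any(bad))
    stop("inconsistent (c, t): t must be 0 exactly when c is 0")
  cpg_joint_logpdf_cpp(as.numeric(c), as.integer(t),
                       rep_len(cpg$lam, n), cpg$alpha[1],
                       rep_len(cpg$gamma, n))
}

#' Marginal log density of a compound Poisson-Gamma score
#'
#' Sums the joint density over the latent count in log space with adaptive
#' truncation: once the series terms decay, the geometric tail bound of the
#' remainder is compared against `rel_tol` times the running sum.
#'
#' @param c nonnegative score(s); exact zeros get log density `-lam`.
#' @param cpg a [cpg_params] object.
#' @param rel_tol relative truncation tolerance for the series tail.
#' @param tcap hard cap on summed terms.
#' @return Numeric vector of marginal log densities.
#' @export
cpg_marginal_logpdf <- function(c, cpg, rel_tol = 1e-12, tcap = 100000L) {
  stopifnot(inherits(cpg, "cpg_params"), rel_tol > 0)
  if (any(c < 0)) stop("scores must be nonnegative")
  n <- length(c)
  cpg_marginal_logpdf_cpp(as.numeric(c), rep_len(cpg$lam, n), cpg$alpha[1],
                          rep_len(cpg$gamma, n), rel_tol, as.integer(tcap))
}

#' Draw compound Poisson-Gamma scores
#'
#' Simulates `C = sum_{i<=T} X_i`, `T ~ Poisson(lam)`,
#' `X_i ~ Gamma(alpha, scale = gamma)`, using R's global RNG stream so draws
#' are reproducible under [set.seed()]. Exact zeros occur with probability
#' `exp(-lam)`.
#'
#' @param n number of draws (ignored if `cpg` holds vector parameters, in
#'   which case one draw per parameter set is returned).
#' @param cpg a [cpg_params] object; `lam` and `gamma` may be vectors.
#' @return Numeric vector of nonnegative scores.
#' @export
rcpg <- function(n, cpg) {
  stopifnot(inherits(cpg, "cpg_params"))
  m <- max(length(cpg$lam), length(cpg$gamma))
  if (m > 1L) n <- m
  rcpg_cpp(rep_len(cpg$lam, n), cpg$alpha[1], rep_len(cpg$gamma, n))
}

#' Gibbs draw of latent counts for positive scores
#'
#' For each `c > 0`, draws the latent Poisson count from the categorical
#' distribution over `1..Tmax` with unnormalized weights proportional to the
#' Poisson mass at `t` times the `Gamma(t alpha, gamma)` density at `c`,
#' computed in log space. Scores equal to zero must be handled upstream
#' (their count is identically zero).
#'
#' @param c strictly positive score(s).
#' @param cpg a [cpg_params] object (`lam`, `gamma` recycled over `c`).
#' @param tmax truncation bound for the categorical support, `>= 1`.
#' @return Integer vector of counts in `[1, tmax]`.
#' @export
sample_latent_t <- function(c, cpg, tmax) {
  stopifnot(inherits(cpg, "cpg_params"), tmax >= 1)
  if (any(c <= 0)) stop("`c` must be strictly positive; zeros have latent count 0")
  n <- length(c)
  sample_latent_t_cpp(as.numeric(c), rep_len(cpg$lam, n), cpg$alpha[1],
                      rep_len(cpg$gamma, n), as.integer(tmax))
}

#' Exact latent-count distribution for one observation
#'
#' Normalized probabilities over `t = 1..tmax` used by [sample_latent_t()];
#' exposed for diagnostics and goodness-of-fit checks.
#'
#' @inheritParams sample_latent_t
#' @return Numeric probability vector of length `tmax`.
#' @export
latent_t_pmf <- function(c, cpg, tmax) {
  stopifnot(inherits(cpg, "cpg_params"), length(c) == 1, c > 0)
  latent_t_pmf_cpp(c, cpg$lam[1], cpg$alpha[1], cpg$gamma[1],
                   as.integer(tmax))
}

#' Adapt the latent-count truncation bound
#'
#' Doubles `tmax` when sampled counts approach it and halves it (never below
#' `floor`) when they are far below, keeping the categorical support tight
#' without clipping mass. The grow/shrink fractions follow the qualitative
#' rule that the bound tracks how large the sampled counts are relative to it.
#'
#' @param sampled_t integer vector of latent counts from the last sweep.
#' @param tmax current bound.
#' @param grow grow when `max(sampled_t) > grow * tmax` (default 0.9).
#' @param shrink shrink when `max(sampled_t) < shrink * tmax` (default 0.3).
#' @param factor multiplicative adaptation factor (default 2).
#' @param floor smallest admissible bound (default 4).
#' @return The adapted bound (integer).
#' @export
adapt_tmax <- function(sampled_t, tmax, grow = 0.9, shrink = 0.3,
                       factor = 2, floor = 4L) {
  stopifnot(tmax >= 1)
  mx <- if (length(sampled_t)) max(sampled_t) else 0L
  if (mx > grow * tmax) return(as.integer(ceiling(tmax * factor)))
  if (mx < shrink * tmax) return(as.integer(max(floor, ceiling(tmax / factor))))
  as.integer(tmax)
}
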