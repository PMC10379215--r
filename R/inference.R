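#' Sampler configuration
#'
#' Defaults follow the published schedule: a preliminary tuning run of 6500
#' iterations adapting the step size, momentum mass and latent-count bound,
#' then 13,500 main iterations of which the first 3500 are discarded as
#' burn-in, leaving 10,000 retained draws. One Gibbs sweep of the latent
#' counts is interleaved every `hmc_steps_per_t_update` Hamiltonian updates.
#'
#' @param n_tune preliminary (tuning) iterations.
#' @param n_main main-phase iterations.
#' @param n_burn burn-in discarded from the main phase.
#' @param hmc_steps_per_t_update Hamiltonian updates per latent-count sweep.
#' @param leapfrog_steps leapfrog steps per Hamiltonian update.
#' @param step_size initial leapfrog step size (adapted during tuning).
#' @param step_jitter uniform relative jitter on the step size per update,
#'   guarding against leapfrog periodicity.
#' @param mass_diagonal optional fixed diagonal of the momentum mass matrix;
#'   estimated from tuning draws when `NULL`.
#' @param target_accept_range acceptance-rate window targeted by tuning.
#' @param tmax initial latent-count truncation bound (adaptive).
#' @param seed integer seed; the tuning phase seeds the RNG with `seed` and
#'   the main phase with `seed + 1`.
#' @param nu_prior_var prior variance of the spot random effects.
#' @param beta_prior_sd prior standard deviation of interaction coefficients.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_tune = 6500L, n_main = 13500L, n_burn = 3500L,
                           hmc_steps_per_t_update = 10L, leapfrog_steps = 10L,
                           step_size = 0.02, step_jitter = 0.1,
                           mass_diagonal = NULL,
                           target_accept_range = c(0.45, 0.65),
                           tmax = 32L, seed = 1L, nu_prior_var = 1,
                           beta_prior_sd = 1) {
  stopifnot(n_tune > 0, n_main > 0, n_burn >= 0, n_burn < n_main,
            leapfrog_steps >= 1, step_size > 0,
            length(target_accept_range) == 2)
  structure(list(n_tune = as.integer(n_tune), n_main = as.integer(n_main),
                 n_burn = as.integer(n_burn),
                 hmc_steps_per_t_update = as.integer(hmc_steps_per_t_update),
                 leapfrog_steps = as.integer(leapfrog_steps),
                 step_size = step_size, step_jitter = step_jitter,
                 mass_diagonal = mass_diagonal,
                 target_accept_range = target_accept_range,
                 tmax = as.integer(tmax), seed = as.integer(seed),
                 nu_prior_var = nu_prior_var, beta_prior_sd = beta_prior_sd),
            class = "sampler_config")
}

#' Initialize spot random effects and model parameters
#'
#' Maximizes the penalized Tweedie quasi-log-posterior of the mixed model
#' over the intercept, interaction coefficients and per-spot sender/receiver
#' offsets (normal priors act as ridge penalties) by Newton-Raphson / Fisher
#' scoring with step halving. The dispersion is profiled from Pearson
#' residuals and the power index is moment-matched so that the implied
#' zero mass `mean(exp(-lambda_i))` tracks the observed zero fraction.
#' The fitted offsets are treated as fixed in the Bayesian run.
#'
#' @param scores a [comm_score_set].
#' @param design a [design_matrix][build_design_matrix].
#' @param nu_prior_var prior variance of the random effects.
#' @param p_init starting power index.
#' @param max_iter,tol Newton-Raphson iteration cap and gradient
#'   infinity-norm tolerance.
#' @param profile_p moment-match the power index after the first fit?
#' @return List with `nu_l`, `nu_r` (per-spot offsets), `b0`, `beta`,
#'   `logphi`, `theta`, `converged`, `iterations`.
#' @export
initialize_random_effects <- function(scores, design, nu_prior_var = 1,
                                      p_init = 1.5, max_iter = 100L,
                                      tol = 1e-6, profile_p = TRUE) {
  stopifnot(inherits(scores, "comm_score_set"), inherits(design, "design_matrix"))
  c_ <- scores$scores
  if (all(c_ == 0)) stop("all communication scores are zero; nothing to fit")
  n <- length(c_)
  N <- design$n_spots
  k <- ncol(design$X)
  # columns: intercept | interactions | sender offsets | receiver offsets;
  # the offset blocks are indicator columns, kept sparse so the Fisher
  # crossproduct scales with the number of pairs, not (k + 2N)^2
  Z <- cbind(Matrix::Matrix(cbind(1, design$X), sparse = TRUE),
             Matrix::sparseMatrix(i = seq_len(n), j = design$sender_idx,
                                  x = 1, dims = c(n, N)),
             Matrix::sparseMatrix(i = seq_len(n), j = design$receiver_idx,
                                  x = 1, dims = c(n, N)))
  row_scale <- function(M, w) {
    # dgCMatrix rows scaled by w without densifying
    M@x <- M@x * w[M@i + 1L]
    M
  }
  pen <- c(1 / 100^2, rep(1, k), rep(1 / nu_prior_var, 2 * N))

  quasi_ll <- function(psi, p, phi) {
    mu <- exp(pmin(as.numeric(Z %*% psi), 30))
    sum(c_ * mu^(1 - p) / (1 - p) - mu^(2 - p) / (2 - p)) / phi -
      0.5 * sum(pen * psi^2)
  }
  fit_at_p <- function(p, psi) {
    phi <- 1
    converged <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      eta <- pmin(as.numeric(Z %*% psi), 30)
      mu <- exp(eta)
      phi_new <- max(mean((c_ - mu)^2 / mu^p), 1e-6)
      if (it <= 20L) phi <- phi_new  # freeze late so Newton can polish
      u <- (c_ - mu) * mu^(1 - p) / phi
      w <- mu^(2 - p) / phi
      score <- as.numeric(Matrix::crossprod(Z, u)) - pen * psi
      if (max(abs(score)) < tol) { converged <- TRUE; break }
      H <- as.matrix(Matrix::crossprod(row_scale(Z, w), Z))
      diag(H) <- diag(H) + pen
      delta <- tryCatch(solve(H, score), error = function(e) score / diag(H))
      # step halving on the penalized quasi-likelihood
      f0 <- quasi_ll(psi, p, phi)
      step <- 1
      repeat {
        cand <- psi + step * delta
        if (quasi_ll(cand, p, phi) >= f0 || step < 1e-4) break
        step <- step / 2
      }
      psi <- psi + step * delta
    }
    mu <- exp(pmin(as.numeric(Z %*% psi), 30))
    list(psi = psi, phi = max(mean((c_ - mu)^2 / mu^p), 1e-6), mu = mu,
         converged = converged, iterations = it)
  }

  psi0 <- c(log(mean(c_[c_ > 0])), rep(0, k + 2 * N))
  fit <- fit_at_p(p_init, psi0)
  p_hat <- p_init
  if (profile_p) {
    zf <- mean(c_ == 0)
    grid <- seq(1.1, 1.9, by = 0.05)
    obj <- vapply(grid, function(p) {
      phi_p <- mean((c_ - fit$mu)^2 / fit$mu^p)
      lam <- fit$mu^(2 - p) / (phi_p * (2 - p))
      abs(mean(exp(-lam)) - zf)
    }, numeric(1))
    p_hat <- grid[which.min(obj)]
    if (p_hat != p_init) fit <- fit_at_p(p_hat, fit$psi)
  }
  if (!fit$converged)
    warning("random-effect initialization did not reach tolerance; ",
            "returning best iterate")
  psi <- unname(fit$psi)
  # Plug-in variance correction: treating the fitted offsets as known makes
  # the conditional posterior of beta too tight. The ratio of the joint
  # (beta, nu) to the conditional-on-nu asymptotic variances from the
  # penalized Fisher information restores calibration of the Wald tests.
  mu <- fit$mu
  w <- mu^(2 - p_hat) / fit$phi
  H <- as.matrix(Matrix::crossprod(row_scale(Z, w), Z))
  diag(H) <- diag(H) + pen
  bidx <- seq_len(k + 1)
  v_joint <- diag(solve(H))[bidx][-1]
  v_cond <- diag(solve(H[bidx, bidx]))[-1]
  list(nu_l = psi[k + 1 + seq_len(N)], nu_r = psi[k + 1 + N + seq_len(N)],
       b0 = psi[1], beta = psi[1 + seq_len(k)],
       logphi = log(max(fit$phi, 1e-8)),
       theta = log((p_hat - 1) / (2 - p_hat)),
       var_inflation = pmax(v_joint / v_cond, 1),
       converged = fit$converged, iterations = fit$iterations)
}

#' Assemble a fitting-ready model
#'
#' Bundles the outcome vector, design, fixed random-effect offsets and prior
#' scales, plus the log-posterior closure used by the sampler.
#'
#' @param scores a [comm_score_set].
#' @param design a [design_matrix][build_design_matrix].
#' @param re random-effect initialization from
#'   [initialize_random_effects()]; computed here when `NULL`.
#' @param beta_prior_sd prior sd of interaction coefficients.
#' @param nu_prior_var prior variance of random effects (used when `re` is
#'   computed internally).
#' @return An object of class `batcom_model`.
#' @export
batcom_model <- function(scores, design, re = NULL, beta_prior_sd = 1,
                         nu_prior_var = 1) {
  stopifnot(inherits(scores, "comm_score_set"), inherits(design, "design_matrix"))
  if (is.null(re))
    re <- initialize_random_effects(scores, design, nu_prior_var = nu_prior_var)
  offset <- re$nu_l[design$sender_idx] + re$nu_r[design$receiver_idx]
  c_ <- scores$scores
  nz <- which(c_ > 0)
  structure(list(
    c = c_, logc = ifelse(c_ > 0, log(c_), 0), X = design$X,
    offset = offset, nz = nz,
    design = design, re = re,
    init = c(re$b0, re$beta, re$logphi, re$theta),
    var_inflation = re$var_inflation,
    beta_prior_sd = beta_prior_sd),
    class = "batcom_model")
}

#' Log joint posterior and exact gradient
#'
#' The augmented-data log posterior: sum over observations of the joint
#' (score, latent count) log density under the per-pair compound
#' Poisson-Gamma parameters implied by the log link, plus the log priors
#' (`b0 ~ N(0, 100^2)`, `beta ~ N(0, beta_prior_sd^2)`,
#' `logphi ~ N(0, 10^2)`, `theta ~ Logistic(0, 1)`), together with its
#' analytic gradient with respect to `(b0, beta, logphi, theta)`.
#'
#' @param par numeric vector `(b0, beta, logphi, theta)`.
#' @param model a [batcom_model].
#' @param t integer latent counts, consistent with the scores (`t = 0` iff
#'   score is 0).
#' @return List with elements `lp` (scalar) and `grad`.
#' @export
log_posterior_and_grad <- function(par, model, t) {
  stopifnot(inherits(model, "batcom_model"))
  cpg_logpost_grad_cpp(as.numeric(par), model$X, model$c, model$logc,
                       as.integer(t), model$offset, 100,
                       model$beta_prior_sd, 10)
}

# per-observation CPG parameters at a parameter state (nonzero rows only
# when idx is given)
.cpg_at <- function(par, model, idx = NULL) {
  k <- ncol(model$X)
  if (is.null(idx)) idx <- seq_along(model$c)
  eta <- par[1] + drop(model$X[idx, , drop = FALSE] %*% par[1 + seq_len(k)]) +
    model$offset[idx]
  phi <- exp(par[k + 2])
  pm1 <- stats::plogis(par[k + 3])
  twomp <- 1 - pm1
  list(lam = exp(twomp * eta) / (phi * twomp), alpha = twomp / pm1,
       gam = phi * pm1 * exp(pm1 * eta))
}

# One Hamiltonian update with jittered step size and diagonal mass.
# Returns list(q, lp, grad, accepted, divergent).
.hmc_update <- function(q, cur, logpost, eps, L, mass, jitter) {
  d <- length(q)
  p0 <- stats::rnorm(d) * sqrt(mass)
  e <- eps * stats::runif(1, 1 - jitter, 1 + jitter)
  qq <- q
  p <- p0 + 0.5 * e * cur$grad
  lg <- cur
  for (l in seq_len(L)) {
    qq <- qq + e * p / mass
    if (!all(is.finite(qq)))
      return(list(q = q, cur = cur, accepted = FALSE, divergent = TRUE))
    lg <- logpost(qq)
    if (!is.finite(lg$lp) || !all(is.finite(lg$grad)))
      return(list(q = q, cur = cur, accepted = FALSE, divergent = TRUE))
    p <- p + (if (l < L) e else 0.5 * e) * lg$grad
  }
  h0 <- -cur$lp + 0.5 * sum(p0^2 / mass)
  h1 <- -lg$lp + 0.5 * sum(p^2 / mass)
  if (!is.finite(h1))
    return(list(q = q, cur = cur, accepted = FALSE, divergent = TRUE))
  if (log(stats::runif(1)) < h0 - h1)
    list(q = qq, cur = lg, accepted = TRUE, divergent = FALSE)
  else
    list(q = q, cur = cur, accepted = FALSE, divergent = FALSE)
}

# Shared chain runner for the augmented CPG model (t_update = TRUE) and for
# plain targets such as the logistic variant (t_update = FALSE).
.run_chain <- function(logpost_fn, q0, t0, model, n_iter, cfg, state,
                       adapt = FALSE, t_update = TRUE,
                       shrink_until = 0L) {
  d <- length(q0)
  draws <- matrix(NA_real_, n_iter, d)
  accepted <- logical(n_iter)
  divergences <- 0L
  q <- q0
  t <- t0
  tmax <- state$tmax
  eps <- state$eps
  mass <- state$mass %||% rep(1, d)
  window <- max(25L, min(100L, n_iter %/% 20L))
  target <- mean(cfg$target_accept_range)
  logpost <- function(qq) logpost_fn(qq, t)
  cur <- logpost(q)
  for (i in seq_len(n_iter)) {
    if (t_update && (i - 1L) %% cfg$hmc_steps_per_t_update == 0L &&
        length(model$nz)) {
      cp <- .cpg_at(q, model, model$nz)
      t_nz <- sample_latent_t_cpp(model$c[model$nz], cp$lam, cp$alpha, cp$gam,
                                  tmax)
      t[model$nz] <- t_nz
      tmax <- adapt_tmax(t_nz, tmax)
      cur <- logpost(q)  # target changed with t
    }
    st <- .hmc_update(q, cur, logpost, eps, cfg$leapfrog_steps, mass,
                      cfg$step_jitter)
    q <- st$q
    cur <- st$cur
    accepted[i] <- st$accepted
    if (st$divergent) divergences <- divergences + 1L
    draws[i, ] <- q
    if (adapt) {
      # Robbins-Monro step-size adaptation toward the middle of the target
      # acceptance window; the learning rate shrinks after the mass update.
      # Divergent trajectories signal the leapfrog stability edge and shrink
      # the step immediately, keeping the equilibrium safely below it.
      gain <- if (i <= n_iter %/% 2L) 0.2 else 0.1
      eps <- eps * exp(gain * ((if (st$accepted) 1 else 0) - target))
      if (st$divergent) eps <- eps * 0.9
      if (i == n_iter %/% 2L && i > 2L * window) {
        v <- apply(draws[(i %/% 2L):i, , drop = FALSE], 2, stats::var)
        mass <- 1 / pmax(v, 1e-10)
      }
    } else if (st$divergent && i <= shrink_until) {
      # Burn-in-only safeguard for the main phase: if the chain drifts into
      # a region stiffer than anything met during tuning (e.g. the latent
      # counts grow), divergences shrink the step while the discarded
      # burn-in draws are being generated; the retained draws always come
      # from a fixed kernel. Healthy chains see no divergences and are
      # unaffected.
      eps <- eps * 0.9
    }
  }
  list(draws = draws, accepted = accepted, divergences = divergences,
       state = list(q = q, t = t, tmax = tmax, eps = eps, mass = mass))
}

#' Tune the sampler on a preliminary run
#'
#' Runs the preliminary phase: the leapfrog step size is adapted
#' multiplicatively in windows so that the acceptance rate settles in the
#' target window (45-65% by default), the diagonal momentum mass is set from
#' preliminary-sample variances halfway through, and the latent-count bound
#' adapts with every Gibbs sweep. The RNG is seeded with `config$seed`.
#'
#' @param model a [batcom_model].
#' @param config a [sampler_config].
#' @return The config updated with tuned `step_size`, `mass_diagonal`,
#'   `tmax`, final tuning acceptance and the end-of-tuning chain state.
#' @export
tune_sampler <- function(model, config) {
  stopifnot(inherits(model, "batcom_model"), inherits(config, "sampler_config"))
  if (!length(model$nz))
    stop("all scores are zero: no nonzero latent counts to augment")
  set.seed(config$seed)
  q0 <- model$init
  t0 <- integer(length(model$c))
  t0[model$nz] <- 1L
  lpfn <- function(q, t) log_posterior_and_grad(q, model, t)
  run <- .run_chain(lpfn, q0, t0, model, config$n_tune, config,
                    state = list(tmax = config$tmax, eps = config$step_size,
                                 mass = config$mass_diagonal),
                    adapt = TRUE, t_update = TRUE)
  tail_n <- max(100L, config$n_tune %/% 5L)
  acc <- mean(run$accepted[(config$n_tune - tail_n + 1L):config$n_tune])
  if (acc <= 0 || acc >= 1)
    stop(sprintf(paste("tuning acceptance rate stuck at %.0f%%;",
                       "consider re-parameterizing or rescaling covariates"),
         100 * acc))
  config$step_size <- 0.95 * run$state$eps
  config$mass_diagonal <- run$state$mass
  config$tmax <- run$state$tmax
  config$tuning_acceptance <- acc
  config$init_state <- run$state
  config
}

#' Run the main MCMC phase
#'
#' Alternates a Gibbs sweep of all latent counts with
#' `hmc_steps_per_t_update` Hamiltonian updates of `(b0, beta, logphi,
#' theta)`, using the tuned step size, mass and latent-count bound; retains
#' the draws after burn-in. Nonfinite Hamiltonians are rejected and counted
#' as divergences (a warning is raised past 1%). The RNG is seeded with
#' `config$seed + 1`, so a fixed seed gives bit-identical draws.
#'
#' @param model a [batcom_model].
#' @param config a tuned [sampler_config] (from [tune_sampler()]).
#' @return An object of class `posterior_samples`: retained `draws` (columns
#'   `b0`, one per interaction, `logphi`, `theta`), `acceptance_rate` over
#'   the main phase, divergence count, final latent counts and `rho`.
#' @export
run_mcmc <- function(model, config) {
  stopifnot(inherits(model, "batcom_model"), inherits(config, "sampler_config"))
  set.seed(config$seed + 1L)
  st <- config$init_state
  if (is.null(st)) {
    q0 <- model$init
    t0 <- integer(length(model$c))
    t0[model$nz] <- 1L
    st <- list(q = q0, t = t0, tmax = config$tmax,
               eps = config$step_size,
               mass = config$mass_diagonal %||% rep(1, length(q0)))
  }
  lpfn <- function(q, t) log_posterior_and_grad(q, model, t)
  run <- .run_chain(lpfn, st$q, st$t, model, config$n_main, config,
                    state = st, adapt = FALSE, t_update = TRUE,
                    shrink_until = config$n_burn)
  if (run$divergences > 0.01 * config$n_main)
    warning(sprintf("%d of %d Hamiltonian updates diverged",
                    run$divergences, config$n_main))
  keep <- (config$n_burn + 1L):config$n_main
  draws <- run$draws[keep, , drop = FALSE]
  colnames(draws) <- c("b0", model$design$interaction_names, "logphi", "theta")
  structure(list(draws = draws,
                 acceptance_rate = mean(run$accepted),
                 divergences = run$divergences,
                 t_final = run$state$t, tmax_final = run$state$tmax,
                 rho = model$design$rho,
                 kept_interactions = model$design$kept_interactions,
                 type_names = model$design$type_names,
                 var_inflation = model$var_inflation,
                 config = config),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws x %d parameters, acceptance %.1f%%, rho = %g\n",
              nrow(x$draws), ncol(x$draws), 100 * x$acceptance_rate, x$rho))
  invisible(x)
}

#' Wald tests with false discovery rate control
#'
#' For each kept interaction, `W = mean^2 / var` of the retained draws is
#' referred to its asymptotic chi-squared(1) null distribution for a
#' pseudo-p-value; pseudo-p-values are Benjamini-Hochberg adjusted across
#' interactions (intercept, dispersion and power excluded) and an
#' interaction is called significant when the adjusted p-value falls below
#' `alpha`.
#'
#' When the spot random effects were estimated and then fixed (the default
#' pipeline), the per-coefficient variance is inflated by the plug-in
#' correction recorded at initialization, so that uncertainty in the fitted
#' offsets is not silently ignored.
#'
#' @param samples a [posterior_samples][run_mcmc] object.
#' @param alpha significance level on the adjusted p-value.
#' @param re_correction apply the plug-in variance correction when
#'   available.
#' @return A `ccc_result` data frame with columns `sender`, `receiver`,
#'   `estimate`, `variance`, `W`, `p`, `adjusted_p`, `significant`, `sign`.
#' @export
wald_inference <- function(samples, alpha = 0.05, re_correction = TRUE) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (nrow(samples$draws) < 100)
    stop("need at least 100 retained draws for Wald inference")
  d <- samples$draws
  keep <- setdiff(colnames(d), c("b0", "logphi", "theta"))
  est <- colMeans(d[, keep, drop = FALSE])
  v <- apply(d[, keep, drop = FALSE], 2, stats::var)
  if (re_correction && !is.null(samples$var_inflation))
    v <- v * samples$var_inflation
  W <- ifelse(v > 0, est^2 / v, Inf)
  p <- pmax(stats::pchisq(W, df = 1, lower.tail = FALSE), 1e-300)
  adj <- stats::p.adjust(p, method = "BH")
  ki <- samples$kept_interactions
  res <- data.frame(
    sender = samples$type_names[ki[, 1]],
    receiver = samples$type_names[ki[, 2]],
    estimate = est, variance = v, W = W, p = p, adjusted_p = adj,
    significant = adj < alpha, sign = sign(est),
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("ccc_result", "data.frame")
  res
}

#' Widely applicable information criterion (variance form)
#'
#' `WAIC2 = 2 sum_i var_s log p(c_i | .) - 2 sum_i log mean_s p(c_i | .)`,
#' where `p(c_i | .)` is the marginal (latent count summed out) compound
#' Poisson-Gamma density at each retained draw, including the fixed
#' random-effect offsets; the mean term uses log-sum-exp. Lower is better.
#'
#' @param samples a [posterior_samples][run_mcmc] object.
#' @param model the fitted [batcom_model] (provides scores, design and
#'   offsets).
#' @param thin evaluate every `thin`-th retained draw.
#' @return Scalar WAIC2 value.
#' @export
compute_waic2 <- function(samples, model, thin = NULL) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(model, "batcom_model"))
  S <- nrow(samples$draws)
  if (is.null(thin)) thin <- max(1L, S %/% 400L)
  idx <- seq(1L, S, by = thin)
  ll <- vapply(idx, function(s) {
    cp <- .cpg_at(samples$draws[s, ], model)
    cpg_marginal_logpdf_cpp(model$c, cp$lam, cp$alpha, cp$gam, 1e-10, 100000L)
  }, numeric(length(model$c)))
  # ll: n x S_thin
  vr <- apply(ll, 1, stats::var)
  mx <- apply(ll, 1, max)
  lppd <- mx + log(rowMeans(exp(ll - mx)))
  2 * sum(vr) - 2 * sum(lppd)
}

#' Select the distance-decay rate by WAIC2
#'
#' Fits the full model once per candidate `rho` and returns the candidate
#' with the lowest WAIC2 (exact ties break toward 0.5, the recommended
#' default). Failed fits are excluded with a warning.
#'
#' @param scores a [comm_score_set].
#' @param design_builder function mapping a `rho` value to a
#'   [design_matrix][build_design_matrix] over the same spot pairs as
#'   `scores`.
#' @param rho_grid candidate decay rates.
#' @param config a [sampler_config].
#' @return List with `best_rho`, the per-candidate `table`
#'   (`rho`, `waic2`), and `fits` (per-candidate `batcom_fit` objects).
#' @export
select_rho <- function(scores, design_builder, rho_grid = c(0.2, 0.5, 0.8),
                       config = sampler_config()) {
  stopifnot(length(rho_grid) >= 1)
  waic <- rep(NA_real_, length(rho_grid))
  fits <- vector("list", length(rho_grid))
  for (i in seq_along(rho_grid)) {
    fits[[i]] <- tryCatch({
      design <- standardize_design(design_builder(rho_grid[i]))
      model <- batcom_model(scores, design,
                            beta_prior_sd = config$beta_prior_sd,
                            nu_prior_var = config$nu_prior_var)
      cfg <- tune_sampler(model, config)
      samples <- run_mcmc(model, cfg)
      list(samples = samples, model = model,
           waic2 = compute_waic2(samples, model))
    }, error = function(e) {
      warning(sprintf("fit at rho = %g failed: %s", rho_grid[i],
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(fits[[i]])) waic[i] <- fits[[i]]$waic2
  }
  tab <- data.frame(rho = rho_grid, waic2 = waic)
  ok <- which(is.finite(waic))
  if (!length(ok)) stop("all candidate fits failed")
  best <- ok[order(waic[ok], abs(rho_grid[ok] - 0.5))][1]
  list(best_rho = rho_grid[best], table = tab, fits = fits)
}

#' Bayesian logistic comparator on the zero/nonzero indicator
#'
#' The LOGISTICS variant: the outcome is `1{C > 0}` and the same design
#' (intercept plus decay-weighted interaction covariates) enters a Bayesian
#' logistic regression with the same coefficient priors, no random effects
#' and no data augmentation; inference reuses the Wald / FDR path.
#'
#' @param scores a [comm_score_set].
#' @param design a [design_matrix][build_design_matrix].
#' @param config a [sampler_config].
#' @param alpha significance level.
#' @return List with `result` (a `ccc_result`), `samples` and
#'   `acceptance_rate`.
#' @export
fit_logistics_variant <- function(scores, design, config = sampler_config(),
                                  alpha = 0.05) {
  stopifnot(inherits(scores, "comm_score_set"), inherits(design, "design_matrix"))
  z <- as.numeric(scores$scores > 0)
  if (all(z == 0) || all(z == 1))
    stop("zero/nonzero indicator is constant; logistic variant undefined")
  X <- design$X
  k <- ncol(X)
  bsd <- config$beta_prior_sd
  lpfn <- function(q, t) {
    eta <- q[1] + drop(X %*% q[1 + seq_len(k)])
    r <- z - stats::plogis(eta)
    lp <- sum(z * eta - log1p(exp(pmin(eta, 30))) - pmax(eta - 30, 0)) -
      0.5 * q[1]^2 / 100^2 - 0.5 * sum(q[-1]^2) / bsd^2
    grad <- c(sum(r) - q[1] / 100^2, drop(crossprod(X, r)) - q[-1] / bsd^2)
    list(lp = lp, grad = grad)
  }
  set.seed(config$seed)
  q0 <- rep(0, k + 1)
  mock <- list(nz = integer(0))
  tune <- .run_chain(lpfn, q0, integer(0), mock, config$n_tune, config,
                     state = list(tmax = 1L, eps = config$step_size,
                                  mass = config$mass_diagonal),
                     adapt = TRUE, t_update = FALSE)
  set.seed(config$seed + 1L)
  run <- .run_chain(lpfn, tune$state$q, integer(0), mock, config$n_main,
                    config, state = tune$state, adapt = FALSE,
                    t_update = FALSE, shrink_until = config$n_burn)
  keep <- (config$n_burn + 1L):config$n_main
  draws <- run$draws[keep, , drop = FALSE]
  colnames(draws) <- c("b0", design$interaction_names)
  samples <- structure(list(draws = draws,
                            acceptance_rate = mean(run$accepted),
                            divergences = run$divergences,
                            rho = design$rho,
                            kept_interactions = design$kept_interactions,
                            type_names = design$type_names,
                            config = config),
                       class = "posterior_samples")
  list(result = wald_inference(samples, alpha), samples = samples,
       acceptance_rate = samples$acceptance_rate)
}
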