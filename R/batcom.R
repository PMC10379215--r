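#' Fit the spatial cell-cell communication model
#'
#' End-to-end fit on one communication score set: optional distance
#' thresholding of spot pairs, interaction filtering, design construction at
#' the chosen decay rate `rho`, random-effect initialization, Hamiltonian
#' Monte Carlo with latent-count augmentation, and Wald / FDR inference on
#' the directed cell-type interactions.
#'
#' Variants: `"batcom"` uses the full proportion matrix; `"maxprop"`
#' one-hot-binarizes each spot at its modal cell type (mimicking single-label
#' tools); `"logistics"` models only the zero/nonzero indicator with a
#' logistic likelihood.
#'
#' @param scores a [comm_score_set] whose `pair_index` defines the modeled
#'   spot pairs.
#' @param props a [cell_type_proportions].
#' @param geom a [spot_geometry][compute_scaled_distances].
#' @param rho distance-decay rate (default 0.5, the recommended default when
#'   fitting a single model; see [select_rho()] for WAIC2-based selection).
#' @param max_distance optional scaled-distance threshold; pairs farther
#'   apart are dropped from the fit.
#' @param variant model variant, see Details.
#' @param config a [sampler_config].
#' @param min_mass interaction filter threshold, see [filter_interactions()].
#' @param alpha significance level on BH-adjusted p-values.
#' @param standardize center and scale the interaction covariates before
#'   fitting (see [standardize_design()]); reported estimates are then
#'   effects per covariate standard deviation.
#' @param compute_waic also compute WAIC2 (adds one pass over the draws).
#' @return An object of class `batcom_fit`: `result` (a `ccc_result` data
#'   frame), `samples`, `design`, `re` (random-effect initialization, where
#'   applicable), `acceptance_rate`, `waic2`, `variant`.
#' @export
batcom <- function(scores, props, geom, rho = 0.5, max_distance = NULL,
                   variant = c("batcom", "maxprop", "logistics"),
                   config = sampler_config(), min_mass = 0, alpha = 0.05,
                   standardize = TRUE, compute_waic = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(scores, "comm_score_set"),
            inherits(props, "cell_type_proportions"),
            inherits(geom, "spot_geometry"))
  if (variant == "maxprop") props <- binarize_proportions(props)
  pairs <- scores$pair_index
  if (!is.null(max_distance)) {
    keep <- geom$D[pairs] <= max_distance
    pairs <- pairs[keep, , drop = FALSE]
    scores <- comm_score_set(pairs, scores$scores[keep], scores$lr_name)
  }
  kept <- filter_interactions(props, geom, pairs, rho, min_mass)
  design <- build_design_matrix(props, geom, pairs, rho, kept)
  if (standardize) design <- standardize_design(design)

  if (variant == "logistics") {
    lf <- fit_logistics_variant(scores, design, config, alpha)
    return(structure(list(result = lf$result, samples = lf$samples,
                          design = design, re = NULL,
                          acceptance_rate = lf$acceptance_rate,
                          waic2 = NA_real_, variant = variant, rho = rho),
                     class = "batcom_fit"))
  }
  re <- initialize_random_effects(scores, design,
                                  nu_prior_var = config$nu_prior_var)
  model <- batcom_model(scores, design, re,
                        beta_prior_sd = config$beta_prior_sd)
  cfg <- tune_sampler(model, config)
  samples <- run_mcmc(model, cfg)
  structure(list(result = wald_inference(samples, alpha), samples = samples,
                 design = design, re = re,
                 acceptance_rate = samples$acceptance_rate,
                 waic2 = if (compute_waic) compute_waic2(samples, model)
                         else NA_real_,
                 variant = variant, rho = rho),
            class = "batcom_fit")
}

#' @export
print.batcom_fit <- function(x, ...) {
  cat(sprintf("<batcom_fit> variant %s, rho = %g, acceptance %.1f%%\n",
              x$variant, x$rho, 100 * x$acceptance_rate))
  cat(sprintf("  %d interactions tested, %d significant (BH-adjusted)\n",
              nrow(x$result), sum(x$result$significant)))
  invisible(x)
}
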