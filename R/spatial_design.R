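#' Spot geometry with adjacency-scaled distances
#'
#' Euclidean pairwise distances rescaled so that the closest two spots are at
#' distance 1 — the natural unit for regular Visium-like lattices, where the
#' decay parameter `rho` is then interpretable per lattice step.
#'
#' @param coords two-column numeric matrix or data frame of (x, y)
#'   coordinates.
#' @param spot_ids optional spot labels (default: rownames or seq).
#' @return An object of class `spot_geometry` with fields `spot_ids`,
#'   `coords` and the scaled symmetric distance matrix `D`.
#' @export
compute_scaled_distances <- function(coords, spot_ids = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 spots")
  if (is.null(spot_ids))
    spot_ids <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  D <- as.matrix(stats::dist(coords))
  off <- D[upper.tri(D)]
  if (all(off == 0)) stop("all spots coincide; no distance scale")
  if (any(off == 0))
    warning("duplicate coordinates; scaling uses the minimum nonzero distance")
  D <- D / min(off[off > 0])
  dimnames(D) <- list(spot_ids, spot_ids)
  structure(list(spot_ids = as.character(spot_ids), coords = coords, D = D),
            class = "spot_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordered spot pairs within a distance threshold
#'
#' Enumerates ordered (sender, receiver) index pairs in deterministic
#' sender-major order, optionally restricted to scaled distance
#' `<= max_distance`. Self-pairs (autocrine signaling) are included by
#' default.
#'
#' @param geom a [spot_geometry][compute_scaled_distances].
#' @param max_distance positive threshold on the scaled distance, or `NULL`
#'   for all pairs.
#' @param include_self keep (i, i) pairs?
#' @return Two-column integer matrix with columns `sender`, `receiver`.
#' @export
select_pairs <- function(geom, max_distance = NULL, include_self = TRUE) {
  stopifnot(inherits(geom, "spot_geometry"))
  n <- length(geom$spot_ids)
  keep <- if (is.null(max_distance)) {
    matrix(TRUE, n, n)
  } else {
    stopifnot(max_distance > 0)
    geom$D <= max_distance
  }
  if (!include_self) diag(keep) <- FALSE
  # sender-major: row index = sender, iterate receivers within sender
  idx <- which(t(keep))
  cbind(sender = (idx - 1L) %/% n + 1L, receiver = (idx - 1L) %% n + 1L)
}

#' Cell-type proportion matrix
#'
#' @param M spot x cell-type matrix; entries in `[0, 1]`, rows summing to 1
#'   (tolerance 1e-6), as produced by deconvolution tools such as RCTD.
#' @param type_names,spot_ids optional labels (default dimnames).
#' @return An object of class `cell_type_proportions`.
#' @export
cell_type_proportions <- function(M, type_names = colnames(M),
                                  spot_ids = rownames(M)) {
  M <- as.matrix(M)
  if (is.null(type_names)) type_names <- paste0("type", seq_len(ncol(M)))
  if (is.null(spot_ids)) spot_ids <- as.character(seq_len(nrow(M)))
  if (any(M < 0) || any(M > 1)) stop("proportions must lie in [0, 1]")
  dev <- abs(rowSums(M) - 1)
  if (any(dev > 1e-6))
    stop(sprintf("proportion rows must sum to 1 (max |row sum - 1| = %.3g)",
                 max(dev)))
  dimnames(M) <- list(spot_ids, type_names)
  structure(list(M = M, type_names = as.character(type_names),
                 spot_ids = as.character(spot_ids)),
            class = "cell_type_proportions")
}

#' One-hot proportions at the modal cell type (MAXPROP)
#'
#' Mimics single-label communication tools by assigning each spot only its
#' most prevalent cell type; ties break toward the lowest column index.
#' Idempotent.
#'
#' @param props a [cell_type_proportions].
#' @return A one-hot [cell_type_proportions].
#' @export
binarize_proportions <- function(props) {
  stopifnot(inherits(props, "cell_type_proportions"))
  M <- props$M
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  out[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))] <- 1
  cell_type_proportions(out, props$type_names, props$spot_ids)
}

#' Regression design for spot-pair communication scores
#'
#' One row per kept (sender, receiver) spot pair; an intercept plus one
#' column per kept directed cell-type interaction (g1, g2), with entry
#' `M[i, g1] * M[j, g2] * exp(-rho * D[i, j])`. The exponential factor
#' down-weights interactions between distant spots; `exp(-rho * 0) = 1` on
#' self-pairs.
#'
#' @param props a [cell_type_proportions].
#' @param geom a [spot_geometry][compute_scaled_distances].
#' @param pairs two-column (sender, receiver) index matrix from
#'   [select_pairs()].
#' @param rho positive distance-decay rate.
#' @param kept_interactions two-column integer matrix of (g1, g2) cell-type
#'   indices; default all `G^2` ordered interactions.
#' @return An object of class `design_matrix` with fields `X` (interaction
#'   columns, no intercept), `sender_idx`, `receiver_idx`, `rho`,
#'   `kept_interactions`, `interaction_names`, `n_spots`.
#' @export
build_design_matrix <- function(props, geom, pairs, rho,
                                kept_interactions = NULL) {
  stopifnot(inherits(props, "cell_type_proportions"),
            inherits(geom, "spot_geometry"))
  if (rho <= 0) stop("`rho` must be positive")
  pairs <- as.matrix(pairs)
  G <- ncol(props$M)
  if (is.null(kept_interactions))
    kept_interactions <- as.matrix(expand.grid(g2 = seq_len(G),
                                               g1 = seq_len(G)))[, c(2, 1)]
  kept_interactions <- as.matrix(kept_interactions)
  decay <- exp(-rho * geom$D[pairs])
  Ms <- props$M[pairs[, 1], , drop = FALSE]
  Mr <- props$M[pairs[, 2], , drop = FALSE]
  X <- Ms[, kept_interactions[, 1], drop = FALSE] *
    Mr[, kept_interactions[, 2], drop = FALSE] * decay
  nm <- paste0(props$type_names[kept_interactions[, 1]], "->",
               props$type_names[kept_interactions[, 2]])
  colnames(X) <- nm
  structure(list(X = X, sender_idx = pairs[, 1], receiver_idx = pairs[, 2],
                 rho = rho, kept_interactions = kept_interactions,
                 interaction_names = nm, n_spots = length(geom$spot_ids),
                 type_names = props$type_names),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d spot pairs x (1 + %d interactions), rho = %g\n",
              nrow(x$X), ncol(x$X), x$rho))
  invisible(x)
}

#' Center and scale design covariates
#'
#' Fitting-layer transform: each interaction column is centered and scaled to
#' unit variance over the fitted spot pairs, so coefficients are effects per
#' standard deviation of their covariate and the standard-normal coefficient
#' prior is scale-appropriate. Constant columns are centered only. The raw
#' design from [build_design_matrix()] is unchanged; centers and scales are
#' kept on the returned object.
#'
#' @param design a [design_matrix][build_design_matrix].
#' @return The design with standardized `X` and fields `x_center`, `x_scale`,
#'   `standardized = TRUE`.
#' @export
standardize_design <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  if (isTRUE(design$standardized)) return(design)
  ctr <- colMeans(design$X)
  scl <- apply(design$X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  design$X <- sweep(sweep(design$X, 2, ctr), 2, scl, "/")
  design$x_center <- ctr
  design$x_scale <- scl
  design$standardized <- TRUE
  design
}

#' Drop cell-type interactions with negligible covariate mass
#'
#' Keeps a directed interaction (g1, g2) iff the total covariate mass
#' `sum over pairs of M[i, g1] M[j, g2] exp(-rho D)` exceeds
#' `min_mass * nrow(pairs)`. With the default `min_mass = 0` every
#' interaction with any positive mass is kept; raising it prunes
#' interactions with minimal or non-existent observations, as is useful on
#' real tissue where some types never co-occur within the threshold.
#'
#' @inheritParams build_design_matrix
#' @param min_mass nonnegative per-pair mass threshold.
#' @return Two-column integer matrix of kept (g1, g2) interactions.
#' @export
filter_interactions <- function(props, geom, pairs, rho, min_mass = 0) {
  stopifnot(min_mass >= 0)
  d <- build_design_matrix(props, geom, pairs, rho)
  mass <- colSums(d$X)
  d$kept_interactions[mass > min_mass * nrow(d$X), , drop = FALSE]
}
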