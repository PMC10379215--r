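#' Spot-by-gene expression matrix
#'
#' Thin validated wrapper around a numeric spot x gene matrix of normalized
#' expression. Normalization is accepted as given; see
#' [normalize_expression()] for an optional convenience transform.
#'
#' @param values numeric matrix, spots in rows, genes in columns, entries
#'   `>= 0`.
#' @param spot_ids,gene_ids optional label vectors; default to the
#'   dimnames of `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, spot_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(spot_ids) || is.null(gene_ids))
    stop("spot and gene labels are required")
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (anyDuplicated(spot_ids)) stop("duplicate spot labels")
  if (anyDuplicated(gene_ids)) stop("duplicate gene labels")
  if (nrow(values) < 2) stop("need at least 2 spots")
  dimnames(values) <- list(spot_ids, gene_ids)
  structure(list(values = values, spot_ids = as.character(spot_ids),
                 gene_ids = as.character(gene_ids)),
            class = "expression_matrix")
}

#' Optional library-size + log1p preprocessing
#'
#' Convenience only: scales each spot to the median library size and applies
#' `log1p`. The model itself takes normalized expression as given.
#'
#' @param expr an [expression_matrix].
#' @return A transformed [expression_matrix].
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  lib <- rowSums(expr$values)
  if (any(lib == 0)) stop("spot(s) with zero total expression")
  v <- log1p(expr$values * (stats::median(lib) / lib))
  expression_matrix(v, expr$spot_ids, expr$gene_ids)
}

#' Ligand-receptor pair
#'
#' @param name pair label, e.g. `"SERPINE1_ITGB5"`.
#' @param ligand_subunits,receptor_subunits character vectors of gene symbols
#'   (multi-subunit complexes list each subunit).
#' @param pathway optional pathway label.
#' @return An object of class `lr_pair`.
#' @export
lr_pair <- function(name, ligand_subunits, receptor_subunits, pathway = NULL) {
  if (!length(ligand_subunits) || !length(receptor_subunits))
    stop("subunit lists must be non-empty")
  if (anyDuplicated(ligand_subunits) || anyDuplicated(receptor_subunits))
    stop("duplicate subunit symbols within a complex")
  structure(list(name = name,
                 ligand_subunits = as.character(ligand_subunits),
                 receptor_subunits = as.character(receptor_subunits),
                 pathway = pathway),
            class = "lr_pair")
}

#' Spot-pair communication scores
#'
#' One nonnegative score per ordered (sender, receiver) spot pair for a
#' ligand-receptor pair (or an aggregate over pairs). The fraction of exact
#' zeros is tracked because it drives both the pair filter and the
#' zero-inflated likelihood.
#'
#' @param pair_index two-column integer matrix of (sender, receiver) spot
#'   indices.
#' @param scores numeric vector of nonnegative scores, one per row of
#'   `pair_index`.
#' @param lr_name label of the LR pair, or `"aggregate"`.
#' @param available `FALSE` when any subunit gene was absent from the
#'   expression matrix (scores are then `NA` and the set is dropped by
#'   [filter_lr_pairs()]).
#' @return An object of class `comm_score_set`.
#' @export
comm_score_set <- function(pair_index, scores, lr_name = "aggregate",
                           available = TRUE) {
  pair_index <- as.matrix(pair_index)
  if (ncol(pair_index) != 2) stop("`pair_index` needs (sender, receiver) columns")
  if (nrow(pair_index) != length(scores))
    stop("one score per spot pair required")
  if (available && any(scores < 0)) stop("scores must be nonnegative")
  structure(list(pair_index = pair_index, scores = as.numeric(scores),
                 lr_name = lr_name, available = available,
                 zero_fraction = if (available) mean(scores == 0) else NA_real_),
            class = "comm_score_set")
}

#' @export
print.comm_score_set <- function(x, ...) {
  cat(sprintf("<comm_score_set> %s: %d spot pairs, %.1f%% zeros%s\n",
              x$lr_name, nrow(x$pair_index), 100 * x$zero_fraction,
              if (!x$available) " (unavailable)" else ""))
  invisible(x)
}

#' Mean expression of a subunit complex at one spot
#'
#' Arithmetic mean over the listed subunit genes (the geometric mean is an
#' option in [compute_comm_scores()] but introduces many more zeros).
#'
#' @param expr an [expression_matrix].
#' @param spot a spot label.
#' @param subunits character vector of gene symbols.
#' @return Nonnegative scalar.
#' @export
subunit_mean <- function(expr, spot, subunits) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!spot %in% expr$spot_ids) stop("unknown spot label: ", spot)
  miss <- setdiff(subunits, expr$gene_ids)
  if (length(miss)) stop("unknown gene symbol(s): ", paste(miss, collapse = ", "))
  mean(expr$values[spot, subunits])
}

#' Spot-to-spot communication scores for one LR pair
#'
#' The score from sender spot i to receiver spot j is the product of the mean
#' ligand-subunit expression at i and the mean receptor-subunit expression at
#' j. Pairs whose subunit genes are absent from the matrix are returned
#' flagged unavailable rather than raising an error, so that batch scoring
#' over a database proceeds and [filter_lr_pairs()] can drop them.
#'
#' @param expr an [expression_matrix].
#' @param lr an [lr_pair].
#' @param pairs two-column matrix of (sender, receiver) spot indices, e.g.
#'   from [select_pairs()]; self-pairs are allowed.
#' @param pooling subunit pooling: arithmetic (default) or geometric mean.
#' @return A [comm_score_set].
#' @export
compute_comm_scores <- function(expr, lr, pairs,
                                pooling = c("arithmetic", "geometric")) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(lr, "lr_pair"))
  pooling <- match.arg(pooling)
  pairs <- as.matrix(pairs)
  miss <- setdiff(c(lr$ligand_subunits, lr$receptor_subunits), expr$gene_ids)
  if (length(miss))
    return(comm_score_set(pairs, rep(NA_real_, nrow(pairs)), lr$name,
                          available = FALSE))
  pool <- function(sub) {
    v <- expr$values[, sub, drop = FALSE]
    if (pooling == "arithmetic") rowMeans(v)
    else exp(rowMeans(log(v))) # 0 if any subunit is 0
  }
  lig <- pool(lr$ligand_subunits)
  rec <- pool(lr$receptor_subunits)
  comm_score_set(pairs, lig[pairs[, 1]] * rec[pairs[, 2]], lr$name)
}

#' Score every LR pair in a database
#'
#' @param expr an [expression_matrix].
#' @param lr_list list of [lr_pair] objects.
#' @inheritParams compute_comm_scores
#' @return List of [comm_score_set] objects (including unavailable ones).
#' @export
score_lr_pairs <- function(expr, lr_list, pairs,
                           pooling = c("arithmetic", "geometric")) {
  pooling <- match.arg(pooling)
  lapply(lr_list, compute_comm_scores, expr = expr, pairs = pairs,
         pooling = pooling)
}

#' Drop uninformative LR pairs
#'
#' Removes score sets whose zero fraction strictly exceeds
#' `max_zero_fraction` (default 0.98: a pair with more than 98% zeros is
#' uninformative) as well as sets flagged unavailable. The zero fraction is
#' evaluated over the supplied pair list, i.e. after any distance threshold,
#' since that is the model's outcome vector.
#'
#' @param score_sets list of [comm_score_set] objects.
#' @param max_zero_fraction retention bound in (0, 1).
#' @return The kept subset of `score_sets`.
#' @export
filter_lr_pairs <- function(score_sets, max_zero_fraction = 0.98) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction < 1)
  keep <- vapply(score_sets, function(s)
    s$available && s$zero_fraction <= max_zero_fraction, logical(1))
  score_sets[keep]
}

#' Aggregate scores across LR pairs
#'
#' Elementwise sum over score sets sharing one pair index — the
#' pathway-level or whole-system outcome.
#'
#' @param score_sets non-empty list of [comm_score_set] objects with
#'   identical `pair_index`.
#' @return A [comm_score_set] named `"aggregate"`.
#' @export
aggregate_scores <- function(score_sets) {
  if (!length(score_sets)) stop("no score sets to aggregate")
  idx <- score_sets[[1]]$pair_index
  for (s in score_sets) {
    if (!s$available) stop("cannot aggregate unavailable score sets")
    if (!identical(dim(s$pair_index), dim(idx)) || any(s$pair_index != idx))
      stop("score sets have mismatched pair indices")
  }
  total <- Reduce(`+`, lapply(score_sets, `[[`, "scores"))
  comm_score_set(idx, total, "aggregate")
}
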