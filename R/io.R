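#' Read an expression matrix
#'
#' Two on-disk layouts are supported: a MatrixMarket triplet file (1-based
#' indices, genes in rows and spots in columns per the features x barcodes
#' convention; transposed to spot x gene in memory) with sidecar text files
#' listing spot and gene labels one per line, or a dense CSV whose first
#' column holds spot ids and whose header row holds gene symbols.
#'
#' @param path `.mtx` or `.csv` file.
#' @param spots_file,genes_file sidecar label files (MTX only).
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, spots_file = NULL, genes_file = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(spots_file) || is.null(genes_file))
      stop("MTX input needs `spots_file` and `genes_file` sidecars")
    m <- Matrix::readMM(path)
    spots <- readLines(spots_file)
    genes <- readLines(genes_file)
    if (nrow(m) != length(genes) || ncol(m) != length(spots))
      stop("MTX dimensions do not match sidecar label counts")
    expression_matrix(t(as.matrix(m)), spots, genes)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    expression_matrix(as.matrix(df[, -1, drop = FALSE]),
                      spot_ids = df[[1]], gene_ids = colnames(df)[-1])
  }
}

#' Read spot coordinates
#'
#' @param path CSV with columns `spot_id`, `x`, `y`.
#' @return A [spot_geometry][compute_scaled_distances] with adjacency-scaled
#'   distances.
#' @export
read_coords <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("spot_id", "x", "y") %in% names(df)))
    stop("coordinates CSV needs columns spot_id, x, y")
  compute_scaled_distances(as.matrix(df[, c("x", "y")]),
                           as.character(df$spot_id))
}

#' Read cell-type proportions
#'
#' @param path CSV with a `spot_id` column and one column per cell type;
#'   rows must sum to 1 (tolerance 1e-6).
#' @return A [cell_type_proportions].
#' @export
read_proportions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "spot_id") stop("proportions CSV must start with spot_id")
  cell_type_proportions(as.matrix(df[, -1, drop = FALSE]),
                        type_names = colnames(df)[-1],
                        spot_ids = as.character(df$spot_id))
}

#' Read a ligand-receptor database
#'
#' CSV with columns `lr_pair`, `ligand`, `receptor` and optional `pathway`;
#' multi-subunit complexes are underscore-joined gene symbols (e.g.
#' `ITGA5_ITGB5`), following the CellTalkDB / CellPhoneDB convention.
#'
#' @param path CSV file.
#' @return List of [lr_pair] objects.
#' @export
read_lr_database <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lr_pair", "ligand", "receptor") %in% names(df)))
    stop("LR database CSV needs columns lr_pair, ligand, receptor")
  lapply(seq_len(nrow(df)), function(i)
    lr_pair(df$lr_pair[i],
            strsplit(df$ligand[i], "_", fixed = TRUE)[[1]],
            strsplit(df$receptor[i], "_", fixed = TRUE)[[1]],
            pathway = if ("pathway" %in% names(df)) df$pathway[i] else NULL))
}

#' Run configuration
#'
#' @param expression,coords,proportions,lr_db input file paths (see the
#'   respective readers); `expression_spots` / `expression_genes` are the MTX
#'   sidecars when needed.
#' @param rho decay rate, or `rho_grid` for WAIC2 selection.
#' @param max_distance optional scaled-distance threshold for spot pairs.
#' @param zero_cutoff LR-pair zero-fraction retention bound.
#' @param variant one of `"batcom"`, `"maxprop"`, `"logistics"`.
#' @param filter_spots drop spots with fewer than 100 detected genes.
#' @param filter_genes drop genes with zero expression in more than 97.5% of
#'   spots.
#' @param sampler a [sampler_config].
#' @param outdir output directory.
#' @param seed integer seed.
#' @param expression_spots,expression_genes MTX sidecar label files.
#' @param rho_grid optional candidate decay rates.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, coords, proportions, lr_db,
                       expression_spots = NULL, expression_genes = NULL,
                       rho = 0.5, rho_grid = NULL, max_distance = NULL,
                       zero_cutoff = 0.98,
                       variant = c("batcom", "maxprop", "logistics"),
                       filter_spots = TRUE, filter_genes = TRUE,
                       sampler = sampler_config(), outdir = ".", seed = 1L) {
  variant <- match.arg(variant)
  paths <- c(expression, coords, proportions, lr_db,
             expression_spots, expression_genes)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(list(expression = expression, coords = coords,
                 proportions = proportions, lr_db = lr_db,
                 expression_spots = expression_spots,
                 expression_genes = expression_genes,
                 rho = rho, rho_grid = rho_grid,
                 max_distance = max_distance, zero_cutoff = zero_cutoff,
                 variant = variant, filter_spots = filter_spots,
                 filter_genes = filter_genes, sampler = sampler,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load and align all inputs
#'
#' Reads the expression matrix, coordinates, proportions and LR list;
#' optionally applies the case-study-style quality filters (spots with at
#' least 100 detected genes; genes with nonzero expression in at least 2.5%
#' of spots, i.e. dropping genes that are zero in more than 97.5% of spots);
#' and aligns spot ordering across inputs by label.
#'
#' @param config a [run_config].
#' @return List with `expr`, `geom`, `props`, `lr_list`.
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  expr <- read_expression(config$expression, config$expression_spots,
                          config$expression_genes)
  geom <- read_coords(config$coords)
  props <- read_proportions(config$proportions)
  lr_list <- read_lr_database(config$lr_db)

  if (config$filter_spots) {
    detected <- rowSums(expr$values > 0)
    expr <- expression_matrix(expr$values[detected >= 100, , drop = FALSE])
  }
  if (config$filter_genes) {
    zero_frac <- colMeans(expr$values == 0)
    expr <- expression_matrix(expr$values[, zero_frac <= 0.975, drop = FALSE])
  }

  mism <- c(setdiff(expr$spot_ids, geom$spot_ids),
            setdiff(expr$spot_ids, props$spot_ids))
  if (length(mism))
    stop("spot labels missing from coordinates/proportions: ",
         paste(unique(mism), collapse = ", "))
  ord <- expr$spot_ids
  geom <- compute_scaled_distances(
    geom$coords[match(ord, geom$spot_ids), , drop = FALSE], ord)
  props <- cell_type_proportions(props$M[match(ord, props$spot_ids), ,
                                         drop = FALSE],
                                 props$type_names, ord)
  list(expr = expr, geom = geom, props = props, lr_list = lr_list)
}

#' Write fit results to disk
#'
#' Emits `results.csv` (all tested interactions), `edges.csv` (significant
#' interactions only: `sender,receiver,weight,sign` with weight
#' `|estimate|`), `heatmap.csv` (cell-type x cell-type estimate matrix, `NA`
#' where the interaction was filtered) and `run_metadata.json` (seed, config
#' hash, acceptance rate, WAIC2 per candidate rho when available).
#'
#' @param fit a `batcom_fit` from [batcom()].
#' @param outdir output directory (created if needed).
#' @param config optional [run_config] recorded in the metadata.
#' @param waic_table optional per-rho WAIC2 table from [select_rho()].
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(fit, outdir, config = NULL, waic_table = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- fit$result
  f_res <- file.path(outdir, "results.csv")
  utils::write.csv(res, f_res, row.names = FALSE)

  sig <- res[res$significant, c("sender", "receiver", "estimate", "sign")]
  edges <- data.frame(sender = sig$sender, receiver = sig$receiver,
                      weight = abs(sig$estimate), sign = sig$sign)
  f_edges <- file.path(outdir, "edges.csv")
  utils::write.csv(edges, f_edges, row.names = FALSE)

  types <- fit$design$type_names
  H <- matrix(NA_real_, length(types), length(types),
              dimnames = list(types, types))
  H[cbind(match(res$sender, types), match(res$receiver, types))] <- res$estimate
  f_heat <- file.path(outdir, "heatmap.csv")
  utils::write.csv(as.data.frame(H), f_heat, row.names = TRUE)

  meta <- list(seed = if (!is.null(config)) config$seed else
                 fit$samples$config$seed,
               variant = fit$variant, rho = fit$rho,
               acceptance_rate = fit$acceptance_rate,
               waic2 = fit$waic2,
               config_hash = if (!is.null(config)) config_hash(config) else NULL,
               waic_table = waic_table)
  f_meta <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(f_res, f_edges, f_heat, f_meta))
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; changes iff any configuration
#' field changes.
#'
#' @param config a [run_config] (or any serializable list).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}
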