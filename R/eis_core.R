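# Core statistic: per-sample expression impact scores (EIS), resampled
# background models, Z standardization and Stouffer combination.

#' Analysis configuration
#'
#' @param n_sampling Number of background resampling replicates per
#'   background model (default 10000).
#' @param min_altered Minimum number of altered tumor samples (with
#'   non-missing expression) for a gene to be analyzed (default 2).
#' @param alpha Significance level applied to the corrected p value
#'   (default 0.05).
#' @param seed Optional integer seed set at the start of [cis_analyze()];
#'   `NULL` leaves the RNG stream untouched.
#' @param epsilon_scale Denominator guard: IQR sums below
#'   `epsilon_scale * IQR(all expression values)` are clamped to that floor
#'   (default 1e-3).
#' @param z_max Cap for the standard score when a background model is
#'   degenerate (sd of resampled medians equals 0; default 50).
#' @param correction Multiple-testing correction across the genes of one
#'   alteration set: `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return A list of class `cis_config`.
#' @export
cis_config <- function(n_sampling = 10000, min_altered = 2, alpha = 0.05,
                       seed = NULL, epsilon_scale = 1e-3, z_max = 50,
                       correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(n_sampling >= 1, min_altered >= 1, alpha > 0, alpha < 1,
            epsilon_scale > 0, z_max > 0)
  structure(list(n_sampling = as.integer(n_sampling),
                 min_altered = as.integer(min_altered),
                 alpha = alpha, seed = seed,
                 epsilon_scale = epsilon_scale, z_max = z_max,
                 correction = correction),
            class = "cis_config")
}

#' Partition tumor samples by copy-number status for one gene
#'
#' Only multi-copy amplifications (+2) or homozygous deletions (-2) count
#' as events; single-copy changes and opposite-sign events are excluded
#' from both the altered and the diploid reference group. Normal samples
#' are returned regardless of their copy-number codes.
#'
#' @param dataset A `cis_dataset` from [align_dataset()].
#' @param gene Gene id.
#' @param direction `"AMP"` or `"DEL"`.
#' @return List with character vectors `altered`, `diploid`, `normal`.
#' @export
select_event_samples <- function(dataset, gene, direction = c("AMP", "DEL")) {
  direction <- match.arg(direction)
  if (!gene %in% rownames(dataset$cna)) {
    stop("gene not in dataset: ", gene, call. = FALSE)
  }
  codes <- dataset$cna[gene, ]
  tumors <- names(dataset$annotation)[dataset$annotation == "TUMOR"]
  normals <- names(dataset$annotation)[dataset$annotation == "NORMAL"]
  target <- if (direction == "AMP") 2L else -2L
  list(altered = tumors[codes[tumors] == target],
       diploid = tumors[codes[tumors] == 0L],
       normal = normals)
}

#' Reference statistics for the EIS denominator and centering
#'
#' @param expr_altered Expression values of the altered tumor group.
#' @param expr_reference Expression values of the reference group (normals
#'   or diploid tumors). Missing values are dropped.
#' @return List with `median_ref`, `iqr_ref`, `iqr_alt`. Interquartile
#'   ranges use linear interpolation (quantile type 7).
#' @export
reference_stats <- function(expr_altered, expr_reference) {
  a <- expr_altered[is.finite(expr_altered)]
  r <- expr_reference[is.finite(expr_reference)]
  if (length(r) == 0) {
    stop("empty reference group", call. = FALSE)
  }
  list(median_ref = median(r),
       iqr_ref = IQR(r),
       iqr_alt = if (length(a)) IQR(a) else 0)
}

#' Per-sample expression impact score
#'
#' `EIS = (exp - median_ref) / max(iqr_alt + iqr_ref, epsilon)`: the
#' deviation of one altered sample's expression from the reference median,
#' scaled by the summed spreads of the altered and reference groups.
#'
#' @param exp Expression value of the gene in the altered sample.
#' @param ref Reference statistics from [reference_stats()].
#' @param epsilon Denominator floor (> 0).
#' @return The score; its sign equals the sign of `exp - median_ref`.
#' @export
compute_sample_eis <- function(exp, ref, epsilon) {
  stopifnot(epsilon > 0)
  (exp - ref$median_ref) / max(ref$iqr_alt + ref$iqr_ref, epsilon)
}

#' Observed per-gene EIS
#'
#' The median of the per-sample scores over all altered samples of the
#' gene (interpolated for even counts).
#'
#' @param sample_scores Numeric vector of per-sample EIS values.
#' @return The median score.
#' @export
observed_gene_eis <- function(sample_scores) {
  x <- sample_scores[is.finite(sample_scores)]
  if (length(x) == 0) {
    stop("no sample scores: gene must be skipped", call. = FALSE)
  }
  median(x)
}

#' Resampled background model for an observed EIS
#'
#' Draws `n` values uniformly with replacement from the pooled per-sample
#' EIS values of the whole alteration set, `n_reps` times, recording the
#' median of each draw. The background model is the mean and standard
#' deviation of those medians. Uses the current RNG stream.
#'
#' @param pool Numeric vector of all per-sample EIS values for one
#'   reference comparison and direction.
#' @param n Number of altered samples of the gene being standardized.
#' @param n_reps Number of resampling replicates.
#' @return List with `mean`, `sd`, `n_reps`.
#' @export
build_background <- function(pool, n, n_reps) {
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0) stop("empty EIS pool", call. = FALSE)
  stopifnot(n >= 1, n_reps >= 2)
  med <- .resample_medians(as.numeric(pool), as.integer(n),
                           as.integer(n_reps))
  list(mean = mean(med), sd = sd(med), n_reps = as.integer(n_reps))
}

#' Standard score of an observed EIS against its background model
#'
#' @param observed Observed per-gene EIS.
#' @param bg Background model from [build_background()].
#' @param z_max Cap used when the background sd is 0 (default 50): returns
#'   0 if the observation equals the background mean, otherwise
#'   `sign(observed - mean) * z_max`.
#' @return The standard score `(observed - mean) / sd`.
#' @export
z_score <- function(observed, bg, z_max = 50) {
  if (bg$sd == 0) {
    d <- observed - bg$mean
    return(if (d == 0) 0 else sign(d) * z_max)
  }
  (observed - bg$mean) / bg$sd
}

#' Stouffer combination of the two standard scores
#'
#' Equal-weight combination `(z_normal + z_tumor) / sqrt(2)`. When no
#' normal samples are available (`z_normal` is `NULL` or `NA`), the
#' tumor-only score is returned unchanged.
#'
#' @param z_normal Standard score versus the normal-sample reference, or
#'   `NA`/`NULL` when absent.
#' @param z_tumor Standard score versus the diploid-tumor reference.
#' @return The combined score.
#' @export
combine_stouffer <- function(z_normal, z_tumor) {
  if (is.null(z_normal) || is.na(z_normal)) return(z_tumor)
  (z_normal + z_tumor) / sqrt(2)
}

#' Significance of combined scores within one alteration set
#'
#' One-sided standard-normal p values in the direction of the expected
#' effect (amplification: upper tail; deletion: lower tail), corrected
#' across the genes of the alteration set.
#'
#' @param z_comb Numeric vector of combined scores.
#' @param direction `"AMP"` or `"DEL"`.
#' @param alpha Significance level on the corrected p value.
#' @param correction `"bh"` or `"bonferroni"`.
#' @return Data frame with `p_value`, `corrected_p`, `is_positive`.
#' @export
eis_significance <- function(z_comb, direction = c("AMP", "DEL"),
                             alpha = 0.05, correction = c("bh", "bonferroni")) {
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  if (length(z_comb) == 0) stop("no scores", call. = FALSE)
  p <- if (direction == "AMP") pnorm(z_comb, lower.tail = FALSE)
       else pnorm(z_comb)
  cp <- p.adjust(p, method = if (correction == "bh") "BH" else "bonferroni")
  data.frame(p_value = p, corrected_p = cp, is_positive = cp <= alpha)
}

# Background model cache: the resampled null depends only on the pool and
# on the number of altered samples n, so models are built once per distinct
# n and shared across genes.
background_table <- function(pool, ns, n_reps) {
  uns <- sort(unique(ns))
  models <- lapply(uns, function(n) build_background(pool, n, n_reps))
  names(models) <- as.character(uns)
  models
}

#' Rank genes by the expression impact of their copy-number alterations
#'
#' Runs the full per-gene pipeline for one alteration set: per-sample EIS
#' against the normal-sample and diploid-tumor references, observed per-gene
#' medians, resampled background models built from the pooled per-sample
#' scores of the whole set, standard scores, Stouffer combination, one-sided
#' p values with multiple-testing correction, and ranking by the combined
#' score (decreasing for amplifications, increasing for deletions; ties
#' broken by gene id).
#'
#' Genes with fewer than `config$min_altered` altered tumors (after
#' excluding missing expression values), or with no diploid tumor samples
#' to serve as reference, are absent from the output. When the dataset has
#' no normal samples, `eis_normal`/`z_normal` are `NA` and the combined
#' score equals the tumor-only score.
#'
#' @param dataset A `cis_dataset` from [align_dataset()].
#' @param direction `"AMP"` (code +2) or `"DEL"` (code -2).
#' @param config A [cis_config()].
#' @return Data frame with one row per analyzed gene: `gene`, `n_altered`,
#'   `eis_normal`, `eis_tumor`, `z_normal`, `z_tumor`, `z_comb`, `p_value`,
#'   `corrected_p`, `rank`, ordered by rank.
#' @export
cis_analyze <- function(dataset, direction = c("AMP", "DEL"),
                        config = cis_config()) {
  direction <- match.arg(direction)
  stopifnot(inherits(dataset, "cis_dataset"))
  if (!is.null(config$seed)) set.seed(config$seed)

  expr <- dataset$expression
  cna <- dataset$cna
  ann <- dataset$annotation
  tumors <- names(ann)[ann == "TUMOR"]
  normals <- names(ann)[ann == "NORMAL"]
  has_normals <- length(normals) > 0
  target <- if (direction == "AMP") 2L else -2L

  code_t <- cna[, tumors, drop = FALSE]
  expr_t <- expr[, tumors, drop = FALSE]
  expr_n <- expr[, normals, drop = FALSE]

  eps <- config$epsilon_scale * IQR(expr[is.finite(expr)])
  if (!is.finite(eps) || eps <= 0) eps <- config$epsilon_scale

  alt_mask <- code_t == target & is.finite(expr_t)
  n_alt <- rowSums(alt_mask)
  genes <- rownames(expr)[n_alt >= config$min_altered]

  empty <- data.frame(gene = character(0), n_altered = integer(0),
                      eis_normal = numeric(0), eis_tumor = numeric(0),
                      z_normal = numeric(0), z_tumor = numeric(0),
                      z_comb = numeric(0), p_value = numeric(0),
                      corrected_p = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0) {
    warning("no gene qualifies for the ", direction, " analysis",
            call. = FALSE)
    return(empty)
  }

  per_gene <- vector("list", length(genes))
  keep <- logical(length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    alt <- which(alt_mask[g, ])
    ea <- expr_t[g, alt]
    dip <- which(code_t[g, ] == 0L & is.finite(expr_t[g, ]))
    if (length(dip) == 0) next  # no diploid-tumor reference: skip gene
    rs_t <- reference_stats(ea, expr_t[g, dip])
    eis_t <- compute_sample_eis(ea, rs_t, eps)
    eis_n <- NULL
    if (has_normals) {
      en <- expr_n[g, is.finite(expr_n[g, ])]
      if (length(en)) {
        rs_n <- reference_stats(ea, en)
        eis_n <- compute_sample_eis(ea, rs_n, eps)
      }
    }
    keep[k] <- TRUE
    per_gene[[k]] <- list(gene = g, n = length(ea),
                          eis_tumor = eis_t, eis_normal = eis_n)
  }
  per_gene <- per_gene[keep]
  if (length(per_gene) == 0) {
    warning("no gene qualifies for the ", direction, " analysis",
            call. = FALSE)
    return(empty)
  }

  ns <- vapply(per_gene, function(x) x$n, integer(1))
  pool_tumor <- unlist(lapply(per_gene, function(x) x$eis_tumor))
  bg_tumor <- background_table(pool_tumor, ns, config$n_sampling)
  obs_tumor <- vapply(per_gene, function(x) observed_gene_eis(x$eis_tumor),
                      numeric(1))
  z_tumor <- vapply(seq_along(per_gene), function(k) {
    z_score(obs_tumor[k], bg_tumor[[as.character(ns[k])]], config$z_max)
  }, numeric(1))

  with_n <- vapply(per_gene, function(x) !is.null(x$eis_normal), logical(1))
  obs_normal <- rep(NA_real_, length(per_gene))
  z_normal <- rep(NA_real_, length(per_gene))
  if (any(with_n)) {
    pool_normal <- unlist(lapply(per_gene[with_n],
                                 function(x) x$eis_normal))
    bg_normal <- background_table(pool_normal, ns[with_n], config$n_sampling)
    obs_normal[with_n] <- vapply(per_gene[with_n],
                                 function(x) observed_gene_eis(x$eis_normal),
                                 numeric(1))
    z_normal[with_n] <- vapply(which(with_n), function(k) {
      z_score(obs_normal[k], bg_normal[[as.character(ns[k])]], config$z_max)
    }, numeric(1))
  }

  z_comb <- vapply(seq_along(per_gene), function(k) {
    combine_stouffer(z_normal[k], z_tumor[k])
  }, numeric(1))

  sig <- eis_significance(z_comb, direction, config$alpha, config$correction)

  res <- data.frame(gene = vapply(per_gene, function(x) x$gene, character(1)),
                    n_altered = ns,
                    eis_normal = obs_normal, eis_tumor = obs_tumor,
                    z_normal = z_normal, z_tumor = z_tumor,
                    z_comb = z_comb,
                    p_value = sig$p_value, corrected_p = sig$corrected_p,
                    stringsAsFactors = FALSE)
  ord <- if (direction == "AMP") order(-res$z_comb, res$gene)
         else order(res$z_comb, res$gene)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
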