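# Circular binary segmentation of probe-ordered log-ratio profiles and
# discrete gene-level gain/loss calling.

#' Segmentation configuration
#'
#' @param alpha_split Permutation significance required to accept a split
#'   (default 0.01).
#' @param n_permutations Permutation replicates per split test (default
#'   1000).
#' @param min_width Minimum arc width considered for a split (default 2).
#' @param gain_cut,loss_cut Segment-mean cutoffs for discrete calls
#'   (defaults +0.2 / -0.2).
#' @param seed Optional integer seed set at the start of
#'   [segment_dataset()].
#' @param kmax Maximum arc length scanned exhaustively at every position in
#'   long segments (default 8). Longer arcs are located through a coarse
#'   boundary grid plus local refinement; arc/complement symmetry makes the
#'   short-arc sweep also cover near-full-length arcs.
#' @param ngrid Number of coarse grid points per segment for the long-arc
#'   scan (default 64).
#' @param exhaustive_limit Segment length up to which all boundary pairs
#'   are scanned exhaustively (default 250).
#' @return A list of class `cbs_config`.
#' @export
segmentation_config <- function(alpha_split = 0.01, n_permutations = 1000,
                                min_width = 2, gain_cut = 0.2,
                                loss_cut = -0.2, seed = NULL, kmax = 8,
                                ngrid = 64, exhaustive_limit = 250) {
  stopifnot(alpha_split > 0, alpha_split < 1, n_permutations >= 10,
            min_width >= 1, loss_cut < 0, gain_cut > 0, kmax >= min_width,
            ngrid >= 8, exhaustive_limit >= 2 * min_width)
  structure(list(alpha_split = alpha_split,
                 n_permutations = as.integer(n_permutations),
                 min_width = as.integer(min_width),
                 gain_cut = gain_cut, loss_cut = loss_cut, seed = seed,
                 kmax = as.integer(kmax), ngrid = as.integer(ngrid),
                 exhaustive_limit = as.integer(exhaustive_limit)),
            class = "cbs_config")
}

#' Arc statistic for one boundary pair
#'
#' Absolute two-sample t-like statistic comparing the mean of the circular
#' arc `x[(i+1)..j]` with the mean of its complement, using the pooled
#' within-group variance. Zero pooled variance yields 0 when the means are
#' equal and `Inf` otherwise (a noiseless change point).
#'
#' @param x Numeric sequence.
#' @param i,j Boundary indices with `0 <= i < j <= length(x)`; the arc is
#'   `(i..j]` and its complement must be nonempty.
#' @return The absolute statistic.
#' @export
cbs_statistic <- function(x, i, j) {
  m <- length(x)
  stopifnot(i >= 0, i < j, j <= m, !(i == 0 && j == m))
  arc <- x[(i + 1):j]
  comp <- x[setdiff(seq_len(m), (i + 1):j)]
  k <- length(arc)
  nc <- length(comp)
  d <- mean(arc) - mean(comp)
  ss <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
  if (m <= 2 || ss <= 1e-10 * sum(x^2)) {
    return(if (d == 0) 0 else Inf)
  }
  s2 <- ss / (m - 2)
  abs(d) / sqrt(s2 * (1 / k + 1 / nc))
}

#' Segment one probe-ordered log-ratio profile
#'
#' Recursive circular binary segmentation: the boundary pair maximizing the
#' arc statistic is accepted as a split when the observed maximum ranks in
#' the upper `alpha_split` tail of the maxima obtained from
#' `n_permutations` random permutations of the segment's values; accepted
#' splits are recursed into until no further split is accepted or segments
#' are narrower than `min_width` allows.
#'
#' @param x Numeric vector of log ratios for one sample, in probe order.
#' @param cfg A [segmentation_config()]. The per-profile RNG state is taken
#'   from the current stream (seed handling is done by
#'   [segment_dataset()]).
#' @return Data frame with columns `start`, `end` (1-based, inclusive,
#'   abutting, covering the profile) and `mean`.
#' @export
segment_profile <- function(x, cfg = segmentation_config()) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  m <- .cbs_segment(as.numeric(x), cfg$alpha_split, cfg$n_permutations,
                    cfg$min_width, cfg$kmax, cfg$ngrid,
                    cfg$exhaustive_limit)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             mean = m[, 3])
}

#' Segment every sample of an intensity matrix
#'
#' @param intensities Numeric matrix of log ratios, genes (probe order) by
#'   samples.
#' @param cfg A [segmentation_config()]; `cfg$seed`, when non-`NULL`, seeds
#'   the RNG once before the first profile.
#' @return Data frame with columns `sample`, `start`, `end`, `mean`.
#' @export
segment_dataset <- function(intensities, cfg = segmentation_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- lapply(colnames(intensities), function(s) {
    seg <- segment_profile(intensities[, s], cfg)
    cbind(sample = s, seg)
  })
  do.call(rbind, out)
}

#' Discrete gene-level gain/loss calls from segment means
#'
#' Each gene inherits the mean of the segment covering it; a gene is called
#' gained (+2) when that mean is at or above `gain_cut`, lost (-2) at or
#' below `loss_cut`, and neutral (0) otherwise. Output codes are +/-2 so
#' the calls feed directly into the multi-copy amplification / homozygous
#' deletion selection of [cis_analyze()].
#'
#' @param segments Data frame from [segment_dataset()] (columns `sample`,
#'   `start`, `end`, `mean`).
#' @param gene_ids Gene ids in probe order; segment indices refer to this
#'   ordering.
#' @param cfg A [segmentation_config()] carrying the cutoffs.
#' @return Integer matrix of codes (genes x samples).
#' @export
call_genes <- function(segments, gene_ids, cfg = segmentation_config()) {
  samples <- unique(segments$sample)
  out <- matrix(0L, nrow = length(gene_ids), ncol = length(samples),
                dimnames = list(gene_ids, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    if (min(seg$start) != 1 || max(seg$end) != length(gene_ids) ||
        sum(seg$end - seg$start + 1) != length(gene_ids)) {
      stop("segments for sample ", s, " do not partition the probe order",
           call. = FALSE)
    }
    code <- integer(length(gene_ids))
    for (r in seq_len(nrow(seg))) {
      v <- if (seg$mean[r] >= cfg$gain_cut) 2L
           else if (seg$mean[r] <= cfg$loss_cut) -2L else 0L
      if (v != 0L) code[seg$start[r]:seg$end[r]] <- v
    }
    out[, s] <- code
  }
  out
}
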