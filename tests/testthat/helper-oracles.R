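# Independent oracles and fixture builders used across the test files.

# Brute-force maximum of the arc statistic over every admissible boundary
# pair; independent of the compiled scan.
brute_cbs_max <- function(x, min_width = 2) {
  m <- length(x)
  best <- list(stat = -1, i = NA, j = NA)
  for (i in 0:(m - 1)) {
    for (j in (i + 1):m) {
      k <- j - i
      if (k < min_width || m - k < min_width) next
      if (i == 0 && j == m) next
      s <- cbs_statistic(x, i, j)
      if (s > best$stat) best <- list(stat = s, i = i, j = j)
    }
  }
  best
}

# Exact background model by exhaustive enumeration of all ordered n-tuples
# drawn with replacement from the pool (population mean and sd of the
# tuple medians).
enum_background <- function(pool, n) {
  grid <- as.matrix(expand.grid(rep(list(pool), n)))
  meds <- apply(grid, 1, median)
  list(mean = mean(meds), sd = sqrt(mean(meds^2) - mean(meds)^2))
}

# MCC through the Pearson correlation of prediction/truth indicator
# vectors; the standard identity used as an independent route.
cor_mcc <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  suppressWarnings(cor(pred, truth))
}

# Small aligned dataset with known structure:
#   gA: amplified in 5/20 tumors, +3 expression shift in carriers
#   gB: deleted in 4/20 tumors, -2 shift in carriers
#   gC: amplified in 3/20 tumors, no expression coupling
#   gD: amplified in 1 tumor (below the default min_altered filter)
#   gE..gJ: neutral genes with scattered ±2 events, no coupling
make_tiny_dataset <- function(seed = 11, n_tumors = 20, n_normals = 6,
                              shift_a = 3, shift_b = -2) {
  set.seed(seed)
  genes <- paste0("g", LETTERS[1:10])
  tumors <- sprintf("T%02d", seq_len(n_tumors))
  normals <- sprintf("N%02d", seq_len(n_normals))
  samples <- c(tumors, normals)
  expr <- matrix(rnorm(length(genes) * length(samples), 7, 0.6),
                 nrow = length(genes),
                 dimnames = list(genes, samples))
  cna <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  cna["gA", tumors[1:5]] <- 2L
  expr["gA", tumors[1:5]] <- expr["gA", tumors[1:5]] + shift_a
  cna["gB", tumors[6:9]] <- -2L
  expr["gB", tumors[6:9]] <- expr["gB", tumors[6:9]] + shift_b
  cna["gC", tumors[10:12]] <- 2L
  cna["gD", tumors[13]] <- 2L
  for (g in c("gE", "gF", "gG")) {
    cna[g, sample(tumors, 3)] <- 2L
  }
  for (g in c("gH", "gI", "gJ")) {
    cna[g, sample(tumors, 3)] <- -2L
  }
  annot <- setNames(c(rep("TUMOR", n_tumors), rep("NORMAL", n_normals)),
                    samples)
  align_dataset(expr, cna, annot)
}

# A fast analysis configuration for unit tests.
tiny_config <- function(seed = 3, n_sampling = 500) {
  cis_config(n_sampling = n_sampling, seed = seed)
}
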