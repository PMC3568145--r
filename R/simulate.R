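# Synthetic copy-number / expression data with ground-truth labels, used by
# the benchmarking harness.

#' Simulation setting
#'
#' Defaults describe the benchmark conditions: 10,000 genes of which 90
#' carry copy-number variations (organized in contiguous regions of 1-10
#' genes with region-level amplitudes of +/-0.5, 1 or 2 on the log2-ratio
#' scale and per-region recurrence between 20% and 80% of tumors) and 54
#' are additionally coupled to expression through the chosen dosage
#' response model.
#'
#' Aberration regions are emitted into the intensity matrix as peaks with
#' tapering flanks: the copy-number signal decays linearly to zero over
#' `flank_range` probes on each side of the region core. This emulates the
#' spatial spread of array intensities around aberrant loci, which is what
#' makes downstream segmentation state substantially more altered genes
#' than the underlying truth. Expression coupling uses the core dosage
#' only, so flank genes are never true positives.
#'
#' @param n_genes Total genes (probe order = genome order).
#' @param n_tumors Tumor samples (the benchmark uses 15 or 100).
#' @param n_normals Normal expression samples (default 10; 0 disables the
#'   normal reference downstream).
#' @param model Dosage-expression response: `"LINEAR"`, `"STEPWISE"` or
#'   `"SIGMOID"`.
#' @param n_cnv_genes Genes with true copy-number variation (default 90).
#' @param n_coupled Expression-coupled true positives (default 54),
#'   drawn from the CNV genes.
#' @param seed Integer seed; every run is reproducible from it.
#' @param amplitudes,amplitude_weights Candidate region amplitudes
#'   (absolute log2 ratios) and their sampling weights.
#' @param region_size_max Maximum region size in genes (sizes are uniform
#'   on 1..`region_size_max`).
#' @param recurrence_range Range of the per-region carrier fraction.
#' @param flank_range Integer range of the tapering flank length (probes
#'   per side).
#' @param flank_shape Exponent of the flank decay: the flank signal is
#'   `amplitude * (1 - k/(f+1))^flank_shape` at distance k; the default 1
#'   is a linear ramp, larger values decay faster.
#' @param noise_sd Gaussian noise sd of the copy-number intensities
#'   (default 0.25).
#' @param expr_noise_sd Gaussian noise sd of the expression values.
#' @param base_mean,base_sd Per-gene baseline expression distribution
#'   (log2 scale).
#' @param beta Expression shift per unit dosage.
#' @param sigmoid_k Steepness of the sigmoid response.
#' @return A list of class `sim_setting`.
#' @export
simulation_setting <- function(n_genes = 10000, n_tumors = 100,
                               n_normals = 10,
                               model = c("LINEAR", "STEPWISE", "SIGMOID"),
                               n_cnv_genes = 90, n_coupled = 54,
                               seed = 1, amplitudes = c(0.5, 1, 2),
                               amplitude_weights = c(0.2, 0.4, 0.4),
                               region_size_max = 10,
                               recurrence_range = c(0.2, 0.8),
                               flank_range = c(9, 22), flank_shape = 1,
                               noise_sd = 0.25, expr_noise_sd = 1.12,
                               base_mean = 7, base_sd = 1, beta = 1,
                               sigmoid_k = 2) {
  model <- match.arg(model)
  stopifnot(n_coupled <= n_cnv_genes, n_cnv_genes <= n_genes,
            n_tumors >= 1, n_normals >= 0, noise_sd >= 0,
            expr_noise_sd >= 0, region_size_max >= 1,
            length(amplitudes) == length(amplitude_weights),
            recurrence_range[1] > 0, recurrence_range[2] <= 1,
            flank_range[1] >= 0, flank_range[2] >= flank_range[1],
            flank_shape > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_tumors = as.integer(n_tumors),
                 n_normals = as.integer(n_normals), model = model,
                 n_cnv_genes = as.integer(n_cnv_genes),
                 n_coupled = as.integer(n_coupled), seed = seed,
                 amplitudes = amplitudes,
                 amplitude_weights = amplitude_weights,
                 region_size_max = as.integer(region_size_max),
                 recurrence_range = recurrence_range,
                 flank_range = as.integer(flank_range),
                 flank_shape = flank_shape,
                 noise_sd = noise_sd, expr_noise_sd = expr_noise_sd,
                 base_mean = base_mean, base_sd = base_sd, beta = beta,
                 sigmoid_k = sigmoid_k),
            class = "sim_setting")
}

#' Place aberration regions and assign carrier dosages
#'
#' Splits the CNV genes into contiguous regions of 1..`region_size_max`
#' genes, places the regions on the genome with enough separation that
#' their tapering flanks never overlap, draws a region amplitude (signed)
#' and a carrier subset of tumors per region, and returns the resulting
#' per-gene per-tumor dosage. Non-CNV genes have dosage 0 everywhere.
#'
#' @param setting A [simulation_setting()]. Uses the current RNG stream.
#' @return List with `dosage` (genes x tumors matrix of core dosages),
#'   `regions` (data frame: start, size, amplitude, flank, n_carriers),
#'   `carriers` (list of tumor index vectors per region) and `cnv_genes`
#'   (integer vector of the region core gene indices, length
#'   `n_cnv_genes`).
#' @export
place_aberrations <- function(setting) {
  G <- setting$n_genes
  Tn <- setting$n_tumors
  dosage <- matrix(0, nrow = G, ncol = Tn)
  if (setting$n_cnv_genes == 0) {
    return(list(dosage = dosage,
                regions = data.frame(start = integer(0), size = integer(0),
                                     amplitude = numeric(0),
                                     flank = integer(0),
                                     n_carriers = integer(0)),
                carriers = list(), cnv_genes = integer(0)))
  }
  sizes <- integer(0)
  while (sum(sizes) < setting$n_cnv_genes) {
    sizes <- c(sizes, sample.int(setting$region_size_max, 1))
  }
  sizes[length(sizes)] <- setting$n_cnv_genes - sum(sizes[-length(sizes)])
  sizes <- sizes[sizes > 0]
  n_reg <- length(sizes)

  sep <- 2L * max(setting$flank_range) + setting$region_size_max + 10L
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n_reg) {
    cand <- sample.int(G - setting$region_size_max -
                         max(setting$flank_range), 1)
    if (all(abs(cand - starts) >= sep)) starts <- c(starts, cand)
    tries <- tries + 1L
    if (tries > 10000L) stop("cannot place aberration regions: genome too ",
                             "small for the requested separation",
                             call. = FALSE)
  }
  starts <- sort(starts)

  amp <- sample(setting$amplitudes, n_reg, replace = TRUE,
                prob = setting$amplitude_weights) *
    sample(c(-1, 1), n_reg, replace = TRUE)
  flank <- sample(seq(setting$flank_range[1], setting$flank_range[2]),
                  n_reg, replace = TRUE)
  recur <- runif(n_reg, setting$recurrence_range[1],
                 setting$recurrence_range[2])
  carriers <- lapply(seq_len(n_reg), function(r) {
    k <- max(1L, round(recur[r] * Tn))
    sort(sample.int(Tn, k))
  })

  cnv_genes <- integer(0)
  for (r in seq_len(n_reg)) {
    idx <- starts[r]:(starts[r] + sizes[r] - 1L)
    cnv_genes <- c(cnv_genes, idx)
    dosage[idx, carriers[[r]]] <- amp[r]
  }
  list(dosage = dosage,
       regions = data.frame(start = starts, size = sizes, amplitude = amp,
                            flank = flank,
                            n_carriers = vapply(carriers, length,
                                                integer(1))),
       carriers = carriers, cnv_genes = cnv_genes)
}

#' Copy-number intensity matrix from placed aberrations
#'
#' Core dosages are emitted as-is; each region additionally contributes a
#' tapering flank (amplitude decaying to zero over the region's flank
#' length, with shape `flank_shape`) to its carrier tumors, after which
#' i.i.d. Gaussian noise is added to every cell.
#'
#' @param placement Result of [place_aberrations()].
#' @param setting The same [simulation_setting()].
#' @return Numeric matrix (genes x tumors) of log-ratio intensities.
#' @export
emit_intensities <- function(placement, setting) {
  intens <- placement$dosage
  G <- nrow(intens)
  reg <- placement$regions
  for (r in seq_len(nrow(reg))) {
    f <- reg$flank[r]
    if (f < 1) next
    ramp <- reg$amplitude[r] * (1 - seq_len(f) / (f + 1))^setting$flank_shape
    carr <- placement$carriers[[r]]
    left <- reg$start[r] - seq_len(f)
    right <- reg$start[r] + reg$size[r] - 1L + seq_len(f)
    ok_l <- left >= 1L
    ok_r <- right <= G
    if (any(ok_l)) intens[left[ok_l], carr] <-
        intens[left[ok_l], carr] + ramp[ok_l]
    if (any(ok_r)) intens[right[ok_r], carr] <-
        intens[right[ok_r], carr] + ramp[ok_r]
  }
  if (setting$noise_sd > 0) {
    intens <- intens + matrix(rnorm(length(intens), 0, setting$noise_sd),
                              nrow = G)
  }
  intens
}

#' Expected expression shift for a gene dosage
#'
#' `LINEAR`: `beta * d`. `STEPWISE`: `beta * sign(d) * min(floor(|d|), 2)`,
#' i.e. quantized to the levels 0, +/-beta, +/-2 beta (sub-unit dosages
#' produce no shift). `SIGMOID`: `2 beta (logistic(k d) - 1/2)`,
#' saturating at +/-beta.
#'
#' @param model `"LINEAR"`, `"STEPWISE"` or `"SIGMOID"`.
#' @param d Dosage (real copy-number deviation, log2-ratio scale).
#' @param beta Shift per unit dosage.
#' @param k Sigmoid steepness.
#' @return Expected expression shift, same shape as `d`.
#' @export
dosage_response <- function(model = c("LINEAR", "STEPWISE", "SIGMOID"), d,
                            beta = 1, k = 2) {
  model <- match.arg(model)
  switch(model,
         LINEAR = beta * d,
         STEPWISE = beta * sign(d) * pmin(floor(abs(d)), 2),
         SIGMOID = 2 * beta * (plogis(k * d) - 0.5))
}

#' Expression matrix (tumors plus normals) from placed aberrations
#'
#' Coupled genes receive the dosage response of their core dosage in each
#' tumor; all other genes -- including CNV genes that are not coupled --
#' and all normal samples are baseline plus noise only.
#'
#' @param placement Result of [place_aberrations()].
#' @param coupled_idx Integer indices of the coupled genes.
#' @param setting The [simulation_setting()].
#' @return Numeric matrix (genes x (tumors + normals)).
#' @export
emit_expression <- function(placement, coupled_idx, setting) {
  G <- setting$n_genes
  Tn <- setting$n_tumors
  Nn <- setting$n_normals
  base <- rnorm(G, setting$base_mean, setting$base_sd)
  expr <- matrix(base, nrow = G, ncol = Tn + Nn)
  if (length(coupled_idx)) {
    d <- placement$dosage[coupled_idx, , drop = FALSE]
    shift <- dosage_response(setting$model, d, setting$beta,
                             setting$sigmoid_k)
    expr[coupled_idx, seq_len(Tn)] <- expr[coupled_idx, seq_len(Tn),
                                           drop = FALSE] + shift
  }
  if (setting$expr_noise_sd > 0) {
    expr <- expr + matrix(rnorm(length(expr), 0, setting$expr_noise_sd),
                          nrow = G)
  }
  expr
}

#' Generate a complete simulated dataset
#'
#' Seeds the RNG from `setting$seed` and produces intensities, expression,
#' annotation and ground truth in one reproducible object.
#'
#' @param setting A [simulation_setting()].
#' @return A list of class `cis_simulation`: `intensities` (genes x
#'   tumors), `expression` (genes x (tumors + normals)), `annotation`
#'   (named vector), `truth` (list with `cnv_genes`, `coupled_genes` as
#'   character ids), `regions`, and `setting`.
#' @export
simulate_dataset <- function(setting = simulation_setting()) {
  stopifnot(inherits(setting, "sim_setting"))
  if (!is.null(setting$seed)) set.seed(setting$seed)
  gene_ids <- sprintf("g%05d", seq_len(setting$n_genes))
  tumor_ids <- sprintf("T%03d", seq_len(setting$n_tumors))
  normal_ids <- if (setting$n_normals > 0)
    sprintf("N%03d", seq_len(setting$n_normals)) else character(0)

  placement <- place_aberrations(setting)
  coupled_idx <- if (setting$n_coupled > 0)
    sort(sample(placement$cnv_genes, setting$n_coupled)) else integer(0)
  intens <- emit_intensities(placement, setting)
  expr <- emit_expression(placement, coupled_idx, setting)

  dimnames(intens) <- list(gene_ids, tumor_ids)
  dimnames(expr) <- list(gene_ids, c(tumor_ids, normal_ids))
  ann <- setNames(c(rep("TUMOR", setting$n_tumors),
                    rep("NORMAL", setting$n_normals)),
                  c(tumor_ids, normal_ids))
  out <- list(intensities = intens, expression = expr, annotation = ann,
              truth = list(cnv_genes = gene_ids[sort(placement$cnv_genes)],
                           coupled_genes = gene_ids[coupled_idx]),
              regions = placement$regions, setting = setting)
  class(out) <- "cis_simulation"
  out
}

#' @export
print.cis_simulation <- function(x, ...) {
  cat(sprintf(paste0("cis_simulation: %d genes, %d tumors, %d normals, ",
                     "%s model\n  %d CNV genes (%d regions), %d coupled\n"),
              x$setting$n_genes, x$setting$n_tumors, x$setting$n_normals,
              x$setting$model, length(x$truth$cnv_genes), nrow(x$regions),
              length(x$truth$coupled_genes)))
  invisible(x)
}

#' Write a simulated dataset as TSV files
#'
#' Writes `intensities.tsv`, `expression.tsv`, `annotation.tsv` and
#' `truth.tsv` (gene, is_cnv, is_coupled) into a directory.
#'
#' @param sim A `cis_simulation`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_simulated <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(sim$intensities, file.path(dir, "intensities.tsv"))
  write_matrix_tsv(sim$expression, file.path(dir, "expression.tsv"))
  writeLines(paste(names(sim$annotation), sim$annotation, sep = "\t"),
             file.path(dir, "annotation.tsv"))
  g <- rownames(sim$expression)
  truth <- data.frame(gene = g,
                      is_cnv = as.integer(g %in% sim$truth$cnv_genes),
                      is_coupled = as.integer(g %in% sim$truth$coupled_genes))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
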