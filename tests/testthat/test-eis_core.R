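test_that("per-sample impact score follows the scaled-deviation formula", {
  ref <- list(median_ref = 5, iqr_ref = 2, iqr_alt = 2)
  expect_equal(compute_sample_eis(5, ref, 0.01), 0)
  expect_equal(compute_sample_eis(9, ref, 0.01), 1)
  # degenerate spreads fall back to the epsilon guard
  ref0 <- list(median_ref = 5, iqr_ref = 0, iqr_alt = 0)
  expect_equal(compute_sample_eis(3, ref0, 0.01), -200)
  # sign tracks the deviation from the reference median
  expect_gt(compute_sample_eis(6, ref, 0.01), 0)
  expect_lt(compute_sample_eis(4, ref, 0.01), 0)
})

test_that("reference stats use interpolated quartiles and drop NA", {
  rs <- reference_stats(c(1, 3), c(2, 4, NA, 6, 8))
  expect_equal(rs$median_ref, 5)
  expect_equal(rs$iqr_ref, IQR(c(2, 4, 6, 8)))
  expect_equal(rs$iqr_alt, 1)  # linear interpolation on the pair (1, 3)
  expect_error(reference_stats(c(1, 2), numeric(0)), "reference")
})

test_that("observed gene score is the median of its sample scores", {
  expect_equal(observed_gene_eis(1), 1)
  expect_equal(observed_gene_eis(c(1, 3)), 2)
  expect_equal(observed_gene_eis(c(-2, 0, 5)), 0)
  expect_error(observed_gene_eis(numeric(0)), "skip")
})

test_that("background resampling matches exhaustive enumeration", {
  # degenerate pool: constant medians
  set.seed(1)
  bg <- build_background(rep(2.5, 4), n = 2, n_reps = 200)
  expect_equal(bg$mean, 2.5)
  expect_equal(bg$sd, 0)

  # enumeration oracle on a skewed pool: 16 ordered draws, mean 2.5
  exact <- enum_background(c(0, 0, 0, 10), 2)
  expect_equal(exact$mean, 2.5)
  set.seed(2)
  bg <- build_background(c(0, 0, 0, 10), n = 2, n_reps = 10000)
  expect_lt(abs(bg$mean - exact$mean), 3 * exact$sd / sqrt(10000))
  expect_lt(abs(bg$sd - exact$sd), 3 * exact$sd / sqrt(2 * 10000))

  expect_error(build_background(numeric(0), 2, 100), "pool")
})

test_that("standard scores handle degenerate backgrounds with the cap", {
  bg <- list(mean = 1, sd = 0.5)
  expect_equal(z_score(1, bg), 0)
  expect_equal(z_score(2, bg), 2)
  bg0 <- list(mean = 0, sd = 0)
  expect_equal(z_score(0, bg0), 0)
  expect_equal(z_score(1, bg0), 50)
  expect_equal(z_score(-1, bg0), -50)
  expect_equal(z_score(1, bg0, z_max = 10), 10)
})

test_that("Stouffer combination is equal-weight with tumor-only fallback", {
  expect_equal(combine_stouffer(1, 1), sqrt(2))
  expect_equal(combine_stouffer(2, -2), 0)
  expect_equal(combine_stouffer(NA, 3), 3)
  expect_equal(combine_stouffer(NULL, 3), 3)
})

test_that("significance is one-sided in the expected direction", {
  expect_equal(eis_significance(0, "AMP")$p_value, 0.5)
  expect_equal(eis_significance(-1.6449, "DEL")$p_value, 0.05,
               tolerance = 1e-4)
  # a single gene: correction is the identity
  one <- eis_significance(qnorm(0.04, lower.tail = FALSE), "AMP")
  expect_equal(one$corrected_p, 0.04, tolerance = 1e-10)
  expect_true(one$is_positive)
  # symmetry: same score is extreme for AMP, null for DEL
  expect_lt(eis_significance(4, "AMP")$p_value, 1e-4)
  expect_gt(eis_significance(4, "DEL")$p_value, 0.99)
})

test_that("event-sample selection excludes single-copy and opposite events", {
  ds <- make_tiny_dataset()
  ds$cna["gE", ] <- 0L
  ds$cna["gE", c("T01", "T02")] <- c(2L, 2L)
  ds$cna["gE", "T03"] <- 1L
  ds$cna["gE", "T04"] <- -2L
  sel <- select_event_samples(ds, "gE", "AMP")
  expect_setequal(sel$altered, c("T01", "T02"))
  expect_false("T03" %in% c(sel$altered, sel$diploid))
  expect_false("T04" %in% c(sel$altered, sel$diploid))
  sel_del <- select_event_samples(ds, "gE", "DEL")
  expect_identical(sel_del$altered, "T04")
  expect_setequal(sel$normal, names(ds$annotation)[ds$annotation == "NORMAL"])
})

test_that("the analysis ranks coupled genes first and filters rare events", {
  ds <- make_tiny_dataset()
  amp <- cis_analyze(ds, "AMP", tiny_config())
  expect_identical(amp$gene[1], "gA")       # strong +3 shift
  expect_false("gD" %in% amp$gene)          # single altered sample
  expect_identical(amp$rank, seq_len(nrow(amp)))
  expect_true(all(diff(amp$z_comb) <= 0))   # decreasing for amplifications
  expect_true(amp$corrected_p[1] <= 0.05)

  del <- cis_analyze(ds, "DEL", tiny_config())
  expect_identical(del$gene[1], "gB")
  expect_true(all(diff(del$z_comb) >= 0))   # increasing for deletions
  expect_lt(del$z_comb[1], 0)
})

test_that("absent normals trigger the tumor-only fallback", {
  ds <- make_tiny_dataset()
  tumors <- names(ds$annotation)[ds$annotation == "TUMOR"]
  ds_nonorm <- align_dataset(ds$expression[, tumors],
                             ds$cna[, tumors], ds$annotation[tumors])
  amp <- cis_analyze(ds_nonorm, "AMP", tiny_config())
  expect_true(all(is.na(amp$eis_normal)))
  expect_true(all(is.na(amp$z_normal)))
  expect_equal(amp$z_comb, amp$z_tumor)
})

test_that("identical seeds give identical results and output files", {
  ds <- make_tiny_dataset()
  a1 <- cis_analyze(ds, "AMP", tiny_config(seed = 42))
  a2 <- cis_analyze(ds, "AMP", tiny_config(seed = 42))
  expect_identical(a1, a2)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(a1, "AMP", f1)
  write_results(a2, "AMP", f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("scores are invariant to per-gene translation and scaling", {
  ds <- make_tiny_dataset()
  base <- cis_analyze(ds, "AMP", tiny_config(seed = 5))

  ds_shift <- ds
  ds_shift$expression["gA", ] <- ds_shift$expression["gA", ] + 100
  shifted <- cis_analyze(ds_shift, "AMP", tiny_config(seed = 5))
  expect_equal(shifted$z_comb, base$z_comb, tolerance = 1e-12)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-12)

  ds_scale <- ds
  ds_scale$expression["gA", ] <- ds_scale$expression["gA", ] * 7
  scaled <- cis_analyze(ds_scale, "AMP", tiny_config(seed = 5))
  expect_equal(scaled$z_comb, base$z_comb, tolerance = 1e-12)
})

test_that("raising altered-sample expression raises the observed score and rank", {
  ds <- make_tiny_dataset()
  cfg <- tiny_config(seed = 9)
  base <- cis_analyze(ds, "AMP", cfg)
  g <- "gC"  # uncoupled amplified gene: starts low in the ranking
  base_row <- base[base$gene == g, ]

  ds_up <- ds
  alt <- select_event_samples(ds, g, "AMP")$altered
  ds_up$expression[g, alt] <- ds_up$expression[g, alt] + 5
  up <- cis_analyze(ds_up, "AMP", cfg)
  up_row <- up[up$gene == g, ]
  expect_gt(up_row$eis_tumor, base_row$eis_tumor)
  expect_gt(up_row$eis_normal, base_row$eis_normal)
  expect_lte(up_row$rank, base_row$rank)
  expect_gte(up_row$z_comb, base_row$z_comb)
})
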