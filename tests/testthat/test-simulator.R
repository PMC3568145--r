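test_that("truth cardinalities hold exactly for every seed", {
  for (seed in c(1, 7, 2026)) {
    sim <- simulate_dataset(simulation_setting(seed = seed, n_tumors = 15))
    expect_equal(nrow(sim$expression), 10000)
    expect_length(sim$truth$cnv_genes, 90)
    expect_length(sim$truth$coupled_genes, 54)
    expect_true(all(sim$truth$coupled_genes %in% sim$truth$cnv_genes))
    expect_equal(ncol(sim$intensities), 15)
    expect_equal(ncol(sim$expression), 25)
    expect_equal(sum(sim$annotation == "NORMAL"), 10)
  }
})

test_that("simulation is reproducible from its seed", {
  s1 <- simulate_dataset(simulation_setting(seed = 5, n_genes = 2000,
                                            n_cnv_genes = 20,
                                            n_coupled = 12, n_tumors = 10))
  s2 <- simulate_dataset(simulation_setting(seed = 5, n_genes = 2000,
                                            n_cnv_genes = 20,
                                            n_coupled = 12, n_tumors = 10))
  expect_identical(s1$intensities, s2$intensities)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth, s2$truth)
})

test_that("aberration placement respects the core-gene contract", {
  setting <- simulation_setting(seed = 9)
  set.seed(setting$seed)
  pl <- place_aberrations(setting)
  # exactly the n_cnv_genes core genes carry nonzero dosage
  expect_equal(sum(rowSums(pl$dosage != 0) > 0), 90)
  expect_length(pl$cnv_genes, 90)
  expect_true(all(rowSums(pl$dosage[pl$cnv_genes, ] != 0) > 0))
  expect_true(all(pl$regions$size >= 1 & pl$regions$size <= 10))
  expect_true(all(abs(pl$regions$amplitude) %in% c(0.5, 1, 2)))
  # recurrence between 20% and 80% of tumors (rounding included)
  expect_true(all(pl$regions$n_carriers >= floor(0.2 * 100) &
                    pl$regions$n_carriers <= ceiling(0.8 * 100)))

  # no CNV genes: all-zero dosage
  set.seed(1)
  pl0 <- place_aberrations(simulation_setting(n_cnv_genes = 0,
                                              n_coupled = 0, seed = 1))
  expect_true(all(pl0$dosage == 0))
})

test_that("noise-free intensities equal the dosage on region cores", {
  setting <- simulation_setting(seed = 3, noise_sd = 0, n_genes = 3000,
                                n_cnv_genes = 30, n_coupled = 18,
                                n_tumors = 12)
  set.seed(setting$seed)
  pl <- place_aberrations(setting)
  intens <- emit_intensities(pl, setting)
  reg <- pl$regions
  for (r in seq_len(nrow(reg))) {
    core <- reg$start[r]:(reg$start[r] + reg$size[r] - 1)
    carr <- pl$carriers[[r]]
    expect_true(all(intens[core, carr] == reg$amplitude[r]))
    # flanks taper strictly below the core amplitude, toward zero
    fl <- reg$start[r] - seq_len(reg$flank[r])
    expect_true(all(abs(intens[fl, carr]) < abs(reg$amplitude[r])))
  }
  # non-carrier tumors keep zero intensity without noise
  expect_true(all(intens[, setdiff(seq_len(12), unique(unlist(pl$carriers)))]
                  == 0))
})

test_that("intensity noise has the configured variance", {
  setting <- simulation_setting(seed = 4, n_genes = 4000, n_cnv_genes = 0,
                                n_coupled = 0, n_tumors = 25,
                                noise_sd = 0.25)
  sim <- simulate_dataset(setting)
  v <- var(as.vector(sim$intensities))
  expect_equal(v, 0.0625, tolerance = 0.05)
})

test_that("dosage response models follow their definitions", {
  for (m in c("LINEAR", "STEPWISE", "SIGMOID")) {
    expect_equal(dosage_response(m, 0), 0)
  }
  expect_equal(dosage_response("LINEAR", 2), 2)
  expect_equal(dosage_response("LINEAR", -0.5, beta = 2), -1)
  # stepwise quantizes to the levels 0, +/-beta, +/-2 beta
  expect_equal(dosage_response("STEPWISE", c(0.5, 1, 2, -2, -0.5)),
               c(0, 1, 2, -2, 0))
  expect_equal(dosage_response("STEPWISE", 5), 2)
  # sigmoid saturates at +/-beta and is symmetric
  expect_equal(dosage_response("SIGMOID", 50), 1, tolerance = 1e-10)
  expect_equal(dosage_response("SIGMOID", -50), -1, tolerance = 1e-10)
  expect_equal(dosage_response("SIGMOID", 0.5),
               2 * (plogis(1) - 0.5), tolerance = 1e-12)
  expect_equal(dosage_response("SIGMOID", -1),
               -dosage_response("SIGMOID", 1))
})

test_that("only coupled genes acquire expression shifts", {
  setting <- simulation_setting(seed = 12, n_genes = 3000,
                                n_cnv_genes = 30, n_coupled = 18,
                                n_tumors = 12, expr_noise_sd = 0,
                                base_sd = 0, model = "LINEAR")
  sim <- simulate_dataset(setting)
  tumors <- names(sim$annotation)[sim$annotation == "TUMOR"]
  normals <- names(sim$annotation)[sim$annotation == "NORMAL"]
  base <- setting$base_mean
  expect_true(all(sim$expression[, normals] == base))
  uncoupled <- setdiff(rownames(sim$expression), sim$truth$coupled_genes)
  expect_true(all(sim$expression[uncoupled, tumors] == base))
  # coupled carriers shift by exactly beta * dosage under the linear model
  set.seed(setting$seed)
  pl <- place_aberrations(setting)
  shifted <- sim$expression[sim$truth$coupled_genes, tumors] - base
  idx <- match(sim$truth$coupled_genes, rownames(sim$expression))
  expect_equal(unname(shifted), unname(setting$beta * pl$dosage[idx, ]),
               tolerance = 1e-12)
})
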