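test_that("Hardy-Weinberg genotype probabilities follow the closed form", {
  expect_equal(hwe_probs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_probs(0), c(1, 0, 0))
  expect_equal(hwe_probs(0.3), c(0.49, 0.42, 0.09))
  expect_error(hwe_probs(0.6), "0.5")
  expect_error(hwe_probs(-0.1), "0.5")
})

test_that("calibration rescales the shape to the target prevalence exactly", {
  # uniform shape: every penetrance equals the prevalence
  m <- calibrate_penetrance(matrix(1, 3, 3), c(0.3, 0.2), 0.1)
  expect_true(all(abs(m$table - 0.1) < 1e-15))

  # recomputed prevalence matches to 1e-9, ratios preserved
  shape <- penetrance_shape("threshold_both_minor", effect = 3)
  m2 <- calibrate_penetrance(shape, c(0.4, 0.4), 0.07)
  p <- genotype_class_probs(m2)
  expect_lt(abs(sum(p$penetrance * p$p_hwe) - 0.07), 1e-9)
  expect_equal(m2$table / m2$table[1, 1], shape / shape[1, 1],
               tolerance = 1e-12)

  # infeasible: shape concentrated on a rare cell
  rare <- matrix(0, 3, 3); rare[3, 3] <- 1
  expect_error(calibrate_penetrance(rare, c(0.05, 0.05), 0.5), "infeasible")
})

test_that("archetype shapes have their defining qualitative structure", {
  x <- penetrance_shape("xor", baseline = 0, effect = 1)
  carrier <- outer(0:2 >= 1, 0:2 >= 1, xor)
  expect_equal(x, carrier + 0)

  thr <- penetrance_shape("threshold_both_minor", effect = 3)
  expect_true(all(thr[1, ] == thr[1, 1]))  # no SNP2 effect when g1 = 0
  expect_true(all(thr[2:3, 2:3] == 4 * thr[1, 1]))

  # zz: zero single-locus marginal penetrance under HWE at MAF 0.5
  zz <- penetrance_shape("zz", baseline = 0.5, effect = 2)
  marg <- as.vector(zz %*% hwe_probs(0.5))
  expect_equal(marg, rep(marg[1], 3), tolerance = 1e-12)
  marg2 <- as.vector(t(zz) %*% hwe_probs(0.5))
  expect_equal(marg2, rep(marg2[1], 3), tolerance = 1e-12)

  expect_error(penetrance_shape("ref39_m3"), "user-supplied")
  custom <- matrix(runif(9), 3)
  expect_equal(penetrance_shape("ref39_m3", table = custom),
               unname(custom))
})

test_that("the case/control mixture reconstructs the HWE distribution", {
  for (model in list(
    calibrate_penetrance(penetrance_shape("xor", 1, 4), c(0.5, 0.5), 0.1),
    calibrate_penetrance(penetrance_shape("zz", 0.5, 2), c(0.5, 0.5), 0.2),
    calibrate_penetrance(penetrance_shape("inverse_marginal", 1, 2),
                         c(0.3, 0.3), 0.05)
  )) {
    p <- genotype_class_probs(model)
    mix <- model$prevalence * p$p_case + (1 - model$prevalence) * p$p_control
    expect_lt(max(abs(mix - p$p_hwe)), 1e-12)
    expect_equal(sum(p$p_case), 1, tolerance = 1e-12)
    expect_equal(sum(p$p_control), 1, tolerance = 1e-12)
  }
})

test_that("simulated datasets have the requested design and are reproducible", {
  m <- fixture_model()
  sim <- simulate_epistasis(m, n_cases = 150, n_controls = 100,
                            n_snps = 20, seed = 5)
  expect_equal(n_cases(sim$data), 150)
  expect_equal(n_controls(sim$data), 100)
  expect_equal(n_snps(sim$data), 20)
  expect_equal(nrow(sim$truth), 2)
  expect_true(all(sim$truth$index %in% 1:20))
  expect_identical(sim$truth$snp_id, snp_ids(sim$data)[sim$truth$index])

  sim2 <- simulate_epistasis(m, 150, 100, 20, seed = 5)
  expect_identical(sim$data, sim2$data)
  expect_identical(sim$truth, sim2$truth)

  expect_error(simulate_epistasis(m, 10, 10, n_snps = 2), "exceed")
})

test_that("background SNPs track their drawn MAFs within 3 binomial SEs", {
  sim <- simulate_epistasis(fixture_model(), 1000, 1000, n_snps = 30,
                            seed = 77)
  n <- nrow(sim$data)
  for (r in seq_len(nrow(sim$background_mafs))) {
    id <- sim$background_mafs$snp_id[r]
    maf <- sim$background_mafs$maf[r]
    maf_hat <- mean(sim$data[[id]]) / 2
    se <- sqrt(maf * (1 - maf) / (2 * n))
    expect_lt(abs(maf_hat - maf), 3 * se)
  }
})

test_that("case genotypes of the causal pair follow the closed-form P(g | case)", {
  model <- calibrate_penetrance(penetrance_shape("xor", baseline = 1,
                                                 effect = 4),
                                mafs = c(0.5, 0.5), prevalence = 0.1,
                                name = "xor")
  sim <- simulate_epistasis(model, n_cases = 2000, n_controls = 2000,
                            n_snps = 5, seed = 31)
  probs <- genotype_class_probs(model)
  cases <- sim$data[sim$data$phenotype == 1, ]
  g1 <- factor(cases[[sim$truth$snp_id[1]]], levels = 0:2)
  g2 <- factor(cases[[sim$truth$snp_id[2]]], levels = 0:2)
  obs <- as.vector(table(g1, g2))  # g1 varies fastest, matching probs rows
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs$p_case))
  expect_gt(gof$p.value, 0.01)
})

test_that("zero-marginal architectures leave causal SNPs marginally silent", {
  # parity model at MAF 0.5: single-SNP MI below the null 99th percentile
  model <- calibrate_penetrance(penetrance_shape("zz", baseline = 0.5,
                                                 effect = 2),
                                mafs = c(0.5, 0.5), prevalence = 0.1,
                                name = "zz")
  sim <- simulate_epistasis(model, n_cases = 10000, n_controls = 10000,
                            n_snps = 4, seed = 13)
  n <- nrow(sim$data)
  null99 <- stats::qchisq(0.99, df = 2) / (2 * n * log(2))
  for (idx in sim$truth$index) {
    expect_lt(snp_mi(sim$data, idx), null99)
  }
  # while the pair MI is far above it
  expect_gt(snp_mi(sim$data, sim$truth$index), 10 * null99)
})

test_that("penetrance models survive a JSON round trip", {
  m <- calibrate_penetrance(penetrance_shape("inverse_marginal", 1, 2),
                            c(0.25, 0.4), 0.02, name = "inv")
  path <- withr::local_tempfile(fileext = ".json")
  write_penetrance(m, path)
  m2 <- read_penetrance(path)
  expect_equal(m2$table, m$table, tolerance = 1e-15)
  expect_equal(m2$mafs, m$mafs)
  expect_equal(m2$prevalence, m$prevalence)
  expect_identical(m2$name, m$name)
})
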