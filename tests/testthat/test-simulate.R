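# Synthetic-data generators: determinism, stated-world parameters, and
# end-to-end pipeline behaviour.

test_that("simulate_population draws the specified distribution", {
  spec <- population_spec("deg", c(`2` = 1), 25)
  expect_true(all(simulate_population(spec)$true_copy_number == 2L))

  g1 <- simulate_population(jh_population_spec(50), seed = 4)
  g2 <- simulate_population(jh_population_spec(50), seed = 4)
  expect_identical(g1, g2)

  # law of large numbers at n = 100,000 within 1% per class
  spec <- jh_population_spec(100000L)
  g <- simulate_population(spec, seed = 8)
  freq <- table(g$true_copy_number) / nrow(g)
  expect_equal(as.numeric(freq[names(spec$distribution)]),
               unname(spec$distribution), tolerance = 0.01)

  expect_error(population_spec("bad", c(`2` = 0.6, `3` = 0.6), 10), "sum to 1")
  expect_error(population_spec("bad", c(`1` = 1), 10), ">= 2")
})

test_that("simulate_ct_table inverts the copy-number equation", {
  g <- data.frame(sample_id = c("a", "b"), true_copy_number = c(4L, 2L))
  quiet <- ct_noise_model(replicate_sd = 0, between_sample_sd = 0)
  w <- simulate_ct_table(g, quiet, seed = 1)
  agg <- aggregate_replicates(w)
  dct <- function(s)
    agg$mean_ct[agg$sample_id == s & agg$assay == "target"] -
      agg$mean_ct[agg$sample_id == s & agg$assay == "control"]
  expect_equal(dct("a"), -1)      # 4 copies: one cycle earlier
  expect_equal(dct("b"), 0)       # 2 copies: no offset

  # efficiency-corrected inverse round-trips through the corrected estimator
  eff <- ct_noise_model(replicate_sd = 0, between_sample_sd = 0,
                        eff_target = 0.98, eff_control = 0.97)
  w2 <- simulate_ct_table(g, eff, seed = 1)
  pol <- calling_policy(efficiency_correction = TRUE,
                        eff_target = 0.98, eff_control = 0.97)
  res <- genotype_population(w2, pol)
  expect_equal(res$raw_estimate[match(c("a", "b"), res$sample_id)],
               c(4, 2), tolerance = 1e-9)

  w3 <- simulate_ct_table(g, ct_noise_model(), seed = 9)
  w4 <- simulate_ct_table(g, ct_noise_model(), seed = 9)
  expect_identical(w3, w4)
})

test_that("simulate_phenotypes honours class means and seeds", {
  g <- data.frame(sample_id = c("a", "b"), true_copy_number = c(3L, 4L))
  eff0 <- jh_growth_effects()
  eff0$sd <- 0
  p <- simulate_phenotypes(g, eff0)
  expect_equal(p$shell_length, c(133.37, 136.57))
  expect_equal(p$body_weight, c(256.85, 267.39))

  p1 <- simulate_phenotypes(g, seed = 6)
  p2 <- simulate_phenotypes(g, seed = 6)
  expect_identical(p1, p2)

  g5 <- data.frame(sample_id = "z", true_copy_number = 5L)
  expect_error(simulate_phenotypes(g5), "no phenotype effects")
})

test_that("cohort means land near generator truth (normal-theory check)", {
  set.seed(12)
  g <- data.frame(sample_id = sprintf("i%03d", 1:89),
                  true_copy_number = rep(c(3L, 4L), c(40, 49)))
  p <- simulate_phenotypes(g, jh_growth_effects())
  # 3 sigma of the mean at the published group sizes (SE 1.29 / 1.30 mm)
  m3 <- mean(p$shell_length[g$true_copy_number == 3L])
  m4 <- mean(p$shell_length[g$true_copy_number == 4L])
  expect_lt(abs(m3 - 133.37), 3 * 1.29)
  expect_lt(abs(m4 - 136.57), 3 * 1.30)
})

test_that("simulate_dilution_series matches the closed form", {
  s <- simulate_dilution_series(2.0, noise_sd = 0)
  fit <- fit_standard_curve(s)
  expect_equal(fit$slope, -log(10) / log(2), tolerance = 1e-12)
  expect_equal(fit$efficiency_percent, 100, tolerance = 1e-9)
  expect_error(simulate_dilution_series(1.0), "amplification factor")
  expect_error(simulate_dilution_series(0.9), "amplification factor")

  # noisy recovery: within 2 efficiency points in most repetitions
  set.seed(14)
  ok <- 0L
  for (i in 1:40) {
    s <- simulate_dilution_series(1.9, noise_sd = 0.05, replicates = 10L)
    eff <- fit_standard_curve(s)$efficiency_percent
    ok <- ok + (abs(eff - 90) <= 2)
  }
  expect_gte(ok, 38L)
})

test_that("call accuracy is non-increasing in true copy number", {
  set.seed(15)
  n_per <- 3000L
  acc <- vapply(2:12, function(cn) {
    g <- data.frame(sample_id = sprintf("c%d_%04d", cn, seq_len(n_per)),
                    true_copy_number = cn)
    w <- simulate_ct_table(g, ct_noise_model(replicate_sd = 0.1))
    res <- genotype_population(w)
    mean(!is.na(res$call) & res$call == cn)
  }, numeric(1))
  # allow 2 points of Monte-Carlo slack between adjacent classes
  expect_true(all(diff(acc) <= 0.02))
  expect_gt(acc[1], 0.95)   # 2 copies are near-perfectly callable
})

test_that("full-pipeline recovery on a JH-like cohort", {
  set.seed(101)
  spec <- jh_population_spec(100L)
  g <- simulate_population(spec)
  w <- simulate_ct_table(g, ct_noise_model(replicate_sd = 0.1))
  res <- genotype_population(w)
  ft <- genotype_frequencies(res, "JH")
  # total-variation distance between called and generating distributions
  classes <- union(names(ft$frequencies), names(spec$distribution))
  called <- setNames(rep(0, length(classes)), classes)
  called[names(ft$frequencies)] <- ft$frequencies
  truth <- setNames(rep(0, length(classes)), classes)
  truth[names(spec$distribution)] <- spec$distribution
  expect_lt(sum(abs(called - truth)) / 2, 0.1)

  # a simulated positive shell-length effect is recovered as positive
  phen <- simulate_phenotypes(g[g$true_copy_number %in% c(3L, 4L), ],
                              jh_growth_effects())
  # only classes 3 and 4 are phenotyped, so the join warns about the rest
  out <- suppressWarnings(associate(res[, c("sample_id", "call")],
                                    phen, 3, 4))
  len <- out$tests[out$tests$trait == "shell_length", ]
  expect_gt(len$estimate, 0)
})

test_that("scenario config round-trips through JSON", {
  cfg <- list(
    population = list(id = "JH", n = 30,
                      distribution = list(`3` = 0.5, `4` = 0.5)),
    noise = list(replicate_sd = 0.05),
    dilution = list(amplification_factor = 1.97))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  sc <- read_scenario(path)
  expect_s3_class(sc$population, "population_spec")
  expect_equal(sc$noise$replicate_sd, 0.05)
  sim <- simulate_scenario(sc, seed = 2)
  expect_equal(nrow(sim$genotypes), 30L)
  expect_equal(nrow(sim$wells), 30L * 2L * 3L)
  expect_equal(fit_standard_curve(sim$dilution)$efficiency_percent, 97,
               tolerance = 1e-6)
})
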