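# Monte Carlo engine: degeneracy, determinism, distributional invariants,
# sensitivity attribution.

test_that("degenerate input distributions collapse to the point estimate", {
  cfg <- degenerate_config(n = 50)
  sim <- run_simulation(cfg)
  for (g in age_groups()) {
    f <- cfg$age_groups[[g]]
    point <- list(oral = add_ingestion(f$AsC_mean, f),
                  dermal = add_dermal(f$AsC_mean, f),
                  inhalation = add_inhalation(f$AsC_mean, f))
    for (p in pathways()) {
      s <- sim$groups[[g]][[p]]$add
      expect_identical(s$sd, 0)
      expect_equal(s$mean, point[[p]], tolerance = 1e-12)
      expect_equal(s$median, point[[p]], tolerance = 1e-12)
      expect_identical(sim$groups[[g]][[p]]$hq$sd, 0)
      expect_identical(sim$groups[[g]][[p]]$cr$sd, 0)
    }
  }
})

test_that("identical configuration and seed give identical results", {
  cfg <- small_config(n = 1000, seed = 314)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  for (m in c("add", "hq", "cr")) {
    expect_identical(summary_table(s1, m), summary_table(s2, m))
  }
  s3 <- run_simulation(small_config(n = 1000, seed = 315))
  expect_false(identical(summary_table(s1, "add"), summary_table(s3, "add")))
})

test_that("hazard index is the within-scenario sum of pathway quotients", {
  sim <- run_simulation(small_config(n = 2000))
  for (g in age_groups()) {
    gg <- sim$groups[[g]]
    expect_equal(gg$hi$mean,
                 gg$oral$hq$mean + gg$dermal$hq$mean + gg$inhalation$hq$mean,
                 tolerance = 1e-12)
    expect_equal(gg$acr$mean,
                 gg$oral$cr$mean + gg$dermal$cr$mean + gg$inhalation$cr$mean,
                 tolerance = 1e-12)
    # a joint sum can never exceed the sum of componentwise maxima
    expect_lte(gg$hi$max, gg$oral$hq$max + gg$dermal$hq$max +
                 gg$inhalation$hq$max + 1e-12)
  }
})

test_that("simulated median factorizes over independent inputs", {
  cfg <- small_config(n = 10000, seed = 2024)
  sim <- run_simulation(cfg, keep_draws = TRUE)
  for (g in c("preschooler", "adult")) {
    d <- sim$groups[[g]]$draws
    f <- cfg$age_groups[[g]]
    k <- add_ingestion(1, f, BW = 1)  # constant multiplier of C/BW
    med_sim <- median(d$add$oral)
    med_fact <- k * median(d$AsC) / median(d$BW)
    boot <- replicate(200, median(sample(d$add$oral, replace = TRUE)))
    expect_lt(abs(med_sim - med_fact), 3 * sd(boot) + 1e-15)
  }
})

test_that("body-weight spread inflates the simulated mean above the point dose",
{
  cfg <- small_config(n = 10000, seed = 8)
  sim <- run_simulation(cfg, keep_draws = TRUE)
  for (g in age_groups()) {
    d <- sim$groups[[g]]$draws
    f <- cfg$age_groups[[g]]
    # Jensen: E[C/BW] = E[C] E[1/BW] >= E[C]/E[BW], strictly for sigma_BW > 0
    point_at_sampled_means <- add_ingestion(mean(d$AsC), f, BW = mean(d$BW))
    expect_gt(sim$groups[[g]]$oral$add$mean, point_at_sampled_means)
  }
})

test_that("simulated moments match closed-form lognormal-ratio moments", {
  specC <- fit_lognormal_moments(15.6, 5.94)   # untruncated
  specB <- lognormal_spec(2.7568823, 0.2641822)
  n <- 1e6
  set.seed(31)
  C <- sample_lognormal(specC, n)
  BW <- sample_lognormal(specB, n)
  k <- 1e-4
  add <- k * C / BW
  mean_cf <- k * exp(specC$mu + specC$sigma^2 / 2) *
    exp(-specB$mu + specB$sigma^2 / 2)
  median_cf <- k * exp(specC$mu - specB$mu)
  expect_equal(mean(add), mean_cf, tolerance = 0.01)
  expect_equal(median(add), median_cf, tolerance = 0.01)
})

test_that("sensitivity attribution sums to one and honours symmetry", {
  cfg <- small_config(n = 10000, seed = 77)
  s <- sensitivity_contributions(cfg, "preschooler", "oral")
  expect_equal(sum(s), 1)
  expect_true(all(s >= 0))
  # concentration has the larger log-spread, so it drives more variance
  expect_gt(s[["AsC"]], s[["BW"]])

  # only the concentration varies: it receives the full attribution
  cfgd <- cfg
  f <- cfgd$age_groups$adult
  f$BW_min <- f$BW_mean; f$BW_max <- f$BW_mean
  cfgd$age_groups$adult <- f
  expect_identical(sensitivity_contributions(cfgd, "adult", "oral"),
                   c(AsC = 1))

  # identically distributed numerator and denominator split evenly
  cfgs <- cfg
  f <- cfgs$age_groups$preschooler
  f$AsC_mean <- f$BW_mean
  f$AsC_sd <- f$BW_mean * sqrt(exp(0.2641822^2) - 1)
  f$AsC_min <- f$BW_min; f$AsC_max <- f$BW_max
  cfgs$age_groups$preschooler <- f
  sym <- sensitivity_contributions(cfgs, "preschooler", "oral")
  expect_equal(unname(sym[["AsC"]]), 0.5, tolerance = 0.05)
})
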