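# Exposure-parameter registry: defaults, validation, config file round trips.

test_that("every default exposure parameter sits in its expected field", {
  cfg <- default_araro_config()

  # table-driven check of the full parameter registry, one row per value
  expected <- rbind(
    data.frame(group = "preschooler",
               field = c("ED", "BW_mean", "BW_min", "BW_max", "AT", "IR",
                         "InhR", "SA"),
               value = c(3.51, 16.31, 10, 39, 1229, 100, 9.5, 760)),
    data.frame(group = "elementary",
               field = c("ED", "BW_mean", "BW_min", "BW_max", "AT", "IR",
                         "InhR", "SA"),
               value = c(8.82, 33.8, 14, 95.7, 3087, 100, 12, 1080)),
    data.frame(group = "adolescent",
               field = c("ED", "BW_mean", "BW_min", "BW_max", "AT", "IR",
                         "InhR", "SA"),
               value = c(15.88, 60.91, 25.9, 158.4, 5558, 30, 15.75, 1840)),
    data.frame(group = "adult",
               field = c("ED", "BW_mean", "BW_min", "BW_max", "AT", "IR",
                         "InhR", "SA"),
               value = c(42.94, 72.67, 45, 194.2, 15029, 30, 14.67, 1935))
  )
  for (i in seq_len(nrow(expected))) {
    expect_identical(cfg$age_groups[[expected$group[i]]][[expected$field[i]]],
                     expected$value[i],
                     label = paste(expected$group[i], expected$field[i]))
  }

  shared <- list(AsC_mean = 15.6, AsC_min = 5.94, AsC_max = 42.53,
                 AsC_sd = 5.94, EF = 350, PEF = 1.36e9, AF = 0.5,
                 ABS = 0.03, EV = 1, CF = 1e-6, cAT = 25550)
  for (g in age_groups()) {
    for (nm in names(shared)) {
      expect_identical(cfg$age_groups[[g]][[nm]], shared[[nm]],
                       label = paste(g, nm))
    }
  }

  expect_identical(cfg$toxicity$rfd_oral, 3.0e-4)
  expect_identical(cfg$toxicity$rfd_dermal_screen, 1.23e-4)
  expect_identical(cfg$toxicity$rfd_hq_dermal, 3.0e-4)
  expect_identical(cfg$toxicity$rfd_inhalation, 1.5e-5)
  expect_identical(cfg$toxicity$sf, 1.5)
  expect_identical(cfg$toxicity$hq_limit, 1)
  expect_identical(cfg$toxicity$cr_limit, 1e-5)
  expect_identical(cfg$n_iterations, 10000L)
  expect_identical(cfg$metadata$DFS, 362.4)
})

test_that("averaging time is consistent with duration x frequency", {
  cfg <- default_araro_config()
  for (g in age_groups()) {
    f <- cfg$age_groups[[g]]
    expect_lt(abs(f$AT - f$ED * f$EF), 1)
  }
  # violating the consistency is flagged, not fatal
  f <- as.list(cfg$age_groups$preschooler)
  f$ED <- 1
  expect_warning(do.call(exposure_factors, f), "differs from ED x EF")
})

test_that("invalid parameters are rejected with the offending field named", {
  f <- as.list(default_araro_config()$age_groups$adult)
  f$BW_mean <- -1
  expect_error(do.call(exposure_factors, f), "BW_mean")

  f <- as.list(default_araro_config()$age_groups$adult)
  f$AsC_min <- 100
  expect_error(do.call(exposure_factors, f), "AsC_min")

  cfg <- default_araro_config()
  expect_error(study_config(cfg$age_groups[c("adult", "preschooler")]),
               "missing age group")
  bad <- cfg$age_groups
  names(bad)[1] <- "toddler"
  expect_error(study_config(bad), "toddler")
})

test_that("configs round-trip through YAML and JSON unchanged", {
  cfg <- default_araro_config()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_config(cfg, path)
    back <- load_config(path)
    expect_equal(back, cfg, tolerance = 1e-12)
  }
})

test_that("config files may override a subset of fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("simulation:\n  n_iterations: 500", path)
  cfg <- load_config(path)
  expect_identical(cfg$n_iterations, 500L)
  expect_equal(cfg$age_groups, default_araro_config()$age_groups)

  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"age_groups": {"adult": {"IR": 50}}}', path2)
  cfg2 <- load_config(path2)
  expect_identical(cfg2$age_groups$adult$IR, 50)
  expect_identical(cfg2$age_groups$adult$SA, 1935)
  expect_identical(cfg2$age_groups$preschooler$IR, 100)

  path3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("age_groups:\n  adult:\n    BW_mean: -1", path3)
  expect_error(load_config(path3), "BW_mean")

  path4 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("age_groups:\n  toddler:\n    IR: 10", path4)
  expect_error(load_config(path4), "toddler")

  path5 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("toxicity:\n  rfd_banana: 2", path5)
  expect_error(load_config(path5), "rfd_banana")
})
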