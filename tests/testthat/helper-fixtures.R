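# Shared fixtures: all synthetic, built in code at test time.

# Default study conditions with a reduced iteration count for fast tests.
small_config <- function(n = 2000, seed = 42) {
  cfg <- default_araro_config()
  cfg$n_iterations <- as.integer(n)
  cfg$seed <- as.integer(seed)
  cfg
}

# A configuration whose two random inputs are point masses, so the Monte
# Carlo engine must collapse to the deterministic dose calculation.
degenerate_config <- function(n = 50, seed = 7) {
  cfg <- small_config(n, seed)
  for (g in age_groups()) {
    f <- cfg$age_groups[[g]]
    f$AsC_sd <- 0
    f$BW_min <- f$BW_mean
    f$BW_max <- f$BW_mean
    cfg$age_groups[[g]] <- f
  }
  cfg
}

toy_survey <- function(conc = c(10, 20, 30), below = rep(FALSE, length(conc)),
                       lod = 4) {
  dust_survey(sprintf("T%02d", seq_along(conc)), conc, below, lod = lod)
}
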