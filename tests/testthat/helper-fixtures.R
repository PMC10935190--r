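# Shared fixtures, built once per test run and memoized.

# A noiseless world: no scatter, no instrument noise, identity instruments.
noiseless_scene <- function() {
  sceneConfig(scatter_mult_sd = 0, scatter_add_sd = 0)
}

identity_profiles <- function(n = 3L, noise_sd = 0) {
  lapply(as.character(seq_len(n)), instrumentProfile, noise_sd = noise_sd)
}

small_season <- function(n = 24L, label = "t", reps = 3L,
                         em_residual_sd = 3.2, sel = 0.35) {
  seasonConfig(label, n, wp_mean = 63.5, wp_sd = 7.3,
               wp_min = 42, wp_max = 79,
               em_residual_sd = em_residual_sd, sel = sel,
               n_replicates = reps)
}

# The full two-season default campaign plus the headline fits, computed at
# most once per test run.
default_campaign <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      camp <- simulateCampaign(list(season2021(), season2022()), seed = 1L)
      ref <- camp$reference
      info <- scanInfo(camp$spectra)
      cal <- camp$spectra[, info$ear_id %in% ref$ear_id[ref$season == "2021"]]
      val <- camp$spectra[, info$ear_id %in% ref$ear_id[ref$season == "2022"]]
      cache <<- list(camp = camp, ref = ref, cal = cal, val = val)
    }
    cache
  }
})

sgd_spec <- function() preprocessSpec("sg_derivative", 2, 11, 2)

# Ear-moisture calibrations on the 2021 scans: pooled and instrument-1-only.
default_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- default_campaign()
      cal_avg <- toAbsorbance(averageReplicates(d$cal, "ear_instrument"))
      y <- d$ref$ear_moisture_wb[match(scanInfo(cal_avg)$ear_id,
                                       d$ref$ear_id)]
      m_all <- fitCalibration(cal_avg, y, spec = sgd_spec())
      cal1 <- toAbsorbance(averageReplicates(
        filterInstruments(d$cal, "1"), "ear_instrument"))
      y1 <- d$ref$ear_moisture_wb[match(scanInfo(cal1)$ear_id,
                                        d$ref$ear_id)]
      m_1 <- fitCalibration(cal1, y1, spec = sgd_spec())
      cache <<- list(cal_avg = cal_avg, y = y, m_all = m_all,
                     cal1 = cal1, y1 = y1, m_1 = m_1)
    }
    cache
  }
})
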