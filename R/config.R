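#' Derive a stage-specific seed from a master seed
#'
#' Deterministic hash of (seed, stage name) into [1, 2^31 - 2], so each
#' pipeline stage gets its own reproducible stream and partial reruns of a
#' stage reproduce the full run's draws.
#' @param seed master integer seed
#' @param stage stage name, e.g. "season:2021" or "scans:3"
#' @export
deriveSeed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

#' Read and validate a simulation run configuration (YAML)
#'
#' Schema: a mandatory integer \code{seed}; \code{seasons}, a list of
#' season blocks (label, n_plants, wp_mean, wp_sd, wp_min, wp_max and
#' optionally em_residual_sd, sel, n_replicates); optional
#' \code{instruments} blocks (instrument_id plus any of wavelength_shift,
#' gain, baseline_offset, noise_sd); an optional \code{scene} block with
#' \code{\link{sceneConfig}} fields. Omitted blocks fall back to the
#' package defaults (three instruments, standard scene).
#'
#' @param path YAML file
#' @return list(seed, seasons, profiles, scene)
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set an integer 'seed'")
  if (is.null(cfg$seasons) || !length(cfg$seasons))
    stop("config must define at least one season")
  seasons <- lapply(cfg$seasons, function(s) {
    need <- c("label", "n_plants", "wp_mean", "wp_sd", "wp_min", "wp_max")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop("season block lacks field(s): ", paste(miss, collapse = ", "))
    do.call(seasonConfig, s)
  })
  profiles <- if (is.null(cfg$instruments)) {
    defaultInstrumentProfiles()
  } else {
    lapply(cfg$instruments, function(p) {
      if (is.null(p$instrument_id))
        stop("instrument block lacks instrument_id")
      do.call(instrumentProfile, p)
    })
  }
  scene <- if (is.null(cfg$scene)) defaultScene() else
    do.call(sceneConfig, cfg$scene)
  list(seed = as.integer(cfg$seed), seasons = seasons,
       profiles = profiles, scene = scene)
}

#' Simulate a campaign from a config and write its CSV outputs
#'
#' Writes \code{spectra.csv} and \code{reference.csv} (the formats of
#' \code{\link{writeSpectra}} / \code{\link{writeReference}}) under
#' \code{outDir}; inputs are never modified. Identical configs produce
#' byte-identical outputs.
#'
#' @param config path to a YAML config or a list from
#'   \code{\link{readRunConfig}}
#' @param outDir output directory (created if needed)
#' @return invisibly, the campaign list from \code{\link{simulateCampaign}}
#' @export
runSimulation <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  camp <- simulateCampaign(config$seasons, config$profiles, config$scene,
                           seed = config$seed)
  writeSpectra(camp$spectra, file.path(outDir, "spectra.csv"))
  writeReference(camp$reference, file.path(outDir, "reference.csv"))
  invisible(camp)
}
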