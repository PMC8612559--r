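.model_from_config <- function(cfg) {
  geom <- cfg$geometry %||% list()
  morph <- switch(cfg$model %||% "ball",
    ball = do.call(ballMorphology, geom),
    ball_and_stick = do.call(ballAndStickMorphology, geom),
    ball_stick_axon = do.call(ballStickAxonMorphology, geom),
    synthetic_branched = generateSyntheticMorphology(
      do.call(SyntheticMorphologySpec, geom)),
    stop("unknown model: ", cfg$model))
  channels <- defaultChannelSet(file = cfg$channelFile %||% NULL)
  buildModel(morph, channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset analysis configurations
#'
#' Named presets covering the package's standard protocols: GABA-only
#' threshold curves with the reciprocal threshold E_GABA ("gaba-thr"),
#' rheobase and the four AP-threshold estimators ("excitability"),
#' AMPA-threshold shift curves ("ampa-shift"), delay scans ("delay-scan"),
#' tonic scans ("tonic-scan") and the GHK conversion table ("ghk").
#'
#' @param name preset name
#' @return a config list accepted by \code{\link{runPipeline}}
#' @export
presetConfig <- function(name = c("gaba-thr", "excitability", "ampa-shift",
                                  "delay-scan", "tonic-scan", "ghk")) {
  name <- match.arg(name)
  base <- list(model = "ball", seed = 1)
  switch(name,
    "gaba-thr" = c(base, list(scan = "gaba-thr",
                              egrid = seq(-44, -40, by = 0.5))),
    "excitability" = c(base, list(scan = "excitability")),
    "ampa-shift" = c(base, list(scan = "ampa-shift", gGaba = 3.95,
                                egrid = seq(-46, -43, by = 0.5))),
    "delay-scan" = c(base, list(scan = "delay-scan", gGaba = 3.95,
                                delays = seq(-150, 150, by = 10),
                                egrid = seq(-51, -42, by = 0.5))),
    "tonic-scan" = c(base, list(scan = "tonic-scan",
                                densities = 8.75e-9 * 10^seq(-2, 3),
                                egrid = seq(-51, -42, by = 0.5))),
    "ghk" = c(base, list(scan = "ghk",
                         egaba = seq(-60, -40, by = 0.5))))
}

#' Run a configured analysis pipeline
#'
#' Executes the scan named in the config on the configured model and returns
#' tidy tables plus a JSON-ready summary. Deterministic scans re-run
#' bit-identically under the same config. Use \code{\link{presetConfig}} for
#' ready-made configurations; any config can also be loaded from a YAML file
#' via \code{yaml::read_yaml}.
#'
#' @param config named list (or path to a YAML file)
#' @param outDir optional directory; when given, tables are written as CSV
#'   and the summary as JSON
#' @return list(tables = list of data.frame, summary = list)
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  tables <- list(); summary <- list(scan = config$scan %||% "none")
  if (!is.null(config$scan)) {
    model <- if (config$scan == "ghk") NULL else .model_from_config(config)
    if (config$scan == "gaba-thr") {
      cur <- scanGGabaThr(model, config$egrid)
      est <- egabaThrReciprocal(cur)
      tables$gthr <- data.frame(egaba = cur@egaba, gthr = cur@gthr)
      summary$egabaThr <- est@value
    } else if (config$scan == "excitability") {
      rb <- rheobaseSearch(model)
      st <- apThresholdST(model, search = rb)
      sw <- runSweep(model, list(IClamp(rb@gThr * 1e-3, delay = 100,
                                        dur = 2000)),
                     SolverConfig(tstop = 2400))
      summary$rheobase_pA <- rb@gThr
      summary$eThrST <- st$value
      summary$eThrDvdt <- apThresholdDvdt(sw)$value
      summary$eThrD3 <- apThresholdD3(sw)$value
      summary$eThrIS <- tryCatch(apThresholdIS(sw)$value,
                                 error = function(e) NA_real_)
      tables$thresholds <- data.frame(
        method = c("rheobase_pA", "ST", "dVdt", "d3", "IS"),
        value = c(summary$rheobase_pA, summary$eThrST, summary$eThrDvdt,
                  summary$eThrD3, summary$eThrIS))
    } else if (config$scan == "ampa-shift") {
      cur <- deltaGAmpaCurve(model, config$egrid,
                             gGaba = config$gGaba %||% 3.95)
      tables$delta <- data.frame(egaba = cur$egaba, withGaba = cur$withGaba,
                                 baseline = cur$baseline, delta = cur$delta)
      summary$egabaThr <- egabaThrIntersection(cur)@value
    } else if (config$scan == "delay-scan") {
      tab <- delayScan(model, delays = config$delays,
                       egrid = config$egrid,
                       gGaba = config$gGaba %||% 3.95)
      tables$delay <- tab
      summary$egabaThrRange <- range(tab$egabaThr, na.rm = TRUE)
    } else if (config$scan == "tonic-scan") {
      tab <- tonicScan(model, densities = config$densities,
                       egrid = config$egrid)
      tables$tonic <- tab
      summary$egabaThr <- tab$egabaThr
    } else if (config$scan == "ghk") {
      tab <- data.frame(egaba = config$egaba,
                        cli = ghkClFromEgaba(config$egaba, warn = FALSE))
      tables$ghk <- tab
    } else stop("unknown scan: ", config$scan)
  }
  summary$seed <- config$seed %||% NA
  summary$configHash <- .config_hash(config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      tab$configHash <- summary$configHash
      utils::write.csv(tab, file.path(outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(tables = tables, summary = summary)
}

.config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
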