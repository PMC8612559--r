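#' Goldman-Hodgkin-Katz parameters
#'
#' Defaults are the experimentally constrained values for immature
#' hippocampal neurons: [Cl-]e 133.5 mM, [HCO3-]e 24 mM, [HCO3-]i 14.1 mM,
#' relative HCO3- permeability 0.44, 60 mV per decade.
#'
#' @param cle,hco3e,hco3i concentrations, mM
#' @param phco3 relative HCO3- permeability (P_Cl = 1)
#' @param slope mV per decade
#' @return a \linkS4class{GhkParams}
#' @export
GhkParams <- function(cle = 133.5, hco3e = 24, hco3i = 14.1, phco3 = 0.44,
                      slope = 60) {
  new("GhkParams", cle = cle, hco3e = hco3e, hco3i = hco3i, phco3 = phco3,
      slope = slope)
}

#' Intracellular chloride from the GABA reversal potential
#'
#' Closed-form GHK relation
#' \code{[Cl-]i = 10^(E/slope) * (P_Cl*[Cl-]e + P_HCO3*[HCO3-]e)
#'   - P_HCO3*[HCO3-]i}, strictly increasing in E.
#'
#' @param egaba GABA-A reversal potential(s), mV
#' @param p a \linkS4class{GhkParams}
#' @param warn warn when the result is outside the physiological (positive)
#'   range
#' @return [Cl-]i, mM
#' @export
ghkClFromEgaba <- function(egaba, p = GhkParams(), warn = TRUE) {
  if (any(!is.finite(egaba))) stop("egaba must be finite")
  cl <- 10^(egaba / p@slope) * (p@cle + p@phco3 * p@hco3e) -
    p@phco3 * p@hco3i
  if (warn && any(cl <= 0))
    warning("E_GABA below the zero-chloride point: ",
            "[Cl-]i outside the physiological range")
  cl
}

#' GABA reversal potential from intracellular chloride
#'
#' Exact inverse of \code{\link{ghkClFromEgaba}}.
#'
#' @param cli intracellular chloride, mM
#' @param p a \linkS4class{GhkParams}
#' @return E_GABA, mV
#' @export
egabaFromCl <- function(cli, p = GhkParams()) {
  x <- (cli + p@phco3 * p@hco3i) / (p@cle + p@phco3 * p@hco3e)
  if (any(x <= 0)) stop("chloride too low: no real reversal potential")
  p@slope * log10(x)
}

#' Threshold-conductance curve over an E_GABA grid
#'
#' Runs one GABA conductance-threshold search per grid value. Grid points at
#' which no spike can be evoked up to the conductance cap are recorded as NA
#' ("no threshold"): these E_GABA lie at or below the threshold E_GABA.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param egrid E_GABA grid, mV (strictly increasing)
#' @param section,pos synapse site
#' @param onset GABA onset, ms
#' @param cap search cap, nS
#' @param window AP analysis window; default c(onset, onset + 800)
#' @param otherStimuli fixed co-stimuli
#' @return a \linkS4class{GThrCurve}
#' @export
scanGGabaThr <- function(model, egrid, section = "soma", pos = 0.5,
                         onset = 100, cap = 200, window = NULL,
                         otherStimuli = list()) {
  gthr <- vapply(egrid, function(e) {
    syn <- gabaSynapse(e, section = section, pos = pos, onsets = onset)
    res <- conductanceThresholdSearch(model, syn, "gGABA", window = window,
                                      otherStimuli = otherStimuli, cap = cap)
    res@gThr
  }, 1.0)
  new("GThrCurve", egaba = egrid, gthr = gthr,
      meta = list(section = section, pos = pos, cap = cap))
}

#' Threshold E_GABA from the reciprocal threshold-conductance plot
#'
#' Fits a straight line to the reciprocal threshold conductances
#' \code{1/gThr} at the \code{nFit} finite grid points nearest the
#' no-threshold region and returns its abscissa intercept: the E_GABA at
#' which the required conductance diverges, i.e. at which the GABA input
#' stops being able to excite.
#'
#' @param curve a \linkS4class{GThrCurve}
#' @param nFit number of reciprocal points in the fit (default 2)
#' @param maxExtrapolate refuse to extrapolate further than this many mV
#'   below the lowest finite grid point
#' @return an \linkS4class{EGabaThrEstimate}
#' @export
egabaThrReciprocal <- function(curve, nFit = 2, maxExtrapolate = 2) {
  fin <- which(is.finite(curve@gthr))
  if (length(fin) < nFit) stop("need at least ", nFit, " finite g_thr points")
  use <- fin[seq_len(nFit)]          # grid increasing: lowest E first
  x <- curve@egaba[use]
  y <- 1 / curve@gthr[use]
  fit <- stats::lm.fit(cbind(1, x), y)$coefficients
  if (!is.finite(fit[2]) || fit[2] <= 0)
    stop("non-positive reciprocal slope: curve does not approach the axis")
  e0 <- unname(-fit[1] / fit[2])
  if (e0 < min(x) - maxExtrapolate)
    stop("intercept extrapolates more than ", maxExtrapolate,
         " mV beyond the grid")
  new("EGabaThrEstimate", value = e0, method = "reciprocal",
      diagnostics = list(intercept = unname(fit[1]), slope = unname(fit[2]),
                         points = data.frame(egaba = x, recip = y)))
}

#' AMPA threshold shift induced by GABA co-stimulation
#'
#' For each E_GABA in the grid, searches the minimal AMPA conductance that
#' triggers a spike with the GABA co-stimulus present, and subtracts the
#' baseline AMPA threshold found without GABA:
#' \code{delta = gAmpaThr(with GABA) - gAmpaThr(without)}. Negative values
#' mean the GABAergic input is excitatory.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param egrid E_GABA grid, mV
#' @param gGaba GABA peak conductance, nS
#' @param gabaSite,ampaSite c(section, pos)
#' @param gabaOnset,ampaOnset onset times, ms
#' @param tonicDensity if > 0, the GABA input is a tonic conductance of this
#'   density (S/cm^2) instead of a phasic synapse
#' @param playback if TRUE the GABAergic input is replaced by the played-back
#'   current recorded from the conductance sweep (isolates the
#'   depolarization from the shunt)
#' @param window optional fixed AMPA analysis window
#' @param baseline optional precomputed baseline gAmpaThr, nS
#' @return list(egaba, withGaba, baseline, delta) -- the quantities of a
#'   Delta-gAMPA curve
#' @export
deltaGAmpaCurve <- function(model, egrid, gGaba = 3.95,
                            gabaSite = c("soma", 0.5),
                            ampaSite = c("soma", 0.5),
                            gabaOnset = 100, ampaOnset = 100,
                            tonicDensity = 0, playback = FALSE,
                            window = NULL, baseline = NULL) {
  ampa <- ampaSynapse(section = ampaSite[[1]], pos = as.numeric(ampaSite[[2]]),
                      onsets = ampaOnset)
  tstop <- max(gabaOnset, ampaOnset) + 600
  cfg <- SolverConfig(tstop = tstop)
  if (is.null(window))
    window <- ampaAnalysisWindow(model, ampa, cfg = cfg)
  if (is.null(baseline)) {
    base <- conductanceThresholdSearch(model, ampa, "gAMPA", window = window,
                                       cfg = cfg)
    baseline <- base@gThr
  }
  withg <- vapply(egrid, function(e) {
    gabaStim <- if (tonicDensity > 0) {
      TonicGaba(tonicDensity, e)
    } else {
      gabaSynapse(e, gmax = gGaba, section = gabaSite[[1]],
                  pos = as.numeric(gabaSite[[2]]), onsets = gabaOnset)
    }
    if (playback && tonicDensity == 0) {
      gabaStim <- recordPlayback(model, gabaStim, cfg)
    }
    res <- conductanceThresholdSearch(model, ampa, "gAMPA", window = window,
                                      otherStimuli = list(gabaStim),
                                      cfg = cfg)
    res@gThr
  }, 1.0)
  list(egaba = egrid, withGaba = withg, baseline = baseline,
       delta = withg - baseline)
}

#' Threshold E_GABA from the Delta-gAMPA sign change
#'
#' Linear interpolation of the E_GABA at which the AMPA-threshold shift
#' changes sign (GABA co-stimulation switches from raising to lowering the
#' AMPA threshold).
#'
#' @param delta a list as returned by \code{\link{deltaGAmpaCurve}}
#' @return an \linkS4class{EGabaThrEstimate}; value NA with method
#'   "out-of-range" if the curve does not change sign on the grid
#' @export
egabaThrIntersection <- function(delta) {
  e <- delta$egaba; d <- delta$delta
  ok <- is.finite(d)
  e <- e[ok]; d <- d[ok]
  if (length(e) < 2) stop("need at least two finite delta values")
  s <- which(d[-length(d)] > 0 & d[-1] <= 0)
  if (!length(s)) {
    return(new("EGabaThrEstimate", value = NA_real_, method = "out-of-range",
               diagnostics = list(delta = d, egaba = e)))
  }
  i <- s[1]
  x <- e[i] + d[i] * (e[i + 1] - e[i]) / (d[i] - d[i + 1])
  new("EGabaThrEstimate", value = x, method = "intersection",
      diagnostics = list(bracket = c(e[i], e[i + 1]),
                         delta = c(d[i], d[i + 1])))
}

#' Threshold E_GABA as a function of the GABA-AMPA delay
#'
#' Shifts the AMPA onset relative to the GABA onset and recomputes the
#' intersection threshold E_GABA for each delay. Negative delays mean the
#' AMPA input precedes the GABA input.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param delays ms (AMPA onset minus GABA onset)
#' @param egrid E_GABA grid for the intersection
#' @param gGaba GABA peak conductance, nS
#' @param gabaOnset ms
#' @param playback replay the GABA current instead of the conductance
#' @return data.frame(delay, egabaThr)
#' @export
delayScan <- function(model, delays = seq(-150, 150, by = 10),
                      egrid = seq(-51, -42, by = 0.5), gGaba = 3.95,
                      gabaOnset = 250, playback = FALSE) {
  out <- vapply(delays, function(d) {
    cur <- deltaGAmpaCurve(model, egrid, gGaba = gGaba,
                           gabaOnset = gabaOnset, ampaOnset = gabaOnset + d,
                           playback = playback)
    egabaThrIntersection(cur)@value
  }, 1.0)
  data.frame(delay = delays, egabaThr = out)
}

#' Somatic peak time of a single synaptic input
#'
#' Control sweep with the spike mechanism disabled; used to align GABA and
#' AMPA inputs so their somatic peak depolarizations coincide.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param syn an \linkS4class{Exp2Synapse} (one onset)
#' @param cfg solver configuration
#' @return peak time relative to onset, ms
#' @export
synapticPeakTime <- function(model, syn, cfg = SolverConfig(tstop = 600)) {
  pcfg <- cfg; pcfg@apMechanism <- FALSE
  s <- syn
  if (s@gmax <= 0) s@gmax <- 0.1
  sw <- runSweep(model, list(s), pcfg)
  onset <- min(s@onsets)
  tr <- sw@time
  v <- sw@v[1, ]
  rest <- v[which.min(abs(tr - onset))]
  dep <- abs(v - rest)
  dep[tr < onset] <- 0
  tr[which.max(dep)] - onset
}

#' Spatial scan of threshold E_GABA over GABA and AMPA dendritic positions
#'
#' For each (GABA position, AMPA position) pair, the AMPA onset is shifted so
#' the somatic peak depolarizations of the two inputs coincide (peak times
#' from spike-mechanism-free control sweeps), then the intersection threshold
#' E_GABA is computed.
#'
#' @param model a ball-and-stick \linkS4class{CompartmentalModel}
#' @param gabaPos,ampaPos normalized dendrite positions
#' @param egrid E_GABA grid
#' @param gGaba GABA peak conductance, nS (reference protocol: 7.89 nS)
#' @param section dendrite section name
#' @return data.frame(gabaPos, ampaPos, egabaThr)
#' @export
spatialScan <- function(model, gabaPos = dendritePositions(),
                        ampaPos = dendritePositions(),
                        egrid = seq(-51, -41, by = 1), gGaba = 7.89,
                        section = "dend") {
  onset <- 150
  gabaPeak <- vapply(gabaPos, function(p)
    synapticPeakTime(model, gabaSynapse(-40, gmax = 1, section = section,
                                        pos = p, onsets = onset)), 1.0)
  ampaPeak <- vapply(ampaPos, function(p)
    synapticPeakTime(model, ampaSynapse(gmax = 0.1, section = section,
                                        pos = p, onsets = onset)), 1.0)
  grid <- expand.grid(gi = seq_along(gabaPos), ai = seq_along(ampaPos))
  res <- mapply(function(gi, ai) {
    shift <- gabaPeak[gi] - ampaPeak[ai]   # AMPA onset offset for peak match
    cur <- deltaGAmpaCurve(model, egrid, gGaba = gGaba,
                           gabaSite = c(section, gabaPos[gi]),
                           ampaSite = c(section, ampaPos[ai]),
                           gabaOnset = onset, ampaOnset = onset + shift)
    egabaThrIntersection(cur)@value
  }, grid$gi, grid$ai)
  data.frame(gabaPos = gabaPos[grid$gi], ampaPos = ampaPos[grid$ai],
             egabaThr = res)
}

#' GABA-only threshold scan along the dendrite
#'
#' For each dendritic GABA position: the threshold-conductance curve over the
#' E_GABA grid, the reciprocal threshold E_GABA, and the somatic peak
#' depolarization at threshold conductance with the spike mechanism off
#' (E_GABA-Peak).
#'
#' @param model a ball-and-stick \linkS4class{CompartmentalModel}
#' @param positions normalized dendrite positions
#' @param egrid E_GABA grid
#' @param section dendrite section name
#' @param cap search cap, nS
#' @param nFit reciprocal fit points
#' @return list(estimates = data.frame(pos, egabaThr, egabaPeak),
#'   curves = list of GThrCurve)
#' @export
dendriticGabaScan <- function(model, positions = dendritePositions(),
                              egrid = seq(-46, -36, by = 1),
                              section = "dend", cap = 200, nFit = 2) {
  curves <- list()
  est <- lapply(positions, function(p) {
    cur <- scanGGabaThr(model, egrid, section = section, pos = p, cap = cap)
    curves[[length(curves) + 1]] <<- cur
    thr <- tryCatch(egabaThrReciprocal(cur, nFit = nFit)@value,
                    error = function(e) NA_real_)
    # E_GABA peak: somatic response at threshold conductance, AP mech off
    fin <- which(is.finite(cur@gthr))
    peak <- NA_real_
    if (length(fin)) {
      i <- fin[1]                     # closest to the no-threshold region
      syn <- gabaSynapse(cur@egaba[i], gmax = cur@gthr[i], section = section,
                         pos = p, onsets = 100)
      cfg <- SolverConfig(tstop = 900, apMechanism = FALSE)
      sw <- runSweep(model, list(syn), cfg)
      peak <- max(sw@v[1, ])
    }
    c(egabaThr = thr, egabaPeak = peak)
  })
  est <- do.call(rbind, est)
  list(estimates = data.frame(pos = positions, egabaThr = est[, "egabaThr"],
                              egabaPeak = est[, "egabaPeak"]),
       curves = curves)
}

#' Threshold E_GABA under tonic GABAergic conductances
#'
#' For each tonic density, computes the AMPA-threshold shift curve against
#' the no-tonic baseline and extracts the intersection threshold E_GABA.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param densities tonic conductance densities, S/cm^2 (physiological
#'   reference 8.75e-9)
#' @param egrid E_GABA grid
#' @param ampaSite c(section, pos)
#' @return data.frame(density, egabaThr)
#' @export
tonicScan <- function(model, densities = 8.75e-9 * 10^seq(-2, 3),
                      egrid = seq(-51, -42, by = 0.5),
                      ampaSite = c("soma", 0.5)) {
  ampa <- ampaSynapse(section = ampaSite[[1]], pos = as.numeric(ampaSite[[2]]),
                      onsets = 100)
  cfg <- SolverConfig(tstop = 700)
  window <- ampaAnalysisWindow(model, ampa, cfg = cfg)
  base <- conductanceThresholdSearch(model, ampa, "gAMPA", window = window,
                                     cfg = cfg)
  out <- vapply(densities, function(dn) {
    if (dn == 0) return(NA_real_)
    cur <- deltaGAmpaCurve(model, egrid, tonicDensity = dn,
                           ampaSite = ampaSite, window = window,
                           baseline = base@gThr)
    egabaThrIntersection(cur)@value
  }, 1.0)
  data.frame(density = densities, egabaThr = out)
}
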