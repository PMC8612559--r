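.soma_trace <- function(sweep) {
  list(t = sweep@time, v = sweep@v[1, ], dt = sweep@dt)
}

#' Detect an action potential in a sweep
#'
#' An AP is counted when the somatic (first recorded) voltage crosses the
#' detection level within the analysis window. For the full-height spikes of
#' the fitted model the verdict is insensitive to the exact level.
#'
#' @param sweep a \linkS4class{Sweep}
#' @param window c(t0, t1) in ms; default the whole sweep
#' @param level detection level, mV
#' @return list(ap = logical, time = first-crossing time or NA)
#' @export
detectAP <- function(sweep, window = NULL, level = 0) {
  tr <- .soma_trace(sweep)
  sel <- if (is.null(window)) rep(TRUE, length(tr$t))
         else tr$t >= window[1] & tr$t <= window[2]
  v <- tr$v[sel]; t <- tr$t[sel]
  i <- which(v >= level)
  if (!length(i)) return(list(ap = FALSE, time = NA_real_))
  list(ap = TRUE, time = t[i[1]])
}

.ap_peak_index <- function(v, level = 0) {
  i <- which(v >= level)
  if (!length(i)) stop("sweep contains no action potential")
  # first local maximum at or after the first crossing
  j <- i[1]
  while (j < length(v) && v[j + 1] >= v[j]) j <- j + 1
  j
}

.central_dv <- function(v, dt) {
  n <- length(v)
  dv <- rep(NA_real_, n)
  dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)   # mV/ms = V/s
  dv
}

#' AP threshold from the dV/dt criterion
#'
#' The membrane potential at which dV/dt first crosses a velocity criterion
#' (default 10 V/s) on the rising phase preceding the spike peak, with linear
#' sub-sample interpolation.
#'
#' @param sweep a \linkS4class{Sweep} containing an AP
#' @param crossing velocity criterion, V/s (= mV/ms)
#' @return list(value mV, time ms, method)
#' @export
apThresholdDvdt <- function(sweep, crossing = 10) {
  tr <- .soma_trace(sweep)
  v <- tr$v; t <- tr$t
  ip <- .ap_peak_index(v)
  dv <- .central_dv(v, tr$dt)
  idx <- which(dv[seq_len(ip)] >= crossing)
  idx <- idx[idx > 1]
  if (!length(idx)) stop("dV/dt never reaches ", crossing, " V/s before the peak")
  i <- idx[1]
  f <- (crossing - dv[i - 1]) / (dv[i] - dv[i - 1])
  f <- min(max(f, 0), 1)
  list(value = unname(v[i - 1] + f * (v[i] - v[i - 1])),
       time = unname(t[i - 1] + f * tr$dt), method = "dVdt")
}

#' AP threshold from the third-derivative criterion
#'
#' The membrane potential at the first positive local maximum of d3V/dt3
#' before the spike peak. Derivatives use the 5-point central stencil at the
#' solver dt; small early ripples are rejected by requiring at least 5% of
#' the pre-peak maximum.
#'
#' @param sweep a \linkS4class{Sweep} containing an AP
#' @return list(value mV, time ms, method)
#' @export
apThresholdD3 <- function(sweep) {
  tr <- .soma_trace(sweep)
  v <- tr$v; t <- tr$t; dt <- tr$dt
  ip <- .ap_peak_index(v)
  n <- length(v)
  d3 <- rep(NA_real_, n)
  i <- 3:(n - 2)
  d3[i] <- (-v[i - 2] + 2 * v[i - 1] - 2 * v[i + 1] + v[i + 2]) / (2 * dt^3)
  pre <- d3[seq_len(ip)]
  top <- max(pre, na.rm = TRUE)
  if (!is.finite(top) || top <= 0) stop("no positive d3V/dt3 peak before the AP peak")
  cand <- which(!is.na(pre) & pre > 0.05 * top)
  cand <- cand[cand > 3 & cand < ip]
  locmax <- cand[vapply(cand, function(j)
    d3[j] >= d3[j - 1] && d3[j] >= d3[j + 1], TRUE)]
  if (!length(locmax)) stop("no positive d3V/dt3 peak before the AP peak")
  j <- locmax[1]
  # sub-sample refinement: parabola through the three samples around the peak
  denom <- d3[j - 1] - 2 * d3[j] + d3[j + 1]
  f <- if (is.finite(denom) && abs(denom) > 0)
    min(max(0.5 * (d3[j - 1] - d3[j + 1]) / denom, -0.5), 0.5) else 0
  tj <- t[j] + f * dt
  vj <- stats::approx(t, v, xout = tj)$y
  list(value = unname(vj), time = unname(tj), method = "d3")
}

#' AP threshold from the line-intersection criterion
#'
#' Intersection of a linear fit to the pre-spike baseline with a linear fit
#' to the rising phase. The baseline window runs from 20 ms before the dV/dt
#' threshold time up to that time; the rising-phase fit uses the samples with
#' dV/dt between two velocity bounds.
#'
#' @param sweep a \linkS4class{Sweep} containing an AP
#' @param baselineLead ms of baseline before the dV/dt threshold time
#' @param riseRange dV/dt window (V/s) defining the rising-phase samples
#' @return list(value mV, time ms, method)
#' @export
apThresholdIS <- function(sweep, baselineLead = 20, riseRange = c(50, 200)) {
  tr <- .soma_trace(sweep)
  v <- tr$v; t <- tr$t
  tdv <- apThresholdDvdt(sweep)$time
  ip <- .ap_peak_index(v)
  base <- which(t >= tdv - baselineLead & t <= tdv)
  dv <- .central_dv(v, tr$dt)
  rise <- which(t <= t[ip] & t > tdv - 1 & dv >= riseRange[1] & dv <= riseRange[2])
  if (length(base) < 2 || length(rise) < 2)
    stop("not enough samples for the intersection fits")
  fb <- stats::lm.fit(cbind(1, t[base]), v[base])$coefficients
  fr <- stats::lm.fit(cbind(1, t[rise]), v[rise])$coefficients
  if (abs(fr[2] - fb[2]) < 1e-9) stop("baseline and rising fits are parallel")
  tx <- (fb[1] - fr[1]) / (fr[2] - fb[2])
  list(value = unname(fb[1] + fb[2] * tx), time = unname(tx), method = "IS")
}

#' Generic alternating threshold search
#'
#' Increase the control variable from zero in coarse steps until a spike
#' appears, then alternately decrease (factor \code{downFrac} of the coarse
#' step) until it vanishes and increase (factor \code{upFrac}) until it
#' reappears, shrinking both step sizes tenfold on each of \code{rounds}
#' rounds. The returned threshold is the smallest tested value that evoked a
#' spike; it is bracketed to the final up-step.
#'
#' @param isAP function(x) -> logical, spike or not (assumed non-decreasing)
#' @param step1 coarse step size
#' @param cap abort the coarse ramp at this value ("no threshold")
#' @param rounds number of refinement rounds
#' @param downFrac,upFrac step fractions of the coarse step per round
#' @return a \linkS4class{ThresholdSearchResult}
#' @export
alternatingSearch <- function(isAP, step1, cap, rounds = 6,
                              downFrac = 0.33, upFrac = 0.1) {
  hist_g <- numeric(0); hist_ap <- logical(0)
  test <- function(g) {
    ap <- isAP(g)
    hist_g <<- c(hist_g, g); hist_ap <<- c(hist_ap, ap)
    ap
  }
  g <- 0; ap <- FALSE
  while (!ap) {
    g <- g + step1
    if (g > cap + 1e-12)
      return(new("ThresholdSearchResult", gThr = NA_real_,
                 sweeps = length(hist_g),
                 history = data.frame(g = hist_g, ap = hist_ap),
                 finalStep = step1, capped = TRUE))
    ap <- test(g)
  }
  su <- step1
  for (r in seq_len(rounds)) {
    sd <- step1 * downFrac * 10^(-(r - 1))
    su <- step1 * upFrac * 10^(-(r - 1))
    while (ap && g - sd > 0) { g <- g - sd; ap <- test(g) }
    while (!ap) { g <- g + su; ap <- test(g) }
  }
  new("ThresholdSearchResult", gThr = g, sweeps = length(hist_g),
      history = data.frame(g = hist_g, ap = hist_ap),
      finalStep = su, capped = FALSE)
}

#' Synaptic conductance threshold search
#'
#' Locates the minimal peak conductance of a synapse that triggers a somatic
#' AP, by the alternating search. GABA searches use a 1 nS coarse step and an
#' 800 ms window after the synaptic onset; AMPA searches use a 0.01 nS coarse
#' step and the window from stimulus onset to the time at which the
#' AMPA-mediated depolarization (measured with the spike mechanism disabled)
#' has decayed to 63% of its peak amplitude.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param synapse template \linkS4class{Exp2Synapse}; its gmax is varied
#' @param variable "gGABA" or "gAMPA" (sets step sizes and default window)
#' @param window c(t0, t1) analysis window, ms; NULL for the variable default
#' @param otherStimuli additional fixed stimuli (co-stimulation, tonic, ...)
#' @param cap coarse-ramp cap, nS
#' @param cfg solver configuration
#' @return a \linkS4class{ThresholdSearchResult} (gThr in nS)
#' @export
conductanceThresholdSearch <- function(model, synapse,
                                       variable = c("gGABA", "gAMPA"),
                                       window = NULL, otherStimuli = list(),
                                       cap = NULL, cfg = NULL) {
  variable <- match.arg(variable)
  onset <- if (length(synapse@onsets)) min(synapse@onsets) else 0
  if (is.null(cfg)) {
    tstop <- if (variable == "gGABA") onset + 850 else
      max(onset + 450, if (!is.null(window)) window[2] + 50 else 0)
    cfg <- SolverConfig(tstop = tstop)
  }
  if (is.null(window)) {
    window <- if (variable == "gGABA") c(onset, onset + 800)
              else ampaAnalysisWindow(model, synapse, otherStimuli, cfg)
  }
  step1 <- if (variable == "gGABA") 1 else 0.01
  if (is.null(cap)) cap <- if (variable == "gGABA") 200 else 20
  isAP <- function(g) {
    s <- synapse; s@gmax <- g
    sw <- runSweep(model, c(list(s), otherStimuli), cfg)
    detectAP(sw, window = window)$ap
  }
  res <- alternatingSearch(isAP, step1 = step1, cap = cap)
  res
}

#' Analysis window for AMPA threshold searches
#'
#' Simulates the AMPA input with the spike mechanism disabled and returns
#' c(onset, t63) where t63 is the time at which the somatic depolarization
#' has decayed to 63% of its peak amplitude.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param synapse the AMPA \linkS4class{Exp2Synapse}
#' @param otherStimuli ignored for the window (the depolarization is that of
#'   the AMPA input alone)
#' @param cfg solver configuration
#' @param g test conductance, nS (the passive response time course is
#'   amplitude-independent)
#' @return c(t0, t1), ms
#' @export
ampaAnalysisWindow <- function(model, synapse, otherStimuli = list(),
                               cfg = SolverConfig(tstop = 1000), g = 0.1) {
  s <- synapse; s@gmax <- g
  pcfg <- cfg; pcfg@apMechanism <- FALSE
  sw <- runSweep(model, list(s), pcfg)
  onset <- if (length(s@onsets)) min(s@onsets) else 0
  tr <- .soma_trace(sw)
  rest <- tr$v[which.min(abs(tr$t - onset))]
  dep <- tr$v - rest
  ipk <- which.max(dep)
  after <- which(tr$t > tr$t[ipk] & dep <= 0.63 * dep[ipk])
  t63 <- if (length(after)) tr$t[after[1]] else tr$t[length(tr$t)]
  c(onset, t63)
}

#' Rheobase search
#'
#' Minimal amplitude of a long somatic current step that elicits an AP, by
#' the alternating search scaled to pA (1 pA coarse step).
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param duration step duration, ms
#' @param delay step onset, ms
#' @param cap pA
#' @return a \linkS4class{ThresholdSearchResult} (gThr in pA)
#' @export
rheobaseSearch <- function(model, duration = 2000, delay = 100, cap = 100) {
  cfg <- SolverConfig(tstop = delay + duration + 100)
  isAP <- function(ipA) {
    sw <- runSweep(model, list(IClamp(ipA * 1e-3, delay = delay,
                                      dur = duration)), cfg)
    detectAP(sw, window = c(delay, delay + duration))$ap
  }
  alternatingSearch(isAP, step1 = 1, cap = cap)
}


# Shared walk-down below a threshold search: step the stimulus down from the
# threshold (growing steps while sweeps still spike anywhere in the extended
# horizon). Among genuinely subthreshold sweeps, return the plateau value of
# the peak potential if the walk converges (near-threshold sweeps saturate on
# the stable branch); if no plateau exists, the peak of the strongest
# subthreshold sweep.
.st_walkdown <- function(search, runfun, tol = 0.05, maxNoAP = 8) {
  g <- search@gThr
  step <- search@finalStep
  first <- NA_real_
  last <- NA_real_
  n_noap <- 0
  for (i in 1:60) {
    g <- g - step
    if (g <= 0) break
    r <- runfun(g)
    if (r$ap) { step <- step * 4; next }
    n_noap <- n_noap + 1
    if (is.na(first)) first <- r$peak
    if (!is.na(last) && abs(r$peak - last) < tol) return(r$peak)
    last <- r$peak
    if (n_noap >= maxNoAP) break
  }
  if (is.na(first)) stop("no subthreshold stimulus found")
  first
}

#' AP threshold from the strongest subthreshold stimulation
#'
#' Runs a rheobase search and returns the maximal somatic potential of the
#' strongest genuinely subthreshold stimulus: starting from the rheobase the
#' amplitude is walked downward (in growing multiples of the final search
#' step) until a sweep fires no AP even over an extended horizon beyond the
#' stimulus, which excludes near-threshold sweeps whose spike is merely
#' delayed past the analysis window. The peak voltage of that sweep is the
#' quasi-stationary spike threshold.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param duration stimulus duration, ms
#' @param delay onset, ms
#' @param search optional precomputed \linkS4class{ThresholdSearchResult}
#' @param horizon extra time simulated past the stimulus to catch delayed
#'   spikes, ms
#' @return list(value mV, rheobase pA, method)
#' @export
apThresholdST <- function(model, duration = 2000, delay = 100, search = NULL,
                          horizon = 2000) {
  if (is.null(search)) search <- rheobaseSearch(model, duration, delay)
  if (is.na(search@gThr)) stop("rheobase search did not converge")
  cfg <- SolverConfig(tstop = delay + duration + horizon)
  vals <- .st_walkdown(search, function(g) {
    sw <- runSweep(model, list(IClamp(g * 1e-3, delay = delay,
                                      dur = duration)), cfg)
    sel <- sw@time >= delay & sw@time <= delay + duration
    list(ap = detectAP(sw)$ap, peak = max(sw@v[1, sel]))
  })
  list(value = vals, rheobase = search@gThr, method = "ST")
}

#' Quasi-stationary threshold from a synaptic conductance search
#'
#' Same walk-down logic as \code{\link{apThresholdST}} applied to a
#' conductance-threshold search: returns the somatic peak voltage of the
#' strongest synaptic stimulus that fires no AP even over an extended
#' horizon.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param synapse template \linkS4class{Exp2Synapse} (gmax is varied)
#' @param search the \linkS4class{ThresholdSearchResult} for this synapse
#' @param otherStimuli fixed co-stimuli used during the search
#' @param horizon ms past the 800 ms GABA window
#' @return max somatic voltage, mV
#' @export
apThresholdSTSynaptic <- function(model, synapse, search,
                                  otherStimuli = list(), horizon = 2000) {
  if (is.na(search@gThr)) stop("search did not converge")
  onset <- if (length(synapse@onsets)) min(synapse@onsets) else 0
  cfg <- SolverConfig(tstop = onset + 800 + horizon)
  .st_walkdown(search, function(g) {
    s <- synapse; s@gmax <- g
    sw <- runSweep(model, c(list(s), otherStimuli), cfg)
    list(ap = detectAP(sw)$ap, peak = max(sw@v[1, sw@time >= onset]))
  })
}

#' Features of an action potential waveform
#'
#' The feature set used by the model-fitting error function: third-derivative
#' threshold, maximal rise and decay slopes, half-width, and peak voltage.
#' The half-width is measured at half amplitude between the dV/dt threshold
#' and the peak.
#'
#' @param sweep a \linkS4class{Sweep} containing an AP
#' @return named numeric: eThrD3 (mV), vRiseMax (V/s), vDecayMax (V/s),
#'   halfWidth (ms), peak (mV)
#' @export
apFeatures <- function(sweep) {
  tr <- .soma_trace(sweep)
  v <- tr$v; t <- tr$t
  ip <- .ap_peak_index(v)
  dv <- .central_dv(v, tr$dt)
  thr <- apThresholdDvdt(sweep)
  i0 <- which.min(abs(t - thr$time))
  iend <- min(ip + round(20 / tr$dt), length(v) - 1)
  half <- (thr$value + v[ip]) / 2
  above <- which(v >= half & seq_along(v) >= i0 & seq_along(v) <= iend)
  hw <- if (length(above)) (max(above) - min(above)) * tr$dt else NA_real_
  c(eThrD3 = apThresholdD3(sweep)$value,
    vRiseMax = max(dv[i0:ip], na.rm = TRUE),
    vDecayMax = min(dv[ip:iend], na.rm = TRUE),
    halfWidth = hw,
    peak = v[ip])
}

#' Weighted AP-feature error
#'
#' Weighted sum of squared feature differences (sim - ref): weight 10 on the
#' third-derivative threshold, 3 on the maximal rise slope, and 1 on the
#' maximal decay slope, half-width and peak. Zero iff all features match.
#'
#' @param sim,ref named vectors as returned by \code{\link{apFeatures}}
#' @return non-negative scalar
#' @export
apFeatureError <- function(sim, ref) {
  need <- c("eThrD3", "vRiseMax", "vDecayMax", "halfWidth", "peak")
  if (!all(need %in% names(sim)) || !all(need %in% names(ref)))
    stop("both feature sets must contain: ", paste(need, collapse = ", "))
  d <- sim[need] - ref[need]
  if (any(!is.finite(d))) stop("missing feature value")
  unname(10 * d["eThrD3"]^2 + 3 * d["vRiseMax"]^2 + d["vDecayMax"]^2 +
         d["halfWidth"]^2 + d["peak"]^2)
}
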