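.section_row <- function(name, kind, L, diam, nseg, parent = "",
                         parentPos = 1, naScale = 0, kScale = 0) {
  data.frame(name = name, kind = kind, L = L, diam = diam, nseg = nseg,
              parent = parent, parentPos = parentPos, naScale = naScale,
              kScale = kScale, stringsAsFactors = FALSE)
}

#' Ball model morphology
#'
#' A single isopotential spherical soma (surface pi*d^2) carrying leak and,
#' by default, the Na/K spike mechanism.
#'
#' @param somaDiam soma diameter, um
#' @param ra axial resistivity, Ohm cm (irrelevant for one compartment)
#' @param cm specific capacitance, uF/cm^2
#' @return a \linkS4class{Morphology}
#' @export
ballMorphology <- function(somaDiam = 46.6, ra = 200, cm = 1.45) {
  new("Morphology",
      sections = .section_row("soma", "sphere", NA_real_, somaDiam, 1,
                              naScale = 1, kScale = 1),
      ra = ra, cm = cm)
}

#' Ball-and-stick morphology
#'
#' Spherical soma with the spike mechanism plus a passive linear dendrite
#' (default 1 mm long, 1 um diameter, 301 segments). Twenty equidistant
#' candidate synapse positions along the dendrite are exposed by
#' \code{\link{dendritePositions}}.
#'
#' @param somaDiam um
#' @param dendL dendrite length, um
#' @param dendDiam dendrite diameter, um
#' @param nseg dendrite segment count
#' @param ra Ohm cm
#' @param cm uF/cm^2
#' @return a \linkS4class{Morphology}
#' @export
ballAndStickMorphology <- function(somaDiam = 46.6, dendL = 1000,
                                   dendDiam = 1, nseg = 301, ra = 200,
                                   cm = 1.45) {
  new("Morphology",
      sections = rbind(
        .section_row("soma", "sphere", NA_real_, somaDiam, 1,
                     naScale = 1, kScale = 1),
        .section_row("dend", "cyl", dendL, dendDiam, nseg, parent = "soma")),
      ra = ra, cm = cm)
}

#' Ball-stick-axon morphology
#'
#' Ball-and-stick plus an axon: an initial segment (10 um x 0.2 um) with full
#' spike-mechanism density and a distal axon of 10 further 10 um sections in
#' which the Na+ and K+ peak conductances are reduced by 10%. The soma and
#' dendrite are passive; GABAergic input in this configuration targets the
#' axon initial segment.
#'
#' @param somaDiam,dendL,dendDiam,nseg,ra,cm as in
#'   \code{\link{ballAndStickMorphology}}
#' @param aisL,axonDiam initial-segment length and axon diameter, um
#' @param nAxon number of distal axon sections
#' @param distalScale conductance scale of the distal axon
#' @return a \linkS4class{Morphology}
#' @export
ballStickAxonMorphology <- function(somaDiam = 46.6, dendL = 1000,
                                    dendDiam = 1, nseg = 301,
                                    aisL = 10, axonDiam = 0.2, nAxon = 10,
                                    distalScale = 0.9, ra = 200, cm = 1.45) {
  secs <- rbind(
    .section_row("soma", "sphere", NA_real_, somaDiam, 1),
    .section_row("dend", "cyl", dendL, dendDiam, nseg, parent = "soma"),
    .section_row("ais", "cyl", aisL, axonDiam, 1, parent = "soma",
                 naScale = 1, kScale = 1))
  prev <- "ais"
  for (i in seq_len(nAxon)) {
    secs <- rbind(secs, .section_row(paste0("axon", i), "cyl", 10, axonDiam,
                                     1, parent = prev,
                                     naScale = distalScale,
                                     kScale = distalScale))
    prev <- paste0("axon", i)
  }
  new("Morphology", sections = secs, ra = ra, cm = cm)
}

#' Equidistant candidate synapse positions along a dendrite
#'
#' @param n number of positions (default 20)
#' @return normalized positions (1/n, 2/n, ..., 1)
#' @export
dendritePositions <- function(n = 20) seq_len(n) / n

#' Discretize a morphology into a compartmental model
#'
#' Spherical sections become single isopotential compartments of area
#' pi*d^2; cylinders are split into nseg equal segments of area pi*d*L/nseg
#' with half-segment axial resistances on either side. Compartments are
#' ordered parent-before-child so the cable system is solvable by one
#' tree-structured (Hines) elimination.
#'
#' @param morph a \linkS4class{Morphology}
#' @param channels list(leak, na, k) as from \code{\link{defaultChannelSet}}
#' @return a \linkS4class{CompartmentalModel}
#' @export
buildModel <- function(morph, channels = defaultChannelSet()) {
  s <- morph@sections
  leak <- channels$leak; na <- channels$na; k <- channels$k
  comp <- NULL
  secfirst <- integer(nrow(s))   # first compartment index of each section
  seclast <- integer(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (s$kind[i] == "sphere") {
      area <- pi * s$diam[i]^2 * 1e-8           # um^2 -> cm^2
      rows <- data.frame(section = s$name[i], pos = 0.5, area = area,
                         rhalf = 0,             # isopotential: no axial term
                         naScale = s$naScale[i], kScale = s$kScale[i])
    } else {
      nseg <- s$nseg[i]
      l <- s$L[i] / nseg                        # um
      area <- pi * s$diam[i] * l * 1e-8
      # half-segment axial resistance, MOhm -> use uS couplings later
      rhalf <- morph@ra * (l / 2 * 1e-4) / (pi * (s$diam[i] / 2 * 1e-4)^2)
      rows <- data.frame(section = s$name[i],
                         pos = (seq_len(nseg) - 0.5) / nseg,
                         area = area, rhalf = rhalf,
                         naScale = s$naScale[i], kScale = s$kScale[i])
    }
    secfirst[i] <- if (is.null(comp)) 1 else nrow(comp) + 1
    comp <- rbind(comp, rows)
    seclast[i] <- nrow(comp)
  }
  n <- nrow(comp)
  parent <- rep(NA_integer_, n)
  gax <- numeric(n)
  pathlen <- numeric(n)
  for (i in seq_len(nrow(s))) {
    idx <- secfirst[i]:seclast[i]
    if (length(idx) > 1) {
      for (j in idx[-1]) {
        parent[j] <- j - 1
        r <- comp$rhalf[j] + comp$rhalf[j - 1]   # Ohm
        gax[j] <- 1e6 / r                        # uS
        pathlen[j] <- NA
      }
    }
    if (s$parent[i] != "") {
      pi_ <- match(s$parent[i], s$name)
      # attach to the parent segment containing parentPos
      pidx <- secfirst[pi_]:seclast[pi_]
      att <- pidx[pmin(length(pidx),
                        pmax(1, ceiling(s$parentPos[i] * length(pidx))))]
      parent[secfirst[i]] <- att
      r <- comp$rhalf[secfirst[i]] + comp$rhalf[att]
      gax[secfirst[i]] <- 1e6 / max(r, 1e-9)
    }
  }
  # path length from the root, segment-center to segment-center
  pathlen <- numeric(n)
  for (j in seq_len(n)) {
    if (is.na(parent[j])) { pathlen[j] <- 0; next }
    si <- match(comp$section[j], s$name)
    l <- if (s$kind[si] == "cyl") s$L[si] / s$nseg[si] else 0
    pl <- parent[j]
    half_par <- if (comp$section[pl] == comp$section[j]) {
      spi <- match(comp$section[pl], s$name)
      s$L[spi] / s$nseg[spi] / 2
    } else 0
    pathlen[j] <- pathlen[pl] + half_par + l / 2
  }
  cmvec <- morph@cm * comp$area * 1e3            # uF/cm^2 * cm^2 -> nF
  out <- data.frame(section = comp$section, pos = comp$pos, area = comp$area,
                    parent = parent, gax = gax, cm = cmvec,
                    gpas = leak@gpas * comp$area * 1e6,
                    gna = na@gmax * comp$naScale * comp$area * 1e6,
                    gk = k@gmax * comp$kScale * comp$area * 1e6,
                    pathlen = pathlen, stringsAsFactors = FALSE)
  new("CompartmentalModel", morph = morph, leak = leak, na = na, k = k,
      comp = out)
}

#' Map a (section, position) site to its compartment index
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param section section name
#' @param pos normalized position in [0, 1]
#' @return 1-based compartment index
#' @export
siteIndex <- function(model, section, pos = 0.5) {
  idx <- which(model@comp$section == section)
  if (!length(idx)) stop("unknown section: ", section)
  idx[which.min(abs(model@comp$pos[idx] - pos))]
}

#' Construct a solver configuration
#' @param dt time step, ms
#' @param tstop total simulated time, ms
#' @param record list of recording sites, each c(section, pos); default soma
#' @param apMechanism enable the Na/K spike mechanism
#' @return a \linkS4class{SolverConfig}
#' @export
SolverConfig <- function(dt = 0.025, tstop = 1000, record = list(),
                         apMechanism = TRUE) {
  new("SolverConfig", dt = dt, tstop = tstop, record = record,
      apMechanism = apMechanism)
}

#' Construct a double-exponential synapse
#' @param section,pos site
#' @param tau1,tau2 ms; \code{gabaSynapse} and \code{ampaSynapse} provide the
#'   receptor-specific kinetics
#' @param erev mV
#' @param gmax peak conductance, nS
#' @param onsets event times, ms
#' @return an \linkS4class{Exp2Synapse}
#' @export
Exp2Synapse <- function(section = "soma", pos = 0.5, tau1 = 0.1, tau2 = 11,
                        erev = 0, gmax = 1, onsets = numeric(0)) {
  new("Exp2Synapse", section = section, pos = pos, tau1 = tau1, tau2 = tau2,
      erev = erev, gmax = gmax, onsets = onsets)
}

#' GABA-A synapse with the experimentally constrained kinetics
#' @param egaba reversal potential, mV (the free parameter of the analyses)
#' @param gmax peak conductance, nS
#' @param section,pos,onsets as in \code{\link{Exp2Synapse}}
#' @export
gabaSynapse <- function(egaba, gmax = 1, section = "soma", pos = 0.5,
                        onsets = numeric(0)) {
  Exp2Synapse(section, pos, tau1 = 0.1, tau2 = 37, erev = egaba, gmax = gmax,
              onsets = onsets)
}

#' AMPA synapse with the experimentally constrained kinetics
#' @param gmax peak conductance, nS
#' @param section,pos,onsets as in \code{\link{Exp2Synapse}}
#' @param erev reversal potential, mV (junction-potential-corrected value)
#' @export
ampaSynapse <- function(gmax = 1, section = "soma", pos = 0.5,
                        onsets = numeric(0), erev = -12) {
  Exp2Synapse(section, pos, tau1 = 0.1, tau2 = 11, erev = erev, gmax = gmax,
              onsets = onsets)
}

#' Tonic GABAergic conductance stimulus
#' @param density S/cm^2 (note: the physiological reference value is
#'   8.75e-9 S/cm^2, i.e. 8.75 nS/cm^2)
#' @param egaba mV
#' @export
TonicGaba <- function(density, egaba) {
  new("TonicGaba", density = density, egaba = egaba)
}

#' Current-step stimulus
#' @param amp nA
#' @param delay,dur ms
#' @param section,pos site
#' @export
IClamp <- function(amp, delay = 100, dur = 800, section = "soma", pos = 0.5) {
  new("IClamp", section = section, pos = pos, delay = delay, dur = dur,
      amp = amp)
}

#' Run one sweep of the compartmental model
#'
#' Integrates the coupled membrane/cable equations with an implicit
#' (backward Euler) voltage step and exponential-Euler channel updates.
#' Identical inputs give bit-identical sweeps. A sweep whose voltage leaves
#' +-500 mV is aborted and flagged as diverged.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param stimuli list of \linkS4class{Exp2Synapse}, \linkS4class{TonicGaba},
#'   \linkS4class{IClamp}, \linkS4class{PlaybackCurrent}
#' @param cfg a \linkS4class{SolverConfig}
#' @param recordSynCurrent indices (into the synapse stimuli, in order) whose
#'   current to record
#' @return a \linkS4class{Sweep}
#' @export
runSweep <- function(model, stimuli = list(), cfg = SolverConfig(),
                     recordSynCurrent = integer(0)) {
  comp <- model@comp
  n <- nrow(comp)
  syn <- Filter(function(x) is(x, "Exp2Synapse"), stimuli)
  ton <- Filter(function(x) is(x, "TonicGaba"), stimuli)
  icl <- Filter(function(x) is(x, "IClamp"), stimuli)
  ply <- Filter(function(x) is(x, "PlaybackCurrent"), stimuli)

  syn_comp <- vapply(syn, function(s) siteIndex(model, s@section, s@pos), 1L)
  ev <- do.call(rbind, lapply(seq_along(syn), function(i) {
    if (length(syn[[i]]@onsets))
      cbind(time = syn[[i]]@onsets, syn = i - 1L) else NULL
  }))
  if (is.null(ev)) ev <- matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("time", "syn")))
  ev <- ev[order(ev[, "time"]), , drop = FALSE]

  gton <- numeric(n); eton <- 0
  if (length(ton)) {
    if (length(ton) > 1) stop("at most one tonic conductance per sweep")
    gton <- ton[[1]]@density * comp$area * 1e6   # S/cm^2 * cm^2 -> uS
    eton <- ton[[1]]@egaba
  }

  play_comp <- integer(0)
  nt <- round(cfg@tstop / cfg@dt) + 1
  play_wave <- matrix(numeric(0), nrow = nt, ncol = 0)
  if (length(ply)) {
    for (p in ply) {
      if (abs(p@dt - cfg@dt) > 1e-12)
        stop("playback waveform dt does not match the solver dt")
      w <- p@wave
      if (length(w) < nt) w <- c(w, rep(w[length(w)], nt - length(w)))
      play_wave <- cbind(play_wave, w[seq_len(nt)])
      play_comp <- c(play_comp, siteIndex(model, p@section, p@pos))
    }
  }

  recsites <- cfg@record
  if (!length(recsites)) recsites <- list(c("soma", "0.5"))
  rec <- vapply(recsites, function(r)
    siteIndex(model, r[[1]], as.numeric(r[[2]])), 1L)

  res <- core_simulate(
    parent = as.integer(ifelse(is.na(comp$parent), -1L, comp$parent - 1L)),
    gax = comp$gax, cm = comp$cm, gpas = comp$gpas, epas = model@leak@epas,
    gna = comp$gna, gk = comp$gk,
    napar = .chan_as_list(model@na), kpar = .chan_as_list(model@k),
    ena = model@na@erev, ek = model@k@erev, active = cfg@apMechanism,
    syn_comp = as.integer(syn_comp - 1L),
    syn_tau1 = vapply(syn, slot, 1, "tau1"),
    syn_tau2 = vapply(syn, slot, 1, "tau2"),
    syn_erev = vapply(syn, slot, 1, "erev"),
    syn_gmax = vapply(syn, slot, 1, "gmax") * 1e-3,   # nS -> uS
    ev_time = as.numeric(ev[, "time"]), ev_syn = as.integer(ev[, "syn"]),
    gton = gton, eton = eton,
    ic_comp = as.integer(vapply(icl, function(s)
      siteIndex(model, s@section, s@pos), 1L) - 1L),
    ic_del = vapply(icl, slot, 1, "delay"),
    ic_dur = vapply(icl, slot, 1, "dur"),
    ic_amp = vapply(icl, slot, 1, "amp"),
    play_comp = as.integer(play_comp - 1L), play_wave = play_wave,
    dt = cfg@dt, tstop = cfg@tstop, vinit = model@leak@epas,
    rec = as.integer(rec - 1L),
    rec_syn = as.integer(recordSynCurrent - 1L),
    vcap = 500)

  nt_eff <- res$laststep + 1
  tm <- seq(0, by = cfg@dt, length.out = nt)
  v <- res$v
  if (res$diverged) { v <- v[, seq_len(nt_eff), drop = FALSE]
                      tm <- tm[seq_len(nt_eff)] }
  labs <- vapply(recsites, function(r) paste0(r[[1]], "@", r[[2]]), "")
  new("Sweep", time = tm, v = v,
      isyn = if (res$diverged) res$isyn[, seq_len(nt_eff), drop = FALSE]
             else res$isyn,
      dt = cfg@dt, sites = labs, diverged = res$diverged)
}

#' Somatic input resistance from a small hyperpolarizing step
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param amp test current, nA
#' @param dur step duration, ms (long enough to reach steady state)
#' @return input resistance, GOhm
#' @export
inputResistance <- function(model, amp = -0.001, dur = 2000) {
  cfg <- SolverConfig(tstop = dur + 200, apMechanism = FALSE)
  sw <- runSweep(model, list(IClamp(amp, delay = 100, dur = dur)), cfg)
  i0 <- which.min(abs(sw@time - 99))
  i1 <- which.min(abs(sw@time - (100 + dur - 1)))
  dv <- sw@v[1, i1] - sw@v[1, i0]               # mV
  dv / amp * 1e-3                               # mV/nA = MOhm -> GOhm
}

#' Calibrate the passive density to a target input resistance
#'
#' Scales gpas (within +-20%) so the model's somatic input resistance matches
#' a target; returns the adjusted channel set.
#'
#' @param morph a \linkS4class{Morphology}
#' @param channels list(leak, na, k)
#' @param targetGOhm target input resistance
#' @return channels with an adjusted leak
#' @export
calibrateInputResistance <- function(morph, channels = defaultChannelSet(),
                                     targetGOhm = 1.045) {
  f <- function(scale) {
    ch <- channels
    ch$leak <- LeakParams(gpas = channels$leak@gpas * scale,
                          epas = channels$leak@epas)
    inputResistance(buildModel(morph, ch)) - targetGOhm
  }
  flo <- f(0.8); fhi <- f(1.2)
  if (sign(flo) == sign(fhi)) {
    sc <- if (abs(flo) < abs(fhi)) 0.8 else 1.2
    warning("target input resistance not reachable within +-20% of gpas; ",
            "returning the nearest bound")
  } else {
    sc <- stats::uniroot(f, c(0.8, 1.2), tol = 1e-4)$root
  }
  channels$leak <- LeakParams(gpas = channels$leak@gpas * sc,
                              epas = channels$leak@epas)
  channels
}
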