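#' Specification for a synthetic branched morphology
#'
#' @param nDendrites number of primary dendrites
#' @param segRange integer range of per-dendrite segment counts
#' @param segLength um per segment
#' @param branchDepth maximum chained sections per dendrite
#' @param somaDiam soma diameter, um
#' @param diam dendrite diameter, um
#' @param seed RNG seed
#' @return a \linkS4class{SyntheticMorphologySpec}
#' @export
SyntheticMorphologySpec <- function(nDendrites = 56, segRange = c(2, 193),
                                    segLength = 7, branchDepth = 2,
                                    somaDiam = 15, diam = 1, seed = 1) {
  new("SyntheticMorphologySpec", nDendrites = nDendrites,
      segRange = segRange, segLength = segLength, branchDepth = branchDepth,
      somaDiam = somaDiam, diam = diam, seed = seed)
}

#' Generate a synthetic branched morphology
#'
#' A seeded stand-in for a reconstructed pyramidal-cell dendritic tree: an
#' active soma plus \code{nDendrites} passive dendrites. Per-dendrite segment
#' counts are drawn log-uniformly over \code{segRange} (reconstructed trees
#' have many short and few long dendrites); a dendrite may be split into up
#' to \code{branchDepth} chained sections attached end-to-end. The same seed
#' reproduces the identical morphology.
#'
#' @param spec a \linkS4class{SyntheticMorphologySpec}
#' @return a \linkS4class{Morphology}
#' @export
generateSyntheticMorphology <- function(spec = SyntheticMorphologySpec()) {
  stopifnot(is(spec, "SyntheticMorphologySpec"))
  secs <- .section_row("soma", "sphere", NA_real_, spec@somaDiam, 1,
                       naScale = 1, kScale = 1)
  if (spec@nDendrites > 0) {
    withr_seed <- .with_seed(spec@seed, {
      nseg <- round(exp(stats::runif(spec@nDendrites,
                                     log(spec@segRange[1]),
                                     log(spec@segRange[2]))))
      nsec <- sample(seq_len(max(1, spec@branchDepth)), spec@nDendrites,
                     replace = TRUE)
      list(nseg = nseg, nsec = nsec)
    })
    nseg <- withr_seed$nseg; nsec <- withr_seed$nsec
    for (i in seq_len(spec@nDendrites)) {
      parts <- .split_int(nseg[i], nsec[i])
      parent <- "soma"
      for (j in seq_along(parts)) {
        nm <- if (length(parts) == 1) sprintf("dend%d", i)
              else sprintf("dend%d_%d", i, j)
        secs <- rbind(secs, .section_row(nm, "cyl",
                                         parts[j] * spec@segLength,
                                         spec@diam, parts[j],
                                         parent = parent))
        parent <- nm
      }
    }
  }
  new("Morphology", sections = secs, ra = 200, cm = 1.45)
}

.split_int <- function(n, k) {
  k <- max(1, min(k, n))
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  base
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

.dendrite_table <- function(model) {
  comp <- model@comp
  dend <- comp[comp$section != "soma", , drop = FALSE]
  if (!nrow(dend)) stop("morphology has no dendritic compartments")
  dend
}

#' Draw a random stimulation pattern
#'
#' Synapse sites are drawn uniformly per unit dendritic length within the
#' allowed region (all dendrites, or the proximal/distal half by path
#' distance relative to the length-weighted median); onset times are uniform
#' over the stimulation window. Identical seeds give identical patterns.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param nAmpa,nGaba synapse counts (frequency mapping over a 2 s window:
#'   2 synapses per Hz/0.5, i.e. 2, 10, 20, 40 for 1, 5, 10, 20 Hz)
#' @param window stimulation window, ms
#' @param seed RNG seed
#' @param ampaPlacement,gabaPlacement "global", "proximal" or "distal"
#' @return a \linkS4class{StimulationPattern}
#' @export
drawPattern <- function(model, nAmpa, nGaba = 0, window = 2000, seed = 1,
                        ampaPlacement = c("global", "proximal", "distal"),
                        gabaPlacement = c("global", "proximal", "distal")) {
  ampaPlacement <- match.arg(ampaPlacement)
  gabaPlacement <- match.arg(gabaPlacement)
  dend <- .dendrite_table(model)
  # per-compartment length weight (area / diam ~ length); use pathlen median
  med <- stats::median(rep(dend$pathlen, times = pmax(1L, round(dend$area /
           min(dend$area)))))
  pick <- function(n, placement) {
    if (n == 0) return(integer(0))
    keep <- switch(placement,
                   global = rep(TRUE, nrow(dend)),
                   proximal = dend$pathlen <= med,
                   distal = dend$pathlen > med)
    if (!any(keep)) stop("empty placement region: ", placement)
    idx <- which(keep)
    sample(idx, n, replace = TRUE, prob = dend$area[idx])
  }
  .with_seed(seed, {
    ia <- pick(nAmpa, ampaPlacement)
    ig <- pick(nGaba, gabaPlacement)
    sites <- rbind(
      if (nAmpa > 0) data.frame(receptor = "ampa",
                                section = dend$section[ia],
                                pos = dend$pos[ia],
                                onset = stats::runif(nAmpa, 0, window)),
      if (nGaba > 0) data.frame(receptor = "gaba",
                                section = dend$section[ig],
                                pos = dend$pos[ig],
                                onset = stats::runif(nGaba, 0, window)))
    if (is.null(sites))
      sites <- data.frame(receptor = character(0), section = character(0),
                          pos = numeric(0), onset = numeric(0))
    new("StimulationPattern", sites = sites, window = window, seed = seed)
  })
}

.pattern_stimuli <- function(pattern, gAmpa, gGaba, egaba) {
  sites <- pattern@sites
  out <- list()
  for (i in seq_len(nrow(sites))) {
    out[[i]] <- if (sites$receptor[i] == "ampa") {
      ampaSynapse(gmax = gAmpa, section = sites$section[i],
                  pos = sites$pos[i], onsets = sites$onset[i])
    } else {
      gabaSynapse(egaba, gmax = gGaba, section = sites$section[i],
                  pos = sites$pos[i], onsets = sites$onset[i])
    }
  }
  out
}

#' Estimate the spike probability under random synaptic bombardment
#'
#' Runs \code{nSweeps} sweeps, each with a freshly drawn pattern (seeds
#' \code{seed + sweep index}), and returns the fraction with at least one
#' somatic AP. Reusing the same \code{seed} across grid points implements
#' common random numbers: every grid point sees the identical sequence of
#' synapse placements and stimulus times.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param nAmpa,nGaba synapse counts per sweep
#' @param gAmpa,gGaba peak conductances, nS
#' @param egaba E_GABA, mV (needed when nGaba > 0 or tonicDensity > 0)
#' @param nSweeps sweeps (reference protocol: 999)
#' @param seed base seed
#' @param window stimulation window, ms
#' @param tonicDensity optional tonic GABA density, S/cm^2
#' @param ampaPlacement,gabaPlacement placement regions
#' @return list(pap, se, nSweeps, apSweeps = logical raster)
#' @export
estimatePAP <- function(model, nAmpa, gAmpa, nGaba = 0, gGaba = 0.789,
                        egaba = -50.5, nSweeps = 999, seed = 1,
                        window = 2000, tonicDensity = 0,
                        ampaPlacement = "global", gabaPlacement = "global") {
  stopifnot(nSweeps >= 1)
  cfg <- SolverConfig(tstop = window + 200)
  aps <- vapply(seq_len(nSweeps), function(s) {
    pat <- drawPattern(model, nAmpa, nGaba, window = window,
                       seed = seed + s,
                       ampaPlacement = ampaPlacement,
                       gabaPlacement = gabaPlacement)
    stim <- .pattern_stimuli(pat, gAmpa, gGaba, egaba)
    if (tonicDensity > 0)
      stim <- c(stim, list(TonicGaba(tonicDensity, egaba)))
    sw <- runSweep(model, stim, cfg)
    detectAP(sw, window = c(0, window + 200))$ap
  }, TRUE)
  p <- mean(aps)
  list(pap = p, se = sqrt(p * (1 - p) / nSweeps), nSweeps = nSweeps,
       apSweeps = aps)
}

#' Spike-probability curve over an AMPA conductance grid
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param gGrid AMPA conductances, nS
#' @param nAmpa synapses per sweep
#' @param ... passed to \code{\link{estimatePAP}}
#' @return a \linkS4class{PAPCurve}
#' @export
papCurveAmpa <- function(model, gGrid, nAmpa, ...) {
  res <- lapply(gGrid, function(g) estimatePAP(model, nAmpa, g, ...))
  new("PAPCurve", grid = gGrid, pap = vapply(res, `[[`, 1.0, "pap"),
      nSweeps = vapply(res, `[[`, 1.0, "nSweeps"),
      se = vapply(res, `[[`, 1.0, "se"),
      meta = list(variable = "gAmpa", nAmpa = nAmpa))
}

#' AMPA conductance giving 50% spike probability
#'
#' Linear interpolation between the two grid points whose spike
#' probabilities bracket 0.5 most closely.
#'
#' @param curve a \linkS4class{PAPCurve} over g_AMPA
#' @return list(gAmpa50 nS, pap50)
#' @export
gAmpa50 <- function(curve) {
  p <- curve@pap; g <- curve@grid
  if (any(p == 0.5)) {
    i <- which(p == 0.5)[1]
    return(list(gAmpa50 = g[i], pap50 = 0.5))
  }
  br <- which(p[-length(p)] < 0.5 & p[-1] >= 0.5)
  if (!length(br)) stop("spike-probability curve does not bracket 0.5")
  i <- br[1]
  g50 <- g[i] + (0.5 - p[i]) * (g[i + 1] - g[i]) / (p[i + 1] - p[i])
  list(gAmpa50 = g50, pap50 = 0.5)
}

#' Threshold E_GABA from spike-probability curves
#'
#' Runs the p_AP(E_GABA) curve with GABA co-stimulation at the AMPA drive
#' \code{gAmpa} (normally the 50%-probability conductance of the same
#' stimulation pattern without GABA) and returns the E_GABA at which the
#' curve crosses the no-GABA reference probability. Baseline and curve share
#' the same per-sweep seeds (common random numbers).
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param egrid E_GABA grid, mV
#' @param nAmpa,nGaba synapse counts per sweep
#' @param gAmpa AMPA conductance, nS
#' @param gGaba GABA conductance, nS
#' @param nSweeps sweeps per grid point
#' @param seed base seed
#' @param papRef reference probability; if NULL it is recomputed from the
#'   same seeds without GABA
#' @param tonicDensity if > 0, tonic GABA of this density replaces the
#'   phasic GABA synapses
#' @param ... further arguments to \code{\link{estimatePAP}}
#' @return list(estimate = EGabaThrEstimate, curve = PAPCurve, papRef)
#' @export
egabaThrFromPAP <- function(model, egrid, nAmpa, gAmpa, nGaba = nAmpa,
                            gGaba = 0.789, nSweeps = 999, seed = 1,
                            papRef = NULL, tonicDensity = 0, ...) {
  if (is.null(papRef))
    papRef <- estimatePAP(model, nAmpa, gAmpa, nGaba = 0, nSweeps = nSweeps,
                          seed = seed, ...)$pap
  res <- lapply(egrid, function(e)
    estimatePAP(model, nAmpa, gAmpa,
                nGaba = if (tonicDensity > 0) 0 else nGaba,
                gGaba = gGaba, egaba = e, nSweeps = nSweeps, seed = seed,
                tonicDensity = tonicDensity, ...))
  p <- vapply(res, `[[`, 1.0, "pap")
  curve <- new("PAPCurve", grid = egrid, pap = p,
               nSweeps = rep(nSweeps, length(egrid)),
               se = vapply(res, `[[`, 1.0, "se"),
               meta = list(variable = "egaba", papRef = papRef))
  br <- which(p[-length(p)] < papRef & p[-1] >= papRef)
  est <- if (!length(br)) {
    new("EGabaThrEstimate", value = NA_real_, method = "out-of-range",
        diagnostics = list(pap = p, papRef = papRef))
  } else {
    i <- br[1]
    x <- egrid[i] + (papRef - p[i]) * (egrid[i + 1] - egrid[i]) /
      (p[i + 1] - p[i])
    new("EGabaThrEstimate", value = x, method = "pap",
        diagnostics = list(bracket = egrid[c(i, i + 1)],
                           pap = p[c(i, i + 1)], papRef = papRef))
  }
  list(estimate = est, curve = curve, papRef = papRef)
}
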