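#' @import methods
NULL

#' Passive leak parameters
#'
#' Uniform passive conductance density and its reversal potential. With no
#' other input the membrane rests exactly at \code{epas}.
#'
#' @slot gpas conductance density, S/cm^2
#' @slot epas reversal potential, mV
#' @export
setClass("LeakParams", representation(gpas = "numeric", epas = "numeric"),
         prototype(gpas = 1.28e-5, epas = -50.5),
         validity = function(object) {
           if (length(object@gpas) != 1 || object@gpas <= 0)
             return("gpas must be a single positive value")
           if (length(object@epas) != 1 || !is.finite(object@epas))
             return("epas must be a single finite voltage")
           TRUE
         })

.chan_validity <- function(object) {
  tt <- c(object@tauAct, object@tauIna, object@tauRelax)
  if (any(!is.finite(tt)) || any(tt <= 0))
    return("all time constants must be positive")
  if (object@kco == 0 || object@kic == 0)
    return("slope factors kco/kic must be non-zero")
  if (object@gmax < 0) return("gmax must be >= 0")
  TRUE
}

#' Cooperative three-state sodium channel parameters
#'
#' Parameters of the modified Naundorf Na+ scheme: closed/open/inactivated
#' states with sigmoidal (Boltzmann) transition rates, a voltage-independent
#' relaxation with time constant \code{tauRelax}, and a cooperativity factor
#' \code{cf} that shifts the voltage sensed by the activation rates by
#' \code{cf * O_Na}, producing the sharp spike onset of real neurons.
#'
#' @slot gmax peak conductance density, S/cm^2
#' @slot erev reversal potential, mV
#' @slot Gco,Goc,Gic,Gci dimensionless rate gains (closed->open, open->closed,
#'   and the inactivation pair)
#' @slot Vco,Vic half-activation voltages, mV
#' @slot kco,kic slope factors, mV
#' @slot tauAct,tauIna,tauRelax rate time constants, ms
#' @slot cf cooperativity factor, mV per unit open fraction
#' @slot q10 fixed multiplicative temperature factor
#' @export
setClass("NaChannelParams",
         representation(gmax = "numeric", erev = "numeric",
                        Gco = "numeric", Goc = "numeric",
                        Gic = "numeric", Gci = "numeric",
                        Vco = "numeric", Vic = "numeric",
                        kco = "numeric", kic = "numeric",
                        tauAct = "numeric", tauIna = "numeric",
                        tauRelax = "numeric", cf = "numeric", q10 = "numeric"),
         validity = .chan_validity)

#' Two-state delayed-rectifier potassium channel parameters
#'
#' Open/closed scheme with Boltzmann rates (activation half-voltage
#' \code{Vco}, deactivation half-voltage \code{Vic}), voltage-independent
#' relaxation \code{tauRelax} and an optional cooperativity factor.
#'
#' @slot gmax peak conductance density, S/cm^2
#' @slot erev reversal potential, mV
#' @slot Gco,Goc rate gains
#' @slot Vco,Vic half voltages, mV
#' @slot kco,kic slope factors, mV
#' @slot tauAct,tauIna,tauRelax time constants, ms
#' @slot cf cooperativity factor, mV per unit open fraction
#' @slot q10 fixed multiplicative temperature factor
#' @export
setClass("KChannelParams",
         representation(gmax = "numeric", erev = "numeric",
                        Gco = "numeric", Goc = "numeric",
                        Vco = "numeric", Vic = "numeric",
                        kco = "numeric", kic = "numeric",
                        tauAct = "numeric", tauIna = "numeric",
                        tauRelax = "numeric", cf = "numeric", q10 = "numeric"),
         validity = .chan_validity)

#' Neuronal morphology as a tree of sections
#'
#' Sections are either an isopotential spherical soma (surface pi*d^2) or
#' cylinders subdivided into \code{nseg} segments. Connectivity must form a
#' tree rooted at the soma. Mechanism densities are per-section scale factors
#' applied to the channel-set densities.
#'
#' @slot sections data.frame with columns name, kind ("sphere"|"cyl"), L (um),
#'   diam (um), nseg, parent (name, "" for root), parentPos (0-1),
#'   naScale, kScale (density scale factors)
#' @slot ra axial resistivity, Ohm cm
#' @slot cm specific capacitance, uF/cm^2
#' @export
setClass("Morphology",
         representation(sections = "data.frame", ra = "numeric", cm = "numeric"),
         validity = function(object) {
           s <- object@sections
           need <- c("name", "kind", "L", "diam", "nseg", "parent",
                     "parentPos", "naScale", "kScale")
           if (!all(need %in% names(s))) return("sections is missing columns")
           if (anyDuplicated(s$name)) return("section names must be unique")
           if (sum(s$parent == "") != 1) return("exactly one root section")
           if (any(s$diam <= 0)) return("diameters must be positive")
           if (any(s$nseg < 1)) return("nseg must be >= 1")
           if (any(s$parent != "" & !(s$parent %in% s$name)))
             return("unknown parent section")
           # tree check: walking parents must terminate at the root
           idx <- match(s$parent, s$name)
           for (i in seq_len(nrow(s))) {
             seen <- integer(0); j <- i
             while (!is.na(idx[j])) {
               if (j %in% seen) return("connectivity contains a cycle")
               seen <- c(seen, j); j <- idx[j]
             }
           }
           if (object@ra <= 0) return("axial resistivity must be positive")
           if (object@cm <= 0) return("specific capacitance must be positive")
           TRUE
         })

#' Discretized compartmental model
#'
#' Result of discretizing a \linkS4class{Morphology} with a channel set:
#' per-compartment areas, tree-structured axial couplings and mechanism
#' conductances, ready for the implicit cable integrator.
#'
#' @slot morph the source morphology
#' @slot leak,na,k the channel parameter objects
#' @slot comp data.frame: section, pos (0-1 within section), area (cm^2),
#'   parent (1-based compartment index, NA for root), gax (uS), cm (nF),
#'   gpas (uS), gna (uS), gk (uS), pathlen (um from soma)
#' @export
setClass("CompartmentalModel",
         representation(morph = "Morphology", leak = "LeakParams",
                        na = "NaChannelParams", k = "KChannelParams",
                        comp = "data.frame"),
         validity = function(object) {
           if (any(object@comp$area <= 0)) return("areas must be positive")
           TRUE
         })

#' Solver configuration
#'
#' @slot dt time step, ms (default 0.025 ms, the largest step for which the
#'   spike shape and all threshold estimators are numerically stable)
#' @slot tstop simulated time, ms
#' @slot record list of c(section, pos) recording sites
#' @slot apMechanism logical; FALSE disables the Na/K spike mechanism
#'   (used for peak-voltage and playback control sweeps)
#' @export
setClass("SolverConfig",
         representation(dt = "numeric", tstop = "numeric", record = "list",
                        apMechanism = "logical"),
         prototype(dt = 0.025, tstop = 1000, record = list(), apMechanism = TRUE),
         validity = function(object) {
           if (object@dt <= 0) return("dt must be positive")
           if (object@tstop <= object@dt) return("tstop must exceed dt")
           TRUE
         })

#' A simulated sweep
#'
#' Uniformly sampled voltage at one or more recording sites, with optional
#' synaptic/injected current traces.
#'
#' @slot time ms
#' @slot v matrix, sites x samples, mV
#' @slot isyn matrix (possibly 0-row), recorded synaptic currents, nA,
#'   depolarizing-positive
#' @slot dt ms
#' @slot sites character labels
#' @slot diverged logical
#' @export
setClass("Sweep",
         representation(time = "numeric", v = "matrix", isyn = "matrix",
                        dt = "numeric", sites = "character",
                        diverged = "logical"),
         validity = function(object) {
           if (ncol(object@v) != length(object@time))
             return("v must have one column per time sample")
           if (!object@diverged && any(!is.finite(object@v)))
             return("non-finite voltages in a non-diverged sweep")
           TRUE
         })

#' Double-exponential conductance synapse
#'
#' Peak-normalized Exp2 synapse: g(t) rises with tau1, decays with tau2, and
#' reaches exactly \code{gmax} at the peak. Multiple onsets sum linearly.
#'
#' @slot section,pos synapse site
#' @slot tau1,tau2 rise/decay time constants, ms (0 < tau1 < tau2)
#' @slot erev reversal potential, mV
#' @slot gmax peak conductance, nS
#' @slot onsets event times, ms
#' @export
setClass("Exp2Synapse",
         representation(section = "character", pos = "numeric",
                        tau1 = "numeric", tau2 = "numeric", erev = "numeric",
                        gmax = "numeric", onsets = "numeric"),
         validity = function(object) {
           if (!(object@tau1 > 0 && object@tau1 < object@tau2))
             return("need 0 < tau1 < tau2")
           if (object@gmax < 0) return("gmax must be >= 0")
           if (object@pos < 0 || object@pos > 1) return("pos must be in [0,1]")
           TRUE
         })

#' Tonic GABAergic conductance
#'
#' A spatially uniform, permanently open conductance density over all
#' membrane, reversing at \code{egaba}.
#'
#' @slot density conductance density, S/cm^2
#' @slot egaba reversal potential, mV
#' @export
setClass("TonicGaba",
         representation(density = "numeric", egaba = "numeric"),
         validity = function(object) {
           if (object@density < 0) return("density must be >= 0")
           TRUE
         })

#' Injected current step
#' @slot section,pos injection site
#' @slot delay,dur ms
#' @slot amp nA
#' @export
setClass("IClamp",
         representation(section = "character", pos = "numeric",
                        delay = "numeric", dur = "numeric", amp = "numeric"))

#' Played-back current waveform
#'
#' A current waveform sampled at the solver dt, injected at a site; used to
#' replay recorded synaptic currents and so isolate the GABAergic
#' depolarization from the conductance shunt.
#'
#' @slot section,pos injection site
#' @slot wave nA per sample (sample 1 at t = 0)
#' @slot dt ms
#' @export
setClass("PlaybackCurrent",
         representation(section = "character", pos = "numeric",
                        wave = "numeric", dt = "numeric"))

#' Result of an alternating conductance/current threshold search
#'
#' @slot gThr threshold value (nS, or pA for rheobase); NA if the cap was
#'   reached without a spike ("no threshold")
#' @slot sweeps number of simulated sweeps
#' @slot history data.frame (g, ap) of every tested value
#' @slot finalStep last up-step size
#' @slot capped logical
#' @export
setClass("ThresholdSearchResult",
         representation(gThr = "numeric", sweeps = "numeric",
                        history = "data.frame", finalStep = "numeric",
                        capped = "logical"))

#' Threshold-conductance curve over an E_GABA grid
#'
#' @slot egaba grid, mV (strictly increasing)
#' @slot gthr threshold conductances, nS; NA where no spike could be evoked
#' @slot meta list of model/synapse metadata
#' @export
setClass("GThrCurve",
         representation(egaba = "numeric", gthr = "numeric", meta = "list"),
         validity = function(object) {
           if (length(object@egaba) != length(object@gthr))
             return("grid and values differ in length")
           if (any(diff(object@egaba) <= 0))
             return("E_GABA grid must be strictly increasing")
           if (any(object@gthr <= 0, na.rm = TRUE))
             return("threshold conductances must be positive")
           TRUE
         })

#' An estimate of the threshold GABA reversal potential
#'
#' @slot value mV
#' @slot method "reciprocal" | "intersection" | "pap"
#' @slot diagnostics list (fit coefficients, bracketing points, ...)
#' @export
setClass("EGabaThrEstimate",
         representation(value = "numeric", method = "character",
                        diagnostics = "list"))

#' Goldman-Hodgkin-Katz parameters for the E_GABA <-> [Cl-]i conversion
#'
#' @slot cle extracellular chloride, mM
#' @slot hco3e,hco3i extra-/intracellular bicarbonate, mM
#' @slot phco3 HCO3- permeability relative to Cl- (P_Cl = 1)
#' @slot slope mV per decade
#' @export
setClass("GhkParams",
         representation(cle = "numeric", hco3e = "numeric", hco3i = "numeric",
                        phco3 = "numeric", slope = "numeric"),
         prototype(cle = 133.5, hco3e = 24, hco3i = 14.1, phco3 = 0.44,
                   slope = 60),
         validity = function(object) {
           if (any(c(object@cle, object@hco3e, object@hco3i) <= 0))
             return("concentrations must be positive")
           if (object@phco3 < 0 || object@phco3 > 1)
             return("phco3 must be in [0,1]")
           TRUE
         })

#' Specification of a synthetic branched morphology
#'
#' Seeded stand-in for a reconstructed pyramidal-cell dendritic tree: a soma
#' plus \code{nDendrites} unbranched or branched dendrites whose segment
#' counts span \code{segRange}.
#'
#' @slot nDendrites number of primary dendrites
#' @slot segRange integer range of per-dendrite segment counts
#' @slot segLength um per segment
#' @slot branchDepth maximum number of chained sections per dendrite
#' @slot somaDiam um
#' @slot diam dendrite diameter, um
#' @slot seed integer RNG seed
#' @export
setClass("SyntheticMorphologySpec",
         representation(nDendrites = "numeric", segRange = "numeric",
                        segLength = "numeric", branchDepth = "numeric",
                        somaDiam = "numeric", diam = "numeric", seed = "numeric"),
         prototype(nDendrites = 56, segRange = c(2, 193), segLength = 7,
                   branchDepth = 2, somaDiam = 15, diam = 1, seed = 1),
         validity = function(object) {
           if (object@nDendrites < 0) return("nDendrites must be >= 0")
           if (length(object@segRange) != 2 || object@segRange[1] < 1 ||
               object@segRange[2] < object@segRange[1])
             return("segRange must be an increasing pair >= 1")
           TRUE
         })

#' A seeded random stimulation pattern
#'
#' Random synapse sites (uniform per unit dendritic length within the allowed
#' region) and uniform random onset times within the stimulation window.
#'
#' @slot sites data.frame: receptor ("ampa"|"gaba"), section, pos, onset (ms)
#' @slot window ms
#' @slot seed integer
#' @export
setClass("StimulationPattern",
         representation(sites = "data.frame", window = "numeric",
                        seed = "numeric"),
         validity = function(object) {
           if (nrow(object@sites) &&
               (any(object@sites$onset < 0) ||
                any(object@sites$onset > object@window)))
             return("onsets must lie within the window")
           TRUE
         })

#' Spike-probability curve
#'
#' @slot grid the scanned variable (g_AMPA in nS, or E_GABA in mV)
#' @slot pap spike probabilities in [0,1]
#' @slot nSweeps sweeps per grid point
#' @slot se binomial standard errors
#' @slot meta list
#' @export
setClass("PAPCurve",
         representation(grid = "numeric", pap = "numeric", nSweeps = "numeric",
                        se = "numeric", meta = "list"),
         validity = function(object) {
           if (any(object@pap < 0 | object@pap > 1))
             return("probabilities must be in [0,1]")
           TRUE
         })
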