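#' Construct leak parameters
#'
#' @param gpas passive conductance density, S/cm^2
#' @param epas leak reversal potential, mV; equals the resting potential of an
#'   otherwise unstimulated membrane
#' @return a \linkS4class{LeakParams} object
#' @export
LeakParams <- function(gpas = 1.28e-5, epas = -50.5) {
  new("LeakParams", gpas = gpas, epas = epas)
}

#' Construct sodium channel parameters
#'
#' Defaults are the package's calibrated set for immature CA3 pyramidal
#' somata (see \code{\link{defaultChannelSet}}).
#'
#' @param gmax,erev,Gco,Goc,Gic,Gci,Vco,Vic,kco,kic,tauAct,tauIna,tauRelax,cf,q10
#'   see \linkS4class{NaChannelParams}
#' @return a \linkS4class{NaChannelParams} object
#' @export
NaChannelParams <- function(gmax = 0.015, erev = 60,
                            Gco = 2, Goc = 2, Gic = 1, Gci = 1,
                            Vco = -24, Vic = -40, kco = 5, kic = 6,
                            tauAct = 0.5, tauIna = 10, tauRelax = 10,
                            cf = 20, q10 = 1) {
  new("NaChannelParams", gmax = gmax, erev = erev, Gco = Gco, Goc = Goc,
      Gic = Gic, Gci = Gci, Vco = Vco, Vic = Vic, kco = kco, kic = kic,
      tauAct = tauAct, tauIna = tauIna, tauRelax = tauRelax, cf = cf,
      q10 = q10)
}

#' Construct potassium channel parameters
#'
#' @param gmax,erev,Gco,Goc,Vco,Vic,kco,kic,tauAct,tauIna,tauRelax,cf,q10
#'   see \linkS4class{KChannelParams}
#' @return a \linkS4class{KChannelParams} object
#' @export
KChannelParams <- function(gmax = 0.006, erev = -90,
                           Gco = 1, Goc = 1, Vco = -25, Vic = -25,
                           kco = 9, kic = 9,
                           tauAct = 2, tauIna = 2, tauRelax = 20,
                           cf = 0, q10 = 1) {
  new("KChannelParams", gmax = gmax, erev = erev, Gco = Gco, Goc = Goc,
      Vco = Vco, Vic = Vic, kco = kco, kic = kic, tauAct = tauAct,
      tauIna = tauIna, tauRelax = tauRelax, cf = cf, q10 = q10)
}

.chan_as_list <- function(p) {
  out <- list(Gco = p@Gco, Goc = p@Goc, Vco = p@Vco, Vic = p@Vic,
              kco = p@kco, kic = p@kic, tauAct = p@tauAct, tauIna = p@tauIna,
              tauRelax = p@tauRelax, cf = p@cf, q10 = p@q10)
  if (is(p, "NaChannelParams")) { out$Gic <- p@Gic; out$Gci <- p@Gci }
  else { out$Gic <- p@Goc; out$Gci <- p@Goc }  # K: beta pair reuses Goc gain
  out
}

#' Sodium channel transition rates
#'
#' Boltzmann-sigmoid rates of the three-state Na+ scheme evaluated at a
#' membrane voltage (apply the cooperative shift \code{v + cf*O} yourself if
#' you need effective-voltage rates).
#'
#' @param v voltage(s), mV; must be finite
#' @param p a \linkS4class{NaChannelParams}
#' @return matrix with columns alphaA, betaA, alphaIC, betaIC (1/ms)
#' @export
naRates <- function(v, p = NaChannelParams()) {
  stopifnot(is(p, "NaChannelParams"))
  if (any(!is.finite(v))) stop("voltage must be finite")
  core_rates(as.numeric(v), .chan_as_list(p))
}

#' Potassium channel transition rates
#'
#' @param v voltage(s), mV
#' @param p a \linkS4class{KChannelParams}
#' @return matrix with columns alphaA, betaA (1/ms)
#' @export
kRates <- function(v, p = KChannelParams()) {
  stopifnot(is(p, "KChannelParams"))
  if (any(!is.finite(v))) stop("voltage must be finite")
  core_rates(as.numeric(v), .chan_as_list(p))[, 1:2, drop = FALSE]
}

.check_na_state <- function(o, h) {
  if (o < 0 || h < 0 || o + h > 1)
    stop("Na channel state outside the unit simplex")
}

#' Time derivatives of the sodium channel state
#'
#' The activation rates are evaluated at the effective voltage
#' \code{v + cf*O} (cooperative opening); the inactivation rates at \code{v}.
#' Both states additionally relax with \code{-state/tauRelax}.
#'
#' @param v voltage, mV
#' @param o open fraction O_Na
#' @param h inactivated fraction H_Na
#' @param p \linkS4class{NaChannelParams}
#' @return c(dO = ..., dH = ...), 1/ms
#' @export
naDerivatives <- function(v, o, h, p = NaChannelParams()) {
  if (!is.finite(v)) stop("voltage must be finite")
  .check_na_state(o, h)
  veff <- v + p@cf * o
  ra <- naRates(veff, p); ri <- naRates(v, p)
  dO <- ra[1, "alphaA"] * (1 - o - h) - ra[1, "betaA"] * o - o / p@tauRelax
  dH <- ri[1, "alphaIC"] * (1 - h) - ri[1, "betaIC"] * h - h / p@tauRelax
  c(dO = unname(dO), dH = unname(dH))
}

#' Time derivative of the potassium channel open fraction
#'
#' Both rates are evaluated at the effective voltage \code{v + cf*O_K}.
#'
#' @param v voltage, mV
#' @param ok open fraction O_K
#' @param p \linkS4class{KChannelParams}
#' @return dO_K/dt, 1/ms
#' @export
kDerivative <- function(v, ok, p = KChannelParams()) {
  if (!is.finite(v)) stop("voltage must be finite")
  if (ok < 0 || ok > 1) stop("O_K outside [0,1]")
  veff <- v + p@cf * ok
  r <- kRates(veff, p)
  unname(r[1, "alphaA"] * (1 - ok) - r[1, "betaA"] * ok - ok / p@tauRelax)
}

#' Ohmic membrane current densities
#'
#' @param v voltage, mV
#' @param o,h Na open/inactivated fractions
#' @param ok K open fraction
#' @param na,k,leak channel parameter objects
#' @return c(iNa, iK, iLeak) in mA/cm^2 (density form g*(v - e))
#' @export
membraneCurrents <- function(v, o, h, ok,
                             na = NaChannelParams(), k = KChannelParams(),
                             leak = LeakParams()) {
  .check_na_state(o, h)
  c(iNa = na@gmax * o * (v - na@erev),
    iK = k@gmax * ok * (v - k@erev),
    iLeak = leak@gpas * (v - leak@epas))
}

#' The package's default channel set
#'
#' Leak, Na+ and K+ parameters calibrated so that the ball and ball-and-stick
#' models reproduce the reference excitability of immature CA3 pyramidal
#' neurons: resting potential -50.5 mV, GOhm-range input resistance, a
#' rheobase near 4.25 pA (ball) and 6.55 pA (ball-and-stick), and
#' action-potential thresholds near -35.6 mV (dV/dt criterion) and -42.8 mV
#' (strongest-subthreshold criterion).
#'
#' @param file optional YAML file overriding any parameter (top-level keys
#'   \code{leak}, \code{na}, \code{k}, each a mapping of slot names to values)
#' @return list(leak, na, k)
#' @export
defaultChannelSet <- function(file = NULL) {
  set <- list(leak = LeakParams(), na = .default_na(), k = .default_k())
  if (!is.null(file)) {
    cfg <- yaml::read_yaml(file)
    for (nm in intersect(names(cfg), c("leak", "na", "k"))) {
      for (slot in names(cfg[[nm]]))
        slot(set[[nm]], slot) <- as.numeric(cfg[[nm]][[slot]])
      validObject(set[[nm]])
    }
  }
  set
}
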