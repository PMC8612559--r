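#' @describeIn Morphology-class compact display
#' @param object a \linkS4class{Morphology}
#' @export
setMethod("show", "Morphology", function(object) {
  s <- object@sections
  cat("Morphology with", nrow(s), "section(s); Ra =", object@ra,
      "Ohm cm; cm =", object@cm, "uF/cm^2\n")
  tot <- sum(s$L[s$kind == "cyl"], na.rm = TRUE)
  cat("  root:", s$name[s$parent == ""], "; total cable length:",
      round(tot, 1), "um\n")
})

#' @describeIn CompartmentalModel-class compact display
#' @param object a \linkS4class{CompartmentalModel}
#' @export
setMethod("show", "CompartmentalModel", function(object) {
  cat("CompartmentalModel:", nrow(object@comp), "compartments,",
      sum(object@comp$gna > 0), "with the spike mechanism\n")
  cat("  membrane area:", signif(sum(object@comp$area), 4), "cm^2; rest =",
      object@leak@epas, "mV\n")
})

#' @describeIn Sweep-class compact display
#' @param object a \linkS4class{Sweep}
#' @export
setMethod("show", "Sweep", function(object) {
  cat("Sweep:", nrow(object@v), "site(s) x", ncol(object@v),
      "samples; dt =", object@dt, "ms; t =", max(object@time), "ms\n")
  if (object@diverged) cat("  [diverged]\n")
  cat("  V range:", paste(round(range(object@v), 2), collapse = " .. "),
      "mV\n")
})

#' @describeIn GThrCurve-class compact display
#' @param object a \linkS4class{GThrCurve}
#' @export
setMethod("show", "GThrCurve", function(object) {
  n <- sum(is.finite(object@gthr))
  cat("GThrCurve:", length(object@egaba), "E_GABA points,", n,
      "with a finite threshold\n")
})

#' @describeIn EGabaThrEstimate-class compact display
#' @param object an \linkS4class{EGabaThrEstimate}
#' @export
setMethod("show", "EGabaThrEstimate", function(object) {
  cat("Threshold E_GABA:", round(object@value, 3), "mV  [",
      object@method, "]\n")
})

#' @describeIn PAPCurve-class compact display
#' @param object a \linkS4class{PAPCurve}
#' @export
setMethod("show", "PAPCurve", function(object) {
  cat("PAPCurve over", object@meta$variable %||% "grid", ":",
      length(object@grid), "points, p_AP in [",
      paste(round(range(object@pap), 3), collapse = ", "), "]\n")
})

#' Time vector of a sweep
#' @param sweep a \linkS4class{Sweep}
#' @return numeric vector, ms
#' @export
sweepTime <- function(sweep) sweep@time

#' Voltage matrix of a sweep
#' @param sweep a \linkS4class{Sweep}
#' @return matrix, sites x samples, mV
#' @export
sweepVoltage <- function(sweep) sweep@v

#' Threshold value of a search result
#' @param x a \linkS4class{ThresholdSearchResult}
#' @return numeric (nS or pA), NA if capped
#' @export
thresholdValue <- function(x) x@gThr

#' Value of a threshold-E_GABA estimate
#' @param x an \linkS4class{EGabaThrEstimate}
#' @return numeric, mV
#' @export
egabaThrValue <- function(x) x@value
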