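#' Autonomic measure kinds
#'
#' The four autonomic conditioned-response measures handled by the package:
#' skin conductance responses (`SCR`), pupil size responses (`PSR`),
#' respiration amplitude responses (`RAR`) and heart period responses
#' (`HPR`). The order is the canonical column/reporting order used
#' throughout (tables, weight vectors, subset enumeration).
#'
#' @return Character vector of the four measure names, in canonical order.
#' @export
#' @examples
#' measure_kinds()
measure_kinds <- function() c("SCR", "PSR", "RAR", "HPR")

#' Expected direction of the conditioned effect
#'
#' Threat conditioning raises skin conductance, dilates the pupil and
#' lengthens heart period for CS+ relative to CS-, so the raw CS+/CS-
#' difference is expected positive for SCR, PSR and HPR. Respiration
#' amplitude decreases in anticipation of the aversive outcome, so the raw
#' RAR difference is expected negative. Multiplying each measure column by
#' its sign orients all measures so that the expected conditioned effect is
#' positive, which fixes the sign conventions of effect sizes and
#' combination weights.
#'
#' @param overrides Optional named numeric vector (values +1 or -1) replacing
#'   the default sign for some measures.
#' @return Named numeric vector over [measure_kinds()], entries +1 or -1.
#' @export
#' @examples
#' effect_signs()
#' effect_signs(c(RAR = 1)) # treat RAR as positively signed
effect_signs <- function(overrides = NULL) {
  signs <- c(SCR = 1, PSR = 1, RAR = -1, HPR = 1)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(signs))
    if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
    if (!all(overrides %in% c(-1, 1))) stop("signs must be +1 or -1")
    signs[names(overrides)] <- overrides
  }
  signs
}

# validate a measure subset, preserving canonical order
check_measures <- function(measures) {
  if (is.null(measures)) return(measure_kinds())
  bad <- setdiff(measures, measure_kinds())
  if (length(bad)) {
    stop("unknown measure(s): ", paste(bad, collapse = ", "),
         "; valid measures are ", paste(measure_kinds(), collapse = ", "))
  }
  intersect(measure_kinds(), measures)
}
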