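# Internal unit helpers. Coordinates are stored in cm so that the electrical
# unit system (mV, ms, mS/cm, uF/cm2, uA/cm2, uA) closes without conversion
# factors; all user-facing lengths are micrometres.

UM_PER_CM <- 1e4

um_to_cm <- function(x) x / UM_PER_CM
cm_to_um <- function(x) x * UM_PER_CM

#' Membrane region taxonomy
#'
#' The labels a membrane facet may carry. `MYELIN` is special: it has
#' `Cm = 0` and no ionic currents, and is realized as a no-flux boundary on
#' both sides of the membrane.
#'
#' @return Character vector of valid region labels.
#' @export
membrane_regions <- function() {
  c("SOMA", "DENDRITE", "APICAL_DENDRITE", "BASAL_DENDRITE",
    "AXON_NECK", "AIS", "PARA_AIS", "MYELIN", "RANVIER", "COLLATERAL")
}

assert_region <- function(region, what = "region label") {
  bad <- setdiff(region, membrane_regions())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s: %s (valid: %s)", what,
                 paste(bad, collapse = ", "),
                 paste(membrane_regions(), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
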