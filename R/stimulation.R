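# Stimulation protocols: constant somatic current density, and constant or
# sinusoidal extracellular electrode stimulation.

#' Constant somatic membrane stimulation (protocol I)
#'
#' A constant current density applied across the membrane of one region of
#' one cell, entering the membrane equation alongside the ionic current. A
#' positive `Is` hyperpolarizes (reduces excitability); a negative `Is`
#' depolarizes.
#'
#' @param Is_uA_per_cm2 Stimulation current density (uA/cm^2).
#' @param region Target region label (default SOMA).
#' @param cell Target cell id.
#' @param window_ms Active window `c(t0, t1)` in ms (default always on).
#' @return A `somatic_stimulus`.
#' @export
somatic_stimulus <- function(Is_uA_per_cm2, region = "SOMA", cell = 1L,
                             window_ms = c(0, Inf)) {
  stopifnot(is.numeric(Is_uA_per_cm2), is.finite(Is_uA_per_cm2))
  assert_region(region)
  stopifnot(length(window_ms) == 2L, window_ms[1] <= window_ms[2])
  structure(list(Is = Is_uA_per_cm2, region = region, cell = as.integer(cell),
                 window = window_ms), class = "somatic_stimulus")
}

#' Current density of a somatic stimulus at a membrane location
#'
#' @param stim A [somatic_stimulus()].
#' @param t Time (ms).
#' @param region,cell Membrane location being evaluated.
#' @return `Is` if the region, cell and time window match; otherwise 0.
#' @export
somatic_current_density <- function(stim, t, region, cell = 1L) {
  on <- t >= stim$window[1] & t < stim$window[2]
  ifelse(on & region == stim$region & cell == stim$cell, stim$Is, 0)
}

#' Extracellular electrode stimulation (protocols II and III)
#'
#' A spherical electrode realized as a cavity in the extracellular mesh.
#' On its surface the Neumann condition
#' \eqn{n_e \cdot \sigma_e \nabla u_e = -I_e/A_e} (constant protocol) or
#' \eqn{n_e \cdot \sigma_e \nabla u_e = (I_e/A_e) \sin(2\pi f t)} with t in
#' seconds (sinusoidal protocol) is applied, where `Ae` is the measured
#' discrete surface area of the cavity, so the total injected current is
#' exact regardless of the staircase approximation. For positive `Ie` the
#' constant protocol emits a negative extracellular potential.
#'
#' @param Ie_uA Stimulation strength (uA); note 1 uA = 1000 nA.
#' @param waveform `"constant"` or `"sinusoidal"`.
#' @param f_Hz Frequency for the sinusoidal waveform (Hz; simulation time
#'   is in ms, so the conversion t_seconds = t_ms/1000 is applied
#'   internally).
#' @param Ae_cm2 Electrode surface area; usually left `NULL` and filled
#'   from the mesh's measured cavity area by the solver.
#' @param sign_convention +1 applies the waveform signs literally
#'   (constant: -Ie/Ae, sinusoidal: +Ie/Ae sin); -1 flips them, for users
#'   needing the alternative reading of the two protocols' signs.
#' @return An `electrode_stimulus`.
#' @export
electrode_stimulus <- function(Ie_uA, waveform = c("constant", "sinusoidal"),
                               f_Hz = NULL, Ae_cm2 = NULL,
                               sign_convention = 1) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(Ie_uA), is.finite(Ie_uA))
  if (waveform == "sinusoidal") {
    if (is.null(f_Hz) || f_Hz <= 0) stop("sinusoidal stimulation needs f_Hz > 0")
  }
  if (!is.null(Ae_cm2) && Ae_cm2 <= 0) stop("Ae must be positive")
  stopifnot(sign_convention %in% c(-1, 1))
  structure(list(Ie = Ie_uA, waveform = waveform, f_Hz = f_Hz,
                 Ae = Ae_cm2, sign = sign_convention),
            class = "electrode_stimulus")
}

#' Electrode boundary flux at a given time
#'
#' Value of \eqn{n_e \cdot \sigma_e \nabla u_e} (uA/cm^2) on the electrode
#' facets at time `t`.
#'
#' @param stim An [electrode_stimulus()] with `Ae` set.
#' @param t Time in ms.
#' @return Boundary flux density (uA/cm^2).
#' @export
electrode_boundary_flux <- function(stim, t) {
  if (is.null(stim$Ae) || stim$Ae <= 0) {
    stop("electrode area Ae is not set (build the mesh with an electrode cavity)")
  }
  base <- switch(stim$waveform,
                 constant = -stim$Ie / stim$Ae,
                 sinusoidal = (stim$Ie / stim$Ae) *
                   sin(2 * pi * stim$f_Hz * t / 1000))
  stim$sign * base
}

# Far-field potential of the electrode at distance r (cm), consistent with
# the boundary flux convention: ue(r, t) = flux(t) * Ae / (4 pi sigma_e r).
# Used by the open-loop (MI+E) workflow.
electrode_farfield <- function(stim, sigma_e, r_cm, t) {
  electrode_boundary_flux(stim, t) * stim$Ae / (4 * pi * sigma_e * r_cm)
}
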