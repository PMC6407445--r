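# Stimulation configurations and the pulse train.

#' Stimulation configuration
#'
#' Contact polarity assignment, drive amplitude and pulse-train waveform.
#' In monopolar mode the named cathode contact is driven to `-amplitude_V`
#' and the IPG is the anodic return (0 V); in bipolar mode the anode is a
#' second lead contact and the IPG is insulated. The waveform is a
#' monophasic square pulse train: 14 Hz, 1 V and 1000 ms by default, with a
#' 0.21 ms pulse width (clinical default; the published settings state only
#' frequency and amplitude).
#'
#' @param mode `"monopolar"` or `"bipolar"`.
#' @param cathode cathode contact index, 0-3.
#' @param anode `"ipg"` (monopolar) or a contact index different from the
#'   cathode (bipolar); defaults to the mode's convention.
#' @param amplitude_V drive amplitude (V), > 0.
#' @param frequency_Hz pulse frequency.
#' @param pulse_width_ms pulse width (ms).
#' @param duration_ms stimulus train duration (ms).
#' @return An object of class `sns_stim`.
#' @export
stim_config <- function(mode = c("monopolar", "bipolar"),
                        cathode = 0L,
                        anode = NULL,
                        amplitude_V = 1.0,
                        frequency_Hz = 14,
                        pulse_width_ms = 0.21,
                        duration_ms = 1000) {
  mode <- match.arg(mode)
  cathode <- as.integer(cathode)
  stopifnot(cathode %in% 0:3, amplitude_V > 0, frequency_Hz > 0,
            pulse_width_ms > 0, duration_ms > 0)
  if (is.null(anode)) {
    anode <- if (mode == "monopolar") "ipg" else (cathode + 1L) %% 4L
  }
  if (mode == "monopolar") {
    if (!identical(anode, "ipg")) {
      stop("monopolar stimulation requires anode = \"ipg\"", call. = FALSE)
    }
  } else {
    anode <- as.integer(anode)
    if (!(anode %in% 0:3) || anode == cathode) {
      stop("bipolar anode must be a lead contact different from the cathode",
           call. = FALSE)
    }
  }
  if (pulse_width_ms >= 1000 / frequency_Hz) {
    stop("pulse width must be shorter than the pulse period", call. = FALSE)
  }
  structure(list(mode = mode, cathode = cathode, anode = anode,
                 amplitude_V = amplitude_V, frequency_Hz = frequency_Hz,
                 pulse_width_ms = pulse_width_ms, duration_ms = duration_ms),
            class = "sns_stim")
}

#' @export
print.sns_stim <- function(x, ...) {
  cat(sprintf("sns_stim: %s, cathode contact %d, anode %s\n", x$mode,
              x$cathode, if (identical(x$anode, "ipg")) "IPG"
              else paste("contact", x$anode)))
  cat(sprintf("  %.3g V, %.3g Hz, %.3g ms pulses, %.4g ms duration\n",
              x$amplitude_V, x$frequency_Hz, x$pulse_width_ms, x$duration_ms))
  invisible(x)
}

#' Pulse onset times of a stimulation train
#'
#' Onsets are `k / frequency` for `k = 0, 1, ...` strictly inside the train
#' duration.
#'
#' @param stim an `sns_stim`.
#' @param duration_ms optional override of the train duration.
#' @return Numeric vector of onset times (ms).
#' @export
pulse_onsets <- function(stim, duration_ms = stim$duration_ms) {
  period <- 1000 / stim$frequency_Hz
  n <- floor((duration_ms - 1e-6) / period) + 1
  (seq_len(n) - 1) * period
}
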