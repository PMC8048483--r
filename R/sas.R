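#' Shade-avoidance response parameters
#'
#' Bundles the neighbour-detection threshold and the response rule constants
#' for one phenotype: hyponasty proceeds at `hyponasty_rate` degrees per
#' triggered day up to `max_angle`, and petiole elongation is multiplied by
#' `1 + elongation_multiplier` on triggered days.
#'
#' @param r_fr_threshold R:FR ratio below which the lamina-tip signal
#'   triggers a response (strict inequality). Default 0.5.
#' @param hyponasty_rate upward leaf movement in degrees per triggered day.
#' @param max_angle cap on the petiole elevation angle, degrees (<= 90).
#' @param elongation_multiplier extra fractional petiole elongation on
#'   triggered days (0 disables the elongation response).
#' @param touch_enabled should virtual leaf touching trigger responses?
#' @param self_touch should contact between leaves of the same plant count?
#'   Neighbour detection only by default.
#' @return an object of class `sas_params`.
#' @export
sas_params <- function(r_fr_threshold = 0.5, hyponasty_rate = 5,
                       max_angle = 80, elongation_multiplier = 0.5,
                       touch_enabled = TRUE, self_touch = FALSE) {
  stopifnot(hyponasty_rate >= 0, max_angle <= 90, max_angle >= 0,
            elongation_multiplier >= 0, r_fr_threshold >= 0)
  structure(list(r_fr_threshold = r_fr_threshold,
                 hyponasty_rate = hyponasty_rate,
                 max_angle = max_angle,
                 elongation_multiplier = elongation_multiplier,
                 touch_enabled = touch_enabled,
                 self_touch = self_touch),
            class = "sas_params")
}

#' Phenotype presets
#'
#' `"canopy"` is the core-vegetation phenotype whose hyponasty rate is the
#' experimental variable; `"weak_sas_competitor"` cannot show hyponasty
#' (rate 0) and elongates slowly; `"strong_sas_competitor"` shows hyponasty
#' at 16 degrees per day with full elongation.
#'
#' @param name one of `"canopy"`, `"weak_sas_competitor"`,
#'   `"strong_sas_competitor"`.
#' @param hyponasty_rate canopy hyponasty rate in degrees/day (only used for
#'   the `"canopy"` preset).
#' @param ... further [sas_params()] overrides.
#' @return an `sas_params` object.
#' @export
sas_preset <- function(name = c("canopy", "weak_sas_competitor",
                                "strong_sas_competitor"),
                       hyponasty_rate = 5, ...) {
  name <- match.arg(name)
  switch(name,
    canopy = sas_params(hyponasty_rate = hyponasty_rate,
                        elongation_multiplier = 1, ...),
    weak_sas_competitor = sas_params(hyponasty_rate = 0,
                                     elongation_multiplier = 0.15, ...),
    strong_sas_competitor = sas_params(hyponasty_rate = 16,
                                       elongation_multiplier = 1, ...))
}

#' @export
print.sas_params <- function(x, ...) {
  cat("<sas_params> R:FR threshold <", x$r_fr_threshold,
      "; hyponasty", x$hyponasty_rate, "deg/day capped at", x$max_angle,
      "deg; elongation multiplier", x$elongation_multiplier,
      if (x$touch_enabled) "; touch on" else "; touch off", "\n")
  invisible(x)
}
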