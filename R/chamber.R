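#' Dissolved-oxygen concentration of air-saturated seawater
#'
#' Default oxygen solubility used to convert between mg L^-1 and percent air
#' saturation: 6.3 mg O2 L^-1, the air-equilibrated concentration of seawater
#' at 29 degrees C and 35 ppt salinity (Benson-Krause scale, rounded to two
#' significant decimals). Override via the `o2_full_saturation` field of
#' [chamber_spec()] for other temperatures or salinities.
#'
#' @format A length-one numeric, mg O2 per litre.
#' @export
O2_SAT_29C_35PPT <- 6.3

#' Respirometry chamber and cycle specification
#'
#' Describes the physical chamber and the intermittent-flow cycle: a sealed
#' inner respirometry chamber flushed with oxygen-saturated water between
#' measurement periods, and an outer chamber holding shoal-mates whose only
#' modelled influence is through the testing condition. Defaults describe a
#' 100 ml inner chamber (tubing included) run on a 9 min measure / 3 min flush
#' cycle with 2 s optode sampling at 29 degrees C.
#'
#' @param inner_volume Inner (respirometry) chamber volume incl. tubing, litres.
#' @param outer_volume Outer (shoal-mate) chamber volume, litres. Not used by
#'   the oxygen mass balance; retained as trial metadata.
#' @param measure_duration Sealed measurement period, seconds.
#' @param flush_duration Flush period, seconds.
#' @param sample_interval Optode sampling interval, seconds. Must be at most
#'   `measure_duration / 10` so each period carries enough samples for a fit.
#' @param temperature Water temperature, degrees C (metadata; solubility is
#'   set explicitly via `o2_full_saturation`).
#' @param o2_full_saturation Dissolved O2 at 100 percent air saturation,
#'   mg L^-1.
#' @return A `chamber_spec` object (a validated list).
#' @examples
#' ch <- chamber_spec()
#' ch$inner_volume
#' @export
chamber_spec <- function(inner_volume = 0.100,
                         outer_volume = 1.10,
                         measure_duration = 540,
                         flush_duration = 180,
                         sample_interval = 2,
                         temperature = 29,
                         o2_full_saturation = O2_SAT_29C_35PPT) {
  spec <- list(
    inner_volume = inner_volume,
    outer_volume = outer_volume,
    measure_duration = measure_duration,
    flush_duration = flush_duration,
    sample_interval = sample_interval,
    temperature = temperature,
    o2_full_saturation = o2_full_saturation
  )
  num <- c("inner_volume", "outer_volume", "measure_duration",
           "flush_duration", "sample_interval", "o2_full_saturation")
  for (f in num) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort_shoalmet(sprintf("`%s` must be a single positive number.", f),
                     "shoalmet_invalid_spec")
    }
  }
  if (sample_interval > measure_duration / 10) {
    abort_shoalmet(
      "`sample_interval` must not exceed `measure_duration`/10.",
      "shoalmet_invalid_spec"
    )
  }
  structure(spec, class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf(
    "<chamber_spec> inner %.3f L, cycle %g s measure / %g s flush, %g s sampling, %g degC (sat %.2f mg/L)\n",
    x$inner_volume, x$measure_duration, x$flush_duration,
    x$sample_interval, x$temperature, x$o2_full_saturation
  ))
  invisible(x)
}

#' Effective respirometer volume
#'
#' Water volume available for oxygen depletion: inner chamber volume minus the
#' fish's body volume at an assumed tissue density of 1 g mL^-1. Body-volume
#' subtraction can be disabled to reproduce analyses that used the nominal
#' chamber volume.
#'
#' @param chamber A [chamber_spec()].
#' @param fish_mass Wet mass of the fish, grams (0 for empty-chamber
#'   background runs).
#' @param subtract_body_volume Subtract `fish_mass`/1000 litres? Default TRUE.
#' @return Effective volume in litres.
#' @export
effective_volume <- function(chamber, fish_mass = 0, subtract_body_volume = TRUE) {
  if (fish_mass < 0 || fish_mass >= chamber$inner_volume * 1000) {
    abort_shoalmet(
      sprintf("fish mass %.3g g does not fit a %.0f mL chamber.",
              fish_mass, chamber$inner_volume * 1000),
      "shoalmet_impossible_geometry"
    )
  }
  if (subtract_body_volume) chamber$inner_volume - fish_mass / 1000 else chamber$inner_volume
}
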