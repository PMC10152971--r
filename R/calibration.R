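# Stimulus level calibration for 750 Hz, 4-ms tone bursts delivered through
# the two transducers of the recording protocol: TDH39 supra-aural headphones
# (air conduction, AC) and a B71 mastoid vibrator (bone conduction, BC).
#
# All conversions between the device dial scale (dB HL) and the derived
# scales are affine with fixed per-transducer offsets read from the device
# calibration table:
#   BC: dB nHL = dB HL - 14,  dB FL  = dB HL + 49
#   AC: dB nHL = dB HL - 12,  dB SPL = dB HL + 9
# The nHL offsets are RETSPL-derived constants for this stimulus; deriving
# them from the ISO/IEC standards is out of scope here.

.NHL_OFFSET <- c(BC = -14, AC = -12)
.PHYS_OFFSET <- c(BC = 49, AC = 9)
.PHYS_SCALE <- c(BC = "FL", AC = "SPL")
.DIAL_RANGE <- c(0, 110)

.check_mode <- function(mode) {
  if (length(mode) != 1L || !is.character(mode) || !mode %in% c("AC", "BC"))
    stop("`mode` must be \"AC\" (air conduction) or \"BC\" (bone conduction)",
         call. = FALSE)
  mode
}

.check_dial <- function(level_hl) {
  if (!is.numeric(level_hl) || any(!is.finite(level_hl)))
    stop("`level_hl` must be finite numeric", call. = FALSE)
  if (any(level_hl < .DIAL_RANGE[1] | level_hl > .DIAL_RANGE[2]))
    stop(sprintf("`level_hl` outside the device dial range [%g, %g] dB HL",
                 .DIAL_RANGE[1], .DIAL_RANGE[2]), call. = FALSE)
  level_hl
}

#' Convert a dial level in dB HL to dB nHL
#'
#' The dial scale of the evoked-response audiometer is calibrated in dB HL
#' for long tones; short 750 Hz tone bursts are reported on the normalized
#' hearing level (nHL) scale, offset by the transducer RETSPL. The protocol's
#' reference level of 100 dB HL corresponds to 86 dB nHL for bone conduction
#' and 88 dB nHL for air conduction.
#'
#' @param mode `"AC"` or `"BC"`.
#' @param level_hl Dial level(s) in dB HL, within the device range 0-110.
#' @return Numeric vector of levels in dB nHL.
#' @examples
#' hl_to_nhl("BC", 100) # 86
#' hl_to_nhl("AC", 110) # 98
#' @export
hl_to_nhl <- function(mode, level_hl) {
  .check_mode(mode)
  .check_dial(level_hl)
  level_hl + .NHL_OFFSET[[mode]]
}

#' Convert a level in dB nHL back to the dial scale in dB HL
#'
#' Inverse of [hl_to_nhl()].
#'
#' @inheritParams hl_to_nhl
#' @param level_nhl Level(s) in dB nHL.
#' @return Numeric vector of dial levels in dB HL.
#' @export
nhl_to_hl <- function(mode, level_nhl) {
  .check_mode(mode)
  .check_dial(level_nhl - .NHL_OFFSET[[mode]])
}

#' Convert a dial level to the physical calibration scale
#'
#' Bone-conducted levels are calibrated as force level at an artificial
#' mastoid (dB FL); air-conducted levels as sound pressure level in an
#' artificial ear (dB SPL, peak-to-peak equivalent for tone bursts).
#'
#' @inheritParams hl_to_nhl
#' @return Numeric vector of physical levels, with attribute `"scale"` set to
#'   `"FL"` (BC) or `"SPL"` (AC).
#' @examples
#' hl_to_physical("BC", 105) # 154 dB FL
#' hl_to_physical("AC", 70)  # 79 dB SPL
#' @export
hl_to_physical <- function(mode, level_hl) {
  .check_mode(mode)
  .check_dial(level_hl)
  structure(level_hl + .PHYS_OFFSET[[mode]], scale = .PHYS_SCALE[[mode]])
}

#' Convert a physical calibration level back to the dial scale
#'
#' Inverse of [hl_to_physical()].
#'
#' @inheritParams hl_to_nhl
#' @param level Physical level(s) in dB FL (BC) or dB SPL (AC).
#' @return Numeric vector of dial levels in dB HL.
#' @export
physical_to_hl <- function(mode, level) {
  .check_mode(mode)
  .check_dial(as.numeric(level) - .PHYS_OFFSET[[mode]])
}

#' Full level conversion table for both transducers
#'
#' Expands dial levels into all calibrated scales, reproducing the layout of
#' the device conversion chart (one row per dial level, six columns).
#'
#' @param levels_hl Dial levels in dB HL (default: the 110 down to 70 dB HL
#'   chart rows in 5-dB steps).
#' @return Data frame with columns `bc_hl`, `bc_nhl`, `bc_fl`, `ac_hl`,
#'   `ac_nhl`, `ac_spl`.
#' @export
level_conversion_table <- function(levels_hl = seq(110, 70, by = -5)) {
  data.frame(
    bc_hl = levels_hl,
    bc_nhl = hl_to_nhl("BC", levels_hl),
    bc_fl = as.numeric(hl_to_physical("BC", levels_hl)),
    ac_hl = levels_hl,
    ac_nhl = hl_to_nhl("AC", levels_hl),
    ac_spl = as.numeric(hl_to_physical("AC", levels_hl))
  )
}

#' Reference stimulation level in dB nHL
#'
#' The protocol's between-subject reference level is a dial level of
#' 100 dB HL, i.e. 86 dB nHL (BC) or 88 dB nHL (AC).
#'
#' @inheritParams hl_to_nhl
#' @return Scalar level in dB nHL.
#' @export
reference_level_nhl <- function(mode) {
  hl_to_nhl(mode, 100)
}

#' Staircase level ladder for threshold determination
#'
#' Builds the descending 5-dB staircase used to bracket the c-VEMP threshold,
#' together with the ascending branch used when there is no response at the
#' starting level.
#'
#' @param start Starting level (dB, any one scale used consistently).
#' @param step Step size in dB (> 0), default 5.
#' @param floor Lowest level the descending branch may reach.
#' @param ceiling Highest level the ascending branch may reach (device
#'   maximum output).
#' @return List with components `descending` (start, start - step, ...,
#'   >= floor) and `ascending` (start + step, ..., <= ceiling; empty when
#'   start is already at the ceiling).
#' @examples
#' staircase_levels(100, 5, floor = 70, ceiling = 110)
#' @export
staircase_levels <- function(start, step = 5, floor, ceiling) {
  stopifnot(is.numeric(start), is.numeric(step), is.numeric(floor),
            is.numeric(ceiling), length(start) == 1L, length(step) == 1L)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (floor > ceiling) stop("`floor` must be <= `ceiling`", call. = FALSE)
  if (start < floor || start > ceiling)
    stop("`start` must lie within [floor, ceiling]", call. = FALSE)
  desc <- seq(start, floor, by = -step)
  asc <- if (start + step > ceiling) numeric(0) else
    seq(start + step, ceiling, by = step)
  list(descending = desc, ascending = asc)
}

#' Tone-burst stimulus specification
#'
#' Records the parameters of the short tone burst: 750 Hz, 4 ms duration with
#' a 1-cycle rise, plateau and fall envelope, delivered at 4 stimuli per
#' second, at a dial level on the device range.
#'
#' @param mode `"AC"` or `"BC"`.
#' @param level_hl Dial level in dB HL.
#' @param frequency_hz Carrier frequency in Hz.
#' @param duration_ms Burst duration in ms.
#' @param envelope_cycles Rise/plateau/fall envelope, in carrier cycles.
#' @param rate_hz Delivery rate, stimuli per second.
#' @return Object of class `vemp_stimulus`, a list of the validated fields
#'   plus the derived `level_nhl` and physical level.
#' @export
stimulus_spec <- function(mode, level_hl, frequency_hz = 750,
                          duration_ms = 4, envelope_cycles = c(1, 1, 1),
                          rate_hz = 4) {
  .check_mode(mode)
  .check_dial(level_hl)
  stopifnot(frequency_hz > 0, duration_ms > 0, rate_hz > 0,
            length(envelope_cycles) == 3L, all(envelope_cycles >= 0))
  phys <- hl_to_physical(mode, level_hl)
  structure(
    list(mode = mode, frequency_hz = frequency_hz, duration_ms = duration_ms,
         envelope_cycles = envelope_cycles, rate_hz = rate_hz,
         level_hl = level_hl, level_nhl = hl_to_nhl(mode, level_hl),
         level_physical = as.numeric(phys),
         physical_scale = attr(phys, "scale")),
    class = "vemp_stimulus"
  )
}

#' @export
print.vemp_stimulus <- function(x, ...) {
  cat(sprintf(
    "<vemp_stimulus> %s tone burst: %g Hz, %g ms (%s cycles), %g/s\n",
    x$mode, x$frequency_hz, x$duration_ms,
    paste(x$envelope_cycles, collapse = "/"), x$rate_hz))
  cat(sprintf("  level: %g dB HL = %g dB nHL = %g dB %s\n",
              x$level_hl, x$level_nhl, x$level_physical, x$physical_scale))
  invisible(x)
}
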