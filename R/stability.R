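# Longitudinal static-stability and pitch-agility metrics.
#
# Longitudinal positions here are expressed as aft-of-humeral-head distances
# (positive towards the tail). In the bird reference frame x is positive
# cranial, so an aft distance is `x_shoulder - x`; with this convention a
# neutral point caudal to the centre of gravity gives a positive static
# margin (stable), matching the standard aeronautics sign.

#' Wing planform from a built wing
#'
#' Reconstructs the chord distribution of one wing from the built geometry:
#' the leading edge runs shoulder -> wrist -> wingtip (propatagium and hand
#' leading edge) and the trailing edge through the tertiary strip and the
#' tips of the secondaries and primaries. Chordwise positions are returned
#' aft-positive, measured from the humeral head.
#'
#' @param wing a built wing from [build_wing()].
#' @param options the [build_options()] used for the build.
#' @param n_stations number of spanwise stations.
#' @return tibble with `y` (m), `chord` (m) and `x_c4` (m, aft-positive local
#'   quarter-chord); attributes `root_chord`, `area` (single wing, m^2) and
#'   `half_span`.
#' @export
wing_planform <- function(wing, options = build_options(), n_stations = 200) {
  W <- wing$W; Tt <- wing$T; E <- wing$E; S <- wing$S
  # trailing-edge points: tertiary strip at the root, then secondary tips
  # (wrist -> elbow attachments, caudal), then primary tips along the hand
  nS <- length(wing$sec_len)
  nP <- length(wing$prim_len)
  sec_attach <- t(vapply(seq_len(nS), function(i) {
    W + (i - 1) / max(nS - 1, 1) * (E - W)
  }, numeric(3)))
  sec_tips <- cbind(sec_attach[, 1] - wing$sec_len, sec_attach[, 2])
  gamma <- atan2(wing$hand_dir[2], wing$hand_dir[1])
  th_tip <- gamma + options$primary_fan_deg * pi / 180
  prim_tips <- t(vapply(seq_len(nP), function(i) {
    attach <- W + (i / nP) * (Tt - W)
    th <- pi + (th_tip - pi) * (i - 1) / max(nP - 1, 1)
    attach[1:2] + wing$prim_len[i] * c(cos(th), sin(th))
  }, numeric(2)))
  te <- rbind(c(S[1] - wing$tertiary_chord, 0), sec_tips, prim_tips)
  le <- rbind(c(S[1], 0), W[1:2], Tt[1:2])

  half_span <- max(c(le[, 2], te[, 2]))
  y <- seq(0, half_span, length.out = n_stations)
  x_le <- stats::approx(le[, 2], le[, 1], xout = y, rule = 2, ties = max)$y
  # trailing edge: most caudal (min x) envelope of the ordered tip points
  ord <- order(te[, 2])
  x_te <- stats::approx(te[ord, 2], cummin(te[ord, 1]), xout = y, rule = 2,
                        ties = min)$y
  chord <- pmax(x_le - x_te, 0)
  x_c4 <- -x_le + chord / 4              # aft-positive from the humeral head
  out <- tibble::tibble(y = y, chord = chord, x_c4 = x_c4)
  dy <- y[2] - y[1]
  structure(out, root_chord = chord[1], area = sum(chord) * dy,
            half_span = half_span)
}

#' Quarter chord of the standard mean chord
#'
#' Area-weighted average of the local quarter-chord position across the
#' half-span, evaluated with a midpoint rule on `n_segments` segments:
#' `x_smc = integral(c(y) x_c4(y) dy) / integral(c(y) dy)`.
#'
#' @param planform tibble with columns `y`, `chord`, `x_c4` (see
#'   [wing_planform()]); linear interpolation is used between stations.
#' @param n_segments number of midpoint segments.
#' @return the standard-mean-chord quarter-chord position (same axis
#'   convention as `x_c4`).
#' @export
smc_quarter_chord <- function(planform, n_segments = 1000) {
  stopifnot(nrow(planform) >= 2L, n_segments >= 1)
  ymax <- max(planform$y)
  h <- ymax / n_segments
  ym <- (seq_len(n_segments) - 0.5) * h
  c_m <- stats::approx(planform$y, planform$chord, xout = ym, rule = 2)$y
  x_m <- stats::approx(planform$y, planform$x_c4, xout = ym, rule = 2)$y
  denom <- sum(c_m) * h
  if (denom <= 0) stop("zero wing area: cannot form the standard mean chord", call. = FALSE)
  sum(c_m * x_m) * h / denom
}

#' Neutral point from the standard-mean-chord quarter chord
#'
#' The wing-body neutral point scales with the standard-mean-chord quarter
#' chord as `x_np / c_r = (x_smc / c_r)^exponent`, with exponent 0.8 by
#' default; `exponent = 1` reduces to the identity.
#'
#' @param smc_x_c4 standard-mean-chord quarter-chord position (m, aft of the
#'   humeral head).
#' @param c_r_max maximum root chord (m).
#' @param exponent scaling exponent.
#' @return neutral-point position (m, aft of the humeral head).
#' @export
neutral_point <- function(smc_x_c4, c_r_max, exponent = 0.8) {
  if (any(smc_x_c4 <= 0) || any(c_r_max <= 0)) {
    stop("smc_x_c4 and c_r_max must be positive", call. = FALSE)
  }
  (smc_x_c4 / c_r_max)^exponent * c_r_max
}

#' Static margin
#'
#' Normalized distance between the neutral point and the centre of gravity,
#' `(x_np - x_cg) / c_r_max` with both positions aft of the humeral head.
#' Positive (neutral point behind the CG) means statically stable in pitch;
#' moving the CG aft strictly decreases it.
#'
#' @param x_cg_aft CG position aft of the humeral head (m).
#' @param x_np neutral-point position aft of the humeral head (m).
#' @param c_r_max maximum root chord (m).
#' @return dimensionless static margin (fraction of `c_r_max`).
#' @export
static_margin <- function(x_cg_aft, x_np, c_r_max) {
  stopifnot(all(c_r_max > 0))
  (x_np - x_cg_aft) / c_r_max
}

#' Pitch agility metric
#'
#' Proportional estimate of the pitch angular acceleration developed per
#' degree change in angle of attack:
#' `[(x_smc/c_r)^e c_r - x_cg] (m^0.12)^2 S_max / Iyy`, with cruise speed
#' entering through the allometric scaling `V ~ m^0.12` and air density and
#' lift slope dropped as shared constants. The sign equals the sign of the
#' static margin computed from the same inputs.
#'
#' @inheritParams static_margin
#' @param smc_x_c4 standard-mean-chord quarter chord (m, aft of humeral head).
#' @param mass body mass (kg).
#' @param S_max maximum single-wing area (m^2).
#' @param Iyy pitch moment of inertia about the CG (kg m^2).
#' @param exponent neutral-point scaling exponent.
#' @return proportional agility (arbitrary units).
#' @export
pitch_agility <- function(x_cg_aft, smc_x_c4, c_r_max, mass, S_max, Iyy,
                          exponent = 0.8) {
  if (any(mass <= 0) || any(S_max <= 0) || any(Iyy <= 0)) {
    stop("mass, S_max and Iyy must be positive", call. = FALSE)
  }
  x_np <- neutral_point(smc_x_c4, c_r_max, exponent)
  (x_np - x_cg_aft) * (mass^0.12)^2 * S_max / Iyy
}
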