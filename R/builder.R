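# Assembly of a full-bird composite model from a morphology row, a feather
# table and an (elbow, wrist) wing configuration.
#
# Frames. The bird reference frame has its origin at the clavicle reference
# point (centre of the spinal cord cut at the clavicle), x positive cranial,
# y positive towards the right wing, z positive dorsal. The humeral heads sit
# at (0, +/- y_shoulder, z_torso). Wings are built in a shoulder-local frame
# (origin at the humeral head, same axes) and then translated/mirrored.

# internal unchecked constructor for hot paths where R is orthonormal by
# construction
new_rt <- function(R, t) {
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

compose_transform <- function(outer, inner) {
  new_rt(outer$R %*% inner$R, outer$R %*% inner$t + outer$t)
}

translate_shape <- function(shape, dt) {
  shape$pose$t <- shape$pose$t + as.numeric(dt)
  shape
}

rotate_shape_about <- function(shape, R, centre = c(0, 0, 0)) {
  centre <- as.numeric(centre)
  shape$pose$R <- R %*% shape$pose$R
  shape$pose$t <- as.numeric(R %*% (shape$pose$t - centre)) + centre
  shape
}

# Mirror a shape through the x-z plane (y -> -y). Axisymmetric solids keep
# their dimensions and get a reflected axis; laminae additionally flip their
# canonical polygon so the world-space footprint is the exact reflection.
mirror_shape <- function(shape) {
  M <- diag(c(1, -1, 1))
  Fc <- diag(c(1, -1, 1))
  if (shape$kind == "flat_plate") {
    R2 <- M %*% shape$pose$R %*% Fc
    v <- shape$dims$vertices
    v[, 2] <- -v[, 2]
    shape$dims$vertices <- v
    shape$pose <- new_rt(R2, M %*% shape$pose$t)
  } else if (shape$kind == "point_mass") {
    shape$pose$t <- as.numeric(M %*% shape$pose$t)
  } else {
    # axisymmetric about canonical z: any rotation taking z onto the
    # reflected axis is equivalent
    d <- as.numeric(M %*% shape$pose$R %*% c(0, 0, 1))
    shape$pose <- new_rt(rotation_z_to(d), M %*% shape$pose$t)
  }
  shape
}

mirror_mass_props <- function(mp) {
  M <- diag(c(1, -1, 1))
  mass_props(mp$mass, as.numeric(M %*% mp$cg), M %*% mp$inertia %*% M,
             frame_id = mp$frame_id, about_point = mp$about_point)
}

#' Build options for the composite bird model
#'
#' Geometric ratios that are not direct measurements: bone wall thickness and
#' slenderness, muscle taper, feather fan angles, torso section proportions.
#' Defaults are plausible for the modelled taxa and documented in the methods
#' vignette; they are deliberately few and dimensionless.
#'
#' @param bone_slenderness bone outer radius as a fraction of bone length.
#' @param bone_wall_ratio inner/outer radius of long-bone cross sections.
#' @param muscle_radius_frac muscle-group root radius as a fraction of the
#'   underlying bone length.
#' @param covert_chord_frac covert strip chord as a fraction of secondary
#'   feather length.
#' @param tertiary_chord_frac tertiary strip chord as a fraction of secondary
#'   feather length.
#' @param primary_fan_deg tip-primary sweep relative to the hand direction
#'   (degrees).
#' @param torso_section_fracs lengths of the cranial cap, mid frustum and
#'   caudal cone as fractions of torso length (sum to 1).
#' @return list of class `avimorph_build_options`.
#' @export
build_options <- function(bone_slenderness = 1 / 18,
                          bone_wall_ratio = 0.55,
                          muscle_radius_frac = 0.12,
                          covert_chord_frac = 0.4,
                          tertiary_chord_frac = 0.5,
                          primary_fan_deg = 30,
                          torso_section_fracs = c(0.2, 0.5, 0.3)) {
  stopifnot(abs(sum(torso_section_fracs) - 1) < 1e-9)
  structure(as.list(environment()), class = "avimorph_build_options")
}

#' Build one flight feather as five primitive shapes
#'
#' A feather is a composite of a calamus (hollow cylinder), the rachis
#' modelled as a tapering cortex shell around a medullary core (hollow
#' frustum shell + solid frustum), and two vane laminae (proximal and
#' distal). The feather's local frame has the shaft along +z from the
#' attachment point; vanes lie in the local x-z plane.
#'
#' @param spec one-row data frame / list with fields `mass`,
#'   `length_calamus`, `length_rachis`, `radius_calamus`,
#'   `width_vane_proximal`, `width_vane_distal`, `length_vane_proximal`,
#'   `length_vane_distal`, `frac_calamus`, `frac_rachis_cortex`,
#'   `frac_rachis_medulla`, `frac_vane_proximal`, `frac_vane_distal`.
#' @param pose [rigid_transform()] placing the feather frame in the parent
#'   frame.
#' @return list of 5 [primitive_shape()]s; their masses sum to `spec$mass`
#'   exactly.
#' @export
build_feather <- function(spec, pose = rigid_transform()) {
  spec <- as.list(spec)
  fr <- c(spec$frac_calamus, spec$frac_rachis_cortex, spec$frac_rachis_medulla,
          spec$frac_vane_proximal, spec$frac_vane_distal)
  if (length(fr) != 5L || any(!is.finite(fr)) || any(fr < 0) ||
      abs(sum(fr) - 1) > 1e-9) {
    stop("feather part mass fractions must be non-negative and sum to 1", call. = FALSE)
  }
  m <- spec$mass * fr
  rc <- spec$radius_calamus
  lc <- spec$length_calamus
  lr <- spec$length_rachis
  # plate canonical x-y maps onto feather z-x (normal along feather y)
  R_plate <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3)
  local <- list(
    primitive_shape("hollow_cylinder", m[1],
                    list(radius_out = rc, radius_in = 0.6 * rc, length = lc),
                    new_rt(diag(3), c(0, 0, lc / 2)), "feather_calamus"),
    primitive_shape("hollow_frustum_shell", m[2],
                    list(radius_base_out = rc, radius_top_out = 0.15 * rc,
                         radius_base_in = 0.6 * rc, radius_top_in = 0.09 * rc,
                         height = lr),
                    new_rt(diag(3), c(0, 0, lc)), "feather_rachis_cortex"),
    primitive_shape("solid_frustum", m[3],
                    list(radius_base = 0.6 * rc, radius_top = 0.09 * rc,
                         height = lr),
                    new_rt(diag(3), c(0, 0, lc)), "feather_rachis_medulla"),
    primitive_shape("flat_plate", m[4],
                    list(vertices = trapezoid_vertices(0, spec$length_vane_proximal,
                                                       spec$width_vane_proximal,
                                                       spec$width_vane_distal)),
                    new_rt(R_plate, c(0, 0, lc)), "feather_vane_proximal"),
    primitive_shape("flat_plate", m[5],
                    list(vertices = trapezoid_vertices(spec$length_vane_proximal,
                                                       spec$length_vane_proximal +
                                                         spec$length_vane_distal,
                                                       spec$width_vane_distal,
                                                       0.15 * spec$width_vane_distal)),
                    new_rt(R_plate, c(0, 0, lc)), "feather_vane_distal")
  )
  lapply(local, function(s) { s$pose <- compose_transform(pose, s$pose); s })
}

# symmetric trapezoid spanning x in [x0, x1] with widths w0, w1 (plate frame)
trapezoid_vertices <- function(x0, x1, w0, w1) {
  matrix(c(x0, -w0 / 2, x1, -w1 / 2, x1, w1 / 2, x0, w0 / 2),
         ncol = 2, byrow = TRUE)
}

# Planar wing linkage. The wrist is constrained to lie on the y axis through
# the shoulder (same x and z), so the shoulder angle differs between
# configurations; S1 points caudally (-x) from the wrist.
wing_linkage <- function(lh, lu, lc, elbow_deg, wrist_deg) {
  if (elbow_deg <= 0 || elbow_deg >= 180 || wrist_deg <= 0 || wrist_deg >= 180) {
    stop("elbow and wrist angles must lie in (0, 180) degrees", call. = FALSE)
  }
  eb <- elbow_deg * pi / 180
  wr <- wrist_deg * pi / 180
  d <- sqrt(lh^2 + lu^2 - 2 * lh * lu * cos(eb))
  W <- c(0, d, 0)
  ey <- (lh^2 - lu^2 + d^2) / (2 * d)
  ex <- -sqrt(max(lh^2 - ey^2, 0))     # elbow caudal of the shoulder-wrist line
  E <- c(ex, ey, 0)
  a <- (E - W) / lu                     # wrist arm towards the elbow
  # hand direction at interior angle `wr` from a, on the distal (y+) side
  rot2 <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                            sin(th) * v[1] + cos(th) * v[2], 0)
  cand1 <- rot2(a, wr)
  cand2 <- rot2(a, -wr)
  dir <- if (cand1[2] >= cand2[2]) cand1 else cand2
  Tt <- W + lc * dir
  list(S = c(0, 0, 0), E = E, W = W, T = Tt, hand_dir = dir, d_sw = d)
}

# hollow cylinder spanning p0 -> p1
bone_shape <- function(mass, p0, p1, r_out, wall_ratio, label) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  primitive_shape("hollow_cylinder", mass,
                  list(radius_out = r_out, radius_in = wall_ratio * r_out,
                       length = len),
                  new_rt(rotation_z_to(axis / len), (p0 + p1) / 2),
                  label)
}

muscle_shape <- function(mass, p0, p1, r_base, label) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  primitive_shape("solid_frustum", mass,
                  list(radius_base = r_base, radius_top = 0.4 * r_base,
                       height = len),
                  new_rt(rotation_z_to(axis / len), p0), label)
}

# flat plate from world-space vertices lying in the z = z0 plane
plate_from_xy <- function(mass, verts_xy, z0 = 0, label = "plate") {
  primitive_shape("flat_plate", mass, list(vertices = verts_xy),
                  new_rt(diag(3), c(0, 0, z0)), label)
}

require_fields <- function(specimen, fields) {
  specimen <- as.list(specimen)
  for (f in fields) {
    v <- specimen[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("missing morphology measurement: ", f, call. = FALSE)
    }
  }
  invisible(TRUE)
}

WING_FIELDS <- c("mass_humerus", "length_humerus", "mass_radius", "length_radius",
                 "mass_ulna", "length_ulna", "mass_carpometacarpus",
                 "length_carpometacarpus", "mass_radiale", "mass_ulnare",
                 "mass_muscle_brachial", "mass_muscle_antebrachial",
                 "mass_muscle_manus", "mass_skin", "mass_coverts",
                 "mass_tertiaries", "n_primaries", "n_secondaries")

#' Build one wing as posed primitive shapes
#'
#' Builds the 12 wing components (6 bones, 3 muscle groups, skin/propatagium,
#' coverts, tertiaries) plus 5 shapes per flight feather in a shoulder-local
#' frame: origin at the humeral head, wing extending towards +y, all
#' structural elements in the z = 0 plane. The wrist is placed on the y axis
#' (in line with the shoulder along x and z) and the first secondary points
#' caudally along -x.
#'
#' @param specimen one-row morphology data frame (see [morphology_schema()]).
#' @param feathers feather table rows for this specimen.
#' @param elbow,wrist joint angles in degrees, each in (0, 180).
#' @param options a [build_options()] list.
#' @return list with `shapes` (list of [primitive_shape()]),
#'   joint positions `S`, `E`, `W`, `T`, and the total wing `mass`.
#' @export
build_wing <- function(specimen, feathers, elbow, wrist,
                       options = build_options()) {
  require_fields(specimen, WING_FIELDS)
  sp <- as.list(specimen)
  fe <- as.data.frame(feathers)
  nP <- as.integer(sp$n_primaries)
  nS <- as.integer(sp$n_secondaries)
  prim <- fe[fe$type == "primary", , drop = FALSE]
  sec <- fe[fe$type == "secondary", , drop = FALSE]
  if (nrow(prim) != nP || nrow(sec) != nS) {
    stop("feather table has ", nrow(prim), " primaries and ", nrow(sec),
         " secondaries; morphology declares ", nP, " and ", nS, call. = FALSE)
  }
  prim <- prim[order(prim$feather_id), , drop = FALSE]
  sec <- sec[order(sec$feather_id), , drop = FALSE]

  lk <- wing_linkage(sp$length_humerus, sp$length_ulna,
                     sp$length_carpometacarpus, elbow, wrist)
  slen <- options$bone_slenderness
  wall <- options$bone_wall_ratio

  ulna_perp <- {
    u <- (lk$W - lk$E) / sp$length_ulna
    n <- c(-u[2], u[1], 0)               # in-plane normal
    if (n[1] < 0) n <- -n                # cranial side
    n
  }
  shapes <- list(
    bone_shape(sp$mass_humerus, lk$S, lk$E, slen * sp$length_humerus, wall, "bone_humerus"),
    bone_shape(sp$mass_ulna, lk$E, lk$W, slen * sp$length_ulna, wall, "bone_ulna"),
    bone_shape(sp$mass_radius, lk$E + ulna_perp * 2.5 * slen * sp$length_ulna,
               lk$W + ulna_perp * 2.5 * slen * sp$length_ulna,
               0.7 * slen * sp$length_radius, wall, "bone_radius"),
    bone_shape(sp$mass_carpometacarpus, lk$W, lk$T,
               0.8 * slen * sp$length_carpometacarpus, wall, "bone_carpometacarpus"),
    primitive_shape("point_mass", sp$mass_radiale, list(),
                    new_rt(diag(3), lk$W + c(0.004, 0, 0)), "bone_radiale"),
    primitive_shape("point_mass", sp$mass_ulnare, list(),
                    new_rt(diag(3), lk$W + c(-0.004, 0, 0)), "bone_ulnare"),
    muscle_shape(sp$mass_muscle_brachial, lk$S, lk$E,
                 options$muscle_radius_frac * sp$length_humerus, "muscle_brachial"),
    muscle_shape(sp$mass_muscle_antebrachial, lk$E, lk$W,
                 0.8 * options$muscle_radius_frac * sp$length_ulna, "muscle_antebrachial"),
    muscle_shape(sp$mass_muscle_manus, lk$W, lk$T,
                 0.4 * options$muscle_radius_frac * sp$length_carpometacarpus,
                 "muscle_manus")
  )

  mean_sec_len <- mean(sec$length_calamus + sec$length_rachis)
  wc <- options$covert_chord_frac * mean_sec_len
  wt <- options$tertiary_chord_frac * mean_sec_len
  shapes <- c(shapes, list(
    plate_from_xy(sp$mass_skin,
                  rbind(lk$S[1:2], lk$W[1:2], lk$E[1:2]), 0, "skin_propatagium"),
    plate_from_xy(sp$mass_coverts,
                  rbind(lk$E[1:2], lk$W[1:2],
                        lk$W[1:2] + c(-wc, 0), lk$E[1:2] + c(-wc, 0)),
                  0, "coverts"),
    plate_from_xy(sp$mass_tertiaries,
                  rbind(lk$S[1:2], lk$E[1:2],
                        lk$E[1:2] + c(-wt, 0), lk$S[1:2] + c(-wt, 0)),
                  0, "tertiaries")
  ))

  # feather poses: shaft direction d in the x-y plane, vane normal along z
  feather_pose <- function(attach, dir_xy) {
    d <- c(dir_xy, 0)
    p <- c(-d[2], d[1], 0)     # z x d, in-plane normal to the shaft
    R <- cbind(p, c(0, 0, 1), d)  # feather x -> p, y -> z, z -> d
    new_rt(R, attach)
  }

  # secondaries: S1 at the wrist pointing caudally, S_n at the elbow
  for (i in seq_len(nS)) {
    f <- (i - 1) / max(nS - 1, 1)
    attach <- lk$W + f * (lk$E - lk$W)
    shapes <- c(shapes, build_feather(sec[i, ], feather_pose(attach, c(-1, 0))))
  }
  # primaries: fan from caudal at the wrist to near the hand direction at tip
  gamma <- atan2(lk$hand_dir[2], lk$hand_dir[1])
  th_root <- pi
  th_tip <- gamma + options$primary_fan_deg * pi / 180
  for (i in seq_len(nP)) {
    f <- i / nP
    attach <- lk$W + f * (lk$T - lk$W)
    th <- th_root + (th_tip - th_root) * (i - 1) / max(nP - 1, 1)
    shapes <- c(shapes, build_feather(prim[i, ],
                                      feather_pose(attach, c(cos(th), sin(th)))))
  }

  mass <- sum(vapply(shapes, `[[`, numeric(1), "mass"))
  list(shapes = shapes, S = lk$S, E = lk$E, W = lk$W, T = lk$T,
       hand_dir = lk$hand_dir, mass = mass,
       prim_len = prim$length_calamus + prim$length_rachis,
       sec_len = sec$length_calamus + sec$length_rachis,
       covert_chord = wc, tertiary_chord = wt)
}

BODY_FIELDS <- c("mass_head", "length_head", "width_head", "mass_neck",
                 "length_neck", "radius_neck", "mass_torso", "length_torso",
                 "width_torso", "height_torso", "torso_cg_x", "torso_cg_z",
                 "mass_legs", "length_leg", "radius_leg", "mass_tail",
                 "length_tail", "width_tail_root", "width_tail_tip")

#' Build the wingless body as 8 primitive shapes
#'
#' Head (ellipsoid), neck (cylinder), torso (hemiellipsoid cap + frustum +
#' caudal cone, 3 shapes), legs (2 cylinders) and tail (trapezoidal lamina).
#' The torso mass is partitioned among its three sections by a one-parameter
#' bisection so the composite torso CG matches the measured balance point
#' (`torso_cg_x`, `torso_cg_z`) relative to the clavicle reference point.
#'
#' @inheritParams build_wing
#' @param neck `"extended"` (cranial, in line with the torso axis) or
#'   `"furled"` (neck rotated up and back; pose-only change).
#' @param torso_mass override for the torso mass used after whole-bird mass
#'   reconciliation (defaults to the measured `mass_torso`).
#' @return list with `shapes` (8 shapes) and the torso section masses.
#' @export
build_body <- function(specimen, neck = c("extended", "furled"),
                       options = build_options(), torso_mass = NULL) {
  neck <- match.arg(neck)
  require_fields(specimen, BODY_FIELDS)
  sp <- as.list(specimen)
  m_torso <- if (is.null(torso_mass)) sp$mass_torso else torso_mass
  L <- sp$length_torso
  r_t <- sqrt(sp$width_torso * sp$height_torso) / 2
  fr <- options$torso_section_fracs
  c_cap <- fr[1] * L; L_mid <- fr[2] * L; L_cone <- fr[3] * L
  z0 <- sp$torso_cg_z

  xhat_neg <- rotation_z_to(c(-1, 0, 0))
  cap <- primitive_shape("hemiellipsoid", 1,
                         list(a = r_t, b = r_t, c = c_cap),
                         rigid_transform(rotation_z_to(c(1, 0, 0)),
                                         c(-c_cap, 0, z0)), "torso_cap")
  mid <- primitive_shape("solid_frustum", 1,
                         list(radius_base = r_t, radius_top = 0.75 * r_t,
                              height = L_mid),
                         rigid_transform(xhat_neg, c(-c_cap, 0, z0)), "torso_mid")
  cone <- primitive_shape("solid_frustum", 1,
                          list(radius_base = 0.75 * r_t, radius_top = 0.05 * r_t,
                               height = L_cone),
                          rigid_transform(xhat_neg, c(-c_cap - L_mid, 0, z0)),
                          "torso_cone")
  # x positions of section CGs are fixed by geometry; only masses move
  xcg <- vapply(list(cap, mid, cone),
                function(s) primitive_mass_properties(s)$cg[1], numeric(1))
  vol <- c(2 / 3 * pi * r_t^2 * c_cap,
           revolution_moments(r_t, 0.75 * r_t, L_mid)$V,
           revolution_moments(0.75 * r_t, 0.05 * r_t, L_cone)$V)
  target <- sp$torso_cg_x
  part_for <- function(s) {
    w <- c(vol[1] * (1 + s), vol[2], vol[3] * (1 - s))
    w / sum(w)
  }
  cg_for <- function(s) sum(part_for(s) * xcg)
  eps <- 1e-6
  lo <- cg_for(-1 + eps); hi <- cg_for(1 - eps)  # cg increases with s (cap cranial)
  if (target < min(lo, hi) - 1e-9 || target > max(lo, hi) + 1e-9) {
    stop(sprintf(
      "torso CG x = %.4f m is outside the feasible range [%.4f, %.4f] m",
      target, min(lo, hi), max(lo, hi)), call. = FALSE)
  }
  s_hat <- stats::uniroot(function(s) cg_for(s) - target,
                          c(-1 + eps, 1 - eps), tol = 1e-12)$root
  w <- part_for(s_hat) * m_torso
  cap$mass <- w[1]; mid$mass <- w[2]; cone$mass <- w[3]

  if (neck == "extended") {
    neck_pose <- rigid_transform(rotation_z_to(c(1, 0, 0)),
                                 c(sp$length_neck / 2, 0, z0))
    head_centre <- c(sp$length_neck + sp$length_head / 2, 0, z0)
  } else {
    # furled: neck rotated 60 degrees dorsally, head brought caudally
    dirn <- c(cos(pi / 3), 0, sin(pi / 3))
    neck_pose <- rigid_transform(rotation_z_to(dirn), dirn * sp$length_neck / 2 + c(0, 0, z0))
    head_centre <- dirn * sp$length_neck + c(sp$length_head / 2, 0, z0)
  }
  shapes <- list(
    cap, mid, cone,
    primitive_shape("solid_cylinder", sp$mass_neck,
                    list(radius = sp$radius_neck, length = sp$length_neck),
                    neck_pose, "neck"),
    primitive_shape("ellipsoid", sp$mass_head,
                    list(a = sp$length_head / 2, b = sp$width_head / 2,
                         c = sp$width_head / 2),
                    rigid_transform(diag(3), head_centre), "head"),
    primitive_shape("solid_cylinder", sp$mass_legs / 2,
                    list(radius = sp$radius_leg, length = sp$length_leg),
                    rigid_transform(diag(3) %*% rotation_z_to(c(1, 0, 0)),
                                    c(-0.55 * L, sp$width_torso / 4,
                                      z0 - 0.4 * sp$height_torso)), "leg_right"),
    primitive_shape("solid_cylinder", sp$mass_legs / 2,
                    list(radius = sp$radius_leg, length = sp$length_leg),
                    rigid_transform(rotation_z_to(c(1, 0, 0)),
                                    c(-0.55 * L, -sp$width_torso / 4,
                                      z0 - 0.4 * sp$height_torso)), "leg_left"),
    plate_from_xy(sp$mass_tail,
                  trapezoid_vertices(-L - sp$length_tail, -L,
                                     sp$width_tail_tip, sp$width_tail_root),
                  z0, "tail")
  )
  list(shapes = shapes, torso_section_masses = w, r_torso = r_t)
}

#' Reconcile component masses against the measured total
#'
#' Component masses (body parts + 2 x one-wing mass) must sum to the measured
#' total within `tol` (default 2%); the residual is absorbed into the torso
#' mass. Larger residuals are treated as an input error.
#'
#' @param specimen one-row morphology data frame.
#' @param wing_mass built single-wing mass (kg).
#' @param tol relative reconciliation tolerance.
#' @return adjusted torso mass (kg).
#' @export
reconcile_mass <- function(specimen, wing_mass, tol = 0.02) {
  sp <- as.list(specimen)
  body_sum <- sp$mass_head + sp$mass_neck + sp$mass_torso + sp$mass_legs +
    sp$mass_tail
  total <- body_sum + 2 * wing_mass
  resid <- sp$mass_total - total
  if (abs(resid) > tol * sp$mass_total) {
    stop(sprintf(
      "component masses (%.4f kg) differ from total mass (%.4f kg) by %.1f%% (> %.0f%% tolerance)",
      total, sp$mass_total, 100 * abs(resid) / sp$mass_total, 100 * tol),
      call. = FALSE)
  }
  sp$mass_torso + resid
}

#' Assemble the full composite bird model
#'
#' Builds the body and both wings for a symmetric (elbow, wrist)
#' configuration. With `n_primaries = 10`, `n_secondaries = 10` and an
#' extended neck the model comprises exactly
#' `8 + 2 * (12 + 5 * (nP + nS)) = 232` primitive shapes. The left wing is
#' the exact reflection of the right wing through the x-z plane.
#'
#' @inheritParams build_wing
#' @inheritParams build_body
#' @param symmetric build both wings mirrored (`TRUE`, default) or the right
#'   wing only.
#' @return A tibble of class `bird_model` with columns `component`, `side`,
#'   `label`, `kind`, `mass` and a `shape` list-column; attributes carry the
#'   specimen row, configuration and shoulder position.
#' @export
assemble_bird <- function(specimen, feathers, elbow, wrist,
                          neck = "extended", symmetric = TRUE,
                          options = build_options()) {
  wing <- build_wing(specimen, feathers, elbow, wrist, options)
  torso_mass <- reconcile_mass(specimen, wing$mass)
  body <- build_body(specimen, neck, options, torso_mass = torso_mass)
  sp <- as.list(specimen)
  shoulder <- c(0, body$r_torso, sp$torso_cg_z)

  wing_r <- lapply(wing$shapes, translate_shape, dt = shoulder)
  rows <- list(
    tibble::tibble(component = "body", side = "centre",
                   shape = body$shapes),
    tibble::tibble(component = "wing", side = "right", shape = wing_r)
  )
  if (symmetric) {
    wing_l <- lapply(wing_r, mirror_shape)
    rows <- c(rows, list(tibble::tibble(component = "wing", side = "left",
                                        shape = wing_l)))
  }
  model <- dplyr::bind_rows(rows)
  model$label <- vapply(model$shape, `[[`, character(1), "label")
  model$kind <- vapply(model$shape, `[[`, character(1), "kind")
  model$mass <- vapply(model$shape, `[[`, numeric(1), "mass")
  model <- model[, c("component", "side", "label", "kind", "mass", "shape")]
  structure(model,
            class = c("bird_model", class(model)),
            specimen = specimen, elbow = elbow, wrist = wrist,
            shoulder = shoulder, neck = neck, symmetric = symmetric,
            wing_geom = wing[c("S", "E", "W", "T", "hand_dir", "prim_len",
                               "sec_len", "covert_chord", "tertiary_chord")])
}

#' Mass properties of an assembled bird
#'
#' Combines all primitive shapes into the whole-bird mass, centre of gravity
#' (bird reference frame, origin at the clavicle point) and inertia tensor
#' about the CG, plus CG coordinates normalized by body length.
#'
#' @param model a `bird_model` from [assemble_bird()].
#' @return One-row tibble with mass, CG, normalized CG
#'   (`x_cg_norm = cg_x / body length`), the six tensor components and the
#'   aft-of-humeral-head CG fraction `x_cg_aft_frac`; the full
#'   [mass_props()] object is attached as attribute `"mass_props"`.
#' @export
bird_mass_properties <- function(model) {
  stopifnot(inherits(model, "bird_model"))
  parts <- lapply(model$shape, primitive_mass_properties)
  total <- combine_components(parts)
  sp <- as.list(attr(model, "specimen"))
  shoulder <- attr(model, "shoulder")
  out <- tidy.mass_props(total)
  out$x_cg_norm <- total$cg[1] / sp$length_body
  out$z_cg_norm <- total$cg[3] / sp$length_body
  out$x_cg_aft_frac <- (shoulder[1] - total$cg[1]) / sp$length_body
  attr(out, "mass_props") <- total
  out
}

#' Single-wing inertia about the humeral head
#'
#' Builds the right wing in the shoulder frame and reports its inertia tensor
#' about the humeral head (origin), the spanwise CG position and its value
#' normalized by the maximum half span (`wingspan / 2`).
#'
#' @inheritParams build_wing
#' @return One-row tibble with `Ixx_wing`, `Iyy_wing`, `Izz_wing`,
#'   `y_cg_wing`, `y_cg_wing_norm` and `mass_wing`.
#' @export
wing_mass_properties_about_shoulder <- function(specimen, feathers, elbow,
                                                wrist, options = build_options()) {
  wing <- build_wing(specimen, feathers, elbow, wrist, options)
  parts <- lapply(wing$shapes, primitive_mass_properties)
  mp <- combine_components(parts, about_point = c(0, 0, 0))
  sp <- as.list(specimen)
  tibble::tibble(
    elbow = elbow, wrist = wrist,
    Ixx_wing = mp$inertia[1, 1], Iyy_wing = mp$inertia[2, 2],
    Izz_wing = mp$inertia[3, 3],
    y_cg_wing = mp$cg[2],
    y_cg_wing_norm = mp$cg[2] / (sp$wingspan / 2),
    mass_wing = mp$mass
  )
}

#' Centre-of-gravity envelope under 90-degree shoulder rotations
#'
#' Recomputes the full-bird CG with both wings rigidly rotated about the
#' humeral head by 90 degrees forwards, backwards, up and down from a
#' reference (extended) configuration, and returns the bounding extrema of
#' the normalized CG shift.
#'
#' @inheritParams build_wing
#' @param elbow,wrist the reference wing configuration (degrees).
#' @return Tibble with one row per orientation (including the unrotated
#'   reference) and attributes `dx_norm`, `dz_norm` giving the envelope
#'   widths as fractions of body length.
#' @export
shoulder_cg_envelope <- function(specimen, feathers, elbow, wrist,
                                 options = build_options()) {
  model <- assemble_bird(specimen, feathers, elbow, wrist, options = options)
  shoulder <- attr(model, "shoulder")
  sp <- as.list(specimen)
  body_idx <- model$component == "body"
  body_parts <- lapply(model$shape[body_idx], primitive_mass_properties)
  wing_r <- model$shape[model$component == "wing" & model$side == "right"]

  orientations <- list(
    reference = diag(3),
    forward = rotation_about("z", -90),
    backward = rotation_about("z", 90),
    up = rotation_about("x", 90),
    down = rotation_about("x", -90)
  )
  rows <- purrr::imap(orientations, function(R, nm) {
    rot <- lapply(wing_r, rotate_shape_about, R = R, centre = shoulder)
    parts_r <- lapply(rot, primitive_mass_properties)
    parts_l <- lapply(parts_r, mirror_mass_props)
    total <- combine_components(c(body_parts, parts_r, parts_l))
    tibble::tibble(orientation = nm, cg_x = total$cg[1], cg_z = total$cg[3],
                   x_cg_norm = total$cg[1] / sp$length_body,
                   z_cg_norm = total$cg[3] / sp$length_body)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dx_norm") <- diff(range(out$x_cg_norm))
  attr(out, "dz_norm") <- diff(range(out$z_cg_norm))
  out
}
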