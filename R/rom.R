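# Marker-based joint angles, range-of-motion convex hulls, and the
# configuration sweep that maps a hull onto inertial/stability surfaces.

#' Interior joint angle from three points
#'
#' The interior angle at `vertex` between the arms towards `p_a` and `p_b`,
#' in degrees, in `[0, 180]`. Invariant to global rotation and translation.
#'
#' @param p_a,vertex,p_b length-3 numeric marker positions (m).
#' @return angle in degrees.
#' @export
joint_angle <- function(p_a, vertex, p_b) {
  u <- as.numeric(p_a) - as.numeric(vertex)
  v <- as.numeric(p_b) - as.numeric(vertex)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length joint arm", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Elbow and wrist angles from a marker table
#'
#' Joint angles are the interior angles defined by three markers: markers
#' 1, 2 (vertex) and 3 for the elbow; markers 2, 3 (vertex) and 4 for the
#' wrist. Frames missing any of markers 1-4 are dropped with a message.
#'
#' @param markers tibble with columns `frame`, `marker` (integer label),
#'   `x`, `y`, `z` (m).
#' @return tibble with columns `frame`, `elbow`, `wrist` (degrees).
#' @export
marker_joint_angles <- function(markers) {
  need <- markers$marker %in% 1:4
  wide <- tidyr::pivot_wider(markers[need, ],
                             id_cols = "frame", names_from = "marker",
                             values_from = c("x", "y", "z"))
  req <- as.vector(outer(c("x_", "y_", "z_"), 1:4, paste0))
  miss_col <- setdiff(req, names(wide))
  if (length(miss_col)) wide[miss_col] <- NA_real_
  ok <- stats::complete.cases(wide[req])
  if (any(!ok)) {
    message(sum(!ok), " frame(s) dropped: missing markers 1-4")
    wide <- wide[ok, , drop = FALSE]
  }
  if (nrow(wide) == 0L) stop("no complete marker frames", call. = FALSE)
  pt <- function(i, r) as.numeric(wide[r, paste0(c("x_", "y_", "z_"), i)])
  tibble::tibble(
    frame = wide$frame,
    elbow = vapply(seq_len(nrow(wide)),
                   function(r) joint_angle(pt(1, r), pt(2, r), pt(3, r)),
                   numeric(1)),
    wrist = vapply(seq_len(nrow(wide)),
                   function(r) joint_angle(pt(2, r), pt(3, r), pt(4, r)),
                   numeric(1))
  )
}

#' Convex hull of the elbow-wrist range of motion
#'
#' @param angles tibble with columns `elbow`, `wrist` (degrees), typically
#'   from [marker_joint_angles()].
#' @return A tibble of class `rom_hull` with hull vertices in
#'   counter-clockwise order (columns `elbow`, `wrist`); attributes `area`
#'   (deg^2) and `n_frames`.
#' @export
rom_hull <- function(angles) {
  pts <- unique(cbind(angles$elbow, angles$wrist))
  if (nrow(pts) < 3L) stop("need at least 3 distinct (elbow, wrist) points", call. = FALSE)
  idx <- grDevices::chull(pts)
  v <- pts[rev(idx), , drop = FALSE]    # chull returns clockwise
  j <- c(seq_len(nrow(v))[-1], 1L)
  area <- abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2)
  if (nrow(v) < 3L || area < 1e-9) {
    stop("degenerate (collinear) range of motion", call. = FALSE)
  }
  out <- tibble::tibble(elbow = v[, 1], wrist = v[, 2])
  structure(out, class = c("rom_hull", class(out)),
            area = area, n_frames = nrow(angles))
}

#' Grid of configurations inside a ROM hull
#'
#' @param hull a [rom_hull()] (or any tibble of polygon vertices with
#'   `elbow`, `wrist` columns).
#' @param grid_step grid spacing in degrees.
#' @return tibble of (`elbow`, `wrist`) grid points inside or on the hull;
#'   hull vertices are always included so extrema are never clipped away.
#' @export
rom_grid <- function(hull, grid_step = 1) {
  stopifnot(grid_step > 0)
  if (nrow(hull) < 3L) {        # degenerate prescription: use the points as-is
    return(tibble::as_tibble(unique(as.data.frame(hull[, c("elbow", "wrist")]))))
  }
  eb <- seq(min(hull$elbow), max(hull$elbow), by = grid_step)
  wr <- seq(min(hull$wrist), max(hull$wrist), by = grid_step)
  g <- expand.grid(elbow = eb, wrist = wr)
  inside <- mgcv::in.out(as.matrix(rbind(hull[, c("elbow", "wrist")],
                                         hull[1, c("elbow", "wrist")])),
                         as.matrix(g))
  g <- g[inside, , drop = FALSE]
  out <- unique(rbind(as.data.frame(hull[, c("elbow", "wrist")]), g))
  if (nrow(out) == 0L) stop("empty configuration grid", call. = FALSE)
  tibble::as_tibble(out)
}

#' Sweep a specimen's ROM and compute inertial and stability surfaces
#'
#' For every grid point inside the hull this builds the full symmetric bird
#' (body reused across configurations, one wing built per configuration and
#' mirrored analytically), computes whole-bird mass properties, single-wing
#' properties about the humeral head, and the planform-derived stability
#' metrics. Specimen-level constants (`c_r_max`, the maximum root chord, and
#' `S_max`, the maximum single-wing area) are taken over the grid before the
#' static margin and agility are evaluated.
#'
#' @inheritParams build_wing
#' @param hull a [rom_hull()] or tibble of hull vertices.
#' @param grid_step grid spacing (degrees).
#' @param np_exponent neutral-point scaling exponent.
#' @param n_segments spanwise segments for the standard-mean-chord integral.
#' @param neck neck state passed to the body builder.
#' @return A tibble of class `avi_sweep`, one row per configuration, with
#'   CG components (normalized by body length), tensor components, wing
#'   metrics and stability metrics; specimen-level constants are attributes.
#' @export
sweep_rom <- function(specimen, feathers, hull, grid_step = 1,
                      np_exponent = 0.8, n_segments = 1000,
                      neck = "extended", options = build_options()) {
  grid <- rom_grid(hull, grid_step)
  sp <- as.list(specimen)

  wing0 <- build_wing(specimen, feathers, grid$elbow[1], grid$wrist[1], options)
  torso_mass <- reconcile_mass(specimen, wing0$mass)
  body <- build_body(specimen, neck, options, torso_mass = torso_mass)
  body_parts <- lapply(body$shapes, primitive_mass_properties)
  shoulder <- c(0, body$r_torso, sp$torso_cg_z)

  rows <- purrr::map2(grid$elbow, grid$wrist, function(eb, wr) {
    wing <- build_wing(specimen, feathers, eb, wr, options)
    parts_s <- lapply(wing$shapes, primitive_mass_properties)      # shoulder frame
    wing_mp <- combine_components(parts_s, about_point = c(0, 0, 0))
    parts_r <- lapply(parts_s, function(p) {
      mass_props(p$mass, p$cg + shoulder, p$inertia)
    })
    parts_l <- lapply(parts_r, mirror_mass_props)
    total <- combine_components(c(body_parts, parts_r, parts_l))
    pf <- wing_planform(wing, options)
    smc <- smc_quarter_chord(pf, n_segments = n_segments)
    tibble::tibble(
      elbow = eb, wrist = wr,
      mass = total$mass,
      cg_x = total$cg[1], cg_y = total$cg[2], cg_z = total$cg[3],
      x_cg_norm = total$cg[1] / sp$length_body,
      z_cg_norm = total$cg[3] / sp$length_body,
      x_cg_aft = shoulder[1] - total$cg[1],
      Ixx = total$inertia[1, 1], Iyy = total$inertia[2, 2],
      Izz = total$inertia[3, 3], Ixy = total$inertia[1, 2],
      Ixz = total$inertia[1, 3], Iyz = total$inertia[2, 3],
      Ixx_wing = wing_mp$inertia[1, 1],
      y_cg_wing = wing_mp$cg[2],
      y_cg_wing_norm = wing_mp$cg[2] / (sp$wingspan / 2),
      smc_x_c4 = smc,
      root_chord = attr(pf, "root_chord"),
      wing_area = attr(pf, "area")
    )
  })
  out <- dplyr::bind_rows(rows)
  c_r_max <- max(out$root_chord)
  S_max <- max(out$wing_area)
  out$x_np <- neutral_point(out$smc_x_c4, c_r_max, exponent = np_exponent)
  out$static_margin <- static_margin(out$x_cg_aft, out$x_np, c_r_max)
  out$agility <- pitch_agility(out$x_cg_aft, out$smc_x_c4, c_r_max,
                               sp$mass_total, S_max, out$Iyy,
                               exponent = np_exponent)
  out$stable <- out$static_margin > 0
  structure(out, class = c("avi_sweep", class(out)),
            specimen = specimen, c_r_max = c_r_max, S_max = S_max,
            np_exponent = np_exponent, grid_step = grid_step)
}

#' Per-specimen extrema over a ROM sweep
#'
#' Exhaustive scan of the sweep grid for the configurations with maximum and
#' minimum static margin, the agility extremes, CG ranges and inertia
#' fold-changes.
#'
#' @param sweep an `avi_sweep` from [sweep_rom()].
#' @return one-row tibble of extrema and ranges.
#' @export
specimen_extremes <- function(sweep) {
  stopifnot(nrow(sweep) >= 1L)
  i_max <- which.max(sweep$static_margin)
  i_min <- which.min(sweep$static_margin)
  tibble::tibble(
    sm_max = sweep$static_margin[i_max],
    sm_max_elbow = sweep$elbow[i_max], sm_max_wrist = sweep$wrist[i_max],
    sm_min = sweep$static_margin[i_min],
    sm_min_elbow = sweep$elbow[i_min], sm_min_wrist = sweep$wrist[i_min],
    agility_max = max(sweep$agility), agility_min = min(sweep$agility),
    abs_agility_max = max(abs(sweep$agility)),
    abs_agility_min = min(abs(sweep$agility)),
    x_cg_aft_mean = mean(sweep$x_cg_aft),
    x_cg_norm_range = diff(range(sweep$x_cg_norm)),
    z_cg_norm_range = diff(range(sweep$z_cg_norm)),
    y_cg_wing_norm_range = diff(range(sweep$y_cg_wing_norm)),
    y_cg_wing_norm_max = max(sweep$y_cg_wing_norm),
    Ixx_fold = max(sweep$Ixx) / min(sweep$Ixx),
    Iyy_fold = max(sweep$Iyy) / min(sweep$Iyy),
    Izz_fold = max(sweep$Izz) / min(sweep$Izz),
    Ixx_wing_max = max(sweep$Ixx_wing),
    c_r_max = attr(sweep, "c_r_max") %||% max(sweep$root_chord),
    S_max = attr(sweep, "S_max") %||% max(sweep$wing_area)
  )
}
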