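# Closed-form mass properties for primitive solids and the rigid-body
# transform algebra (rotation, parallel axis, mass-weighted composition)
# used to assemble composite bodies.
#
# Sign convention: inertia tensors are stored as the dynamics matrix, i.e.
# the matrix that multiplies angular velocity. Diagonal entries are
# integral(y^2 + z^2) dm etc.; off-diagonal entries are -integral(xy) dm etc.
# All internal units are SI (kg, m); angles are degrees at user interfaces
# and radians internally.

PRIMITIVE_KINDS <- c(
  "solid_cylinder", "hollow_cylinder", "solid_frustum", "hollow_frustum_shell",
  "ellipsoid", "hemiellipsoid", "flat_plate", "point_mass"
)

#' Create a rigid transform
#'
#' A rigid transform maps coordinates in a shape's canonical frame into a
#' parent frame: `x_parent = R x_local + t`.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation numeric length-3 translation (m).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  check_rotation(rotation)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != 3L) || any(!is.finite(R))) {
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  invisible(R)
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis one of "x", "y", "z".
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

# Rotation taking the canonical +z axis onto unit vector `d` (minimal twist).
rotation_z_to <- function(d) {
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3], z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate pi about x
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Create a primitive shape
#'
#' Supported kinds and their `dims` entries (all lengths in metres), each in
#' its canonical frame:
#' * `solid_cylinder`: `radius`, `length`; axis +z, CG at the origin.
#' * `hollow_cylinder`: `radius_out`, `radius_in`, `length`; axis +z, CG at
#'   the origin.
#' * `solid_frustum`: `radius_base`, `radius_top`, `height`; base centre at
#'   the origin, axis +z. `radius_top` may be zero (cone).
#' * `hollow_frustum_shell`: `radius_base_out`, `radius_top_out`,
#'   `radius_base_in`, `radius_top_in`, `height`; as `solid_frustum` with the
#'   inner solid removed.
#' * `ellipsoid`: semi-axes `a`, `b`, `c` along x, y, z; centred at origin.
#' * `hemiellipsoid`: semi-axes `a`, `b`, `c`; flat face in the z = 0 plane,
#'   bulge towards +z.
#' * `flat_plate`: `vertices`, an n x 2 matrix of polygon vertices in the
#'   z = 0 plane (triangular or trapezoidal laminae in practice).
#' * `point_mass`: no dimensions.
#'
#' @param kind one of the catalogue names above.
#' @param mass shape mass (kg), non-negative.
#' @param dims named list of kind-specific dimensions.
#' @param pose [rigid_transform()] placing the canonical frame in the parent
#'   frame.
#' @param label optional component label.
#' @return An object of class `primitive_shape`.
#' @export
primitive_shape <- function(kind, mass, dims = list(),
                            pose = rigid_transform(), label = kind) {
  if (!kind %in% PRIMITIVE_KINDS) {
    stop("unknown primitive kind: ", kind, call. = FALSE)
  }
  if (!is.finite(mass) || mass < 0) stop("mass must be finite and >= 0", call. = FALSE)
  validate_dims(kind, dims)
  structure(list(kind = kind, mass = mass, dims = dims, pose = pose,
                 label = label),
            class = "primitive_shape")
}

validate_dims <- function(kind, dims) {
  need <- function(nms) {
    miss <- setdiff(nms, names(dims))
    if (length(miss)) stop("missing dimension(s) for ", kind, ": ",
                           paste(miss, collapse = ", "), call. = FALSE)
    vals <- unlist(dims[nms])
    if (any(!is.finite(vals))) stop("non-finite dimension for ", kind, call. = FALSE)
    vals
  }
  pos <- function(v) {
    if (any(v <= 0)) stop("dimensions must be strictly positive for ", kind, call. = FALSE)
  }
  switch(kind,
    solid_cylinder = pos(need(c("radius", "length"))),
    hollow_cylinder = {
      v <- need(c("radius_out", "radius_in", "length")); pos(v)
      if (dims$radius_in >= dims$radius_out) {
        stop("hollow_cylinder requires radius_in < radius_out", call. = FALSE)
      }
    },
    solid_frustum = {
      v <- need(c("radius_base", "radius_top", "height"))
      if (dims$radius_base <= 0 || dims$height <= 0 || dims$radius_top < 0) {
        stop("solid_frustum requires radius_base > 0, height > 0, radius_top >= 0",
             call. = FALSE)
      }
    },
    hollow_frustum_shell = {
      v <- need(c("radius_base_out", "radius_top_out", "radius_base_in",
                  "radius_top_in", "height"))
      if (any(v < 0) || dims$height <= 0 || dims$radius_base_out <= 0) {
        stop("hollow_frustum_shell dimensions invalid", call. = FALSE)
      }
      if (dims$radius_base_in >= dims$radius_base_out ||
          dims$radius_top_in > dims$radius_top_out) {
        stop("hollow_frustum_shell requires inner radii < outer radii", call. = FALSE)
      }
    },
    ellipsoid = pos(need(c("a", "b", "c"))),
    hemiellipsoid = pos(need(c("a", "b", "c"))),
    flat_plate = {
      vv <- dims$vertices
      if (is.null(vv) || !is.matrix(vv) || ncol(vv) != 2L || nrow(vv) < 3L ||
          any(!is.finite(vv))) {
        stop("flat_plate requires a finite n x 2 vertices matrix (n >= 3)", call. = FALSE)
      }
    },
    point_mass = invisible(NULL)
  )
  invisible(TRUE)
}

#' Construct mass properties
#'
#' @param mass mass (kg).
#' @param cg centre of gravity, length-3 (m), in frame `frame_id`.
#' @param inertia 3x3 inertia tensor (kg m^2) about `about_point`, dynamics
#'   sign convention.
#' @param frame_id,about_point labels recording the frame and reference point.
#' @return An object of class `mass_props`.
#' @export
mass_props <- function(mass, cg, inertia, frame_id = "parent",
                       about_point = "cg") {
  cg <- as.numeric(cg)
  inertia <- unname(as.matrix(inertia))
  stopifnot(mass >= 0, length(cg) == 3L, all(dim(inertia) == 3L))
  structure(list(mass = mass, cg = cg, inertia = inertia,
                 frame_id = frame_id, about_point = about_point),
            class = "mass_props")
}

#' @export
print.mass_props <- function(x, ...) {
  cat(sprintf("<mass_props> m = %.6g kg, frame '%s', inertia about %s\n",
              x$mass, x$frame_id, x$about_point))
  cat("  cg:", signif(x$cg, 6), "\n")
  print(signif(x$inertia, 6))
  invisible(x)
}

# Gauss-Legendre nodes on [0, 1], fixed at namespace build time; the
# integrands for solids of revolution with linear r(z) are polynomials of
# degree <= 6, which 8 nodes integrate exactly.
.gl8 <- pracma::gaussLegendre(8, 0, 1)

# exact integration of f on [0, h]
gl_int <- function(f, h) {
  h * sum(.gl8$w * f(h * .gl8$x))
}

# unit-density properties of a solid of revolution about +z on [0, h] with
# linear radius r(z): returns volume, first moment Sz, axial/transverse
# second moments about the base origin.
revolution_moments <- function(r1, r2, h) {
  z <- h * .gl8$x
  w <- h * .gl8$w
  r2z <- (r1 + (r2 - r1) * .gl8$x)^2
  r4z <- r2z^2
  V <- pi * sum(w * r2z)
  Sz <- pi * sum(w * r2z * z)
  Iz <- pi / 2 * sum(w * r4z)                      # about the axis
  Ix0 <- pi * sum(w * (r4z / 4 + r2z * z^2))       # about the base origin
  list(V = V, Sz = Sz, Iz = Iz, Ix0 = Ix0)
}

# polygon lamina properties (z = 0 plane): signed area, centroid and second
# area moments about the origin via the shoelace formulas. Orientation
# cancels because every moment is scaled by mass / signed area.
polygon_moments <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100) stop("degenerate polygon", call. = FALSE)
  cx <- sum((v[, 1] + v[j, 1]) * cr) / (6 * A)
  cy <- sum((v[, 2] + v[j, 2]) * cr) / (6 * A)
  Ix <- sum((v[, 2]^2 + v[, 2] * v[j, 2] + v[j, 2]^2) * cr) / 12     # int y^2 dA
  Iy <- sum((v[, 1]^2 + v[, 1] * v[j, 1] + v[j, 1]^2) * cr) / 12     # int x^2 dA
  Ixy <- sum((v[, 1] * v[j, 2] + 2 * v[, 1] * v[, 2] +
              2 * v[j, 1] * v[j, 2] + v[j, 1] * v[, 2]) * cr) / 24   # int xy dA
  list(A = A, cx = cx, cy = cy, Ix = Ix, Iy = Iy, Ixy = Ixy)
}

# closed-form mass properties in the canonical frame: list(cg, I_cg)
canonical_mass_props <- function(shape) {
  m <- shape$mass
  d <- shape$dims
  switch(shape$kind,
    point_mass = list(cg = c(0, 0, 0), I = matrix(0, 3, 3)),
    solid_cylinder = {
      r <- d$radius; l <- d$length
      Ia <- m * r^2 / 2
      It <- m * (3 * r^2 + l^2) / 12
      list(cg = c(0, 0, 0), I = diag(c(It, It, Ia)))
    },
    hollow_cylinder = {
      ro <- d$radius_out; ri <- d$radius_in; l <- d$length
      Ia <- m * (ro^2 + ri^2) / 2
      It <- m * (3 * (ro^2 + ri^2) + l^2) / 12
      list(cg = c(0, 0, 0), I = diag(c(It, It, Ia)))
    },
    solid_frustum = {
      mm <- revolution_moments(d$radius_base, d$radius_top, d$height)
      rho <- m / mm$V
      zc <- mm$Sz / mm$V
      Iz <- rho * mm$Iz
      Ix <- rho * mm$Ix0 - m * zc^2
      list(cg = c(0, 0, zc), I = diag(c(Ix, Ix, Iz)))
    },
    hollow_frustum_shell = {
      mo <- revolution_moments(d$radius_base_out, d$radius_top_out, d$height)
      mi <- revolution_moments(d$radius_base_in, d$radius_top_in, d$height)
      V <- mo$V - mi$V
      rho <- m / V
      zc <- (mo$Sz - mi$Sz) / V
      Iz <- rho * (mo$Iz - mi$Iz)
      Ix <- rho * (mo$Ix0 - mi$Ix0) - m * zc^2
      list(cg = c(0, 0, zc), I = diag(c(Ix, Ix, Iz)))
    },
    ellipsoid = {
      a <- d$a; b <- d$b; c_ <- d$c
      list(cg = c(0, 0, 0),
           I = diag(m / 5 * c(b^2 + c_^2, a^2 + c_^2, a^2 + b^2)))
    },
    hemiellipsoid = {
      a <- d$a; b <- d$b; c_ <- d$c
      # about the flat-face centre the per-mass integrals equal the full
      # ellipsoid's; shift down to the CG at z = 3c/8
      zc <- 3 * c_ / 8
      Ix <- m * (b^2 + c_^2) / 5 - m * zc^2
      Iy <- m * (a^2 + c_^2) / 5 - m * zc^2
      Iz <- m * (a^2 + b^2) / 5
      list(cg = c(0, 0, zc), I = diag(c(Ix, Iy, Iz)))
    },
    flat_plate = {
      pm <- polygon_moments(d$vertices)
      sig <- m / pm$A        # signed; moments below re-scale consistently
      Ixx <- sig * pm$Ix     # int y^2 dm (z = 0)
      Iyy <- sig * pm$Iy
      Pxy <- sig * pm$Ixy
      I0 <- matrix(c(Ixx, -Pxy, 0,
                     -Pxy, Iyy, 0,
                     0, 0, Ixx + Iyy), 3, 3)
      cg <- c(pm$cx, pm$cy, 0)
      # shift from origin moments to CG
      list(cg = cg, I = I0 - point_mass_inertia(m, cg))
    },
    stop("unknown primitive kind: ", shape$kind, call. = FALSE)
  )
}

# inertia of a point mass m at displacement r (about the origin)
point_mass_inertia <- function(m, r) {
  m * (sum(r^2) * diag(3) - tcrossprod(r))
}

#' Mass properties of a primitive shape
#'
#' Evaluates the closed-form centre of gravity and inertia tensor of a
#' primitive in its canonical frame, then maps the result through the shape's
#' pose into the parent frame. The returned inertia is about the shape's own
#' CG, expressed on parent-frame axes.
#'
#' @param shape a [primitive_shape()].
#' @return A [mass_props()] in the parent frame, about the shape CG.
#' @export
primitive_mass_properties <- function(shape) {
  stopifnot(inherits(shape, "primitive_shape"))
  cp <- canonical_mass_props(shape)
  R <- shape$pose$R
  cg <- as.numeric(R %*% cp$cg + shape$pose$t)
  I <- rotate_inertia(cp$I, R)
  mass_props(shape$mass, cg, I, frame_id = "parent", about_point = "cg")
}

#' Rotate an inertia tensor
#'
#' Re-expresses a tensor on rotated axes: `R I t(R)`. Trace and eigenvalues
#' are invariant.
#'
#' @param I 3x3 inertia tensor.
#' @param R 3x3 orthonormal rotation.
#' @return Rotated 3x3 tensor.
#' @export
rotate_inertia <- function(I, R) {
  check_rotation(R)
  R %*% I %*% t(R)
}

#' Parallel-axis shift of mass properties
#'
#' Transfers an inertia tensor from the body's CG to an arbitrary point in the
#' same frame. Mass and CG are unchanged; shifting back recovers the input.
#'
#' @param mp a [mass_props()] whose inertia is about its CG (or another
#'   reference point; the shift is algebraic either way, `from` names the
#'   current point).
#' @param new_point length-3 point (m) about which the inertia is wanted.
#' @param from length-3 point the current tensor is about; defaults to the CG.
#' @return A [mass_props()] about `new_point`.
#' @export
parallel_axis_shift <- function(mp, new_point, from = mp$cg) {
  stopifnot(inherits(mp, "mass_props"))
  new_point <- as.numeric(new_point)
  # generalised shift: go via the CG (Huygens-Steiner holds only CG <-> point)
  I_cg <- mp$inertia - point_mass_inertia(mp$mass, mp$cg - as.numeric(from))
  I_new <- I_cg + point_mass_inertia(mp$mass, mp$cg - new_point)
  mass_props(mp$mass, mp$cg, I_new, frame_id = mp$frame_id,
             about_point = "point")
}

#' Combine component mass properties
#'
#' Mass-weighted composition of rigid components expressed in one frame:
#' total mass is the exact sum, the CG is the mass-weighted mean, and the
#' inertia is the sum of each component tensor parallel-axis shifted to
#' `about_point` (default: the composite CG). The operation is associative
#' and permutation-invariant.
#'
#' @param parts list of [mass_props()] with inertia about each part's CG.
#' @param about_point length-3 point for the composite tensor, or `"cg"`.
#' @return A [mass_props()] for the composite.
#' @export
combine_components <- function(parts, about_point = "cg") {
  if (length(parts) == 0L) stop("no components to combine", call. = FALSE)
  stopifnot(all(vapply(parts, inherits, logical(1), "mass_props")))
  m <- vapply(parts, `[[`, numeric(1), "mass")
  M <- sum(m)
  if (M <= 0) stop("total mass must be positive", call. = FALSE)
  cgs <- vapply(parts, `[[`, numeric(3), "cg")
  cg <- as.numeric(cgs %*% m) / M
  pt <- if (identical(about_point, "cg")) cg else as.numeric(about_point)
  I <- matrix(0, 3, 3)
  for (i in seq_along(parts)) {
    I <- I + parts[[i]]$inertia + point_mass_inertia(m[i], cgs[, i] - pt)
  }
  mass_props(M, cg, I, frame_id = parts[[1]]$frame_id,
             about_point = if (identical(about_point, "cg")) "cg" else "point")
}

#' Validate an inertia tensor's physical invariants
#'
#' Checks symmetry, positive semidefiniteness and the triangle inequality
#' among the principal moments.
#'
#' @param I 3x3 tensor.
#' @param tol relative tolerance for the symmetry check.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
check_inertia <- function(I, tol = 1e-9) {
  s <- max(abs(I), 1e-300)
  if (max(abs(I - t(I))) > tol * s) stop("inertia tensor not symmetric", call. = FALSE)
  ev <- eigen((I + t(I)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * s) stop("inertia tensor not positive semidefinite", call. = FALSE)
  ev <- sort(ev)
  if (ev[3] > ev[1] + ev[2] + tol * s) {
    stop("principal moments violate the rigid-body triangle inequality", call. = FALSE)
  }
  invisible(TRUE)
}

#' Tidy a mass_props object
#'
#' @param x a [mass_props()].
#' @param ... unused.
#' @return One-row tibble with mass, CG components and the six independent
#'   tensor components.
#' @export
tidy.mass_props <- function(x, ...) {
  tibble::tibble(
    mass = x$mass,
    cg_x = x$cg[1], cg_y = x$cg[2], cg_z = x$cg[3],
    Ixx = x$inertia[1, 1], Iyy = x$inertia[2, 2], Izz = x$inertia[3, 3],
    Ixy = x$inertia[1, 2], Ixz = x$inertia[1, 3], Iyz = x$inertia[2, 3],
    frame_id = x$frame_id, about_point = x$about_point
  )
}
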