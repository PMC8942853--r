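# Independent oracles used across the suite.
#
# The Monte-Carlo mass-properties oracle approximates any primitive by a
# cloud of equal-mass sample points drawn uniformly inside the solid (or on
# the lamina), maps the points through the shape's pose, and accumulates
# point-mass sums. It shares no code with the closed-form path: no
# parallel-axis algebra, no tensor rotation, no composition.

mc_sample_canonical <- function(shape, n) {
  d <- shape$dims
  switch(shape$kind,
    point_mass = matrix(0, 1, 3),
    solid_cylinder = {
      p <- cbind(runif(n, -d$radius, d$radius), runif(n, -d$radius, d$radius),
                 runif(n, -d$length / 2, d$length / 2))
      p[p[, 1]^2 + p[, 2]^2 <= d$radius^2, , drop = FALSE]
    },
    hollow_cylinder = {
      p <- cbind(runif(n, -d$radius_out, d$radius_out),
                 runif(n, -d$radius_out, d$radius_out),
                 runif(n, -d$length / 2, d$length / 2))
      r2 <- p[, 1]^2 + p[, 2]^2
      p[r2 <= d$radius_out^2 & r2 >= d$radius_in^2, , drop = FALSE]
    },
    solid_frustum = {
      rmax <- max(d$radius_base, d$radius_top)
      p <- cbind(runif(n, -rmax, rmax), runif(n, -rmax, rmax),
                 runif(n, 0, d$height))
      rz <- d$radius_base + (d$radius_top - d$radius_base) * p[, 3] / d$height
      p[p[, 1]^2 + p[, 2]^2 <= rz^2, , drop = FALSE]
    },
    hollow_frustum_shell = {
      rmax <- max(d$radius_base_out, d$radius_top_out)
      p <- cbind(runif(n, -rmax, rmax), runif(n, -rmax, rmax),
                 runif(n, 0, d$height))
      ro <- d$radius_base_out + (d$radius_top_out - d$radius_base_out) * p[, 3] / d$height
      ri <- d$radius_base_in + (d$radius_top_in - d$radius_base_in) * p[, 3] / d$height
      r2 <- p[, 1]^2 + p[, 2]^2
      p[r2 <= ro^2 & r2 >= ri^2, , drop = FALSE]
    },
    ellipsoid = {
      p <- cbind(runif(n, -d$a, d$a), runif(n, -d$b, d$b), runif(n, -d$c, d$c))
      p[(p[, 1] / d$a)^2 + (p[, 2] / d$b)^2 + (p[, 3] / d$c)^2 <= 1, , drop = FALSE]
    },
    hemiellipsoid = {
      p <- cbind(runif(n, -d$a, d$a), runif(n, -d$b, d$b), runif(n, 0, d$c))
      p[(p[, 1] / d$a)^2 + (p[, 2] / d$b)^2 + (p[, 3] / d$c)^2 <= 1, , drop = FALSE]
    },
    flat_plate = {
      v <- d$vertices
      p <- cbind(runif(n, min(v[, 1]), max(v[, 1])),
                 runif(n, min(v[, 2]), max(v[, 2])))
      keep <- mgcv::in.out(rbind(v, v[1, ]), p)
      cbind(p[keep, , drop = FALSE], 0)
    },
    stop("oracle: unknown kind ", shape$kind)
  )
}

# world-frame point cloud for a shape
mc_points <- function(shape, n) {
  pts <- mc_sample_canonical(shape, n)
  if (nrow(pts) < 100 && shape$kind != "point_mass") {
    stop("oracle: too few accepted samples")
  }
  t(shape$pose$R %*% t(pts)) +
    matrix(shape$pose$t, nrow(pts), 3, byrow = TRUE)
}

# point-mass accumulation about `about` (or the cloud's own centroid)
mc_mass_props <- function(shapes, n = 1e6, about = NULL) {
  if (inherits(shapes, "primitive_shape")) shapes <- list(shapes)
  m <- vapply(shapes, `[[`, numeric(1), "mass")
  clouds <- lapply(shapes, mc_points, n = n)
  M <- sum(m)
  cg <- colSums(do.call(rbind, Map(function(p, mi) colMeans(p) * mi, clouds, m))) / M
  pt <- if (is.null(about)) cg else as.numeric(about)
  I <- matrix(0, 3, 3)
  for (k in seq_along(clouds)) {
    p <- sweep(clouds[[k]], 2, pt)
    w <- m[k] / nrow(p)
    r2 <- rowSums(p^2)
    I <- I + w * (sum(r2) * diag(3) - crossprod(p))
  }
  list(mass = M, cg = cg, inertia = I)
}

# componentwise tensor difference relative to the largest principal moment
rel_tensor_err <- function(I1, I2) {
  scale <- max(abs(diag(I2)))
  max(abs(I1 - I2)) / scale
}

expect_tensor_close <- function(I1, I2, tol = 0.005) {
  expect_lt(rel_tensor_err(I1, I2), tol)
}

# random rotation via QR of a Gaussian matrix (det +1 enforced)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_shape <- function(kind = NULL, posed = TRUE) {
  kinds <- c("solid_cylinder", "hollow_cylinder", "solid_frustum",
             "hollow_frustum_shell", "ellipsoid", "hemiellipsoid", "flat_plate")
  if (is.null(kind)) kind <- sample(kinds, 1)
  u <- function(a, b) runif(1, a, b)
  dims <- switch(kind,
    solid_cylinder = list(radius = u(0.02, 0.2), length = u(0.05, 0.5)),
    hollow_cylinder = {
      ro <- u(0.05, 0.2); list(radius_out = ro, radius_in = u(0.3, 0.9) * ro,
                               length = u(0.05, 0.5))
    },
    solid_frustum = list(radius_base = u(0.05, 0.2), radius_top = u(0, 0.15),
                         height = u(0.05, 0.5)),
    hollow_frustum_shell = {
      rb <- u(0.08, 0.2); rt <- u(0.03, 0.1)
      list(radius_base_out = rb, radius_top_out = rt,
           radius_base_in = 0.6 * rb, radius_top_in = 0.6 * rt,
           height = u(0.05, 0.5))
    },
    ellipsoid = list(a = u(0.02, 0.2), b = u(0.02, 0.2), c = u(0.02, 0.2)),
    hemiellipsoid = list(a = u(0.02, 0.2), b = u(0.02, 0.2), c = u(0.02, 0.2)),
    flat_plate = list(vertices = {
      # simple star-shaped quadrilateral: spread angles guarantee no
      # self-intersection
      th <- 2 * pi * (0:3) / 4 + runif(4, -0.6, 0.6)
      r <- runif(4, 0.05, 0.3)
      cbind(r * cos(th), r * sin(th)) +
        matrix(runif(2, -0.1, 0.1), 4, 2, byrow = TRUE)
    })
  )
  pose <- if (posed) {
    rigid_transform(random_rotation(), runif(3, -0.3, 0.3))
  } else {
    rigid_transform()
  }
  primitive_shape(kind, mass = u(0.1, 2), dims = dims, pose = pose)
}

# quadratic-time hull-edge oracle: (i, j) is a hull edge iff every other
# point lies on one side of the directed line i -> j
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pts[j, ] - pts[i, ]
      cr <- d[1] * (pts[, 2] - pts[i, 2]) - d[2] * (pts[, 1] - pts[i, 1])
      if (all(cr >= -1e-9) || all(cr <= 1e-9)) {
        on_hull[i] <- TRUE
        on_hull[j] <- TRUE
      }
    }
  }
  pts[on_hull, , drop = FALSE]
}

# law-of-cosines interior angle oracle
loc_angle <- function(p_a, v, p_b) {
  a <- sqrt(sum((p_a - v)^2))
  b <- sqrt(sum((p_b - v)^2))
  cc <- sqrt(sum((p_a - p_b)^2))
  acos((a^2 + b^2 - cc^2) / (2 * a * b)) * 180 / pi
}
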