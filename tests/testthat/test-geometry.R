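# Closed-form primitive mass properties and the transform algebra.

test_that("textbook closed forms hold for cylinders and point masses", {
  cyl <- primitive_shape("solid_cylinder", 1, list(radius = 0.1, length = 0.3))
  mp <- primitive_mass_properties(cyl)
  expect_equal(mp$inertia[3, 3], 0.005)                      # 1/2 m r^2
  expect_equal(mp$inertia[1, 1], (3 * 0.01 + 0.09) / 12)     # m(3r^2+l^2)/12
  expect_equal(mp$inertia[2, 2], 0.01)
  expect_equal(mp$cg, c(0, 0, 0))

  pm <- primitive_mass_properties(primitive_shape("point_mass", 2))
  expect_equal(pm$inertia, matrix(0, 3, 3))
  expect_equal(pm$cg, c(0, 0, 0))
  expect_equal(pm$mass, 2)
})

test_that("every primitive matches the Monte-Carlo point-cloud oracle", {
  set.seed(101)
  kinds <- setdiff(avimorph:::PRIMITIVE_KINDS, "point_mass")
  for (k in kinds) {
    s <- random_shape(k)
    cf <- primitive_mass_properties(s)
    mc <- mc_mass_props(s, 2e5)
    scale <- max(sqrt(diag(cf$inertia) / cf$mass))  # gyration radius
    expect_lt(max(abs(cf$cg - mc$cg)), 0.01 * scale)
    # Monte-Carlo noise at 2e5 samples; the strict 0.5% check at 1e6 samples
    # lives in the acceptance suite
    expect_tensor_close(mc$inertia, cf$inertia, tol = 0.01)
    expect_equal(mc$mass, cf$mass)
  }
})

test_that("invalid shapes are rejected with informative errors", {
  expect_error(primitive_shape("torus", 1), "unknown primitive kind")
  expect_error(primitive_shape("solid_cylinder", 1,
                               list(radius = -0.1, length = 0.3)),
               "strictly positive")
  expect_error(primitive_shape("hollow_cylinder", 1,
                               list(radius_out = 0.1, radius_in = 0.2,
                                    length = 0.3)),
               "radius_in < radius_out")
  expect_error(primitive_shape("solid_cylinder", -1,
                               list(radius = 0.1, length = 0.3)),
               "mass")
  expect_error(primitive_shape("flat_plate", 1,
                               list(vertices = matrix(0, 2, 2))),
               "vertices")
})

test_that("parallel-axis shift follows md^2 and round-trips exactly", {
  pm <- mass_props(2, c(0, 0, 0), matrix(0, 3, 3))
  shifted <- parallel_axis_shift(pm, c(1, 0, 0))
  expect_equal(shifted$inertia, diag(c(0, 2, 2)))
  expect_equal(shifted$cg, pm$cg)
  expect_equal(shifted$mass, pm$mass)

  # zero shift is the identity
  expect_equal(parallel_axis_shift(pm, c(0, 0, 0))$inertia, pm$inertia)

  set.seed(7)
  for (i in 1:20) {
    s <- random_shape()
    mp <- primitive_mass_properties(s)
    p <- runif(3, -1, 1)
    back <- parallel_axis_shift(parallel_axis_shift(mp, p), mp$cg, from = p)
    expect_lt(rel_tensor_err(back$inertia, mp$inertia), 1e-12)
  }
})

test_that("shifted tensors agree with the oracle about the same point", {
  set.seed(8)
  s <- random_shape()
  p <- c(0.2, -0.1, 0.15)
  mp <- parallel_axis_shift(primitive_mass_properties(s), p)
  mc <- mc_mass_props(s, 1e6, about = p)
  expect_tensor_close(mc$inertia, mp$inertia, tol = 0.005)
})

test_that("rotation preserves eigenvalues and composes to the identity", {
  I <- diag(c(1, 2, 3))
  expect_equal(rotate_inertia(I, diag(3)), I)

  # 90 degrees about z swaps Ixx and Iyy when Ixy = 0
  Rz <- rotation_about("z", 90)
  expect_equal(diag(rotate_inertia(I, Rz)), c(2, 1, 3))

  set.seed(9)
  for (i in 1:50) {
    R <- random_rotation()
    s <- random_shape()
    I <- primitive_mass_properties(s)$inertia
    Ir <- rotate_inertia(I, R)
    ev0 <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
    ev1 <- sort(eigen(Ir, symmetric = TRUE, only.values = TRUE)$values)
    expect_lt(max(abs(ev0 - ev1)) / max(ev0), 1e-10)
    expect_lt(abs(sum(diag(Ir)) - sum(diag(I))) / sum(diag(I)), 1e-10)
    back <- rotate_inertia(Ir, t(R))
    expect_lt(rel_tensor_err(back, I), 1e-10)
  }
  expect_error(rotate_inertia(I, matrix(1, 3, 3)), "orthonormal")
})

test_that("combination conserves mass, CG and matches hand examples", {
  p1 <- mass_props(1, c(1, 0, 0), matrix(0, 3, 3))
  p2 <- mass_props(1, c(-1, 0, 0), matrix(0, 3, 3))
  comb <- combine_components(list(p1, p2))
  expect_equal(comb$mass, 2)
  expect_equal(comb$cg, c(0, 0, 0))
  expect_equal(comb$inertia, diag(c(0, 2, 2)))

  # single part is the identity
  one <- combine_components(list(p1))
  expect_equal(one$cg, p1$cg)
  expect_equal(one$inertia, p1$inertia)

  expect_error(combine_components(list()), "no components")
  zero <- mass_props(0, c(0, 0, 0), matrix(0, 3, 3))
  expect_error(combine_components(list(zero, zero)), "total mass")
})

test_that("combination is associative and permutation-invariant", {
  set.seed(10)
  parts <- lapply(1:8, function(i) primitive_mass_properties(random_shape()))
  ref <- combine_components(parts)
  # grouped: combine first half about its CG, then with the rest
  gA <- combine_components(parts[1:4])
  gB <- combine_components(parts[5:8])
  grouped <- combine_components(list(gA, gB))
  expect_equal(grouped$mass, ref$mass)
  expect_lt(max(abs(grouped$cg - ref$cg)), 1e-12)
  expect_lt(rel_tensor_err(grouped$inertia, ref$inertia), 1e-12)
  shuffled <- combine_components(parts[sample(8)])
  expect_lt(rel_tensor_err(shuffled$inertia, ref$inertia), 1e-12)
})

test_that("a composite of random solids matches the pooled oracle", {
  set.seed(11)
  shapes <- lapply(1:10, function(i) random_shape())
  parts <- lapply(shapes, primitive_mass_properties)
  comb <- combine_components(parts, about_point = c(0, 0, 0))
  mc <- mc_mass_props(shapes, 2e5, about = c(0, 0, 0))
  expect_equal(mc$mass, comb$mass)
  expect_tensor_close(mc$inertia, comb$inertia, tol = 0.005)
})

test_that("tensors satisfy rigid-body invariants and CG-minimal trace", {
  set.seed(12)
  for (i in 1:20) {
    mp <- primitive_mass_properties(random_shape())
    expect_true(check_inertia(mp$inertia))
    tr_cg <- sum(diag(mp$inertia))
    for (j in 1:5) {
      p <- mp$cg + runif(3, -0.5, 0.5)
      tr_p <- sum(diag(parallel_axis_shift(mp, p)$inertia))
      expect_gte(tr_p, tr_cg)
    }
  }
})
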