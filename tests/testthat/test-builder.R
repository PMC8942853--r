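# Feather, wing, body and whole-bird assembly.

test_that("a feather is five shapes whose masses sum exactly", {
  g <- test_specimen()
  f1 <- g$feathers[1, ]
  shapes <- build_feather(f1)
  expect_length(shapes, 5)
  expect_equal(sum(vapply(shapes, `[[`, numeric(1), "mass")), f1$mass)

  bad <- f1
  bad$frac_calamus <- bad$frac_calamus + 0.1
  expect_error(build_feather(bad), "sum to 1")
})

test_that("vanishing vane widths remove the vanes' spanwise contribution", {
  g <- test_specimen()
  f1 <- as.list(g$feathers[1, ])
  thin <- f1
  thin$width_vane_proximal <- 1e-9
  thin$width_vane_distal <- 1e-9
  shapes <- build_feather(thin)
  # about the shaft axis (canonical z) the lamina second moments vanish
  about_axis <- combine_components(lapply(shapes, primitive_mass_properties),
                                   about_point = c(0, 0, 0))$inertia[3, 3]
  shaft_only <- combine_components(lapply(shapes[1:3], primitive_mass_properties),
                                   about_point = c(0, 0, 0))$inertia[3, 3]
  expect_lt(abs(about_axis - shaft_only) / about_axis, 1e-6)
})

test_that("a feather composite matches the point-cloud oracle", {
  set.seed(20)
  g <- test_specimen()
  shapes <- build_feather(g$feathers[3, ],
                          rigid_transform(random_rotation(), c(0.1, 0.2, 0)))
  cf <- combine_components(lapply(shapes, primitive_mass_properties))
  mc <- mc_mass_props(shapes, 4e5)
  expect_tensor_close(mc$inertia, cf$inertia, tol = 0.005)
})

test_that("a wing has 12 + 5(nP + nS) shapes and honours wrist alignment", {
  g <- test_specimen()
  fe <- g$feathers[g$feathers$specimen_id == g$morphology$specimen_id, ]
  w <- build_wing(g$morphology, fe, elbow = 120, wrist = 140)
  expect_length(w$shapes, 12 + 5 * 20)
  expect_lt(abs(w$W[1]), 1e-9)          # wrist in line with the shoulder in x
  expect_lt(abs(w$W[3]), 1e-9)          # and in z
  expect_equal(w$mass,
               sum(fe$mass) + g$morphology$mass_humerus + g$morphology$mass_radius +
                 g$morphology$mass_ulna + g$morphology$mass_carpometacarpus +
                 g$morphology$mass_radiale + g$morphology$mass_ulnare +
                 g$morphology$mass_muscle_brachial +
                 g$morphology$mass_muscle_antebrachial +
                 g$morphology$mass_muscle_manus + g$morphology$mass_skin +
                 g$morphology$mass_coverts + g$morphology$mass_tertiaries)

  m2 <- g$morphology
  m2$mass_ulna <- NA
  expect_error(build_wing(m2, fe, 120, 140), "mass_ulna")
  expect_error(build_wing(g$morphology, fe, 0, 140), "elbow and wrist")
})

test_that("extension moves the wing CG distally and raises roll inertia", {
  g <- test_specimen()
  wrists <- seq(80, 160, by = 20)
  res <- lapply(wrists, function(wr) {
    wing_mass_properties_about_shoulder(g$morphology, g$feathers, 150, wr)
  })
  ycg <- vapply(res, `[[`, numeric(1), "y_cg_wing")
  ixx <- vapply(res, `[[`, numeric(1), "Ixx_wing")
  expect_true(all(diff(abs(ycg)) > 0))
  expect_true(all(diff(ixx) > 0))
  folded <- wing_mass_properties_about_shoulder(g$morphology, g$feathers, 60, 70)
  expect_lt(folded$Ixx_wing, min(ixx))
})

test_that("wing tensors about the humeral head match the oracle", {
  set.seed(21)
  g <- test_specimen()
  w <- build_wing(g$morphology, g$feathers, 130, 150)
  cf <- combine_components(lapply(w$shapes, primitive_mass_properties),
                           about_point = c(0, 0, 0))
  mc <- mc_mass_props(w$shapes, 5e4, about = c(0, 0, 0))
  expect_tensor_close(mc$inertia, cf$inertia, tol = 0.005)
})

test_that("the body is 8 shapes and reproduces the measured torso CG", {
  g <- test_specimen()
  b <- build_body(g$morphology)
  expect_length(b$shapes, 8)
  torso <- combine_components(
    lapply(b$shapes[1:3], primitive_mass_properties))
  expect_lt(abs(torso$cg[1] - g$morphology$torso_cg_x), 1e-6)
  expect_lt(abs(torso$cg[3] - g$morphology$torso_cg_z), 1e-6)
  expect_equal(sum(b$torso_section_masses), g$morphology$mass_torso)

  infeasible <- g$morphology
  infeasible$torso_cg_x <- -0.9 * infeasible$length_torso
  expect_error(build_body(infeasible), "feasible range")
})

test_that("the body composite matches the point-cloud oracle", {
  set.seed(22)
  g <- test_specimen()
  b <- build_body(g$morphology)
  cf <- combine_components(lapply(b$shapes, primitive_mass_properties))
  mc <- mc_mass_props(b$shapes, 3e5)
  expect_tensor_close(mc$inertia, cf$inertia, tol = 0.005)
})

test_that("shape counts follow 8 + 2(12 + 5(nP + nS)) for any feather count", {
  g <- generate_specimen(synthetic_config(seed = 5, n_species = 4), 2)
  model <- assemble_bird(g$morphology, g$feathers, 120, 140)
  expect_identical(nrow(model), 232L)

  g9 <- generate_specimen(synthetic_config(seed = 5, n_species = 4,
                                           n_primaries = 9), 2)
  model9 <- assemble_bird(g9$morphology, g9$feathers, 120, 140)
  expect_identical(nrow(model9), 222L)

  right_only <- assemble_bird(g$morphology, g$feathers, 120, 140,
                              symmetric = FALSE)
  expect_identical(nrow(right_only), 120L)
})

test_that("symmetric models have mirror symmetry and exact total mass", {
  g <- test_specimen()
  model <- assemble_bird(g$morphology, g$feathers, 110, 125)
  props <- bird_mass_properties(model)
  expect_equal(props$mass, g$morphology$mass_total)
  tr <- props$Ixx + props$Iyy + props$Izz
  expect_lt(abs(props$cg_y), 1e-12)
  expect_lt(abs(props$Ixy), 1e-10 * tr)
  expect_lt(abs(props$Iyz), 1e-10 * tr)

  # mirrored-wing CG y components cancel pairwise
  r_cg <- sapply(model$shape[model$side == "right"],
                 function(s) primitive_mass_properties(s)$cg[2])
  l_cg <- sapply(model$shape[model$side == "left"],
                 function(s) primitive_mass_properties(s)$cg[2])
  expect_lt(max(abs(r_cg + l_cg)), 1e-12)
})

test_that("mirroring the whole bird preserves I diag and Ixz, flips Ixy, Iyz", {
  g <- test_specimen()
  model <- assemble_bird(g$morphology, g$feathers, 100, 150)
  mp <- attr(bird_mass_properties(model), "mass_props")
  mirrored <- combine_components(lapply(model$shape, function(s) {
    primitive_mass_properties(avimorph:::mirror_shape(s))
  }))
  expect_equal(diag(mirrored$inertia), diag(mp$inertia), tolerance = 1e-10)
  expect_equal(mirrored$inertia[1, 3], mp$inertia[1, 3], tolerance = 1e-10)
  expect_equal(mirrored$inertia[1, 2], -mp$inertia[1, 2], tolerance = 1e-10)
  expect_equal(mirrored$inertia[2, 3], -mp$inertia[2, 3], tolerance = 1e-10)
})

test_that("the full 232-shape composite matches the point-cloud oracle", {
  set.seed(23)
  g <- test_specimen()
  model <- assemble_bird(g$morphology, g$feathers, 130, 150)
  cf <- attr(bird_mass_properties(model), "mass_props")
  mc <- mc_mass_props(model$shape, 3e4)
  expect_equal(mc$mass, cf$mass)
  expect_lt(max(abs(mc$cg - cf$cg)), 2e-4)
  expect_tensor_close(mc$inertia, cf$inertia, tol = 0.005)
})

test_that("mass reconciliation absorbs small residuals and rejects large ones", {
  g <- test_specimen()
  m <- g$morphology
  wing_mass <- build_wing(m, g$feathers, 120, 140)$mass
  expect_equal(reconcile_mass(m, wing_mass), m$mass_torso)

  m_off <- m
  m_off$mass_total <- m$mass_total * 1.01      # within the 2% tolerance
  adj <- reconcile_mass(m_off, wing_mass)
  expect_equal(adj, m$mass_torso + 0.01 * m$mass_total)

  m_bad <- m
  m_bad$mass_total <- m$mass_total * 1.1
  expect_error(reconcile_mass(m_bad, wing_mass), "tolerance")
})

test_that("shoulder rotations bound the elbow/wrist CG range", {
  g <- test_specimen()
  env <- shoulder_cg_envelope(g$morphology, g$feathers, 150, 160)
  sw <- test_sweep()
  expect_gte(max(env$x_cg_norm) + 1e-12, max(sw$x_cg_norm))
  expect_lte(min(env$x_cg_norm) - 1e-12, min(sw$x_cg_norm))
  expect_gt(attr(env, "dx_norm"), diff(range(sw$x_cg_norm)))

  # zero-mass wings leave the CG fixed: zero envelope
  m0 <- g$morphology
  wing_cols <- grep("^mass_", avimorph:::WING_FIELDS, value = TRUE)
  for (cc in wing_cols) m0[[cc]] <- 0
  f0 <- g$feathers
  f0$mass <- 0
  m0$mass_total <- m0$mass_head + m0$mass_neck + m0$mass_torso +
    m0$mass_legs + m0$mass_tail
  env0 <- shoulder_cg_envelope(m0, f0, 150, 160)
  expect_lt(attr(env0, "dx_norm"), 1e-12)
  expect_lt(attr(env0, "dz_norm"), 1e-12)
})
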