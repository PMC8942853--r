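# Seeded generators for synthetic specimens, marker traces, trees and
# traits. The cohort emulates the data shapes the pipeline consumes: a
# morphology table (one row per specimen), a feather table (one row per
# flight feather), per-specimen elbow/wrist ROM hulls and marker traces, an
# ultrametric phylogeny and species trait tables. Allometry is isometric by
# construction (lengths ~ mass^(1/3), areas ~ mass^(2/3)) with lognormal
# species scatter, so the allometric analyses have known null slopes.

#' Configuration for the synthetic cohort
#'
#' @param seed integer seed; all downstream draws derive from it.
#' @param n_species number of species.
#' @param specimens_per_species specimens per species (recycled).
#' @param mass_range body-mass range (kg), sampled log-uniformly across
#'   species.
#' @param length_exponent,area_exponent allometric exponents for lengths and
#'   areas.
#' @param species_cv lognormal coefficient of variation of species-level
#'   deviations from isometry.
#' @param n_primaries,n_secondaries flight-feather counts.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_species = 22,
                             specimens_per_species = 2,
                             mass_range = c(0.02, 3),
                             length_exponent = 1 / 3, area_exponent = 2 / 3,
                             species_cv = 0.12,
                             n_primaries = 10, n_secondaries = 10) {
  stopifnot(all(mass_range > 0), n_species >= 3)
  structure(as.list(environment()), class = "synthetic_config")
}

species_name <- function(i) sprintf("species_%02d", i)

#' Generate one synthetic specimen
#'
#' Component masses sum exactly to the total mass; all lengths scale
#' isometrically with species mass; the torso balance point is placed inside
#' the range reachable by the torso mass partition.
#'
#' @param config a [synthetic_config()].
#' @param species_index species number in `1:n_species`.
#' @param specimen_rep replicate number within the species.
#' @return list with one-row tibble `morphology` and tibble `feathers`.
#' @export
generate_specimen <- function(config, species_index, specimen_rep = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed * 10000L + species_index * 100L + specimen_rep)
  lm_range <- log(config$mass_range)
  # species masses log-spaced across the range, individuals jittered
  lmass <- lm_range[1] + (species_index - 1) / max(config$n_species - 1, 1) *
    diff(lm_range)
  mass <- exp(lmass + stats::rnorm(1, 0, 0.05))
  le <- config$length_exponent
  jit <- function(cv) exp(stats::rnorm(1, 0, cv))
  sc <- jit(config$species_cv)          # shared species-level size deviation

  wingspan <- 1.05 * mass^le * sc
  length_body <- 0.42 * mass^le * sc
  L_t <- 0.45 * length_body
  w_t <- 0.36 * L_t * jit(0.05)
  h_t <- 0.9 * w_t
  half <- wingspan / 2

  nP <- config$n_primaries; nS <- config$n_secondaries
  # component mass fractions, jittered then renormalized so sums are exact
  fr <- c(torso = 0.48, head = 0.07, neck = 0.05, legs = 0.10, tail = 0.015,
          wings = 0.285)
  fr <- fr * exp(stats::rnorm(length(fr), 0, 0.05))
  fr <- fr / sum(fr)
  m_wing <- fr[["wings"]] * mass / 2

  # single-wing internal split; the feather pool absorbs the remainder
  wfr <- c(humerus = 0.13, radius = 0.035, ulna = 0.08, carpometacarpus = 0.045,
           radiale = 0.003, ulnare = 0.003, brachial = 0.20,
           antebrachial = 0.11, manus = 0.02, skin = 0.06, coverts = 0.045,
           tertiaries = 0.025)
  m_feathers <- m_wing * (1 - sum(wfr))

  l_hum <- 0.18 * half; l_uln <- 0.22 * half; l_cmc <- 0.15 * half
  prim_len <- (0.60 + 0.40 * (seq_len(nP) / nP)) * 0.38 * half
  sec_len <- rep(0.30 * half, nS) * exp(stats::rnorm(nS, 0, 0.02))
  all_len <- c(prim_len, sec_len)
  fm <- m_feathers * all_len^2 / sum(all_len^2)

  feather_row <- function(id, type, len, m) {
    lc <- 0.2 * len; lr <- 0.8 * len
    tibble::tibble(
      feather_id = id, type = type, mass = m,
      length_calamus = lc, length_rachis = lr,
      radius_calamus = 0.004 * sqrt(len / 0.25),
      width_vane_proximal = 0.18 * len, width_vane_distal = 0.12 * len,
      length_vane_proximal = 0.45 * lr, length_vane_distal = 0.55 * lr,
      frac_calamus = 0.08, frac_rachis_cortex = 0.28,
      frac_rachis_medulla = 0.06, frac_vane_proximal = 0.30,
      frac_vane_distal = 0.28
    )
  }
  feathers <- dplyr::bind_rows(
    purrr::map(seq_len(nP), function(i)
      feather_row(sprintf("P%02d", i), "primary", prim_len[i], fm[i])),
    purrr::map(seq_len(nS), function(i)
      feather_row(sprintf("S%02d", i), "secondary", sec_len[i], fm[nP + i]))
  )
  specimen_id <- sprintf("%s_%d", species_name(species_index), specimen_rep)
  feathers <- dplyr::bind_cols(tibble::tibble(specimen_id = specimen_id),
                               feathers)

  morphology <- tibble::tibble(
    species = species_name(species_index),
    specimen_id = specimen_id,
    mass_total = mass,
    wingspan = wingspan,
    length_body = length_body,
    mass_head = fr[["head"]] * mass, length_head = 0.16 * length_body,
    width_head = 0.10 * length_body,
    mass_neck = fr[["neck"]] * mass, length_neck = 0.25 * length_body,
    radius_neck = 0.035 * length_body,
    mass_torso = fr[["torso"]] * mass, length_torso = L_t,
    width_torso = w_t, height_torso = h_t,
    torso_cg_x = -(0.40 + stats::runif(1, -0.025, 0.025)) * L_t,
    torso_cg_z = -0.02 * L_t,
    mass_legs = fr[["legs"]] * mass, length_leg = 0.35 * L_t,
    radius_leg = 0.04 * L_t,
    mass_tail = fr[["tail"]] * mass, length_tail = 0.30 * length_body,
    width_tail_root = 0.8 * w_t, width_tail_tip = 1.2 * w_t,
    mass_humerus = wfr[["humerus"]] * m_wing, length_humerus = l_hum,
    mass_radius = wfr[["radius"]] * m_wing, length_radius = l_uln,
    mass_ulna = wfr[["ulna"]] * m_wing, length_ulna = l_uln,
    mass_carpometacarpus = wfr[["carpometacarpus"]] * m_wing,
    length_carpometacarpus = l_cmc,
    mass_radiale = wfr[["radiale"]] * m_wing,
    mass_ulnare = wfr[["ulnare"]] * m_wing,
    mass_muscle_brachial = wfr[["brachial"]] * m_wing,
    mass_muscle_antebrachial = wfr[["antebrachial"]] * m_wing,
    mass_muscle_manus = wfr[["manus"]] * m_wing,
    mass_skin = wfr[["skin"]] * m_wing,
    mass_coverts = wfr[["coverts"]] * m_wing,
    mass_tertiaries = wfr[["tertiaries"]] * m_wing,
    n_primaries = nP, n_secondaries = nS,
    estimated_fields = ""
  )
  list(morphology = morphology, feathers = feathers)
}

#' Generate the full synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @return list with `morphology` (one row per specimen), `feathers` and
#'   `hulls` (one [rom_hull()] per specimen, named by specimen id).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  reps <- rep_len(config$specimens_per_species, config$n_species)
  out <- purrr::flatten(purrr::map(seq_len(config$n_species), function(i) {
    purrr::map(seq_len(reps[i]), function(j) generate_specimen(config, i, j))
  }))
  morphology <- dplyr::bind_rows(purrr::map(out, "morphology"))
  feathers <- dplyr::bind_rows(purrr::map(out, "feathers"))
  hulls <- purrr::map(seq_len(nrow(morphology)), function(k) {
    generate_rom_hull(config, k)
  })
  names(hulls) <- morphology$specimen_id
  list(morphology = morphology, feathers = feathers, hulls = hulls)
}

#' Generate a specimen's elbow-wrist ROM hull
#'
#' A convex pentagon in (elbow, wrist) space with mild per-specimen jitter,
#' spanning roughly 55-150 degrees of elbow and 60-165 degrees of wrist
#' extension.
#'
#' @param config a [synthetic_config()].
#' @param index specimen index (seeds the jitter).
#' @return a [rom_hull()].
#' @export
generate_rom_hull <- function(config, index = 1) {
  set.seed(config$seed * 1000L + 7L * index)
  j <- function() stats::runif(1, -4, 4)
  v <- rbind(
    c(55 + j(), 62 + j()),
    c(150 + j(), 72 + j()),
    c(152 + j(), 165 + j()),
    c(78 + j(), 167 + j()),
    c(56 + j(), 135 + j())
  )
  rom_hull(tibble::tibble(elbow = v[, 1], wrist = v[, 2]))
}

#' Generate a synthetic motion-capture marker trace
#'
#' Builds planar four-marker chains (markers 1-4: shoulder, elbow, wrist,
#' hand tip) whose interior angles at markers 2 and 3 reproduce prescribed
#' (elbow, wrist) pairs drawn from a hull (its vertices are always visited),
#' plus six filler markers, under a random rigid motion per frame and
#' optional Gaussian marker noise.
#'
#' @param specimen one-row morphology tibble (bone lengths set the segment
#'   lengths).
#' @param hull a [rom_hull()] prescribing the angles.
#' @param n_frames number of frames.
#' @param noise_sd marker noise standard deviation (m), e.g. 5e-4.
#' @param seed integer seed.
#' @return tibble with columns `frame`, `marker`, `x`, `y`, `z`.
#' @export
generate_rom_trace <- function(specimen, hull, n_frames = 100,
                               noise_sd = 0, seed = 1) {
  set.seed(seed)
  sp <- as.list(specimen)
  lens <- c(sp$length_humerus, sp$length_ulna, sp$length_carpometacarpus)
  hv <- as.matrix(hull[, c("elbow", "wrist")])
  pts <- hv
  while (nrow(pts) < n_frames) {
    cand <- cbind(stats::runif(n_frames, min(hv[, 1]), max(hv[, 1])),
                  stats::runif(n_frames, min(hv[, 2]), max(hv[, 2])))
    keep <- mgcv::in.out(rbind(hv, hv[1, ]), cand)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n_frames), , drop = FALSE]

  rows <- purrr::map(seq_len(n_frames), function(f) {
    th_e <- pts[f, 1] * pi / 180
    th_w <- pts[f, 2] * pi / 180
    rot2 <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                              sin(th) * v[1] + cos(th) * v[2], 0)
    d1 <- c(1, 0, 0)
    p1 <- c(0, 0, 0); p2 <- p1 + lens[1] * d1
    d2 <- rot2(-d1, th_e)
    p3 <- p2 + lens[2] * d2
    d4 <- rot2(-d2, th_w)
    p4 <- p3 + lens[3] * d4
    extras <- lapply(1:6, function(k) p2 + k / 7 * (p3 - p2) + c(0, 0, 0.002 * k))
    pm <- rbind(p1, p2, p3, p4, do.call(rbind, extras))
    # random rigid motion: angles are invariant to it
    ang <- stats::runif(3, 0, 2 * pi)
    R <- rotation_about("z", ang[1] * 180 / pi) %*%
      rotation_about("y", ang[2] * 180 / pi) %*%
      rotation_about("x", ang[3] * 180 / pi)
    tr <- stats::runif(3, -0.5, 0.5)
    pm <- t(R %*% t(pm)) + matrix(tr, nrow(pm), 3, byrow = TRUE)
    if (noise_sd > 0) pm <- pm + stats::rnorm(length(pm), 0, noise_sd)
    tibble::tibble(frame = f, marker = seq_len(10),
                   x = pm[, 1], y = pm[, 2], z = pm[, 3])
  })
  dplyr::bind_rows(rows)
}

#' Generate an ultrametric tree and simulated traits
#'
#' The tree is pure-birth (Yule) and rescaled to unit height. Traits are
#' simulated from the exact Gaussian covariance of the requested model --
#' the same covariance the likelihood functions use -- so recovery tests are
#' internally consistent. `alpha = 0` routes to the BM simulator.
#'
#' @param config a [synthetic_config()] (supplies the seed and species
#'   count).
#' @param model `"BM"` or `"OU"`.
#' @param params named parameters: BM `sigma2`, `z0`; OU `alpha`, `sigma2`,
#'   `theta`.
#' @param n_traits number of independent replicate traits to simulate.
#' @return list with `tree` (class `phylo`, tips named as the cohort
#'   species) and `traits` (matrix, tips x replicates).
#' @export
generate_tree_and_traits <- function(config,
                                     model = c("BM", "OU"),
                                     params = c(sigma2 = 1, z0 = 0),
                                     n_traits = 1) {
  model <- match.arg(model)
  set.seed(config$seed + 999L)
  n <- config$n_species
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- species_name(seq_len(n))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tt <- tree_times(tree)
  if (model == "OU" && params[["alpha"]] <= 0) model <- "BM"
  if (model == "BM") {
    V <- params[["sigma2"]] * tt$C
    mu <- if ("z0" %in% names(params)) params[["z0"]] else params[["theta"]]
  } else {
    V <- params[["sigma2"]] * ou_correlation(params[["alpha"]], tt)
    mu <- params[["theta"]]
  }
  Lc <- chol(V)
  z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
  traits <- mu + crossprod(Lc, z)
  rownames(traits) <- rownames(tt$C)
  list(tree = tree, traits = traits)
}
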