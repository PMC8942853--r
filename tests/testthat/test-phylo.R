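# Evolutionary model likelihoods, fitting, model selection and the
# statistical battery.

star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

two_tip_tree <- function() ape::read.tree(text = "(A:1,B:1);")

test_that("BM likelihood on a star tree is a product of iid normals", {
  tr <- star_tree(8, depth = 2)
  set.seed(50)
  y <- stats::setNames(rnorm(8), tr$tip.label)
  ll <- bm_loglik(tr, y, sigma2 = 0.7, z0 = 0.3)
  ll_iid <- sum(dnorm(y, 0.3, sqrt(0.7 * 2), log = TRUE))
  expect_equal(ll, ll_iid, tolerance = 1e-10)
})

test_that("two-tip likelihoods match hand-computed bivariate densities", {
  tr <- two_tip_tree()
  y <- c(A = 0.4, B = -0.2)
  s2 <- 0.5
  # BM: independent tips, variance s2 * depth
  expect_equal(bm_loglik(tr, y, s2, 0.1),
               sum(dnorm(y, 0.1, sqrt(s2), log = TRUE)), tolerance = 1e-10)
  # OU, root at theta: var = s2/(2a)(1 - e^{-2at}), cov via d_ij = 2
  a <- 1.3; th <- 0.05
  v <- s2 / (2 * a) * (1 - exp(-2 * a * 1))
  cv <- s2 / (2 * a) * exp(-a * 2) * (1 - exp(-2 * a * 0))  # shared time 0
  S <- matrix(c(v, cv, cv, v), 2)
  r <- y - th
  ll_hand <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * drop(t(r) %*% solve(S) %*% r)
  expect_equal(ou_loglik(tr, y, a, s2, th), ll_hand, tolerance = 1e-10)
})

test_that("the OU likelihood converges to BM as alpha -> 0", {
  tt <- test_tree_traits_ou()
  y <- stats::setNames(tt$traits[, 1], rownames(tt$traits))
  ll_bm <- bm_loglik(tt$tree, y, sigma2 = 0.8, z0 = 0.2)
  ll_ou <- ou_loglik(tt$tree, y, alpha = 1e-8, sigma2 = 0.8, theta = 0.2)
  expect_lt(abs(ll_ou - ll_bm), 1e-4)
})

test_that("ML fits recover simulated parameters and flag degeneracy", {
  cfg <- synthetic_config(seed = 11, n_species = 50)
  set.seed(11)
  sims <- generate_tree_and_traits(cfg, "BM", c(sigma2 = 2, z0 = 1),
                                   n_traits = 200)
  s2_hat <- apply(sims$traits, 2, function(y) {
    names(y) <- rownames(sims$traits)
    fit_evo_model(sims$tree, y, "BM")$params[["sigma2"]]
  })
  expect_lt(abs(stats::median(s2_hat) - 2) / 2, 0.3)

  const <- stats::setNames(rep(1, 50), rownames(sims$traits))
  fit_const <- fit_evo_model(sims$tree, const, "BM")
  expect_true(fit_const$degenerate)
})

test_that("AICc identities hold exactly and penalty arithmetic is right", {
  tt <- test_tree_traits_ou()
  y <- stats::setNames(tt$traits[, 1], rownames(tt$traits))
  fb <- fit_evo_model(tt$tree, y, "BM")
  fo <- fit_evo_model(tt$tree, y, "OU")
  n <- fb$n_tips
  expect_equal(fb$aicc, -2 * fb$loglik + 2 * 2 + 2 * 2 * 3 / (n - 3))
  expect_equal(fo$aicc, -2 * fo$loglik + 2 * 3 + 2 * 3 * 4 / (n - 4))
  # equal log-likelihoods at n = 22: the difference is pure penalty
  pen <- (2 * 3 + 24 / 18) - (2 * 2 + 12 / 19)
  expect_equal(compare_models_aicc(fb, fo),
               (-2 * fo$loglik + 2 * 3 + 24 / 18) -
                 (-2 * fb$loglik + 2 * 2 + 12 / 19))
  expect_equal(pen, 2.70175438596491, tolerance = 1e-10)
  # OU nests BM, so the OU maximum likelihood can never be lower
  expect_gte(fo$loglik, fb$loglik - 1e-6)
})

test_that("strong selection in simulated traits is detected by pmc", {
  tt <- test_tree_traits_ou()
  y <- stats::setNames(tt$traits[, 1], rownames(tt$traits))
  res <- pmc_bootstrap(tt$tree, y, n_sim = 150, seed = 3)
  expect_lt(res$p_exceed, 0.05)
  expect_gt(res$power, 0.6)
  expect_equal(res$lr_obs,
               2 * (res$fit_ou$loglik - res$fit_bm$loglik))

  res1 <- pmc_bootstrap(tt$tree, y, n_sim = 1, seed = 4)
  expect_length(res1$lr_bm, 1)
  expect_length(res1$lr_ou, 1)
})

test_that("phylogenetic GLS equals OLS on a star tree and nails exact lines", {
  tr <- star_tree(12)
  set.seed(52)
  x <- stats::setNames(rnorm(12), tr$tip.label)
  y <- 2 + 0.5 * x + rnorm(12, 0, 0.1)
  names(y) <- tr$tip.label
  fit <- pgls_allometry(tr, y, x, null_slope = 0)
  ols <- stats::lm(y ~ x)
  expect_equal(fit$slope, unname(stats::coef(ols)[2]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(stats::coef(ols)[1]), tolerance = 1e-8)

  # exact isometric line: slope equals the null, zero-width interval
  y_iso <- 1 + (5 / 3) * x
  names(y_iso) <- tr$tip.label
  fit_iso <- pgls_allometry(tr, y_iso, x, null_slope = 5 / 3)
  expect_equal(fit_iso$slope, 5 / 3, tolerance = 1e-10)
  expect_lt(fit_iso$conf_high - fit_iso$conf_low, 1e-8)
  expect_false(fit_iso$differs_from_null)

  expect_error(pgls_allometry(tr, y, stats::setNames(rep(1, 12), tr$tip.label)),
               "singular")
})

test_that("GLS slope intervals achieve near-nominal coverage under BM", {
  cfg <- synthetic_config(seed = 13, n_species = 22)
  sims <- generate_tree_and_traits(cfg, "BM", c(sigma2 = 1, z0 = 0),
                                   n_traits = 150)
  # fixed regressor (log-spaced masses), BM-distributed residuals
  x <- stats::setNames(seq(log(0.02), log(3), length.out = 22),
                       rownames(sims$traits))
  cover <- vapply(seq_len(150), function(i) {
    y <- (5 / 3) * x + sims$traits[, i]
    names(y) <- rownames(sims$traits)
    f <- pgls_allometry(sims$tree, y, x, null_slope = 5 / 3)
    !f$differs_from_null
  }, logical(1))
  expect_gt(mean(cover), 0.88)
})

test_that("partial eta-squared matches a manual sums-of-squares oracle", {
  # hand-built 6-row dataset
  d <- tibble::tibble(elbow = c(60, 80, 100, 120, 140, 160),
                      wrist = c(70, 150, 90, 130, 110, 60),
                      resp = c(0.2, 0.8, 0.35, 0.62, 0.5, 0.15))
  fit <- joint_effect_model(d, "resp", min_rows = 6)

  # oracle: residual-SS differences on the same scaled design
  e <- as.numeric(scale(d$elbow)); w <- as.numeric(scale(d$wrist))
  X <- cbind(1, e, w, e * w)
  rss <- function(Xm) sum(stats::lm.fit(Xm, d$resp)$residuals^2)
  rss_full <- rss(X)
  for (j in 2:4) {
    ss_term <- rss(X[, -j, drop = FALSE]) - rss_full
    expect_equal(fit$partial_eta2[j - 1], ss_term / (ss_term + rss_full),
                 tolerance = 1e-10)
  }
})

test_that("pure and null responses give extreme and tiny effect sizes", {
  set.seed(53)
  grid <- expand.grid(elbow = seq(60, 150, by = 10),
                      wrist = seq(70, 160, by = 10))
  pure <- tibble::tibble(elbow = grid$elbow, wrist = grid$wrist,
                         resp = 0.3 + 0.01 * grid$wrist)
  fit <- joint_effect_model(pure, "resp")
  expect_equal(fit$partial_eta2[fit$term == "wrist"], 1, tolerance = 1e-9)
  expect_lt(fit$partial_eta2[fit$term == "elbow"], 1e-9)

  eta_null <- replicate(30, {
    d <- tibble::tibble(elbow = grid$elbow, wrist = grid$wrist,
                        resp = rnorm(nrow(grid)))
    mean(joint_effect_model(d, "resp")$partial_eta2)
  })
  expect_lt(mean(eta_null), 0.05)

  expect_error(joint_effect_model(pure[1:5, ], "resp"), "at least")
  const <- tibble::tibble(elbow = rep(100, 12), wrist = seq_len(12),
                          resp = rnorm(12))
  expect_error(joint_effect_model(const, "resp"), "rank-deficient")
})

test_that("the CG-error bootstrap respects its bounds and recovers signs", {
  cfg <- synthetic_config(seed = 17, n_species = 12)
  tt <- generate_tree_and_traits(cfg)
  set.seed(17)
  # constructed cohort: stable maxima, unstable minima, wide separation
  st <- tibble::tibble(
    species = sprintf("species_%02d", seq_len(12)),
    sm_max = 0.3 + rnorm(12, 0, 0.02),
    sm_min = -0.2 + rnorm(12, 0, 0.02),
    c_r_max = 0.1,
    length_torso = 0.12,
    mass_frac_tt = 0.5
  )
  res <- cg_error_bootstrap(st, tt$tree, n_boot = 40, seed = 5)
  th_max <- res$theta[res$trait == "sm_max"]
  th_min <- res$theta[res$trait == "sm_min"]
  expect_true(all(th_max > 0))
  expect_true(all(th_min < 0))

  # zero perturbation: degenerate at the point estimate
  res0 <- cg_error_bootstrap(st, tt$tree, n_boot = 5, frac = 0, seed = 6)
  expect_lt(stats::sd(res0$theta[res0$trait == "sm_max"]), 1e-12)

  # a bound exceeding the cap is clipped: effect never exceeds cap/c_r * frac_tt
  st_big <- st
  st_big$length_torso <- 1            # 15% of torso would be 0.15 m > 4 cm cap
  res_big <- cg_error_bootstrap(st_big, tt$tree, n_boot = 30, seed = 7)
  max_shift <- 0.04 * st$mass_frac_tt[1] / st$c_r_max[1]
  expect_lt(max(res_big$theta[res_big$trait == "sm_max"]),
            max(st$sm_max) + max_shift + 1e-9)
})
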