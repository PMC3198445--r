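# Generate a downstream series that satisfies the discretized CKE exactly
# (the scheme-consistent implicit recursion), so the rate solve has a
# zero-residual optimum at the true rates.
trapezoid_series <- function(a, b, y0, dt = 1 / 3) {
  y <- numeric(length(a))
  y[1] <- y0
  for (i in seq_len(length(a) - 1L)) {
    y[i + 1] <- (y[i] + dt / 2 * (a[i] - b[i] * y[i] + a[i + 1])) /
      (1 + dt / 2 * b[i + 1])
  }
  y
}

test_that("factor inversion recovers the affinity constant", {
  expect_equal(hill_from_factor(0.5, 1, 1), 1)
  expect_equal(hill_from_factor(0.8, 2, 2), 1)  # (0.8/0.2)^(1/2) / 2
  # round trip: the impact at the key level reproduces the factor
  for (f in c(0.1, 0.35, 0.9)) {
    for (cc in 1:4) {
      gam <- hill_from_factor(f, 1234, cc)
      a <- hill_impact(1234, cc, gam)
      expect_equal(a / (1 + a), f, tolerance = 1e-12)
    }
  }
  expect_error(hill_from_factor(1.2, 1, 1), "strictly inside")
  expect_error(hill_from_factor(0.5, 0, 1), "inversion")
})

test_that("the discretized residual system has 38 equations over two conditions", {
  sys <- td_test_system()
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m, KO = sys$m * 0.7),
    R1 = list(kind = "protein", WT = sys$p, KO = sys$p * 0),
    G = list(kind = "mRNA", WT = rep(600, 19), KO = rep(650, 19))))
  pars <- td_params(sys$hill, 0, 0, 0)
  rs <- discretize_residuals(sys$arch, pars, ps)
  expect_length(rs$residuals, 38L)
  expect_equal(rs$n_unknowns, 5L)
  # zero rates against constant data: every residual vanishes
  expect_equal(max(abs(rs$residuals)), 0)
})

test_that("residuals vanish on scheme-consistent data at the true parameters", {
  sys <- td_test_system()
  F19 <- committed_fraction(hill_impact(sys$p, 2, 1 / 800),
                            has_activators = FALSE)
  kT <- 150; kR <- 5e-5; kD <- 0.3
  a <- kT * F19
  b <- kR * sys$m + kD
  D <- trapezoid_series(a, b, 900)
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = D)))
  rs <- discretize_residuals(sys$arch, td_params(sys$hill, kT, kR, kD), ps)
  expect_lt(max(abs(rs$residuals)), 1e-9)

  # the forward scheme likewise vanishes on forward-recursion data
  dt <- 1 / 3
  Df <- numeric(19); Df[1] <- 900
  for (i in 1:18) Df[i + 1] <- Df[i] + dt * (a[i] - b[i] * Df[i])
  psf <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = Df)))
  cfg <- campaign_config(residual_scheme = "forward")
  rsf <- discretize_residuals(sys$arch, td_params(sys$hill, kT, kR, kD),
                              psf, cfg)
  expect_lt(max(abs(rsf$residuals)), 1e-9)
})

test_that("nonnegative least squares recovers planted rates on noise-free data", {
  sys <- td_test_system()
  F19 <- committed_fraction(hill_impact(sys$p, 2, 1 / 800),
                            has_activators = FALSE)
  truth <- c(k_transcr = 120, k_react = 6e-5, k_deg = 0.25)
  D <- trapezoid_series(truth[1] * F19, truth[2] * sys$m + truth[3], 900)
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = D)))
  sol <- solve_rates(sys$arch, sys$hill, ps)
  expect_lt(max(abs(sol$rates - truth) / truth), 1e-6)
  expect_lt(sol$rss, 1e-12)

  # an all-zero downstream profile is degenerate for scoring, but the rate
  # solve on a near-zero profile drives every rate to zero
  ps0 <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = c(rep(1e-9, 19)))))
  sol0 <- solve_rates(sys$arch, sys$hill, ps0)
  expect_lt(sol0$rates[["k_transcr"]], 1e-9)
})

test_that("the NNLS solution beats a brute-force grid over the rate space", {
  sys <- td_test_system()
  set.seed(31)
  D <- 500 + 300 * sin(time_grid()) + stats::rnorm(19, 0, 30)
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = pmax(D, 0))))
  sol <- solve_rates(sys$arch, sys$hill, ps)
  rs <- function(rates) {
    p <- td_params(sys$hill, rates[1], rates[2], rates[3])
    sum(discretize_residuals(sys$arch, p, ps)$residuals^2)
  }
  expect_equal(rs(sol$rates), sol$rss, tolerance = 1e-8)
  grid_pts <- expand.grid(
    k_transcr = seq(0, 400, length.out = 9),
    k_react = seq(0, 2e-4, length.out = 9),
    k_deg = seq(0, 1.5, length.out = 9))
  brute <- apply(grid_pts, 1L, rs)
  expect_lte(sol$rss, min(brute) + 1e-9)
})

test_that("degenerate regressor columns are flagged and zeroed", {
  sys <- td_test_system()
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = rep(0, 19)),  # no miRNA signal at all
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = 400 + 20 * time_grid())))
  sol <- solve_rates(sys$arch, sys$hill, ps)
  expect_true(sol$degenerate[["k_react"]])
  expect_equal(sol$rates[["k_react"]], 0)
})

test_that("protein decay is estimated from the declining profile segment", {
  d <- c(0, 1.5, 3, 6)
  k <- estimate_protein_decay(d, 1000 * exp(-0.45 * d))
  expect_equal(as.numeric(k), 0.45, tolerance = 1e-9)
  # rise then fall: only the declining suffix is used
  k2 <- estimate_protein_decay(
    d, c(500, 900, 900 * exp(-0.6 * 1.5), 900 * exp(-0.6 * 4.5)))
  expect_equal(as.numeric(k2), 0.6, tolerance = 1e-9)
  # strictly increasing profile: no declining segment, flagged fallback
  k3 <- estimate_protein_decay(d, c(10, 20, 40, 80))
  expect_equal(as.numeric(k3), 0)
  expect_lt(attr(k3, "n_points"), 2L)
})

test_that("the fitter recovers noise-free data generated inside its search space", {
  sys <- td_test_system()
  # planted factor 0.6 at the key instant (max of R1), 2 binding sites
  key <- max(sys$p)
  gam <- hill_from_factor(0.6, key, 2L)
  hill <- hill_params("R1", "repressor", 2L, gam)
  truth <- td_params(hill, 140, 7e-5, 0.3)
  up <- list(M1 = list(kind = "miRNA", WT = sys$m, KO = sys$m * 0.6),
             R1 = list(kind = "protein", WT = sys$p, KO = rep(0, 19)))
  ps_up <- make_profile_set(up)
  obs <- lapply(c(WT = "WT", KO = "KO"), function(cc) {
    predict_downstream(sys$arch, truth, ps_up, cc, initial_value = 900)
  })
  ps <- make_profile_set(c(up, list(
    G = list(kind = "mRNA", WT = obs$WT, KO = obs$KO))))
  fit <- fit_architecture(sys$arch, ps)
  expect_lt(fit$objective, 1)  # ErrPred below 1% in both conditions
  expect_true(fit$validated)
  expect_equal(fit$n_params, 5L)
})

test_that("a constant downstream profile fits as a synthesis-decay steady state", {
  sys <- td_test_system()
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = rep(0, 19)),
    R1 = list(kind = "protein", WT = rep(700, 19)),
    G = list(kind = "mRNA", WT = rep(550, 19))))
  fit <- fit_architecture(sys$arch, ps)
  expect_lt(fit$objective, 1e-6)
})

test_that("the fit equals exhaustive enumeration for one regulator", {
  sys <- td_test_system()
  set.seed(17)
  D <- pmax(800 * exp(-0.3 * time_grid()) + stats::rnorm(19, 0, 25), 0)
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = D)))
  fgrid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cfg <- campaign_config(factor_grid = fgrid, refine = FALSE, audit = TRUE)
  fit <- fit_architecture(sys$arch, ps, cfg)

  # independent enumeration over the full candidate product set through
  # the public single-candidate operations
  key <- max(sys$p)
  best <- Inf
  for (cc in 1:4) {
    for (f in fgrid) {
      hill <- hill_params("R1", "repressor", cc, hill_from_factor(f, key, cc))
      rates <- solve_rates(sys$arch, hill, ps, cfg)$rates
      pred <- predict_downstream(
        sys$arch, td_params(hill, rates[1], rates[2], rates[3]), ps, "WT",
        step = cfg$step, knockout = cfg$knockout)
      best <- min(best, errpred_global(pred, D))
    }
  }
  expect_equal(fit$objective, best, tolerance = 1e-10)
  # audit: the returned optimum is the minimum over evaluated candidates
  expect_equal(nrow(fit$audit), 4L * length(fgrid))
  expect_equal(fit$objective, min(fit$audit$objective))
})

test_that("enlarging the factor grid never worsens the fitted objective", {
  sys <- td_test_system()
  set.seed(23)
  D <- pmax(600 + 150 * cos(time_grid() / 2) + stats::rnorm(19, 0, 20), 0)
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = D)))
  coarse <- fit_architecture(sys$arch, ps, campaign_config(
    factor_grid = c(0.2, 0.5, 0.8), refine = FALSE))
  fine <- fit_architecture(sys$arch, ps, campaign_config(
    factor_grid = c(0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.9), refine = FALSE))
  refined <- fit_architecture(sys$arch, ps, campaign_config(
    factor_grid = c(0.2, 0.5, 0.8), refine = TRUE))
  expect_lte(fine$objective, coarse$objective + 1e-12)
  expect_lte(refined$objective, coarse$objective + 1e-12)
})

test_that("the candidate budget is enforced", {
  arch <- transcr_degr_arch("G", "m1", rep_proteins = "R1",
                            act_proteins = c("A1", "A2"))
  g <- time_grid()
  ps <- make_profile_set(list(
    m1 = list(kind = "miRNA", WT = 100 + 0 * g),
    R1 = list(kind = "protein", WT = 200 + 10 * g),
    A1 = list(kind = "protein", WT = 300 - 10 * g),
    A2 = list(kind = "protein", WT = 250 + 5 * g),
    G = list(kind = "mRNA", WT = 500 - 20 * g)))
  expect_error(
    fit_architecture(arch, ps, campaign_config(max_candidates = 100)),
    "budget")
})

test_that("a downstream protein vanishing in one condition is scored on the other only", {
  g <- time_grid()
  arch <- transl_inhib_arch("GeneX", "ProtX", "m1")
  up <- list(
    m1 = list(kind = "miRNA", WT = 200 + 100 * g, KO = 200 + 100 * g),
    GeneX = list(kind = "mRNA", WT = 900 * exp(-0.5 * g),
                 KO = 900 * exp(-0.5 * g)))
  ps_up <- make_profile_set(up)
  truth <- ti_params(hill_params("m1", "mirna", 1L,
                                 hill_from_factor(0.5, 800, 1L)),
                     k_transl = 0.5, k_degp = 0.45)
  pwt <- predict_downstream(arch, truth, ps_up, "WT", initial_value = 1000)
  ps <- make_profile_set(c(up, list(
    ProtX = list(kind = "protein", WT = pwt, KO = rep(0, 19)))))
  fit <- fit_architecture(arch, ps, campaign_config(k_degp = 0.45))
  expect_named(fit$errpred, "WT")
  expect_lt(fit$errpred[["WT"]], 1)
  expect_true(fit$validated)
  expect_equal(fit$n_params, 3L)
})
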