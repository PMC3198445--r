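test_that("Hill impacts and saturating factors behave as stated", {
  expect_equal(hill_impact(0, 3, 0.5), 0)
  a <- hill_impact(2, 1, 0.5)  # gamma * level = 1
  expect_equal(a, 1)
  expect_equal(a / (1 + a), 0.5)
  a2 <- hill_impact(2, 2, 1)
  expect_equal(a2, 4)
  expect_equal(a2 / (1 + a2), 0.8)
  # the saturating factor stays inside [0, 1)
  lv <- seq(0, 1e4, length.out = 50)
  f <- hill_impact(lv, 3, 1e-3) / (1 + hill_impact(lv, 3, 1e-3))
  expect_true(all(f >= 0 & f < 1))
  expect_error(hill_impact(-1, 1, 1), "nonnegative")
})

test_that("synthetic impacts are the sums of individual impacts", {
  h0 <- hill_params(character(), character(), integer(), numeric())
  expect_equal(synthetic_impacts(numeric(), numeric(), h0),
               list(REP = 0, ACT = 0))

  h <- hill_params(c("r1", "r2"), c("repressor", "repressor"), c(1L, 1L),
                   c(1, 3))
  got <- synthetic_impacts(c(1, 1), numeric(), h)
  expect_equal(got$REP, 4)  # impacts 1 and 3

  set.seed(5)
  hr <- hill_params(c("r1", "r2", "a1"),
                    c("repressor", "repressor", "activator"),
                    sample(1:4, 3, TRUE), stats::runif(3, 1e-4, 1e-2))
  lev <- stats::runif(3, 0, 2000)
  got <- synthetic_impacts(lev[1:2], lev[3], hr)
  brute_rep <- sum((hr$gamma[1:2] * lev[1:2])^hr$sites[1:2])
  brute_act <- (hr$gamma[3] * lev[3])^hr$sites[3]
  expect_equal(got$REP, brute_rep)
  expect_equal(got$ACT, brute_act)
})

test_that("the committed fraction has the stated form and monotonicity", {
  expect_equal(committed_fraction(0, has_activators = FALSE), 1)
  expect_equal(committed_fraction(1, has_activators = FALSE), 0.5)
  expect_equal(committed_fraction(0, 3, has_activators = TRUE), 0.75)
  r <- seq(0, 10, by = 0.5)
  expect_true(all(diff(committed_fraction(r, 2, TRUE)) < 0))
  a <- seq(0, 10, by = 0.5)
  expect_true(all(diff(committed_fraction(rep(1, length(a)), a, TRUE)) > 0))
  f <- committed_fraction(stats::runif(20, 0, 50), stats::runif(20, 0, 50),
                          TRUE)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("the CKE right-hand sides evaluate the stated balances", {
  expect_equal(transcr_degr_rhs(1, 1, 1, 0, 0, 0), 0)
  expect_equal(transcr_degr_rhs(0, 5, 1, 2, 0.7, 0.9), 2)
  expect_equal(transcr_degr_rhs(1, 1, 0.5, 2, 0.3, 0.2), 0.5)
  expect_equal(transl_inhib_rhs(0, 3, 0, 1.5, 0.4), 4.5)
  expect_equal(transl_inhib_rhs(2, 4, 1, 0, 0.25), -0.5)
  expect_equal(transl_inhib_rhs(2, 4, 1, 1, 0.25), 1.5)
})

test_that("zero dynamics and pure decay integrate in closed form", {
  sys <- td_test_system()
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = rep(0, 19)),
    R1 = list(kind = "protein", WT = sys$p),
    G = list(kind = "mRNA", WT = rep(800, 19))))

  # all rates zero: constant profile at the initial value
  flat <- predict_downstream(sys$arch,
                             td_params(sys$hill, 0, 0, 0), ps, "WT")
  expect_equal(flat, rep(800, 19))

  # no synthesis, half-life 3 days: value at t = 3 is half the start
  dec <- predict_downstream(sys$arch,
                            td_params(sys$hill, 0, 0, log(2) / 3), ps, "WT")
  g <- time_grid()
  expect_equal(dec[g == 3], 400, tolerance = 1e-9)
  expect_equal(dec, 800 * exp(-log(2) / 3 * g), tolerance = 1e-9)

  # constant committed fraction: the full linear-ODE solution
  const_rep <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = rep(0, 19)),
    R1 = list(kind = "protein", WT = rep(800, 19))))
  kT <- 120; kD <- 0.5
  Fc <- committed_fraction(hill_impact(800, 2, 1 / 800), has_activators = FALSE)
  pred <- predict_downstream(sys$arch, td_params(sys$hill, kT, 0, kD),
                             const_rep, "WT", initial_value = 100)
  exact <- (100 - kT * Fc / kD) * exp(-kD * g) + kT * Fc / kD
  expect_equal(pred, exact, tolerance = 1e-8)
})

test_that("RK4 predictions match an independent fine-step Euler oracle", {
  sys <- td_test_system()
  ps <- make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p)))
  set.seed(9)
  g <- time_grid()
  h <- 1 / 300000
  tt <- seq(0, 6, by = h)
  mf <- pracma::pchip(g, sys$m, tt)
  pf <- pracma::pchip(g, sys$p, tt)
  for (trial in 1:3) {
    kT <- stats::runif(1, 50, 150)
    kR <- stats::runif(1, 0, 1e-4)
    kD <- stats::runif(1, 0.02, 0.15)
    pred <- predict_downstream(sys$arch, td_params(sys$hill, kT, kR, kD),
                               ps, "WT", initial_value = 1000)
    a <- kT / (1 + (pf / 800)^2)
    b <- kR * mf + kD
    y <- 1000
    out <- numeric(19)
    out[1] <- y
    k <- 2L
    nsub <- round(1 / 3 / h)
    for (i in seq_len(length(tt) - 1L)) {
      y <- y + h * (a[i] - b[i] * y)
      if (i %% nsub == 0L) { out[k] <- y; k <- k + 1L }
    }
    expect_lt(max(abs(pred - out) / pmax(abs(out), 1)), 1e-6)
  }
})

test_that("predictions are scale invariant under the model's reparameterization", {
  sys <- td_test_system()
  s <- 7.3
  base <- list(M1 = list(kind = "miRNA", WT = sys$m),
               R1 = list(kind = "protein", WT = sys$p))
  scaled <- list(M1 = list(kind = "miRNA", WT = s * sys$m),
                 R1 = list(kind = "protein", WT = s * sys$p))
  p1 <- predict_downstream(
    sys$arch, td_params(hill_params("R1", "repressor", 2L, 1 / 800),
                        100, 5e-5, 0.3),
    make_profile_set(base), "WT", initial_value = 1000)
  p2 <- predict_downstream(
    sys$arch, td_params(hill_params("R1", "repressor", 2L, 1 / 800 / s),
                        100, 5e-5 / s, 0.3),
    make_profile_set(scaled), "WT", initial_value = 1000)
  expect_equal(p1, p2, tolerance = 1e-12)

  # same invariance for translation inhibition (gamma -> gamma/s)
  ti <- transl_inhib_arch("G", "P", "M1")
  base_ti <- make_profile_set(c(base, list(
    G = list(kind = "mRNA", WT = 500 + 100 * time_grid()))))
  scaled_ti <- make_profile_set(c(scaled, list(
    G = list(kind = "mRNA", WT = s * (500 + 100 * time_grid())))))
  q1 <- predict_downstream(
    ti, ti_params(hill_params("M1", "mirna", 2L, 1 / 900), 0.8, 0.5),
    base_ti, "WT", initial_value = 700)
  q2 <- predict_downstream(
    ti, ti_params(hill_params("M1", "mirna", 2L, 1 / 900 / s), 0.8 / s, 0.5),
    scaled_ti, "WT", initial_value = 700)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("predictions are nonnegative and monotone in repression", {
  sys <- td_test_system()
  mk <- function(mult) make_profile_set(list(
    M1 = list(kind = "miRNA", WT = mult * sys$m),
    R1 = list(kind = "protein", WT = sys$p)))
  pars <- td_params(sys$hill, 80, 8e-5, 0.4)
  lo <- predict_downstream(sys$arch, pars, mk(1), "WT", initial_value = 900)
  hi <- predict_downstream(sys$arch, pars, mk(3), "WT", initial_value = 900)
  expect_true(all(lo >= 0))
  expect_true(all(hi <= lo + 1e-9))

  # raising a repressor protein also never increases the prediction
  mkp <- function(shift) make_profile_set(list(
    M1 = list(kind = "miRNA", WT = sys$m),
    R1 = list(kind = "protein", WT = sys$p + shift)))
  p_lo <- predict_downstream(sys$arch, pars, mkp(0), "WT", initial_value = 900)
  p_hi <- predict_downstream(sys$arch, pars, mkp(400), "WT",
                             initial_value = 900)
  expect_true(all(p_hi <= p_lo + 1e-9))
})

test_that("missing upstream profiles raise a dependency error naming the molecule", {
  sys <- td_test_system()
  ps <- make_profile_set(list(M1 = list(kind = "miRNA", WT = sys$m)))
  expect_error(
    predict_downstream(sys$arch, td_params(sys$hill, 1, 0, 0), ps, "WT",
                       initial_value = 1),
    "R1")
  # a knocked-out molecule is substituted by zeros instead
  pred <- predict_downstream(sys$arch, td_params(sys$hill, 1, 0, 0), ps,
                             "WT", initial_value = 1,
                             knockout = list(WT = "R1"))
  expect_true(all(pred >= 1))  # F = 1 with zero repressor
})
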