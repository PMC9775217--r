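test_that("binning uses half-open windows anchored at zero", {
  obs <- data.frame(replicate = 1, ph = 6, frame = 1:4,
                    insertion = c(-5.3, -5, -0.001, 0),
                    protonated = c(1L, 0L, 1L, 0L))
  b <- bin_observations(obs, bin_width = 1, burn_in_fraction = 0)
  # -5.3 -> [-6,-5); exactly -5 -> [-5,-4); -0.001 -> [-1,0); 0 -> [0,1)
  expect_setequal(b$bin_low, c(-6, -5, -1, 0))
  expect_equal(b$n, rep(1, 4))
  expect_equal(b$bin_high, b$bin_low + 1)
  b2 <- bin_observations(obs, bin_width = 2, burn_in_fraction = 0)
  expect_setequal(b2$bin_low, c(-6, -2, 0))
})

test_that("burn-in drops the first half of each stream by frame order", {
  obs <- data.frame(replicate = 1, ph = 6, frame = 100:1,   # shuffled order
                    insertion = c(rep(-2.5, 50), rep(-7.5, 50)),
                    protonated = 1L)
  # frames 1..50 carry insertion -7.5; they must be the ones dropped
  b <- bin_observations(obs, burn_in_fraction = 0.5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$bin_low, -3)
  expect_equal(b$n, 50)
  b0 <- bin_observations(obs, burn_in_fraction = 0)
  expect_equal(sum(b0$n), 100)
  # odd stream length: floor(0.5 * 101) = 50 dropped
  obs2 <- rbind(obs, data.frame(replicate = 1, ph = 6, frame = 101,
                                insertion = -2.5, protonated = 0L))
  expect_equal(sum(bin_observations(obs2, burn_in_fraction = 0.5)$n), 51)
})

test_that("cell criterion needs ten of each protonation state", {
  mk <- function(np, nd) {
    obs <- cell_obs(-2.5, rep(c(5, 6), each = 3), rep(1:3, 2),
                    rep(np, 6), rep(nd, 6))
    apply_bin_criteria(bin_observations(obs, burn_in_fraction = 0))
  }
  expect_true(all(mk(10, 10)$cells$ok1))
  expect_false(any(mk(9, 11)$cells$ok1))     # 9 protonated is short
  expect_false(any(mk(11, 9)$cells$ok1))     # 9 deprotonated is short
  expect_true(all(mk(10, 10)$per_bin$fit_ok))
  expect_false(any(mk(9, 11)$per_bin$profile_ok))
})

test_that("replicate and pH coverage thresholds are sharp", {
  mk <- function(n_rep, n_ph) {
    ph <- rep(seq(5, by = 1, length.out = n_ph), each = n_rep)
    obs <- cell_obs(-2.5, ph, rep(seq_len(n_rep), n_ph),
                    rep(20, length(ph)), rep(20, length(ph)))
    apply_bin_criteria(bin_observations(obs, burn_in_fraction = 0))
  }
  expect_true(mk(3, 2)$per_bin$fit_ok)
  expect_false(mk(2, 2)$per_bin$profile_ok)  # 2 replicates < 3
  expect_false(any(mk(2, 2)$per_ph$ok2))
  c1 <- mk(3, 1)
  expect_true(c1$per_bin$profile_ok)         # one pH still profiles
  expect_false(c1$per_bin$fit_ok)            # but cannot be fitted
})

test_that("the monotonicity tolerance is applied to pooled averages", {
  mk <- function(rise) {
    n <- 100
    lo <- 50L
    hi <- as.integer(round((0.5 + rise) * n))
    obs <- rbind(
      cell_obs(-2.5, rep(5, 3), 1:3, rep(lo, 3), rep(n - lo, 3)),
      cell_obs(-2.5, rep(6, 3), 1:3, rep(hi, 3), rep(n - hi, 3)))
    apply_bin_criteria(bin_observations(obs, burn_in_fraction = 0))
  }
  expect_true(mk(0.04)$per_bin$mono_ok)      # within the 0.05 allowance
  expect_true(mk(0.04)$per_bin$fit_ok)
  expect_false(mk(0.06)$per_bin$mono_ok)     # rises too much with pH
  expect_false(mk(0.06)$per_bin$fit_ok)
  expect_true(mk(0.06)$per_bin$profile_ok)   # profiles ignore criterion 3
  expect_true(mk(-0.30)$per_bin$mono_ok)     # decreasing is always fine
})

test_that("counts are conserved from observations to cells", {
  obs <- make_hill_obs(n_replicates = 3, n_frames = 200, seed = 2)
  b <- bin_observations(obs, burn_in_fraction = 0.25)
  n_streams <- length(unique(interaction(obs$replicate, obs$ph)))
  expect_equal(sum(b$n), nrow(obs) - n_streams * floor(0.25 * 200))
  expect_equal(sum(b$n), nrow(attr(b, "obs")))
  expect_equal(sum(b$n_prot), sum(attr(b, "obs")$protonated))
  expect_true(all(b$mean_prot >= 0 & b$mean_prot <= 1))
})

test_that("the Hill fit recovers exact curves and rejects degenerate input", {
  ph <- c(5, 6, 7)
  ft <- hill_fit(ph, hill_curve(ph, 6, 1))
  expect_equal(ft$pKa, 6, tolerance = 1e-6)
  expect_equal(ft$n, 1, tolerance = 1e-6)
  expect_lt(ft$residual, 1e-12)
  # the classic three-point table 10/11, 1/2, 1/11
  ft2 <- hill_fit(c(5, 6, 7), c(10 / 11, 0.5, 1 / 11))
  expect_equal(ft2$pKa, 6, tolerance = 1e-6)
  expect_equal(ft2$n, 1, tolerance = 1e-6)
  # steeper curve, uneven weights
  ft3 <- hill_fit(seq(4, 8, by = 0.5),
                  hill_curve(seq(4, 8, by = 0.5), 6.3, 2.4),
                  weight = 1:9)
  expect_equal(ft3$pKa, 6.3, tolerance = 1e-6)
  expect_equal(ft3$n, 2.4, tolerance = 1e-5)
  expect_error(hill_fit(c(6, 6), c(0.4, 0.6)), "two pH")
  expect_error(hill_fit(ph, c(1, 1, 1)), "identifiable")
  expect_error(hill_fit(ph, c(0, 0, 0)), "identifiable")
})

test_that("the Hill fit agrees with a reference nonlinear least squares", {
  skip_if_not_installed("minpack.lm")
  set.seed(4)
  ph <- seq(4, 8, by = 0.5)
  prot <- pmin(pmax(hill_curve(ph, 6.1, 1.3) + rnorm(9, 0, 0.03), 0), 1)
  w <- runif(9, 0.5, 2)
  ours <- hill_fit(ph, prot, w)
  ref <- minpack.lm::nlsLM(
    prot ~ 1 / (1 + 10^(n * (ph - pKa))),
    start = list(pKa = 6, n = 1), weights = w,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, maxiter = 200))
  expect_equal(ours$pKa, coef(ref)[["pKa"]], tolerance = 1e-5)
  expect_equal(ours$n, coef(ref)[["n"]], tolerance = 1e-4)
})

test_that("the Bayesian bootstrap is deterministic and degenerates to zero", {
  samples <- data.frame(ph = rep(c(5, 6, 7), each = 3),
                        replicate = rep(1:3, 3),
                        prot = rep(c(10 / 11, 0.5, 1 / 11), each = 3),
                        n = 100)
  bb <- bayesian_bootstrap_pka(samples, B = 200, seed = 1)
  # identical replicate samples: every bootstrap refits the same curve
  expect_equal(bb$pKa, 6, tolerance = 1e-6)
  expect_equal(bb$error, 0, tolerance = 1e-6)
  expect_equal(bb$n_fail, 0L)
  bb2 <- bayesian_bootstrap_pka(samples, B = 200, seed = 1)
  expect_identical(bb, bb2)
  bb3 <- bayesian_bootstrap_pka(samples, B = 200, seed = 2)
  expect_equal(bb3$pKa, bb$pKa, tolerance = 1e-6)
  # the seed argument must not disturb the caller's RNG stream
  set.seed(10); u1 <- runif(1)
  set.seed(10)
  invisible(bayesian_bootstrap_pka(samples, B = 10, seed = 3))
  expect_identical(runif(1), u1)
})

test_that("an unreliable bin aborts instead of reporting a number", {
  # protonation that rises sharply with pH: every bootstrap re-check of
  # the monotonicity criterion must fail
  samples <- data.frame(ph = rep(c(5, 6), each = 4),
                        replicate = rep(1:4, 2),
                        prot = c(0.10, 0.15, 0.12, 0.14,
                                 0.60, 0.70, 0.65, 0.68),
                        n = 100)
  expect_error(bayesian_bootstrap_pka(samples, B = 200, seed = 1),
               "unreliable")
})

test_that("the pKa profile recovers a depth-dependent midpoint", {
  pka_true <- function(z) 5.5 + 0.25 * (-z)   # 5.75 .. 7 over [-6, 0)
  obs <- make_hill_obs(pka_fun = function(z)
    pka_true(floor(z) + 0.5),                 # constant within each bin
    n_replicates = 4, n_frames = 1200, ph = c(4, 5, 6, 7, 8), seed = 5)
  prof <- pka_profile(obs, B = 200, seed = 9)
  val <- prof[prof$valid, ]
  expect_gte(nrow(val), 5)
  expect_lt(max(abs(val$pKa - pka_true(val$bin_mid))), 0.1)
  expect_true(all(val$error < 0.15))
  expect_true(all(val$n_ph >= 2 & val$n_replicates >= 3))
  # deterministic under the same seed
  prof2 <- pka_profile(obs, B = 200, seed = 9)
  expect_identical(as.data.frame(prof), as.data.frame(prof2))
})

test_that("protonation profiles honour criteria one and two only", {
  obs <- make_hill_obs(n_replicates = 3, n_frames = 600,
                       ph = c(5, 6, 7), seed = 6)
  pp <- protonation_profile(obs)
  expect_true(all(pp$n_replicates >= 3))
  expect_true(all(pp$mean_prot >= 0 & pp$mean_prot <= 1))
  # at fixed bin the pooled protonation falls with pH
  for (bl in unique(pp$bin_low)) {
    d <- pp[pp$bin_low == bl, ]
    d <- d[order(d$ph), ]
    if (nrow(d) >= 2) expect_true(all(diff(d$mean_prot) < 0.05))
  }
})

test_that("property profiles pool scalars with the same gates", {
  obs <- make_hill_obs(n_replicates = 4, n_frames = 400,
                       ph = c(5, 6), seed = 7)
  obs$width <- 39 + 0 * obs$insertion          # constant scalar
  pr <- property_profile(obs, "width")
  expect_true(nrow(pr) > 0)
  expect_true(all(pr$mean == 39))
  expect_true(all(pr$sem == 0))
  expect_true(all(pr$n_replicates >= 3))
  # with only two replicates everything is rejected
  pr2 <- property_profile(obs[obs$replicate <= 2, ], "width")
  expect_equal(nrow(pr2), 0L)
})
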