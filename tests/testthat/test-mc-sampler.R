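test_that("coupled pair selection is strict in the threshold", {
  expect_equal(nrow(coupled_pairs(two_site_system(W = 0))), 0L)
  cp <- coupled_pairs(two_site_system(W = 5))
  expect_equal(nrow(cp), 1L)
  expect_setequal(c(cp$site_i, cp$site_j), c("A", "B"))
  # exactly at the threshold is excluded ("larger than")
  expect_equal(nrow(coupled_pairs(two_site_system(W = 2))), 0L)
  expect_equal(nrow(coupled_pairs(two_site_system(W = -2.2))), 1L)
})

test_that("exact enumeration reproduces single-site closed forms", {
  sys <- single_site_system(6)
  b <- all_baths(sys)
  expect_equal(enumerate_exact(sys, b, gradient_spec(6, 6))
               $mean_protonation[["A"]], 0.5)
  expect_equal(enumerate_exact(sys, b, gradient_spec(7, 7))
               $mean_protonation[["A"]], 1 / 11)
  # identical anticooperative sites have equal means by symmetry
  sym <- titration_system(
    data.frame(site_id = rep(c("A", "B"), each = 2),
               tautomer = rep(c("d", "p"), 2),
               n_protons = rep(c(0L, 1L), 2), g = rep(c(0, -6), 2)),
    pairs = data.frame(site_i = "A", tau_i = "p", site_j = "B",
                       tau_j = "p", W = 1.5))
  e <- enumerate_exact(sym, all_baths(sym), gradient_spec(6, 6))
  expect_equal(e$mean_protonation[["A"]], e$mean_protonation[["B"]])
  expect_error(enumerate_exact(random_system(25, max_tautomers = 4,
                                             seed = 1),
                               all_baths(random_system(25, seed = 1)),
                               gradient_spec(6, 6)),
               "state space")
})

test_that("MC titration matches Henderson-Hasselbalch within 3 SE", {
  sys <- single_site_system(6)
  b <- all_baths(sys)
  r <- mc_titrate(sys, b, gradient_spec(7, 7), mc_settings(30000, seed = 1))
  expect_lt(abs(r$mean_protonation[["A"]] - 1 / 11), 3 * r$se[["A"]])
  # at pH = pK every single-site flip is accepted, so the chain alternates
  # deterministically and the batch SE collapses to zero; floor it
  r2 <- mc_titrate(sys, b, gradient_spec(6, 6),
                   mc_settings(30000, seed = 2))
  expect_lt(abs(r2$mean_protonation[["A"]] - 0.5),
            3 * max(r2$se[["A"]], 1e-4))
})

test_that("uncoupled multi-site means factorize into single-site forms", {
  set.seed(3)
  pk <- runif(6, 4, 8)
  tt <- data.frame(site_id = rep(sprintf("S%d", 1:6), each = 2),
                   tautomer = rep(c("d", "p"), 6),
                   n_protons = rep(c(0L, 1L), 6),
                   g = as.vector(rbind(0, -pk)))
  sys <- titration_system(tt)
  b <- mixed_baths(sys)
  g <- gradient_endpoints(6.0, 1.0)   # in 6.5, out 5.5
  r <- mc_titrate(sys, b, g, mc_settings(50000, seed = 4))
  ph <- ifelse(unclass(b)[sys$site_ids] == "in", g$pH_in, g$pH_out)
  expected <- 1 / (1 + 10^(ph - pk))
  for (k in 1:6)
    expect_lt(abs(r$mean_protonation[[k]] - expected[k]),
              3 * max(r$se[[k]], 1e-4))
})

test_that("MC titration is deterministic under a fixed seed", {
  sys <- random_system(5, seed = 7)
  b <- mixed_baths(sys)
  g <- gradient_endpoints(6, 0.8)
  r1 <- mc_titrate(sys, b, g, mc_settings(5000, seed = 99))
  r2 <- mc_titrate(sys, b, g, mc_settings(5000, seed = 99))
  expect_identical(r1, r2)
})

test_that("protonation decreases monotonically with bath pH", {
  sys <- single_site_system(6)
  b <- all_baths(sys)
  exact <- vapply(4:8, function(p)
    enumerate_exact(sys, b, gradient_spec(p, p))$mean_protonation[["A"]],
    numeric(1))
  expect_true(all(diff(exact) < 0))
  mc <- vapply(4:8, function(p)
    mc_titrate(sys, b, gradient_spec(p, p),
               mc_settings(20000, seed = p))$mean_protonation[["A"]],
    numeric(1))
  expect_true(all(diff(mc) < 0))
})

test_that("the chain satisfies detailed balance on a coupled 2-site system", {
  sys <- two_site_system(6, 6.5, W = 3)
  b <- all_baths(sys)
  g <- gradient_spec(6.2, 6.2)
  e <- enumerate_exact(sys, b, g)
  set.seed(11)
  n <- 6000
  x <- microstate(c(A = "d", B = "d"), sys)
  states <- character(n)
  for (i in seq_len(n)) {
    x <- mc_cycle(x, sys, b, g)
    states[i] <- paste(x, collapse = "")
  }
  trans <- table(factor(states[-n], levels = c("dd", "dp", "pd", "pp")),
                 factor(states[-1], levels = c("dd", "dp", "pd", "pp")))
  pi_emp <- table(factor(states, levels = c("dd", "dp", "pd", "pp"))) / n
  for (a in 1:4) for (bb in 1:4) {
    if (a >= bb) next
    f_ab <- trans[a, bb] / n
    f_ba <- trans[bb, a] / n
    tol <- 4 * sqrt((f_ab + f_ba) / n) + 2e-3
    expect_lt(abs(f_ab - f_ba), tol)
  }
  # and the empirical occupancy matches enumeration loosely
  expect_lt(abs(mean(states %in% c("pd", "pp")) -
                  e$mean_protonation[["A"]]), 0.05)
})

test_that("zero-gradient MC runs are bitwise identical to single bath", {
  sys <- random_system(6, seed = 13)
  g0 <- gradient_spec(6.4, 6.4)
  r_mixed <- mc_titrate(sys, mixed_baths(sys), g0,
                        mc_settings(4000, seed = 5))
  r_out <- mc_titrate(sys, all_baths(sys), g0, mc_settings(4000, seed = 5))
  expect_identical(r_mixed$mean_protonation, r_out$mean_protonation)
  expect_identical(r_mixed$final_state, r_out$final_state)
})

test_that("MC means agree with enumeration on coupled mixed-bath systems", {
  for (s in 1:3) {
    sys <- random_system(5, max_tautomers = 3, seed = 100 + s)
    b <- mixed_baths(sys)
    g <- gradient_endpoints(6, 1.2)
    e <- enumerate_exact(sys, b, g)
    m <- mc_titrate(sys, b, g, mc_settings(50000, seed = 200 + s))
    for (k in seq_along(sys$site_ids))
      expect_lt(abs(m$mean_protonation[[k]] - e$mean_protonation[[k]]),
                3 * max(m$se[[k]], 2e-3))
  }
})
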