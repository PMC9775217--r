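test_that("membrane center is the mean P z and is translation-equivariant", {
  fr <- hand_frame(x = rep(1:12, 2), y = rep(1:2, each = 12),
                   z = rep(c(19.5, -19.5), each = 12),
                   monolayer = rep(c("upper", "lower"), each = 12))
  expect_equal(membrane_center(fr), 0)
  fr2 <- fr
  fr2$atoms$z <- fr2$atoms$z + 3
  expect_equal(membrane_center(fr2), 3)
  # only P atoms count
  fr3 <- fr
  fr3$atoms$name[1:12] <- "O1"
  expect_equal(membrane_center(fr3), -19.5)
  fr3$atoms$name <- "O1"
  expect_error(membrane_center(fr3), "phosphorus")
})

test_that("one-monolayer dimple shifts the center by half its mean", {
  spec <- synthetic_frame_spec(A = -4, sigma = 3, noise_sd = 0,
                               deform = "upper")
  fr <- generate_membrane_frames(spec, 1, seed = 1)
  a <- fr[[1]]$atoms
  p <- a[substr(a$name, 1, 1) == "P" & a$monolayer == "upper", ]
  bump_mean <- mean(p$z) - 19.5            # mean displacement, upper only
  expect_lt(bump_mean, 0)
  expect_equal(membrane_center(fr[[1]]), bump_mean / 2, tolerance = 1e-10)
})

test_that("local surface uses in-radius atoms or the 10 nearest fallback", {
  # 12 atoms inside the 6 A radius, constant z
  fr <- hand_frame(x = c(rep(2, 6), rep(-2, 6), 30, 40),
                   y = c(seq(-2.5, 2.5, length.out = 6),
                         seq(-2.5, 2.5, length.out = 6), 0, 0),
                   z = c(rep(19, 12), 18, 18), box = c(100, 100, 60))
  s <- local_surface_z(fr, c(0, 0), "upper")
  expect_equal(s$z, 19)
  expect_equal(s$n_atoms, 12)
  # 4 atoms inside, next 6 nearest further out at z = 18
  fr2 <- hand_frame(x = c(2, -2, 0, 0, 9, -9, 0, 0, 10, -10),
                    y = c(0, 0, 2, -2, 0, 0, 9, -9, 0, 0),
                    z = c(rep(19, 4), rep(18, 6)), box = c(100, 100, 60))
  s2 <- local_surface_z(fr2, c(0, 0), "upper")
  expect_equal(s2$n_atoms, 10)
  expect_equal(s2$z, (4 * 19 + 6 * 18) / 10)
  expect_error(local_surface_z(fr2, c(0, 0), "lower"), "phosphate")
})

test_that("surface search honours xy periodic images", {
  # probe at the box edge; nearby atoms wrapped to the opposite side
  fr <- hand_frame(x = c(rep(1, 6), rep(59, 6)),
                   y = seq(-2.5, 2.5, length.out = 6)[c(1:6, 1:6)] %% 60,
                   z = c(rep(19, 6), rep(21, 6)), box = c(60, 60, 60))
  s <- local_surface_z(fr, c(0, 0), "upper")
  expect_equal(s$n_atoms, 12)         # 59 is 1 A away across the boundary
  expect_equal(s$z, 20)
  # unwrapped copy gives the same answer
  fr2 <- fr
  fr2$atoms$x[7:12] <- -1
  s2 <- local_surface_z(fr2, c(0, 0), "upper")
  expect_equal(s2$z, s$z)
})

test_that("signed insertion is negative toward the membrane interior", {
  mk <- function(probe_z) {
    up <- hand_frame(x = rep(seq(-6, 6, by = 2), 2),
                     y = rep(c(-2, 2), each = 7), z = rep(19, 14),
                     box = c(60, 60, 60), probe = c(0, 0, probe_z))
    lo <- data.frame(name = "P", resname = "POPC",
                     resid = 100 + 1:14, x = up$atoms$x[1:14],
                     y = up$atoms$y[1:14], z = rep(-19, 14),
                     monolayer = "lower", role = "phosphate")
    up$atoms <- rbind(up$atoms, lo)
    structure(list(up), class = "frame_stack")
  }
  expect_equal(insertion_series(mk(13))$insertion, -6)   # interior
  expect_equal(insertion_series(mk(22))$insertion, 3)    # water side
  expect_equal(insertion_series(mk(-13))$insertion, -6)  # lower monolayer
  expect_equal(insertion_series(mk(-13))$monolayer, "lower")
  expect_warning(
    expect_error(insertion_series(mk(13), residue = "XXX"), "no frame"),
    "skipped")
})

test_that("annulus half-thickness recovers flat and dimpled membranes", {
  flat <- generate_membrane_frames(
    synthetic_frame_spec(A = 0, noise_sd = 0), 2, probe_z = 21, seed = 1)
  prof <- annulus_half_thickness(flat)
  expect_true(all(abs(prof$half_thickness - 19.5) < 1e-10))
  def <- local_deformation(prof)
  expect_true(all(abs(def$deformation) < 1e-10))

  spec <- synthetic_frame_spec(A = -3, sigma = 4, noise_sd = 0.3)
  fr <- generate_membrane_frames(spec, 40, probe_z = 21, seed = 2)
  prof2 <- annulus_half_thickness(fr)
  # predicted bin values from a noiseless twin on the same lipid grid
  fr0 <- generate_membrane_frames(
    synthetic_frame_spec(A = -3, sigma = 4, noise_sd = 0), 1,
    probe_z = 21, seed = 3)
  pred <- annulus_half_thickness(fr0)
  m <- merge(as.data.frame(prof2), as.data.frame(pred),
             by = c("monolayer", "bin_low"))
  expect_gt(nrow(m), 10)
  expect_true(all(abs(m$half_thickness.x - m$half_thickness.y) <
                    pmax(4 * m$sem.x, 0.05)))
  # bulk region is unperturbed
  def2 <- local_deformation(prof2)
  far <- def2$bin_low >= 20
  expect_lt(max(abs(def2$deformation[far])), 0.15)
  # the innermost populated bin shows the depression
  near <- def2[def2$bin_low == min(def2$bin_low), ]
  expect_lt(near$deformation[1], -1)
})

test_that("geometry is invariant under rigid translations", {
  spec <- synthetic_frame_spec(n_side = 8, A = -2, noise_sd = 0.2)
  fr <- generate_membrane_frames(spec, 5, probe_z = 16, seed = 4)
  shift <- function(st, dx, dy, dz) {
    structure(lapply(st, function(f) {
      f$atoms$x <- (f$atoms$x + dx) %% f$box[1]
      f$atoms$y <- (f$atoms$y + dy) %% f$box[2]
      f$atoms$z <- f$atoms$z + dz
      f
    }), class = "frame_stack")
  }
  fr2 <- shift(fr, 13.7, -8.1, 5.5)
  i1 <- insertion_series(fr)
  i2 <- insertion_series(fr2)
  expect_equal(i2$insertion, i1$insertion, tolerance = 1e-10)
  d1 <- local_deformation(annulus_half_thickness(fr))
  d2 <- local_deformation(annulus_half_thickness(fr2))
  expect_equal(d2$deformation, d1$deformation, tolerance = 1e-10)
  expect_error(local_deformation(annulus_half_thickness(fr), 1000),
               "bulk")
})

test_that("profile SEM shrinks like one over root n frames", {
  spec <- synthetic_frame_spec(n_side = 8, A = 0, noise_sd = 0.5)
  sem_at <- function(n, seed) {
    fr <- generate_membrane_frames(spec, n, probe_z = 21, seed = seed)
    p <- annulus_half_thickness(fr)
    mean(p$sem)
  }
  s20 <- sem_at(20, 5)
  s80 <- sem_at(80, 6)
  expect_gt(s20 / s80, 1.5)
  expect_lt(s20 / s80, 2.7)
})
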