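test_that("distance series recovers static and planted-Gaussian geometries", {
  s <- make_point_structure(rbind(c(0, 0, 0), c(5, 0, 0)))
  tr <- new_trajectory(s, list(as.matrix(s$atoms[, c("x", "y", "z")]),
                               as.matrix(s$atoms[, c("x", "y", "z")])))
  ds <- distance_series(tr, 1L, 2L)
  expect_equal(ds$values, c(5, 5))
  expect_equal(ds$sd, 0)

  ## planted N(4.19, 0.75) distances measured back exactly, mean near truth
  spec <- planted_trajectory_spec(
    n_frames = 2000,
    distance_law = list(dist = "gaussian", mean = 4.19, sd = 0.75),
    seed = 6)
  pt <- make_planted_trajectory(spec)
  truth <- attr(pt, "truth")
  dd <- distance_series(pt, truth$roles$oxo, truth$roles$target_h)
  expect_equal(dd$values, truth$distances, tolerance = 1e-9)
  expect_lt(abs(dd$mean - 4.19), 3 * 0.75 / sqrt(2000))

  ## min mode equals brute force per frame
  set.seed(12)
  s2 <- make_point_structure(matrix(rnorm(24, sd = 3), ncol = 3))
  frames <- lapply(1:3, function(i) matrix(rnorm(24, sd = 3), ncol = 3))
  t2 <- new_trajectory(s2, frames)
  got <- distance_series(t2, 1:4, 5:8, mode = "min")$values
  want <- vapply(frames, function(f)
    brute_min_distance(f[1:4, , drop = FALSE], f[5:8, , drop = FALSE]),
    numeric(1))
  expect_equal(got, want)
})

test_that("attack angle has the oxo vertex and recovers planted distributions", {
  xyz <- rbind(c(0, 0, -1.65), c(0, 0, 0), c(0, 0, 3))   # collinear
  s <- make_point_structure(xyz)
  tr <- new_trajectory(s, list(xyz))
  expect_equal(attack_angle_series(tr, 1L, 2L, 3L)$values, 180)
  xyz2 <- rbind(c(0, 0, -1), c(0, 0, 0), c(2, 0, 0))     # right angle
  tr2 <- new_trajectory(s, list(xyz2))
  expect_equal(attack_angle_series(tr2, 1L, 2L, 3L)$values, 90)

  spec <- planted_trajectory_spec(
    n_frames = 2000,
    angle_law = list(dist = "gaussian", mean = 142.0, sd = 7.7),
    seed = 8)
  pt <- make_planted_trajectory(spec)
  truth <- attr(pt, "truth")
  aa <- attack_angle_series(pt, truth$roles$fe, truth$roles$oxo,
                            truth$roles$target_c)
  expect_equal(aa$values, truth$angles, tolerance = 1e-9)
  expect_lt(abs(aa$mean - 142.0), 3 * 7.7 / sqrt(2000))

  expect_error(attack_angle_series(tr, 1L, 2L, 2L), "distinct")
})

test_that("NAC fraction counts frames within threshold and tracks the planted CDF", {
  d4 <- structure(list(name = "d", values = c(3, 5, 3, 5), mean = 4, sd = 1),
                  class = "etk_series")
  expect_equal(nac_summary(d4, threshold = 4)$fraction_within, 0.5)
  dall <- structure(list(name = "d", values = c(1, 2, 3), mean = 2,
                         sd = 0.8), class = "etk_series")
  expect_equal(nac_summary(dall, threshold = 4)$fraction_within, 1)

  ## planted-law CDF at the threshold, within the binomial 99% CI
  spec <- planted_trajectory_spec(
    n_frames = 2000,
    distance_law = list(dist = "gaussian", mean = 4.63, sd = 1.01),
    seed = 10)
  pt <- make_planted_trajectory(spec)
  truth <- attr(pt, "truth")
  dd <- distance_series(pt, truth$roles$oxo, truth$roles$target_h)
  ns <- nac_summary(dd, threshold = 4)
  p_true <- pnorm((4 - 4.63) / 1.01)
  ci <- 2.576 * sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(ns$fraction_within - p_true), ci)

  ## monotone in the threshold
  fr <- vapply(c(3, 4, 5, 6), function(th)
    nac_summary(dd, threshold = th)$fraction_within, numeric(1))
  expect_true(all(diff(fr) >= 0))

  ## length mismatch between distance and angle series
  a3 <- structure(list(name = "a", values = c(1, 2, 3), mean = 2, sd = 1),
                  class = "etk_series")
  expect_error(nac_summary(d4, a3), "length")
})

test_that("hbond occupancy applies both criteria and matches exact planting", {
  ## geometry passing distance but failing the 135-degree angle -> 0%
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1.5, 0))
  s <- new_structure(data.frame(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    resname = "GLY", resid = 1:3, chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_hetero = FALSE))
  tr <- new_trajectory(s, list(xyz))
  expect_equal(hbond_occupancy(tr, 1L, 2L, 3L), 0)

  ## exact planting: 37.28% of 10000 frames
  spec <- planted_trajectory_spec(n_frames = 10000,
                                  hbond_frame_fraction = 0.3728, seed = 3)
  pt <- make_planted_trajectory(spec)
  truth <- attr(pt, "truth")
  occ <- hbond_occupancy(pt, truth$roles$donor, truth$roles$hydrogen,
                         truth$roles$acceptor)
  expect_equal(occ, 37.28)
  ## all-frames case
  spec1 <- planted_trajectory_spec(n_frames = 50, hbond_frame_fraction = 1,
                                   seed = 3)
  pt1 <- make_planted_trajectory(spec1)
  expect_equal(hbond_occupancy(pt1, 5L, 6L, 7L), 100)

  ## hydrogen not bonded to the claimed donor
  expect_error(hbond_occupancy(pt, truth$roles$acceptor,
                               truth$roles$hydrogen, truth$roles$donor),
               "not covalently bonded")
})

test_that("RMSD is zero under rigid motion and matches the closed form for a point displacement", {
  s <- make_two_domain_structure(1)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  ang <- 0.8
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  moved <- xyz %*% R + matrix(rep(c(3, -7, 2), each = nrow(xyz)), ncol = 3)
  tr <- new_trajectory(s, list(xyz, moved))
  rs <- rmsd_series(tr, 1)
  expect_equal(rs$values, c(0, 0), tolerance = 1e-9)

  ## regular polygon + center atom; center displaced by delta along the axis.
  ## The optimal rotation stays the identity; with the centroid shift removed
  ## the residual is delta * sqrt(N-1) / N.
  m <- 7
  th <- 2 * pi * (0:(m - 1)) / m
  poly <- rbind(cbind(cos(th), sin(th), 0), c(0, 0, 0))
  N <- m + 1
  delta <- 0.4
  disp <- poly
  disp[N, 3] <- delta
  sp <- make_point_structure(poly)
  tp <- new_trajectory(sp, list(poly, disp))
  expect_equal(rmsd_series(tp, 1)$values[2], delta * sqrt(N - 1) / N,
               tolerance = 1e-9)

  ## cross-check against bio3d's fitted RMSD on a random deformation
  set.seed(44)
  f2 <- xyz + matrix(rnorm(length(xyz), 0, 0.3), ncol = 3)
  tr2 <- new_trajectory(s, list(xyz, f2))
  ours <- rmsd_series(tr2, 1)$values[2]
  ref <- bio3d::rmsd(as.numeric(t(xyz)), as.numeric(t(f2)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)

  expect_error(rmsd_series(tr, 1, selection = 1:2), "at least 3")
  line <- make_point_structure(cbind(1:4, 0, 0))
  tl <- new_trajectory(line, list(as.matrix(line$atoms[, c("x", "y", "z")])))
  expect_error(rmsd_series(tl, 1), "collinear")
})

test_that("interaction energies satisfy LJ/Coulomb identities and the pair oracle", {
  mk <- function(r) {
    s <- make_point_structure(rbind(c(0, 0, 0), c(r, 0, 0)))
    new_trajectory(s, list(as.matrix(s$atoms[, c("x", "y", "z")])))
  }
  tab <- data.frame(serial = 1:2, charge_e = c(1, 1), sigma_A = c(3, 3),
                    epsilon_kcal = c(0.1, 0.1))
  np <- nonbonded_params(tab)
  ## Coulomb constant definition at r = 1
  e1 <- interaction_energy_series(mk(1), 1L, 2L, np)
  expect_equal(e1$electrostatic, 332.0636)
  ## LJ zero crossing at r = sigma, minimum -eps at 2^(1/6) sigma
  expect_equal(interaction_energy_series(mk(3), 1L, 2L, np)$vdw, 0,
               tolerance = 1e-12)
  expect_equal(interaction_energy_series(mk(2^(1 / 6) * 3), 1L, 2L, np)$vdw,
               -0.1, tolerance = 1e-9)
  ## beyond the cutoff contributes nothing
  np10 <- nonbonded_params(tab, cutoff = 10)
  far <- interaction_energy_series(mk(50), 1L, 2L, np10)
  expect_equal(far$electrostatic, 0)
  expect_equal(far$vdw, 0)

  ## 5x5 groups against a brute-force double loop (infinite cutoff)
  set.seed(23)
  xyz <- matrix(runif(30, 0, 8), ncol = 3)
  s10 <- make_point_structure(xyz)
  tab10 <- data.frame(serial = 1:10, charge_e = runif(10, -0.8, 0.8),
                      sigma_A = runif(10, 2.5, 3.5),
                      epsilon_kcal = runif(10, 0.05, 0.21))
  np10b <- nonbonded_params(tab10, cutoff = 1e9)
  tr10 <- new_trajectory(s10, list(xyz))
  en <- interaction_energy_series(tr10, 1:5, 6:10, np10b)
  ee <- 0; vv <- 0
  for (i in 1:5) for (j in 6:10) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ee <- ee + 332.0636 * tab10$charge_e[i] * tab10$charge_e[j] / r
    sg <- (tab10$sigma_A[i] + tab10$sigma_A[j]) / 2
    ep <- sqrt(tab10$epsilon_kcal[i] * tab10$epsilon_kcal[j])
    vv <- vv + 4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  expect_equal(en$electrostatic, ee, tolerance = 1e-12)
  expect_equal(en$vdw, vv, tolerance = 1e-12)

  ## symmetric under swapping the groups
  sw <- interaction_energy_series(tr10, 6:10, 1:5, np10b)
  expect_equal(sw$electrostatic, en$electrostatic)
  expect_equal(sw$vdw, en$vdw)

  ## missing parameters are reported by atom serial
  tab9 <- tab10[-3, ]
  expect_error(interaction_energy_series(tr10, 1:5, 6:10,
                                         nonbonded_params(tab9)),
               "serial")
})
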