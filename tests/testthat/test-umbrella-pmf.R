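test_that("window-center construction is inclusive and commensurate", {
  expect_length(generate_window_centers(14.1, 23.1, 0.2), 46L)
  expect_length(generate_window_centers(14.1, 25.9, 0.2), 60L)
  expect_length(generate_window_centers(14.1, 27.9, 0.2), 70L)
  expect_equal(generate_window_centers(0, 1, 1), c(0, 1))
  cs <- generate_window_centers(14.1, 23.1, 0.2)
  expect_equal(cs[1], 14.1)
  expect_equal(cs[length(cs)], 23.1)
  expect_equal(diff(cs), rep(0.2, 45), tolerance = 1e-12)
  expect_error(generate_window_centers(0, 1, 0.3), "commensurate")
})

test_that("burn-in discards the leading ceiling(fraction * n) samples per window", {
  w <- list(umbrella_window(1, 0, 1, seq_len(100)),
            umbrella_window(2, 1, 1, seq_len(10)))
  out <- apply_burn_in(w, 0.15)
  expect_length(out[[1]]$rc_samples, 85L)
  expect_equal(out[[1]]$rc_samples[1], 16)
  expect_length(out[[2]]$rc_samples, 8L)
  expect_equal(attr(out, "n_dropped"), c(15L, 2L))
  expect_equal(apply_burn_in(w, 0)[[1]]$rc_samples, seq_len(100))
  tiny <- list(umbrella_window(7, 0, 1, 1))
  expect_error(apply_burn_in(tiny, 0.5), "window 7")
})

test_that("MBAR handles the unbiased single-window and symmetric two-window limits", {
  w1 <- list(umbrella_window(1, 0, 0, rnorm(50)))
  m1 <- solve_mbar(w1)
  expect_equal(m1$f, 0)
  expect_equal(m1$weights, rep(1 / 50, 50))
  expect_true(m1$converged)

  set.seed(4)
  xs <- rnorm(200, 0.5, 0.3)
  w2 <- list(umbrella_window(1, 0.5, 3, xs), umbrella_window(2, 0.5, 3, xs))
  m2 <- solve_mbar(w2)
  expect_lt(abs(m2$f[2]), 1e-8)
})

test_that("MBAR free energies match 1-D quadrature of analytic partition functions", {
  pot <- potential_harmonic(kappa = 2, x0 = 0)
  sp <- sampler_spec(pot, centers = seq(-1.2, 1.2, length.out = 9),
                     force_constant = 5, n_samples = 1500, seed = 11)
  w <- sample_umbrella_windows(sp)
  mb <- solve_mbar(w)
  expect_true(mb$converged)
  beta <- 1 / (0.0019872041 * 300)
  Zk <- vapply(sp$centers, function(c0)
    stats::integrate(function(x)
      exp(-beta * (pot$U(x) + 5 * (x - c0)^2)), -10, 10)$value, numeric(1))
  f_oracle <- -log(Zk / Zk[1]) / beta
  expect_lt(max(abs(mb$f - f_oracle)), 0.15)
  ## weights: strictly positive, normalized to 1e-10
  expect_true(all(mb$weights > 0))
  expect_lt(abs(sum(mb$weights) - 1), 1e-10)
})

test_that("MBAR is invariant to a constant shift of all bias energies", {
  set.seed(8)
  bU <- matrix(runif(3 * 60, 0, 4), nrow = 3)
  Nk <- c(20L, 20L, 20L)
  a <- etkit:::.mbar_solve(bU, Nk, 1e-10, 1e5)
  b <- etkit:::.mbar_solve(bU + 2.5, Nk, 1e-10, 1e5)
  expect_equal(a$g, b$g, tolerance = 1e-8)
  wa <- exp(-a$logD) / sum(exp(-a$logD))
  wb <- exp(-b$logD) / sum(exp(-b$logD))
  expect_equal(wa, wb, tolerance = 1e-8)
})

test_that("doubling the sample count leaves free energies stable", {
  pot <- potential_double_well(1.5, 1)
  f_at <- function(n, seed) {
    sp <- sampler_spec(pot, centers = seq(-1.5, 1.5, length.out = 16),
                       force_constant = 8, n_samples = n, seed = seed)
    solve_mbar(sample_umbrella_windows(sp))$f
  }
  ## bound = 3x the correlation-aware error scale kT sqrt(2 tau / n) with
  ## tau ~ 50 Metropolis steps near the barrier top
  expect_lt(max(abs(f_at(4000, 21) - f_at(8000, 22))), 0.25)
})

test_that("dihedral PCA isolates planted variation modes", {
  expect_error(fit_dihedral_pca(matrix(1, 10, 3)), "zero total variance")

  set.seed(5)
  n <- 500
  ## only dihedral 2 varies: PC loadings supported on its sin/cos pair,
  ## and (rank <= 2) the first two components carry all variance
  X <- cbind(rep(0.4, n), rnorm(n, 0, 0.3), rep(-2, n))
  p <- fit_dihedral_pca(X)
  offpair <- p$components[1, -(3:4)]
  expect_lt(max(abs(offpair)), 1e-10)
  Z <- etkit:::.embed_dihedrals(X)
  total_var <- sum(apply(Z, 2, var))
  expect_equal(sum(p$explained_variance[1:2]), total_var, tolerance = 1e-9)
  expect_lt(p$explained_variance[3], 1e-20)

  ## two orthogonal small-angle modes with variance ratio ~4:1
  X2 <- cbind(rnorm(n, 0, 0.2), rnorm(n, 0, 0.1))
  p2 <- fit_dihedral_pca(X2)
  expect_equal(p2$explained_variance[1] / p2$explained_variance[2], 4,
               tolerance = 0.35)

  ## components orthonormal; PC1 sign fixed (largest loading positive)
  G <- p2$components %*% t(p2$components)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  expect_gt(p2$components[1, which.max(abs(p2$components[1, ]))], 0)
  expect_true(all(diff(p2$explained_variance) <= 1e-12))

  ## invariant under relabeling of samples
  perm <- sample(n)
  p3 <- fit_dihedral_pca(X2[perm, ])
  expect_equal(p3$components, p2$components, tolerance = 1e-9)
  expect_equal(p3$pc1_score(X2), p2$pc1_score(X2), tolerance = 1e-9)
})

test_that("PMF projection inverts a known Boltzmann density", {
  ## uniform weights on standard-normal samples: F(s) = kB T s^2 / 2 + const
  set.seed(31)
  w <- list(umbrella_window(1, 0, 0, rnorm(50000)))
  mb <- solve_mbar(w)
  pr <- project_pmf(mb, cv_rc(), bin_edges = seq(-2, 2, length.out = 61))
  kT <- 0.0019872041 * 300
  ok <- !pr$empty_mask
  fit <- lm(pr$F[ok] ~ I(pr$bin_centers[ok]^2))
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(unname(coef(fit)[2]), kT / 2, tolerance = 0.08)

  ## single unbiased window reduces to -kT log(histogram mass), min-shifted
  counts <- vapply(seq_len(60), function(m) {
    e <- seq(-2, 2, length.out = 61)
    idx <- findInterval(mb$rc, e, rightmost.closed = TRUE)
    sum(idx == m)
  }, numeric(1))
  inside <- sum(counts)
  Fref <- -kT * log(counts / inside)
  Fref <- Fref - min(Fref[is.finite(Fref)])
  expect_equal(pr$F[ok], Fref[ok], tolerance = 1e-9)
})

test_that("degenerate projections are flagged rather than silently wrong", {
  ## all weight effectively on one sample
  fake <- structure(list(
    f = 0, weights = c(1, rep(0, 9)), converged = TRUE,
    rc = c(5, 1:9 / 10), features = NULL, bias = bias_model()),
    class = "etk_mbar")
  pr <- project_pmf(fake, cv_rc(), bin_edges = seq(0, 6, by = 1))
  expect_true(pr$width_warning)
  expect_equal(sum(!pr$empty_mask), 1L)
  expect_equal(pr$F[!pr$empty_mask], 0)
  expect_true(all(is.na(pr$F[pr$empty_mask])))
  ## non-converged MBAR refuses to project
  bad <- structure(list(converged = FALSE), class = "etk_mbar")
  expect_error(project_pmf(bad, cv_rc()), "converge")
})

test_that("barrier extraction reads basins and the inter-basin maximum", {
  prof <- structure(list(bin_centers = c(0, 1, 2), F = c(0, 5, 1),
                         weight = c(1, 1, 1), empty_mask = rep(FALSE, 3),
                         width_warning = FALSE, cv = "rc",
                         temperature = 300), class = "etk_pmf")
  b <- extract_barrier(prof, c(-0.5, 0.5), c(1.5, 2.5))
  expect_equal(b$barrier, 5)
  expect_equal(b$delta_AB, 1)
  ## monotone profile: barrier equals the endpoint difference
  mono <- prof
  mono$F <- c(0, 1.5, 3)
  bm <- extract_barrier(mono, c(-0.5, 0.5), c(1.5, 2.5))
  expect_equal(bm$barrier, 3)
  expect_error(extract_barrier(prof, c(0, 1.6), c(1.5, 2.5)), "overlap")
})

test_that("double-well umbrella run recovers the planted barrier", {
  sp <- sampler_spec(potential_double_well(1.5, 1),
                     centers = seq(-1.5, 1.5, length.out = 31),
                     force_constant = 10, n_samples = 2000, seed = 13)
  w <- apply_burn_in(sample_umbrella_windows(sp), 0.15)
  mb <- solve_mbar(w)
  expect_true(mb$converged)
  pr <- project_pmf(mb, cv_rc(), n_bins = 50)
  b <- extract_barrier(pr, c(-1.4, -0.6), c(0.6, 1.4))
  expect_lt(abs(b$barrier - 1.5), 0.4)
  expect_lt(abs(b$delta_AB), 0.3)  # symmetric wells
})

test_that("PC1 of planted dihedral windows serves as a projection coordinate", {
  ## rc and one dihedral co-vary; projecting on PC1 gives a well-formed PMF
  set.seed(41)
  centers <- seq(-1, 1, length.out = 7)
  w <- lapply(seq_along(centers), function(k) {
    x <- rnorm(400, centers[k], 0.25)
    umbrella_window(k, centers[k], 3, x,
                    feature_samples = cbind(0.8 * x + rnorm(400, 0, 0.05),
                                            rep(1.2, 400)))
  })
  mb <- solve_mbar(w)
  pca <- fit_dihedral_pca(do.call(rbind, lapply(w, `[[`, "feature_samples")))
  pr <- project_pmf(mb, cv_pc1(pca), n_bins = 30)
  expect_true(sum(!pr$empty_mask) > 10)
  expect_equal(min(pr$F, na.rm = TRUE), 0)
})

test_that("conformations classify by the 20/22-Angstrom thresholds", {
  expect_equal(classify_conformation(27.4), "distal")
  expect_equal(classify_conformation(18.38), "proximal")
  expect_equal(classify_conformation(21.0), "intermediate")
  expect_equal(classify_conformation(c(23.56, 19.78, 20.5)),
               c("distal", "proximal", "intermediate"))
  expect_error(classify_conformation(-1), ">= 0")
})

test_that("umbrella CSV round-trips windows with dihedral features", {
  w <- list(umbrella_window(1, 14.1, 100, c(14.0, 14.2),
                            feature_samples = rbind(c(0.1, 0.2), c(0.3, 0.4))),
            umbrella_window(2, 14.3, 100, c(14.25, 14.31)))
  f <- tempfile(fileext = ".csv")
  ## windows must share feature presence for MBAR, but the CSV layer is lax
  write_umbrella_csv(w[1], f)
  back <- read_umbrella_csv(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$rc_samples, w[[1]]$rc_samples)
  expect_equal(back[[1]]$feature_samples, w[[1]]$feature_samples,
               ignore_attr = TRUE)
  expect_equal(back[[1]]$force_constant, 100)
  unlink(f)
})
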