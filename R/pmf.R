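## Umbrella-sampling free-energy machinery: window containers, MBAR solver
## (self-consistent multistate reweighting with log-sum-exp stabilization),
## collective-variable projection, dihedral PCA, barrier extraction, and
## distal/proximal classification.

#' Harmonic-bias convention and thermodynamic state
#'
#' The bias energy of window k at reaction-coordinate value x is
#' `U_k(x) = k (x - c_k)^2` under `k_full` (default, the convention under
#' which a stated force constant of 100 kcal/mol/A^2 is meaningful for the
#' MD engine family producing such data) or `U_k(x) = k/2 (x - c_k)^2` under
#' `k_half`.
#'
#' @param convention `"k_full"` or `"k_half"`.
#' @param temperature Temperature in K (default 300).
#' @return An `etk_bias_model` with fields `convention`, `temperature`, `kB`
#'   (0.0019872041 kcal/mol/K) and `beta` (1/kB T).
#' @export
bias_model <- function(convention = c("k_full", "k_half"), temperature = 300) {
  convention <- match.arg(convention)
  stopifnot(temperature > 0)
  structure(list(convention = convention, temperature = temperature,
                 kB = .kB, beta = 1 / (.kB * temperature)),
            class = "etk_bias_model")
}

#' A single umbrella window
#'
#' @param window_id Integer id.
#' @param bias_center Bias center (reaction-coordinate units, e.g. Angstrom).
#' @param force_constant Harmonic force constant, kcal/mol per unit^2;
#'   `0` denotes an unbiased window.
#' @param rc_samples Numeric vector of reaction-coordinate samples (>= 1).
#' @param feature_samples Optional per-sample feature matrix (rows aligned
#'   1:1 with `rc_samples`), e.g. backbone dihedrals in radians.
#' @return An `etk_window`.
#' @export
umbrella_window <- function(window_id, bias_center, force_constant,
                            rc_samples, feature_samples = NULL) {
  stopifnot(force_constant >= 0, length(rc_samples) >= 1L,
            all(is.finite(rc_samples)))
  if (!is.null(feature_samples)) {
    feature_samples <- as.matrix(feature_samples)
    if (nrow(feature_samples) != length(rc_samples))
      stop("feature_samples must align 1:1 with rc_samples")
  }
  structure(list(window_id = as.integer(window_id),
                 bias_center = bias_center,
                 force_constant = force_constant,
                 rc_samples = as.numeric(rc_samples),
                 feature_samples = feature_samples),
            class = "etk_window")
}

#' Inclusive arithmetic sequence of window centers
#'
#' @param rc_min,rc_max Range endpoints (inclusive).
#' @param spacing Positive spacing; `(rc_max - rc_min) / spacing` must be an
#'   integer to within 1e-6.
#' @return Numeric vector of centers `rc_min, rc_min + spacing, ..., rc_max`.
#' @examples
#' length(generate_window_centers(14.1, 23.1, 0.2))  # 46
#' @export
generate_window_centers <- function(rc_min, rc_max, spacing) {
  stopifnot(rc_max > rc_min, spacing > 0)
  n <- (rc_max - rc_min) / spacing
  if (abs(n - round(n)) > 1e-6)
    stop("range is not commensurate with spacing")
  rc_min + spacing * seq(0, round(n))
}

#' Discard equilibration samples from each window
#'
#' The first `ceiling(fraction * n)` samples of each window are dropped
#' (e.g. fraction 0.15 retains the last 85 of 100 samples).
#'
#' @param windows List of [umbrella_window()] objects.
#' @param fraction Burn-in fraction in `[0, 1)`.
#' @return The windows with early samples removed; the number dropped per
#'   window is recorded in attribute `"n_dropped"`.
#' @export
apply_burn_in <- function(windows, fraction = 0.15) {
  stopifnot(fraction >= 0, fraction < 1)
  dropped <- integer(length(windows))
  out <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    n <- length(w$rc_samples)
    nd <- ceiling(fraction * n)
    if (n - nd < 1L)
      stop("burn-in would empty window ", w$window_id)
    dropped[i] <<- nd
    if (nd > 0L) {
      w$rc_samples <- w$rc_samples[-seq_len(nd)]
      if (!is.null(w$feature_samples))
        w$feature_samples <- w$feature_samples[-seq_len(nd), , drop = FALSE]
    }
    w
  })
  attr(out, "n_dropped") <- dropped
  out
}

#' Solve the MBAR equations for a set of umbrella windows
#'
#' Estimates the relative dimensionless free energies `f_k` of the biased
#' ensembles by the multistate Bennett acceptance ratio: the self-consistent
#' identities
#' `exp(-b f_k) = sum_n exp(-b U_k(x_n)) / sum_j N_j exp(-b (U_j(x_n) - f_j))`
#' are iterated (with log-sum-exp stabilization, preceded by quasi-Newton
#' minimization of the equivalent convex objective) until the largest change
#' in any `f_k` is below `tolerance`. Unbiased sample weights
#' `w_n \propto 1 / sum_j N_j exp(b f_j - b U_j(x_n))` (reweighting to the
#' unbiased ensemble, `U_0 = 0`) are returned normalized to sum 1.
#'
#' @param windows List of [umbrella_window()] objects (samples as retained,
#'   i.e. after any [apply_burn_in()]).
#' @param bias An [bias_model()].
#' @param tolerance Convergence threshold on `max |delta f|`, kcal/mol.
#' @param max_iter Iteration cap for the self-consistent stage.
#' @return An `etk_mbar`: `f` (kcal/mol, `f[1] = 0`), `weights` (one per
#'   retained sample, pooled in window order), `n_retained_per_window`,
#'   `converged`, `final_residual`, plus the pooled `rc`, `features`,
#'   `window_of` and the `bias` model for downstream projection.
#' @export
solve_mbar <- function(windows, bias = bias_model(), tolerance = 1e-8,
                       max_iter = 1e5) {
  stopifnot(length(windows) >= 1L)
  K <- length(windows)
  centers <- vapply(windows, function(w) w$bias_center, numeric(1))
  kcons <- vapply(windows, function(w) w$force_constant, numeric(1))
  Nk <- vapply(windows, function(w) length(w$rc_samples), integer(1))
  x <- unlist(lapply(windows, function(w) w$rc_samples), use.names = FALSE)
  if (any(!is.finite(x))) stop("non-finite sample values")
  feats <- NULL
  if (!is.null(windows[[1]]$feature_samples))
    feats <- do.call(rbind, lapply(windows, function(w) w$feature_samples))
  window_of <- rep(seq_len(K), Nk)
  kfac <- if (bias$convention == "k_full") 1 else 0.5
  ## bU[k, n] = beta * U_k(x_n)
  bU <- matrix(0, K, length(x))
  for (k in seq_len(K))
    bU[k, ] <- bias$beta * kfac * kcons[k] * (x - centers[k])^2
  if (any(!is.finite(bU))) stop("non-finite bias energies")

  sol <- .mbar_solve(bU, Nk, tolerance * bias$beta, max_iter)
  w <- exp(-sol$logD - .logsumexp(-sol$logD))
  structure(list(
    f = sol$g / bias$beta,
    weights = w,
    n_retained_per_window = Nk,
    converged = sol$converged,
    final_residual = sol$residual / bias$beta,
    rc = x, features = feats, window_of = window_of,
    centers = centers, force_constants = kcons, bias = bias
  ), class = "etk_mbar")
}

#' @export
print.etk_mbar <- function(x, ...) {
  cat(sprintf(
    "etk_mbar: %d windows, %d samples, converged = %s (residual %.2e kcal/mol)\n",
    length(x$f), length(x$weights), x$converged, x$final_residual))
  cat("  f (kcal/mol):", paste(sprintf("%.3f", utils::head(x$f, 8)),
                               collapse = " "),
      if (length(x$f) > 8) "...\n" else "\n")
  invisible(x)
}

## Core solver on the dimensionless bias matrix. g_k = beta * f_k, g[1] = 0.
.mbar_solve <- function(bU, Nk, gtol, max_iter) {
  K <- nrow(bU); N <- ncol(bU)
  logNk <- log(Nk)
  col_lse <- function(M) {
    mx <- M[1, ]
    if (K > 1) for (k in 2:K) mx <- pmax(mx, M[k, ])
    mx + log(colSums(exp(M - rep(mx, each = K))))
  }
  logD_of <- function(g) col_lse((logNk + g) - bU)
  obj <- function(g) mean(logD_of(g)) - sum(Nk * g) / N
  grad <- function(g) {
    M <- (logNk + g) - bU
    L <- col_lse(M)
    rowSums(exp(M - rep(L, each = K))) / N - Nk / N
  }
  g <- numeric(K)
  if (K > 1) {
    opt <- stats::optim(g, obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-15))
    g <- opt$par - opt$par[1]
  }
  ## self-consistent polish until the stated identities hold to tolerance
  converged <- FALSE
  residual <- Inf
  for (it in seq_len(max_iter)) {
    L <- logD_of(g)
    M <- -bU - rep(L, each = K)
    mx <- apply(M, 1, max)
    gnew <- -(mx + log(rowSums(exp(M - mx))))
    gnew <- gnew - gnew[1]
    residual <- max(abs(gnew - g))
    g <- gnew
    if (residual <= gtol) { converged <- TRUE; break }
  }
  list(g = g, converged = converged, residual = residual,
       logD = logD_of(g))
}

#' Collective-variable evaluators
#'
#' `cv_rc()` is the identity on the reaction coordinate; `cv_pc1(pca)` scores
#' each sample's dihedral feature vector on the first principal component of
#' a fitted [fit_dihedral_pca()] model; `make_cv()` wraps an arbitrary
#' function of `(rc, features)`.
#'
#' @param name Label for the variable.
#' @param fun Function `(rc, features) -> numeric` evaluated on the pooled
#'   samples.
#' @return An `etk_cv` object.
#' @export
make_cv <- function(name, fun) {
  structure(list(name = name, fun = fun), class = "etk_cv")
}

#' @rdname make_cv
#' @export
cv_rc <- function() make_cv("rc", function(rc, features) rc)

#' @rdname make_cv
#' @param pca A [fit_dihedral_pca()] model.
#' @export
cv_pc1 <- function(pca) {
  stopifnot(inherits(pca, "etk_dihedral_pca"))
  make_cv("pc1", function(rc, features) {
    if (is.null(features)) stop("cv_pc1 requires feature samples")
    pca$pc1_score(features)
  })
}

#' Principal component analysis of backbone dihedrals
#'
#' Each dihedral phi is embedded as `(cos phi, sin phi)` to remove the
#' periodic discontinuity, the embedded features are mean-centered, and the
#' covariance is eigendecomposed. Components are sorted by decreasing
#' variance; each component's sign is fixed so that its largest-magnitude
#' loading is positive, making PC1 reproducible.
#'
#' @param feature_samples n x m matrix of dihedrals in radians (n >= 2
#'   samples, m >= 1 dihedrals).
#' @return An `etk_dihedral_pca`: `feature_mean` (over the 2m embedded
#'   columns), `components` (orthonormal rows), `explained_variance`
#'   (non-increasing), and `pc1_score(newX)` mapping a dihedral matrix to
#'   PC1 scores.
#' @export
fit_dihedral_pca <- function(feature_samples) {
  X <- as.matrix(feature_samples)
  stopifnot(nrow(X) >= 2L, ncol(X) >= 1L)
  Z <- .embed_dihedrals(X)
  if (sum(apply(Z, 2, stats::var)) <= 0)
    stop("zero total variance: all samples identical")
  p <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  rot <- p$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  ctr <- p$center
  structure(list(
    feature_mean = ctr,
    components = t(rot),
    explained_variance = p$sdev^2,
    pc1_score = function(newX) {
      Zn <- .embed_dihedrals(as.matrix(newX))
      as.numeric(sweep(Zn, 2, ctr) %*% rot[, 1])
    }
  ), class = "etk_dihedral_pca")
}

.embed_dihedrals <- function(X) {
  m <- ncol(X)
  Z <- matrix(0, nrow(X), 2 * m)
  Z[, 2 * seq_len(m) - 1] <- cos(X)
  Z[, 2 * seq_len(m)] <- sin(X)
  colnames(Z) <- paste0(rep(c("cos", "sin"), m),
                        rep(seq_len(m), each = 2))
  Z
}

#' Project the unbiased free-energy profile onto a collective variable
#'
#' Bins the MBAR-reweighted unbiased probability
#' `P0(s_m) = sum_n w_n 1[s(x_n) in bin m] / sum_n w_n` and reports
#' `F0(s_m) = -kB T log P0(s_m)`, min-shifted to zero over non-empty bins;
#' empty bins are masked (NA).
#'
#' @param mbar A converged [solve_mbar()] result.
#' @param cv An `etk_cv` evaluator (default [cv_rc()]).
#' @param n_bins Number of equal-width bins (default 50) over the weighted
#'   0.5--99.5 percentile range of the variable.
#' @param bin_edges Optional explicit bin edges (overrides `n_bins`).
#' @return An `etk_pmf`: `bin_centers`, `F` (kcal/mol), `weight` (per-bin
#'   effective weight), `empty_mask`, `width_warning` (TRUE when every sample
#'   fell into a single bin), and the CV `name`.
#' @export
project_pmf <- function(mbar, cv = cv_rc(), n_bins = 50, bin_edges = NULL) {
  stopifnot(inherits(mbar, "etk_mbar"))
  if (!mbar$converged) stop("MBAR did not converge; cannot project")
  s <- cv$fun(mbar$rc, mbar$features)
  if (length(s) != length(mbar$weights))
    stop("collective variable must be evaluable for every retained sample")
  w <- mbar$weights
  width_warning <- FALSE
  if (is.null(bin_edges)) {
    qq <- .weighted_quantile(s, w, c(0.005, 0.995))
    if (qq[1] == qq[2]) {
      width_warning <- TRUE
      qq <- qq + c(-0.5, 0.5)
    }
    bin_edges <- seq(qq[1], qq[2], length.out = n_bins + 1)
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(s, bin_edges, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= nb
  wsum <- sum(w[inside])
  wt <- vapply(seq_len(nb), function(m) sum(w[inside & idx == m]),
               numeric(1))
  P <- wt / wsum
  kT <- mbar$bias$kB * mbar$bias$temperature
  F <- ifelse(P > 0, -kT * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  if (sum(P > 0) == 1L) width_warning <- TRUE
  structure(list(
    bin_centers = (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2,
    F = F, weight = wt, empty_mask = P == 0,
    width_warning = width_warning, cv = cv$name,
    temperature = mbar$bias$temperature
  ), class = "etk_pmf")
}

#' @export
print.etk_pmf <- function(x, ...) {
  cat(sprintf("etk_pmf over '%s': %d bins, F range [0, %.2f] kcal/mol%s\n",
              x$cv, length(x$F), max(x$F, na.rm = TRUE),
              if (x$width_warning) " (width warning)" else ""))
  invisible(x)
}

#' @export
plot.etk_pmf <- function(x, ...) {
  graphics::plot(x$bin_centers, x$F, type = "b", pch = 16,
                 xlab = x$cv, ylab = "F (kcal/mol)", ...)
  invisible(x)
}

#' Transition barrier between two basins of a free-energy profile
#'
#' `barrier = max F over the span between the two basin minima - F(basin A
#' minimum)`; `delta_AB = F(basin B minimum) - F(basin A minimum)`.
#'
#' @param profile An `etk_pmf`.
#' @param basin_A_range,basin_B_range Length-2 numeric ranges (CV units),
#'   non-overlapping, each containing at least one non-empty bin.
#' @return List with `barrier` and `delta_AB`, kcal/mol.
#' @export
extract_barrier <- function(profile, basin_A_range, basin_B_range) {
  stopifnot(length(basin_A_range) == 2L, length(basin_B_range) == 2L)
  a <- sort(basin_A_range); b <- sort(basin_B_range)
  if (max(a[1], b[1]) < min(a[2], b[2]))
    stop("basin ranges overlap")
  bc <- profile$bin_centers
  ok <- !profile$empty_mask & !is.na(profile$F)
  inA <- which(ok & bc >= a[1] & bc <= a[2])
  inB <- which(ok & bc >= b[1] & bc <= b[2])
  if (!length(inA) || !length(inB))
    stop("each basin range must contain at least one non-empty bin")
  iA <- inA[which.min(profile$F[inA])]
  iB <- inB[which.min(profile$F[inB])]
  span <- seq(min(iA, iB), max(iA, iB))
  span <- span[ok[span]]
  list(barrier = max(profile$F[span]) - profile$F[iA],
       delta_AB = profile$F[iB] - profile$F[iA])
}

#' Classify ferredoxin-domain conformations by d[FeS-Heme]
#'
#' Distances above 22 Angstrom are distal, below 20 Angstrom proximal,
#' in between intermediate.
#'
#' @param d_fes_heme Distance(s), Angstrom, >= 0.
#' @return Character vector: `"distal"`, `"proximal"` or `"intermediate"`.
#' @export
classify_conformation <- function(d_fes_heme) {
  if (any(!is.finite(d_fes_heme)) || any(d_fes_heme < 0))
    stop("distances must be finite and >= 0")
  ifelse(d_fes_heme > 22, "distal",
         ifelse(d_fes_heme < 20, "proximal", "intermediate"))
}

#' Read / write umbrella-window tables
#'
#' CSV layout: `window_id,bias_center,force_constant,sample_index,rc_value`
#' plus optional dihedral columns `dih_1,...,dih_m` (radians).
#'
#' @param file Path to a CSV file.
#' @return For `read_umbrella_csv`, a list of [umbrella_window()] objects.
#' @export
read_umbrella_csv <- function(file) {
  df <- utils::read.csv(file)
  need <- c("window_id", "bias_center", "force_constant", "sample_index",
            "rc_value")
  if (!all(need %in% names(df)))
    stop("window CSV must have columns ", paste(need, collapse = ", "))
  dihcols <- grep("^dih_", names(df), value = TRUE)
  lapply(split(df, df$window_id), function(d) {
    d <- d[order(d$sample_index), ]
    umbrella_window(d$window_id[1], d$bias_center[1], d$force_constant[1],
                    d$rc_value,
                    if (length(dihcols)) as.matrix(d[, dihcols, drop = FALSE])
                    else NULL)
  })
}

#' @rdname read_umbrella_csv
#' @param windows List of [umbrella_window()] objects.
#' @export
write_umbrella_csv <- function(windows, file) {
  rows <- lapply(windows, function(w) {
    d <- data.frame(window_id = w$window_id, bias_center = w$bias_center,
                    force_constant = w$force_constant,
                    sample_index = seq_along(w$rc_samples),
                    rc_value = w$rc_samples)
    if (!is.null(w$feature_samples)) {
      fs <- as.data.frame(w$feature_samples)
      names(fs) <- paste0("dih_", seq_len(ncol(fs)))
      d <- cbind(d, fs)
    }
    d
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}
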