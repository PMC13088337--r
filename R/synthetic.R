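## Synthetic-data generators. Every generator is a pure function of its spec
## (seed included) and attaches a machine-readable truth record that the test
## suite consumes directly.

#' Analytic 1-D potentials
#'
#' `potential_harmonic`: `U(x) = kappa/2 (x - x0)^2`.
#' `potential_double_well`: `U(x) = a (x^2 - b^2)^2`, with minima at `+/- b`
#' and an exact barrier of `a b^4` at `x = 0`. Energies in kcal/mol.
#' The double-well default (`a = 1.5`, `b = 1`) plants a 1.5 kcal/mol
#' barrier -- the hardest-to-resolve regime of interest; `a = 6` or
#' `a = 17.5` give the stiffer presets for stress tests.
#'
#' @param kappa Harmonic spring constant, kcal/mol per unit^2.
#' @param x0 Harmonic minimum position.
#' @return An `etk_potential`: `kind`, `U(x)`, `params`, `analytic_barrier`,
#'   `analytic_minima`.
#' @export
potential_harmonic <- function(kappa = 2, x0 = 0) {
  stopifnot(kappa > 0)
  structure(list(kind = "harmonic",
                 U = function(x) 0.5 * kappa * (x - x0)^2,
                 params = list(kappa = kappa, x0 = x0),
                 analytic_barrier = NA_real_,
                 analytic_minima = x0),
            class = "etk_potential")
}

#' @rdname potential_harmonic
#' @param a Quartic stiffness, kcal/mol per unit^4.
#' @param b Well position (minima at `+/- b`).
#' @export
potential_double_well <- function(a = 1.5, b = 1) {
  stopifnot(a > 0, b > 0)
  structure(list(kind = "double_well",
                 U = function(x) a * (x^2 - b^2)^2,
                 params = list(a = a, b = b),
                 analytic_barrier = a * b^4,
                 analytic_minima = c(-b, b)),
            class = "etk_potential")
}

#' Umbrella-sampler specification
#'
#' Defaults reproduce the reference double-well study design: 46 windows
#' spanning the two wells of the default [potential_double_well()] (barrier
#' 1.5 kcal/mol), a harmonic bias `U = k (x - c)^2` (`k_full`) with
#' `k = 10` kcal/mol per unit^2 chosen so adjacent windows overlap well,
#' 5000 production samples per window at 300 K.
#'
#' @param potential An `etk_potential`.
#' @param centers Window bias centers.
#' @param force_constant Bias force constant (kcal/mol per unit^2).
#' @param convention Bias convention, see [bias_model()].
#' @param n_samples Production samples per window.
#' @param step_size Initial Metropolis step; auto-tuned to ~40% acceptance
#'   during burn-in, then frozen.
#' @param burn_in_steps Tuning/equilibration steps discarded per window.
#' @param temperature K.
#' @param seed Integer RNG seed (recorded in the truth record).
#' @return An `etk_sampler_spec`.
#' @export
sampler_spec <- function(potential = potential_double_well(),
                         centers = seq(-1.5, 1.5, length.out = 46),
                         force_constant = 10,
                         convention = c("k_full", "k_half"),
                         n_samples = 5000, step_size = NULL,
                         burn_in_steps = 500, temperature = 300, seed = 1) {
  convention <- match.arg(convention)
  stopifnot(inherits(potential, "etk_potential"), n_samples >= 1,
            force_constant >= 0, burn_in_steps >= 0)
  structure(list(potential = potential, centers = centers,
                 force_constant = force_constant, convention = convention,
                 n_samples = as.integer(n_samples), step_size = step_size,
                 burn_in_steps = as.integer(burn_in_steps),
                 temperature = temperature, seed = as.integer(seed)),
            class = "etk_sampler_spec")
}

#' Metropolis sampling of biased umbrella windows
#'
#' Samples `exp(-beta (U(x) + U_bias(x)))` per window by Metropolis Monte
#' Carlo (exact for the target distribution at any step size). The step size
#' is tuned toward ~40% acceptance during burn-in and then frozen; the
#' production acceptance rate is recorded, with a warning flag when it falls
#' outside `[0.1, 0.9]`.
#'
#' @param spec An [sampler_spec()].
#' @return List of [umbrella_window()] objects with attribute `"truth"`
#'   recording the potential, seed, per-window acceptance rates, step sizes
#'   and warning flags.
#' @export
sample_umbrella_windows <- function(spec) {
  stopifnot(inherits(spec, "etk_sampler_spec"))
  set.seed(spec$seed)
  beta <- 1 / (.kB * spec$temperature)
  kfac <- if (spec$convention == "k_full") 1 else 0.5
  U <- spec$potential$U
  kc <- spec$force_constant
  acc_rates <- numeric(length(spec$centers))
  steps <- numeric(length(spec$centers))
  windows <- vector("list", length(spec$centers))
  for (wi in seq_along(spec$centers)) {
    c0 <- spec$centers[wi]
    Etot <- function(x) U(x) + kfac * kc * (x - c0)^2
    step <- if (is.null(spec$step_size)) {
      ## start near the biased-distribution width
      if (kc > 0) sqrt(1 / (beta * 2 * kfac * kc)) else 0.5
    } else spec$step_size
    x <- c0
    e <- Etot(x)
    ## burn-in with step tuning every 50 moves
    nacc <- 0L
    for (t in seq_len(spec$burn_in_steps)) {
      xp <- x + stats::rnorm(1, 0, step)
      ep <- Etot(xp)
      if (log(stats::runif(1)) < -beta * (ep - e)) {
        x <- xp; e <- ep; nacc <- nacc + 1L
      }
      if (t %% 50L == 0L) {
        r <- nacc / 50
        if (r > 0.5) step <- step * 1.25
        if (r < 0.3) step <- step / 1.25
        nacc <- 0L
      }
    }
    ## production
    xs <- numeric(spec$n_samples)
    nacc <- 0L
    for (t in seq_len(spec$n_samples)) {
      xp <- x + stats::rnorm(1, 0, step)
      ep <- Etot(xp)
      if (log(stats::runif(1)) < -beta * (ep - e)) {
        x <- xp; e <- ep; nacc <- nacc + 1L
      }
      xs[t] <- x
    }
    acc_rates[wi] <- nacc / spec$n_samples
    steps[wi] <- step
    windows[[wi]] <- umbrella_window(wi, c0, kc, xs)
  }
  attr(windows, "truth") <- list(
    potential = spec$potential, seed = spec$seed,
    convention = spec$convention, temperature = spec$temperature,
    acceptance = acc_rates, step_sizes = steps,
    acceptance_warning = acc_rates < 0.1 | acc_rates > 0.9
  )
  windows
}

#' Random toy tunneling graph with an exhaustively enumerated optimum
#'
#' Builds a random geometric graph (3 <= n <= 12 nodes) with mixed covalent /
#' hydrogen-bond / through-space edges, donor at node 1 and acceptor at node
#' n, and computes the oracle best path by exhaustive enumeration of all
#' simple paths with the same tie-breaking as [best_pathway()]. If donor and
#' acceptor come out disconnected the graph is regenerated (up to 100
#' attempts).
#'
#' @param n_nodes Number of nodes (3..12; the oracle is exhaustive).
#' @param edge_density Probability of keeping each candidate pair.
#' @param seed Integer RNG seed.
#' @param params [tunneling_params()] used for decays.
#' @return List with `graph` (`etk_tunneling_graph`), `donor`, `acceptor`,
#'   and `oracle` (the enumerated `etk_pathway`).
#' @export
make_toy_graph <- function(n_nodes, edge_density = 0.5, seed = 1,
                           params = tunneling_params()) {
  stopifnot(n_nodes >= 3, n_nodes <= 12)
  set.seed(seed)
  for (attempt in seq_len(100)) {
    xyz <- matrix(stats::runif(3 * n_nodes, 0, 5), ncol = 3)
    pairs <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < edge_density
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                         xyz[pairs[, 2], , drop = FALSE])^2))
    type <- ifelse(d < 3.5,
                   sample(c("covalent", "hbond", "space"), nrow(pairs),
                          replace = TRUE, prob = c(0.35, 0.25, 0.4)),
                   "space")
    decay <- ifelse(
      type == "covalent", params$eps_covalent,
      ifelse(type == "hbond",
             pmin(params$hbond_prefactor *
                    exp(-params$hbond_decay * (d - params$hbond_offset)),
                  params$eps_covalent),
             pmin(params$space_prefactor *
                    exp(-params$space_decay * (d - params$space_offset)),
                  params$eps_covalent)))
    g <- structure(list(nodes = seq_len(n_nodes),
                        edges = data.frame(i = pairs[, 1], j = pairs[, 2],
                                           type = type, distance = d,
                                           decay = decay),
                        labels = as.character(seq_len(n_nodes))),
                   class = "etk_tunneling_graph")
    oracle <- exhaustive_pathway(g, 1L, n_nodes)
    if (oracle$found)
      return(list(graph = g, donor = 1L, acceptor = n_nodes,
                  oracle = oracle))
  }
  stop("could not generate a connected toy graph in 100 attempts")
}

#' Exhaustive best-pathway oracle
#'
#' Enumerates every simple path between the donor and acceptor sets and
#' returns the one maximizing the coupling product, ties broken by smaller
#' total length then lexicographic node sequence -- the reference against
#' which the Dijkstra-based [best_pathway()] is validated. Exponential cost;
#' intended for graphs of at most ~12 nodes.
#'
#' @param graph An `etk_tunneling_graph`.
#' @param donor,acceptor Atom-index sets.
#' @return An `etk_pathway` (with `found = FALSE` when no route exists).
#' @export
exhaustive_pathway <- function(graph, donor, acceptor) {
  nodes <- graph$nodes
  n <- length(nodes)
  pos <- function(a) match(a, nodes)
  e <- graph$edges
  ei <- pos(e$i); ej <- pos(e$j)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], k)
    adj[[ej[k]]] <- c(adj[[ej[k]]], k)
  }
  dset <- pos(intersect(donor, nodes))
  aset <- pos(intersect(acceptor, nodes))
  if (!length(dset) || !length(aset))
    stop("donor/acceptor atoms not present in the graph")
  best <- NULL
  lex_less <- function(a, b) {
    m <- min(length(a), length(b))
    for (t in seq_len(m)) {
      if (a[t] < b[t]) return(TRUE)
      if (a[t] > b[t]) return(FALSE)
    }
    length(a) < length(b)
  }
  consider <- function(path_nodes, path_edges) {
    W <- sum(-log(e$decay[path_edges]))
    R <- sum(e$distance[path_edges])
    sq <- nodes[path_nodes]
    if (is.null(best) ||
        W < best$W - 1e-9 ||
        (abs(W - best$W) <= 1e-9 &&
         (R < best$R - 1e-9 ||
          (abs(R - best$R) <= 1e-9 && lex_less(sq, best$seq))))) {
      best <<- list(W = W, R = R, seq = sq, edges = path_edges)
    }
  }
  visited <- rep(FALSE, n)
  dfs <- function(v, path_nodes, path_edges) {
    if (v %in% aset) {
      consider(path_nodes, path_edges)
      return(invisible())  # stopping at the first acceptor hit is optimal
    }
    for (k in adj[[v]]) {
      u <- if (ei[k] == v) ej[k] else ei[k]
      if (visited[u]) next
      visited[u] <<- TRUE
      dfs(u, c(path_nodes, u), c(path_edges, k))
      visited[u] <<- FALSE
    }
  }
  for (s in dset) {
    visited[] <- FALSE
    visited[s] <- TRUE
    if (s %in% aset) next
    dfs(s, s, integer())
  }
  if (is.null(best))
    return(structure(list(found = FALSE, node_sequence = integer(),
                          step_types = character(),
                          step_distances = numeric(),
                          total_R = NA_real_, total_coupling = NA_real_,
                          residue_trace = character()),
                     class = "etk_pathway"))
  lab <- if (is.null(graph$labels)) as.character(best$seq)
         else graph$labels[match(best$seq, nodes)]
  out <- structure(list(
    found = TRUE, node_sequence = best$seq,
    step_types = e$type[best$edges],
    step_distances = e$distance[best$edges],
    total_R = best$R,
    total_coupling = prod(e$decay[best$edges]),
    residue_trace = rle(lab)$values
  ), class = "etk_pathway")
  attr(out, "node_labels") <- lab
  out
}

#' Planted-trajectory specification
#'
#' Distance/angle laws: `list(dist = "constant", value = )`,
#' `list(dist = "gaussian", mean = , sd = )`, or
#' `list(dist = "mixture", means = , sds = , weights = )`. Defaults mirror a
#' wild-type reactive-geometry ensemble: d[Fe=O-H] ~ N(4.63, 1.01) Angstrom,
#' attack angle ~ N(157.3, 9.2) degrees, H-bond present in 37.28% of frames.
#'
#' @param n_frames Number of frames.
#' @param distance_law,angle_law Distribution specs (see above).
#' @param hbond_frame_fraction Fraction of frames with the planted H-bond
#'   formed (planted exactly: `round(fraction * n)` frames).
#' @param seed Integer RNG seed.
#' @return An `etk_planted_spec`.
#' @export
planted_trajectory_spec <- function(n_frames = 2000,
                                    distance_law = list(dist = "gaussian",
                                                        mean = 4.63,
                                                        sd = 1.01),
                                    angle_law = list(dist = "gaussian",
                                                     mean = 157.3, sd = 9.2),
                                    hbond_frame_fraction = 0.3728,
                                    seed = 1) {
  stopifnot(n_frames >= 1, hbond_frame_fraction >= 0,
            hbond_frame_fraction <= 1)
  structure(list(n_frames = as.integer(n_frames),
                 distance_law = distance_law, angle_law = angle_law,
                 hbond_frame_fraction = hbond_frame_fraction,
                 seed = as.integer(seed)),
            class = "etk_planted_spec")
}

.draw_law <- function(law, n, lo, hi) {
  x <- switch(law$dist,
    constant = rep(law$value, n),
    gaussian = stats::rnorm(n, law$mean, law$sd),
    mixture = {
      comp <- sample.int(length(law$weights), n, replace = TRUE,
                         prob = law$weights)
      stats::rnorm(n, law$means[comp], law$sds[comp])
    },
    stop("unknown distribution kind: ", law$dist))
  if (law$dist == "constant") {
    if (any(x <= lo | x >= hi))
      stop("infeasible geometry: constant value outside (", lo, ", ", hi, ")")
    return(x)
  }
  ## redraw the negligible mass outside the embeddable range
  bad <- which(x <= lo | x >= hi)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- switch(law$dist,
      gaussian = stats::rnorm(length(bad), law$mean, law$sd),
      mixture = {
        comp <- sample.int(length(law$weights), length(bad), replace = TRUE,
                           prob = law$weights)
        stats::rnorm(length(bad), law$means[comp], law$sds[comp])
      })
    bad <- which(x <= lo | x >= hi)
    guard <- guard + 1L
    if (guard > 1000L) stop("infeasible geometry: law mass outside range")
  }
  x
}

#' Trajectory with planted geometric distributions
#'
#' Builds a minimal 7-atom topology (heme Fe, oxo O, substrate C25 and its
#' abstractable hydrogen, plus a donor N-H / acceptor O triplet) whose
#' per-frame coordinates embed the drawn values exactly: the measured
#' d[Fe=O-H] series equals the distance draws, the Fe-O...C25 attack-angle
#' series equals the angle draws, and the H-bond is geometrically formed in
#' exactly the planted frames.
#'
#' @param spec An [planted_trajectory_spec()].
#' @return An `etk_trajectory` with attribute `"truth"` holding the drawn
#'   `distances`, `angles`, `hbond` frame labels, the atom roles, and the
#'   spec.
#' @export
make_planted_trajectory <- function(spec) {
  stopifnot(inherits(spec, "etk_planted_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  d <- .draw_law(spec$distance_law, n, lo = 0.2, hi = 50)
  th <- .draw_law(spec$angle_law, n, lo = 1, hi = 179)
  n_hb <- round(spec$hbond_frame_fraction * n)
  hb <- rep(FALSE, n)
  hb[sample.int(n, n_hb)] <- TRUE

  atoms <- data.frame(
    serial = 1:7,
    name = c("FE", "O1", "H25", "C25", "NZ", "HZ", "O"),
    element = c("Fe", "O", "H", "C", "N", "H", "O"),
    resname = c("HEM", "HEM", "VD3", "VD3", "LYS", "LYS", "THR"),
    resid = c(902L, 902L, 903L, 903L, 346L, 346L, 681L),
    chain = "A",
    x = 0, y = 0, z = 0, is_hetero = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                       FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  frame_of <- function(di, thi, hbi) {
    a <- thi * pi / 180
    v <- c(sin(a), 0, -cos(a))  # unit vector at angle theta from O->Fe
    rbind(
      FE = c(0, 0, -1.65),
      O1 = c(0, 0, 0),
      H25 = di * v,
      C25 = (di + 1.09) * v,
      NZ = c(10, 0, 0),
      HZ = c(11, 0, 0),
      O = if (hbi) c(12.8, 0, 0) else c(16, 0, 0)
    )
  }
  frames <- lapply(seq_len(n), function(i) frame_of(d[i], th[i], hb[i]))
  atoms[, c("x", "y", "z")] <- frames[[1]]
  traj <- new_trajectory(new_structure(atoms), frames)
  attr(traj, "truth") <- list(
    distances = d, angles = th, hbond = hb,
    roles = list(fe = 1L, oxo = 2L, target_h = 3L, target_c = 4L,
                 donor = 5L, hydrogen = 6L, acceptor = 7L),
    spec = spec
  )
  traj
}

#' Small two-domain structure fixture with a planted tunneling route
#'
#' A ~54-atom structure holding a [2Fe-2S] cluster, a heme iron, a covalent
#' chain from the FES iron toward the heme broken by one 3.5-Angstrom
#' through-space gap (so the optimal iron-to-iron tunneling route is known by
#' construction, total R = 13.75 Angstrom), a planted hydrogen-bond triplet,
#' and a decorative 10-residue helix kept more than 6 Angstrom from the
#' route. Deterministic given the seed (which only jitters the helix).
#'
#' @param seed Integer RNG seed.
#' @return An `etk_structure` with attribute `"truth"`: `route` (atom
#'   indices), `steps` (per-step distances), `total_R`, `donor`, `acceptor`,
#'   `hbond` (donor, hydrogen, acceptor indices), and the planted
#'   conformation `label` for the Fe-Fe distance.
#' @export
make_two_domain_structure <- function(seed = 1) {
  set.seed(seed)
  rows <- list(
    ## [2Fe-2S] cluster + route chain along x (y = z = 0)
    list("FE1", "Fe", "FES", 901L, TRUE, c(0, 0, 0)),
    list("FE2", "Fe", "FES", 901L, TRUE, c(0, 2.7, 0)),
    list("S1", "S", "FES", 901L, TRUE, c(1.35, 1.35, 0)),
    list("S2", "S", "FES", 901L, TRUE, c(-1.35, 1.35, 0)),
    list("SG", "S", "CYS", 347L, FALSE, c(2.2, 0, 0)),
    list("CB", "C", "CYS", 347L, FALSE, c(3.7, 0, 0)),
    list("CA", "C", "CYS", 347L, FALSE, c(5.2, 0, 0)),
    list("NZ", "N", "LYS", 346L, FALSE, c(8.7, 0, 0)),
    list("CE", "C", "LYS", 346L, FALSE, c(10.2, 0, 0)),
    list("N1", "N", "HEM", 902L, TRUE, c(11.7, 0, 0)),
    list("FE", "Fe", "HEM", 902L, TRUE, c(13.75, 0, 0)),
    ## planted hydrogen-bond triplet, far from the route
    list("N", "N", "GLY", 100L, FALSE, c(0, 20, 0)),
    list("H", "H", "GLY", 100L, FALSE, c(1, 20, 0)),
    list("O", "O", "GLY", 101L, FALSE, c(2.85, 20, 0))
  )
  ## decorative helix: 10 ALA residues (N, CA, C, O), centered at x = 25
  helix_center <- c(25, 20, 0)
  u <- 0L
  for (i in 1:10) {
    for (nm in c("N", "CA", "C")) {
      ang <- u * 33.3 * pi / 180
      p <- helix_center + c(2.3 * cos(ang), 2.3 * sin(ang), 0.5 * u)
      rows[[length(rows) + 1L]] <-
        list(nm, substr(nm, 1, 1), "ALA", as.integer(i), FALSE, p)
      if (nm == "C") {
        po <- helix_center + c(3.5 * cos(ang), 3.5 * sin(ang), 0.5 * u)
        rows[[length(rows) + 1L]] <-
          list("O", "O", "ALA", as.integer(i), FALSE, po)
      }
      u <- u + 1L
    }
  }
  atoms <- data.frame(
    serial = seq_along(rows),
    name = vapply(rows, `[[`, "", 1),
    element = vapply(rows, `[[`, "", 2),
    resname = vapply(rows, `[[`, "", 3),
    resid = vapply(rows, `[[`, 1L, 4),
    chain = "A",
    x = 0, y = 0, z = 0,
    is_hetero = vapply(rows, `[[`, TRUE, 5),
    stringsAsFactors = FALSE
  )
  xyz <- t(vapply(rows, `[[`, numeric(3), 6))
  ## seed-controlled jitter on the decorative helix only
  hel <- atoms$resname == "ALA"
  xyz[hel, ] <- xyz[hel, ] + stats::runif(sum(hel) * 3, -0.02, 0.02)
  xyz <- round(xyz, 3)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  s <- new_structure(atoms, title = "synthetic two-domain ET fixture")
  route <- match(c("FE1", "SG", "CB", "CA", "NZ", "CE", "N1", "FE"),
                 atoms$name)
  attr(s, "truth") <- list(
    route = route,
    steps = c(2.2, 1.5, 1.5, 3.5, 1.5, 1.5, 2.05),
    total_R = 13.75,
    donor = which(atoms$name %in% c("FE1", "FE2")),
    acceptor = which(atoms$name == "FE"),
    hbond = match(c("N", "H", "O"), atoms$name),
    fe_fe_distance = 13.75,
    label = "proximal",
    seed = seed
  )
  s
}
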