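## Tunneling-graph construction and best-pathway search under the empirical
## Pathways decay model, plus the exponential distance-decay ET rate law.

#' Pathways-model decay parameters
#'
#' Per-step decay factors of the empirical tunneling model: covalent steps
#' carry a constant decay `eps_covalent`; hydrogen-bond and through-space
#' steps decay exponentially with distance,
#' `prefactor * exp(-decay * (d - offset))`, clamped to at most the covalent
#' decay. The defaults are the classic Pathways parameterization (covalent
#' 0.6; through-space `0.6 exp(-1.7 (d - 1.4))`; H-bond
#' `0.36 exp(-1.7 (d - 2.8))`); all are user-overridable.
#'
#' @param eps_covalent Covalent per-step decay (unitless, in (0,1]).
#' @param space_prefactor,space_decay,space_offset Through-space decay
#'   parameters (unitless, 1/Angstrom, Angstrom).
#' @param hbond_prefactor,hbond_decay,hbond_offset Hydrogen-bond decay
#'   parameters.
#' @param space_cutoff Maximum heavy-atom distance for a through-space edge
#'   (Angstrom). Beyond ~6 A a jump decays below 2.4e-4 of a covalent step
#'   and never competes.
#' @return An `etk_tunneling_params` list.
#' @export
tunneling_params <- function(eps_covalent = 0.6,
                             space_prefactor = 0.6, space_decay = 1.7,
                             space_offset = 1.4,
                             hbond_prefactor = 0.36, hbond_decay = 1.7,
                             hbond_offset = 2.8,
                             space_cutoff = 6.0) {
  stopifnot(space_decay > 0, hbond_decay > 0,
            eps_covalent > 0, eps_covalent <= 1,
            space_prefactor > 0, space_prefactor <= 1,
            hbond_prefactor > 0, hbond_prefactor <= 1,
            space_cutoff > space_offset)
  structure(list(eps_covalent = eps_covalent,
                 space_prefactor = space_prefactor,
                 space_decay = space_decay, space_offset = space_offset,
                 hbond_prefactor = hbond_prefactor,
                 hbond_decay = hbond_decay, hbond_offset = hbond_offset,
                 space_cutoff = space_cutoff),
            class = "etk_tunneling_params")
}

#' Distance-decay ET rate-law constants
#'
#' Defaults follow the empirical biological tunneling calibration
#' `A(0) = 2e12 s^-1`, `beta = 1.06 / Angstrom`.
#'
#' @param A0 Pre-exponential rate at contact, 1/s.
#' @param beta_tunnel Distance-decay constant, 1/Angstrom.
#' @return An `etk_rate_params` list.
#' @export
et_rate_params <- function(A0 = 2e12, beta_tunnel = 1.06) {
  stopifnot(A0 > 0, beta_tunnel > 0)
  structure(list(A0 = A0, beta_tunnel = beta_tunnel),
            class = "etk_rate_params")
}

#' Geometric hydrogen-bond criterion
#'
#' @param donor_acceptor_max Maximum donor--acceptor heavy-atom distance,
#'   Angstrom (default 3.5).
#' @param dha_angle_min Minimum donor--H--acceptor angle, degrees
#'   (default 135).
#' @return An `etk_hbond_criterion` list.
#' @export
hbond_criterion <- function(donor_acceptor_max = 3.5, dha_angle_min = 135) {
  stopifnot(donor_acceptor_max > 0,
            dha_angle_min > 0, dha_angle_min <= 180)
  structure(list(donor_acceptor_max = donor_acceptor_max,
                 dha_angle_min = dha_angle_min),
            class = "etk_hbond_criterion")
}

#' Detect hydrogen bonds in a single structure/frame
#'
#' Donors are N/O/S atoms with a covalently attached hydrogen; acceptors are
#' N/O/F/S atoms not covalently bonded to the donor. A hydrogen bond requires
#' `d(donor, acceptor) <= donor_acceptor_max` and a donor-H-acceptor angle of
#' at least `dha_angle_min`.
#'
#' @param structure An `etk_structure`.
#' @param bonds An `etk_bonds`; inferred with defaults when `NULL`.
#' @param criterion An [hbond_criterion()].
#' @param coords Optional coordinate override (n_atoms x 3).
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance` (donor-acceptor, Angstrom), `angle` (degrees).
#' @export
detect_hbonds <- function(structure, bonds = NULL,
                          criterion = hbond_criterion(), coords = NULL) {
  if (is.null(bonds)) bonds <- infer_covalent_bonds(structure)
  at <- structure$atoms
  el <- .normalize_element(at$element)
  xyz <- if (is.null(coords)) as.matrix(at[, c("x", "y", "z")]) else coords
  bmat <- bonds$bonds
  partners <- function(i) {
    c(bmat[bmat[, 1] == i, 2], bmat[bmat[, 2] == i, 1])
  }
  is_h <- el == "H"
  res <- list()
  for (h in which(is_h)) {
    p <- partners(h)
    don <- p[el[p] %in% c("N", "O", "S")]
    if (length(don) != 1L) next
    acc <- which(el %in% c("N", "O", "F", "S"))
    acc <- setdiff(acc, c(don, partners(don)))
    if (!length(acc)) next
    dda <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[don, ])^2))
    acc <- acc[dda <= criterion$donor_acceptor_max]
    dda <- dda[dda <= criterion$donor_acceptor_max]
    for (k in seq_along(acc)) {
      ang <- .angle_deg(xyz[don, ], xyz[h, ], xyz[acc[k], ])
      if (ang >= criterion$dha_angle_min)
        res[[length(res) + 1L]] <- data.frame(
          donor = don, hydrogen = h, acceptor = acc[k],
          distance = dda[k], angle = ang)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, res)
}

#' Build a tunneling graph over the heavy atoms of a structure
#'
#' Edges carry one step type each, with precedence covalent > hydrogen bond >
#' through-space. Covalent edges take the constant decay `eps_covalent`;
#' H-bond edges use the donor-acceptor distance; through-space edges connect
#' non-bonded heavy-atom pairs within `space_cutoff`. Exponential decays are
#' clamped to at most the covalent decay.
#'
#' @param structure An `etk_structure`.
#' @param bonds An `etk_bonds` covalent topology (inferred when `NULL`).
#' @param params An [tunneling_params()] object.
#' @param criterion H-bond criterion passed to [detect_hbonds()].
#' @return An `etk_tunneling_graph`: `nodes` (atom indices of heavy atoms),
#'   `edges` (data frame `i`, `j`, `type`, `distance`, `decay`, with `i`,`j`
#'   atom indices), and `labels` (residue label per node).
#' @export
build_tunneling_graph <- function(structure, bonds = NULL,
                                  params = tunneling_params(),
                                  criterion = hbond_criterion()) {
  if (is.null(bonds)) bonds <- infer_covalent_bonds(structure)
  at <- structure$atoms
  el <- .normalize_element(at$element)
  heavy <- which(el != "H")
  if (length(heavy) < 2L) stop("need at least two heavy atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
  pos <- match(seq_len(nrow(at)), heavy)  # atom index -> heavy position

  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edges <- list()
  seen <- character()

  ## covalent edges between heavy atoms
  b <- bonds$bonds
  if (nrow(b)) {
    hb <- b[el[b[, 1]] != "H" & el[b[, 2]] != "H", , drop = FALSE]
    if (nrow(hb)) {
      d <- dmat[cbind(pos[hb[, 1]], pos[hb[, 2]])]
      edges$cov <- data.frame(i = hb[, 1], j = hb[, 2], type = "covalent",
                              distance = d, decay = params$eps_covalent)
      seen <- c(seen, edge_key(hb[, 1], hb[, 2]))
    }
  }

  ## hydrogen-bond edges (donor-acceptor heavy pairs)
  hbl <- detect_hbonds(structure, bonds, criterion)
  if (nrow(hbl)) {
    key <- edge_key(hbl$donor, hbl$acceptor)
    new <- !key %in% seen & !duplicated(key)
    if (any(new)) {
      hh <- hbl[new, ]
      dec <- pmin(params$hbond_prefactor *
                    exp(-params$hbond_decay *
                          (hh$distance - params$hbond_offset)),
                  params$eps_covalent)
      edges$hb <- data.frame(i = hh$donor, j = hh$acceptor, type = "hbond",
                             distance = hh$distance, decay = dec)
      seen <- c(seen, key[new])
    }
  }

  ## through-space edges for remaining heavy pairs within cutoff
  idx <- which(dmat <= params$space_cutoff & upper.tri(dmat), arr.ind = TRUE)
  if (nrow(idx)) {
    ai <- heavy[idx[, 1]]
    aj <- heavy[idx[, 2]]
    key <- edge_key(ai, aj)
    new <- !key %in% seen
    if (any(new)) {
      d <- dmat[idx[new, , drop = FALSE]]
      dec <- pmin(params$space_prefactor *
                    exp(-params$space_decay * (d - params$space_offset)),
                  params$eps_covalent)
      edges$sp <- data.frame(i = ai[new], j = aj[new], type = "space",
                             distance = d, decay = dec)
    }
  }

  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL
  labels <- sprintf("%s%d", at$resname[heavy], at$resid[heavy])
  structure(list(nodes = heavy, edges = edges, labels = labels),
            class = "etk_tunneling_graph")
}

#' @export
print.etk_tunneling_graph <- function(x, ...) {
  tab <- table(x$edges$type)
  cat(sprintf("etk_tunneling_graph: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Most favorable tunneling pathway between donor and acceptor sets
#'
#' Maximizes the product of per-step decays (equivalently, minimizes the sum
#' of `-log(decay)` by Dijkstra search). Ties in total coupling are broken by
#' smaller total path length, then by lexicographic node sequence, so repeated
#' runs are bit-identical. If donor and acceptor are disconnected, a result
#' with `found = FALSE` is returned rather than an error.
#'
#' @param graph An `etk_tunneling_graph`.
#' @param donor,acceptor Non-empty, disjoint atom-index vectors present in the
#'   graph.
#' @return An `etk_pathway`: `found`, `node_sequence` (atom indices),
#'   `step_types`, `step_distances` (Angstrom), `total_R` (sum of step
#'   distances), `total_coupling` (product of decays), `residue_trace`
#'   (consecutive same-residue nodes collapsed).
#' @export
best_pathway <- function(graph, donor, acceptor) {
  donor <- unique(as.integer(donor))
  acceptor <- unique(as.integer(acceptor))
  if (!length(donor) || !length(acceptor))
    stop("donor and acceptor sets must be non-empty")
  if (length(intersect(donor, acceptor)))
    stop("donor and acceptor sets must be disjoint")
  nodes <- graph$nodes
  dset <- intersect(donor, nodes)
  aset <- intersect(acceptor, nodes)
  if (!length(dset) || !length(aset))
    stop("donor/acceptor atoms not present in the graph (hydrogens are not nodes)")

  n <- length(nodes)
  pos <- function(a) match(a, nodes)
  e <- graph$edges
  ei <- pos(e$i); ej <- pos(e$j)
  w <- -log(e$decay)
  ## adjacency as edge-id lists
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], k)
    adj[[ej[k]]] <- c(adj[[ej[k]]], k)
  }
  other <- function(k, v) if (ei[k] == v) ej[k] else ei[k]

  ## multi-source Dijkstra from the donor set
  dist <- rep(Inf, n)
  dist[pos(dset)] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (k in adj[[u]]) {
      v <- other(k, u)
      if (dist[u] + w[k] < dist[v]) dist[v] <- dist[u] + w[k]
    }
  }
  apos <- pos(aset)
  Wstar <- min(dist[apos])
  if (!is.finite(Wstar))
    return(structure(list(found = FALSE, node_sequence = integer(),
                          step_types = character(),
                          step_distances = numeric(),
                          total_R = NA_real_, total_coupling = NA_real_,
                          residue_trace = character()),
                     class = "etk_pathway"))

  tol <- 1e-9 * max(1, Wstar)
  targets <- apos[dist[apos] <= Wstar + tol]
  ## suffix DP over the shortest-path DAG: best (R, lexicographic sequence)
  ## from each node to a target. Process nodes by decreasing dist.
  bestR <- rep(NA_real_, n)
  bestSeq <- vector("list", n)
  bestEdges <- vector("list", n)
  ord <- order(dist, decreasing = TRUE)
  lex_less <- function(a, b) {
    la <- length(a); lb <- length(b)
    m <- min(la, lb)
    for (t in seq_len(m)) {
      if (a[t] < b[t]) return(TRUE)
      if (a[t] > b[t]) return(FALSE)
    }
    la < lb
  }
  for (v in ord) {
    if (!is.finite(dist[v])) next
    if (v %in% targets) {
      bestR[v] <- 0
      bestSeq[[v]] <- nodes[v]
      bestEdges[[v]] <- integer()
      next  # shortest paths never pass through an optimal target
    }
    for (k in adj[[v]]) {
      u <- other(k, v)
      if (is.na(bestR[u])) next
      if (abs(dist[v] + w[k] - dist[u]) > tol) next
      candR <- e$distance[k] + bestR[u]
      candSeq <- c(nodes[v], bestSeq[[u]])
      if (is.na(bestR[v]) || candR < bestR[v] - 1e-9 ||
          (abs(candR - bestR[v]) <= 1e-9 && lex_less(candSeq, bestSeq[[v]]))) {
        bestR[v] <- candR
        bestSeq[[v]] <- candSeq
        bestEdges[[v]] <- c(k, bestEdges[[u]])
      }
    }
  }
  starts <- pos(dset)
  starts <- starts[!is.na(bestR[starts])]
  stopifnot(length(starts) > 0)
  sb <- starts[1]
  for (v in starts[-1]) {
    if (bestR[v] < bestR[sb] - 1e-9 ||
        (abs(bestR[v] - bestR[sb]) <= 1e-9 &&
         lex_less(bestSeq[[v]], bestSeq[[sb]])))
      sb <- v
  }
  eids <- bestEdges[[sb]]
  seq_atoms <- bestSeq[[sb]]
  lab <- if (is.null(graph$labels)) as.character(seq_atoms)
         else graph$labels[match(seq_atoms, nodes)]
  out <- structure(list(
    found = TRUE,
    node_sequence = seq_atoms,
    step_types = e$type[eids],
    step_distances = e$distance[eids],
    total_R = sum(e$distance[eids]),
    total_coupling = prod(e$decay[eids]),
    residue_trace = rle(lab)$values
  ), class = "etk_pathway")
  attr(out, "node_labels") <- lab
  out
}

#' @export
print.etk_pathway <- function(x, ...) {
  if (!x$found) {
    cat("etk_pathway: no pathway between donor and acceptor\n")
    return(invisible(x))
  }
  cat(sprintf("etk_pathway: %d steps, total R = %.2f A, coupling = %.3g\n",
              length(x$step_distances), x$total_R, x$total_coupling))
  cat("  route:", paste(x$residue_trace, collapse = " -> "), "\n")
  if (length(x$step_types)) {
    tab <- table(x$step_types)
    cat("  steps:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Total tunneling-path length
#'
#' Sums the per-step distances of a pathway. At `level = "residue"` only the
#' steps that cross a residue boundary are summed (the residue-level
#' convention of adding the shortest distances between neighboring residues
#' along the route); intra-residue hops are regarded as part of the residue.
#'
#' @param path An `etk_pathway`, or a numeric vector of step distances.
#' @param level `"atom"` (default: every step) or `"residue"`.
#' @return Path length in Angstrom.
#' @export
path_length <- function(path, level = c("atom", "residue")) {
  level <- match.arg(level)
  if (is.numeric(path)) return(sum(path))
  stopifnot(inherits(path, "etk_pathway"))
  if (!path$found) return(NA_real_)
  if (length(path$step_distances) == 0L) return(0)
  if (level == "atom") return(sum(path$step_distances))
  lab <- attr(path, "node_labels")
  if (is.null(lab)) return(sum(path$step_distances))
  ## step k joins nodes k and k+1; count it when the residue label changes
  sum(path$step_distances[lab[-1] != lab[-length(lab)]])
}

#' Distance-decay electron-transfer rate
#'
#' `k_ET = A0 * exp(-beta * R)` with the empirical tunneling constants of
#' [et_rate_params()].
#'
#' @param R Donor-acceptor tunneling-path length, Angstrom (vectorized).
#' @param params An [et_rate_params()] object.
#' @return Rate(s), 1/s.
#' @examples
#' compute_ket(32.36)  # ~2.54e-3 /s
#' compute_ket(28.31)  # ~1.86e-1 /s
#' @export
compute_ket <- function(R, params = et_rate_params()) {
  if (any(!is.finite(R)) || any(R < 0)) stop("R must be finite and >= 0")
  params$A0 * exp(-params$beta_tunnel * R)
}

.angle_deg <- function(a, vertex, b) {
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("coincident atoms: angle undefined")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
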