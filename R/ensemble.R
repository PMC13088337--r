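## Per-frame geometric and energetic observables over trajectories.
## All summary spreads are population standard deviations (divisor n), to
## match "mean +/- standard deviation over frames" reporting.

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

.new_series <- function(name, values) {
  structure(list(name = name, values = values,
                 mean = mean(values), sd = .pop_sd(values)),
            class = "etk_series")
}

#' @export
print.etk_series <- function(x, ...) {
  cat(sprintf("etk_series '%s': n = %d, mean = %.3f, sd = %.3f\n",
              x$name, length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Per-frame distance between two atom sets
#'
#' @param traj An `etk_trajectory`.
#' @param selA,selB Atom-index vectors or selection strings (resolved against
#'   the topology); non-empty and disjoint.
#' @param mode Distance mode as in [min_distance()]: `"min"`, `"cog"`, or
#'   `"fe-fe"`.
#' @param name Series label.
#' @return An `etk_series` (values in Angstrom; `mean`, `sd` population).
#' @export
distance_series <- function(traj, selA, selB,
                            mode = c("min", "cog", "fe-fe"),
                            name = "distance") {
  mode <- match.arg(mode)
  top <- traj$topology
  selA <- .resolve_selection(top, selA)
  selB <- .resolve_selection(top, selB)
  vals <- vapply(traj$frames, function(f)
    min_distance(top, selA, selB, mode = mode, coords = f), numeric(1))
  .new_series(name, vals)
}

#' Per-frame attack angle Fe-O...target with vertex at the oxo oxygen
#'
#' @param traj An `etk_trajectory`.
#' @param fe_atom,oxo_atom,target_atom Three distinct atom indices; the angle
#'   is measured at `oxo_atom`.
#' @return An `etk_series` of angles in degrees, in `[0, 180]`.
#' @export
attack_angle_series <- function(traj, fe_atom, oxo_atom, target_atom) {
  ids <- c(fe_atom, oxo_atom, target_atom)
  if (anyDuplicated(ids)) stop("fe, oxo and target atoms must be distinct")
  vals <- vapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    tryCatch(.angle_deg(f[fe_atom, ], f[oxo_atom, ], f[target_atom, ]),
             error = function(e)
               stop("coincident atoms in frame ", i, call. = FALSE))
  }, numeric(1))
  .new_series("attack_angle", vals)
}

#' Near-attack-conformation summary
#'
#' Fraction of frames whose Fe=O-to-substrate-hydrogen distance is within the
#' reactive threshold, plus distance/angle means and spreads.
#'
#' @param dist An `etk_series` of distances (Angstrom).
#' @param angle Optional `etk_series` of attack angles (degrees), same
#'   length.
#' @param threshold Reactive distance threshold, Angstrom (default 4.0).
#' @return An `etk_nac`: `threshold`, `fraction_within`, `mean_distance`,
#'   `sd_distance`, `mean_angle`, `sd_angle`, `n`.
#' @export
nac_summary <- function(dist, angle = NULL, threshold = 4.0) {
  stopifnot(inherits(dist, "etk_series"))
  if (!is.null(angle)) {
    stopifnot(inherits(angle, "etk_series"))
    if (length(angle$values) != length(dist$values))
      stop("distance and angle series must have the same length")
  }
  structure(list(
    threshold = threshold,
    fraction_within = mean(dist$values <= threshold),
    mean_distance = dist$mean, sd_distance = dist$sd,
    mean_angle = if (is.null(angle)) NA_real_ else angle$mean,
    sd_angle = if (is.null(angle)) NA_real_ else angle$sd,
    n = length(dist$values)
  ), class = "etk_nac")
}

#' @export
print.etk_nac <- function(x, ...) {
  cat(sprintf(
    "etk_nac: %.1f%% of %d frames within %.2f A (d = %.2f +/- %.2f A%s)\n",
    100 * x$fraction_within, x$n, x$threshold, x$mean_distance,
    x$sd_distance,
    if (is.na(x$mean_angle)) ""
    else sprintf(", theta = %.1f +/- %.1f deg", x$mean_angle, x$sd_angle)))
  invisible(x)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Percentage of frames in which `d(donor, acceptor) <= donor_acceptor_max`
#' and the donor-H-acceptor angle is at least `dha_angle_min`.
#'
#' @param traj An `etk_trajectory`.
#' @param donor,hydrogen,acceptor Three distinct atom indices; the hydrogen
#'   must be covalently bonded to the donor in the topology.
#' @param criterion An [hbond_criterion()].
#' @param bonds Optional `etk_bonds` (inferred from the topology when `NULL`).
#' @return Occupancy percentage in `[0, 100]`.
#' @export
hbond_occupancy <- function(traj, donor, hydrogen, acceptor,
                            criterion = hbond_criterion(), bonds = NULL) {
  ids <- c(donor, hydrogen, acceptor)
  if (anyDuplicated(ids)) stop("donor, hydrogen, acceptor must be distinct")
  if (is.null(bonds)) bonds <- infer_covalent_bonds(traj$topology)
  b <- bonds$bonds
  bonded <- any((b[, 1] == donor & b[, 2] == hydrogen) |
                  (b[, 2] == donor & b[, 1] == hydrogen))
  if (!bonded) stop("hydrogen is not covalently bonded to the donor")
  hit <- vapply(traj$frames, function(f) {
    d <- sqrt(sum((f[donor, ] - f[acceptor, ])^2))
    if (d > criterion$donor_acceptor_max) return(FALSE)
    .angle_deg(f[donor, ], f[hydrogen, ], f[acceptor, ]) >=
      criterion$dha_angle_min
  }, logical(1))
  100 * mean(hit)
}

#' RMSD time series after least-squares superposition
#'
#' Each frame is optimally superposed (Kabsch rotation with proper-rotation
#' enforcement, plus translation) onto the reference frame over the selection,
#' then the RMSD over the selection is reported.
#'
#' @param traj An `etk_trajectory`.
#' @param reference_frame Frame index used as reference (default 1).
#' @param selection Atom indices or selection string; at least 3 atoms,
#'   non-collinear in the reference. `NULL` selects all atoms.
#' @return An `etk_series` of RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1, selection = NULL) {
  top <- traj$topology
  sel <- if (is.null(selection)) seq_len(nrow(top$atoms))
         else .resolve_selection(top, selection)
  if (length(sel) < 3L) stop("selection must contain at least 3 atoms")
  ref <- traj$frames[[reference_frame]][sel, , drop = FALSE]
  refc <- sweep(ref, 2, colMeans(ref))
  if (qr(refc)$rank < 2L)
    stop("degenerate (collinear) selection in the reference frame")
  vals <- vapply(traj$frames, function(f) {
    .kabsch_rmsd(refc, f[sel, , drop = FALSE])
  }, numeric(1))
  .new_series("rmsd", vals)
}

## refc must already be centered; proper rotation enforced via the sign of
## det(V U^T).
.kabsch_rmsd <- function(refc, mov) {
  movc <- sweep(mov, 2, colMeans(mov))
  H <- t(movc) %*% refc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fit <- movc %*% t(R)
  sqrt(mean(rowSums((fit - refc)^2)))
}

#' Nonbonded interaction parameters
#'
#' @param table Data frame with columns `serial`, `charge_e`, `sigma_A`,
#'   `epsilon_kcal` giving per-atom partial charges (e) and Lennard-Jones
#'   parameters (Angstrom, kcal/mol).
#' @param combining LJ combining rule: `"lorentz_berthelot"`
#'   (`sigma = (si+sj)/2`, `eps = sqrt(ei ej)`) or `"geometric"`
#'   (`sigma = sqrt(si sj)`).
#' @param coulomb_constant kcal A / (mol e^2); default 332.0636.
#' @param dielectric Relative dielectric (default 1).
#' @param cutoff Pair cutoff in Angstrom (default 99, a generous value that
#'   keeps long-range electrostatics; hard truncation, no switching).
#' @return An `etk_nonbonded_params`.
#' @export
nonbonded_params <- function(table,
                             combining = c("lorentz_berthelot", "geometric"),
                             coulomb_constant = .coulomb_const,
                             dielectric = 1, cutoff = 99) {
  combining <- match.arg(combining)
  need <- c("serial", "charge_e", "sigma_A", "epsilon_kcal")
  if (!all(need %in% names(table)))
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  stopifnot(all(table$epsilon_kcal >= 0), all(table$sigma_A > 0),
            dielectric > 0, cutoff > 0)
  structure(list(table = table, combining = combining,
                 coulomb_constant = coulomb_constant,
                 dielectric = dielectric, cutoff = cutoff),
            class = "etk_nonbonded_params")
}

#' Per-frame electrostatic and van der Waals interaction energies
#'
#' For every cross pair (i in A, j in B) with `r <= cutoff`:
#' `elec = sum C q_i q_j / (dielectric * r)` and
#' `vdW = sum 4 eps [(sigma/r)^12 - (sigma/r)^6]` with combined LJ
#' parameters. Truncation at the cutoff is hard (no switching/shifting).
#'
#' @param traj An `etk_trajectory`.
#' @param groupA,groupB Disjoint atom-index vectors or selection strings.
#' @param params An [nonbonded_params()] object covering every group atom.
#' @return An `etk_energy`: per-frame `electrostatic` and `vdw` vectors
#'   (kcal/mol) plus `mean_elec`, `sd_elec`, `mean_vdw`, `sd_vdw`
#'   (population sd over frames).
#' @export
interaction_energy_series <- function(traj, groupA, groupB, params) {
  stopifnot(inherits(params, "etk_nonbonded_params"))
  top <- traj$topology
  A <- .resolve_selection(top, groupA)
  B <- .resolve_selection(top, groupB)
  if (!length(A) || !length(B)) stop("groups must be non-empty")
  if (length(intersect(A, B))) stop("groups must be disjoint")
  tab <- params$table
  row_of <- match(top$atoms$serial, tab$serial)
  missing_at <- c(A, B)[is.na(row_of[c(A, B)])]
  if (length(missing_at))
    stop("missing nonbonded parameters for atom serial(s): ",
         paste(top$atoms$serial[missing_at], collapse = ", "))
  qA <- tab$charge_e[row_of[A]]; qB <- tab$charge_e[row_of[B]]
  sA <- tab$sigma_A[row_of[A]]; sB <- tab$sigma_A[row_of[B]]
  eA <- tab$epsilon_kcal[row_of[A]]; eB <- tab$epsilon_kcal[row_of[B]]
  sig <- if (params$combining == "lorentz_berthelot")
    outer(sA, sB, function(a, b) (a + b) / 2)
  else sqrt(outer(sA, sB))
  eps <- sqrt(outer(eA, eB))
  qq <- outer(qA, qB)
  C <- params$coulomb_constant / params$dielectric
  elec <- numeric(length(traj$frames))
  vdw <- numeric(length(traj$frames))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    XA <- f[A, , drop = FALSE]; XB <- f[B, , drop = FALSE]
    r2 <- outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
    r <- sqrt(pmax(r2, 0))
    ok <- r <= params$cutoff & r > 0
    sr6 <- (sig / r)^6
    elec[i] <- sum((C * qq / r)[ok])
    vdw[i] <- sum((4 * eps * (sr6^2 - sr6))[ok])
  }
  structure(list(electrostatic = elec, vdw = vdw,
                 mean_elec = mean(elec), sd_elec = .pop_sd(elec),
                 mean_vdw = mean(vdw), sd_vdw = .pop_sd(vdw)),
            class = "etk_energy")
}

#' @export
print.etk_energy <- function(x, ...) {
  cat(sprintf(
    "etk_energy: elec %.1f +/- %.1f, vdW %.1f +/- %.1f kcal/mol (n = %d)\n",
    x$mean_elec, x$sd_elec, x$mean_vdw, x$sd_vdw, length(x$electrostatic)))
  invisible(x)
}
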