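## Structure and trajectory containers + basic geometry.
## Atom indexing is 1-based throughout; residue ids are the author numbering
## as given in the file. Fixed-column PDB v3.3 dialect; altloc other than
## ' '/'A' is skipped; insertion codes are rejected.

#' Read a protein structure from PDB text or a PDB file
#'
#' Parses fixed-column (v3.3) `ATOM`/`HETATM` records into an `etk_structure`.
#' Cofactor residues are auto-registered as named atom-index groups:
#' `HEM`/`HEC` as `HEME`, `FMN` as `FMN`, and `FES`/`SF4`/`FS4`/`F3S` as `FES`.
#' Only the first `MODEL` of a multi-model file is read (use
#' [read_trajectory()] for the frames). Alternate locations other than
#' `' '`/`'A'` are skipped; insertion codes are rejected.
#'
#' @param x Path to a PDB file, or a character scalar/vector holding PDB text.
#' @return An object of class `etk_structure`: a list with `atoms` (data frame
#'   with columns `serial`, `name`, `element`, `resname`, `resid`, `chain`,
#'   `x`, `y`, `z`, `is_hetero`), `cofactor_groups` (named list of 1-based
#'   atom indices), and `title`.
#' @examples
#' pdb <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
#' s <- read_structure(pdb)
#' s$atoms[, c("name", "x", "y", "z")]
#' @export
read_structure <- function(x) {
  lines <- .as_pdb_lines(x)
  lines <- .validate_pdb_lines(lines)
  ## first model only
  end1 <- grep("^ENDMDL", lines)[1]
  if (!is.na(end1)) lines <- lines[seq_len(end1)]
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom
  element <- .element_from_pdb(at$elesy, at$elety, at$type == "HETATM")
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = element,
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z,
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  title <- trimws(sub("^TITLE", "", grep("^TITLE", lines, value = TRUE)[1]))
  if (is.na(title)) title <- ""
  new_structure(atoms, title = title)
}

#' Construct an `etk_structure` from an atom table
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`, `is_hetero`.
#' @param cofactor_groups Named list of atom-index vectors; by default the
#'   cofactor groups `HEME`, `FMN`, `FES` are derived from residue names.
#' @param title Optional title string.
#' @return An `etk_structure`.
#' @export
new_structure <- function(atoms, cofactor_groups = NULL, title = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z", "is_hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("a structure must contain at least one atom")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element field")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) atom records")
  if (is.null(cofactor_groups)) {
    rn <- toupper(atoms$resname)
    cofactor_groups <- list()
    heme <- which(rn %in% c("HEM", "HEC"))
    fmn <- which(rn == "FMN")
    fes <- which(rn %in% c("FES", "SF4", "FS4", "F3S"))
    if (length(heme)) cofactor_groups$HEME <- heme
    if (length(fmn)) cofactor_groups$FMN <- fmn
    if (length(fes)) cofactor_groups$FES <- fes
  } else {
    for (g in cofactor_groups)
      if (any(g < 1L | g > nrow(atoms))) stop("cofactor group index out of range")
  }
  structure(list(atoms = atoms, cofactor_groups = cofactor_groups,
                 title = title),
            class = "etk_structure")
}

#' @export
print.etk_structure <- function(x, ...) {
  cat(sprintf("etk_structure: %d atoms, %d residues\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  if (length(x$cofactor_groups))
    cat("  cofactor groups:",
        paste(sprintf("%s (%d atoms)", names(x$cofactor_groups),
                      lengths(x$cofactor_groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a structure as PDB text
#'
#' @param structure An `etk_structure`.
#' @param file Optional path; when `NULL` the PDB text is returned invisibly
#'   as a character vector of lines.
#' @return Character vector of PDB lines (invisibly when `file` is given).
#' @export
write_structure <- function(structure, file = NULL) {
  at <- structure$atoms
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    pdb = NULL, file = tmp,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$is_hetero, "HETATM", "ATOM"),
    resno = at$resid, resid = at$resname,
    eleno = at$serial, elety = at$name,
    chain = ifelse(nzchar(at$chain), at$chain, NA),
    o = rep(1, nrow(at)), b = rep(0, nrow(at)),
    elesy = toupper(at$element)
  )
  txt <- readLines(tmp)
  if (is.null(file)) {
    unlink(tmp)
    return(txt)
  }
  invisible(txt)
}

#' Read a coordinate trajectory (multi-model PDB or multi-frame XYZ)
#'
#' The format is auto-detected from the content: a leading integer-only line
#' marks XYZ (count line, comment line, then `element x y z` rows per frame);
#' otherwise `MODEL`/`ENDMDL` blocks of a PDB file delimit frames.
#'
#' @param x Path or text (as in [read_structure()]).
#' @param topology An `etk_structure` giving the atom order; every frame must
#'   have the same atom count.
#' @param frame_times Optional numeric vector of frame times (ns), strictly
#'   increasing.
#' @return An `etk_trajectory`: list with `topology`, `frames` (list of
#'   n_atoms x 3 coordinate matrices, Angstrom) and `times`.
#' @export
read_trajectory <- function(x, topology, frame_times = NULL) {
  stopifnot(inherits(topology, "etk_structure"))
  lines <- .as_pdb_lines(x)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop("empty trajectory input")
  frames <- if (grepl("^\\s*[0-9]+\\s*$", first)) {
    .parse_xyz_frames(lines, nrow(topology$atoms))
  } else {
    .parse_pdb_frames(lines, nrow(topology$atoms))
  }
  new_trajectory(topology, frames, frame_times)
}

#' Construct a trajectory from in-memory frames
#'
#' @param topology An `etk_structure`.
#' @param frames List of n_atoms x 3 numeric matrices.
#' @param times Optional strictly increasing frame times (ns).
#' @return An `etk_trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "etk_structure"), is.list(frames),
            length(frames) >= 1L)
  na <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L)
      stop("frame ", i, " is not an n x 3 coordinate matrix")
    if (nrow(f) != na)
      stop("frame ", i, " has ", nrow(f), " atoms; topology has ", na)
  }
  if (!is.null(times)) {
    if (length(times) != length(frames))
      stop("frame_times length does not match frame count")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "etk_trajectory")
}

#' @export
print.etk_trajectory <- function(x, ...) {
  cat(sprintf("etk_trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `etk_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Write a trajectory as multi-frame XYZ text
#'
#' @param traj An `etk_trajectory`.
#' @param file Optional path; when `NULL` the text lines are returned.
#' @return Character vector of XYZ lines (invisibly when `file` is given).
#' @export
write_trajectory_xyz <- function(traj, file = NULL) {
  el <- traj$topology$atoms$element
  na <- length(el)
  out <- unlist(lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    c(as.character(na), sprintf("frame %d", i),
      sprintf("%-3s %12.6f %12.6f %12.6f", el, f[, 1], f[, 2], f[, 3]))
  }))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Explicit bond topology
#'
#' @param pairs Two-column integer matrix of unordered atom-index pairs.
#' @param n_atoms Number of atoms the indices refer to.
#' @param source `"explicit"` or `"inferred"`.
#' @return An `etk_bonds` object (`bonds` stored with `i < j`).
#' @export
bond_topology <- function(pairs, n_atoms, source = "explicit") {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] == pairs[, 2])) stop("self-bonds are not allowed")
    if (any(pairs < 1L | pairs > n_atoms)) stop("bond index out of range")
    pairs <- t(apply(pairs, 1, sort))
    pairs <- unique(pairs)
  }
  structure(list(bonds = pairs, n_atoms = as.integer(n_atoms),
                 source = source),
            class = "etk_bonds")
}

#' Infer covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff `|r_i - r_j| <= rcov(i) + rcov(j) + tolerance`
#' using consensus single-bond covalent radii (H 0.31, C 0.76, N 0.71, O 0.66,
#' S 1.05, Fe 1.32 Angstrom, ...). A hydrogen is kept bonded to at most one
#' heavy atom (the nearest); H-H contacts are never bonds.
#'
#' @param structure An `etk_structure`.
#' @param tolerance Distance slack in Angstrom (default 0.4).
#' @return An `etk_bonds` with `source = "inferred"`.
#' @export
infer_covalent_bonds <- function(structure, tolerance = 0.4) {
  stopifnot(tolerance > 0)
  at <- structure$atoms
  r <- .covalent_radius(at$element)  # errors on unknown elements
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2L) return(bond_topology(matrix(integer(), ncol = 2), n, "inferred"))
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") + tolerance
  hit <- d <= thr & upper.tri(d)
  idx <- which(hit, arr.ind = TRUE)
  is_h <- .normalize_element(at$element) == "H"
  keep <- rep(TRUE, nrow(idx))
  if (nrow(idx)) {
    hh <- is_h[idx[, 1]] & is_h[idx[, 2]]
    keep[hh] <- FALSE
    ## each H bonds to its single nearest heavy atom
    for (h in which(is_h)) {
      rows <- which((idx[, 1] == h | idx[, 2] == h) & keep)
      if (length(rows) > 1L) {
        dd <- d[cbind(idx[rows, 1], idx[rows, 2])]
        keep[rows[-which.min(dd)]] <- FALSE
      }
    }
  }
  bond_topology(idx[keep, , drop = FALSE], n, "inferred")
}

#' @export
print.etk_bonds <- function(x, ...) {
  cat(sprintf("etk_bonds (%s): %d bonds over %d atoms\n",
              x$source, nrow(x$bonds), x$n_atoms))
  invisible(x)
}

#' Minimum / center-of-geometry / Fe-Fe distance between two atom sets
#'
#' Modes: `"min"` (minimum pairwise Euclidean distance), `"cog"` (distance
#' between centers of geometry), `"fe-fe"` (minimum pairwise distance between
#' the iron atoms of each set -- the convention for d\[FeS-Heme\], which takes
#' the FES iron that minimizes the distance to the heme iron).
#'
#' @param structure An `etk_structure` (supplies elements and, by default,
#'   coordinates).
#' @param setA,setB Non-empty, disjoint 1-based atom-index vectors, or
#'   selection strings for [select_atoms()].
#' @param mode One of `"min"`, `"cog"`, `"fe-fe"`.
#' @param coords Optional n_atoms x 3 matrix overriding the structure's
#'   coordinates (e.g. a trajectory frame).
#' @return Distance in Angstrom (scalar).
#' @export
min_distance <- function(structure, setA, setB,
                         mode = c("min", "cog", "fe-fe"), coords = NULL) {
  mode <- match.arg(mode)
  setA <- .resolve_selection(structure, setA)
  setB <- .resolve_selection(structure, setB)
  if (length(setA) == 0L || length(setB) == 0L)
    stop("both atom sets must be non-empty")
  if (length(intersect(setA, setB)))
    stop("atom sets must be disjoint")
  xyz <- if (is.null(coords)) as.matrix(structure$atoms[, c("x", "y", "z")])
         else coords
  if (mode == "fe-fe") {
    fe <- .normalize_element(structure$atoms$element) == "Fe"
    setA <- setA[fe[setA]]
    setB <- setB[fe[setB]]
    if (length(setA) == 0L || length(setB) == 0L)
      stop("mode 'fe-fe' requires at least one Fe atom in each set")
  }
  if (mode == "cog") {
    a <- colMeans(xyz[setA, , drop = FALSE])
    b <- colMeans(xyz[setB, , drop = FALSE])
    return(sqrt(sum((a - b)^2)))
  }
  .min_pair_dist(xyz[setA, , drop = FALSE], xyz[setB, , drop = FALSE])
}

## ---- internal helpers ------------------------------------------------------

.as_pdb_lines <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) == 1L && !grepl("\n", x) &&
      !grepl("^(ATOM|HETATM|MODEL|HEADER|TITLE|REMARK|CRYST1|TER|END)", x) &&
      file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

## Validates ATOM/HETATM records, drops altloc != ' '/'A', rejects insertion
## codes. Returns the retained lines.
.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM or HETATM record found (empty input?)")
  keep <- rep(TRUE, length(lines))
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed fixed-column record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (anyNA(coords))
      stop("malformed fixed-column record at line ", i,
           ": unparseable coordinates")
    if (!substr(ln, 27, 27) %in% c(" ", ""))
      stop("insertion codes are not supported (line ", i, ")")
    alt <- substr(ln, 17, 17)
    if (!alt %in% c(" ", "A", "")) keep[i] <- FALSE
  }
  lines[keep]
}

.element_from_pdb <- function(elesy, elety, is_het) {
  elesy <- trimws(elesy)
  elety <- trimws(elety)
  guess <- function(name, het) {
    stem <- gsub("[^A-Za-z]", "", name)
    two <- .normalize_element(substr(stem, 1, 2))
    if (het && nchar(stem) >= 2 && two %in% names(.covalent_radii) &&
        !two %in% c("C", "N", "O", "S", "H", "P"))
      return(two)
    .normalize_element(substr(stem, 1, 1))
  }
  out <- .normalize_element(elesy)
  fix <- which(!nzchar(out) | is.na(out))
  for (i in fix) out[i] <- guess(elety[i], is_het[i])
  out
}

.parse_pdb_frames <- function(lines, n_atoms) {
  starts <- grep("^MODEL", lines)
  coords_of <- function(block, frame_idx) {
    rec <- block[grepl("^(ATOM  |HETATM)", block)]
    if (length(rec) != n_atoms)
      stop("frame ", frame_idx, " has ", length(rec),
           " atoms; topology has ", n_atoms)
    m <- matrix(suppressWarnings(as.numeric(c(
      substr(rec, 31, 38), substr(rec, 39, 46), substr(rec, 47, 54)))),
      ncol = 3)
    if (anyNA(m)) stop("unparseable coordinates in frame ", frame_idx)
    m
  }
  if (length(starts) == 0L) return(list(coords_of(lines, 1L)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i)
    coords_of(lines[starts[i]:ends[i]], i))
}

.parse_xyz_frames <- function(lines, n_atoms) {
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_idx <- frame_idx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("bad atom-count line in XYZ frame ", frame_idx)
    if (n != n_atoms)
      stop("frame ", frame_idx, " has ", n, " atoms; topology has ", n_atoms)
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame ", frame_idx)
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad)) stop("malformed XYZ row in frame ", frame_idx)
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(m)) stop("unparseable coordinates in XYZ frame ", frame_idx)
    frames[[frame_idx]] <- m
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in XYZ input")
  frames
}

.min_pair_dist <- function(A, B) {
  ## min over all cross pairs, vectorized
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

.resolve_selection <- function(structure, sel) {
  if (is.character(sel) && length(sel) == 1L)
    return(select_atoms(structure, sel))
  as.integer(sel)
}
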