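# Fixture builders and brute-force oracles shared across the suite.

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          element, hetero = FALSE, altloc = " ",
                          insert = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetero) "HETATM" else "ATOM", serial,
          formatC(name, width = 4, flag = "-"), altloc, resname, chain,
          resid, insert, x, y, z, 1, 0, toupper(element))
}

# n_res CA-only residues spaced along x
make_ca_chain <- function(n_res = 20, spacing = 3.8) {
  atoms <- data.frame(
    serial = seq_len(n_res), name = "CA", element = "C", resname = "ALA",
    resid = seq_len(n_res), chain = "A",
    x = spacing * seq_len(n_res), y = 0, z = 0, is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
  new_structure(atoms)
}

make_point_structure <- function(xyz, element = "C", resname = "LIG",
                                 hetero = TRUE) {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = paste0(element, seq_len(n)),
    element = element, resname = resname, resid = 1L, chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_hetero = hetero,
    stringsAsFactors = FALSE
  )
  new_structure(atoms)
}

# all-pairs bond oracle
brute_bonds <- function(structure, tolerance = 0.4) {
  at <- structure$atoms
  el <- etkit:::.normalize_element(at$element)
  r <- etkit:::.covalent_radii[el]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  out <- list()
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (el[i] == "H" && el[j] == "H") next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= r[i] + r[j] + tolerance) out[[length(out) + 1L]] <- c(i, j, d)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) return(matrix(integer(), ncol = 2))
  # hydrogen keeps only its nearest heavy partner
  keep <- rep(TRUE, nrow(m))
  for (h in which(el == "H")) {
    rows <- which((m[, 1] == h | m[, 2] == h) & keep)
    if (length(rows) > 1L) keep[rows[-which.min(m[rows, 3])]] <- FALSE
  }
  m[keep, 1:2, drop = FALSE]
}

brute_min_distance <- function(X, Y) {
  best <- Inf
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
    best <- min(best, sqrt(sum((X[i, ] - Y[j, ])^2)))
  best
}

# hand-built tunneling graph from an edge table
toy_graph <- function(edges, n_nodes, labels = NULL) {
  structure(list(nodes = seq_len(n_nodes), edges = edges,
                 labels = if (is.null(labels)) as.character(seq_len(n_nodes))
                          else labels),
            class = "etk_tunneling_graph")
}

same_path <- function(a, b) {
  a$found && b$found &&
    identical(a$node_sequence, b$node_sequence) &&
    isTRUE(all.equal(a$total_R, b$total_R, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$total_coupling, b$total_coupling, tolerance = 1e-9))
}

# batch-means standard error for correlated series
batch_se <- function(x, n_batch = 20) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(means) / sqrt(n_batch)
}
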