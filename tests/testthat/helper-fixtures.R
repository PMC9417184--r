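# Fixtures are built in code at test time; nothing is stored on disk.

# A minimal atom row builder.
atom_row <- function(chain, seq_id, resname, atom, x, y, z,
                     element = substr(atom, 1, 1), occupancy = 1) {
  tibble::tibble(chain = chain, seq_id = seq_id, ins = "", resname = resname,
                 atom = atom, element = element, x = x, y = y, z = z,
                 occupancy = occupancy)
}

# Two chains x two residues x three atoms = 12 atoms, written as literal
# PDB text (fixture constructed to count).
write_toy_pdb <- function(path) {
  tpl <- "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s"
  rows <- list(
    list("N", "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    list("CA", "GLY", "A", 1, 1.5, 0.0, 0.0, "C"),
    list("C", "GLY", "A", 1, 2.3, 1.2, 0.0, "C"),
    list("N", "ALA", "A", 2, 3.5, 1.0, 0.0, "N"),
    list("CA", "ALA", "A", 2, 4.9, 1.4, 0.1, "C"),
    list("CB", "ALA", "A", 2, 5.8, 0.3, 0.6, "C"),
    list("N", "ARG", "B", 1, 0.0, 8.0, 0.0, "N"),
    list("CA", "ARG", "B", 1, 1.4, 8.2, 0.2, "C"),
    list("NH1", "ARG", "B", 1, 4.2, 9.1, 1.0, "N"),
    list("N", "MSE", "B", 2, 2.2, 9.9, 0.3, "N"),
    list("CA", "MSE", "B", 2, 3.6, 10.3, 0.4, "C"),
    list("SD", "MSE", "B", 2, 5.2, 11.5, 1.2, "S")
  )
  lines <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    sprintf(tpl, i, r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]], r[[7]],
            1, 0, r[[8]])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# One atom present in two alternate conformations (A occ 0.6, B occ 0.4).
write_altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AGLY A   1       1.500   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BGLY A   1       1.700   0.100   0.000  0.40  0.00           C",
    "ATOM      4  C   GLY A   1       2.300   1.200   0.000  1.00  0.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}

# Uniform solid-sphere bead model: n beads uniform in a sphere of radius r,
# one single-atom glycine pseudo-residue per bead (equal form factors at
# residue granularity).
make_sphere_beads <- function(n, radius, seed = 1) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(3 * n, -radius, radius), ncol = 3)
    cand <- cand[rowSums(cand^2) <= radius^2, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  assembly(tibble::tibble(
    chain = "A", seq_id = seq_len(n), ins = "", resname = "GLY", aa = "G",
    atom = "CA", element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3]
  ))
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# A hand-built C2 fixture in which a single A->W mutation plants a designed
# hydrogen bond with an aspartate across the two-fold, and a second identical
# motif is offset along z. All coordinates are chosen so that unmutated atoms
# contribute no score terms (every wild-type cross pair is > 3.6 A apart and
# clash-free).
planted_hbond_subunit <- function(n_motifs = 2) {
  rows <- list()
  for (m in seq_len(n_motifs)) {
    z <- (m - 1) * 8
    base <- (m - 1) * 2
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      atom_row("A", base + 1, "ALA", "CA", 5.5, 0.2, z),
      atom_row("A", base + 1, "ALA", "SC", 5.5 - 1.53, 0.2, z, element = "C"),
      atom_row("A", base + 2, "ASP", "CA", 4.1, -0.2, z),
      atom_row("A", base + 2, "ASP", "SC", 1.6, -0.2, z, element = "C")
    )
  }
  assembly(dplyr::bind_rows(rows))
}

c2_symdef <- function() {
  symmetry_definition(list(rigid_transform(), axis_rotation("z", pi)),
                      point_group = "C2")
}

# Default coarse assembly spec used across tests (kept small for speed).
test_spec <- function(point_group = "D3", seed = 1, ...) {
  synthetic_spec(point_group = point_group, seed = seed, ...)
}

# Independent brute-force oracle: all-pairs distances plus an explicit
# donor/acceptor table written out here, kept separate from the package's
# grid-based implementation.
brute_pairs <- function(asm, ga, gb, cutoff) {
  part <- partition(asm)
  A <- asm[asm$chain %in% names(part)[part == ga], ]
  B <- asm[asm$chain %in% names(part)[part == gb], ]
  out <- list()
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B$x - A$x[i])^2 + (B$y - A$y[i])^2 + (B$z - A$z[i])^2)
    hit <- which(d <= cutoff)
    if (length(hit)) {
      out[[length(out) + 1]] <- data.frame(
        i_atom = paste(A$chain[i], A$seq_id[i], A$atom[i]),
        j_atom = paste(B$chain[hit], B$seq_id[hit], B$atom[hit]),
        d = d[hit]
      )
    }
  }
  do.call(rbind, out)
}

oracle_donor <- function(aa, atom) {
  atom == "N" |
    (aa == "R" & atom %in% c("NE", "NH1", "NH2")) | (aa == "K" & atom == "NZ") |
    (aa == "S" & atom == "OG") | (aa == "W" & atom == "NE1") |
    (atom == "SC" & aa %in% c("R", "K", "H", "N", "Q", "S", "T", "Y", "W"))
}
oracle_acceptor <- function(aa, atom) {
  atom %in% c("O", "OXT") |
    (aa == "D" & atom %in% c("OD1", "OD2")) | (aa == "E" & atom %in% c("OE1", "OE2")) |
    (atom == "SC" & aa %in% c("D", "E", "N", "Q", "H", "S", "T", "Y"))
}

random_two_group_fixture <- function(seed, n_per = 120) {
  set.seed(seed)
  mk <- function(chain, centre) {
    kinds <- list(
      c("GLY", "N", "N"), c("GLY", "CA", "C"), c("GLY", "O", "O"),
      c("ARG", "NH1", "N"), c("ASP", "OD1", "O"), c("LYS", "NZ", "N"),
      c("GLU", "OE1", "O"), c("SER", "SC", "C"), c("TRP", "SC", "C")
    )
    pick <- sample(length(kinds), n_per, replace = TRUE)
    tibble::tibble(
      chain = chain, seq_id = seq_len(n_per), ins = "",
      resname = vapply(kinds[pick], `[`, character(1), 1),
      atom = vapply(kinds[pick], `[`, character(1), 2),
      element = vapply(kinds[pick], `[`, character(1), 3),
      x = rnorm(n_per, centre[1], 4), y = rnorm(n_per, centre[2], 4),
      z = rnorm(n_per, centre[3], 4)
    )
  }
  assembly(dplyr::bind_rows(mk("A", c(0, 0, 0)), mk("B", c(6, 0, 0))),
           partition = c(A = "g1", B = "g2"))
}

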