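# Cross-group atomic neighbour search. A uniform spatial grid with cell edge
# equal to the cutoff keeps the scan near-linear in atom count: each atom is
# only compared with atoms in the 27 neighbouring cells.

#' @keywords internal
cross_group_pairs <- function(model, group_a, group_b, cutoff) {
  part <- partition(model)
  for (g in c(group_a, group_b)) {
    if (!g %in% part) stop("unknown partition group: ", g)
  }
  ia <- which(model$chain %in% names(part)[part %in% group_a])
  ib <- which(model$chain %in% names(part)[part %in% group_b])
  if (!length(ia) || !length(ib)) stop("partition group with zero atoms")
  A <- coords_matrix(model[ia, ])
  B <- coords_matrix(model[ib, ])

  cell <- function(m) floor(m / cutoff)
  ca <- cell(A); cb <- cell(B)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  bmap <- new.env(hash = TRUE, parent = emptyenv())
  kb <- key(cb)
  for (grp in split(seq_len(nrow(B)), kb)) {
    assign(key(cb[grp[1], , drop = FALSE]), grp, envir = bmap)
  }
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

  res_i <- list(); res_j <- list(); res_d <- list(); n <- 0L
  ka <- key(ca)
  for (grp in split(seq_len(nrow(A)), ka)) {
    c0 <- ca[grp[1], ]
    cand <- unlist(lapply(seq_len(nrow(off)), function(o) {
      k <- paste(c0[1] + off[o, 1], c0[2] + off[o, 2], c0[3] + off[o, 3])
      if (exists(k, envir = bmap, inherits = FALSE)) get(k, envir = bmap) else NULL
    }), use.names = FALSE)
    if (!length(cand)) next
    d2 <- outer(rowSums(A[grp, , drop = FALSE]^2), rowSums(B[cand, , drop = FALSE]^2), "+") -
      2 * tcrossprod(A[grp, , drop = FALSE], B[cand, , drop = FALSE])
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    n <- n + 1L
    res_i[[n]] <- grp[hit[, 1]]
    res_j[[n]] <- cand[hit[, 2]]
    res_d[[n]] <- sqrt(pmax(d2[hit], 0))
  }
  if (n == 0L) {
    return(list(ia = integer(0), ib = integer(0), distance = numeric(0)))
  }
  i <- unlist(res_i); j <- unlist(res_j); d <- unlist(res_d)
  ord <- order(i, j)
  list(ia = ia[i][ord], ib = ib[j][ord], distance = d[ord])
}

#' @keywords internal
pairs_to_contacts <- function(model, pr, kind) {
  a <- model[pr$ia, ]; b <- model[pr$ib, ]
  tibble::tibble(
    chain_a = a$chain, seq_id_a = a$seq_id, aa_a = a$aa, atom_a = a$atom,
    chain_b = b$chain, seq_id_b = b$seq_id, aa_b = b$aa, atom_b = b$atom,
    distance = pr$distance, kind = kind
  )
}

#' Heavy-atom contacts across a chain partition
#'
#' All heavy-atom pairs with one atom in each group and distance at or below
#' the cutoff, found with a spatial grid (near-linear in atom count) and
#' symmetric in group order.
#'
#' @param model An [assembly()].
#' @param group_a,group_b Partition group labels.
#' @param cutoff Distance cutoff in Angstrom (default 5.5, the interfacial
#'   proximity criterion).
#' @return Tibble of contact records (one row per atom pair) with atom
#'   identities, `distance` and `kind = "contact"`.
#' @export
atomic_contacts <- function(model, group_a, group_b, cutoff = 5.5) {
  model <- check_assembly(model)
  if (cutoff <= 0) stop("cutoff must be positive")
  pairs_to_contacts(model, cross_group_pairs(model, group_a, group_b, cutoff),
                    "contact")
}

#' @keywords internal
is_donor_atom <- function(aa, atom) {
  if (!length(aa)) return(logical(0))
  atom == "N" |
    mapply(function(a, at) at %in% (sidechain_donors[[a]] %||% character(0)),
           aa, atom) |
    (atom == "SC" & aa %in% sc_donor_residues)
}

#' @keywords internal
is_acceptor_atom <- function(aa, atom) {
  if (!length(aa)) return(logical(0))
  atom %in% c("O", "OXT") |
    mapply(function(a, at) at %in% (sidechain_acceptors[[a]] %||% character(0)),
           aa, atom) |
    (atom == "SC" & aa %in% sc_acceptor_residues)
}

#' Interfacial hydrogen bonds by the distance-only criterion
#'
#' A hydrogen bond is a donor-capable N/O against an acceptor-capable N/O
#' within the cutoff; classification uses a fixed residue-specific atom-name
#' table with no hydrogens and no angular term. In coarse models the `SC`
#' side-chain pseudo-atom inherits the polar capability of its residue type.
#'
#' @inheritParams atomic_contacts
#' @param cutoff Distance cutoff in Angstrom (default 3.6).
#' @return Tibble of contact records with `kind = "hydrogen_bond"`.
#' @export
hydrogen_bonds <- function(model, group_a, group_b, cutoff = 3.6) {
  ct <- atomic_contacts(model, group_a, group_b, cutoff)
  keep <- (is_donor_atom(ct$aa_a, ct$atom_a) & is_acceptor_atom(ct$aa_b, ct$atom_b)) |
    (is_donor_atom(ct$aa_b, ct$atom_b) & is_acceptor_atom(ct$aa_a, ct$atom_a))
  out <- ct[keep, , drop = FALSE]
  out$kind <- "hydrogen_bond"
  out
}

#' @keywords internal
is_basic_atom <- function(aa, atom) {
  if (!length(aa)) return(logical(0))
  mapply(function(a, at) at %in% (basic_atoms[[a]] %||% character(0)), aa, atom) |
    (atom == "SC" & aa %in% sc_basic_residues)
}

#' @keywords internal
is_acidic_atom <- function(aa, atom) {
  if (!length(aa)) return(logical(0))
  mapply(function(a, at) at %in% (acidic_atoms[[a]] %||% character(0)), aa, atom) |
    (atom == "SC" & aa %in% sc_acidic_residues)
}

#' Interfacial salt bridges
#'
#' Pairs of charged-group heavy atoms (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2
#' against Asp OD1/OD2, Glu OE1/OE2) across the partition within the cutoff.
#'
#' @inheritParams atomic_contacts
#' @param cutoff Distance cutoff in Angstrom (default 4.0, a standard
#'   literature value).
#' @return Tibble of contact records with `kind = "salt_bridge"`.
#' @export
salt_bridges <- function(model, group_a, group_b, cutoff = 4.0) {
  ct <- atomic_contacts(model, group_a, group_b, cutoff)
  keep <- (is_basic_atom(ct$aa_a, ct$atom_a) & is_acidic_atom(ct$aa_b, ct$atom_b)) |
    (is_basic_atom(ct$aa_b, ct$atom_b) & is_acidic_atom(ct$aa_a, ct$atom_a))
  out <- ct[keep, , drop = FALSE]
  out$kind <- "salt_bridge"
  out
}

#' @keywords internal
sidechain_centroids <- function(model, idx) {
  sub <- model[idx, ]
  key <- paste(sub$chain, sub$seq_id, sub$ins, sep = "\r")
  sc <- sub[sub$is_sidechain, ]
  key_sc <- paste(sc$chain, sc$seq_id, sc$ins, sep = "\r")
  cen <- lapply(split(seq_len(nrow(sc)), key_sc), function(ii) {
    colMeans(coords_matrix(sc[ii, , drop = FALSE]))
  })
  cen
}

#' Interface residues by the proximity and side-chain-orientation criteria
#'
#' A residue is interfacial if (i) any of its heavy atoms lies within
#' `proximity_cutoff` of any heavy atom of the opposite group
#' ("proximity"), or (ii) its side-chain centroid is within
#' `orientation_cutoff` of the nearest opposite-group heavy atom and the
#' angle between CA-to-side-chain-centroid and CA-to-that-atom is at most
#' `orientation_angle` degrees ("orientation": the side chain points at the
#' opposite subunit). Glycine has no side chain and can only satisfy (i);
#' residues lacking a CA are skipped for (ii) with a warning.
#'
#' @inheritParams atomic_contacts
#' @param proximity_cutoff Heavy-atom distance for criterion (i), Angstrom
#'   (default 5.5).
#' @param orientation_cutoff Side-chain-centroid distance for criterion (ii),
#'   Angstrom (default 9).
#' @param orientation_angle Maximum pointing angle in degrees (default 90).
#' @return A list of class `interface_report`: `groups`, `contacts`,
#'   `hydrogen_bonds`, `salt_bridges`, `interface_residues` (tibble with
#'   `group`, `chain`, `seq_id`, `aa`, `criterion`), and `summary` counts.
#' @export
interface_residues <- function(model, group_a, group_b, proximity_cutoff = 5.5,
                               orientation_cutoff = 9, orientation_angle = 90) {
  model <- check_assembly(model)
  part <- partition(model)
  contacts <- atomic_contacts(model, group_a, group_b, proximity_cutoff)
  hb <- hydrogen_bonds(model, group_a, group_b)
  sb <- salt_bridges(model, group_a, group_b)

  side_residues <- function(g_self, g_opp, ct_self_chain, ct_self_seq) {
    idx_self <- which(model$chain %in% names(part)[part %in% g_self])
    idx_opp <- which(model$chain %in% names(part)[part %in% g_opp])
    opp_xyz <- coords_matrix(model[idx_opp, ])
    sub <- model[idx_self, ]
    res <- dplyr::distinct(sub[, c("chain", "seq_id", "ins", "aa")])
    prox_key <- unique(paste(ct_self_chain, ct_self_seq))
    out <- vector("list", nrow(res))
    for (r in seq_len(nrow(res))) {
      rk <- paste(res$chain[r], res$seq_id[r])
      if (rk %in% prox_key) {
        out[[r]] <- "proximity"
        next
      }
      ratoms <- sub[sub$chain == res$chain[r] & sub$seq_id == res$seq_id[r] &
                      sub$ins == res$ins[r], ]
      sc <- ratoms[ratoms$is_sidechain, ]
      if (!nrow(sc)) { out[[r]] <- NA_character_; next }
      ca <- ratoms[ratoms$atom == "CA", ]
      if (!nrow(ca)) {
        warning(sprintf("residue %s%d has no CA; skipped for orientation criterion",
                        res$chain[r], res$seq_id[r]))
        out[[r]] <- NA_character_; next
      }
      cen <- colMeans(coords_matrix(sc))
      dd <- sqrt(rowSums(sweep(opp_xyz, 2, cen)^2))
      jmin <- which.min(dd)
      if (dd[jmin] > orientation_cutoff) { out[[r]] <- NA_character_; next }
      ca_xyz <- as.numeric(coords_matrix(ca)[1, ])
      v1 <- cen - ca_xyz
      v2 <- opp_xyz[jmin, ] - ca_xyz
      if (sum(v1^2) < 1e-12 || sum(v2^2) < 1e-12) { out[[r]] <- NA_character_; next }
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      out[[r]] <- if (ang <= orientation_angle) "orientation" else NA_character_
    }
    res$criterion <- unlist(out)
    res <- res[!is.na(res$criterion), , drop = FALSE]
    res
  }

  ra <- side_residues(group_a, group_b, contacts$chain_a, contacts$seq_id_a)
  rb <- side_residues(group_b, group_a, contacts$chain_b, contacts$seq_id_b)
  if (nrow(ra)) ra$group <- group_a
  if (nrow(rb)) rb$group <- group_b
  iface <- dplyr::bind_rows(ra, rb)
  if (!nrow(iface)) {
    iface <- tibble::tibble(chain = character(), seq_id = integer(),
                            ins = character(), aa = character(),
                            criterion = character(), group = character())
  }
  iface <- iface[, c("group", "chain", "seq_id", "ins", "aa", "criterion")]

  structure(
    list(groups = c(group_a, group_b), contacts = contacts,
         hydrogen_bonds = hb, salt_bridges = sb, interface_residues = iface,
         summary = c(contacts = nrow(contacts), hydrogen_bonds = nrow(hb),
                     salt_bridges = nrow(sb), residues = nrow(iface))),
    class = "interface_report"
  )
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report> %s vs %s\n", x$groups[1], x$groups[2]))
  cat(sprintf("  contacts: %d | hydrogen bonds: %d | salt bridges: %d | interface residues: %d\n",
              x$summary["contacts"], x$summary["hydrogen_bonds"],
              x$summary["salt_bridges"], x$summary["residues"]))
  invisible(x)
}

#' Write an interface report's contacts as TSV
#'
#' @param report An `interface_report` from [interface_residues()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_interface_tsv <- function(report, path) {
  all_ct <- dplyr::bind_rows(report$contacts, report$hydrogen_bonds,
                             report$salt_bridges)
  utils::write.table(all_ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
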