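# Seeded generators for coarse homomeric assemblies, noisy SAXS profiles and
# homolog pairs with planted interface differences. Every generator is a pure
# function of its spec and seed, and restores the caller's RNG state.

#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic coarse assembly
#'
#' Describes a coarse homomeric assembly of pseudo-residue bead subunits:
#' a single chain of CA + side-chain pseudo-atom residues packed in a sphere,
#' replicated under an exact point-group geometry. Defaults give a subunit
#' roughly the coarse size of a small protein domain and inter-subunit gaps
#' of a few Angstrom, so interfaces exist under the 5.5 / 9 Angstrom
#' interfacial criteria without steric clashes.
#'
#' @param subunit_beads Number of pseudo-residues per subunit (default 60).
#' @param subunit_radius Packing-sphere radius in Angstrom (default 13).
#' @param point_group `"C1"`, `"C2"`, `"dimer_of_dimers"` (tilted D2-like
#'   tetramer) or `"D3"` (hexamer of three dimers).
#' @param tilt_angle Tilt in degrees between the two dimer axes of a
#'   dimer-of-dimers (0 recovers a parallel, octamer-like arrangement;
#'   default 30).
#' @param ring_radius Distance from the principal axis to each subunit
#'   centroid, Angstrom (default 13.5).
#' @param dimer_offset Half-separation of the two chains within a dimer,
#'   Angstrom (default 12).
#' @param noise_rel Relative intensity noise for [make_noisy_profile()]
#'   (default 0.02, in `[0, 0.5]`).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(subunit_beads = 60, subunit_radius = 13,
                           point_group = c("C2", "C1", "dimer_of_dimers", "D3"),
                           tilt_angle = 30, ring_radius = 13.5,
                           dimer_offset = 12,
                           noise_rel = 0.02, seed = 1) {
  point_group <- match.arg(point_group)
  stopifnot(subunit_beads > 0, subunit_radius > 0, ring_radius > 0,
            dimer_offset > 0)
  if (noise_rel < 0 || noise_rel > 0.5) stop("noise_rel must be in [0, 0.5]")
  structure(
    list(subunit_beads = subunit_beads, subunit_radius = subunit_radius,
         point_group = point_group, tilt_angle = tilt_angle,
         ring_radius = ring_radius, dimer_offset = dimer_offset,
         noise_rel = noise_rel, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @keywords internal
#' Sequential rejection packing of a coarse chain in a sphere at the local
#' origin. `images` is a list of rigid transforms mapping local coordinates
#' onto the relative positions of every other symmetry copy; candidate atoms
#' are rejected when any image of any atom (including their own) would come
#' within `d_cross` Angstrom, which makes the assembled multimer clash-free
#' by construction while letting subunit surfaces meet tightly.
pack_chain <- function(n, r_max, aas, images = list(), d_cross = 3.0,
                       min_sep = 3.5) {
  img_xyz <- matrix(numeric(0), 0, 3)
  add_images <- function(p) {
    if (!length(images)) return(invisible())
    for (h in images) {
      img_xyz <<- rbind(img_xyz, transform_coords(h, rbind(p)))
    }
  }
  clear_of_images <- function(p) {
    if (length(images)) {
      own <- t(vapply(images, function(h) as.numeric(transform_coords(h, rbind(p))),
                      numeric(3)))
      if (min(rowSums(sweep(own, 2, p)^2)) < d_cross^2) return(FALSE)
      if (nrow(img_xyz) && min(rowSums(sweep(img_xyz, 2, p)^2)) < d_cross^2) {
        return(FALSE)
      }
    }
    TRUE
  }
  ca <- matrix(NA_real_, n, 3)
  sc <- matrix(NA_real_, n, 3)
  has_sc <- logical(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("bead packing failed; lower subunit_beads or increase ",
           "subunit_radius / ring_radius / dimer_offset")
    }
    p <- stats::runif(3, -r_max, r_max)
    if (sum(p^2) > r_max^2) next
    if (placed > 0) {
      if (min(rowSums(sweep(ca[seq_len(placed), , drop = FALSE], 2, p)^2)) <
            min_sep^2) next
    }
    if (!clear_of_images(p)) next
    placed <- placed + 1L
    ca[placed, ] <- p
    add_images(p)
    d_sc <- sc_centroid_distance[aas[placed]]
    if (d_sc > 0) {
      pos <- NULL
      for (k in 1:60) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- p + d_sc * u
        if (sum(cand^2) > (r_max + 1)^2) next
        if (!clear_of_images(cand)) next
        pos <- cand
        break
      }
      if (is.null(pos)) {
        # point inward: images lie outward, so this is always safe
        u <- -p / sqrt(sum(p^2))
        pos <- p + d_sc * u
      }
      has_sc[placed] <- TRUE
      sc[placed, ] <- pos
      add_images(pos)
    }
  }
  list(ca = ca, sc = sc, has_sc = has_sc)
}

#' @keywords internal
chain_from_packing <- function(pk, aas, chain = "A") {
  n <- nrow(pk$ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tb <- tibble::tibble(
      chain = chain, seq_id = i, ins = "",
      resname = unname(aa_one_to_three[aas[i]]), aa = aas[i],
      atom = "CA", element = "C",
      x = pk$ca[i, 1], y = pk$ca[i, 2], z = pk$ca[i, 3],
      occupancy = 1, is_sidechain = FALSE
    )
    if (pk$has_sc[i]) {
      tb <- dplyr::bind_rows(tb, tibble::tibble(
        chain = chain, seq_id = i, ins = "",
        resname = unname(aa_one_to_three[aas[i]]), aa = aas[i],
        atom = "SC", element = "C",
        x = pk$sc[i, 1], y = pk$sc[i, 2], z = pk$sc[i, 3],
        occupancy = 1, is_sidechain = TRUE
      ))
    }
    rows[[i]] <- tb
  }
  dplyr::bind_rows(rows)
}

#' Generate a coarse single-chain subunit
#'
#' Pseudo-residues (a CA bead plus, except for glycine, a single `SC`
#' side-chain pseudo-atom at the idealized centroid distance for the residue
#' type) are random-packed in a sphere of `subunit_radius` with minimum CA
#' separation 3.5 Angstrom; side-chain pseudo-atoms are kept within 1
#' Angstrom of the packing sphere. The finished chain is centred so the
#' all-atom centroid sits at the origin. Deterministic under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A one-chain [assembly()] (chain `"A"`).
#' @export
make_subunit <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$subunit_beads
    aas <- sample(names(sc_centroid_distance), n, replace = TRUE)
    pk <- pack_chain(n, spec$subunit_radius, aas)
    atoms <- chain_from_packing(pk, aas)
    cen <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
    atoms$x <- atoms$x - cen[1]; atoms$y <- atoms$y - cen[2]
    atoms$z <- atoms$z - cen[3]
    assembly(atoms)
  })
}

#' @keywords internal
point_group_transforms <- function(spec) {
  r <- spec$ring_radius
  z0 <- spec$dimer_offset
  place <- function(...) Reduce(compose_transforms, list(...))
  trans <- function(t) rigid_transform(diag(3), t)
  switch(spec$point_group,
    C1 = list(tfs = list(rigid_transform()), groups = "sub1", label = "C1"),
    C2 = list(
      tfs = list(trans(c(r, 0, 0)),
                 place(axis_rotation("z", pi), trans(c(r, 0, 0)))),
      groups = c("subA", "subB"), label = "C2"
    ),
    D3 = {
      p3 <- trans(c(r, 0, z0))
      tfs <- list(); groups <- character(0)
      dimer_names <- c("dimerA", "dimerB", "dimerC")
      for (k in 0:2) {
        for (j in 0:1) {
          tf <- place(axis_rotation("z", 2 * pi * k / 3),
                      if (j == 0) rigid_transform() else axis_rotation("x", pi),
                      p3)
          tfs <- c(tfs, list(tf))
          groups <- c(groups, dimer_names[k + 1])
        }
      }
      list(tfs = tfs, groups = groups, label = "D3")
    },
    dimer_of_dimers = {
      alpha <- spec$tilt_angle * pi / 360  # half the tilt, in radians
      p2 <- trans(c(r, 0, 0))
      m <- place(trans(c(0, z0, 0)), axis_rotation("y", alpha))
      tfs <- list(); groups <- character(0)
      for (i in 0:1) {
        for (j in 0:1) {
          tf <- place(if (i == 0) rigid_transform() else axis_rotation("x", pi),
                      m,
                      if (j == 0) rigid_transform() else axis_rotation("z", pi),
                      p2)
          tfs <- c(tfs, list(tf))
          groups <- c(groups, c("dimerA", "dimerB")[i + 1])
        }
      }
      list(tfs = tfs, groups = groups, label = "D2-like")
    }
  )
}

#' Generate a coarse assembly with exact point-group symmetry
#'
#' Builds the subunit with [make_subunit()] and replicates it under the exact
#' generating transforms of the requested point group: `C2` (two copies
#' related by a two-fold), `D3` (three dimers at 120 degrees around the
#' principal axis, the hexamer-of-dimers geometry), or `dimer_of_dimers`
#' (two C2 dimers related by a perpendicular two-fold, their dimer axes
#' tilted by `tilt_angle`; tilt 0 recovers the parallel, octamer-like
#' arrangement). The returned symmetry definition holds the exact generating
#' transforms relative to the first chain.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `assembly` (an [assembly()] with per-dimer partition),
#'   `symdef` (a [symmetry_definition()]), `spec`.
#' @export
make_assembly <- function(spec) {
  pg <- point_group_transforms(spec)
  n_copy <- length(pg$tfs)
  # relative transforms between copies, expressed in the local subunit frame,
  # used to pack the subunit aware of its own symmetry images
  images <- list()
  seen <- character(0)
  for (k in seq_len(n_copy)) {
    for (l in seq_len(n_copy)) {
      if (k == l) next
      h <- compose_transforms(invert_transform(pg$tfs[[k]]), pg$tfs[[l]])
      key <- paste(round(c(h$R, h$t), 6), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        images <- c(images, list(h))
      }
    }
  }
  sub <- with_seed(spec$seed, {
    n <- spec$subunit_beads
    aas <- sample(names(sc_centroid_distance), n, replace = TRUE)
    pk <- pack_chain(n, spec$subunit_radius, aas, images = images)
    assembly(chain_from_packing(pk, aas))
  })
  t1_inv <- invert_transform(pg$tfs[[1]])
  rel <- lapply(pg$tfs, function(tf) compose_transforms(tf, t1_inv))
  # place chain A, then express all transforms relative to it
  placed <- sub
  xyz <- transform_coords(pg$tfs[[1]], coords_matrix(sub))
  placed$x <- xyz[, 1]; placed$y <- xyz[, 2]; placed$z <- xyz[, 3]
  symdef <- symmetry_definition(rel, point_group = pg$label,
                                reference_chain = "A", groups = pg$groups)
  asm <- apply_symmetry(placed, symdef)

  chains <- assembly_chains(asm)
  for (i in seq_along(chains)) {
    for (j in seq_len(i - 1L)) {
      a <- coords_matrix(asm[asm$chain == chains[i], ])
      b <- coords_matrix(asm[asm$chain == chains[j], ])
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      if (min(d2) < 2.5^2) {
        stop(sprintf(
          "inter-subunit clash (%.2f A between chains %s and %s); increase ring_radius or dimer_offset",
          sqrt(max(min(d2), 0)), chains[i], chains[j]))
      }
    }
  }
  list(assembly = asm, symdef = symdef, spec = spec)
}

#' Simulate a noisy experimental SAXS profile from a model
#'
#' The Debye profile of the model with multiplicative Gaussian noise
#' (`sigma = noise_rel * I`, the constant-relative-error approximation of
#' merged SEC-SAXS curves); the `sigma` column records the true noise level.
#' Deterministic under the seed.
#'
#' @param model An [assembly()].
#' @param q_grid Scattering vector grid (1/Angstrom).
#' @param noise_rel Relative noise level (e.g. 0.02).
#' @param seed Integer seed.
#' @param granularity Debye granularity (default `"residue"`).
#' @return A [saxs_profile()] (no `sigma` column when `noise_rel = 0`).
#' @export
make_noisy_profile <- function(model, q_grid, noise_rel = 0.02, seed = 1,
                               granularity = "residue") {
  theo <- debye_profile(model, q_grid, granularity)
  if (noise_rel == 0) return(theo)
  with_seed(seed, {
    sig <- noise_rel * theo$intensity
    saxs_profile(theo$q,
                 theo$intensity + sig * stats::rnorm(length(sig)),
                 sigma = sig, label = "synthetic_experimental")
  })
}

#' Generate a template assembly and a candidate homolog with planted
#' interface differences
#'
#' Emulates a template multimer / candidate-dimer homolog pair: the template
#' is a synthetic assembly (default D3 hexamer); the candidate sequence is
#' the template chain-A sequence with exactly `n_interface_diffs` interfacial
#' positions (by the two interfacial criteria, against the other partition
#' groups) and `n_noninterface_diffs` non-interfacial positions substituted.
#' The planted sites are returned as ground truth, and a coarse candidate
#' subunit (template chain-A geometry carrying the candidate sequence, side
#' chains re-placed for the substituted types) is provided for screening.
#'
#' @param spec A [synthetic_spec()] (point group should be a multimer).
#' @param n_interface_diffs Number of interfacial substitutions to plant.
#' @param n_noninterface_diffs Non-interfacial substitutions (default 3).
#' @return A list: `template`, `symdef`, `candidate_seq`, `subunit` (candidate
#'   chain model), `planted_interface`, `planted_noninterface` (tibbles with
#'   `position`, `template_aa`, `candidate_aa`).
#' @export
make_homolog_pair <- function(spec, n_interface_diffs = 7,
                              n_noninterface_diffs = 3) {
  gen <- make_assembly(spec)
  template <- gen$assembly
  part <- partition(template)
  g_a <- part[["A"]]
  others <- setdiff(unique(part), g_a)
  if (!length(others)) stop("template must be a multimer to have an interface")
  iface <- dplyr::bind_rows(lapply(others, function(gb) {
    interface_residues(template, g_a, gb)$interface_residues
  }))
  iface <- iface[iface$chain == "A", , drop = FALSE]
  iface_pos <- sort(unique(iface$seq_id))
  res <- residue_table(template, "A")
  if (length(iface_pos) < n_interface_diffs) {
    stop(sprintf("only %d interfacial residues available (need %d)",
                 length(iface_pos), n_interface_diffs))
  }
  non_pos <- setdiff(res$seq_id, iface_pos)
  if (length(non_pos) < n_noninterface_diffs) {
    stop("not enough non-interfacial residues for the requested differences")
  }
  with_seed(spec$seed + 7919L, {
    pick_i <- sort(sample(iface_pos, n_interface_diffs))
    pick_n <- sort(sample(non_pos, n_noninterface_diffs))
    subst <- function(aa1) {
      vapply(aa1, function(a) sample(setdiff(names(aa_residue_mass), a), 1),
             character(1), USE.NAMES = FALSE)
    }
    cand <- res$aa
    ti <- match(pick_i, res$seq_id)
    tn <- match(pick_n, res$seq_id)
    cand[ti] <- subst(cand[ti])
    cand[tn] <- subst(cand[tn])
    planted_i <- tibble::tibble(position = pick_i, template_aa = res$aa[ti],
                                candidate_aa = cand[ti])
    planted_n <- tibble::tibble(position = pick_n, template_aa = res$aa[tn],
                                candidate_aa = cand[tn])
    chain_a <- assembly(template[template$chain == "A", ])
    subunit <- mutate_residues(
      chain_a,
      tibble::tibble(position = c(pick_i, pick_n),
                     new_aa = c(planted_i$candidate_aa, planted_n$candidate_aa))
    )
    list(template = template, symdef = gen$symdef,
         candidate_seq = paste0(cand, collapse = ""), subunit = subunit,
         planted_interface = planted_i, planted_noninterface = planted_n)
  })
}
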