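# The dimer-to-hexamer ("2-to-6") engineering screen: enumerate all
# combinations of candidate interface mutations, rebuild a coarse mutant
# assembly under the template symmetry for each, score it over repeated
# side-chain perturbations with a transparent surrogate interaction energy,
# rank by best score, and assess the finalists by interface hydrogen bonds.

#' Parse mutation sites from strings like "K98R"
#'
#' @param x Character vector of `<wild><position><mutant>` strings
#'   (e.g. `c("K98R", "A134R")`).
#' @return Tibble with columns `position`, `wild_aa`, `mutant_aa`.
#' @export
#' @examples
#' mutation_sites(c("K98R", "G151E"))
mutation_sites <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  bad <- lengths(m) != 4
  if (any(bad)) stop("unparseable mutation string: ", paste(x[bad], collapse = ", "))
  out <- tibble::tibble(
    position = as.integer(vapply(m, `[`, character(1), 3)),
    wild_aa = vapply(m, `[`, character(1), 2),
    mutant_aa = vapply(m, `[`, character(1), 4)
  )
  if (any(out$wild_aa == out$mutant_aa)) {
    stop("wild-type and mutant residues must differ")
  }
  out
}

#' Enumerate all combinations of mutation sites
#'
#' The full power set (including the empty, wild-type subset) in
#' deterministic binary-counter order: subset `b` contains site `i` when bit
#' `i` of `b` is set, so 7 sites give 128 combinations.
#'
#' @param sites Tibble of mutation sites ([mutation_sites()]); positions
#'   must be distinct.
#' @return List of integer vectors (row indices into `sites`), length
#'   `2^nrow(sites)`.
#' @export
enumerate_mutants <- function(sites) {
  sites <- tibble::as_tibble(sites)
  if (anyDuplicated(sites$position)) stop("duplicate mutation positions")
  k <- nrow(sites)
  if (k > 20) stop("refusing to enumerate more than 2^20 combinations")
  lapply(0:(2^k - 1), function(b) {
    if (k == 0) return(integer(0))
    which(bitwAnd(b, bitwShiftL(1L, 0:(k - 1))) > 0)
  })
}

#' @keywords internal
#' Replace residue types in a coarse model; side-chain pseudo-atoms are
#' re-placed at the new idealized centroid distance along the existing
#' CA-to-side-chain direction (outward from the chain centroid when the wild
#' type was glycine).
mutate_residues <- function(subunit, changes) {
  subunit <- check_assembly(subunit)
  atoms <- tibble::as_tibble(subunit)
  cen <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
  for (r in seq_len(nrow(changes))) {
    pos <- changes$position[r]
    new_aa <- changes$new_aa[r]
    idx <- which(atoms$seq_id == pos)
    if (!length(idx)) stop("mutation position absent from subunit: ", pos)
    atoms$aa[idx] <- new_aa
    atoms$resname[idx] <- unname(aa_one_to_three[new_aa])
    i_ca <- idx[atoms$atom[idx] == "CA"]
    i_sc <- idx[atoms$atom[idx] == "SC"]
    d_new <- sc_centroid_distance[new_aa]
    if (d_new == 0) {
      if (length(i_sc)) atoms <- atoms[-i_sc, ]
      next
    }
    ca <- c(atoms$x[i_ca], atoms$y[i_ca], atoms$z[i_ca])
    if (length(i_sc)) {
      u <- c(atoms$x[i_sc], atoms$y[i_sc], atoms$z[i_sc]) - ca
      u <- u / sqrt(sum(u^2))
      sc <- ca + d_new * u
      atoms$x[i_sc] <- sc[1]; atoms$y[i_sc] <- sc[2]; atoms$z[i_sc] <- sc[3]
    } else {
      u <- ca - cen
      u <- u / sqrt(sum(u^2))
      sc <- ca + d_new * u
      atoms <- dplyr::bind_rows(atoms, tibble::tibble(
        chain = atoms$chain[i_ca], seq_id = pos, ins = atoms$ins[i_ca],
        resname = unname(aa_one_to_three[new_aa]), aa = new_aa,
        atom = "SC", element = "C", x = sc[1], y = sc[2], z = sc[3],
        occupancy = 1, is_sidechain = TRUE
      ))
    }
  }
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$seq_id, atoms$ins, atoms$is_sidechain), ]
  assembly(atoms, partition = partition(subunit))
}

#' Build a mutant assembly under the template symmetry
#'
#' Applies a subset of mutations to the subunit (every symmetry copy carries
#' them) and replicates it with [apply_symmetry()].
#'
#' @param subunit A one-subunit [assembly()].
#' @param sites Mutation-site tibble ([mutation_sites()]).
#' @param subset Integer vector of row indices into `sites` (possibly empty).
#' @param symdef A [symmetry_definition()].
#' @return The mutant [assembly()].
#' @export
build_mutant_assembly <- function(subunit, sites, subset, symdef) {
  sub <- subunit
  if (length(subset)) {
    sub <- mutate_residues(subunit, tibble::tibble(
      position = sites$position[subset], new_aa = sites$mutant_aa[subset]
    ))
  }
  apply_symmetry(sub, symdef)
}

#' Default weights of the surrogate interaction score
#'
#' @return Named list: `clash` (soft-core repulsion weight), `clash_radius`
#'   (Angstrom), `hbond` and `salt` (reward weights), `interface_cutoff`
#'   (pair inclusion distance, Angstrom).
#' @export
surrogate_weights <- function() {
  list(clash = 1, clash_radius = 3.0, hbond = 1, salt = 2, interface_cutoff = 8)
}

#' Surrogate interface interaction score over perturbed samples
#'
#' A transparent stand-in for an all-atom design energy: over all cross-group
#' heavy-atom pairs within `interface_cutoff`, sums a soft-core clash
#' repulsion `clash * ((clash_radius/d)^8 - 1)` for `d < clash_radius`, a
#' hydrogen-bond reward of `-hbond` per donor-acceptor pair within 3.6
#' Angstrom, and a salt-bridge reward of `-salt` per charged pair within 4.0
#' Angstrom; lower is better. Each sample applies Gaussian jitter of
#' `perturb_sigma` to side-chain pseudo-atoms (restricted, when
#' `relax_positions` is given, to side chains within `relax_radius` of any
#' mutation site).
#'
#' @param assembly_model An [assembly()] with >= 2 partition groups.
#' @param perturb_sigma Jitter standard deviation in Angstrom (default 0.3).
#' @param n_samples Number of independent samples (default 50).
#' @param seed Integer seed.
#' @param weights Score weights, see [surrogate_weights()].
#' @param relax_positions Optional integer residue positions; jitter is
#'   limited to side chains within `relax_radius` of any atom of these
#'   residues.
#' @param relax_radius Radius of the relaxation sphere, Angstrom (default 12).
#' @return A list of class `surrogate_score`: `sample_scores`, `best_score`,
#'   `best_sample` (index), `best_assembly` (the jittered coordinates of the
#'   best sample), `n_pairs`.
#' @export
surrogate_score <- function(assembly_model, perturb_sigma = 0.3,
                            n_samples = 50, seed = 1,
                            weights = surrogate_weights(),
                            relax_positions = NULL, relax_radius = 12) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (perturb_sigma < 0) stop("perturb_sigma must be >= 0")
  model <- check_assembly(assembly_model)
  part <- partition(model)
  groups <- unique(part)
  if (length(groups) < 2) stop("assembly must have at least 2 partition groups")
  cutoff <- weights$interface_cutoff
  margin <- cutoff + 6 * perturb_sigma + 0.5

  pair_i <- integer(0); pair_j <- integer(0)
  for (a in seq_along(groups)) {
    for (b in seq_len(a - 1L)) {
      pr <- cross_group_pairs(model, groups[a], groups[b], margin)
      pair_i <- c(pair_i, pr$ia); pair_j <- c(pair_j, pr$ib)
    }
  }
  if (!length(pair_i)) {
    warning("empty interface: no cross-group atom pairs within ", cutoff, " A")
    return(structure(list(sample_scores = rep(0, n_samples), best_score = 0,
                          best_sample = 1L, best_assembly = model, n_pairs = 0L),
                     class = "surrogate_score"))
  }

  hb_mask <- (is_donor_atom(model$aa[pair_i], model$atom[pair_i]) &
                is_acceptor_atom(model$aa[pair_j], model$atom[pair_j])) |
    (is_donor_atom(model$aa[pair_j], model$atom[pair_j]) &
       is_acceptor_atom(model$aa[pair_i], model$atom[pair_i]))
  sb_mask <- (is_basic_atom(model$aa[pair_i], model$atom[pair_i]) &
                is_acidic_atom(model$aa[pair_j], model$atom[pair_j])) |
    (is_basic_atom(model$aa[pair_j], model$atom[pair_j]) &
       is_acidic_atom(model$aa[pair_i], model$atom[pair_i]))

  jit_idx <- which(model$is_sidechain)
  if (!is.null(relax_positions)) {
    site_xyz <- coords_matrix(model[model$seq_id %in% relax_positions, ])
    if (nrow(site_xyz)) {
      sc_xyz <- coords_matrix(model[jit_idx, ])
      near <- vapply(seq_along(jit_idx), function(i) {
        min(rowSums(sweep(site_xyz, 2, sc_xyz[i, ])^2)) <= relax_radius^2
      }, logical(1))
      jit_idx <- jit_idx[near]
    } else {
      jit_idx <- integer(0)
    }
  }

  xyz0 <- coords_matrix(model)
  xi <- xyz0[pair_i, , drop = FALSE]; xj <- xyz0[pair_j, , drop = FALSE]
  score_one <- function(dx_jit) {
    xi_s <- xi; xj_s <- xj
    if (!is.null(dx_jit)) {
      mi <- match(pair_i, jit_idx); has_i <- !is.na(mi)
      mj <- match(pair_j, jit_idx); has_j <- !is.na(mj)
      xi_s[has_i, ] <- xi_s[has_i, ] + dx_jit[mi[has_i], , drop = FALSE]
      xj_s[has_j, ] <- xj_s[has_j, ] + dx_jit[mj[has_j], , drop = FALSE]
    }
    d <- sqrt(rowSums((xi_s - xj_s)^2))
    inside <- d <= cutoff
    d_in <- d[inside]
    clash <- d_in < weights$clash_radius
    rep_term <- sum(weights$clash * ((weights$clash_radius / d_in[clash])^8 - 1))
    hb_term <- -weights$hbond * sum(hb_mask[inside] & d_in <= 3.6)
    sb_term <- -weights$salt * sum(sb_mask[inside] & d_in <= 4.0)
    rep_term + hb_term + sb_term
  }

  scores <- numeric(n_samples)
  jitters <- vector("list", n_samples)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      dx <- if (perturb_sigma > 0 && length(jit_idx)) {
        matrix(stats::rnorm(3 * length(jit_idx), sd = perturb_sigma),
               ncol = 3)
      } else NULL
      jitters[s] <- list(dx)
      scores[s] <- score_one(dx)
    }
  })
  best <- which.min(scores)
  best_model <- model
  if (!is.null(jitters[[best]])) {
    xyz_b <- xyz0
    xyz_b[jit_idx, ] <- xyz_b[jit_idx, ] + jitters[[best]]
    best_model$x <- xyz_b[, 1]; best_model$y <- xyz_b[, 2]
    best_model$z <- xyz_b[, 3]
  }
  structure(
    list(sample_scores = scores, best_score = scores[best],
         best_sample = best, best_assembly = best_model,
         n_pairs = length(pair_i)),
    class = "surrogate_score"
  )
}

#' @keywords internal
#' Total hydrogen bonds across all unordered partition-group pairs.
interface_hbond_count <- function(model, cutoff = 3.6) {
  groups <- unique(partition(model))
  total <- 0L
  for (a in seq_along(groups)) {
    for (b in seq_len(a - 1L)) {
      total <- total + nrow(hydrogen_bonds(model, groups[a], groups[b], cutoff))
    }
  }
  total
}

#' Run the combinatorial interface-mutant screen
#'
#' Enumerates every subset of the mutation sites, builds each mutant assembly
#' under the template symmetry, scores it with [surrogate_score()] over
#' `n_samples` perturbed samples, ranks candidates by their best (lowest)
#' sample score, takes the top `finalists`, counts interface hydrogen bonds
#' on each finalist's best sample, and selects the finalist with the most
#' hydrogen bonds (ties broken by better score, then lower binary index).
#' The whole screen is a pure function of its inputs and seed.
#'
#' @param subunit A one-subunit [assembly()].
#' @param sites Mutation-site tibble ([mutation_sites()]).
#' @param symdef A [symmetry_definition()].
#' @param n_samples Samples per candidate (default 50).
#' @param finalists Number of top-scoring candidates assessed by hydrogen
#'   bonds (default 5).
#' @param perturb_sigma Side-chain jitter in Angstrom (default 0.3).
#' @param seed Integer seed.
#' @param weights Score weights ([surrogate_weights()]).
#' @param relax_radius Relaxation sphere around mutation sites, Angstrom
#'   (default 12).
#' @return A `design_screen` list: `candidates` tibble (`id`, `mutations`,
#'   `n_mutations`, `best_score`, `rank`, `is_finalist`, `hbonds`),
#'   `selected` (id), `selected_assembly`, `sites`, `seed`, `config`.
#' @export
run_screen <- function(subunit, sites, symdef, n_samples = 50, finalists = 5,
                       perturb_sigma = 0.3, seed = 1,
                       weights = surrogate_weights(), relax_radius = 12) {
  sites <- tibble::as_tibble(sites)
  subsets <- enumerate_mutants(sites)
  n_cand <- length(subsets)
  best_scores <- numeric(n_cand)
  fits <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    asm <- build_mutant_assembly(subunit, sites, subsets[[i]], symdef)
    fits[[i]] <- withCallingHandlers(
      surrogate_score(asm, perturb_sigma = perturb_sigma,
                      n_samples = n_samples, seed = seed + i,
                      weights = weights,
                      relax_positions = if (length(subsets[[i]]))
                        sites$position[subsets[[i]]] else NULL,
                      relax_radius = relax_radius),
      warning = function(w) invokeRestart("muffleWarning")
    )
    best_scores[i] <- fits[[i]]$best_score
  }
  rank_order <- order(best_scores, seq_len(n_cand))
  ranks <- integer(n_cand); ranks[rank_order] <- seq_len(n_cand)
  n_fin <- min(finalists, n_cand)
  finalist_ids <- rank_order[seq_len(n_fin)]
  hbonds <- rep(NA_integer_, n_cand)
  for (i in finalist_ids) {
    hbonds[i] <- interface_hbond_count(fits[[i]]$best_assembly)
  }
  fin_tbl <- data.frame(i = finalist_ids, hb = hbonds[finalist_ids],
                        sc = best_scores[finalist_ids])
  fin_tbl <- fin_tbl[order(-fin_tbl$hb, fin_tbl$sc, fin_tbl$i), ]
  sel <- fin_tbl$i[1]
  mut_label <- vapply(subsets, function(ss) {
    if (!length(ss)) return("wild-type")
    paste0(sites$wild_aa[ss], sites$position[ss], sites$mutant_aa[ss],
           collapse = "+")
  }, character(1))
  candidates <- tibble::tibble(
    id = seq_len(n_cand) - 1L,
    mutations = mut_label,
    n_mutations = lengths(subsets),
    best_score = best_scores,
    rank = ranks,
    is_finalist = seq_len(n_cand) %in% finalist_ids,
    hbonds = hbonds
  )
  structure(
    list(candidates = candidates, selected = sel - 1L,
         selected_mutations = mut_label[sel],
         selected_assembly = fits[[sel]]$best_assembly,
         sites = sites, seed = seed,
         config = list(n_samples = n_samples, finalists = finalists,
                       perturb_sigma = perturb_sigma,
                       relax_radius = relax_radius, weights = weights)),
    class = "design_screen"
  )
}

#' @export
print.design_screen <- function(x, ...) {
  cat(sprintf("<design_screen> %d candidates from %d sites, seed %d\n",
              nrow(x$candidates), nrow(x$sites), x$seed))
  cat(sprintf("  selected: %s (id %d)\n", x$selected_mutations, x$selected))
  fin <- x$candidates[x$candidates$is_finalist, ]
  fin <- fin[order(fin$rank), ]
  cat("  finalists:\n")
  for (i in seq_len(nrow(fin))) {
    cat(sprintf("    %-30s score %8.3f  H-bonds %d\n",
                fin$mutations[i], fin$best_score[i], fin$hbonds[i]))
  }
  invisible(x)
}
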