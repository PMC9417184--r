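#' Symmetry definition of a homomeric assembly
#'
#' An ordered set of rigid-body transforms mapping a reference subunit onto
#' every symmetry-equivalent position of an assembly (the first transform is
#' the identity), together with an inferred point-group label. This plays the
#' role of a Rosetta-style symmetry definition for building full assemblies
#' from a single subunit.
#'
#' @param transforms List of [rigid_transform()]; the first must be the
#'   identity.
#' @param point_group Point-group label, e.g. `"C2"`, `"D3"` (informational).
#' @param reference_chain Chain id of the reference subunit.
#' @param groups Optional character vector (one per transform) assigning each
#'   symmetry copy to a partition group (e.g. pairing copies into dimers).
#' @param rmsd Optional per-transform superposition RMSDs (from
#'   [derive_symmetry()]).
#' @return A `symmetry_definition` object.
#' @export
symmetry_definition <- function(transforms, point_group = "unknown",
                                reference_chain = "A", groups = NULL,
                                rmsd = NULL) {
  stopifnot(length(transforms) >= 1)
  id <- transforms[[1]]
  if (max(abs(id$R - diag(3))) > 1e-9 || max(abs(id$t)) > 1e-9) {
    stop("the first transform must be the identity")
  }
  if (is.null(groups)) {
    groups <- paste0("sub", seq_along(transforms))
  }
  stopifnot(length(groups) == length(transforms))
  structure(
    list(transforms = transforms, point_group = point_group,
         reference_chain = reference_chain, groups = groups, rmsd = rmsd),
    class = "symmetry_definition"
  )
}

#' @export
print.symmetry_definition <- function(x, ...) {
  cat(sprintf("<symmetry_definition> %d transforms, point group %s, reference chain %s\n",
              length(x$transforms), x$point_group, x$reference_chain))
  if (!is.null(x$rmsd)) {
    cat(sprintf("  per-chain superposition RMSD: %s A\n",
                paste(signif(x$rmsd, 3), collapse = ", ")))
  }
  invisible(x)
}

#' @keywords internal
infer_point_group <- function(transforms, tol_deg = 2) {
  n <- length(transforms)
  if (n == 1) return("C1")
  ang <- vapply(transforms, function(tf) rotation_angle(tf$R), numeric(1)) * 180 / pi
  # rotation_angle folds into [0, 180], so fold the expected multisets too
  fold <- function(th) pmin(th %% 360, 360 - th %% 360)
  cyc <- fold((360 / n) * (seq_len(n) - 1))
  near <- function(a, b) all(abs(sort(a) - sort(b)) < tol_deg)
  if (near(ang, cyc)) {
    axes <- lapply(transforms[-1], function(tf) rotation_axis(tf$R))
    ok <- all(vapply(axes, function(a) {
      abs(abs(sum(a * axes[[1]])) - 1) < 1e-3
    }, logical(1)))
    if (ok || n == 2) return(paste0("C", n))
  }
  if (n %% 2 == 0) {
    m <- n / 2
    dih <- c(fold((360 / m) * (seq_len(m) - 1)), rep(180, m))
    if (near(ang, dih)) return(paste0("D", m))
  }
  "unknown"
}

#' Derive the symmetry definition of a homomeric assembly
#'
#' For every chain, computes the least-squares (Kabsch) transform superposing
#' the reference chain's CA atoms onto that chain's CA atoms, residues matched
#' by order for equal-length chains or by global sequence alignment otherwise.
#' Deposited structures are only approximately symmetric, so each per-chain
#' RMSD is reported and checked against `rmsd_tol`.
#'
#' @param reference An [assembly()] whose chains are >= 70% mutually identical
#'   in sequence (a homomer).
#' @param reference_chain Chain to use as the reference subunit (default:
#'   first chain).
#' @param rmsd_tol Maximum allowed per-chain superposition RMSD in Angstrom
#'   (default 2.0); larger values indicate a wrong chain pairing.
#' @param min_ca Minimum number of matched CA atoms per chain (default 20).
#' @return A [symmetry_definition()] with the reference (identity) transform
#'   first and per-chain RMSDs; the point-group label is inferred from the
#'   transform count and rotation angles (reported, not enforced).
#' @export
derive_symmetry <- function(reference, reference_chain = NULL, rmsd_tol = 2.0,
                            min_ca = 20) {
  reference <- check_assembly(reference)
  chains <- assembly_chains(reference)
  if (is.null(reference_chain)) reference_chain <- chains[1]
  if (!reference_chain %in% chains) stop("unknown chain: ", reference_chain)

  ref_seq <- chain_sequence(reference, reference_chain)
  for (ch in setdiff(chains, reference_chain)) {
    pid <- percent_identity(ref_seq, chain_sequence(reference, ch))
    if (pid < 70) {
      stop(sprintf("chain %s is only %.1f%% identical to chain %s; not a homomer",
                   ch, pid, reference_chain))
    }
  }

  ca_tbl <- function(ch) {
    sub <- reference[reference$chain == ch & reference$atom == "CA", ]
    sub[order(sub$seq_id, sub$ins), ]
  }
  ref_ca <- ca_tbl(reference_chain)

  transforms <- list()
  rmsds <- numeric(0)
  others <- c(reference_chain, setdiff(chains, reference_chain))
  for (ch in others) {
    if (ch == reference_chain) {
      transforms <- c(transforms, list(rigid_transform()))
      rmsds <- c(rmsds, 0)
      next
    }
    tgt_ca <- ca_tbl(ch)
    if (nrow(ref_ca) == nrow(tgt_ca)) {
      ia <- seq_len(nrow(ref_ca)); ib <- ia
    } else {
      al <- align_pair(paste0(ref_ca$aa, collapse = ""),
                       paste0(tgt_ca$aa, collapse = ""))
      ia <- al$i_a; ib <- al$i_b
    }
    if (length(ia) < min_ca) {
      stop(sprintf("chain %s: only %d matched CA atoms (need >= %d)",
                   ch, length(ia), min_ca))
    }
    fit <- superpose(coords_matrix(ref_ca[ia, ]), coords_matrix(tgt_ca[ib, ]))
    if (fit$rmsd > rmsd_tol) {
      stop(sprintf("chain %s superposes on chain %s with RMSD %.2f A (> %.2f A tolerance)",
                   ch, reference_chain, fit$rmsd, rmsd_tol))
    }
    transforms <- c(transforms, list(fit$transform))
    rmsds <- c(rmsds, fit$rmsd)
  }
  symmetry_definition(transforms,
                      point_group = infer_point_group(transforms),
                      reference_chain = reference_chain, rmsd = rmsds)
}

#' Build a full assembly by applying a symmetry definition to a subunit
#'
#' Places one copy of the subunit per transform; chains are relabelled
#' deterministically (`A`, `B`, `C`, ...) and each copy is assigned the
#' partition group recorded in the symmetry definition.
#'
#' @param subunit An [assembly()] holding the reference subunit.
#' @param symdef A [symmetry_definition()].
#' @return An [assembly()] with `length(symdef$transforms)` copies.
#' @export
apply_symmetry <- function(subunit, symdef) {
  subunit <- check_assembly(subunit)
  sub_chains <- assembly_chains(subunit)
  n_copy <- length(symdef$transforms)
  labels <- c(LETTERS, letters, as.character(0:9))
  if (n_copy * length(sub_chains) > length(labels)) {
    stop("too many chains to relabel uniquely")
  }
  pieces <- vector("list", n_copy)
  part <- character(0)
  k <- 0L
  for (i in seq_len(n_copy)) {
    copy <- subunit
    xyz <- transform_coords(symdef$transforms[[i]], coords_matrix(copy))
    copy$x <- xyz[, 1]; copy$y <- xyz[, 2]; copy$z <- xyz[, 3]
    new_ids <- labels[k + seq_along(sub_chains)]
    copy$chain <- new_ids[match(copy$chain, sub_chains)]
    k <- k + length(sub_chains)
    part[new_ids] <- symdef$groups[i]
    pieces[[i]] <- tibble::as_tibble(copy)
  }
  assembly(dplyr::bind_rows(pieces), partition = part)
}

#' Serialize a symmetry definition to JSON
#'
#' Rotation matrices are written row-major; translations in Angstrom.
#'
#' @param symdef A [symmetry_definition()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_symmetry_json <- function(symdef, path) {
  obj <- list(
    point_group = symdef$point_group,
    reference_chain = symdef$reference_chain,
    groups = symdef$groups,
    transforms = lapply(symdef$transforms, function(tf) {
      list(rotation = as.vector(t(tf$R)), translation = tf$t)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a symmetry definition from JSON
#'
#' @param path Path written by [write_symmetry_json()].
#' @return A [symmetry_definition()].
#' @export
read_symmetry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tfs <- lapply(seq_len(nrow(obj$transforms)), function(i) {
    rigid_transform(matrix(unlist(obj$transforms$rotation[i]), 3, 3, byrow = TRUE),
                    unlist(obj$transforms$translation[i]))
  })
  symmetry_definition(tfs, point_group = obj$point_group,
                      reference_chain = obj$reference_chain,
                      groups = obj$groups)
}
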