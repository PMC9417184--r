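#' Construct an assembly model from an atom table
#'
#' An assembly is a tibble of heavy-atom records (one row per atom) carrying a
#' chain-to-group partition as an attribute. It is the container every other
#' stage of the pipeline consumes: interface analysis compares partition
#' groups, symmetry derivation superposes chains, and SAXS computation uses
#' the coordinates and residue identities.
#'
#' @param atoms A data frame with columns `chain` (single-character chain id),
#'   `seq_id` (integer author residue number), `ins` (insertion code, `""` if
#'   none), `resname` (3-letter residue name), `aa` (1-letter code; derived
#'   from `resname` when absent), `atom` (atom name), `element` (element
#'   symbol), `x`, `y`, `z` (Angstrom), and optionally `occupancy` (defaults
#'   to 1) and `is_sidechain` (derived from the atom name when absent).
#' @param partition Named character vector mapping every chain id to a group
#'   label, e.g. `c(A = "dimerA", B = "dimerA", C = "dimerB", ...)`. Defaults
#'   to one group per chain, labelled by the chain id.
#' @param ligands Optional tibble of HETATM ligand records with the same
#'   columns; excluded from all geometric analyses by default.
#'
#' @return A tibble of class `oligo_assembly` with attributes `partition` and
#'   `ligands`.
#' @export
#' @examples
#' atoms <- tibble::tibble(
#'   chain = "A", seq_id = 1:2, ins = "", resname = c("GLY", "ALA"),
#'   atom = "CA", element = "C", x = c(0, 3.8), y = 0, z = 0
#' )
#' assembly(atoms)
assembly <- function(atoms, partition = NULL, ligands = NULL) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("chain", "seq_id", "ins", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(atoms)) stop("assembly must contain at least one atom")
  if (!"aa" %in% names(atoms)) atoms$aa <- aa_one_letter(atoms$resname)
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"is_sidechain" %in% names(atoms)) {
    atoms$is_sidechain <- !(atoms$atom %in% backbone_atom_names)
  }
  atoms <- atoms[, c("chain", "seq_id", "ins", "resname", "aa", "atom",
                     "element", "x", "y", "z", "occupancy", "is_sidechain")]
  atoms$seq_id <- as.integer(atoms$seq_id)
  chains <- unique(atoms$chain)
  if (is.null(partition)) {
    partition <- stats::setNames(chains, chains)
  }
  partition <- partition[chains]
  if (anyNA(partition)) {
    stop("partition must assign every chain to exactly one group")
  }
  names(partition) <- chains
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("atom coordinates must be finite")
  }
  dup <- duplicated(atoms[, c("chain", "seq_id", "ins", "atom")])
  if (any(dup)) {
    stop("duplicate atom name within a residue: ",
         paste(atoms$chain[dup][1], atoms$seq_id[dup][1], atoms$atom[dup][1]))
  }
  structure(
    atoms,
    partition = partition,
    ligands = if (is.null(ligands)) NULL else tibble::as_tibble(ligands),
    class = c("oligo_assembly", class(tibble::tibble()))
  )
}

#' @export
print.oligo_assembly <- function(x, ...) {
  part <- partition(x)
  cat(sprintf("<oligo_assembly> %d atoms, %d chains, %d groups\n",
              nrow(x), length(part), length(unique(part))))
  grp <- split(names(part), part)
  for (g in names(grp)) {
    cat(sprintf("  %s: chains %s\n", g, paste(grp[[g]], collapse = ", ")))
  }
  NextMethod()
}

#' Chain-to-group partition of an assembly
#'
#' @param model An `oligo_assembly`.
#' @return Named character vector mapping chain ids to group labels.
#' @export
partition <- function(model) {
  attr(model, "partition", exact = TRUE)
}

#' Replace the partition of an assembly
#'
#' @param model An `oligo_assembly`.
#' @param value Named character vector (chain id -> group label).
#' @export
`partition<-` <- function(model, value) {
  assembly(model, partition = value, ligands = ligands(model))
}

#' Ligand (HETATM) records kept aside from the protein model
#'
#' @param model An `oligo_assembly`.
#' @return Tibble of ligand atom records, or `NULL`.
#' @export
ligands <- function(model) {
  attr(model, "ligands", exact = TRUE)
}

#' @keywords internal
coords_matrix <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' @keywords internal
assembly_chains <- function(model) unique(model$chain)

#' @keywords internal
check_assembly <- function(model) {
  if (!inherits(model, "oligo_assembly")) {
    model <- assembly(model)
  }
  model
}

#' One-letter sequence of a chain
#'
#' Residues are ordered by `(seq_id, insertion code)`; non-standard residues
#' map to `X` except selenomethionine (`MSE`), which maps to `M`.
#'
#' @param model An `oligo_assembly`.
#' @param chain_id Single-character chain identifier.
#' @return A one-letter amino-acid string (empty for an empty chain).
#' @export
chain_sequence <- function(model, chain_id) {
  model <- check_assembly(model)
  if (!chain_id %in% model$chain) stop("unknown chain: ", chain_id)
  res <- dplyr::distinct(
    model[model$chain == chain_id, c("seq_id", "ins", "aa")]
  )
  res <- res[order(res$seq_id, res$ins), ]
  paste0(res$aa, collapse = "")
}

#' Per-residue table of a chain
#' @keywords internal
residue_table <- function(model, chain_id = NULL) {
  atoms <- if (is.null(chain_id)) model else model[model$chain == chain_id, ]
  res <- dplyr::distinct(atoms[, c("chain", "seq_id", "ins", "resname", "aa")])
  res[order(res$chain, res$seq_id, res$ins), ]
}

#' Theoretical average molecular mass of a set of chains
#'
#' Sums IUPAC average residue masses and adds one water per chain, the
#' standard sequence-based estimate used to check a measured molecular weight
#' against a proposed subunit composition (e.g. a 218.3 kDa complex of four
#' roughly 50 kDa subunits).
#'
#' @param sequences Character vector of one-letter amino-acid sequences (one
#'   element per chain). Only the 20 standard codes are accepted.
#' @return Mass in kDa.
#' @export
#' @examples
#' theoretical_mass(strrep("G", 10)) # 0.58853 kDa
theoretical_mass <- function(sequences) {
  if (!length(sequences)) return(0)
  per_chain <- vapply(sequences, function(s) {
    if (!nzchar(s)) return(0)
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(aa, names(aa_residue_mass))
    if (length(bad)) {
      stop("non-standard amino acid code: ", paste(unique(bad), collapse = ", "))
    }
    sum(aa_residue_mass[aa]) + water_mass
  }, numeric(1))
  sum(per_chain) / 1000
}
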