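#' Read a PDB file into an assembly model
#'
#' Protein `ATOM` records become the assembly; `HETATM` ligands (e.g. the
#' active-site inhibitor CABP) are kept in a separate ligand table and
#' excluded from interface and SAXS computations by default. Waters and
#' hydrogens are dropped. Alternate locations are resolved per `altloc_policy`.
#' Chain-group partition labels written by [write_pdb()] (`REMARK 300 GROUP`)
#' are restored when present.
#'
#' @param path Path to a PDB-format text file.
#' @param altloc_policy `"occupancy"` (default: keep the highest-occupancy
#'   conformer, ties broken by the alphabetically first altloc id) or
#'   `"first"` (keep the first conformer encountered).
#' @return An [assembly()] (`oligo_assembly` tibble).
#' @export
read_pdb <- function(path, altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d (truncated)", i))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz)) {
      stop(sprintf("malformed PDB record at line %d (unparseable coordinates)", i))
    }
  }

  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  elem <- at$elesy
  guess <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety))
  elem[is.na(elem) | !nzchar(elem)] <- guess[is.na(elem) | !nzchar(elem)]
  at$element <- toupper(elem)

  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  to_tbl <- function(d) {
    tibble::tibble(
      chain = d$chain, seq_id = as.integer(d$resno), ins = d$insert,
      resname = d$resid, aa = aa_one_letter(d$resid), atom = d$elety,
      element = d$element, x = d$x, y = d$y, z = d$z,
      occupancy = d$o,
      is_sidechain = !(d$elety %in% backbone_atom_names),
      alt = d$alt
    )
  }

  resolve_alt <- function(tb) {
    if (!nrow(tb)) return(tb)
    key <- paste(tb$chain, tb$seq_id, tb$ins, tb$atom, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(tb)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      sub <- tb[idx, ]
      if (altloc_policy == "first") return(idx[1])
      best <- which(sub$occupancy == max(sub$occupancy))
      idx[best[order(sub$alt[best])[1]]]
    }), use.names = FALSE)
    tb[sort(keep), ]
  }

  prot <- resolve_alt(to_tbl(at[at$type == "ATOM", , drop = FALSE]))
  lig <- resolve_alt(to_tbl(at[at$type == "HETATM", , drop = FALSE]))
  prot$alt <- NULL
  if (nrow(lig)) lig$alt <- NULL else lig <- NULL
  if (!nrow(prot)) stop("no protein ATOM records found in ", path)

  part <- NULL
  grp_lines <- grep("^REMARK 300 GROUP ", lines, value = TRUE)
  if (length(grp_lines)) {
    part <- character(0)
    for (gl in grp_lines) {
      m <- regmatches(gl, regexec("^REMARK 300 GROUP (\\S+) CHAINS (.+)$", gl))[[1]]
      if (length(m) == 3) {
        ids <- strsplit(trimws(m[3]), "\\s+")[[1]]
        part[ids] <- m[2]
      }
    }
    if (!all(unique(prot$chain) %in% names(part))) part <- NULL
  }

  assembly(prot, partition = part, ligands = lig)
}

#' @keywords internal
format_atom_name <- function(name, element) {
  # Names of atoms with 1-letter elements start in column 14 unless 4 chars.
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(element) == 1, sprintf(" %-3s", name),
                sprintf("%-4s", name)))
}

#' Write an assembly model as a PDB file
#'
#' Emits standard `ATOM` records with 3-decimal coordinates, preserving chain
#' ids and residue numbering, plus `REMARK 300 GROUP` lines recording the
#' chain partition so [read_pdb()] round-trips it. Ligands, when present, are
#' appended as `HETATM` records.
#'
#' @param model An [assembly()].
#' @param path Output file path.
#' @param include_ligands Write the ligand table as HETATM records
#'   (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path, include_ligands = TRUE) {
  model <- check_assembly(model)
  lig <- if (include_ligands) ligands(model) else NULL
  n_atoms <- nrow(model) + if (is.null(lig)) 0 else nrow(lig)
  if (n_atoms > 99999) {
    stop("PDB format cannot hold more than 99999 atoms (have ", n_atoms, ")")
  }
  part <- partition(model)
  out <- character(0)
  for (g in unique(part)) {
    out <- c(out, sprintf("REMARK 300 GROUP %s CHAINS %s", g,
                          paste(names(part)[part == g], collapse = " ")))
  }
  serial0 <- 0L
  fmt_rec <- function(kind, a) {
    recs <- sprintf(
      "%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      kind, serial0 + seq_len(nrow(a)), format_atom_name(a$atom, a$element),
      a$resname, a$chain, a$seq_id, ifelse(nzchar(a$ins), a$ins, " "),
      a$x, a$y, a$z, a$occupancy, 0, a$element)
    serial0 <<- serial0 + nrow(a)
    recs
  }
  for (ch in assembly_chains(model)) {
    out <- c(out, fmt_rec("ATOM", model[model$chain == ch, ]), "TER")
  }
  if (!is.null(lig) && nrow(lig)) {
    out <- c(out, fmt_rec("HETATM", lig))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
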