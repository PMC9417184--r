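#' @keywords internal
#' Global pairwise alignment of two one-letter protein sequences.
#' Returns the aligned strings and the matched (ungapped-column) position
#' indices into each input sequence. BLOSUM62 with affine gaps (open 10,
#' extend 0.5) — standard defaults, documented in the methods vignette.
align_pair <- function(seq_a, seq_b, gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  blosum <- get_blosum62()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = blosum, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global"
  )
  a <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  list(aligned_a = a, aligned_b = b,
       i_a = pos_a[both], i_b = pos_b[both],
       match = a[both] == b[both])
}

#' @keywords internal
get_blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Percent sequence identity from a global alignment
#'
#' Identities divided by aligned ungapped columns, times 100; alignment by
#' BLOSUM62 with affine gap penalties (see [align_pair()] internals, settings
#' documented in the vignette).
#'
#' @param seq_a,seq_b One-letter amino-acid sequences.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("AAAA", "AATA") # 75
percent_identity <- function(seq_a, seq_b) {
  al <- align_pair(seq_a, seq_b)
  if (!length(al$match)) return(0)
  100 * sum(al$match) / length(al$match)
}

#' Interfacial positions where a candidate homolog differs from the template
#'
#' Locates the template's interfacial residues (by the two geometric criteria
#' of [interface_residues()]) on one chain, aligns the candidate sequence to
#' that chain, and reports the interfacial template positions whose aligned
#' candidate residue differs. Gapped columns are excluded. This is the
#' site-selection step of the dimer-to-hexamer ("2-to-6") engineering screen.
#'
#' @param template An [assembly()] (e.g. a hexamer partitioned into dimers).
#' @param candidate_seq One-letter sequence of the candidate homolog subunit.
#' @param group_a Partition group holding the chain of interest.
#' @param group_b Opposite partition group(s); defaults to all other groups.
#' @param chain_id Chain whose sequence anchors the alignment (default: first
#'   chain of `group_a`).
#' @param ... Passed to [interface_residues()] (cutoffs).
#' @return Tibble with columns `position` (template author number),
#'   `template_aa`, `candidate_aa`, `criterion`.
#' @export
differing_interface_sites <- function(template, candidate_seq, group_a = NULL,
                                      group_b = NULL, chain_id = NULL, ...) {
  template <- check_assembly(template)
  part <- partition(template)
  groups <- unique(part)
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b)) group_b <- setdiff(groups, group_a)
  if (is.null(chain_id)) chain_id <- names(part)[part == group_a][1]

  iface <- dplyr::bind_rows(lapply(group_b, function(gb) {
    interface_residues(template, group_a, gb, ...)$interface_residues
  }))
  iface <- iface[iface$chain == chain_id, , drop = FALSE]
  iface <- iface[!duplicated(iface$seq_id), , drop = FALSE]

  res <- residue_table(template, chain_id)
  tmpl_seq <- paste0(res$aa, collapse = "")
  al <- align_pair(tmpl_seq, candidate_seq)
  cand_chars <- strsplit(candidate_seq, "")[[1]]

  out <- tibble::tibble(
    position = res$seq_id[al$i_a],
    template_aa = res$aa[al$i_a],
    candidate_aa = cand_chars[al$i_b]
  )
  out <- out[out$position %in% iface$seq_id &
               out$template_aa != out$candidate_aa, , drop = FALSE]
  out$criterion <- iface$criterion[match(out$position, iface$seq_id)]
  out
}
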