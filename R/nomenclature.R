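# Codon-level consequences of C-to-U edits and standardized site labels.
# Labels follow the gene + "eU" + CDS position + aa_before + aa_after grammar
# (e.g. ndhDeU878SL: serine -> leucine at CDS nucleotide 878). Internally all
# sequence is DNA (T); "U" appears only inside labels.

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Apply C-to-U edits to a CDS
#'
#' Returns a copy of `cds` with `C` replaced by `T` at every position in
#' `positions` (1-based). Every listed position must hold `C`.
#'
#' @param cds DNA string.
#' @param positions Integer vector of 1-based positions (may be empty).
#' @return The edited DNA string, same length as `cds`.
#' @examples
#' apply_edits("ACG", 2)   # "ATG": start-codon creation by editing
#' @export
apply_edits <- function(cds, positions) {
  stopifnot(is.character(cds), length(cds) == 1L)
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(cds)
  if (anyDuplicated(positions)) positions <- unique(positions)
  if (any(positions < 1L | positions > nchar(cds)))
    stop("edit position out of range: ",
         paste(positions[positions < 1L | positions > nchar(cds)],
               collapse = ", "))
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  notC <- positions[chars[positions] != "C"]
  if (length(notC))
    stop("position(s) without genomic C: ", paste(notC, collapse = ", "))
  chars[positions] <- "T"
  paste(chars, collapse = "")
}

#' Characterize one C-to-U editing site
#'
#' Computes the codon context and consequence of editing the cytidine at
#' `cds_pos` of a gene's CDS, and assigns the standardized label
#' `gene + "eU" + cds_pos + aa_before + aa_after`. When further edited
#' cytidines of the *same codon* are given in `co_edits`, the edited amino
#' acid is computed with all of them applied jointly (the mRNA-level
#' consequence of a co-edited codon).
#'
#' `aa_before` is always translated from the genomic codon; `creates_start`
#' is set when the edit turns codon 1 into ATG; `creates_stop` when the
#' edited codon is a stop.
#'
#' @param gene A [gene_sequence()].
#' @param cds_pos 1-based position of the edited C within the CDS.
#' @param co_edits Integer vector of additional edited positions, restricted
#'   to the same codon as `cds_pos`.
#' @return A one-row data frame with columns `gene`, `cds_pos`,
#'   `codon_index`, `codon_pos`, `genomic_codon`, `edited_codon`,
#'   `aa_before`, `aa_after`, `silent`, `creates_start`, `creates_stop`,
#'   `label`.
#' @export
characterize_edit <- function(gene, cds_pos, co_edits = integer()) {
  stopifnot(inherits(gene, "GeneSequence"))
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > nchar(gene$cds))
    stop("cds_pos ", cds_pos, " out of range for ", gene$gene)
  base <- substr(gene$cds, cds_pos, cds_pos)
  if (base != "C") {
    if (base == "T")
      stop("pre-edited position, not an editing site: ", gene$gene, " ",
           cds_pos, " holds T on DNA level")
    stop("position ", cds_pos, " of ", gene$gene, " holds ", base, ", not C")
  }
  codon_index <- ((cds_pos - 1L) %/% 3L) + 1L
  codon_pos <- cds_pos - 3L * (codon_index - 1L)
  co_edits <- setdiff(as.integer(co_edits), cds_pos)
  codon_start <- 3L * (codon_index - 1L) + 1L
  if (length(co_edits)) {
    in_codon <- co_edits >= codon_start & co_edits <= codon_start + 2L
    if (!all(in_codon))
      stop("co_edit position(s) outside codon ", codon_index, ": ",
           paste(co_edits[!in_codon], collapse = ", "))
  }
  genomic_codon <- substr(gene$cds, codon_start, codon_start + 2L)
  edited_codon <- apply_edits(genomic_codon,
                              c(cds_pos, co_edits) - codon_start + 1L)
  aa_before <- translate_codon(genomic_codon)
  aa_after <- translate_codon(edited_codon)
  if (is.na(aa_before) || is.na(aa_after))
    stop("codon ", codon_index, " of ", gene$gene,
         " contains ambiguous bases; cannot translate")
  data.frame(
    gene = gene$gene, cds_pos = cds_pos, codon_index = codon_index,
    codon_pos = codon_pos, genomic_codon = genomic_codon,
    edited_codon = edited_codon, aa_before = aa_before, aa_after = aa_after,
    silent = aa_before == aa_after,
    creates_start = codon_index == 1L && edited_codon == "ATG" &&
      genomic_codon != "ATG",
    creates_stop = aa_after == "*" && aa_before != "*",
    label = paste0(gene$gene, "eU", cds_pos, aa_before, aa_after),
    stringsAsFactors = FALSE)
}

#' Exhaustive codon effect table for single C-to-U edits
#'
#' Enumerates, over all 64 codons and every codon position holding `C`, the
#' amino acid before and after a single C-to-U edit at that position, and
#' whether the edit is silent. Used to reason about alternative codon
#' changes reachable at one orthologous site (e.g. PL, SL, SF).
#'
#' @return Data frame with columns `codon`, `codon_pos`, `aa_before`,
#'   `aa_after`, `silent`; one row per (codon, C position) pair.
#' @export
codon_effect_table <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  out <- list()
  for (codon in codons) {
    for (p in 1:3) {
      if (substr(codon, p, p) != "C") next
      edited <- codon
      substr(edited, p, p) <- "T"
      a <- translate_codon(codon)
      b <- translate_codon(edited)
      out[[length(out) + 1L]] <- data.frame(
        codon = codon, codon_pos = p, aa_before = a, aa_after = b,
        silent = a == b, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Label and characterize a set of edited positions of one gene
#'
#' Convenience wrapper: characterizes every position in `positions`, passing
#' the other edited positions of the same codon as co-edits (the joint
#' mRNA-level consequence).
#'
#' @param gene A [gene_sequence()].
#' @param positions Integer vector of edited CDS positions.
#' @return Data frame, one row per position (see [characterize_edit()]),
#'   with an extra logical column `co_edited`.
#' @export
characterize_edits <- function(gene, positions) {
  positions <- sort(unique(as.integer(positions)))
  if (!length(positions)) {
    out <- empty_sites_df()
    out$cds_pos <- integer()
    out$co_edited <- logical()
    return(out[, c(setdiff(names(out), "co_edited"), "co_edited")])
  }
  codon_of <- ((positions - 1L) %/% 3L) + 1L
  rows <- lapply(seq_along(positions), function(i) {
    mates <- positions[codon_of == codon_of[i] & positions != positions[i]]
    row <- characterize_edit(gene, positions[i], co_edits = mates)
    row$co_edited <- length(mates) > 0L
    row
  })
  do.call(rbind, rows)
}
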