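#' Construct a GeneSequence
#'
#' A `GeneSequence` holds one in-frame protein-coding sequence (CDS) for one
#' gene in one species, stored in the DNA alphabet (any `U` is converted to
#' `T` on input). Position 1 is the first base of the annotated start codon.
#'
#' @param species_id Non-empty species identifier (e.g. `"Amborella_trichopoda"`).
#' @param gene Non-empty gene name (e.g. `"ndhD"`).
#' @param cds Character scalar over `A`, `C`, `G`, `T`, `N` (case-insensitive;
#'   `U` accepted and stored as `T`).
#' @param complete Logical; `TRUE` when the CDS starts at codon 1 and its
#'   length is divisible by 3. Defaults to `nchar(cds) %% 3 == 0`.
#' @return An object of class `GeneSequence`.
#' @export
gene_sequence <- function(species_id, gene, cds, complete = NULL) {
  if (!is.character(species_id) || length(species_id) != 1L || !nzchar(species_id))
    stop("'species_id' must be a non-empty string")
  if (!is.character(gene) || length(gene) != 1L || !nzchar(gene))
    stop("'gene' must be a non-empty string")
  if (!is.character(cds) || length(cds) != 1L || !nzchar(cds))
    stop("'cds' must be a non-empty DNA string")
  cds <- chartr("u", "t", cds)
  cds <- toupper(cds)
  cds <- chartr("U", "T", cds)
  bad <- gsub("[ACGTN]", "", cds)
  if (nzchar(bad))
    stop("'cds' contains non-DNA characters: ", substr(bad, 1L, 10L))
  if (is.null(complete)) complete <- (nchar(cds) %% 3L == 0L)
  if (complete && nchar(cds) %% 3L != 0L)
    stop("a complete CDS must have length divisible by 3 (", gene, ": ",
         nchar(cds), " nt)")
  structure(
    list(species_id = species_id, gene = gene, cds = cds,
         complete = isTRUE(complete)),
    class = "GeneSequence")
}

#' @export
print.GeneSequence <- function(x, ...) {
  cat(sprintf("GeneSequence %s|%s: %d nt%s\n", x$species_id, x$gene,
              nchar(x$cds), if (x$complete) "" else " (incomplete)"))
  invisible(x)
}

#' Construct an Editome
#'
#' An `Editome` is the set of C-to-U editing sites of one species, keyed by
#' `(gene, cds_pos)`. It is stored as a data frame with one row per site and
#' the columns of [characterize_edit()] plus `species_id`.
#'
#' @param species_id Species identifier.
#' @param sites A data frame of editing sites (zero rows allowed) with at
#'   least columns `gene` and `cds_pos`; usually rows produced by
#'   [characterize_edit()].
#' @return An object of class `Editome` (a data frame).
#' @export
editome <- function(species_id, sites = NULL) {
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- empty_sites_df()
  } else {
    sites <- as.data.frame(sites, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "cds_pos") %in% names(sites)))
    key <- paste(sites$gene, sites$cds_pos)
    if (anyDuplicated(key))
      stop("duplicate editing site(s): ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    sites <- sites[order(sites$gene, sites$cds_pos), , drop = FALSE]
    rownames(sites) <- NULL
  }
  attr(sites, "species_id") <- species_id
  class(sites) <- c("Editome", "data.frame")
  sites
}

empty_sites_df <- function() {
  data.frame(gene = character(), cds_pos = integer(), codon_index = integer(),
             codon_pos = integer(), genomic_codon = character(),
             edited_codon = character(), aa_before = character(),
             aa_after = character(), silent = logical(),
             creates_start = logical(), creates_stop = logical(),
             label = character(), stringsAsFactors = FALSE)
}

#' @export
print.Editome <- function(x, ...) {
  cat(sprintf("Editome of %s: %d site(s)\n", attr(x, "species_id"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Construct a ReferenceEditome
#'
#' A reference editome couples one genomic CDS per gene with the species'
#' editing sites; its derived edited mRNA per gene is the CDS with all site
#' positions converted C to T. Every site position must hold `C` in the
#' genomic CDS.
#'
#' @param genes Named list of [gene_sequence()] objects (names = gene).
#' @param sites An [editome()] for the same species.
#' @return An object of class `ReferenceEditome`.
#' @export
reference_editome <- function(genes, sites) {
  stopifnot(is.list(genes), length(genes) > 0L)
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    names(genes) <- vapply(genes, function(g) g$gene, character(1))
  for (g in genes) stopifnot(inherits(g, "GeneSequence"))
  stopifnot(inherits(sites, "Editome"))
  sp <- attr(sites, "species_id")
  for (i in seq_len(nrow(sites))) {
    gname <- sites$gene[i]
    if (!gname %in% names(genes)) next  # sites for genes without sequence are tolerated but unusable
    base <- substr(genes[[gname]]$cds, sites$cds_pos[i], sites$cds_pos[i])
    if (base != "C")
      stop("editing site ", gname, " position ", sites$cds_pos[i],
           " does not hold C in the genomic CDS of ", sp, " (found ", base, ")")
  }
  structure(list(species_id = sp, genes = genes, sites = sites),
            class = "ReferenceEditome")
}

#' Edited mRNA (as DNA) of one gene of a reference editome
#'
#' @param ref A [reference_editome()].
#' @param gene Gene name present in `ref$genes`.
#' @return Character scalar: the CDS with all editing-site positions C->T.
#' @export
edited_cds <- function(ref, gene) {
  stopifnot(inherits(ref, "ReferenceEditome"), gene %in% names(ref$genes))
  pos <- ref$sites$cds_pos[ref$sites$gene == gene]
  apply_edits(ref$genes[[gene]]$cds, pos)
}

#' Construct a PPR repeat array
#'
#' PLS-type PPR proteins bind RNA with one nucleotide per repeat. Each repeat
#' carries the key residues at its positions 3 and 6, plus its own first
#' residue (position 1), which acts as position 1' of the *preceding* repeat.
#'
#' @param protein_id Identifier of the protein (e.g. `"CRR28"`).
#' @param repeats Data frame with columns `index` (1-based order), `type`
#'   (one of `"P"`, `"L"`, `"S"`), `res1`, `res3`, `res6` (single uppercase
#'   amino-acid letters or `"-"`).
#' @param tail_domains Character vector, subset of `c("E1","E2","DYW")`.
#' @param tail_res1 First residue of the domain following the last repeat
#'   (used as that repeat's position 1'), or `"-"` if unknown.
#' @return An object of class `PPRArray`.
#' @export
ppr_array <- function(protein_id, repeats, tail_domains = character(),
                      tail_res1 = "-") {
  repeats <- as.data.frame(repeats, stringsAsFactors = FALSE)
  need <- c("index", "type", "res1", "res3", "res6")
  if (!all(need %in% names(repeats)))
    stop("'repeats' must have columns ", paste(need, collapse = ", "))
  stopifnot(nrow(repeats) >= 1L)
  repeats <- repeats[order(repeats$index), , drop = FALSE]
  rownames(repeats) <- NULL
  if (!all(repeats$type %in% c("P", "L", "S")))
    stop("repeat types must be P, L or S")
  for (col in c("res1", "res3", "res6")) {
    ok <- grepl("^[A-Z-]$", repeats[[col]])
    if (!all(ok)) stop("column '", col, "' must hold single uppercase ",
                       "residues or '-'")
  }
  stopifnot(all(tail_domains %in% c("E1", "E2", "DYW")))
  structure(list(protein_id = protein_id, repeats = repeats,
                 tail_domains = tail_domains, tail_res1 = tail_res1),
            class = "PPRArray")
}

#' Construct a target window around an editing site
#'
#' The window covers contiguous offsets relative to the edited cytidine at
#' offset 0; the base at offset 0 must be `C`.
#'
#' @param site_label Label of the editing site the window belongs to.
#' @param sequence RNA or DNA string (stored as DNA).
#' @param offset_of_first_base Integer offset of the first base of
#'   `sequence`; usually negative (upstream).
#' @return An object of class `TargetWindow`.
#' @export
target_window <- function(site_label, sequence, offset_of_first_base) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- chartr("uU", "tT", sequence)
  sequence <- toupper(sequence)
  offs <- seq(offset_of_first_base, length.out = nchar(sequence))
  if (!0L %in% offs)
    stop("window must cover offset 0 (the edited C)")
  if (substr(sequence, which(offs == 0L), which(offs == 0L)) != "C")
    stop("base at offset 0 must be C")
  structure(list(site_label = site_label, sequence = sequence,
                 offset_of_first_base = as.integer(offset_of_first_base)),
            class = "TargetWindow")
}

#' Base of a target window at a given offset
#' @param window A [target_window()].
#' @param offset Integer offset (0 = edited C).
#' @return Single character, or `NA` if outside the window.
#' @export
window_base <- function(window, offset) {
  i <- offset - window$offset_of_first_base + 1L
  if (i < 1L || i > nchar(window$sequence)) return(NA_character_)
  substr(window$sequence, i, i)
}

#' Construct a presence/absence matrix of binary characters over taxa
#'
#' @param characters Character vector of character names (editing-site labels
#'   or factor gene names).
#' @param taxa Character vector of taxon names.
#' @param state Character matrix `characters x taxa` with entries
#'   `"PRESENT"`, `"ABSENT"` or `"UNKNOWN"`.
#' @return An object of class `PresenceMatrix` (a character matrix).
#' @export
presence_matrix <- function(characters, taxa, state) {
  state <- as.matrix(state)
  stopifnot(nrow(state) == length(characters), ncol(state) == length(taxa))
  if (!all(state %in% c("PRESENT", "ABSENT", "UNKNOWN")))
    stop("states must be PRESENT, ABSENT or UNKNOWN")
  dimnames(state) <- list(characters, taxa)
  class(state) <- c("PresenceMatrix", class(state))
  state
}
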