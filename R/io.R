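# Readers and writers for the plain-text formats the pipeline touches:
# CDS FASTA (headers "species|gene"), editome TSV, presence/state TSV, Newick.

#' Read in-frame CDSs from a FASTA file
#'
#' Headers must follow the convention `species|gene` (anything after a space
#' is ignored). Sequences are uppercased and `U` is converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @return List of [gene_sequence()] objects.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  headers <- sub("[ \t].*$", "", names(seqs))
  bad <- headers[!grepl("^[^|]+\\|[^|]+$", headers)]
  if (length(bad))
    stop("FASTA header(s) not of the form 'species|gene': ",
         paste(bad, collapse = ", "))
  lapply(seq_along(seqs), function(i) {
    parts <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    gene_sequence(parts[1], parts[2], as.character(seqs[[i]]))
  })
}

#' Write GeneSequences to a FASTA file
#' @param genes List of [gene_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  lines <- unlist(lapply(genes, function(g)
    c(paste0(">", g$species_id, "|", g$gene), g$cds)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an editome table
#'
#' The TSV must have columns `species`, `gene`, `cds_pos` (and optionally
#' `label`, which is checked against the recomputed label). Each site is
#' completed (codons, amino acids, flags, label) from the corresponding
#' CDS via [characterize_edit()]; edited positions sharing a codon are
#' treated as co-edits.
#'
#' @param path Path to the TSV.
#' @param genes Named list of [gene_sequence()] objects (names = gene) for
#'   the species of the table.
#' @return An [editome()].
#' @export
read_editome_table <- function(path, genes) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "gene", "cds_pos")
  if (!all(need %in% names(tab)))
    stop("editome table must have columns ", paste(need, collapse = ", "))
  if (length(unique(tab$species)) > 1L)
    stop("editome table mixes species: ",
         paste(unique(tab$species), collapse = ", "))
  key <- paste(tab$gene, tab$cds_pos)
  if (anyDuplicated(key))
    stop("duplicate editing site row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, function(g) g$gene, character(1))
  rows <- lapply(unique(tab$gene), function(gname) {
    if (!gname %in% names(genes))
      stop("no CDS provided for gene ", gname)
    characterize_edits(genes[[gname]], tab$cds_pos[tab$gene == gname])
  })
  sites <- do.call(rbind, rows)
  if ("label" %in% names(tab) && any(nzchar(tab$label))) {
    m <- match(paste(sites$gene, sites$cds_pos), paste(tab$gene, tab$cds_pos))
    given <- tab$label[m]
    mismatch <- nzchar(given) & !is.na(given) & given != sites$label
    if (any(mismatch))
      warning("label(s) in table differ from recomputed label(s): ",
              paste(given[mismatch], "vs", sites$label[mismatch],
                    collapse = "; "))
  }
  editome(tab$species[1], sites)
}

#' Write an editome as TSV
#' @param ed An [editome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_editome_table <- function(ed, path) {
  stopifnot(inherits(ed, "Editome"))
  out <- cbind(species = rep(attr(ed, "species_id"), nrow(ed)),
               as.data.frame(ed))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree, rooted, with unique tip labels.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in ", path)
  if (!ape::is.rooted(tree))
    stop("tree in ", path, " is not rooted")
  tree
}

#' Write a tree to a Newick file
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a presence/absence table into a PresenceMatrix
#'
#' Long-format TSV with columns `taxon`, `character`, `state` (PRESENT /
#' ABSENT / UNKNOWN); an optional `reason` column is ignored by all
#' downstream counters. Missing (taxon, character) combinations become
#' UNKNOWN.
#'
#' @param path Path to the TSV.
#' @return A [presence_matrix()].
#' @export
read_presence_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("taxon", "character", "state")
  if (!all(need %in% names(tab)))
    stop("presence table must have columns ", paste(need, collapse = ", "))
  chars <- unique(tab$character)
  taxa <- unique(tab$taxon)
  m <- matrix("UNKNOWN", length(chars), length(taxa),
              dimnames = list(chars, taxa))
  m[cbind(match(tab$character, chars), match(tab$taxon, taxa))] <-
    toupper(tab$state)
  presence_matrix(chars, taxa, m)
}

#' Write a matrix (state or presence) as TSV
#' @param m A matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(row = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PPR repeat annotation table
#'
#' TSV with columns `index`, `type` (P/L/S), `res1`, `res3`, `res6`;
#' position 1' of repeat i is derived as res1 of repeat i+1.
#'
#' @param path Path to the TSV.
#' @param protein_id Protein identifier; default: file name without extension.
#' @param tail_res1 First residue of the E domain following the final
#'   repeat (`"-"` if unknown).
#' @param tail_domains Carboxyterminal domains present.
#' @return A [ppr_array()].
#' @export
read_ppr_table <- function(path, protein_id = NULL, tail_res1 = "-",
                           tail_domains = character()) {
  # residue columns must stay character ("F" would otherwise become FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  tab$index <- as.integer(tab$index)
  if (is.null(protein_id))
    protein_id <- tools::file_path_sans_ext(basename(path))
  ppr_array(protein_id, tab, tail_domains = tail_domains,
            tail_res1 = tail_res1)
}
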