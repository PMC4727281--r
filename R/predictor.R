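# Reference-based prediction of C-to-U editing sites by codon restoration:
# a candidate edit in the query is supported by a reference when it converts
# the query amino acid into the reference's EDITED-mRNA amino acid at the
# aligned position (references contribute their edited, i.e. conserved,
# protein; an edit that is silent at protein level can never gain support).

#' Globally align two protein sequences
#'
#' Global alignment with free end gaps, BLOSUM62 and affine gap penalties
#' (opening 10, extension 1). Returns the score and the residue-level map
#' from the first onto the second sequence.
#'
#' @param query_aa,ref_aa Protein strings (may contain `*`).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param matrix Name of the substitution matrix (default `"BLOSUM62"`).
#' @return List with `score`, `map` (integer vector of length
#'   `nchar(query_aa)`: position in `ref_aa` or `NA` where the query residue
#'   is unaligned or faces a gap), and `identity` (percent).
#' @export
align_proteins <- function(query_aa, ref_aa, gap_opening = 10,
                           gap_extension = 1, matrix = "BLOSUM62") {
  if (!nzchar(query_aa) || !nzchar(ref_aa))
    stop("cannot align empty protein sequence(s)")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(ref_aa),
    substitutionMatrix = matrix, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "overlap")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  si <- Biostrings::start(Biostrings::subject(pa)) - 1L
  map <- rep(NA_integer_, nchar(query_aa))
  for (k in seq_along(ap)) {
    pgap <- ap[k] == "-"
    sgap <- as[k] == "-"
    if (!pgap) qi <- qi + 1L
    if (!sgap) si <- si + 1L
    if (!pgap && !sgap) map[qi] <- si
  }
  list(score = Biostrings::score(pa), map = map,
       identity = Biostrings::pid(pa))
}

translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)  # drop the terminal stop, keep internal ones
}

# Enumerate, for one query gene against one reference, the per-candidate
# support: for every C of the query, is the (single or codon-joint) edit
# supported by this reference, and does the reference's alignment cover the
# codon at all.
support_one_ref <- function(query, ref, gap_opening, gap_extension) {
  gene <- query$gene
  ref_aa <- translate_cds(edited_cds(ref, gene))
  query_aa <- translate_cds(query$cds)
  aln <- align_proteins(query_aa, ref_aa, gap_opening, gap_extension)
  ref_res <- strsplit(ref_aa, "")[[1]]
  chars <- strsplit(query$cds, "", fixed = TRUE)[[1]]
  n_codon <- nchar(query_aa)
  out <- list()
  for (ci in seq_len(n_codon)) {
    start <- 3L * (ci - 1L) + 1L
    cpos <- start:(start + 2L)
    cpos <- cpos[chars[cpos] == "C"]
    if (!length(cpos)) next
    j <- aln$map[ci]
    covered <- !is.na(j)
    codon <- substr(query$cds, start, start + 2L)
    g_aa <- translate_codon(codon)
    r_aa <- if (covered) ref_res[j] else NA_character_
    single_hit <- logical(length(cpos))
    if (covered && !is.na(g_aa) && r_aa != g_aa) {
      for (k in seq_along(cpos)) {
        ec <- codon
        substr(ec, cpos[k] - start + 1L, cpos[k] - start + 1L) <- "T"
        single_hit[k] <- identical(translate_codon(ec), r_aa)
      }
      joint_hit <- FALSE
      if (!any(single_hit) && length(cpos) > 1L) {
        ec <- codon
        for (p in cpos - start + 1L) substr(ec, p, p) <- "T"
        joint_hit <- identical(translate_codon(ec), r_aa)
      }
      support <- if (any(single_hit)) single_hit else
        rep(joint_hit, length(cpos))
      route <- if (any(single_hit)) "single" else "joint"
    } else {
      support <- rep(FALSE, length(cpos))
      route <- "single"
    }
    out[[length(out) + 1L]] <- data.frame(
      cds_pos = cpos, codon_index = ci, covered = covered,
      support = support,
      route = ifelse(support, route, "single"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

candidate_table <- function(query, panel, gap_opening, gap_extension) {
  stopifnot(inherits(query, "GeneSequence"))
  if (!length(panel)) stop("reference panel is empty")
  has_gene <- vapply(panel, function(r) query$gene %in% names(r$genes),
                     logical(1))
  if (!any(has_gene))
    stop("no reference coverage: gene ", query$gene,
         " absent from every panel member")
  skipped <- vapply(panel[!has_gene], function(r) r$species_id, character(1))
  per_ref <- lapply(panel[has_gene], function(r)
    cbind(support_one_ref(query, r, gap_opening, gap_extension),
          ref = r$species_id))
  tab <- do.call(rbind, per_ref)
  agg <- split(tab, tab$cds_pos)
  cand <- do.call(rbind, lapply(agg, function(d) data.frame(
    cds_pos = d$cds_pos[1], codon_index = d$codon_index[1],
    support_count = sum(d$support),
    covered_count = sum(d$covered),
    joint = any(d$route == "joint" & d$support),
    supporting_refs = paste(sort(d$ref[d$support]), collapse = ","),
    stringsAsFactors = FALSE)))
  cand <- cand[order(cand$cds_pos), , drop = FALSE]
  cand$support_fraction <- ifelse(cand$covered_count > 0,
                                  100 * cand$support_count / cand$covered_count,
                                  0)
  rownames(cand) <- NULL
  attr(cand, "skipped_refs") <- unname(skipped)
  cand
}

#' Predict C-to-U editing sites in a query CDS
#'
#' For every cytidine of the (complete, in-frame) query CDS, the candidate
#' C-to-U edit is put to a vote across a panel of reference editomes: a
#' reference supports the candidate when the edited query amino acid equals
#' the reference's edited-mRNA amino acid at the aligned position while the
#' unedited query amino acid differs from it. When no single edit of a codon
#' can reach the reference residue but the joint edit of all its cytidines
#' can, each contributing cytidine receives the joint support. A prediction
#' is emitted when at least `min_count` references support it and they make
#' up at least `min_fraction` percent of the references whose alignment
#' covers the codon (gapped or unaligned references are not counted as
#' covered). Silent candidates can never gain support and are never emitted.
#'
#' @param query A complete [gene_sequence()].
#' @param panel List of [reference_editome()] objects; members lacking the
#'   query's gene are skipped and reported in the `skipped_refs` attribute.
#' @param min_count Minimum absolute number of supporting references
#'   (default 8).
#' @param min_fraction Minimum percent of covering references that must
#'   support (default 70).
#' @param gap_opening,gap_extension Alignment gap penalties (see
#'   [align_proteins()]).
#' @return Data frame of predictions: the [characterize_edit()] columns plus
#'   `support_count`, `covered_count`, `support_fraction` (percent) and
#'   `supporting_refs`. Attributes: `candidates` (the full pre-threshold
#'   candidate table used by [confront()] and [threshold_sweep()]),
#'   `skipped_refs`, `params`.
#' @export
predict_sites <- function(query, panel, min_count = 8, min_fraction = 70,
                          gap_opening = 10, gap_extension = 1) {
  if (!query$complete)
    stop("query CDS must be complete (in frame, starting at codon 1)")
  cand <- candidate_table(query, panel, gap_opening, gap_extension)
  keep <- cand$support_count >= min_count &
    cand$support_fraction >= min_fraction
  hits <- cand[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    mates <- hits$cds_pos[hits$codon_index == hits$codon_index[i] &
                            hits$cds_pos != hits$cds_pos[i] & hits$joint]
    co <- if (hits$joint[i]) mates else integer()
    site <- characterize_edit(query, hits$cds_pos[i], co_edits = co)
    cbind(site, hits[i, c("support_count", "covered_count",
                          "support_fraction", "supporting_refs")])
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    s <- empty_sites_df()
    cbind(s, data.frame(support_count = integer(), covered_count = integer(),
                        support_fraction = numeric(),
                        supporting_refs = character()))
  }
  rownames(out) <- NULL
  attr(out, "candidates") <- cand
  attr(out, "skipped_refs") <- attr(cand, "skipped_refs")
  attr(out, "params") <- list(min_count = min_count,
                              min_fraction = min_fraction,
                              gap_opening = gap_opening,
                              gap_extension = gap_extension)
  out
}

#' Prediction counts across a range of support-fraction thresholds
#'
#' @param query,panel,min_count,... As in [predict_sites()].
#' @param fractions Numeric vector of percent thresholds in (0, 100].
#' @return Data frame with columns `fraction` and `n_predicted`; counts are
#'   non-increasing as the fraction increases.
#' @export
threshold_sweep <- function(query, panel, fractions = c(70, 80, 90),
                            min_count = 8, ...) {
  stopifnot(all(fractions > 0 & fractions <= 100))
  pred <- predict_sites(query, panel, min_count = min_count,
                        min_fraction = min(fractions), ...)
  cand <- attr(pred, "candidates")
  n <- vapply(fractions, function(f)
    sum(cand$support_count >= min_count & cand$support_fraction >= f),
    integer(1))
  data.frame(fraction = fractions, n_predicted = n)
}

#' Confront predictions with an observed editome
#'
#' Partitions the union of predicted and observed sites of one gene into
#' confirmed-and-predicted, confirmed-but-unpredicted (sub-classified as
#' `silent`, `below_threshold` — some reference support but under the
#' thresholds — or `orphan` — no reference support at all), and
#' predicted-but-unconfirmed.
#'
#' @param predictions Result of [predict_sites()].
#' @param observed An [editome()] (or data frame of sites) for the same gene.
#' @return List of class `Confrontation` with elements `confirmed_predicted`,
#'   `confirmed_unpredicted` (with a `class` column), `predicted_unconfirmed`.
#' @export
confront <- function(predictions, observed) {
  cand <- attr(predictions, "candidates")
  params <- attr(predictions, "params")
  obs <- as.data.frame(observed)
  pred_key <- paste(predictions$gene, predictions$cds_pos)
  obs_key <- paste(obs$gene, obs$cds_pos)
  conf_pred <- obs[obs_key %in% pred_key, , drop = FALSE]
  conf_unpred <- obs[!obs_key %in% pred_key, , drop = FALSE]
  if (nrow(conf_unpred)) {
    sup <- cand$support_count[match(conf_unpred$cds_pos, cand$cds_pos)]
    sup[is.na(sup)] <- 0L
    conf_unpred$class <- ifelse(isTRUE_vec(conf_unpred$silent), "silent",
                                ifelse(sup > 0L, "below_threshold", "orphan"))
  } else conf_unpred$class <- character(0)
  pred_unconf <- predictions[!pred_key %in% obs_key, , drop = FALSE]
  structure(list(confirmed_predicted = conf_pred,
                 confirmed_unpredicted = conf_unpred,
                 predicted_unconfirmed = pred_unconf,
                 params = params),
            class = "Confrontation")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.Confrontation <- function(x, ...) {
  cat("Confrontation of predictions with observed editing:\n",
      sprintf("  confirmed & predicted:   %d\n", nrow(x$confirmed_predicted)),
      sprintf("  confirmed, unpredicted:  %d (%s)\n",
              nrow(x$confirmed_unpredicted),
              if (nrow(x$confirmed_unpredicted))
                paste(names(table(x$confirmed_unpredicted$class)),
                      table(x$confirmed_unpredicted$class),
                      sep = "=", collapse = ", ") else "-"),
      sprintf("  predicted, unconfirmed:  %d\n",
              nrow(x$predicted_unconfirmed)), sep = "")
  invisible(x)
}
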