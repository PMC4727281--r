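# PPR-RNA recognition: key residues at repeat positions 6 and 1' (the first
# residue of the following repeat) select the bound nucleotide under the
# core code T+N:A, N+N:C, T+D:G, N+D:U. The array is anchored with its
# terminal S-type repeat on nucleotide -4 upstream of the edited cytidine;
# each repeat binds one nucleotide, one position per repeat moving upstream.

CORE_CODE <- data.frame(
  res6 = c("T", "N", "T", "N"),
  res1prime = c("N", "N", "D", "D"),
  nt = c("A", "C", "G", "T"),  # T stands for U on the RNA level
  stringsAsFactors = FALSE)

#' Derive per-repeat key-residue combinations of a PPR array
#'
#' Position 1' of repeat *i* is the first residue (position 1) of repeat
#' *i + 1*; the terminal repeat takes it from the first residue of the
#' following E domain when available, otherwise a gap. (So the terminal
#' S-type repeat contributes position 1' to the preceding repeat.)
#'
#' @param array A [ppr_array()] with at least two repeats.
#' @return Data frame with columns `index`, `type`, `res3`, `res6`,
#'   `res1prime`.
#' @export
derive_combinations <- function(array) {
  stopifnot(inherits(array, "PPRArray"))
  rp <- array$repeats
  if (nrow(rp) < 2L)
    stop("PPR array must have at least two repeats to derive 1' residues")
  res1prime <- c(rp$res1[-1L], array$tail_res1)
  data.frame(index = rp$index, type = rp$type, res3 = rp$res3,
             res6 = rp$res6, res1prime = res1prime,
             stringsAsFactors = FALSE)
}

#' Anchor a PPR array on a target window
#'
#' The terminal scored repeat sits over nucleotide offset -4 in front of the
#' edited cytidine; each earlier repeat binds the next nucleotide upstream,
#' so an array of n repeats covers offsets -(n + 3) .. -4 contiguously.
#'
#' @param array A [ppr_array()].
#' @param window A [target_window()] covering at least offsets
#'   `-(n_repeats + 3) .. 0`.
#' @param anchor Offset of the terminal repeat (default -4).
#' @return Data frame with columns `index`, `offset`, `nt` (the window base
#'   bound by each repeat).
#' @export
anchor_alignment <- function(array, window, anchor = -4L) {
  stopifnot(inherits(array, "PPRArray"), inherits(window, "TargetWindow"))
  n <- nrow(array$repeats)
  anchor <- as.integer(anchor)
  offsets <- anchor - (n - seq_len(n))  # repeat i at anchor - (n - i)
  need <- min(offsets)
  if (window$offset_of_first_base > need)
    stop("target window too short: needs to reach offset ", need,
         " but starts at ", window$offset_of_first_base)
  nt <- vapply(offsets, function(o) window_base(window, o), character(1))
  data.frame(index = array$repeats$index, offset = offsets, nt = nt,
             stringsAsFactors = FALSE)
}

#' Score one key-residue combination against a nucleotide
#'
#' `MATCH` when the (position 6, position 1') pair selects the nucleotide
#' under the core code (with serine accepted for threonine at position 6
#' when `st_equiv`). With `partial` enabled, a non-match still scores
#' `PARTIAL` when position 6 alone separates purines from pyrimidines in
#' agreement with the target: T (or S) at position 6 with a purine (A/G),
#' N with a pyrimidine (C/U). Everything else, including unrecognized
#' residue letters (warned about), is a `MISMATCH`.
#'
#' @param res6,res1prime Single residue letters (or `"-"`).
#' @param nucleotide One of `A`, `C`, `G`, `T`/`U`.
#' @param st_equiv Treat S as T at position 6.
#' @param partial Enable the purine/pyrimidine PARTIAL level.
#' @return `"MATCH"`, `"PARTIAL"` or `"MISMATCH"`.
#' @export
score_match <- function(res6, res1prime, nucleotide, st_equiv = FALSE,
                        partial = FALSE) {
  nt <- chartr("uU", "tT", toupper(nucleotide))
  if (!nt %in% c("A", "C", "G", "T"))
    stop("nucleotide must be one of A, C, G, U/T")
  r6 <- res6
  if (st_equiv && identical(r6, "S")) r6 <- "T"
  if (!r6 %in% c("T", "N", "-") || !res1prime %in% c("N", "D", "-")) {
    if (!grepl("^[A-Z-]$", res6) || !grepl("^[A-Z-]$", res1prime))
      warning("unrecognized residue letter(s): ", res6, "/", res1prime)
  }
  hit <- CORE_CODE$nt[CORE_CODE$res6 == r6 & CORE_CODE$res1prime == res1prime]
  if (length(hit) && hit == nt) return("MATCH")
  if (partial) {
    if (r6 == "T" && nt %in% c("A", "G")) return("PARTIAL")
    if (r6 == "N" && nt %in% c("C", "T")) return("PARTIAL")
  }
  "MISMATCH"
}

#' Score a full PPR array against its anchored target
#'
#' Anchors the array (terminal repeat at offset -4), derives the key-residue
#' combinations and scores each repeat against the nucleotide it binds.
#' P- and S-type repeats are scored; L-type repeats are reported with their
#' score but flagged non-canonical and excluded from the summary counts.
#'
#' @param array A [ppr_array()].
#' @param window A [target_window()].
#' @param st_equiv,partial Options passed to [score_match()].
#' @param anchor Offset of the terminal repeat (default -4).
#' @return List with `table` (per repeat: index, type, res3, res6,
#'   res1prime, offset, nt, score, canonical) and `summary` (MATCH /
#'   PARTIAL / MISMATCH counts over P- and S-type repeats).
#' @export
score_array <- function(array, window, st_equiv = FALSE, partial = FALSE,
                        anchor = -4L) {
  comb <- derive_combinations(array)
  pos <- anchor_alignment(array, window, anchor = anchor)
  stopifnot(identical(comb$index, pos$index))
  score <- mapply(score_match, comb$res6, comb$res1prime, pos$nt,
                  MoreArgs = list(st_equiv = st_equiv, partial = partial))
  tab <- cbind(comb, pos[, c("offset", "nt")],
               score = unname(score),
               canonical = comb$type %in% c("P", "S"))
  counts <- table(factor(tab$score[tab$canonical],
                         levels = c("MATCH", "PARTIAL", "MISMATCH")))
  list(table = tab, summary = as.integer(counts) |>
         stats::setNames(names(counts)))
}

#' Residue conservation profile across orthologous PPR arrays
#'
#' All arrays must share repeat count and typing. For each repeat and each
#' key position (3, 6, 1') the residue frequencies across arrays are
#' tabulated (the numeric basis of a sequence-logo display).
#'
#' @param arrays List of [ppr_array()] objects with identical architecture.
#' @return List with `frequencies` (data frame: repeat index, type,
#'   position, residue, freq; frequencies sum to 1 per repeat/position) and
#'   `consensus` (data frame: repeat index, type, res3, res6, res1prime of
#'   the most frequent residues).
#' @export
conservation_profile <- function(arrays) {
  stopifnot(length(arrays) >= 1L)
  combos <- lapply(arrays, derive_combinations)
  arch <- lapply(combos, function(cb) paste(cb$type, collapse = ""))
  if (length(unique(unlist(arch))) != 1L ||
      length(unique(vapply(combos, nrow, integer(1)))) != 1L)
    stop("arrays differ in repeat count or typing: ",
         paste(vapply(arrays, function(a) a$protein_id, character(1)),
               unlist(arch), sep = "=", collapse = ", "))
  n <- nrow(combos[[1]])
  freq_rows <- list()
  consensus <- combos[[1]][, c("index", "type")]
  cons_res <- matrix("", n, 3L,
                     dimnames = list(NULL, c("res3", "res6", "res1prime")))
  for (i in seq_len(n)) {
    for (posname in c("res3", "res6", "res1prime")) {
      res <- vapply(combos, function(cb) cb[[posname]][i], character(1))
      tab <- sort(table(res), decreasing = TRUE)
      freq_rows[[length(freq_rows) + 1L]] <- data.frame(
        index = combos[[1]]$index[i], type = combos[[1]]$type[i],
        position = sub("res", "", posname), residue = names(tab),
        freq = as.numeric(tab) / length(arrays), stringsAsFactors = FALSE)
      cons_res[i, posname] <- names(tab)[1]
    }
  }
  list(frequencies = do.call(rbind, freq_rows),
       consensus = cbind(consensus, as.data.frame(cons_res)))
}
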