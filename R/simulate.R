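# Generators with known ground truth: reference families with planted
# editing sites, rooted trees with loss-only character evolution, PPR arrays
# built to match (or miss) a target, and the hand-encoded ndhD editing-state
# matrix. All generators are deterministic under a fixed seed.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

# one fixed codon per amino acid (avoids C where possible so that planted
# sites are the only candidate edits gaining support)
BACK_CODON <- c(A="GCT", C="TGT", D="GAT", E="GAA", F="TTT", G="GGT",
                H="CAT", I="ATT", K="AAA", L="TTA", M="ATG", N="AAT",
                P="CCA", Q="CAA", R="AGA", S="AGT", T="ACT", V="GTT",
                W="TGG", Y="TAT")

#' Simulate a reference panel with planted editing sites
#'
#' Draws an ancestral protein, plants editing sites at distinct codons where
#' the conserved state requires U while the query genome carries C, and
#' derives `n_refs` reference editomes: each reference independently retains
#' the conserved (edited) state at a planted site with its per-site
#' conservation probability, otherwise it carries a random different
#' residue; all other codons are substituted i.i.d. at rate `divergence`
#' per reference. Silent sites (third-position synonymous C-to-U) can be
#' planted as well; they are invisible to codon-restoration prediction.
#'
#' @param n_refs Number of reference editomes (> 0).
#' @param gene_length_codons Gene length in codons.
#' @param n_sites Number of planted non-silent sites.
#' @param n_silent Number of planted silent sites.
#' @param per_site_conservation Scalar or vector (length `n_sites`) of
#'   per-site reference conservation probabilities in [0, 1].
#' @param divergence Per-codon amino-acid substitution probability in [0, 1).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param gene,species_prefix Naming of the synthetic gene and references.
#' @return List with `query` ([gene_sequence()]), `panel` (list of
#'   [reference_editome()]), `truth` ([editome()] of planted sites, with the
#'   `silent` column flagging silent plants).
#' @export
simulate_reference_family <- function(n_refs, gene_length_codons = 120,
                                      n_sites = 10, n_silent = 0,
                                      per_site_conservation = 1.0,
                                      divergence = 0.05, seed = 1,
                                      gene = "synth",
                                      species_prefix = "ref") {
  if (n_refs < 1L) stop("n_refs must be at least 1")
  if (any(per_site_conservation < 0 | per_site_conservation > 1))
    stop("per_site_conservation must lie in [0, 1]")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  n_planted <- n_sites + n_silent
  if (n_planted + 2L > gene_length_codons)
    stop("gene too short for the requested number of planted sites")
  cons <- rep(per_site_conservation, length.out = n_sites)
  set.seed(seed)
  anc_aa <- sample(AA20, gene_length_codons, replace = TRUE)
  anc_aa[1] <- "M"
  # codons 2..L-1 eligible for planting (start and stop stay untouched)
  planted <- sort(sample(2:(gene_length_codons - 1L), n_planted))
  site_codon <- planted[seq_len(n_sites)]
  silent_codon <- if (n_silent) planted[n_sites + seq_len(n_silent)] else
    integer()
  codons <- unname(BACK_CODON[anc_aa])
  # non-silent plants: conserved L encoded CTA, query genomic CCA (P -> L
  # at codon position 2)
  codons[site_codon] <- "CTA"
  anc_aa[site_codon] <- "L"
  # silent plants: serine TCC, edit at codon position 3 is synonymous (TCT)
  codons[silent_codon] <- "TCC"
  anc_aa[silent_codon] <- "S"
  query_codons <- codons
  query_codons[site_codon] <- "CCA"
  query <- gene_sequence("query", gene, paste(query_codons, collapse = ""))
  truth <- characterize_edits(
    query, c(3L * (site_codon - 1L) + 2L, 3L * silent_codon))
  truth <- editome("query", truth[, setdiff(names(truth), "co_edited")])
  panel <- vector("list", n_refs)
  for (r in seq_len(n_refs)) {
    ref_codons <- codons
    # divergence at unplanted codons (uniform over the other 19 residues)
    for (ci in setdiff(seq_len(gene_length_codons)[-1], planted)) {
      if (stats::runif(1) < divergence) {
        ref_codons[ci] <- BACK_CODON[[sample(setdiff(AA20, anc_aa[ci]), 1)]]
      }
    }
    edit_pos <- integer()
    for (k in seq_len(n_sites)) {
      ci <- site_codon[k]
      if (stats::runif(1) < cons[k]) {
        # reference shares the pre-edited genomic state and edits it
        ref_codons[ci] <- "CCA"
        edit_pos <- c(edit_pos, 3L * (ci - 1L) + 2L)
      } else {
        ref_codons[ci] <- BACK_CODON[[sample(setdiff(AA20, "L"), 1)]]
      }
    }
    for (ci in silent_codon) {
      ref_codons[ci] <- "TCC"
      edit_pos <- c(edit_pos, 3L * ci)
    }
    sp <- sprintf("%s%02d", species_prefix, r)
    g <- gene_sequence(sp, gene, paste(ref_codons, collapse = ""))
    sites <- characterize_edits(g, edit_pos)
    sites <- sites[, setdiff(names(sites), "co_edited")]
    genes <- list(g); names(genes) <- gene
    panel[[r]] <- reference_editome(genes, editome(sp, sites))
  }
  list(query = query, panel = panel, truth = truth)
}

#' Simulate loss-only character evolution on a random rooted tree
#'
#' Generates a random rooted bifurcating tree and evolves one or more
#' binary characters from a PRESENT root: each edge independently converts
#' PRESENT to ABSENT with probability `loss_prob_per_edge`; absence is
#' irreversible. The true loss events are the converting edges after
#' pruning conversions nested below an earlier loss.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param loss_prob_per_edge Probability in [0, 1).
#' @param seed Integer seed.
#' @param n_chars Number of independent characters.
#' @return List with `tree` (`ape::phylo`), `states`
#'   ([presence_matrix()], characters x taxa) and `true_losses` (per
#'   character, the number of effective loss events).
#' @export
simulate_tree_losses <- function(n_taxa, loss_prob_per_edge = 0.1, seed = 1,
                                 n_chars = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  if (loss_prob_per_edge < 0 || loss_prob_per_edge >= 1)
    stop("loss_prob_per_edge must lie in [0, 1)")
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = TRUE,
                     tip.label = sprintf("t%02d", seq_len(n_taxa)))
  kids <- children_of(tree)
  root <- ape::Ntip(tree) + 1L
  states <- matrix("PRESENT", n_chars, n_taxa,
                   dimnames = list(sprintf("char%02d", seq_len(n_chars)),
                                   tree$tip.label))
  true_losses <- integer(n_chars)
  for (ch in seq_len(n_chars)) {
    lost_edge <- stats::runif(nrow(tree$edge)) < loss_prob_per_edge
    node_state <- rep(TRUE, ape::Ntip(tree) + ape::Nnode(tree))  # TRUE=present
    n_events <- 0L
    # preorder: root to tips
    walk <- function(nd) {
      for (child in kids[[nd]]) {
        e <- which(tree$edge[, 1] == nd & tree$edge[, 2] == child)
        node_state[child] <<- node_state[nd]
        if (node_state[nd] && lost_edge[e]) {
          node_state[child] <<- FALSE
          n_events <<- n_events + 1L   # nested conversions are not counted
        }
        if (child > ape::Ntip(tree)) walk(child)
      }
    }
    walk(root)
    tips_absent <- !node_state[seq_len(ape::Ntip(tree))]
    states[ch, tree$tip.label[tips_absent]] <- "ABSENT"
    true_losses[ch] <- n_events
  }
  list(tree = tree,
       states = presence_matrix(rownames(states), colnames(states), states),
       true_losses = stats::setNames(true_losses, rownames(states)))
}

#' Simulate a PPR array matched to a target window
#'
#' For each nucleotide bound upstream of the edited cytidine (anchor -4),
#' emits the canonical code pair with probability `1 - noise_rate`, else a
#' random non-matching pair. L-type repeats can be planted at chosen
#' positions; the terminal repeat is always S-type.
#'
#' @param window A [target_window()] covering the repeat span.
#' @param n_repeats Number of repeats; default: as many as the window allows.
#' @param noise_rate Probability in [0, 1] of a non-matching pair.
#' @param l_positions Indices (1-based from the first repeat) typed L.
#' @param seed Integer seed.
#' @return List with `array` ([ppr_array()]) and `truth` (data frame:
#'   index, nt, planted_match).
#' @export
simulate_ppr_array <- function(window, n_repeats = NULL, noise_rate = 0,
                               l_positions = integer(), seed = 1) {
  stopifnot(inherits(window, "TargetWindow"))
  if (noise_rate < 0 || noise_rate > 1)
    stop("noise_rate must lie in [0, 1]")
  max_n <- -4L - window$offset_of_first_base + 1L
  if (max_n < 2L) stop("window too short for a two-repeat array")
  if (is.null(n_repeats)) n_repeats <- max_n
  if (n_repeats > max_n)
    stop("window supports at most ", max_n, " repeats")
  set.seed(seed)
  offsets <- -4L - (n_repeats - seq_len(n_repeats))
  nts <- vapply(offsets, function(o) window_base(window, o), character(1))
  types <- rep("P", n_repeats)
  types[intersect(l_positions, seq_len(n_repeats))] <- "L"
  types[n_repeats] <- "S"
  pair_for <- function(nt) {
    i <- match(nt, CORE_CODE$nt)
    c(CORE_CODE$res6[i], CORE_CODE$res1prime[i])
  }
  res6 <- character(n_repeats)
  res1p <- character(n_repeats)
  planted <- logical(n_repeats)
  for (i in seq_len(n_repeats)) {
    if (stats::runif(1) >= noise_rate) {
      p <- pair_for(nts[i]); planted[i] <- TRUE
    } else {
      repeat {
        p <- c(sample(c("T", "N", "V", "S"), 1), sample(c("N", "D", "P"), 1))
        hit <- CORE_CODE$nt[CORE_CODE$res6 == p[1] &
                              CORE_CODE$res1prime == p[2]]
        if (!length(hit) || hit != nts[i]) break
      }
    }
    res6[i] <- p[1]; res1p[i] <- p[2]
  }
  # res1' of repeat i lives on repeat i+1 (position 1); terminal from tail
  res1 <- c("-", res1p[-n_repeats])
  arr <- ppr_array("synthPPR",
                   data.frame(index = seq_len(n_repeats), type = types,
                              res1 = res1, res3 = rep("F", n_repeats),
                              res6 = res6, stringsAsFactors = FALSE),
                   tail_domains = c("E1", "E2"), tail_res1 = res1p[n_repeats])
  list(array = arr,
       truth = data.frame(index = seq_len(n_repeats), nt = nts,
                          planted_match = planted,
                          stringsAsFactors = FALSE))
}
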