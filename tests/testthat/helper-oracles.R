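# Independent oracles used by the tests. These reimplement small problems
# from first principles (exhaustive dynamic programming, exhaustive subset
# search) and stay independent of the package code paths they check.

# Exhaustive Gotoh dynamic programming for global protein alignment with
# free end gaps; affine gap of length L costs opening + L * extension.
oracle_align_score <- function(x, y, gap_opening = 10, gap_extension = 1) {
  sm <- get(utils::data("BLOSUM62", package = "Biostrings",
                        envir = environment()))
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  n <- length(xs); m <- length(ys)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # ends in a gap in y (x consumed)
  Iy <- matrix(NEG, n + 1, m + 1)  # ends in a gap in x (y consumed)
  M[1, 1] <- 0
  Ix[2:(n + 1), 1] <- 0  # free leading end gaps
  Iy[1, 2:(m + 1)] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[xs[i], ys[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_opening - gap_extension,
                              Ix[i, j + 1] - gap_extension)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_opening - gap_extension,
                              Iy[i + 1, j] - gap_extension)
    }
  }
  # free trailing end gaps: best score in the last row or column
  max(M[n + 1, ], Ix[n + 1, ], Iy[n + 1, ],
      M[, m + 1], Ix[, m + 1], Iy[, m + 1])
}

# Tips below every edge of an ape tree (list over edge rows).
tips_below_edges <- function(tree) {
  ntip <- ape::Ntip(tree)
  below <- function(nd) {
    if (nd <= ntip) return(nd)
    unlist(lapply(tree$edge[tree$edge[, 1] == nd, 2], below))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below(tree$edge[e, 2]))
}

# Exhaustive minimum over loss-edge subsets: the smallest number of edges,
# none of which has a PRESENT tip below it, that together cover every
# ABSENT tip. UNKNOWN tips constrain nothing.
oracle_dollo_min <- function(tree, states) {
  states <- states[tree$tip.label]
  absent <- which(states == "ABSENT")
  present <- which(states == "PRESENT")
  if (!length(absent)) return(0L)
  if (!length(present)) return(1L)  # single loss at the root explains all
  below <- tips_below_edges(tree)
  allowed <- which(vapply(below, function(tp) !any(tp %in% present),
                          logical(1)))
  for (k in seq_along(allowed)) {
    sets <- utils::combn(allowed, k, simplify = FALSE)
    for (s in sets) {
      covered <- unique(unlist(below[s]))
      if (all(absent %in% covered)) return(k)
    }
  }
  stop("no covering subset found (malformed input)")
}

# Small helper: a reference bundle holding one synthetic gene.
make_bundle <- function(species, gene, cds, edit_positions = integer()) {
  g <- gene_sequence(species, gene, cds)
  sites <- characterize_edits(g, edit_positions)
  sites <- sites[, setdiff(names(sites), "co_edited")]
  genes <- list(g)
  names(genes) <- gene
  reference_editome(genes, editome(species, sites))
}

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  back <- c(A="GCT", C="TGT", D="GAT", E="GAA", F="TTT", G="GGT", H="CAT",
            I="ATT", K="AAA", L="CTA", M="ATG", N="AAT", P="CCA", Q="CAA",
            R="CGT", S="TCA", T="ACT", V="GTT", W="TGG", Y="TAT")
  paste(c("ATG", back[sample(aa, n_codons - 1L, replace = TRUE)]),
        collapse = "")
}
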