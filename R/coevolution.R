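# Minimum independent losses of binary characters on a rooted cladogram
# under a loss-only (Dollo) model with presence at the root, and site-factor
# co-loss concordance. An ABSENT state covers both routes to absence
# (genomic C-to-T conversion, or loss of the gene altogether); UNKNOWN taxa
# impose no constraint.

as_state_vector <- function(states, taxa = NULL) {
  if (is.matrix(states)) stop("pass one character (a named vector), not a matrix")
  states <- toupper(states)
  if (is.null(names(states)) && !is.null(taxa)) names(states) <- taxa
  if (is.null(names(states))) stop("tip states must be named by taxon")
  if (!all(states %in% c("PRESENT", "ABSENT", "UNKNOWN")))
    stop("states must be PRESENT, ABSENT or UNKNOWN")
  states
}

# children list per internal node of an ape phylo tree
children_of <- function(tree) {
  n_node <- ape::Nnode(tree) + ape::Ntip(tree)
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

#' Minimum independent losses of a binary character on a rooted tree
#'
#' Counts the minimum number of loss-only events that explain the observed
#' tip states of one character, assuming presence at the root and forbidding
#' regains. Losses are placed as shallow as possible: one loss on the edge
#' above each maximal clade whose known tips are all ABSENT. UNKNOWN tips
#' impose no constraint (and are reported with the ancestral state).
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param states Named character vector (taxon -> PRESENT/ABSENT/UNKNOWN)
#'   covering every tip, or a row of a [presence_matrix()].
#' @param root_state `"PRESENT"` (default). `"ABSENT"` is only consistent
#'   when no tip is PRESENT (regain is forbidden) and then needs no loss.
#' @return List of class `LossReport`: `character` (attribute name if
#'   available), `n_losses`, `loss_edges` (data frame `parent`, `child`,
#'   with node labels where available), `absent_tips`, `unknown_tips`.
#' @export
dollo_losses <- function(tree, states, root_state = "PRESENT") {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  states <- as_state_vector(states)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("no state for tip(s): ", paste(missing, collapse = ", "))
  states <- states[tree$tip.label]
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  if (root_state == "ABSENT") {
    if (any(states == "PRESENT"))
      stop("root_state ABSENT is inconsistent with PRESENT tip(s): ",
           "regain is forbidden under the loss-only model")
    return(structure(list(character = attr(states, "character"),
                          n_losses = 0L,
                          loss_edges = data.frame(parent = character(),
                                                  child = character()),
                          absent_tips = names(states)[states == "ABSENT"],
                          unknown_tips = names(states)[states == "UNKNOWN"]),
                     class = "LossReport"))
  }
  kids <- children_of(tree)
  n_node <- length(kids)
  # postorder over nodes: all-known-tips-below-are-ABSENT, with >= 1 known tip
  all_absent <- rep(NA, n_node)
  has_known <- rep(NA, n_node)
  for (i in seq_len(ntip)) {
    has_known[i] <- states[i] != "UNKNOWN"
    all_absent[i] <- states[i] == "ABSENT"
  }
  # bottom-up passes: a node is ready once all its children are done
  todo <- setdiff(seq_len(n_node), seq_len(ntip))
  while (length(todo)) {
    progressed <- FALSE
    for (nd in todo) {
      ch <- kids[[nd]]
      if (any(is.na(all_absent[ch]))) next
      has_known[nd] <- any(has_known[ch])
      all_absent[nd] <- if (has_known[nd])
        all(!has_known[ch] | all_absent[ch]) else FALSE
      todo <- setdiff(todo, nd)
      progressed <- TRUE
    }
    if (!progressed) stop("malformed tree: cycle in edge table")
  }
  node_name <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    if (!is.null(tree$node.label) && nzchar(tree$node.label[nd - ntip]))
      return(tree$node.label[nd - ntip])
    paste0("node", nd)
  }
  losses <- list()
  if (isTRUE(all_absent[root])) {
    losses[[1L]] <- data.frame(parent = NA_character_,
                               child = node_name(root))
  } else {
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
      if (isTRUE(all_absent[c_]) && has_known[c_] && !isTRUE(all_absent[p]))
        losses[[length(losses) + 1L]] <- data.frame(
          parent = node_name(p), child = node_name(c_))
    }
  }
  loss_edges <- if (length(losses)) do.call(rbind, losses) else
    data.frame(parent = character(), child = character())
  structure(list(character = attr(states, "character"),
                 n_losses = nrow(loss_edges),
                 loss_edges = loss_edges,
                 absent_tips = names(states)[states == "ABSENT"],
                 unknown_tips = names(states)[states == "UNKNOWN"]),
            class = "LossReport")
}

#' @export
print.LossReport <- function(x, ...) {
  cat(sprintf("Dollo loss report: %d independent loss(es), %d ABSENT tip(s)\n",
              x$n_losses, length(x$absent_tips)))
  if (nrow(x$loss_edges)) print.data.frame(x$loss_edges)
  invisible(x)
}

#' Site-factor co-loss concordance
#'
#' Evaluates, per taxon, the retention rule for an editing specificity
#' factor: the factor is expected PRESENT if and only if at least one of its
#' target editing sites is PRESENT. Taxa violating the rule are listed with
#' the direction of the discordance.
#'
#' @param tree Rooted `ape::phylo` tree (taxa must be tips; used for
#'   validation and ordering).
#' @param site_columns Named list of target-site state vectors
#'   (taxon -> PRESENT/ABSENT/UNKNOWN), e.g. rows of a [presence_matrix()].
#' @param factor_column State vector for the factor gene over the same taxa.
#' @return List of class `ConcordanceReport`: `factor`, `targets`, `table`
#'   (per-taxon states plus `rule_predicted`), `discordant_taxa` (data frame
#'   `taxon`, `direction`).
#' @export
concordance <- function(tree, site_columns, factor_column) {
  stopifnot(is.list(site_columns), length(site_columns) >= 1L)
  taxa <- tree$tip.label
  fac <- as_state_vector(factor_column)
  cols <- lapply(site_columns, as_state_vector)
  for (col in c(cols, list(fac))) {
    missing <- setdiff(taxa, names(col))
    if (length(missing))
      stop("missing state for taxon/taxa: ", paste(missing, collapse = ", "))
  }
  site_states <- vapply(cols, function(col) col[taxa], character(length(taxa)))
  if (is.null(dim(site_states)))
    site_states <- matrix(site_states, ncol = length(cols),
                          dimnames = list(taxa, names(cols)))
  predicted <- apply(site_states, 1L, function(s) {
    if (any(s == "PRESENT")) "PRESENT"
    else if (any(s == "UNKNOWN")) "UNKNOWN"
    else "ABSENT"
  })
  fac <- fac[taxa]
  known <- fac != "UNKNOWN" & predicted != "UNKNOWN"
  disc <- which(known & fac != predicted)
  direction <- ifelse(fac[disc] == "PRESENT",
                      "factor retained though all targets lost",
                      "factor lost though a target persists")
  tab <- data.frame(taxon = taxa, site_states, factor = fac,
                    rule_predicted = predicted, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(factor = if (!is.null(attr(factor_column, "character")))
                   attr(factor_column, "character") else "factor",
                 targets = names(site_columns),
                 table = tab,
                 discordant_taxa = data.frame(taxon = taxa[disc],
                                              direction = direction,
                                              row.names = NULL)),
            class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf("Concordance of %s with target(s) %s: %d discordant taxa\n",
              x$factor, paste(x$targets, collapse = ", "),
              nrow(x$discordant_taxa)))
  if (nrow(x$discordant_taxa)) print.data.frame(x$discordant_taxa)
  invisible(x)
}

#' Extract one character of a PresenceMatrix as a named state vector
#' @param m A [presence_matrix()].
#' @param character Row name.
#' @return Named character vector with attribute `character`.
#' @export
presence_column <- function(m, character) {
  stopifnot(character %in% rownames(m))
  out <- stats::setNames(unclass(m)[character, ], colnames(m))
  attr(out, "character") <- character
  out
}
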