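# Cross-species editome comparison: orthologous site mapping through the
# protein alignment of edited translations, editing-state matrices in
# reference-species coordinates, and three-way editome partitions.
#
# States follow the editing-state legend: "ED" edited, "P" pre-edited
# (genomic T), "C" genomic C not (known to be) edited, any other letter is
# the amino acid actually encoded at the orthologous codon ("OTHER"),
# "ABSENT" when no orthologous position aligns.

species_bundle <- function(x) {
  if (inherits(x, "ReferenceEditome")) return(x)
  if (is.list(x) && length(x) == 2L &&
      inherits(x[[1]], "GeneSequence") && inherits(x[[2]], "Editome")) {
    genes <- list(x[[1]])
    names(genes) <- x[[1]]$gene
    return(reference_editome(genes, x[[2]]))
  }
  stop("expected a ReferenceEditome or a list(GeneSequence, Editome)")
}

# Codon-level map between two species for one gene, computed on the edited
# translations. Canonical orientation (lexicographic species order) makes
# the mapping symmetric by construction.
codon_map <- function(a, b, gene) {
  swap <- a$species_id > b$species_id
  x <- if (swap) b else a
  y <- if (swap) a else b
  aln <- align_proteins(translate_cds(edited_cds(x, gene)),
                        translate_cds(edited_cds(y, gene)))
  fwd <- aln$map
  if (!swap) return(fwd)
  rev_map <- rep(NA_integer_, nchar(translate_cds(edited_cds(a, gene))))
  ok <- which(!is.na(fwd))
  rev_map[fwd[ok]] <- ok
  rev_map
}

state_at <- function(bundle, gene, cds_pos) {
  seqs <- bundle$genes[[gene]]
  base <- substr(seqs$cds, cds_pos, cds_pos)
  is_site <- any(bundle$sites$gene == gene & bundle$sites$cds_pos == cds_pos)
  if (is_site) return("ED")
  if (base == "T") return("P")
  if (base == "C") return("C")
  ci <- ((cds_pos - 1L) %/% 3L) + 1L
  codon <- substr(seqs$cds, 3L * (ci - 1L) + 1L, 3L * ci)
  aa <- translate_codon(codon)
  if (is.na(aa)) "OTHER" else aa
}

#' Map orthologous editing sites between two species for one gene
#'
#' Sites are paired through the protein alignment of the two species' edited
#' translations, mapped back to codon coordinates; an orthologous site must
#' sit at the same codon position of the aligned codon. Unpaired sites are
#' reported with the partner's state at the orthologous position.
#'
#' @param a,b [reference_editome()] bundles (or `list(GeneSequence, Editome)`).
#' @param gene Gene name.
#' @return Data frame with columns `pos_a`, `label_a`, `state_a`, `pos_b`,
#'   `label_b`, `state_b`; one row per orthologous site (paired or not).
#'   The mapping is symmetric: swapping `a` and `b` transposes the rows.
#' @export
map_orthologous_sites <- function(a, b, gene) {
  a <- species_bundle(a); b <- species_bundle(b)
  empty <- data.frame(pos_a = integer(), label_a = character(),
                      state_a = character(), pos_b = integer(),
                      label_b = character(), state_b = character(),
                      stringsAsFactors = FALSE)
  sa <- a$sites[a$sites$gene == gene, , drop = FALSE]
  sb <- b$sites[b$sites$gene == gene, , drop = FALSE]
  if (!gene %in% names(a$genes) || !gene %in% names(b$genes)) {
    # gene missing on one side: every site is unpaired with state ABSENT
    rows <- rbind(
      if (nrow(sa)) data.frame(pos_a = sa$cds_pos, label_a = sa$label,
                               state_a = "ED", pos_b = NA_integer_,
                               label_b = NA_character_, state_b = "ABSENT"),
      if (nrow(sb)) data.frame(pos_a = NA_integer_, label_a = NA_character_,
                               state_a = "ABSENT", pos_b = sb$cds_pos,
                               label_b = sb$label, state_b = "ED"))
    return(if (is.null(rows)) empty else rows)
  }
  map_ab <- codon_map(a, b, gene)
  ok <- which(!is.na(map_ab))
  map_ba <- rep(NA_integer_, max(map_ab[ok], 0L,
                                 nchar(translate_cds(edited_cds(b, gene)))))
  map_ba[map_ab[ok]] <- ok
  project <- function(pos, map) {
    ci <- ((pos - 1L) %/% 3L) + 1L
    cp <- pos - 3L * (ci - 1L)
    cj <- if (ci <= length(map)) map[ci] else NA_integer_
    if (is.na(cj)) NA_integer_ else 3L * (cj - 1L) + cp
  }
  rows <- list()
  for (i in seq_len(nrow(sa))) {
    pb <- project(sa$cds_pos[i], map_ab)
    if (is.na(pb) || pb > nchar(b$genes[[gene]]$cds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pos_a = sa$cds_pos[i], label_a = sa$label[i], state_a = "ED",
        pos_b = NA_integer_, label_b = NA_character_, state_b = "ABSENT")
      next
    }
    j <- which(sb$cds_pos == pb)
    rows[[length(rows) + 1L]] <- data.frame(
      pos_a = sa$cds_pos[i], label_a = sa$label[i], state_a = "ED",
      pos_b = pb,
      label_b = if (length(j)) sb$label[j] else NA_character_,
      state_b = if (length(j)) "ED" else state_at(b, gene, pb))
  }
  for (j in seq_len(nrow(sb))) {
    pa <- project(sb$cds_pos[j], map_ba)
    if (!is.na(pa) && any(sa$cds_pos == pa)) next  # already paired above
    rows[[length(rows) + 1L]] <- data.frame(
      pos_a = pa, label_a = NA_character_,
      state_a = if (is.na(pa) || pa > nchar(a$genes[[gene]]$cds)) "ABSENT"
                else state_at(a, gene, pa),
      pos_b = sb$cds_pos[j], label_b = sb$label[j], state_b = "ED")
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(ifelse(is.na(out$pos_a), Inf, out$pos_a),
            ifelse(is.na(out$pos_b), Inf, out$pos_b)), , drop = FALSE]
}

#' Build an editing-state matrix for one gene across species
#'
#' Rows are the union of editing sites of all species, expressed in the
#' coordinates of a designated reference species; columns are species.
#' Cell states follow the legend: `ED`, `P` (pre-edited, genomic T), `C`
#' (genomic unedited C), an amino-acid letter for any other residue, and
#' `ABSENT` (no aligned position). Editing observed only in species listed
#' in `predicted_species` (prediction-only editomes) is marked as a
#' candidate in the `candidate` attribute.
#'
#' @param gene Gene name.
#' @param species_data List of [reference_editome()] bundles.
#' @param reference_species Species id giving row coordinates.
#' @param predicted_species Character vector of species whose editomes are
#'   predictions, not cDNA-confirmed observations.
#' @return Character matrix (sites x species) of class `EditingStateMatrix`
#'   with attributes `candidate` (logical matrix, prediction-only ED cells),
#'   `site_rows` (data frame: ref position, label, candidate-site flag).
#' @export
build_state_matrix <- function(gene, species_data, reference_species,
                               predicted_species = character()) {
  bundles <- lapply(species_data, species_bundle)
  ids <- vapply(bundles, function(x) x$species_id, character(1))
  names(bundles) <- ids
  if (!reference_species %in% ids)
    stop("reference species ", reference_species, " not in species_data")
  ref <- bundles[[reference_species]]
  others <- bundles[ids != reference_species]
  maps <- lapply(others, function(b) map_orthologous_sites(ref, b, gene))
  # union of sites in reference coordinates
  site_pos <- ref$sites$cds_pos[ref$sites$gene == gene]
  site_lab <- ref$sites$label[ref$sites$gene == gene]
  extra <- list()
  for (sp in names(maps)) {
    m <- maps[[sp]]
    new <- m[is.na(m$label_a) & !is.na(m$pos_a) & m$state_b == "ED", ,
             drop = FALSE]
    for (k in seq_len(nrow(new))) {
      p <- new$pos_a[k]
      if (p %in% site_pos || p %in% vapply(extra, `[[`, numeric(1), "pos"))
        next
      # label in reference coordinates with the donor species' codon change
      change <- sub("^.*eU[0-9]+", "", new$label_b[k])
      extra[[length(extra) + 1L]] <- list(
        pos = p, label = paste0(gene, "eU", p, change))
    }
  }
  all_pos <- c(site_pos, vapply(extra, `[[`, numeric(1), "pos"))
  all_lab <- c(site_lab, vapply(extra, `[[`, character(1), "label"))
  o <- order(all_pos)
  all_pos <- as.integer(all_pos[o]); all_lab <- all_lab[o]
  state <- matrix("ABSENT", length(all_pos), length(bundles),
                  dimnames = list(all_lab, ids))
  state[, reference_species] <-
    vapply(all_pos, function(p) state_at(ref, gene, p), character(1))
  for (sp in names(maps)) {
    m <- maps[[sp]]
    idx <- match(all_pos, m$pos_a)
    state[!is.na(idx), sp] <- m$state_b[idx[!is.na(idx)]]
    # positions never touched by a site on either side: evaluate directly
    miss <- which(is.na(idx))
    if (length(miss)) {
      cm <- codon_map(ref, bundles[[sp]], gene)
      for (i in miss) {
        p <- all_pos[i]
        ci <- ((p - 1L) %/% 3L) + 1L
        cj <- if (ci <= length(cm)) cm[ci] else NA_integer_
        if (is.na(cj)) next
        pb <- 3L * (cj - 1L) + (p - 3L * (ci - 1L))
        if (pb <= nchar(bundles[[sp]]$genes[[gene]]$cds))
          state[i, sp] <- state_at(bundles[[sp]], gene, pb)
      }
    }
  }
  candidate <- state == "ED" &
    matrix(ids %in% predicted_species, length(all_pos), length(ids),
           byrow = TRUE)
  cand_site <- vapply(seq_along(all_pos), function(i) {
    ed <- state[i, ] == "ED"
    any(ed) && all(candidate[i, ed])
  }, logical(1))
  structure(state,
            candidate = candidate,
            site_rows = data.frame(pos = all_pos, label = all_lab,
                                   candidate_site = cand_site,
                                   stringsAsFactors = FALSE),
            class = c("EditingStateMatrix", class(state)))
}

#' Partition three editomes into the seven regions of a Venn diagram
#'
#' Orthologous sites are identified across the three species by pairwise
#' codon mapping (connected components over the three pairwise mappings);
#' each orthology class is assigned to exactly one region according to
#' which species carry the edit.
#'
#' @param editomes List of exactly three [reference_editome()] bundles.
#' @return List with `counts` (named integer vector over regions `"A"`,
#'   `"B"`, `"C"`, `"AB"`, `"AC"`, `"BC"`, `"ABC"`, names taken from the
#'   species ids) and `regions` (per region, the site labels, using the
#'   first member species' coordinates where shared).
#' @export
venn_partition <- function(editomes) {
  if (length(editomes) != 3L) stop("exactly three editomes are required")
  bundles <- lapply(editomes, species_bundle)
  ids <- vapply(bundles, function(x) x$species_id, character(1))
  node_key <- function(i, gene, pos) paste(ids[i], gene, pos, sep = "::")
  # collect nodes: one per (species, gene, cds_pos) editing site
  nodes <- character()
  labels <- character()
  node_sp <- integer()
  for (i in 1:3) {
    s <- bundles[[i]]$sites
    if (nrow(s)) {
      nodes <- c(nodes, node_key(i, s$gene, s$cds_pos))
      labels <- c(labels, s$label)
      node_sp <- c(node_sp, rep(i, nrow(s)))
    }
  }
  idx_of <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(k1, k2) {
    r1 <- find(idx_of[[k1]]); r2 <- find(idx_of[[k2]])
    if (r1 != r2) parent[max(r1, r2)] <<- min(r1, r2)
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    shared <- intersect(names(bundles[[i]]$genes), names(bundles[[j]]$genes))
    shared <- intersect(shared, union(bundles[[i]]$sites$gene,
                                      bundles[[j]]$sites$gene))
    for (gene in shared) {
      m <- map_orthologous_sites(bundles[[i]], bundles[[j]], gene)
      paired <- m[m$state_a == "ED" & m$state_b == "ED", , drop = FALSE]
      for (k in seq_len(nrow(paired)))
        union_(node_key(i, gene, paired$pos_a[k]),
               node_key(j, gene, paired$pos_b[k]))
    }
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  region_names <- c("100", "010", "001", "110", "101", "011", "111")
  pretty <- c(ids[1], ids[2], ids[3],
              paste(ids[1], ids[2], sep = "&"),
              paste(ids[1], ids[3], sep = "&"),
              paste(ids[2], ids[3], sep = "&"),
              paste(ids, collapse = "&"))
  regions <- stats::setNames(vector("list", 7L), pretty)
  for (r in seq_len(7L)) regions[[r]] <- character()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    sp <- node_sp[members]
    mask <- paste0(as.integer(1 %in% sp), as.integer(2 %in% sp),
                   as.integer(3 %in% sp))
    ridx <- match(mask, region_names)
    lab <- labels[members[order(sp)]][1]  # first member species' label
    regions[[ridx]] <- c(regions[[ridx]], lab)
  }
  counts <- vapply(regions, length, integer(1))
  list(counts = counts, regions = regions)
}
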