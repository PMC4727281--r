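# Hand-encoded comparative fixtures: the ndhD editing-state matrix across
# eleven angiosperms, and the 65-taxon angiosperm cladogram with the
# presence/absence characters for two editing factors and their target
# editing sites (shipped as plain-text files under inst/extdata).

#' The ndhD editing-state matrix across eleven angiosperms
#'
#' Twenty editing-site rows (in the coordinates of *Amborella trichopoda*)
#' by eleven species, encoded from the published comparison of chloroplast
#' *ndhD* editing patterns. Cell states: `ED` edited, `P` pre-edited
#' (genomic T), or an amino-acid letter where another residue is encoded
#' (cysteine in *Zingiber* at eU59, methionine in *Arabidopsis* at eU239,
#' phenylalanine in *Arabidopsis* at eU313 and in *Amborella* at eU1193).
#' The *Ceratophyllum* and *Zingiber* columns are predictions (not
#' cDNA-confirmed); sites eU145HY and eU1424TI are unconfirmed candidates
#' existing only as *Zingiber* predictions.
#'
#' @return Character matrix of class `EditingStateMatrix` (20 sites x 11
#'   species) with attributes `candidate` (logical matrix of
#'   prediction-only ED cells), `site_rows` (positions, labels,
#'   candidate-site flags) and `predicted_species`.
#' @export
table1_fixture <- function() {
  labels <- paste0("ndhDeU",
                   c("2TM", "59SL", "145HY", "239PL", "305SL", "313RW",
                     "383SL", "548SL", "599SL", "668AV", "674SL", "878SL",
                     "887PL", "944SF", "947TI", "1163SL", "1193SL",
                     "1298SL", "1310SL", "1424TI"))
  species <- c("Amborella_trichopoda", "Calycanthus_floridus",
               "Ceratophyllum_demersum", "Chloranthus_spicatus",
               "Illicium_oligandrum", "Liriodendron_tulipifera",
               "Magnolia_kwangsiensis", "Nuphar_advena",
               "Zingiber_spectabile", "Arabidopsis_thaliana",
               "Cucumis_sativus")
  # per-species state strings, one character per site row
  # (E = edited, P = pre-edited T, other letters = encoded residue)
  enc <- c(
    Amborella_trichopoda   = "EEPPEPEPEEEEPEEEFPEP",
    Calycanthus_floridus   = "EEPEPEEEPPEEPPEPPEPP",
    Ceratophyllum_demersum = "EEPPPPPPEPPEPPPPPEPP",
    Chloranthus_spicatus   = "EEPPPEEEEPEEEPPPEEEP",
    Illicium_oligandrum    = "EEPPPPEEPEEEEPPPEEEP",
    Liriodendron_tulipifera= "EEPPPEEEEPEEEPEPEEEP",
    Magnolia_kwangsiensis  = "EEPPPEEEEPPEEPEPEEEP",
    Nuphar_advena          = "EPPPEEPPPPEEPPPPPEEP",
    Zingiber_spectabile    = "ECEPPPEPPPPEEPEPEPPE",
    Arabidopsis_thaliana   = "EPPMPFEPPPEEEPPPPPPP",
    Cucumis_sativus        = "EPPPPPEPEPEEEPPPPPPP")
  state <- matrix(NA_character_, length(labels), length(species),
                  dimnames = list(labels, species))
  for (sp in species) {
    chars <- strsplit(enc[[sp]], "")[[1]]
    state[, sp] <- ifelse(chars == "E", "ED", chars)
  }
  predicted_species <- c("Ceratophyllum_demersum", "Zingiber_spectabile")
  candidate <- state == "ED" &
    matrix(species %in% predicted_species, length(labels), length(species),
           byrow = TRUE)
  cand_site <- vapply(seq_along(labels), function(i) {
    ed <- state[i, ] == "ED"
    any(ed) && all(candidate[i, ed])
  }, logical(1))
  structure(state,
            candidate = candidate,
            site_rows = data.frame(
              pos = as.integer(sub("^ndhDeU([0-9]+).*$", "\\1", labels)),
              label = labels, candidate_site = cand_site,
              stringsAsFactors = FALSE),
            predicted_species = predicted_species,
            class = c("EditingStateMatrix", "matrix", "array"))
}

#' The 65-taxon angiosperm cladogram fixture
#'
#' A rooted, order-level cladogram of 65 angiosperms with sequenced nuclear
#' genomes, shipped as a Newick file. Topology encoded by hand following
#' current angiosperm phylogeny (Amborella sister to all other flowering
#' plants, monocots, and the major rosid/asterid orders).
#'
#' @return `ape::phylo` tree with 65 uniquely labelled tips.
#' @export
angiosperm_cladogram <- function() {
  read_newick(system.file("extdata", "angiosperm65.nwk",
                          package = "editcoevo", mustWork = TRUE))
}

#' Presence/absence characters on the 65-taxon angiosperm cladogram
#'
#' Characters: editing sites `ndhBeU467PL`, `ndhDeU878SL` and `accDeU923SL`
#' and their nuclear specificity factors `CRR28` and `RARE1`, over the 65
#' fixture taxa. The two ndh site columns and the CRR28 column encode the
#' text-stated loss sets (ndhDeU878SL absent in Eucalyptus, Fragaria,
#' Cicer, Nicotiana and the palms; ndhBeU467PL absent in Linum and the
#' Fabales bean clade; CRR28 absent only in chickpea). The accD/RARE1
#' columns are figure-derived at genus resolution (see the header of the
#' shipped TSV): a 30-taxon absence set in 14 maximal clades, with RARE1
#' present exactly where the editing site is.
#'
#' @return A [presence_matrix()] (5 characters x 65 taxa).
#' @export
angiosperm_presence <- function() {
  read_presence_tsv(system.file("extdata", "angiosperm65_states.tsv",
                                package = "editcoevo", mustWork = TRUE))
}
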