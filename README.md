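# editcoevo

Comparative analysis of C-to-U RNA editing in plant chloroplast coding
sequences, and of the coevolution between editing sites and the nuclear
pentatricopeptide-repeat (PPR) proteins that serve them.

In flowering-plant organelles, specific cytidines of mRNAs are converted to
uridines after transcription, typically restoring amino-acid codons that are
conserved across species. Early-branching angiosperms carry far more
chloroplast editing than the classic model plants, and each editing site
depends on a nuclear-encoded PPR specificity factor that is expected to decay
once its target disappears from the chloroplast genome. `editcoevo` provides
the building blocks for this kind of study:

* **Editing-site nomenclature** — codon-level consequences of C-to-U edits
  and standardized labels of the form `gene` + `eU` + CDS position +
  amino-acid change (e.g. `ndhDeU878SL`, a serine-to-leucine edit at CDS
  nucleotide 878 of *ndhD*), including silent edits, co-edited codons, and
  start/stop-codon creation.
* **Codon-restoration prediction** — candidate editing sites in a query CDS
  are put to a vote across a panel of reference editomes: a reference
  supports a candidate edit when the edit converts the query amino acid into
  the reference's *edited*-mRNA amino acid at the aligned position. A site is
  predicted when supported by at least `min_count` references (default 8)
  making up at least `min_fraction` percent (default 70) of the references
  whose alignment covers the codon. Predictions can be confronted with an
  observed editome, sub-classifying missed sites as silent, below-threshold
  or orphan.
* **Cross-species comparison** — orthologous site mapping through protein
  alignments of edited translations, editing-state matrices (edited /
  pre-edited `P` / unedited `C` / other residue / absent) in the coordinates
  of a reference species, and three-way editome partitions.
* **Loss-only (Dollo) counting** — the minimum number of independent losses
  of a binary character (an editing site, or a factor gene) on a rooted
  cladogram with presence at the root and no regains, plus the site-factor
  concordance rule: a specificity factor is retained if and only if at least
  one of its target sites still needs to be served.
* **PPR recognition code** — scoring of P/S-type PPR repeats against the RNA
  upstream of an editing site under the core code (position 6 + position 1'
  → nucleotide: T+N:A, N+N:C, T+D:G, N+D:U), with the array anchored so that
  the terminal S-type repeat faces nucleotide −4 in front of the edited
  cytidine; optional serine-for-threonine equivalence and a
  purine/pyrimidine partial-match level.
* **Synthetic data** — generators with known ground truth for reference
  families with planted editing sites, loss-only character evolution on
  random trees, and PPR arrays built to match a target, so every stage is
  testable without downloads. Hand-encoded comparative fixtures (the *ndhD*
  editing-state matrix across eleven angiosperms and a 65-taxon angiosperm
  cladogram with editing-site/factor presence characters) ship with the
  package.

## Worked example

Predict editing sites in a synthetic query against 17 simulated references
with 30 planted non-silent sites (and 4 silent ones), then count documented
losses of `ndhDeU878SL` on the packaged 65-taxon angiosperm cladogram:

```r
library(editcoevo)

sim <- simulate_reference_family(n_refs = 17, gene_length_codons = 150,
                                 n_sites = 30, n_silent = 4,
                                 per_site_conservation = 1, divergence = 0.05,
                                 seed = 2016)
pred <- predict_sites(sim$query, sim$panel, min_count = 8, min_fraction = 70)
head(pred[, c("label", "genomic_codon", "edited_codon", "support_count",
              "covered_count", "support_fraction")], 3)
#>         label genomic_codon edited_codon support_count covered_count support_fraction
#> 1 syntheU11PL           CCA          CTA            17            17              100
#> 2 syntheU26PL           CCA          CTA            17            17              100
#> 3 syntheU44PL           CCA          CTA            17            17              100

confront(pred, sim$truth)
#> Confrontation of predictions with observed editing:
#>   confirmed & predicted:   30
#>   confirmed, unpredicted:  4 (silent=4)
#>   predicted, unconfirmed:  0

tree   <- angiosperm_cladogram()
states <- angiosperm_presence()
dollo_losses(tree, presence_column(states, "ndhDeU878SL"))
#> Dollo loss report: 5 independent loss(es), 7 ABSENT tip(s)
#>    parent              child
#> 1  node72             node73
#> 2  node88    Cicer_arietinum
#> 3  node94     Fragaria_vesca
#> 4 node102 Eucalyptus_grandis
#> 5 node120            node121
```

All 30 planted non-silent sites are recovered at full support (17/17
references, 100 %); the 4 silent sites are invisible to codon restoration by
construction and are classified as such. On the cladogram, the editing site
`ndhDeU878SL` is absent from seven taxa that fall into five separate
lineages (*Eucalyptus*, *Fragaria*, *Cicer*, the two *Nicotiana* species and
the palm clade — `node73` and `node121` are the stems of the two-tip
clades), so the loss-only model needs exactly five independent loss events.

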