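---
title: "Methods: editome prediction, loss counting and the PPR code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: editome prediction, loss counting and the PPR code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editcoevo)
```

# Scope and data model

`editcoevo` works on pre-extracted, in-frame chloroplast coding sequences:
position 1 is the first base of the annotated start codon, and all internal
storage uses the DNA alphabet (`U` appears only inside editing-site labels).
Whole-plastome annotation, strand handling and genome coordinates are out of
scope; they belong to upstream annotation. Incomplete CDSs are flagged and
rejected by the predictor, because a frame-shifted numbering would silently
corrupt every downstream label. An editome is the set of C-to-U editing
sites of one species, keyed by `(gene, cds_pos)`; a reference editome
couples genomic CDSs with those sites, so that each reference's *edited*
mRNA — the CDS with every site position converted C→T — is always derivable.

# Editing-site nomenclature

A site label is `gene + "eU" + cds_pos + aa_before + aa_after`. `aa_before`
is translated from the genomic codon, `aa_after` from the codon with the
edit applied. Three choices deserve explanation:

* **Silent sites** keep the uniform grammar with doubled letters
  (`accDeU6SS`): the label grammar stays machine-parseable and silent sites
  remain first-class objects, even though comparative tables usually only
  print non-silent changes.
* **Co-edited codons.** When several observed edits share a codon,
  `aa_after` of each site is computed with *all* of that codon's edits
  applied, and the sites are flagged `co_edited`. The mRNA-level consequence
  of editing is joint; reporting per-site intermediate codons would describe
  molecules that never exist.
* **Start creation** (`ACG` → `AUG` at codon 1) is exposed as a
  `creates_start` flag rather than a special label form. The label grammar
  stays uniform; consumers that care about initiation can filter on the
  flag.

Translation uses the standard genetic code; the plastid code differs only in
its start-codon set, which is covered by the `creates_start` logic rather
than by a separate translation table.

# Codon-restoration prediction

## The vote

For every cytidine of the query CDS, the candidate C-to-U edit is evaluated
against each reference in the panel:

1. The query's genomic translation is aligned globally (free end gaps,
   BLOSUM62, gap opening 10 / extension 1) with the reference's *edited*
   translation. References contribute their edited protein because
   restoration targets the conserved — i.e. edited — state; aligning
   against unedited references would penalize exactly the positions the
   method is looking for.
2. A reference *covers* a codon when its alignment places a residue (not a
   gap) opposite it. Support and coverage are counted per reference; a
   reference lacking the gene entirely is skipped and reported.
3. A reference *supports* the candidate when the edited query amino acid
   equals the reference residue while the unedited query amino acid differs
   from it. The difference requirement is what makes the method blind to
   silent edits: a synonymous change can never look like restoration at
   protein level.
4. Codons with several cytidines are first tried one edit at a time; only
   when no single edit can reach the reference residue but the joint edit of
   all of the codon's cytidines can, the joint edit is used and every
   contributing cytidine receives the shared support.

A prediction is emitted when `support_count >= min_count` (default 8) and
`support_count / covered_count >= min_fraction` (default 70 %). The
fraction is taken over *covering* references, not panel size, because real
reference sets differ in gene content; an absolute count alone would
penalize well-covered genes, a fraction alone would over-trust genes
covered by two references. Counts are non-increasing in the fraction
threshold by construction, which `threshold_sweep()` exposes directly.

## Confrontation

`confront()` partitions predicted and observed sites. Observed-but-
unpredicted sites are sub-classified: `silent` (invisible to restoration),
`below_threshold` (some support, under the thresholds), `orphan` (no
support from any covering reference). The orphan class is reported rather
than suppressed: such sites are either taxon-specific novelties or hints of
reference-set gaps, and both are findings.

## Alignment parameters

Gap opening 10 and extension 1 with BLOSUM62 are conventional protein-
alignment defaults; both are exposed as arguments. End gaps are free since
reference genes may be partial. Tie-breaking is delegated to the alignment
engine, which returns a single deterministic optimum; the test suite checks
the *score* against an independent exhaustive dynamic-programming oracle on
short sequences, because equal-scoring gap placements are legitimately
ambiguous while the score is not.

# Cross-species comparison

Orthologous sites are paired through the protein alignment of edited
translations, mapped back to codon coordinates, and must sit at the same
codon position of the aligned codon. To make the mapping exactly symmetric,
the alignment is always computed in a canonical orientation (lexicographic
species order) and inverted for the other direction — two independent
alignments could place gaps differently and break symmetry at no fault of
either. Unpaired sites are never dropped: the partner's state at the
orthologous position is reported as `P` (genomic T, pre-edited), `C`
(genomic unedited C), the encoded amino-acid letter otherwise, or `ABSENT`
when the codon aligns to a gap. The distinction matters: a pre-edited
position and a missing gene tell very different evolutionary stories.

State matrices use the coordinates of a designated reference species
(exposed as a parameter); rows contributed only by prediction-only species
are flagged as candidate sites. Three-way editome partitions identify
orthology classes as connected components over the three pairwise mappings,
which handles sites shared by any subset of the species without ad-hoc
coordinate juggling.

# Loss-only (Dollo) counting

Editing sites and editing factors are assumed present at the angiosperm
root, and regains are forbidden — the model the "independent losses"
phrasing implies. Under this model the minimum number of losses explaining
the tip states is the number of *maximal* clades whose known tips are all
ABSENT, and the deterministic edge placement is "as shallow as possible":
one loss on the edge above each such clade. `UNKNOWN` tips (taxa without
plastome data) impose no constraint and are reported with the ancestral
state. Two degenerate inputs are defined explicitly: a character absent
from every known tip is reported as a single loss at the root (there is no
edge above the root to place it on), and `root_state = "ABSENT"` with any
PRESENT tip is an error, since it would require a regain.

An input table may carry a reason for absence (genomic C-to-T conversion
vs. loss of the whole gene); the counter deliberately ignores it — both
routes are the same character state.

The test suite and the acceptance script check the counter against an
independent exhaustive oracle: the smallest subset of edges, none of which
spans a PRESENT tip, covering all ABSENT tips, found by brute-force subset
enumeration on trees of up to 12 tips.

Concordance applies the retention rule — factor PRESENT iff at least one
target site PRESENT — per taxon and reports violations with their
direction. No significance test is attached: with a handful of loss events
the evidence is descriptive congruence, and pretending otherwise would
overstate it.

# The PPR recognition code

Scoring uses the core code for positions 6 and 1′ (T+N:A, N+N:C, T+D:G,
N+D:U), where the code letters are the literal amino acids threonine,
asparagine, aspartate (and serine under the optional S≡T equivalence at
position 6) — not IUPAC classes. Position 1′ of repeat *i* is the first
residue of repeat *i*+1; the terminal repeat reads it from the following E
domain when annotated. Anchoring is fixed: the terminal S-type repeat faces
nucleotide −4 in front of the edited cytidine, one nucleotide per repeat
moving upstream. E1/E2 are not given nucleotide positions of their own; the
anchor is defined on the last repeat exactly as stated, and nothing else in
the package depends on how the tail domains would be counted.

The optional `PARTIAL` level implements "pyrimidines vs. purines decided by
position 6 only": T (or S under S≡T) at position 6 agrees with purine
targets (A/G), N with pyrimidine targets (C/U), position 1′ disregarded.
This is the reading consistent with position 6's role in the core code,
where T selects the purines and N the pyrimidines. L-type repeats are
scored and reported but flagged non-canonical and excluded from summary
counts — they are not established RNA-binding contributors, yet their
conservation (e.g. the valine-6/proline-1′ combination facing adenine) is
exactly the kind of signal a user may want to look at. Position 3 is
carried through all tables but excluded from match logic; its contribution
is qualitative in the current code proposals, and silently folding it into
scores would fabricate precision.

Repeat typing (P/L/S) is *input*, not computed: reliable PLS-type repeat
calling from raw protein sequence is a hard problem in its own right and
out of scope here.

# Synthetic data and fixtures

## Generators

`simulate_reference_family()` emulates a reference panel the way the
predictor sees one: an ancestral protein, planted non-silent sites where
the conserved amino acid requires U while the query carries C (CCA→CTA,
P→L), planted silent sites (TCC third-position), per-site reference
conservation, and i.i.d. per-codon amino-acid divergence (uniform over the
other 19 residues — only the conservation level matters for the vote, so an
exchange-matrix bias would add realism the predictor cannot see).
What it does *not* emulate: codon-level substitution processes, indels,
partial genes, editing-extent variation, and correlated divergence along a
phylogeny. Passing tests therefore demonstrate the correctness of the vote
and thresholds, not robustness to alignment error on distant real
sequences.

`simulate_tree_losses()` evolves characters by irreversible per-edge loss on
a random rooted bifurcating tree and reports effective (non-nested) loss
events as truth. `simulate_ppr_array()` builds arrays whose key-residue
pairs match the target under the core code except at a controlled noise
rate. All generators are deterministic under a fixed seed.

## Hand-encoded fixtures

The *ndhD* editing-state matrix (20 sites × 11 species) is encoded from the
published comparison table; every encoded column reproduces the printed
per-species totals, the four exceptional residues called out in its legend,
and the 18-confirmed/2-candidate row split, which is as strong a check of
the transcription as is available. The 65-taxon cladogram is hand-encoded
at order-level topology following current angiosperm phylogeny, with a
genus set chosen to include every genus named in the loss analyses. The
`ndhBeU467PL`, `ndhDeU878SL` and `CRR28` columns encode text-stated loss
sets; the `accDeU923SL`/`RARE1` columns are figure-derived at genus
resolution (30 of 65 taxa absent, arranged in 14 maximal clades, factor
present exactly where the site is) and are labelled as partially synthetic
in the fixture file header. Conclusions that depend on the exact identity
of the 14 accD loss clades should not be drawn from this fixture.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use: synthetic families of 17
references with 30 planted non-silent and 4 silent sites at conservation
1.0 and divergence 0.05; threshold sweeps over 70/80/90 %; 200 random trees
of 4–12 tips for the exhaustive Dollo cross-check; and the packaged 20×11
state matrix and 65-taxon cladogram. These sizes keep the full suite in the
low minutes on a single core while exercising every code path; all
stochastic steps flow from a single user-supplied seed.

# Known limitations

* Prediction operates per gene on protein-level restoration; non-coding,
  intron and tRNA editing, and editing-extent quantification are out of
  scope.
* The per-reference vote is one defensible reading of "commons" aggregation
  across references; pooled-alignment schemes could give slightly different
  counts on real panels.
* The Dollo counter assumes the character was present at the root; for
  characters plausibly gained within the tree, the count is an upper bound
  on losses given that assumption, not a model comparison.
* The PPR scorer does not model binding affinity, MORF/RIP interactions or
  de novo repeat detection; it evaluates the stated combinatorial code and
  nothing more.
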