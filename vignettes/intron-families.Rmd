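---
title: "Classifying plant mitochondrial group II introns into paralogue families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant mitochondrial group II introns into paralogue families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronfam)
```

## The problem

Mitochondrial genomes of land plants and their charophyte algal relatives
carry an unusually dynamic complement of group II introns. Unlike the static
chloroplast intron set, mitochondrial group II introns have repeatedly copied
themselves into new gene locations by retrotransposition, producing
*paralogues* at distinct insertion sites; they have also been lost
independently in many lineages, occasionally leaving behind degenerate
"fossil" copies in intergenic spacers or pseudogenes. An intron's identity is
its *insertion site*: the host gene plus the nucleotide position in the
reference homologue (the liverwort *Marchantia polymorpha* coding sequence)
after which it inserts, written `cox2i373g2`. Introns at the same site in
different taxa are *orthologues*; introns at different sites are potential
*paralogues*, and paralogues related by ancient copy events form *families*.

`intronfam` implements the full analysis chain:

1. sensitive all-vs-all nucleotide similarity (seed-and-extend local search
   with Karlin–Altschul statistics),
2. the most-distant-ortholog (MDO) clustering criterion that turns pairwise
   similarity into family assignments,
3. fossil detection in intergenic regions,
4. maturase ORF annotation, domain grading and protein clustering, which
   extend families into maturase-based families and superfamilies,
5. structural screens (domain V, splice-boundary motifs),
6. weighted gain–loss (Sankoff) parsimony of intron presence/absence over
   alternative land-plant phylogenies, and
7. a fully seeded simulator that generates genomes with known family,
   fossil and maturase truth, so every stage is testable end to end.

## The MDO criterion

A priori, group II intron paralogues share almost no sequence similarity
beyond the short 5' motif (GUGCG), the 3' terminus (AY) and the 34-nt domain
V. The MDO idea turns this problem around: for every insertion site with at
least two members, the *lowest* orthologue-pair bit score (the most distant
orthologue pair) defines that site's cutoff. A cross-site hit whose bit score
*exceeds* a site's cutoff is stronger evidence than common descent at that
site itself, so the two sites are linked; families are the connected
components (single linkage) of the resulting graph.

Decisions the package codifies where the underlying procedure is open:

* **Whose cutoff?** A hit links two sites when it exceeds the cutoff of *at
  least one* of them (one-sided, the permissive reading); a two-sided mode is
  available (`two_sided = TRUE`).
* **Most distant = lowest bit score.** The alternative reading (the pair
  spanning the deepest phylogenetic split) would need a reference phylogeny;
  the bit-score minimum is phylogeny-free and is what the package uses.
* **Unbridged orthologue pairs.** Orthologue pairs with *no* significant hit
  do not zero the cutoff; they are counted separately (`n_missing`) and
  handled by positional rescue. Single-member sites get an infinite sentinel
  cutoff — they can join families only through another site's cutoff or
  maturase evidence.
* **Low-score gating.** Links below 200 bits survive only with independent
  similarity in ≥ 2 non-overlapping intron regions or ≥ 30% query coverage;
  low-complexity tracts are masked before seeding (Shannon entropy < 1 bit
  over 16-nt windows) so repeat-driven similarity cannot seed a link.
* **Refinement, not reassignment.** A record with no significant hit to its
  own site's family stays there as a positional orthologue
  (`positional_rescue`); if its best similarity points at a *different*
  family it is flagged (`conflicting_positional`), never silently moved.
* **Numbering.** Families are numbered by descending size, ties broken by
  the lexicographically smallest member label, so output is independent of
  input order.

## Similarity engine and statistics

The search reimplements a word-seeded local aligner at the sensitive
settings used for intron scans: match +2, mismatch −3, gap open 5, gap
extend 2 (a gap of length *k* costs 5 + 2*k*), word size 7, expectation
cutoff 1e-5, both subject strands searched (fossils occur antisense). Exact
7-mer seeds are clustered by diagonal; sparse clusters must survive a cheap
ungapped x-drop extension before a cluster is extended by *optimal banded
affine-gap alignment* in a padded window around it. Because every heuristic
alignment is a valid local alignment of the full pair, the heuristic score
can never exceed the exact Smith–Waterman optimum — a property the test
suite asserts, alongside the requirement that planted homologues of ≥ 70%
identity are recovered at ≥ 95% of the exact score.

Significance follows Karlin–Altschul: `lambda` is the unique positive root
of `sum p_i p_j exp(lambda s_ij) = 1`, found by bisection to 1e-9 and
oracle-tested against an independent grid scan. For the constant `K` the
package uses the documented surrogate `K = min(1, H/lambda)` (H the relative
entropy of the induced target frequencies): any constant shifts all bit
scores equally by `−log2 K`, so rankings, cutoff comparisons and the
qualitative behaviour of the 1e-5 threshold are unaffected, and the exact
renewal-theory constant adds nothing testable here. Bit scores are
`(lambda·raw − ln K)/ln 2`; E-values are `m·n·2^(−bits)` with per-pair
search space and no edge-effect correction — the simplest defensible
convention, recorded in output headers.

## Fossils

Queries are searched against intergenic spacers (derived as the complement
of gene features when not annotated) and pseudogenes, on both strands. Hits
shorter than 100 nt are discarded — domain V alone (34 nt) must never count
as a fossil. Overlapping hits from paralogous queries collapse to the
best-scoring source. Termini completeness records whether the alignment
reaches the source intron's first and last 5 nt — the distinction between a
fossil with perfect ends (a dead but complete copy) and an internal
fragment. Genome fraction is computed on merged intervals, so overlapping
hits count once; genomes are treated as linear (the simulator never creates
origin-spanning features).

## Maturases

Intron-borne maturases are found as ATG-initiated ORFs ≥ 200 aa on the
intron's sense strand; a frameshift-tolerant mode chains collinear sub-ORFs
in different frames, because decayed maturases frequently survive only as
frameshifted fragments. Domain conservation is graded against a motif table
that is *data, not code*: short peptide signatures for the reverse
transcriptase core (a YADD-containing motif), the maturase X domain and the
En endonuclease domain. The grades mirror the usual four display classes:
`intact` (all motifs, in order), `partial` (RT+X intact, En absent),
`traces` (a strict motif hit, or a length-plausible remnant with a relaxed
2-mismatch hit), `absent`. The mapping from motif evidence to grades is this
package's codification of an otherwise visual convention; grading is
monotone under C-terminal truncation, which the tests assert. Protein
clustering is single linkage over local BLOSUM62 alignments at ≥ 35%
identity and ≥ 50% coverage of the shorter protein — thresholds chosen as
conservative defaults for "same maturase lineage", standing in for the tree
inference that is out of scope here. Clusters spanning two or more
nucleotide families unite them into superfamilies (`SF01-02` style);
solitary sites joining one family get `maturase_link`; solitary-only
clusters become maturase-based `mF` families numbered after the cores.

## Gain–loss parsimony

Presence/absence of each intron across the seven embryophyte clades
(LIV, MOS, HOR, LYC, FER, GYM, ANG) plus the streptophyte algae (SAL/ALG) is
coded 1/0, fossils and pseudogene-context records excluded. Two rooted
topologies are packaged: `NLE_HT` (liverworts sister to all other
embryophytes, hornworts sister to tracheophytes) and `BRY_SET`
(monophyletic bryophytes with a moss+liverwort clade). Ancestral states are
reconstructed per intron by Sankoff dynamic programming with asymmetric
costs — gain `w_gain` (default 4), loss `w_loss` (default 1).

Two decisions matter and are both encoded explicitly:

* **Root prior.** Presence at the root costs `w_gain` (a "root-stem gain"),
  so every presence is ultimately explained by at least one gain and even
  universally present introns contribute one gain event. A `free` root is
  available behind an argument.
* **Tie policy.** At 4:1, one gain and four losses cost the same, so
  co-optimal histories are common. The default `min-gains` policy minimizes
  gains among minimum-cost labelings, then losses, then prefers absence —
  implemented exactly by a lexicographic dynamic program over
  (cost, gains, losses, presences) tuples, not by ad hoc backtracking. A
  `max-gains` policy exists so co-optimum tables can be reported. Totals are
  therefore policy-dependent and the policy id is embedded in outputs.

The weighted optimum is verified against exhaustive enumeration of all
ancestral labelings on every tree up to 8 leaves (a seeded 1000-instance
property test). Weight selection follows the empirical rule: among candidate
weightings (8:1, 4:1, 2:1, 1:1), choose the one whose total gain count is
smallest while at least the number of distinct introns (one origin each),
ties toward fewer gains and then the larger gain weight.

```{r gainloss}
emb <- catalog_matrix(embryophyte_only = TRUE)
cmp <- compare_topologies(emb, preset_topology("NLE_HT"),
                          preset_topology("BRY_SET"), 4, 1)
cmp
```

## The packaged catalog and its provenance

`inst/extdata/intron_catalog.tsv` holds the 161 streptophyte insertion
sites with an 8-character clade-occurrence string and a family id. It is a
*reconstruction* assembled from published per-family distribution
descriptions and stated aggregate constraints (161 sites, 101 present in
embryophytes, 13 shared between algae and embryophytes, `atp9i87g2` the
only intron in all three bryophyte clades); each row carries a provenance
flag: `text` (clade set fully stated in prose), `inferred` (partly stated,
completed from the literature on plant mitochondrial intron distributions)
or `schematic` (placeholder entries — single-clade solitaries and algae-only
sites whose identity is inert for every analysis shipped here, since a
single-clade intron contributes exactly one gain and no losses on any
topology). The clade-level matrix deliberately ignores within-clade
(species-level) variation: gain totals are robust to this (roughly one
origin per intron), loss totals are not, and published species-level loss
counts are therefore expected to exceed what an 8-leaf clade matrix can
produce. The two intron sequences needed for the hornwort twintron identity
check (`atp1i1050g2ii1536g2` vs `cox2i98g2`, ≥ 98% global identity) must be
extracted from GenBank NC_049004.1 by the user; public sequence records are
not redistributed with the package.

## The simulator

`simulate_introns()` evolves a root genome along a clade-labelled tree:

* **Genome.** 10 genes of 8 exons (240 nt each, codon-structured with
  synonymous-codon sampling so frame-shifted readings have realistic stop
  densities), 300-nt spacers. Exon junctions are the insertion-site space.
* **Founders.** 5 founder introns (= true families):
  `GUGCG | random core | (maturase ORF) | random core | domain V | AC`, each
  with its own randomized domain V (layout conserved, sequence free — as in
  real families). 60% carry a 300-aa maturase with the packaged motif
  peptides embedded at 35%/60%/85% of the protein.
* **Processes per branch.** Substitutions under JC69 (exact
  `p = 3/4·(1 − e^(−4d/3))`) or K2P (closed-form transition/transversion
  split); loss with probability 0.1 (excision restoring exon continuity);
  on loss, fossilization with probability 0.3 (a copy at twice the branch
  divergence plus short geometric indels, inserted into a random spacer on
  either strand); retrotransposition with probability 0.15 per intron
  (the current sequence copied into a junction unoccupied in *any* lineage,
  so every site traces to exactly one founder — the "new-locus occupation"
  reading; independent site collisions, the real-data "analogue" cases, are
  deliberately not generated, which is one way passing tests understate the
  difficulty of real data); maturase decay with probability 0.15
  (frameshift, premature stop or truncation, with the implied truth grade
  recorded).
* **Truth and replay.** Every stochastic outcome — substitution positions
  and bases, event records with inserted sequences — is logged, so
  `replay_truth()` rebuilds each tip genome byte-for-byte *without* an RNG,
  and the presence/absence matrix derived from the event log must equal the
  one derived from the emitted genomes.

Default rates were chosen once to produce, on an 8-clade tree with ~0.1
substitutions/site root-to-tip, family sizes (2–13 copies), loss counts and
fossil numbers in the range reported for real streptophyte mitogenomes.
What the simulator does **not** emulate: RNA editing, *trans*-splicing
arrangements, twintron nesting, horizontal transfer, rate heterogeneity
across sites, and same-site analogues. Clustering accuracy on simulated
data (ARI ≥ 0.9) therefore demonstrates the pipeline's internal
consistency, not its performance on such confounders.

## Problem sizes and numerical choices

The test suite runs simulations with 300-nt intron cores and 240-aa
maturases (10 family-recovery replicates), 100 planted-homologue replicates
at 300 nt in 3.3-kb subjects, and 1000 random parsimony instances on trees
of up to 8 leaves — sizes chosen so the full suite completes in minutes on
one CPU while each property retains power. Bisection tolerances (1e-9 for
lambda), the E-value convention, the minimum fossil length (100 nt), the
domain V mismatch tolerance (1 per stem, G·U counts as paired), the
boundary-correction radius (10 nt) and tie-breaks are all fixed constants
documented at their definition sites; none is data-dependent.

## Known limitations

* The catalog's `inferred`/`schematic` rows bound the fidelity of
  clade-level analyses; per-row provenance lets users substitute a curated
  matrix.
* Loss totals from an 8-clade matrix are not comparable to species-level
  loss counts (see above).
* The Karlin–Altschul `K` surrogate shifts absolute bit scores by a small
  constant; E-values are comparable within, not across, scoring schemes.
* Protein clustering replaces phylogenetic inference of maturase history;
  deep paraphyly inside a cluster is invisible to single linkage.
* The boundary corrector assumes the spliced exons form a codon-multiple
  coding sequence; it abstains (`unverifiable`) rather than guess when no
  motif-bearing candidate exists in the search radius.
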