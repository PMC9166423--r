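---
title: "Ecogenomic analysis of freshwater CPR genomes with cprlib"
author: "cprlib authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecogenomic analysis of freshwater CPR genomes with cprlib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprlib)
```

# Scope and model

The candidate phyla radiation (CPR, Patescibacteria) comprises small-genome,
largely uncultivated bacteria recovered almost exclusively as
metagenome-assembled genomes (MAGs). `cprlib` implements the downstream
ecogenomic analysis of such MAGs as a tested, reusable pipeline:

1. **Bin decontamination** — per-gene taxonomy from alignment hits, a
   bin-wide majority vote, and removal of contigs whose assigned genes
   disagree with the dominant class, plus a viral-gene filter.
2. **Quality estimation** — completeness/contamination/strain heterogeneity
   from a fixed set of 43 single-copy marker genes (SCGs), with a strict
   quality gate.
3. **Dereplication** — single-linkage clustering of pairwise average
   nucleotide identity (ANI) above a strict threshold, and a scored
   representative per cluster.
4. **Abundance and replication** — fragment recruitment with rRNA masking,
   normalization as coverage per gigabase of metagenome, and an ori/ter
   replication-skew index from window coverages.
5. **Rhodopsin classification** — Type I ion pumps vs heliorhodopsins from
   transmembrane topology and the helix-7 retinal-binding motif.
6. **Genome traits** — streamlining statistics across lifestyle categories,
   KEGG-module completeness averaging, and CAZy tabulation.

A synthetic-data module generates every input with planted ground truth, so
each stage has a closed-loop test and the whole pipeline runs without
databases or downloads.

# Decontamination and quality gating

Gene taxonomy comes from a tabular alignment-hit file. A hit survives only
if it passes four criteria simultaneously (e-value $\le 10^{-3}$, similarity
$\ge 10\%$, query coverage $\ge 10\%$, bitscore $\ge 50$); the surviving hit
with the highest bitscore supplies the class. The bin's *dominant class* is
the class with the most assigned genes, computed once per bin, before any
removal — there is no iterative re-voting. A contig is discarded when
strictly fewer than 30% of its assigned genes match the dominant class, or
when strictly more than 25% of its genes carry a viral flag. All boundary
semantics are strict exactly as stated: 30% dominant is retained, 25% viral
is retained.

Two denominator decisions deserve emphasis:

* **Unassigned genes do not enter the vote.** CPR proteins frequently have
  no database homolog; counting unassigned genes against a contig would
  systematically purge the most novel sequence. Contigs with zero assigned
  genes are therefore retained and flagged for inspection rather than
  removed. The choice is switchable by supplying a taxonomy vector that
  maps unassigned genes to a sentinel class.
* **Viral fractions use all predicted genes** (a viral flag is evidence
  regardless of taxonomic assignability); contigs with no genes at all are
  retained for lack of evidence.

Quality is estimated from copy counts over the 43-marker set:
completeness $=100\,m_{\ge 1}/43$ (markers present),
contamination $=100\sum_i \max(0, c_i-1)/43$ (extra copies), and strain
heterogeneity the percentage of multi-copy markers whose extra copies are
$\ge 90\%$ identical to the first copy (0 when nothing is multi-copy; the
identity threshold is configurable). The gate passes iff completeness
$> 40$ and contamination $< 5$, both strict. This simple-count estimator is
the literal reading of running a checkpointing tool restricted to a fixed
43-marker set; collocation-based marker weighting is deliberately out of
scope.

# Dereplication

Genomes are clustered by single-linkage on the graph whose edges join pairs
with ANI strictly above 99% — the literal interpretation of dereplicating
"at ANI > 99%". Two-stage sketch pre-clustering used by some dereplication
tools is not reproduced; on data where pre-clusters are well separated the
partitions coincide. Missing pairs in sparse tables count as below
threshold. Each cluster's representative maximizes

$$\mathrm{score} = comp - 5\,cont + cont \cdot \frac{SH}{100}
  + 0.5 \log_{10} N50 + 0 \cdot \log_{10} size + centrality,$$

the weight vector (1, 5, 1, 0.5, 0, 1) being the default of the scoring
scheme this follows; centrality is the genome's mean ANI to the rest of its
cluster. Exact ties break to the lexicographically smallest id so results
are order-invariant.

# Abundance and the replication-skew index

rRNA genes recruit reads promiscuously across taxa, so their intervals are
masked to N (overlaps merged first) and excluded from the *effective* genome
length. Abundance is reported as

$$\mathrm{coverage\ per\ Gbp} =
  \frac{\text{mapped bases} / \text{effective genome length}}
       {\text{sampled bases} / 10^9},$$

a fold coverage normalized by the amount of metagenome sampled, comparable
across genomes and metagenomes. No closed formula for this normalization is
universal; this definition is dimensionally a fold-coverage per sampled
gigabase and reproduces the intended invariances (halving when twice as
much metagenome is sampled; stable in expectation under read subsampling).
Both hit counts and mapped bases are carried in the result so either
convention can be recomputed. The bundled matcher is a contract more than
an engine: a read is recruited if an ungapped full-length alignment at
$\ge 95\%$ identity exists on either strand of unmasked sequence, and
precomputed hit tables from an external mapper are accepted at scale.

The replication-skew index summarizes the coverage gradient that active
bidirectional replication leaves between origin and terminus. Window
coverages (5 kb windows by default) are smoothed with a centered moving
average (9 windows), sorted, the extreme 2% of windows discarded on each
side, and the index taken as the mean of the remaining top decile over the
mean of the remaining bottom decile, floored at 1. The smoothing step is a
numerical necessity, not cosmetics: at 20-fold coverage a 5 kb window holds
roughly 670 read starts, so raw window coverages carry ~4% sampling noise,
and the ratio of extreme-decile means of pure noise already sits near 1.12.
Averaging over 9 windows multiplies every window of an exponential gradient
by the same factor (so the ratio is unchanged) while shrinking the noise
threefold. The index is reported as NA below a mean-coverage floor of 0.2
(too little signal to call replication), mirroring the refinement step of
coverage-based replication estimators. The decile ratio is a deliberately
conservative statistic: it underestimates large gradients (about $-12\%$ at
a true ori:ter ratio of 3) because decile means average over the gradient's
interior; within the 1-1.4 range observed for slow-growing CPR it is nearly
unbiased.

# Rhodopsin classification

Candidates from an upstream profile search are filtered on length
(strictly more than 150 residues) and score (P value strictly below
$10^{-2}$). Topology is predicted from first principles instead of an
external predictor binary, keeping the decision logic identical: a
transmembrane helix is a maximal stretch whose 19-residue window mean
Kyte-Doolittle hydropathy reaches 1.6 (window expansion is trimmed of
terminal hydrophilic residues; stretches separated by fewer than 5 residues
merge; minimum length 19), and orientation follows the positive-inside
rule — loops alternate sides from the N-terminal tail, and the side holding
more K+R residues is cytoplasmic, with differences below 2 residues called
ambiguous. All parameters are exposed and configurable.

Classification then requires exactly 7 helices; the 7th helix span (±3
residues of slack for prediction jitter) is scanned for D-x(3)-K (Type I
retinal-binding motif) and then S-x(3)-K (heliorhodopsin motif, whose
carriers have inverted topology — cytoplasmic N-terminus). Motif and
orientation must agree: DxxxK with an extracellular (or ambiguous)
N-terminus is an ion pump, SxxxK with a cytoplasmic (or ambiguous)
N-terminus a heliorhodopsin, a contradictory pair is reported `ambiguous`
(a category of this package — upstream literature does not define the
case), no motif is `rhodopsin_like_unclassified`, and any other helix count
is rejected. The motifs most often observed in CPR heliorhodopsins (SLVAK,
SLIAK, SFVAK) all satisfy the SxxxK rule and are the motifs the synthetic
generator plants.

# Genome traits

Per genome: GC is computed over unmasked bases; coding density is the union
of gene spans over assembly length (overlaps counted once — the natural
reading when genes may overlap); and the estimated genome size extrapolates
assembly length by completeness, $size = assembly \times 100 / comp$, the
only definition consistent with reporting both an assembly length and a
larger estimated size for partial MAGs. KEGG-module completeness is the
fraction of a module's KOs present; group values average per genome first
and then per group, unweighted, so gene-rich genomes do not dominate. CAZy
summaries report per-genome counts, each family's share of all hits, and
its prevalence across genomes.

Lifestyle categories (CPR classes, free-living, symbiont) are inputs:
curating reference genomes into those categories is a manual, literature
driven exercise and no algorithm here pretends otherwise.

# The synthetic-data module

Every generator plants its truth and is byte-deterministic under a fixed
seed; all randomness in a pipeline run derives from one seed via
`deriveSeed()`.

* `makeBin()` plants foreign contigs at 20% dominant-class genes (below the
  30% floor), viral contigs at 40% viral genes, optional exact-boundary
  contigs (exactly 30% / exactly 25%, both retained under strict
  inequalities — representable only when genes per contig is divisible by
  20, enforced with an error), and unannotated contigs. Hit tables include
  decoy hits that fail exactly one criterion, so filter order is exercised.
* `makeScgProfile()` snaps targets to the 43-marker grid
  (`round(pct/100*43)` markers), making estimator recovery exact by
  construction.
* `simulateReads()` draws read starts from an exponential density whose
  ori:ter ratio is the planted `ptr` (`ptr = 1` uniform); reads are
  error-free and ungapped by default, mirroring ungapped mapping, with an
  optional substitution rate for robustness tests.
* `makeRhodopsinProtein()` builds helices from strongly hydrophobic
  residues (I/L/V/F) and loops from clearly hydrophilic ones (N/Q/P, never
  serine or aspartate, so no spurious motif can arise), placing two K/R per
  cytoplasmic loop away from helix edges. This makes topology and motif
  recovery provable rather than probable: a 19-residue window can reach the
  hydropathy threshold only inside a true helix.
* `makeAniMatrix()` draws within- and between-cluster identities from
  disjoint ranges straddling the threshold, erroring when ranges overlap
  (the truth would be ambiguous).
* `makeTraitTable()` centers its groups on the trait locations typical of
  freshwater CPR MAGs (estimated size median 1.02 Mbp, coding density
  median 89.47%, GC median 42.04%) next to free-living and
  symbiont/parasite reference distributions; `makeCazyTable()` plants a
  mean of 15 CAZy genes per genome with GT4 at 35% and GT2 at 23% of hits.

What passing on these data does **not** show: the generators produce i.i.d.
random sequence with no codon structure, no shared k-mer background between
foreign and host contigs, no alignment noise in hit tables, and cleanly
separated ANI blocks. Real data violate all of these — taxonomies are
noisy, ANI distributions overlap near species boundaries, topology
predictors disagree on marginal helices. The closed-loop suites verify the
decision logic and its boundary semantics, not robustness to adversarial
real-world inputs.

# Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold is stated strictly; ties in
  votes, scores and representatives break lexicographically.
* The replication index needs at least 20 windows, reports NA below the
  0.2x coverage floor or when the bottom decile is all zero, and is floored
  at 1.
* Problem sizes in the test and acceptance runs (50 synthetic bins; 10,000
  random marker profiles; 200-genome ANI matrices; one 1 Mbp genome at
  20-fold depth over 20 seeds per planted ratio; 200 synthetic proteins per
  class; a 282-genome / 174-cluster dereplication study) were chosen as the
  smallest sizes at which every property is statistically decisive.
* Reading a gene on an unknown contig, a coordinate outside its contig, a
  non-numeric score field, an out-of-bounds mask interval, an empty KO set,
  or an unmapped protein each raise immediate, named errors rather than
  propagating silently.

# Known limitations

* The 43-marker estimator ignores marker collocation and lineage-specific
  marker sets; completeness of very incomplete bins is coarse (grid
  resolution 1/43 ≈ 2.3%).
* Single-linkage dereplication can chain clusters through intermediate
  genomes where a sketch-pre-clustered tool would split them; at very large
  genome counts the representative count may differ slightly.
* The bundled read matcher is quadratic in genome size times read count and
  intended for method-scale inputs; production-scale recruitment should
  supply external hit tables.
* The decile-ratio replication index compresses strong gradients (see
  above) and assumes a single linearized replicon.
* The hydropathy topology predictor has no evolutionary information; on
  real proteins it is cruder than profile-based predictors, and borderline
  helices will differ.
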