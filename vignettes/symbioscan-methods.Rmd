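---
title: "Methods: symbiont triage, host association, and selection scanning"
author: "symbioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbiont triage, host association, and selection scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioscan)
```

# Scope

`symbioscan` packages the bespoke computations used to pull a low-titer
bacterial endosymbiont (a *Wolbachia*-like organism) out of community
metagenome assemblies and to characterize its biology:

1. **Contig triage** — separating symbiont contigs from host and background
   contigs using GC content, relative coverage, and two-step best-hit
   classification over precomputed BLAST hit tables.
2. **Host association** — converting assembler kmer coverage to read
   coverage, normalizing a sample-by-taxon abundance matrix, and screening
   all column pairs with Spearman midrank correlation under
   Benjamini–Hochberg FDR control, to nominate which community member hosts
   the symbiont.
3. **Selection scanning** — sliding-window Ka/Ks (dN/dS) over pairwise codon
   alignments of orthologs, gene-level aggregation, and quantile
   partitioning into most- and least-conserved gene sets.
4. **GO enrichment** — Fisher hypergeometric tests over an is_a DAG with the
   elim decorrelation pass, applied to quantile sets and to gene-repertoire
   (core/pangenome/Venn) sets.
5. **Branch transitions** — repeating the quantile-enrichment analysis for
   each adjacent pair along an ordered chain of strains and classifying
   enriched functions as unique to a branch, shared, or universally
   conserved.

Everything upstream (read trimming, assembly, gene prediction, ortholog
clustering, running BLAST) is out of scope; those tools' outputs are this
package's inputs. A synthetic-data module generates inputs with the
statistical structure each stage assumes, so the whole pipeline is testable
offline.

# Contig triage

A draft symbiont bin assembled from a mixed community is contaminated by
host DNA, co-occurring bacteria, and horizontally transferred fragments
residing in abundant non-target genomes. Triage applies three rules in a
fixed order (classification, GC, coverage), recording for each removed
contig the first rule it failed:

* **Classification.** A contig with a hit in the step-1 custom database
  (e.g. symbiont 16S/genome sequences) is a candidate; its final label is
  the best step-2 hit against a comprehensive database (maximum bitscore,
  ties broken by minimum evalue then subject id). Candidates whose best
  broad-database hit is not a target label are removed; candidates with no
  step-2 hit remain positive on the step-1 evidence alone.
* **GC band.** Contigs longer than 1,000 bp are removed when GC is strictly
  below 0.24 or strictly above 0.42. The bounds are exclusive — equality
  retains the contig — a package decision: the filter is conventionally
  stated in terms of values *below* and *above* the band, which leaves
  boundary values in.
* **Relative coverage.** Contigs longer than 5,000 bp are removed when
  their coverage strictly exceeds twice a reference coverage. "Average
  coverage of the longest contigs" is made precise here as the arithmetic
  mean over the 10 longest contigs (ties by id; configurable `n_longest`),
  computed once from the input set — which makes the kept set independent of
  the order the rules run in.

The iterative subtractive-enrichment loop that grows the symbiont bin is
represented by its stopping rule: continue while the total retained length
strictly increased in the last cycle and fewer than `max_iterations`
(default 10 — a safety cap; such loops typically converge within a handful
of cycles) cycles have run.

# Host association

Assemblers report kmer coverage; total read coverage follows from

$$C = \frac{C_K \, R}{R - K + 1}$$

for kmer length $K$ and read length $R$. Coverages are normalized to each
sample's total read count and scaled to per-million; the scale is cosmetic
for everything downstream because Spearman correlation is rank-invariant.

`spearman_midrank()` computes rho as the Pearson correlation of midranks
(ties get their average rank) on pairwise-complete observations, with the
two-sided p-value from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, the
behavior of the correlation-matrix routines commonly used for this screen.
An exact test is not attempted; at the sample sizes where the t
approximation is doubtful, no correlation from this screen should be
over-read either. `association_screen()` tests **all** column pairs and
applies BH across the full family, not only the symbiont pairs — matching
the all-pairs matrix routine this mirrors; restricting the family to
symbiont pairs would only make the adjusted p-values smaller, so the choice
is conservative. Degenerate (constant) columns are excluded with a message
rather than failing the screen.

# Sliding-window dN/dS

## Windows

Alignments are split into 1,200 bp windows every 600 bp, preserving codon
frame. The last window is the first one reaching the end of the alignment;
a trailing window shorter than 1,200 bp is kept only if it spans at least
`min_tail = 300` bp. The tail threshold mirrors the 300 bp gene-assignment
overlap, so no gene can be scored on less sequence than would qualify it
for a window in the first place.

## Estimator

Within each window the package uses the Nei–Gojobori (1986) counting
method: per-codon synonymous site fractions (changes to stop codons count
as nonsynonymous, so each position contributes a full site), averaged over
the two sequences; observed differences resolved by averaging over all
minimal substitution pathways with equal weights, excluding pathways that
pass through a stop codon (if every pathway is blocked — possible only for
some triple-substitution codon pairs — the average falls back to all
pathways); and the Jukes–Cantor multiple-hit correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined at $p \ge 3/4$. The
window ratio is $K_a/K_s$, undefined when $K_s$ is zero or either
correction saturates; undefined ratios are reported but excluded from
ranking, since they cannot be ordered.

Model-averaged maximum-likelihood estimators (as in KaKs Calculator) are a
common alternative for window scans of this kind.
NG86 is used here because it is fully specified, exactly testable against
an exhaustive enumeration oracle, and the downstream partitioning consumes
only the *ranks* of gene scores, which are robust to the estimator choice.
Per-codon-pair difference counts and site fractions are precomputed into
lookup tables once per genetic code (table 11 by default; identical to the
standard code on all sense codons), so scans are table lookups.

## Filtering, aggregation, partitioning

Windows with $K_s$ above a cutoff are treated as saturated: 2.0 for
divergent strain pairs, 2.5 for the closely related within-clade pair.
Genes attach to every window they overlap by at least 300 bp, and a gene's
score is the **unweighted mean** of its surviving windows' ratios. Mean
(rather than median or window-as-observation) is a package decision — with
2–3 windows per typical gene the mean is the least lossy summary; genes
whose every window was filtered are dropped with a logged reason.
Quantile sets (`top10`, `top25`, `bottom10`, `bottom25`) take the first or
last $\lceil f\,n\rceil$ genes after sorting by score descending with ties
broken by gene id, which makes partitions deterministic and nested.

## Divergence-time calibration

`calibrate_divergence_time()` applies the linear clock of 216 million years
per 2.8% 16S rRNA divergence: 3.934% maps to ≈303 My and 4.211% to
≈325 My. It is a straight proportionality, offered for reporting, not a
substitute for proper clock models.

# GO enrichment

The DAG is read from OBO 1.2 (`id`, `name`, `namespace`, `is_a`, `alt_id`,
`is_obsolete`; other relationship types are ignored), validated acyclic by
topological layering. Annotations propagate to all ancestors (true-path
rule). Genes with no propagated annotation are dropped from both the study
and universe totals so every 2×2 table is well defined.

The per-term statistic is the hypergeometric upper tail
(`fisher_tail()`). Two scores are reported:

* **classic** — every term tested independently on propagated counts;
* **elim** — terms processed children-before-parents (decreasing depth);
  when a term's current p-value falls below `elim_alpha = 0.01`, its study
  genes are removed from all ancestors' gene sets before those are tested.
  This decorrelates the hierarchy: an ancestor significant only because of
  one enriched descendant loses that signal. topGO's default hybrid
  `weight01` scoring is not reimplemented; elim is implemented because it
  has a precise published definition and is testable by construction.
  Recovery of
  planted terms, not p-value equality with any particular topGO version, is
  the acceptance standard. Reported counts are the pre-elimination counts,
  as users of DAG-aware enrichment tools expect.

No multiple-testing correction is applied to enrichment p-values; terms are
thresholded at raw p < 0.05, the convention for DAG-aware scores. Those
scores are decorrelated, not multiplicity-adjusted, and should be read as
rankings.

# Repertoire sets and branch transitions

Presence/absence matrices come from Roary-style CSVs: presence is "cell
nonempty", strain columns are either given explicitly or taken as
everything after the fixed 14-column metadata preamble. Core sets
(intersection), pangenomes (union), Venn region counts (every gene assigned
to exactly one membership signature), and shared fractions
$|A \cap R|/|R|$ follow directly. Paralog multiplicity inside a cell is
deliberately ignored: repertoire comparisons of this kind are set counts.

For branch transitions, each adjacent pair of an ordered strain chain
carries a bundle (one concatenated pairwise alignment plus gene intervals,
optionally a per-pair Ks cutoff). The pipeline composes the scan with
enrichment, taking each quantile set as the study against the universe of
all scored, annotated genes of that pair — the universe for such a test is
a modelling choice, and "scored and annotated" is the only one under which
every tested term's 2×2 table is well defined. Enriched terms of a chosen class are classified `universal`
(present in every pair's set), `unique:<pair>`, or `shared:<pairs>`. A
"clade core" pseudo-strain (e.g. comparing the shared gene set of two
sister strains against the next outgroup) is expressed by how the user
builds that pair's bundle; no special casing is needed.

# Synthetic data: what it emulates, and what it does not

* `simulate_codon_pair()` plants substitutions per codon position using the
  estimator's own site definitions: a position with synonymous site
  fraction $f$ receives a synonymous difference with probability
  $p_s f$ and a nonsynonymous one with probability $p_n (1-f)$, where
  $p_s, p_n$ invert the Jukes–Cantor correction at the target $K_s$ and
  $K_a$. All events are placed on one lineage (the other sequence is the
  ancestor); expected NG86 estimates are unchanged by this and the
  construction stays exactly inverse to the estimator. Events creating a
  stop codon are resampled. Because the generator matches the estimator's
  site accounting, recovery tests are well posed: across 50 replicates of
  2,000 codons, planted ratios in [0.02, 0.5] are recovered within 0.05
  mean absolute error.
* `simulate_ortholog_panel()` assigns each gene to one category with that
  category's planted ratio and GO terms, recording the truth table.
* `simulate_go_universe()` grows a rooted acyclic is_a graph, one or two
  parents per term, depth-capped.
* `simulate_community_matrix()` draws independent lognormal taxon columns
  and appends a symbiont column
  `corr_strength * host + (1 - corr_strength) * noise_sd * sd(host) * e`,
  floored at zero. Scaling the noise by the host column's standard
  deviation makes `corr_strength` span pure-host (1) to pure-noise (0)
  regardless of abundance scale.
* `simulate_contig_set()` draws GC from normals clipped to [0, 1],
  coverage from truncated normals, and lengths log-uniform on
  [500, 60,000] bp.

The generators deliberately do **not** emulate: indels or alignment error,
codon-usage or GC bias within genes, rate variation along a gene,
read-level sequencing noise, compositional (relative-abundance) structure
or phylogenetic correlation among community columns, or chimeric contigs.
Passing the recovery tests therefore demonstrates that the estimators and
set logic are correct under their own assumptions — not that real
assemblies meet those assumptions.

# Numerical and degenerate-input choices

* Jukes–Cantor saturation, zero synonymous sites in a window, or $K_s = 0$
  yield `NA` ratios that are excluded from ranking but kept in reports.
* Quantile sets use ceiling sizes with gene-id tie-breaks; best-hit ties
  break by evalue then subject id; the longest-contig set breaks length
  ties by contig id — all orderings are total, so results are
  deterministic.
* All generators take explicit integer seeds and are byte-reproducible.
* GC of an all-N sequence, empty study sets, empty reference sets,
  sub-3-observation correlations, and out-of-range p-values raise immediate
  errors rather than propagating `NaN`s.

Test problem sizes (e.g. 60-gene panels of 1,000 codons over 20 seeds for
partition/enrichment recovery, 200 replicates for FDR control, the full
61×61 codon-pair oracle sweep) were chosen so each property is measured
with comfortable statistical margin while the whole suite stays quick to
run; they are package choices, stated here so they can be scaled up.

# Known limitations

* NG86 with JC correction underestimates divergence under strong
  transition/transversion bias relative to ML codon models; rank-based
  downstream results are insensitive, absolute ratios less so.
* The elim scores are not identical to `weight01` scores, so term lists
  near the significance boundary can differ from analyses run with that
  scoring.
* The t-approximation p-values for rho are approximate for n below ~10 and
  in the presence of many ties.
* The triage filters assume coverage is supplied per contig; computing
  coverage from alignments is out of scope.
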