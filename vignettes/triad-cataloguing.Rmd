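---
title: "Cataloguing homoeologous gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing homoeologous gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadkit)
```

## The problem

Hexaploid bread wheat carries three diploid subgenomes (A, B and D), so most
genes exist as a *homoeolog group*: ideally one copy per subgenome (a
**triad**, composition 1:1:1), but deletion and tandem duplication also leave
**diads** (one subgenome missing), **tetrads** (one subgenome duplicated,
e.g. 1:1:2) and **singletons**. A genome-wide catalogue of a gene family in
such a genome needs, beyond the usual identification and curation steps, a
layer of subgenome-aware bookkeeping: which copies are homoeologs of each
other, how to name them so homoeology is visible in the name, and how the
copies divide expression among themselves. `triadkit` implements that layer
as a reusable, testable pipeline, developed around the wheat
nitrate-transporter families (NPF, NRT2, CLC and SLAC1/SLAH) whose complete
curated catalogue ships with the package as a plain-text reference table.

## Candidate curation

Candidates arrive as two evidence streams — retrieval by conserved-domain
identifier and an HMM profile search — both performed upstream; `triadkit`
consumes their hit tables. `merge_evidence()` takes the set union by gene ID,
recording dual evidence and keeping the better confidence call.
`curate()` then applies deterministic rules: drop low-confidence candidates,
collapse splice variants onto the canonical gene (explicit `canonical_id` or
a stripped `.n` transcript suffix), collapse duplicate IDs, and drop
candidates without an annotated gene model. Each removal is written to a
report so a human can review what an upstream "manual curation" would have
touched; the operation is idempotent. We deliberately detect duplicates by
gene ID rather than sequence identity: sequence-level redundancy calls are
not reproducible without the alignment parameters that produced them, and a
deterministic rule keeps `curate(curate(x)) == curate(x)`.

## Homoeolog grouping from gene trees

Groups are inferred per subfamily from a gene tree plus gene locations
(`infer_homoeolog_groups()`). A clade is a *candidate group* when:

* it has 2–4 leaves, none on an unplaced scaffold;
* subgenome multiplicity is at most 1 for 2–3 leaves, and exactly
  `{1, 1, 2}` for 4 leaves;
* for 4 leaves, the two same-subgenome copies are **sister leaves** — a
  tetrad records a tandem duplication, and a tandem pair is monophyletic.
  Without this restriction a 4-leaf clade can swallow an unrelated
  same-subgenome gene that happens to branch next to a triad, which both
  inflates tetrad counts and (as our exhaustive-search test shows) breaks
  the optimality of greedy extraction;
* all members share one chromosome group. Clades rejected *only* by this
  rule are logged in a `conflicts` attribute rather than silently dropped,
  because real catalogues contain such cases and they deserve eyes.

Candidates are extracted greedily. Because clades of one tree are laminar
(nested or disjoint), conflicts are only between a clade and its
sub-/super-clades; ties are broken deterministically — more distinct
subgenomes first, then the smaller clade, then the lexicographically
smallest member ID — which favours canonical triads over larger composites.
Remaining leaves become singletons, and genes on unplaced scaffolds are
always singletons (they cannot satisfy the chromosome-group rule). Bootstrap
support values are ignored: no defensible support threshold exists for this
decision, so the topology is taken at face value and the chromosome-group
constraint acts as the error brake. The test suite verifies on trees of up
to 12 leaves that this greedy procedure groups exactly as many genes as an
exhaustive search over all disjoint candidate sets.

## Nomenclature

Names render as `<prefix><subfamily>-<chromosome group><subgenome><serial>`
(e.g. `TaNPF1-3A1`), with group IDs `<prefix><subfamily>-<T|D|S|TT><ordinal>`.
Two rules that the rendered catalogue only shows implicitly are made
explicit here:

* serial counters run per (subfamily, chromosome group) and are **shared
  across subgenomes**: each group consumes one serial for all its members,
  and a group missing a subgenome still advances the counter — which is why
  a run of A-only singletons after a triad numbers `4A2…4A6`;
* ordering is physical: chromosome group first (unplaced last), then the
  leftmost member position, then the smallest member ID, so names never
  depend on input file order. Whether published catalogues order by position
  or by accession number is usually moot (the two coincide in IWGSC-style
  IDs); we fix position as the rule.

Duplicated within-subgenome copies get `x`/`y` suffixes by ascending start
position. Unplaced members are named from a separate per-subfamily `Un`
counter. The species prefix defaults to `"Ta"` and is configurable, so the
scheme transfers to other allopolyploids.

## Expression bias on the ternary simplex

For each triad and tissue, TPM values are aggregated over stages and
cultivars by **maximum** (the pooling a "expressed anywhere in this tissue"
reading implies; it is also robust to unbalanced sampling between
cultivars), then filtered: a (triad, tissue) pair is kept when
`tpm_A + tpm_B + tpm_D >= 1` TPM. The threshold applies to the triad sum by
default — the natural reading of "triads below one TPM" — with a
`per_homoeolog` switch for sensitivity analysis. Retained triples are
normalized to fractions `(f_A, f_B, f_D)` on the 2-simplex and assigned to
the nearest of seven centroids by Euclidean distance:

| category | centroid |
|---|---|
| Balanced | (1/3, 1/3, 1/3) |
| A/B/D dominant | (1,0,0) / (0,1,0) / (0,0,1) |
| A/B/D suppressed | (0,1/2,1/2) / (1/2,0,1/2) / (1/2,1/2,0) |

The suppressed centroids place the silenced subgenome at zero and split the
remainder equally. These coordinates are the single largest imported
assumption in the package: the category *names* are standard in the wheat
expression literature but coordinates are rarely restated, so we fix them
here and expose `bias_centroids()` so users can see (or test against)
exactly what is used. Ties are broken in the fixed order Balanced,
A/B/D dominant, A/B/D suppressed. The classifier is scale-invariant by
construction and permutation-equivariant in the subgenome labels; both are
enforced as property tests. All-zero triples are a hard error — the filter
must remove them first — because silently mapping 0/0 to a category would
manufacture data.

Tissue specificity is called per gene over three tissue classes (root,
leaf/shoot, spike/grain, again pooling by maximum): `not_expressed` below
1 TPM everywhere, `<class>_specific` when exactly one class reaches the
threshold, `ubiquitous` otherwise.

## SNP-to-gene proximity

`distance_mb()` is plain integer arithmetic, `|gene - snp| / 1e6`, exact at
six printed decimals for genomic coordinates; cross-chromosome queries are
an error rather than a large number. `find_nearby_genes()` reports all
same-chromosome pairs within a window. "Close proximity" has no universal
definition, so the window is a required, logged parameter; the default of
15 Mb covers the distances typically reported between marker–trait
associations and candidate genes on wheat's ~0.5–1 Gb chromosomes. The
representative gene coordinate is the annotated start by default (the
convention the packaged panel uses), with a nearest-boundary option for
general use. Cluster hits published as ranges (`TaNPF5-3B3-TaNPF5-3B10`)
expand over consecutive serials after dash normalization; endpoints that do
not align in subfamily/chromosome/subgenome are kept verbatim with a
warning so typographic quirks surface as diagnostics, not silent fixes.

## The synthetic-data generator

Every stage must be testable without downloads, so `simulate_catalog()`,
`simulate_expression()` and `simulate_snps()` generate a genome with planted
ground truth. The generator emulates:

* a 3-subgenome genome with 7 chromosome groups plus an `Un` pseudo-
  chromosome (600 Mb chromosomes, genes of 1–25 kb, 2–8 exons; NRT2-family
  models are intronless, matching that family's known structure);
* homoeolog groups drawn from the category mix of the packaged wheat
  catalogue's summary table, 103:26:2:48 over triad/diad/tetrad/singleton
  (about 19% of singletons sit on `Un`, again following the catalogue);
  tetrad copies are placed within 100 kb as a tandem pair and appear as
  sister leaves in the subfamily tree, in which every planted group is a
  clade;
* triad expression drawn per (triad, tissue): a bias category (default 60%
  balanced, the remainder uniform — the balanced share reported for wheat
  tissues sits in the high fifties to mid sixties of percent), homoeolog
  fractions from a Dirichlet distribution centred on the category centroid,
  and a log-normal total magnitude (median 10 TPM, log-sd 1, matching the
  1–10^2 TPM range typical of these families) added to three times the
  detection threshold so an expressed triad always passes the filter;
* per-group tissue-specificity classes (defaults 56% ubiquitous, 5/3/4%
  root/leaf-shoot/spike-grain specific, 32% not expressed, echoing the
  published family-level fractions); unexpressed tissues draw below
  `threshold / 6` per member so even a triad sum stays under threshold;
* SNPs either planted at a uniform offset within the window of a random
  gene's start (true distance recorded) or placed outside the window by
  rejection, so window recovery is exact by construction.

Noise is parameterized by a single Dirichlet `concentration`:
`Inf` is the exact zero-noise limit (fractions equal the centroid; dominant
categories give literal zeros for the other homoeologs). For finite
concentration the Dirichlet shape is `concentration * centroid + 0.01`; the
small additive term keeps zero-coordinate components from being frozen at
zero, so "noise" means noise on every coordinate, while vanishing as
concentration grows. A single master seed drives everything; each stage
derives its own stream as `(seed * 97 + k * 1009) mod (2^31 - 1)`, so stages
are reproducible in isolation and identical configuration gives
byte-identical artifacts (the pipeline manifests record md5 checksums to
audit exactly that).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: no sequences (no alignment or search scores, so
curation confidence is an input, not simulated), no expression correlation
across tissues or stages (replicates within a tissue share one draw), no
mapping bias between subgenomes (a known confounder of homoeolog expression
estimates), no LD structure behind the SNP panel, and gene trees are exactly
compatible with the planted groups (no discordance, no paralog
interleaving beyond what the category mix creates). Recovery rates measured
on simulations are upper bounds for real catalogues.

## Problem sizes and numerical choices

The shipped tests run the pieces at desk scale: recovery of planted bias
categories uses 125 triads x 4 tissues = 500 classifications per
concentration setting; grouping oracle equivalence enumerates all disjoint
candidate-clade sets on trees of at most 12 leaves; the full pipeline tests
simulate a few hundred genes. These sizes were chosen so the entire suite
and the acceptance script each finish in seconds while keeping every
assertion exact (truth recovery at zero noise is equality, not tolerance).
Percentages are reported rounded to one decimal, the convention of the
catalogues this package mirrors; distances print at six decimals and are
computed on raw integers so no floating-point rounding is visible at that
precision.

## Known limitations

* The packaged reference tables are hand transcriptions of published
  catalogue tables; they preserve the published typography (including a few
  tokens that do not parse as canonical gene names, and range rows whose
  printed [min, max] distances refer to unprinted cluster-member
  positions). Summaries computed from them count what the tables actually
  contain.
* A small number of published name assignments contradict the stated naming
  scheme (e.g. groups whose members sit on different chromosome groups than
  their names claim). `triadkit` enforces the scheme and logs such
  conflicts rather than reproducing them.
* Differential-expression analysis (e.g. nitrogen starvation/recovery
  response calls) is out of scope: it requires replicate-level data and an
  explicit significance criterion, neither of which this package models.
* Grouping quality is bounded by the input trees; `triadkit` infers no
  trees and ignores bootstrap support.
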