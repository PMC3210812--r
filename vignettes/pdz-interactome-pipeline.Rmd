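---
title: "From array spots to a motif-annotated PDZ interactome"
author: "pdzscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From array spots to a motif-annotated PDZ interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzscreen)
```

`pdzscreen` implements the computational arc of a PDZ-domain interactome
screen: duplicate-spot hit calling on single-channel protein microarrays,
assembly of an interactor list from multiple evidence sources,
annotation-similarity clustering of that list, and C-terminal motif
analysis. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic generators do and do not
emulate, and the numerical choices and limitations a careful user should
know about.

## 1. Hit calling on duplicate-spot arrays

### Model and assumptions

A functional protein array prints each protein twice per slide; the screen
is run on replicate slides. The processing chain per slide is:

1. **Background correction.** `net = max(fg − bg, 0)`, using the
   scanner's local background estimate. Flooring at zero acknowledges that
   a spot cannot have negative signal; it only affects spots already
   indistinguishable from background.
2. **Spatial de-trending.** Single-channel arrays show smooth spatial and
   print-run drift. `lowess_detrend()` fits a locally weighted regression
   of `log2(net + 1)` on the row-major print-order index
   (`frac = 0.3`, 3 robustifying iterations by default) and subtracts it,
   re-centring at the median fit. Log scale is used because fluorescence
   noise is approximately multiplicative. The smoother span is a
   bias/variance trade-off: 0.3 tracks plate-scale drift while leaving
   isolated strong binders untouched (their influence is also suppressed
   by the robustness iterations). For recovery checks on very small
   slides a wider span (e.g. 0.5) is less sensitive to a pair of extreme
   spots inside one smoothing window.
3. **Concentration adjustment.** Printed spots differ in deposited protein
   amount, and binding signal grows sublinearly (roughly with the square
   root of concentration, saturating). `concentration_adjust()` removes a
   locally weighted fit of the de-trended signal on `log10(conc)`
   (`frac = 0.5`), leaving the residual; when all concentrations are
   equal this degenerates to centring. Blank spots (`conc = 0`) are
   excluded from every fit and are never callable.
4. **Standardisation.** `slide_zscores()` computes
   `z = (adj − mean(adj)) / sd(adj)` over all non-blank spots of the
   slide (sample standard deviation, divisor n − 1). A robust variant
   (median and 1.4826 × MAD) is available for slides where strong binders
   inflate the scale; the classical estimator is the default because the
   hit rule was defined against an ordinary Z-score.

A protein is a **hit** on a slide when its duplicate pair has
`mean(z) > 3` and a replicate coefficient of variation `< 0.5`, both
strict inequalities, so values exactly at a threshold are non-hits. The CV
is computed on the concentration-adjusted signals back-transformed to the
linear scale (`2^adj`) with the sample standard deviation, i.e.
`|s1 − s2| / (sqrt(2) · mean)`; a configuration switch allows raw or
net signal instead, since quantification software does not always document
its choice. CV is conventionally a linear-scale statistic, which is why the
log-scale `adj` values are back-transformed first. Pairs with zero mean
signal get `CV = Inf` and are never hits. The screen-level result is the
intersection of the per-slide hit sets (`reproducible_hits()`).

Decisions are invariant to re-ordering spots in the file, to swapping
replicate labels, and to multiplying all fluorescence by a positive
constant (Z and CV are both scale-free).

### What the array generator emulates

`simulate_array_experiment()` draws, for each spot, a log-normal
background (`meanlog = log(200)`, `sdlog = 0.35` by default) modulated by a
smooth spatial surface (sum of one row and one column sinusoid, amplitude
0.3 of background, identical for the two members of a duplicate pair), and
adds specific signal

`signal = base · effect · sqrt(conc)-factor · trend · noise`

where `base` equals the expected background, `effect` is the planted fold
(default 8) for the chosen binders and 1 otherwise, the concentration
factor is normalised to mean 1 over the log-uniform concentration draw
(4–250 ng/µL, the usual printed dilution range), and `noise` is log-normal
with unit mean and CV 0.10. The reported local background equals the
realised background draw, so the expected net signal of a planted binder
is `effect` times the local background trend, and the planted-to-background
moment ratio is recoverable from the generated tables — this is what the
parameter-recovery tests check. Because the non-planted effect is 1, a
"null" screen has every protein at background level and the Z > 3 rule
calls essentially nothing.

The generator does **not** emulate scanner saturation, optical bleed,
spot-shape segmentation artefacts, or inter-slide intensity scaling;
passing recovery tests therefore demonstrates the statistical logic of the
caller, not robustness to those instrument effects.

## 2. Interactor-list assembly and enrichment

Array hits can derive from cDNAs that encode no annotated protein.
`filter_annotated()` partitions a roster by record status (`annotated`
versus 3′-UTR constructs, withdrawn records, suppressed non-coding
records, and nonsense-mediated-decay candidates) and returns a removal
tally that always conserves the input count. `merge_sources()` unifies
records by numeric gene identifier — never by symbol, and never across
species automatically, since ortholog conflation should be an explicit
curation step — taking the union of provenance tags and resolving field
conflicts first-seen (logged). `overlap_counts()` gives pairwise
intersection counts between screens' identifier universes, the quantity
behind statements like "half the proteins in one library appear in
another".

`domain_enrichment()` compares the proportion of hits in an annotation
category with the array background and reports percentages rounded
half-even to one decimal (so 11/62 prints as 17.7 and 448/8000 as 5.6).
The published analyses of this kind reported proportions only; the
attached upper-tail hypergeometric probability is a convenience this
package adds, and is labelled as such.

## 3. Clustering by GO annotation similarity

### simUI and its matrix

The induced annotation set of a protein in an aspect (BP, MF or CC) is its
direct GO terms plus all ancestors through `is_a` and `part_of` edges up
to the aspect root; `part_of` inclusion matches the classical
induced-graph definition and can be switched off. All evidence codes are
accepted by default (IEA exclusion is a flag), because the underlying
clustering method stated no evidence filter. The simUI similarity is the
Jaccard ratio of two induced sets; `1 − simUI` is a metric in [0, 1].
Proteins with no annotation in an aspect are excluded from that aspect's
matrix with a logged message rather than an error — in real interactomes a
few members always lack annotation, and they should drop out of the
clustering, not halt it.

### PAM, silhouette, and choosing k

`pam_cluster()` is a deterministic partitioning-around-medoids: BUILD
greedily adds the medoid that most reduces total
dissimilarity-to-nearest-medoid; SWAP repeatedly applies the single
medoid/non-medoid exchange that most lowers the cost until no exchange
improves it. All ties break toward the lowest point index, so results are
bit-reproducible without randomness (a `seed` argument is accepted for
interface symmetry but unused). The number of clusters is chosen by
maximum average silhouette width over `k = 2 … min(15, n − 1)`
(`select_k()`), ties toward the smaller k; singleton clusters contribute a
silhouette of 0.

A known, documented limitation: BUILD + single-swap descent is a local
search. On small unstructured random matrices it lands in a strictly
local optimum a few percent of the time (the reference `cluster::pam`
implementation behaves identically on the same instances); on matrices
with genuine block structure — the regime the method is used in — it
recovers the optimal medoids essentially always, and the package's
planted-group recovery tests run at 100% ARI.

### Networks

`cluster_network()` keeps edges with dissimilarity **at or below** the
aspect threshold (0.4 for BP and MF, 0.3 for CC, overridable) — the rule
"remove edges above the threshold" read strictly — and assigns a display
width decreasing linearly in dissimilarity so near-identical proteins get
thick edges. One medoid per cluster is flagged and sized larger. Export is
GraphML (via igraph, with node and edge attributes) and SIF plus a
node-attribute table. Cluster labels default to the medoid's direct term
with the highest information content over the clustered set
(`IC = −log` induced frequency; the root has IC 0), with a manual override
table for curated names.

### What the GO generator emulates

`simulate_go_corpus()` builds one namespace with a single root and one
complete subtree per latent group (defaults: 3 groups × 8 proteins, depth
3, branching 3 — 13 terms per subtree), and gives each protein 3 direct
annotations from its own subtree, each replaced by a draw from another
group's subtree with probability `noise_p` (default 0.05). These defaults
give within-group simUI clearly above between-group simUI while keeping
matrices small enough that the whole k-selection path runs in seconds.
Real GO is deeper, multi-parented and unevenly annotated; recovering
planted groups here validates the simUI/PAM/silhouette machinery, not
robustness to real GO's annotation bias.

## 4. C-terminal motif analysis

Positions follow PDZ ligand convention: 0 is the C-terminal residue,
counting −1, −2 leftward. `classify_cterm()` applies, in precedence
order: terminal-cysteine (position 0 = C, the non-canonical ligand class
some PDZ domains select), Class I (S/T at −2 and hydrophobic 0),
hydrophobic-0, other. The default hydrophobic set is
{A, F, G, I, L, M, V, W, Y}: glycine is included because small Gly-ended
termini are counted with the major hydrophobic-0 class in practice, and
cysteine is excluded because it forms its own class; the set is an
argument for users who draw the line elsewhere. The classifier covers the
three classes the analysis needs; arbitrary extra motif tables can be
expressed by the caller on top of the returned residue columns.

`compare_to_wildtype()` distinguishes natural termini (token `WT` or an
identical sequence), artificial tails (differing sequence — the signature
of a partial cDNA construct), and untranslated records.
`conservative_match()` compares the final three residues under standard
physicochemical substitution groups ({S,T}, {A,V,L,I,M}, {F,Y,W},
{K,R,H}, {D,E}, {N,Q}, {C}, {G}, {P}); the groups are an argument because
"conservative" is not uniquely defined, which also makes match counts
against published lists soft rather than exact targets.
`binding_site_identity()` applies the specificity-transfer rule: percent
identity over the 17 ligand-contacting residues, transfer predicted
strictly above 70%. The 17-residue site strings are inputs; mapping them
out of full domain sequences requires a structural alignment outside this
package's scope.

The termini generator plants Class I and terminal-Cys motifs at exact
floor-rounded counts. When any planting fraction is positive, background
sequences are drawn to avoid all motif signatures so that planted classes
are exactly recoverable; with no planting requested, sequences are uniform
over the twenty amino acids (so, e.g., a terminal cysteine appears at the
binomial 1/20 rate). This duality keeps both exact-recovery tests and
null-frequency tests meaningful.

## 5. Numerical choices, degenerate inputs, problem sizes

* LOWESS fits use `stats::lowess`; fitted values are mapped back to data
  points by interpolation (exact at the data points, ties averaged).
* Zero-variance slides, fewer than 10 non-blank spots, fewer than 3
  annotated proteins, k outside range, and proteins with other than two
  replicate spots are errors, not silent results.
* Identical printed concentrations degrade concentration adjustment to
  centring, with a message.
* PAM costs compare with a `1e-12` slack so floating-point noise cannot
  cycle the SWAP phase; cluster indices and all tie-breaks are
  deterministic.
* Reported enrichment percentages use R's round-half-even at one decimal;
  the underlying counts are returned alongside.
* Test and validation problem sizes were chosen to exercise every code
  path quickly: 200-protein slides with 10 planted binders over 20 seeds
  for caller recovery, 24-protein/3-group corpora over 20 seeds for
  k-selection recovery, and n ≤ 8 instances for exhaustive-oracle
  comparisons. These sizes are the package's validation conditions, and
  the full synthetic pipeline runs in well under a minute on one core.

## 6. Known limitations

* The hit caller starts from quantified spot tables; no image analysis.
* The vendor software's exact LOWESS geometry, CV basis and Z population
  are not published; this package documents and exposes its own choices
  (print-order de-trending, adjusted-linear CV with n − 1, whole-slide Z)
  as configuration, so results on real slides may differ from historical
  vendor output in reproducible ways.
* simUI clustering inherits GO's granularity: adjacent clusters of
  related function blur into each other, and annotation-poor proteins
  drop out per aspect.
* PAM is a local search (see above); silhouette-based k selection shares
  silhouette's preference for compact, balanced clusters.
* Cross-species identifier unification is deliberately manual.
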