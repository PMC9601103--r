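---
title: "Scoring metabolic capability in MAGs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metabolic capability in MAGs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magmetab)
```

`magmetab` scores metabolic capability in metagenome-assembled genomes
(MAGs) from gene functional annotations. This vignette explains the model,
the parameters that matter, the numerical and design choices made where the
problem left room, and what the package's validation does and does not
demonstrate.

## The module model

A KEGG metabolic module is a Boolean expression over gene-family
accessions. We parse the standard DEFINITION dialect into a tree with six
node kinds: `LEAF` (one accession), `AND` (consecutive reaction steps,
written with spaces), `OR` (alternative routes, written with commas),
`COMPLEX` (`+`-joined subunits forming one step), `OPTIONAL`
(`-`-prefixed non-essential components), and `GAP` (`--`, a reaction with
no known gene).

**Operator precedence.** The comma binds looser than the space, and
`+`/`-` bind tighter than both; parentheses override. This is the reading
under which published definitions such as
`(K01007,K01006) K01595,K01959+K01960,K01958` mean what they
biologically must: a choice between whole routes (a two-step
phosphotransferase route versus a one-step carboxylase), not a choice of
first steps followed by mandatory leftovers. We verified this reading
against several real multi-route definitions before freezing the grammar.

**Completeness.** For gene set $G$, completeness is the best fraction of
satisfied steps over all alternative paths:

$$C(G) \;=\; \max_{P} \frac{\#\{\,s \in P : s \subseteq G\,\}}{|P|}$$

where each step $s$ is the set of accessions that must *all* be present.
Three grain decisions follow KEGG's semantics conservatively:

* a **complex is one step and binary** — it counts only when every
  required subunit is present. Fractional subunit credit would blur the
  step grain; for sensitivity analysis a gene-counting mode
  (`count_mode = "genes"`) scores distinct accessions on the best path
  instead.
* an **optional component counts in neither numerator nor denominator**:
  genomes lacking a dispensable subunit should not be penalized.
* a **gap step can never be satisfied but stays in the denominator**: an
  undefined reaction caps attainable completeness below 1, never above.

**Presence threshold.** A metabolism is called present when
$C \ge 2/3 - 10^{-9}$. The familiar "67%" criterion is interpreted as the
exact fraction two-thirds: 2 of 3 steps passes, and the epsilon guard only
protects the floating-point comparison at exact boundaries. The threshold
is a parameter (`threshold`, in (0, 1]) everywhere it appears.

## The evaluator: exact frontier propagation

The obvious recursive rule — AND sums its children's (satisfied, total)
pairs, OR keeps the child with the best ratio — is **not correct**: the
locally best ratio can be globally wrong. With
`AND(OR(x, long), pad)` where `x` scores 1/1, `long` scores 9/10 and
`pad` adds 0/10, the greedy choice gives 1/11 while the true optimum is
9/20. The evaluator therefore carries, for every subtree, the *Pareto
frontier* of achievable (satisfied, total) pairs: OR takes the union of
frontiers, AND their Minkowski sum, and dominated pairs (another pair
with at least the numerator at no more denominator) are pruned — pruning
is safe because domination survives addition. Frontier sizes are bounded
by the subtree's step count, so this is cheap, and all comparisons use
integer cross-multiplication: no floating-point drift can reorder two
ratios. A unit test pins the counterexample above, and the suite checks
exact agreement with exhaustive path enumeration on hundreds of random
trees.

**Tie-breaking.** Equal ratios resolve toward fewer total steps, then
toward the leftmost alternative in tree order, making the reported
witness path deterministic. (Path enumeration is still provided —
`enumerate_paths()`, capped at `max_paths = 10000` with an explicit
truncation flag — but the default scoring never depends on it, so
truncation cannot change scores.)

**Degenerate modules.** A module whose only routes are entirely optional
has no scorable steps. It is reported with completeness 0, zero total
steps and `degenerate = TRUE` rather than being called trivially present;
callers can decide what an all-optional module means for them.

## Annotations, filtering, quality

Annotations arrive as anvi'o-style exports: a functions table, a
contig-to-bin map, and per-MAG metadata. Genes on unmapped contigs go to
a reserved `UNBINNED` pseudo-MAG (excluded from pipeline scoring) rather
than being dropped silently.

**E-values.** Module detection applies **no e-value filter by default**:
the only cutoff the underlying screening convention states is the marker
screen's `< 1e-100`, and silently filtering everything would change
heatmap-style results. Per-source cutoffs are opt-in
(`evalue_thresholds`), always strict (`<`), hence idempotent and
order-independent.

**Quality bands.** High requires completion > 90 and redundancy < 10;
medium covers completion in [42, 90] and redundancy in [0, 11]. The two
published bands overlap nowhere (high needs completion above 90, medium
at most 90), but the medium band's redundancy ceiling (11) exceeding the
high band's (10) leaves completion > 90 with redundancy in [10, 11]
formally unassigned; we apply the high rule first and leave that corner
unclassified — the conservative reading, since such a genome meets
neither stated band verbatim.

## Marker screens

The nitrogen-fixation screen demands KOfam hits to both nifH (K02588)
and nifD (K02586) with e-value strictly below `e_max = 1e-100`.
COG1348 hits are surfaced in an advisory field but never count as
evidence, because that COG also contains protochlorophyllide reductase
subunits — homologs of nifH from pigment synthesis. Whether the two
markers must share a contig or merely a MAG is genuinely ambiguous in
the "contains both genes" phrasing; the default is same-MAG, with
`require_same_contig = TRUE` as the strict variant. Accessory genes
(nifD COG2710, PII COG0347, nifB COG0535) are reported only from contigs
that carry a qualifying nifH hit — co-location is the evidence, so no
cross-contig inference is attempted. COG labels written without leading
zeros ("COG 347") are accepted and compared numerically.

Gene suites use the ANY rule with field-wise EC wildcard matching
(`1.4.*` matches `1.4.1.2`, not `1.14.13.25`). An extractor for
`(EC x.x.x.x)` tags embedded in free-text function fields exists but is
off by default: embedded tags are annotation-pipeline folklore, not
evidence of a dedicated EC assignment. The shipped suite file is an
editable example — the ammonification-hydrolase EC families are the
standard C–N-cleaving classes, while the DOM transporter lists are
synthetic placeholders (K5xxxx codes) for a curated catalogue the user
should supply.

## The synthetic generator

The generator emulates the *annotation-table level* of a study: per-MAG
gene rows with sources, accessions and e-values, a bin map, and sample
metadata. It plants (i) module completeness — choosing a path and
marking $\lceil f \cdot \text{steps} \rceil$ full step-sets present, so
the realized fraction (reported in the ground truth) is the ceiling of
the target; (ii) suite matches, instantiating EC wildcards with concrete
numbers; (iii) diazotrophs (both markers plus same-contig accessory
genes); and (iv) the COG1348 homolog trap without the markers.

Choices that keep the ground truth *exact*:

* **Disjoint accession pools.** Plantable synthetic modules use unique
  KOs below K10000 (skipping K02586/K02588), suites K5xxxx, distractors
  K9xxxx/COG9xxx. Disjointness is asserted at generation time and a
  violation is an error, because overlapping pools would silently
  falsify the ground truth.
* **Equal-length alternative paths.** In plantable modules, OR branches
  are single steps, so every path has the same length and the planted
  $k/\text{total}$ is both attainable and maximal.
* **E-value model.** Planted hits draw $\log_{10} e \sim U[-180, -20]$;
  half the distractors are near-threshold decoys on $U[-90, -5]$. The
  planted nitrogenase markers draw from $U[-180, -110]$ — below the
  screen cutoff — because `plant_diazotroph = TRUE` must *mean* a
  detectable diazotroph; letting marker e-values straddle the cutoff
  would make the planted truth stochastic. These distributions exist to
  exercise thresholds and routing; they are not a model of real HMM
  score distributions.

One pseudo-random stream per MAG spec, seeded explicitly (derived from
the community seed unless given), makes all outputs byte-reproducible
from `(specs, seed)`.

**What passing these tests shows — and does not.** Exact recovery on
synthetic communities validates the logic: parsing, path algebra,
threshold semantics, routing, screens and matrix assembly. It says
nothing about annotation quality on real data: real KOfam/COG calls have
correlated errors, shared accessions across real modules, copy-number
effects and incomplete binning, none of which the generator simulates —
deliberately, since everything upstream of the annotation table is out
of scope here.

## Validation problem sizes

The shipped suite validates round-tripping on 1,000 random definition
trees plus fixture files; evaluator-versus-enumeration agreement on 500
random trees of up to 12 leaves with random presence sets (exact integer
comparison); threshold semantics and monotonicity under 1,000 random
accession additions; a 50-seed community sweep with exact
ground-truth recovery including zero homolog-trap false positives;
strict-boundary behavior at exactly 1e-100; exhaustive quality-band
disjointness on a 0.5-step grid over $[0,100]^2$; and byte-identity of
repeated pipeline runs. These sizes were chosen to exercise each
property densely while keeping the default check fast on one CPU.

## Known limitations

* Completeness is presence/absence at the step grain; no
  abundance-weighting or copy-number awareness.
* Accessions compare as strings (KO/EC) or numerically (COG); no
  ortholog-mapping between sources, so a module defined over KOs is
  invisible to a COG-only annotation set.
* The `genes` counting mode maximizes over enumerated paths and is a
  lower bound if enumeration truncates (a warning says so); the default
  `steps` mode is always exact.
* The grammar covers DEFINITION strings only — no module hierarchies,
  reaction cross-references, or signature modules.
* Quality bands are consumed metadata; the package does not estimate
  completion or redundancy from marker genes.
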