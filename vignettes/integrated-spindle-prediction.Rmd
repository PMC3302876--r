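---
title: "Integrated evidence scoring of spindle-proteome candidates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated evidence scoring of spindle-proteome candidates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spip)
```

## The problem

The mitotic spindle is a microtubule-based machine that segregates
chromosomes during cell division. Its composition is hard to pin down
experimentally: many components act transiently or regulate the
structure rather than build it, so any single assay — proteomics,
siRNA screening, literature curation — sees only part of the picture.
`spip` scores every protein in a proteome for membership in such a
module by combining orthogonal evidence channels, each seeded by a set
of curated known members (the "seeding set"), into a single unified
p-value per candidate.

The channels fall into three approaches:

* **Literature mining (LM)** — direct (`d-COCITE`) and indirect
  (`i-COCITE`) co-citation specificity over a literature interaction
  network restricted to physically tagged relations.
* **Neural-network inference (NNI)** — `MLNN`, a feed-forward ensemble
  over precomputed protein features.
* **Domain and genomic context (DGC)** — domain fusion (`CODAcath`,
  `CODApfam`), domain over-representation (`DORA`),
  homology-inherited interactions (`hiPPI`), expression correlation
  (`GECO`) and ontology semantic similarity (`GOSS`).

## Channel models

### Co-citation specificity

For a candidate $i$ and reference set $R$, the direct score uses
$n_{ri}$ (edges between $i$ and reference members), $N_r$ (total degree
of the reference members touching $i$) and $N_i$ (degree of $i$). The
indirect score extends this to length-2 paths through connector
proteins $c$, with $n_{rci}$ path counts and degree sums $N_{r2}$,
$N_c$. The published description fixes the variables and their roles —
specific contacts raise the score, overall promiscuity ("sticky"
proteins) lowers it — but not the algebraic combination, so the
functional form is pluggable. The default is

$$S_1 = \frac{n_{ri}^2}{N_r\,N_i}, \qquad
  S_2 = \frac{n_{rci}^2}{N_{r2}\,N_c\,N_i},$$

which satisfies every stated property: zero when no (indirect) contact
exists, strictly increasing in the specific counts, non-increasing in
each degree total. The form name is recorded in the output metadata.
An isolated protein has no defined score (`NA`), which is distinct
from a well-connected protein with no reference contact (score 0).

### Domain fusion (Rosetta-stone)

Two proteins $p, q$ of the query genome are candidates when some other
genome fuses one domain superfamily from each into a single protein.
$J_{p,q}$ is the set of cross pairs $(a, b)$, $a \in D_p$,
$b \in D_q$, $a \ne b$; pairs of proteins sharing any superfamily are
excluded entirely (the stricter of the two possible readings of the
published rule, which states the shared-domain case is ignored). For a
domain pair, the per-pair score is maximised over the set $T$ of
genomes containing a fusion protein; the protein-pair score is the
maximum over $J_{p,q}$. The published score's algebra is again
unprinted beyond its arguments; the default form

$$s_{a,b} = \max_{t \in T}\; \frac{|T|}{f^g_a\, f^g_b\, f^t_a\, f^t_b}$$

rewards corroboration by many genomes and rarity of both families, and
is monotone in each argument in the direction the text implies.
Whether $|T|$ counts all scanned genomes or only fusion-bearing ones
is unstated; it is implemented as the genomes containing a fusion
protein, matching the printed definition of $T$. Two independent
domain-annotation sources are scored separately, giving two channels.

### Domain over-representation

`DORA` scores a family $i$ by the ratio of its relative frequency in
the reference set to its relative frequency in the genome,
$C_{ij} = (F_t/N_t)\,/\,(F_b/N_b)$; a protein with several families
takes the best-scoring one. A family absent from the background is
undefined rather than infinite.

### Homology-inherited interactions

Protein families are sub-clustered at 11 nested sequence-identity
levels (S-levels 1–11). A known interaction between $A_1$ and $B_1$
supports a candidate pair $A_2, B_2$ with a base score equal to the
mean of the S-levels at which $A_2$ joins $A_1$ and $B_2$ joins $B_1$;
each extra experimental evidence type or species adds a halving series
($+\mathrm{base}/2$, then $+\mathrm{base}/4$, ...), evidence types
counted before species — the order that reproduces the published
worked trace (base 8, +4 for a second source, +2 for a second
species). The pair score sums over all distinct supporting known
interactions. The published S-level numbering is internally
inconsistent (11 levels for 0–100% identity, yet a 100% cluster is
placed at level 9); the arithmetic on level indices is kept as the
contract and the identity-to-level mapping is left to the clustering
input rather than resolved here.

### Expression correlation

`GECO` is the Pearson correlation of expression profiles over
conditions observed in both genes, gated by at most 5 missing values
per full profile (the published cap, read as per-profile), a minimum
common support of 3 conditions, and non-degenerate variance. Per
target the most positive correlation with any reference gene is kept,
matching the platform-wide "higher is more module-like" orientation.

### Semantic similarity

`GOSS` is Resnik similarity: the information content
$\mathrm{IC}(c) = -\ln p(c)$ of the most informative common ancestor,
with $p(c)$ the cumulative annotation frequency. Aggregation across
two proteins' annotation sets is unprinted; the default is the
maximum, consistent with the best-score collapse used everywhere else
(best-match-average is available). Natural logarithms throughout; a
single ontology namespace is assumed per DAG.

### Feature-based ensemble

The labelled training set is homology-reduced (greedy removal of the
most-neighboured protein above a similarity threshold, default 0.4,
then a completion sweep so the retained set is a maximal independent
set). Feature subsets are chosen by a greedy search driven by
cross-validated Matthews correlation: singles, then pairs of the top
singles, then extensions, stopping when no improvement appears. The
ensemble trains three networks on each of the four best subsets
(12 members), single hidden layer of $\max(2, \lceil d/2 \rceil)$
units with weight decay; the prediction is the mean member output in
$[0, 1]$. All fits are seeded, so a run is reproducible exactly.

## Integration

Each channel's scores are converted to add-one empirical right-tail
p-values against the channel's own score distribution,
$p(s) = (1 + \#\{s' \ge s\})/(n + 1)$ — distribution-free, monotone,
never exactly zero. Channels are combined by Fisher's method
($-2\sum\ln p \sim \chi^2_{2k}$) in two stages: within each approach
(LM, NNI, DGC), then across approaches, following the platform's
workflow; a flat single-stage mode exists for sensitivity analysis.
Missing channels are skipped with the degrees of freedom reduced,
rather than imputed at $p = 1$: imputation would penalise proteins
invisible to the literature or the array platform for reasons
unrelated to function.

Channel independence — the assumption behind Fisher's method — is
inspected with the normalised mutual-information distance
$D(X, Y) = 1 - I(X;Y)/H(X,Y)$, a metric equal to 1 under exact
independence and 0 under mutual determination, computed on
equal-frequency-binned p-values (10 bins by default; the plug-in
estimator needs bin occupancy and no binning rule is published).

## The synthetic benchmark

`generate_bundle()` fabricates every input with a planted positive
module so the whole platform can be exercised without downloads. At
the default desk scale, 500 proteins contain a 40-member module
(matching the roughly 0.5% module-to-proteome ratio of the real
system), split 60/40 into a seeding set and a holdout that carries
signal but never seeds a scorer — so ranking holdout members highly is
genuine recovery, not leakage. Module members co-cite preferentially
(edge probability 0.25 vs 0.02 background, 85% of edges tagged
physical), carry module-enriched superfamilies fused in 4 target
genomes, inherit module interactions at high S-levels, co-express at
$\rho = 0.6$ over 30 conditions through a single latent factor, share
deep low-frequency ontology terms, and have 4 of 12 features shifted
by 1.2 SD. The `null` preset removes every planted difference; the
`strong` preset raises them. These sizes keep a full nine-channel run
around ten seconds, so multi-seed calibration and recovery studies
stay cheap.

What the generator does not emulate: literature-mining noise at the
sentence level, realistic domain grammar or family-size distributions,
batch structure in expression compendia, or annotation bias toward
well-studied proteins. Passing tests therefore demonstrate the
correctness and calibration of the machinery under clean planted
signal, not performance on real proteomes.

## Numerical choices and degenerate inputs

* Ties in ranked lists break deterministically by identifier; AUC uses
  average ranks and agrees with the trapezoid rule.
* All-identical channel scores give every target $p = 1$, flagged.
* `p = 0` never arises (add-one estimator), so Fisher's logarithm is
  finite without clamping.
* Zero-variance expression profiles, isolated network nodes,
  unannotated proteins and background-absent families yield `NA`
  ("no score"), distinct from a true zero, and propagate as missing
  channels.
* The hidden-hub ratio uses $\max(k_{KG}, 1)$ in the denominator so a
  protein with no known interaction at all can still qualify.

## Known limitations

* Under the `null` preset the integrated p-values are conservative
  (stochastically larger than uniform): several channels have discrete
  score distributions at desk scale (most targets have zero direct
  co-citation; DORA takes few distinct values), and the add-one
  estimator assigns tie groups their largest compatible p-value.
  A strict uniformity test on the integrated p-values therefore
  rejects, even though the integration itself is calibrated — feeding
  exactly uniform channel p-values through the two-stage combination
  yields uniform output (this is covered by the test suite). Smoothing
  the score distributions (the published platform fitted parametric
  densities) would trade the distribution-free guarantee for exact
  uniformity.
* The hidden-hub thresholds ("low" known degree at most 5, module
  specificity at least 0.5) quantify published qualitative criteria
  and are configurable and reported with the output; only the
  five-fold predicted-to-known ratio is printed in the source
  description.
* Evaluation against a curated holdout treats every unlabelled protein
  as a negative, which understates precision whenever uncharacterised
  true members exist — the same conservatism the published benchmarks
  accept.
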