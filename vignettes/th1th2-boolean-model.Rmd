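---
title: "A Boolean-network account of Th1/Th2 differentiation: model, dynamics and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Boolean-network account of Th1/Th2 differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thboolnet)
```

## The model

CD4+ T helper cells differentiate into (at least) two effector programs:
Th1 cells, marked by the transcription factor T-bet and the cytokine
IFN-γ, and Th2 cells, marked by GATA3 and IL-4/IL-5/IL-13. The two
programs are classically described as counter-regulatory — each master
regulator promotes its own program and represses the other. `thboolnet`
implements a synchronous Boolean network over 43 signed regulatory rules
covering antigen receptor signalling, cytokine receptors, JAK/STAT
signalling and the Th1/Th2 transcription-factor core, and provides the
machinery to ask whether the network's dynamics actually supports strict
counter-regulation.

Each gene is binary. A rule lists activators and (minus-tagged)
inhibitors of one target, and the update semantics is deliberately
coarse:

> a gene switches on at the next step iff **at least one activator is
> active and no inhibitor is active**,

with all genes updated simultaneously (synchronous update) from the same
source state. The state space is finite ($2^n$ states) and the dynamics
deterministic, so every trajectory ends in a limit cycle — an
*attractor* — of length one (a fixed point, "static equilibrium") or more
("dynamical equilibrium"). Attractors are read as stable cell programs.

Rule-less genes (ANTIGEN, CD80, CD86, IFN-a, IL-7, IL-12, IL-18, TNFSF4)
are *input nodes*, modelling extracellular stimuli. Two stimulation
modalities are supported:

* **temporary** — inputs receive an impulse and then decay: their update
  function becomes constant OFF, so any initial activity disappears after
  one step;
* **persisting** — each input gets a pure self-activation loop and
  becomes a *frozen bit* holding its initial value forever. Enumeration
  then conditions on every assignment of the frozen bits ($2^8 = 256$
  input contexts for the packaged model) and sums the attractor counts.

## The transcription ambiguity and the consensus variant

The available transcription of the rule table renders several receptor
symbols with damaged glyphs. Taken literally (variant `"literal"`), the
table contains a receptor `IFN-gR1` driven by IFN-γ and activating STAT1,
STAT6 and STAT4. That reading is biologically surprising (IFN-γ signalling
does not activate STAT6) and, more decisively, it is dynamically
inconsistent: the literal network has **six** wild-type attractors under
temporary stimulation, and none of them matches the published Th1 fixed
point, because IFN-γ forces the receptor on, which forces STAT6 on, which
re-activates the Th2 arm inside the Th1 program.

The packaged default (variant `"consensus"`) reads the damaged symbol as
the **type-I interferon receptor chain** (`IFN-aR1`) with its ligand
`IFN-a` as an additional extracellular input. This is canonical human
T-cell biology — type I interferon signals through IFNAR1/JAK to STAT1,
STAT4 (a human-specific route) and STAT6 — and it restores the dynamics
exactly: the wild-type temporary-stimulation landscape has exactly four
attractors whose active-gene sets are, gene for gene, the published Th0
(quiescent all-OFF), Th1 (IFN-γ, IFN-γR, SOCS1, STAT1, TBET), Th2 (GATA3,
IL-13, IL-4, IL-4R, IL-5, IRF4, JAK1, JAK3, MAF, NFAT, STAT6) and the
mixed three-state ThX cycle. The literal variant is shipped untouched so
the discrepancy can be inspected:

```{r variants}
for (v in c("consensus", "literal")) {
  tmp <- apply_stimulation_modality(th1th2_network(v), "temporary")
  atts <- enumerate_symbolic(tmp)
  cat(v, ":", atts$counts$total, "attractors —",
      paste(sort(vapply(atts$attractors, classify_attractor, character(1))),
            collapse = ", "), "\n")
}
```

## Knockout semantics

`apply_knockout()` implements two readings of an *in silico* knockout:

* **clamp** — the gene is forced to constant OFF but keeps its roster
  position. This is the cleaner abstraction for comparing attractor
  counts over a common state space.
* **delete** (the default, used by `run_screen()`) — the gene is removed
  from the network: its rule is dropped and it is erased from every
  regulator list. Deletion has two knock-on effects that clamping does
  not: a target that loses its *only* activator becomes rule-less and is
  thereafter treated exactly like a native input node (decays under
  temporary stimulation, frozen under persisting stimulation); and a
  target left with inhibitors only keeps a rule whose activation clause
  is vacuously satisfied (`next = !any(inhibitors)`).

The distinction matters scientifically: deleting a kinase such as LCK,
ZAP70, ITK, PI3K, COT or NIK leaves its sole downstream substrate
unregulated, and under persisting stimulation that orphan behaves as an
extra frozen bit, roughly doubling the attractor count relative to the
clamp reading. Deleting STAT6 leaves MAF orphaned and GATA3 governed by
`!TBET` alone, which both abolishes the quiescent fixed point and
releases a large family of GATA3–TBET toggle attractors. The packaged
reference counts (`ko_reference()`) — 24 genes × 2 modalities, with
static/dynamical splits and maximal cycle lengths — are reproduced cell
for cell by the deletion semantics and **not** by the clamp semantics;
this empirical fit is why deletion is the screen default. The clamp
reading remains available for state-space-comparable experiments.

```{r screen-row}
rep <- run_screen(th1th2_network(), genes = c("GATA3", "IRF4"))
rep
attr(compare_to_reference(rep), "all_match")
```

## Exact enumeration at desk scale

Two independent enumeration routes are provided, and their agreement is
continuously tested:

* `enumerate_exhaustive()` — after exact constant-propagation reduction
  (`reduce_network()`), builds the full successor table over the free
  genes in vectorized R and finds all cycles by pointer-chasing with
  colouring (every state visited at most twice, in compiled code). It
  refuses state spaces beyond `max_bits` (default 24) — under persisting
  stimulation the 8 frozen inputs alone push the packaged model past the
  budget — and is the oracle for the second route.
* `enumerate_symbolic()` — conditions on every assignment of the frozen
  bits (self-loop genes), re-reduces each context, compiles the residual
  rules into per-gene bitmasks, and finds cycles by a set-based
  image-fixpoint: starting from the full state set, the image operator is
  iterated to its fixpoint, which is exactly the union of the limit
  cycles; the successor restricted to that set is a permutation and is
  decomposed into its cycles.

Reduction is exact, not heuristic: it only ever fixes a gene whose value
is forced in every attractor (inputs with constant-OFF functions,
targets of all-OFF activator sets, targets of fixed-ON inhibitors), and
it never fixes a pure self-activation gene, whose both values are
recurrent. Under temporary stimulation the packaged model's 51 genes
reduce to a free core of 16, because the entire TCR-proximal cascade is
provably OFF once the inputs decay; under persisting stimulation the
worst input context leaves ~21 free genes (~2M states), which the
compiled successor table enumerates in well under a second. The full
24-gene × 2-modality screen completes in under a minute on one CPU.

Canonical form: an attractor is stored with its cycle rotated so the
numerically smallest encoded state (roster order defines bit positions,
gene 1 = least significant) comes first; attractor sets are compared as
sets of state-sets, which is rotation-independent.

## Phenotype classification and cytokine profiles

`classify_attractor()` uses exact set matching — Th0 iff the all-OFF
fixed point; Th1/Th2 iff a fixed point equals the respective published
active set; ThX iff a 3-cycle matches the three mixed states as sets
under any rotation; everything else is `other`. Exactness is deliberate:
fuzzy matching would hide exactly the transcription problems this
package had to resolve. `cytokine_profile()` summarizes an attractor set
by whether IL-4 and/or IFN-γ appear anywhere along each cycle — the
four-bin breakdown (IL-4 only / IFN-γ only / both / neither) used to
judge counter-regulation after knockouts.

## The expression-analysis stage

The dynamic analysis is complemented by a microarray-style pipeline with
the study design it assumes: several case–control datasets of CD4+
T-cell expression (≥ 5 samples per group), one disease per dataset.

* `differential_genes()` — per-gene two-sided unpaired Student's t-test
  (pooled variance), genes with `p < alpha` flagged. **No
  multiple-testing correction is applied anywhere**, by design: the
  downstream quantities are *fractions* of fixed gene sets, and the
  nominal per-gene error rate is exactly what the null calibration test
  checks (type-I error within Monte-Carlo error of `alpha` on a
  10,000-gene null). Default `alpha = 0.05`; genes with zero variance in
  both groups are untestable and counted as not-DE, with a warning.
* `attractor_ratio_correlation()` — per disease, the fraction of Th1
  attractor genes that are DE and likewise for Th2; then the Pearson
  correlation of the two fraction vectors across diseases. Strict
  counter-regulation predicts a negative correlation; concordant
  activation a positive one. Ratios use only measured genes; constant
  ratio vectors make the correlation undefined and are reported as `NA`
  rather than guessed.
* `inhibitory_pair_correlations()` — Pearson correlations, over pooled
  healthy-control samples, of seven literature-annotated
  counter-regulatory pairs (headed by GATA3–TBET). Because datasets come
  from different platforms, each gene is z-scored within each dataset's
  controls before pooling (`standardize = FALSE` restores naive
  pooling); without this, between-dataset location shifts would
  masquerade as positive correlation. The SOCS1–JAK3 pair is
  literature-annotated rather than rule-derived (the packaged JAK3 rule
  carries no SOCS1 inhibitor); the pair list is shipped as a literal
  fixture.

## The synthetic-data generators

`generate_expression_study()` emulates the statistical structure the
pipeline assumes, with known ground truth: a per-disease bivariate
standard-normal severity pair with correlation `coupling` drives the Th1
and Th2 modules; a module gene is truly DE in a disease iff the severity
plus per-gene threshold noise (`de_latent_sd`, default 0.5) is positive;
DE genes gain `effect_size` residual-SDs in patients; per-dataset
baseline offsets mimic platform batch effects; background genes are
never DE. Defaults — 10 diseases, 10 samples per group, effect size 2
SD, unit noise — are realistic for the microarray case-control studies
the design emulates (10 samples per group gives essentially full power
at 2 SD, so the DE fractions track the latent severities and the sign of
`coupling` is recoverable). What the generator does **not** emulate:
probe-level artifacts, correlated background genes, missingness, or
network-mediated expression correlations among module genes — so passing
the synthetic tests validates the pipeline's statistics, not the
biological claim itself.

`generate_random_network()` fuels the oracle-equivalence corpus: random
regulator sets with at least one activator, disjoint signs, no
self-loops (except the unavoidable one-gene self-activator), optional
rule-less inputs. The continuous acceptance tests run 200 such networks
of 8–14 genes (a fifth of them under persisting stimulation) through
both enumerators and the no-reduction oracle.

## Numerical and design choices

* **State encoding** — roster order is fixed by the rule file (regulated
  genes in rule order, then inputs alphabetically); canonical attractor
  keys are therefore reproducible across runs.
* **Within-rule vs across-rule sign conflicts** — a gene may inhibit in
  one rule and activate in another (STAT6 inhibits STAT4, activates
  MAF); only within-rule overlap is an error.
* **Impulse initial conditions** — temporary-modality attractors are
  enumerated over the full state space rather than by simulating
  explicit impulses: inputs decay deterministically, so every impulse
  trajectory lands in an attractor of that same space.
* **Persisting counts** — totals sum over all frozen-bit assignments
  (256 input contexts for the wild type; knockout-created orphans add
  further frozen bits). This reading reproduces the reference counts
  exactly.
* **Medians** — the screen summary uses the even-count convention (mean
  of the two middle values), which is what makes the persisting median
  604.
* **Budgets** — successor tables are capped at `max_bits = 24` free
  genes (16M states); frozen-bit conditioning is capped at 16 bits. The
  packaged analyses sit far below both caps.
* **Gene naming** — symbols are normalized (case, separators, Greek
  letters) and passed through a small alias table (e.g. `PLCPG` →
  `PLCG`); display names are preserved for output.

## Problem sizes used in the shipped checks

The test suite enumerates the packaged model (51 genes; 16-gene free
core under temporary stimulation, 256–512 contexts of up to ~21 free
genes under persisting stimulation), runs the full 24-gene × 2-modality
screen, checks enumerator equivalence on 200 random 8–14-gene networks,
and calibrates the DE step on a 10,000-gene null with 10 samples per
group. These sizes were chosen as the smallest that exercise every code
path at full fidelity; the screen itself is the genuine full-size
analysis, not a scaled-down stand-in.

## Known limitations

* Synchronous updating only; asynchronous or probabilistic schedules can
  change which cycles exist and are out of scope.
* Basin-of-attraction sizes are not computed.
* The expression stage ships no downloader or normalizer for real
  microarray repositories; real data enter through the TSV reader, and
  probe-to-gene collapse is left to the caller (collapse by
  highest-mean probe is the convention assumed).
* The consensus reading of the damaged receptor symbols is a curation
  decision. It is the unique reading we found under which the published
  attractor table and all 48 published knockout counts reproduce
  exactly, but the literal transcription is shipped alongside and every
  analysis can be re-run on it.
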