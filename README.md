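# thboolnet

Synchronous Boolean-network analysis of human Th1/Th2 T-helper-cell
differentiation: exact attractor enumeration, systematic *in silico*
knockout screening, Th-phenotype classification, and a companion
expression-correlation pipeline.

## The scientific problem

Th1 and Th2 cells are classically held to be counter-regulatory: T-bet
drives the Th1 program (IFN-γ) and represses GATA3, while GATA3 drives
the Th2 program (IL-4/IL-5/IL-13) and represses T-bet. Whether a
comprehensive regulatory network actually behaves that way is a dynamics
question. This package ships a 43-rule signed regulatory network of
Th1/Th2 differentiation (51 genes: antigen/costimulation inputs, the
TCR-proximal cascade, cytokine receptors, JAK/STAT signalling and the
transcription-factor core) and the machinery to interrogate it.

The update semantics is deliberately coarse. With `x_g(t) ∈ {0,1}` and a
rule listing activators `A(g)` and inhibitors `I(g)`:

    x_g(t+1) = ( OR_{a ∈ A(g)} x_a(t) ) AND NOT ( OR_{i ∈ I(g)} x_i(t) )

— a gene turns on iff at least one activator and no inhibitor is active,
all genes updating synchronously. The dynamics is deterministic on a
finite state space, so every trajectory ends in a limit cycle
(*attractor*): a fixed point ("static equilibrium") or a longer cycle
("dynamical equilibrium"). Attractors are read as stable cell programs.

Extracellular inputs are modelled in two stimulation modalities:
*temporary* (an impulse that decays — input update functions become
constant OFF) and *persisting* (self-loops freeze each input at its
initial value; enumeration conditions on all 2^8 = 256 input contexts
and sums the counts).

For whom: systems immunologists and anyone analysing logical models of
gene regulation who needs exact, fully enumerated synchronous attractor
landscapes with an audited reference screen.

## What it computes

* **model_io** — `parse_rules()`/`read_rules()` for the signed rule
  grammar, `th1th2_network()` (consensus and literal transcription
  variants), exports to GML / BoolNet / CNET with exact round-trips,
  `apply_knockout()` (deletion and clamp semantics),
  `apply_stimulation_modality()`.
* **dynamics** — `step_state()`, `trajectory()`, and exact
  constant-propagation reduction `reduce_network()`.
* **attractors** — two independent exact enumerators
  (`enumerate_exhaustive()`: full successor map + pointer-chasing;
  `enumerate_symbolic()`: frozen-bit conditioning + set-based
  image-fixpoint, compiled bitmask tables), `classify_attractor()`
  (Th0/Th1/Th2/ThX/other), `cytokine_profile()` (IL-4/IFN-γ bins).
* **knockout_screen** — `run_screen()` over the 24 intracellular genes ×
  both modalities, `screen_summary()` (medians/ranges),
  `compare_to_reference()` against the packaged published counts
  (`ko_reference()`).
* **expression_analysis** — `differential_genes()` (unpaired Student's
  t-test, no multiplicity correction by design),
  `attractor_ratio_correlation()` (per-disease Th1/Th2 DE-ratio
  correlation), `inhibitory_pair_correlations()` (pooled, per-dataset
  z-scored controls).
* **synthetic_data** — `generate_expression_study()` (latent-severity
  case–control generator with known coupling sign) and
  `generate_random_network()` (oracle-test fuel).

## Worked example

```r
library(thboolnet)

net <- th1th2_network()
net
#> Boolean network: 51 genes (43 regulated, 8 inputs)
#>   inputs: ANTIGEN, CD80, CD86, IFN-a, IL-12, IL-18, IL-7, TNFSF4

tmp  <- apply_stimulation_modality(net, "temporary")
atts <- enumerate_symbolic(tmp)
atts
#> Attractor set: 4 attractors (3 static / 1 dynamical), max length 3
as.data.frame(atts)[, c("length", "kind", "label")]
#>   length      kind label
#> 1      1    static   Th0
#> 2      3 dynamical   ThX
#> 3      1    static   Th2
#> 4      1    static   Th1
```

Four attractors: the quiescent Th0 state, the Th1 program (active genes
TBET, IFNG, STAT1, IFNGR, SOCS1), the Th2 program (GATA3, IL-13, IL-4,
IL-4R, IL-5, IRF4, JAK1, JAK3, MAF, NFAT, STAT6), and a three-state
mixed cycle (ThX) co-expressing Th1 and Th2 genes — the dynamical
counter-example to strict counter-regulation.

```r
rep <- run_screen(net, genes = c("GATA3", "IRF4", "STAT6"))
rep
#> Knockout screen: 6 rows (delete knockouts)
#>   gene   modality attractors static dynamical max_length
#>  GATA3  temporary          3      3         0          1
#>  GATA3 persisting        322    322         0          1
#>   IRF4  temporary          9      3         6          5
#>   IRF4 persisting        604    450       154          5
#>  STAT6  temporary          6      3         3          3
#>  STAT6 persisting       1664   1088       576          3
attr(compare_to_reference(rep), "all_match")
#> [1] TRUE
```

Each row is one knocked-out gene under one stimulation modality: the
total number of attractors, the static/dynamical split, and the longest
cycle. Removing GATA3 collapses all oscillation (every attractor is a
fixed point); removing STAT6 releases the largest landscape in the
screen (1664 attractors under persisting stimulation). The full 24-gene
screen over both modalities (`run_screen(net)`) matches the packaged
published reference row for row and completes in under a minute.

Command-line wrappers for the screen and the expression simulator are in
`inst/cli/`.

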