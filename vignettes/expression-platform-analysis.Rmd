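---
title: "Kinetic-barrier analysis of riboswitch expression platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-barrier analysis of riboswitch expression platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboswitchEP)
```

## The system and the model

Transcriptional ON-riboswitches of the ZTP class decide between termination
and antitermination while RNA polymerase is still transcribing. The decision
is executed by an internal strand displacement reaction: the 3' *invader*
segment of the expression platform (EP) pairs with the 3' end of the
aptamer's P3 stem — the *nucleating base pair* — and branch-migrates through
P3 and the pseudoknot, zipping up an intrinsic terminator hairpin. Ligand
binding rigidifies the aptamer and blocks the invasion, so polymerase reads
through.

Two quantitative models organize the analysis:

1. **Dose-response.** Normalized reporter fluorescence against ligand
   concentration [Z] (mM) follows the hyperbolic saturation curve
   $F = a + b\,[Z]/(EC_{50} + [Z])$, with baseline $a$ (the leak),
   amplitude $b$, and half-maximal concentration $EC_{50}$. There is no Hill
   coefficient; `fit_dose_response()` implements exactly this three-parameter
   form.

2. **Kinetic barriers.** A noncomplementary element in the invader — a
   wobble pair, mismatch, or bulge — slows branch migration and thereby
   raises the ON state. Its effect decays with the squared distance $r$
   (nucleotides) from the nucleation site:
   $\Delta F_{ON}(r) = B/r^2$, where $\Delta F_{ON}$ is the mutant's
   ON-state (saturating-ligand) excess over the perfectly complementary
   reference and $B$ is a per-mutation-class barrier size. The model is
   phenomenological: it captures that nucleation-proximal barriers gate the
   committed step of hairpin formation, while distal ones act after the
   invasion is effectively committed.

The core assumption tying the two together is separability: a barrier shifts
the ON amplitude without, to first order, changing the baseline or the
EC50 (the one documented exception in the literature of this system is an
r = 1 bulge, which also shifts sensitivity).

## Coordinates and the barrier index

All coordinates are 1-based closed intervals numbered from the construct's
first transcribed nucleotide, so residue labels match mutation names
(`A26Δ`, `G108C`). The barrier index anchors $r = 1$ at the 5'-most invader
nucleotide (the one forming the nucleating pair). A bulge "at position $k$"
means an insertion immediately 3' of the invader nucleotide with index $k$;
with the invader starting at residue 108, a position-3 bulge sits between
residues 110 and 111. Mutation names always use reference numbering, never
renumbered mutant coordinates, so compound mutants remain addressable.

Because no rule infers the transcription start from sequence alone, region
annotations (P3, invader, poly-U, ...) travel with each construct as an
explicit config (`load_construct()`, YAML via `read_region_config()`).

## Duplex alignment

`align_duplex()` performs an antiparallel global alignment of the invader
against the substrate window, by dynamic programming with column scores
WC = +3, wobble = +1, mismatch = −2 and −4 per bulged nucleotide. These are
annotation parameters, not thermodynamic quantities; the criterion for the
defaults is that they reproduce the reference EP's annotation, and they are
exposed in `align_params()` for other systems. Design choices that the
published record leaves open, and how they are fixed here:

- **Substrate window.** The invader is aligned against the window ending at
  P3's 3' terminus with length = invader length + `window_slack` (default
  4 nt), since invasion proceeds from the P3 3' end through the pseudoknot
  but the 5' extent of invasion is not defined. Unused window at the far
  (hairpin-base) end is left unaligned at no cost, so the slack widens the
  search without forcing spurious substrate bulges.
- **Tie-breaking.** The traceback prefers pairing over gaps and places
  bulges toward the nucleation end. This makes the output deterministic and
  matches how elements are indexed in this field. One visible consequence:
  a mismatch introduced immediately 3' of a natural bulge can trade places
  with it at equal score, and the canonical (nucleation-proximal-bulge)
  orientation is reported.
- **Element merging.** Adjacent same-kind bulge or mismatch columns merge
  into one element (they form one physical loop), but adjacent wobble
  columns remain separate elements — two stacked wobble pairs are still two
  base pairs, and the reference EP's element count (three wobbles, two
  bulges) depends on this distinction.

The alignment optimum is verified in the test suite against exhaustive
enumeration of all antiparallel gapped alignments for random pairs up to
8 nt (200 pairs per run, fixed seed).

## Hairpin free energy

`hairpin_delta_g()` ranks stem variants with a reduced nearest-neighbor sum:
the standard Watson-Crick RNA stack table, coarse values for
wobble-containing stacks, hairpin-loop initiation by loop length, and
bulge/internal-loop penalties; mismatched or bulged columns interrupt
stacking. This is deliberately not an ensemble folding calculation — its
role is a sane stability ranking (every added defect weakly raises ΔG),
because equilibrium stability does not explain the position dependence of
the barrier effect; the kinetic index $r$ does. Note that a weak all-A:U
stem with a short loop can legitimately have ΔG > 0 under any realistic
parameter set; stability claims in the tests therefore use GC-containing
stems.

## Mutant libraries

The scans substitute deterministic rules for the named exemplars:

- *Mismatch*: each paired invader base is replaced by its own Watson-Crick
  complement (G↔C, A↔U), which breaks the pair regardless of the substrate
  base and reproduces every named mismatch mutant.
- *Deletion*: every invader position.
- *Bulge*: poly-A insertions of length 1-3 after each invader index up to
  (invader length − 1); an insertion after the last invader residue would
  fall outside the stem and is not a barrier.
- *Wobble*: C→U at G:C pairs. A→G at U:A pairs creates U:G wobbles in the
  direction that has been observed to *favor* strand displacement; these are
  included by default but flagged (`"wobble-to-WC direction reversed"`), and
  a flag excludes them from barrier scans.

Edits that are sequence-equivalent within homopolymer runs (e.g. deleting
either U of a UU run) collapse to their 5'-most representative, keeping
libraries duplicate-free; the same left-alignment convention is used when
diffing a mutant back against its reference.

`perfect_invader()` removes every noncomplementary element (wobbles
corrected toward the substrate, invader bulges deleted) and is idempotent;
the corrected scaffold is the background in which single barriers are
measured in isolation.

## Curation, chimeras and flipped logic

`curate_eps()` applies three filters in order: a poly-U tract of ≥ 5 Us
within the EP, exact string identity of P3 to the reference (near-identity
is rejected — the point of the filter is a shared substrate), and the
loop + invader architecture (≥ 8 paired columns, apical loop of 3-12 nt,
poly-U within 2 nt of the invader 3' end). `build_chimera()` fuses the
reference aptamer (through the residue before the invader) to a foreign
invader, keeping the reference poly-U and downstream sequence.

`design_flip()` converts the ON-switch into an OFF-switch by inserting a
flipping domain between the hairpin 3' end and the poly-U tract. The
default domain is the reverse complement of the invader's 8-nt 3' suffix —
the stated pairing target is the invader remnant left by failed strand
displacement — yielding a perfect 8-bp synthetic holo stem; an explicit
domain can be supplied instead (e.g. a validated construct). The
"apo-termination ablated" flag (spacer ≥ 8 nt) is a reported heuristic,
never used in any fit. `tune_flip()` applies a barrier to the parent
invader before re-deriving the design and records its class, size and $r$.

## The synthetic assay generator

`simulate_assay()` emulates the bulk fluorescence reporter assay whose
statistical structure the quantification assumes: for each construct and
concentration, 3 experimental replicates × 3 biological replicates = 9
wells, plus blank wells on every plate. The generative model is

- true value $v = (a + \text{leak\_shift}) + (b + B/r^2)\,Z/(EC_{50}+Z)$;
- one multiplicative batch factor per experimental replicate,
  $\mathrm{LogNormal}(0, 0.05)$ — media are prepared per experimental
  replicate, so the factor is shared across every well of the plate;
- per-well biological noise, multiplicative Gaussian with CV 5%;
- raw fluorescence $= v \times OD_{true} + \text{blank F draw}$ and raw
  OD $= OD_{true} + \text{blank OD draw}$, with $OD_{true} = 0.4$
  (exponential-phase subculture) and blanks around (100 au, 0.05 OD).

Defaults $a = 100$, $b = 900$, $EC_{50} = 0.05$ mM were chosen once as
plausible for a constitutive-promoter sfGFP reporter responding in the
0-1 mM ligand range: a ~10-fold reference dynamic range, with barrier sizes
of a few hundred units spanning the observed ~2- to ~30-fold tunable range.
The noise magnitudes (CV 5%, batch SD 0.05) are an assumption — only
9-point standard deviations are reported for the real assay, and the split
between biological and experimental variance is not — so they are exposed
in `ground_truth()` rather than asserted.

What the generator does *not* emulate: growth dynamics (OD is a constant),
plasmid copy-number effects, ligand toxicity, plate-position effects, or
any transcription kinetics — the barrier term enters the ON amplitude
directly by construction. Passing recovery tests therefore demonstrates
that the analysis inverts this generative model correctly, not that the
model captures every feature of real plate-reader data.

One bookkeeping consequence of the model: the measured ON-state shift at
1 mM carries the saturation factor $Z/(EC_{50}+Z) = 1/(EC_{50}+1)$
(≈ 0.952 at the defaults), so recovery analyses divide the measured
$\Delta F_{ON}$ by it before comparing the fitted $B$ to the generative
value. With real data, where $B$ is defined by the measured shift itself,
no such correction applies. Similarly the idealized fold-change identity
$(a + b + B/r^2)/a$ holds exactly only in the saturating limit; at 1 mM the
simulated fold change is $(a + (b + B/r^2)/(EC_{50}+1))/a$.

## Fitting choices

- **Dose-response**: Levenberg-Marquardt least squares; initialization
  $a_0 = \min$, $b_0 = \max - \min$, $EC_{50,0} =$ geometric mean of the
  nonzero concentrations; bounds $a \ge 0$, $EC_{50} > 0$, $b$ free in
  sign. Requires ≥ 3 distinct concentrations including 0; standard errors
  come from the fit covariance. The fit is scale-equivariant, so arbitrary
  fluorescence units are safe.
- **Barrier model**: the single-parameter least-squares optimum is closed
  form, $\hat B = \sum_i \Delta F_i r_i^{-2} / \sum_i r_i^{-4}$, with
  $SE(\hat B)$ from the residual variance (undefined at one point).
  $\hat B$ may be negative — direction-reversed wobble scans sit below the
  reference — and is flagged rather than constrained, since nothing in the
  model requires nonnegativity. By default fits use per-mutant means
  (matching mean ± SD bar-chart reporting), but any per-well values can be
  passed.
- **Welch tests**: two-tailed, unequal variance, Welch-Satterthwaite df.
  Significance tiers (\*, \*\*, \*\*\*, \*\*\*\*) are assigned from the
  *pre-correction* p at α = 0.05, 0.01, 0.001, 0.0001 — the convention in
  this literature's figure captions — while the Bonferroni-adjusted
  $p_{adj} = \min(1, pm)$ is always reported alongside. Two identical
  constant groups return $t = 0$, $p = 1$ rather than NaN.
- **Normalization**: (F − mean blank F)/(OD − mean blank OD) per well;
  wells with corrected OD ≤ 0 are excluded with a warning, and a table
  without blanks is a configuration error.

## Problem sizes and determinism

The test and acceptance workloads are sized for interactive runs: the
alignment oracle checks 200 random pairs of ≤ 8 nt; stochastic recovery
uses a 3 × 6 (B × r) grid with 20 seeded replicate datasets per barrier
size, recovering the mean $\hat B$ within 10% and a seeded noisy EC50
within 15%; noiseless pipeline identities hold to 1e-6 relative (dose
response) and 1e-9 (barrier fit). All simulation entry points take an
integer seed, restore the caller's RNG state, and are byte-reproducible:
the same seed yields an identical table.

## Known limitations

- The alignment annotates a static duplex; it does not model
  cotranscriptional folding order, pausing, or pseudoknot formation, and
  the window slack only brackets how far invasion reaches past P3.
- The synthetic reference construct reproduces published anatomy but is not
  a genomic sequence; analyses of real systems should load their own
  annotated FASTA.
- $B/r^2$ is descriptive. It summarizes position dependence well enough to
  rank barrier classes, but carries no rate-constant interpretation, and
  class fits pool heterogeneous sequence contexts.
- Curation reports filter verdicts only; it does not predict whether a
  chimera will be functional.
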