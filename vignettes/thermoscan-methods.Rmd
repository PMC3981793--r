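---
title: "thermoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscan)
```

## The method

RNA thermometers regulate gene expression by refolding in response to
temperature. Because thermodynamic structure prediction degrades on
sequences of several hundred nucleotides, `thermoscan` analyzes a long
sequence (typically a 5′ UTR) through local windows: every window of every
size $w \in [w_{\min}, w_{\max}]$, sliding one nucleotide at a time, is
folded at a reference temperature $T_1$ and a shock temperature $T_2$, and
the change is scored by the base-pair distance
$d(S_1, S_2) = |P_1 \,\Delta\, P_2|$, the number of base pairs present in
exactly one of the two predictions. Each window contributes one dot at
$(x, y) = (\text{left-most}, \text{right-most position})$, with intensity
$d / d_{\max}$ where $d_{\max}$ is the largest distance in the run: windows
with no change are invisible, the largest change is black. A region whose
many overlapping windows all refold shows up as a dense dark cluster; the
reading remains qualitative, and `position_profile()` (the mean intensity
of the windows covering each position) is provided as a reading aid, not as
a significance test. No cluster-significance statistic is computed — that
would require calibration against experimental data the method does not
assume.

The step size is fixed at one nucleotide and both coordinates are 1-based
and inclusive. Intensities are normalized by the **global** maximum of the
run (per sequence, per scan) rather than per window size; the alternative
normalization per window size would make dots from different window sizes
incomparable within one plot, which is exactly where the cluster reading
happens. With $t_1 = t_2$ a scan is legal (and useful as a negative
control): it is identically zero and is reported with a warning.

## The built-in energy model

The engine uses a deliberately reduced nearest-neighbor model, shipped as a
human-readable table (`inst/extdata/energy_params_v1.tsv`, version
`nn-lite-1.0`):

* **Stacks.** Each ordered context (outer pair, inner pair) over the six
  canonical pair types AU, UA, CG, GC, GU, UG carries an enthalpy
  $\Delta H$ (kcal/mol) and entropy $\Delta S$ (kcal/mol/K), giving
  $\Delta G(T) = \Delta H - T\,\Delta S$. Values are loosely modeled on
  published Watson–Crick nearest-neighbor measurements with moderate
  generic values for wobble stacks; every stack is stabilizing
  ($\Delta H < 0$, $\Delta S < 0$), so all stacks weaken as $T$ rises.
  No number in the table is claimed to reproduce any published set, and
  every test is self-consistent against the shipped file.
* **Loops.** Hairpin loops (size 3–30) and internal/bulge loops (total
  unpaired 1–30) carry only a tabulated $\Delta G_{37} \ge 0$, rescaled
  purely entropically: $\Delta G(T) = (T / 310.15\,\mathrm{K})\,
  \Delta G_{37}$. Beyond the tables a Jacobson–Stockmayer term
  $1.75\,R\,310.15\,\ln(s/s_{\max})$ extrapolates, with
  $R = 1.98717 \times 10^{-3}$ kcal/(mol K).
* **Everything else is zero.** Multibranch loops cost nothing beyond their
  branches; exterior unpaired bases are free; there are no terminal-AU
  penalties, dangles, special tetraloops or coaxial stacks.

The reduction is the point: with this model the Zuker-style minimum-free-
energy recursion, the McCaskill-style partition function and a brute-force
enumeration of all structures provably agree, so the dynamic programs can
be tested *exactly* against an independent oracle. Hairpins still melt
realistically — the designed 10-bp demonstration hairpin has a sharp
sigmoidal closing-pair probability around its predicted melting
temperature. A consequence worth knowing: because loops scale with $T$,
$E/RT$ approaches a constant at high temperature, so pair probabilities
converge to entropy-only odds rather than to the uniform limit a
temperature-independent energy would give.

Structural conventions: minimum hairpin loop of 3 unpaired bases; GU/UG
wobble pairs allowed; lonely (isolated) pairs permitted — a divergence from
common `RNAfold` defaults, accepted to keep the enumeration oracle simple;
no pseudoknots. The interior-loop size cap of 30 total unpaired bases
applies to the dynamic programs (both MFE and partition function, keeping
the two ensembles identical); `score_structure()` itself prices any valid
structure via the extrapolation, and oracle equivalence is asserted on
lengths where the cap cannot bind.

## Folding engines

`fold_mfe()` fills the usual $V$ (best energy closed by pair $i,j$) and $M$
(at least one branch) tables; the exterior array and a deterministic
traceback finish the job. Ties are broken toward hairpin closure, then
stacking, then the smallest interior loop, then the bifurcation with the
smallest split point — any fixed order gives determinism; this one prefers
simple structures. `partition_function()` computes inside quantities
($Q^b$, $Q^m$, and a two-or-more-branch variant $Q^{mb}$, giving an
$O(n^3)$ inside pass at fixed loop cap) and pair probabilities by an
outside recursion; `centroid_structure()` thresholds at $p > 1/2$, which in
a non-crossing ensemble can never select two conflicting pairs.

A scan exploits one structural fact: $V(i,j)$, $M(i,j)$ and the inside
partition arrays depend only on the subsequence $[i..j]$, never on the
window around it. They are therefore filled **once** per temperature for
all spans up to $w_{\max}$ and shared by every window; only the exterior
array and traceback are per-window work. This replaces per-window
memoization and makes the MFE scan fast (a 281-nt scan at windows 55–80,
5577 windows, runs in seconds). The outside (probability) recursion is
window-dependent and $O(w^4)$, so centroid scans are intended for short
sequences or modest windows; MFE mode is the default.

Numerics: partition sums are plain doubles without rescaling, which is safe
for the window sizes the scan recommends (well beyond 150 nt windows the
Boltzmann sums of a GC-rich window could eventually overflow; window sizes
that large are already flagged as unreliable for prediction accuracy).
Traceback compares candidate energies by exact floating equality, which is
sound because the traceback recomputes each candidate with the identical
arithmetic expression used when the table was filled.

External engines plug in through a one-function contract
`(residues, celsius, mode) -> list(dotbracket, energy)`;
`rnafold_engine()` adapts ViennaRNA's `RNAfold` (full Turner parameters)
and passes user options such as `--noLP` or `-d2` through without claiming
a default, since the appropriate choice depends on the study. Parsed
external structures are checked for balance and length only — their
conventions (e.g. lonely pairs, non-canonical pairs) are not second-guessed.
Built-in and external predictions will generally disagree structure by
structure; only the contract is asserted in tests.

## Scan parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `t1` | 37 | °C | physiological reference |
| `t2` | 40 | °C | mild heat shock; any bracket may be supplied |
| `wmin`, `wmax` | 55, 80 | nt | windows of 50–80 nt balance local prediction reliability against context; below 50 or above 150 triggers a warning (not an error) |
| `mode` | `"mfe"` | — | centroid mode is available for ensemble-representative structures |
| `engine` | `"builtin"` | — | any registered adapter may be named |

A sequence shorter than `wmin` is an error that names the remedy
(`clamp_window = TRUE` / `--clamp-window`), which replaces the range by the
single window of the sequence length.

## The synthetic-data generator

`make_record()` emulates the validation design of scanning one sequence
that contains a thermometer and one control that does not:

* `design_hairpin()` searches stem compositions (counts of GC, AU and GU
  pairs in a fixed arrangement, strong pairs outermost) for a melting
  temperature $T_m = \Delta H_{tot} / \Delta S_{tot}$ strictly inside the
  requested bracket, preferring the composition closest to the bracket
  midpoint so the hairpin is comfortably folded at $T_1$ and molten at
  $T_2$. $T_m$ here is the closed-form root of the designed structure's
  $\Delta G(T)$ under the builtin model — a testable surrogate for
  experimental melting, with no claim of biophysical accuracy. Loop bases
  are drawn from whichever of A or C has fewer partners in the stem.
* Flanks are sampled from an A/C-rich alphabet (A 0.35, C 0.35, G 0.15,
  U 0.15) and rejection-sampled until their standalone MFE at `tm_low` is
  $\ge -0.5$ kcal/mol, with a fixed cap of 1000 attempts; both constants
  are chosen so that generation succeeds in practice for flanks up to
  ~150 nt while keeping the background almost structure-free.
* Defaults — 10-bp stem, 6-nt loop, bracket (37, 55) °C, 87-nt flanks,
  200 nt total — give a record whose scan at the bracket temperatures
  produces an unambiguous cluster over the annotated interval.
  `stem_length = 0` is the control sentinel: flanks only, no annotation.

What the generator does **not** emulate: real thermometer families (FourU,
ROSE and relatives are not embedded), sequence conservation, long-range
interactions beyond the window, kinetic effects, and the full Turner
energy surface. A passing detection suite therefore demonstrates that the
pipeline recovers a planted temperature-sensitive hairpin under its own
thermodynamic model — not that any particular biological thermometer would
be found; for biological sequences the external RNAfold engine is the
appropriate folder.

## Verification

The package's guarantees are enforced by the test suite at these problem
sizes, chosen so the whole suite runs in well under a minute: 200 random
sequences of length 8–14 for exact MFE/enumeration agreement; 50 sequences
of length ≤ 12 for partition-function agreement to relative error
$10^{-9}$ (observed: machine precision) and centroid validity; 1000 random
structure triples for the metric properties of the base-pair distance; a
281-nt scan at windows 55–80 for the closed-form dot count (5577); a
150-nt identity scan; 20 synthetic thermometer records (stems 8–12 bp) and
20 controls at 200 nt, windows 30–50, for detection (profile argmax within
the annotated interval ± $w_{\max}$, scan maximum ≥ stem length) versus
no such enrichment in controls; and byte-identical TSVs across repeated
runs. `scripts/acceptance.R` recomputes the same quantities end to end
from a single seed.

## Known limitations

* The builtin parameter set is reduced and generic; its predictions are
  for method development and testing, not for quantitative biophysics.
* Centroid scans cost $O(w^4)$ per window; prefer MFE mode for long
  sequences or wide window ranges.
* No pseudoknots, no suboptimal-structure enumeration outside the test
  oracle, no constraint folding, no cluster-significance statistics, and
  no more than two temperatures per run.
* Long-range base pairs that never fit inside a window are invisible to
  any windowed scan, whatever the engine.
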