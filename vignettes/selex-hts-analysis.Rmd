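---
title: "Analyzing sequenced SELEX selections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing sequenced SELEX selections: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexenrich)
```

This vignette is the package's account of its methods: what each stage of
the pipeline computes, which parameters matter and why they default to the
values they do, what the synthetic-data generator does and does not emulate,
and where the numerical and design decisions were genuinely open.

## The selection experiment being analyzed

A CE-SELEX experiment starts from a single-stranded DNA library whose
molecules share fixed flanks (a 20-nt forward primer and a 20-nt
reverse-primer region) around a 25-nt random region. Over successive rounds,
DNA is incubated with the target protein (here the ovarian-cancer biomarker
HE4, carrying a GST purification tag), protein-bound molecules are separated
from unbound by capillary electrophoresis, and the recovered fraction is
PCR-amplified into the next round's input. Counter-selection (negative)
rounds against the free GST tag purge tag binders. Sequencing every round's
archived DNA turns the selection into a time series of sequence pools.

Two quantitative signatures matter downstream:

- a truly selected binder gains *relative frequency* in positive rounds and
  is essentially absent from the pools sequenced out of negative rounds;
- a *parasite* — enriched by amplification or nonspecific capture — is
  abundant in positive **and** negative pools alike.

## Read processing

Each read should be `forward primer + region + reverse primer + adaptor`.
`trim_primers()` anchors the forward primer at position 0 (the reads are
amplicons, so a missing prefix means a defective read, not an offset one)
and scans for the reverse-primer region left to right after it, taking the
leftmost window within budget; everything from that window onward is
discarded, which removes sequencing adaptors without ever inspecting them.

Parameters:

- `mismatch_frac = 0.05`: substitution budget per primer,
  `floor(0.05 * 20) = 1` substitution for the 20-nt primers. Indels are
  rejected outright — the match is substitution-only by construction.
- `N` counts as a mismatch everywhere (it is evidence against identity, not
  for it), and two `N`s never match each other. Regions containing `N`
  after trimming are kept and treated as ordinary symbols downstream.
- `length_target = 25, length_tol = 2`: the accepted region window.
  Quality strings are read and carried but never used; the pipeline applies
  no quality filter.

Reads failing either primer or the length window are counted per failure
mode, never silently dropped, so accepted + rejected always equals input.

`duplication_percent()` offers two definitions, because "percent duplicated"
is ambiguous: `fraction_of_total` (`100*(total-unique)/total`, the
FastQC-style quantity, default) and `relative_to_unique`
(`100*(total-unique)/unique`). Reported duplication values of the HE4 study
(11.8%-37.7%) cannot adjudicate between them without the raw data, so both
are exposed.

## Fold enrichment

Pools from different rounds have unequal depth, so enrichment is a ratio of
read *fractions*, not counts. For sequence $s$ with counts $c_r, c_t$ and
depths $T_r, T_t$:

$$\mathrm{FE}(s) = \frac{c_t/T_t}{\max(c_r, p)/T_r}, \qquad p = 1.$$

The pseudocount $p$ applies only as a floor on the reference count: a
sequence unseen in the reference gets the largest finite enrichment
consistent with "fewer than one read", and the ordering among observed
sequences is untouched. The reference round defaults to the unselected
library R0, so per-round enrichments share a common baseline (a sequence
equally frequent in R0 and a later round has FE 1 regardless of the rounds
between); any pool can be passed as reference for consecutive-round
analyses. Enrichment operates on random regions only — the primers are
identical across all sequences and carry no information.

Ranking is made deterministic by breaking FE ties with the higher target
count, then lexicographically.

## Identity and clustering

`global_identity()` is a full Needleman-Wunsch global alignment with linear
gap costs (defaults 1/-1/-2) and identity defined as matched columns over
alignment columns (gaps included in the denominator). Among alignments of
equal score, the kernel deterministically prefers more matches, then fewer
gap columns — the identity is then a pure function of the two sequences,
which matters because a threshold decision should not depend on traceback
arbitrariness. An alternative denominator (shorter-sequence length, as some
clustering tools use) would only raise identities; the alignment-column
choice is the more conservative one.

`greedy_cluster()` reimplements the standard greedy incremental rule:
sequences in count-descending order (ties lexicographic), each compared to
**all** existing representatives, joining the best cluster at identity
`>= 0.8`, else seeding a new one. Word-filter heuristics of production
clustering tools are deliberately not reproduced — inputs here are at most
1000 sequences per round, so the exact O(n^2) alignment scan is tractable
and removes a layer of approximation. Whether the original tooling assigned
"highest identity across all clusters" during the scan or in a second pass
is not recoverable; the single-scan rule is this package's fixed semantics,
and the brute-force oracle in the test suite pins it down.

Clustering is run on full-length sequences (primers attached), which is how
the experiment's own analysis was configured. A consequence worth knowing:
with 40 of ~65 columns shared by construction, two *random* 25-nt regions
already align at ~0.85 overall identity, so the 0.8 threshold produces few,
large, heterogeneous clusters. In the simulation, cluster membership
therefore adds little discrimination between planted binders and drifted
background — cluster size is reported as an annotation, and the discovery
burden rests on enrichment plus the negative-pool filters. Raising the
threshold or clustering bare regions sharpens families; both are one
argument away.

## Candidate filtering

- `flag_parasites()`: abundant (`>= min_count`) in at least one positive
  and one negative pool. "Abundant" has no canonical value; the default of
  100 reads corresponds to 0.1% of the default simulated depth (1e5), far
  above the level at which nonspecific carryover scatters ordinary
  sequences into negative pools, and far below planted-parasite abundance.
- `library_homologs()`: library sequences with identity **strictly**
  greater than 0.85 at >= 5 library counts — a candidate with such a
  relative likely owes its abundance to library synthesis bias rather than
  selection. Homology is computed on bare regions (the comparison concerns
  the variable segment).
- `in_negative_pools()`: presence at `>= min_count` (default 1, the strict
  "not found in any negative round" reading; at simulated depths a higher
  threshold is appropriate, and the analysis scripts use the parasite
  threshold).

`build_candidate_table()` joins all of this into one row per enriched
sequence. Flags annotate rather than delete: in-silico filtering is a
reported decision, and downstream users apply their own policy. External
binding-potential scores (e.g. Z-scores from sequence-statistics tools) are
joined passively by sequence and never influence ranks.

## Binding isotherms

Both assay formats — affinity probe CE (ratioed free-DNA peak height) and
fluorescence anisotropy ($r - r_0$) — are fit with the same quadratic
ligand-depletion model. With probe concentration $A$ fixed and protein $T$
titrated, the equilibrium complex concentration is the smaller root of the
mass-action quadratic:

$$[C] = \tfrac{1}{2}\left(A + T + K_d - \sqrt{(A+T+K_d)^2 - 4AT}\right),$$

and the fitted signal is

$$\mathrm{signal}(T) = \frac{\mathrm{constant}}{1 + K_d/(T + [C])}.$$

Notes on this form:

- The denominator term $T + [C]$ (free protein *plus* complex) follows the
  published equation exactly. It differs from the more conventional
  bound-fraction form $\mathrm{constant}\cdot[C]/A$; the conventional form
  is available via `form = "fraction_bound"` for comparison but is never
  the default. For $A \ll K_d$ the two coincide with the Langmuir curve
  $T/(T+K_d)$, which the tests verify to 1e-6.
- At $T = 0$ the printed expression is singular; the signal is defined as 0
  by continuity, and the tests confirm the $\varepsilon \to 0$ limit.
- The root is evaluated as $2AT/(s + \sqrt{s^2 - 4AT})$ with
  $s = A+T+K_d$ — algebraically identical to the subtractive form but
  immune to the cancellation that costs ~7 significant digits when
  $4AT \ll s^2$. The discriminant is clamped at zero against round-off.

`fit_isotherm()` uses unweighted Levenberg-Marquardt least squares with
replicates entering as individual points (nothing in the source experiment
indicates weighting or replicate averaging), $K_d$ on the log scale to
enforce positivity, and starting values `Kd0 = median` nonzero $T$,
`constant0 = max` signal. Standard errors come from the local curvature
(delta method for $K_d$). Identifiability is design-limited: a $K_d$ well
above the titrated range (e.g. 26 uM probed over 0-750 nM) yields large,
honest standard errors; the analysis scripts display rather than hide this.

Random-library bookkeeping (`library_statistics()`) uses
$N_A = 6.02214076\times 10^{23}$ exactly: a 25-nt region spans
$4^{25} \approx 1.1\times10^{15}$ sequences, 100 pmol of input is
$\approx 6\times10^{13}$ molecules, so any one sequence is expected
$\approx 0.05$ times — the selection starts from a sparse sample of
sequence space.

## The synthetic-data generator

`sim_config()` + `simulate_selex()` emulate the study conditions end to
end, with ground truth attached to every sequence:

- **Library**: i.i.d. per-position draws with a thymine-biased composition
  (default A/C/G/T = 0.22/0.22/0.22/0.34), reflecting the bias observed in
  ostensibly random synthesized libraries. An adaptor-derived contaminant
  is spiked at 5% of reads — the most abundant library sequence, mimicking
  the adaptor-contamination signature seen in real unselected pools.
- **Affinity**: sequences carrying the planted 8-nt motif (<= 1 mismatch)
  get `Kd_motif = 390` nM, a representative selected-aptamer affinity;
  everything else gets `Kd_bg = 1e6` nM. Parasite sequences (5, drawn
  motif-free) have no affinity but carry an amplification advantage.
- **Rounds**: the positive-round target concentrations default to
  50, 10, 5, 1, 0.5 nM with negative rounds after rounds 2 and 3, and each
  round's output seeds the next — including through negative rounds, as in
  the real selection chain. Per round, every sequence receives capture
  weight `capture_efficiency * bound_fraction + background_carryover`
  (bound fraction from the quadratic model at the round's protein
  concentration; binders are treated as background in negative rounds,
  where the tag-only target gives them no advantage; parasites get their
  carryover multiplied by `parasite_pcr_gain = 4` in every round). The next
  pool is a multinomial sample of `depth_per_round = 1e5` reads.
  Amplification bias is a per-sequence multiplicative weight, not
  cycle-by-cycle PCR — sufficient to produce persistent parasites at a
  fraction of the cost.
- The pool sequenced from a negative round is this capture-weighted
  ("bound/sticky") fraction, so parasites concentrate there while binders
  and background pass through at carryover level — reproducing the
  signature that lets the negative-pool comparison work.

What the generator does **not** emulate: sequencing errors, chimera
formation, realistic quality profiles, length variants of the random
region, or cycle-dependent PCR artifacts. Passing tests therefore
demonstrate the pipeline's logic under clean reads with known truth — not
robustness to base-calling noise, which real data would add on top.

Determinism: the whole simulation is a pure function of the seed (sorting
uses radix order, i.e. C-locale byte order, so ties are
platform-independent), and written FASTQ round-trips bit-exactly through
the read-processing stage.

## Problem sizes and test design

The test suite and the acceptance script run, by the package's own choice
of scale: a 3-round selection at 1e5 reads/round for recovery checks
(planted binders should dominate the top-50 enrichment list; all planted
parasites flagged; no binder flagged; the contaminant showing the
library-abundant non-enriched pattern); 100 simulated titrations per assay
design for Kd recovery; 200 random small instances against a brute-force
restatement of the greedy rule; exhaustive alignment enumeration up to
7 nt plus an independent dynamic-programming score check up to 12 nt; and a
48-point grid against a numerical mass-action solve at 1e-9 relative
tolerance. The 5-round analysis workflow intentionally runs past the sweet
spot: late rounds show parasites overtaking the raw enrichment ranking and
stochastic-drift survivors among clean candidates — both worth seeing,
since they motivate the negative-pool filter and early-round candidate
picks (the study's own strongest candidates came from rounds well before
the endpoint).

## Known limitations

- Greedy clustering is order-dependent by definition; representatives are
  unmergeable only under the scan order, not globally.
- Identity at threshold 0.8 over primer-attached sequences is weakly
  discriminating (see above).
- The enrichment pseudocount makes FE values for reference-absent
  sequences depth-dependent (scale invariance holds exactly only for
  sequences observed in both pools).
- The isotherm's `as_printed` form and the conventional bound-fraction
  form disagree quantitatively away from the Langmuir limit; fits of the
  same data under the two forms yield different `Kd` estimates, so the
  form in use is always recorded in the fit object.
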