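---
title: "Phosphomimetic peptide-phage display: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphomimetic peptide-phage display: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosdisplay)
library(dplyr)
```

## The problem

Short linear motifs (SLiMs) in intrinsically disordered protein regions
mediate a large share of regulatory protein-protein interactions, and
phosphorylation of serine/threonine residues in or around a motif can
switch an interaction on or off. Proteomic peptide-phage display
(ProP-PD) probes SLiM-based interactions at scale by displaying a
designed peptidome on phage and selecting against purified bait
domains. The phosphomimetic variant of the approach displays, for every
candidate phosphosite, both the wild-type peptide and a version in
which that serine or threonine is replaced by glutamate — a genetically
encodable proxy for the phosphorylated residue. Comparing the
enrichment of the two members of each pair across selections reads out
whether "phosphorylation" (as mimicked by glutamate) enables or
disables binding.

`phosdisplay` implements this workflow end to end: library design,
selection-sequencing processing, the phosphomimetic enrichment score
(PES) with significance testing, fluorescence-polarization (FP)
affinity analysis for orthogonal validation, and a seeded simulator
that makes every step testable without laboratory data.

## Library design

Phosphosites enter the design from a phosphoproteomics-derived table
and are filtered on two per-site quality scores in $[0,1]$:
localization probability (how confidently the site is placed on the
exact residue) at $\ge 0.75$, and a functional score (how likely the
site is biologically relevant) at $\ge 0.4524$. Both defaults match
the published design this package models. Two rescue mechanisms keep
the design from discarding whole proteins: a protein none of whose
sites pass contributes its single highest-functional-score site
(ties broken toward the N-terminal site — the tie break is not
specified in the original description and is fixed here for
determinism), and proteins on an explicit rescue list keep all their
sites. Rescued sites bypass both cutoffs; they are flagged `rescued`
so downstream analyses can stratify on them.

Disordered regions are tiled into 16-mer peptides overlapping by 12
residues (step 4). Region ends rarely fall on the tiling grid, so when
the last regular tile stops short of the region end one extra tile is
anchored at the end; regions shorter than 16 residues yield a single
short peptide rather than being padded, since no padding scheme is
described for the parent library. Every region residue is therefore
covered, and most interior sites end up on 3–4 overlapping peptides —
which is what later gives the enrichment score several datapoints per
site.

Each (tile, contained site) pair produces one phosphomimetic entry
with exactly that site mutated S/T→E. A tile with $k$ sites yields
$k$ single mutants sharing one wild-type entry; double mutants are
never generated, so each pair isolates one site's effect.

Reverse translation to display oligos is deterministic: each residue
gets its top-ranked codon from an *E. coli*-optimised table
(`ecoli_codon_table()`), and whenever the assembled construct —
including the fixed phagemid flanks, because a restriction site can
straddle the junction — contains a forbidden motif, the left-most
codon overlapping the left-most occurrence is bumped to its next rank
and the scan repeats. The default forbidden motif is the SmaI site
`CCCGGG`, which must be absent because SmaI digestion is used to
eliminate non-recombinant phagemid during library construction. With
at least two codons per amino acid available around any P/G-rich
stretch the procedure always terminates; the test suite asserts this
over whole synthetic designs.

## Selection sequencing processing

Reads are demultiplexed by exact match of the unique 5'/3' barcode
pair (no mismatch tolerance, for determinism), kept when their mean
Phred score is at least 20 (inclusive), trimmed between the constant
adapters and translated with the standard genetic code. Reads whose
insert is missing an adapter, out of frame, or contains a stop codon
are rejected with a reason code. Peptides are matched to the design by
exact amino-acid identity, so synonymous DNA variants collapse;
peptides absent from the design and singletons (read count 1) are
removed. Counts are then normalized to counts-per-million per
experiment — the original description says only "normalised", and a
fixed per-experiment total makes replicates and days directly
comparable. Selection days of the same replicate are merged by
averaging normalized counts, with a peptide absent on a day counted as
zero on that day; the merge is order-invariant.

Per-peptide confidence levels use four additive binary criteria
(occurrence in at least two replicates, an enriched overlapping
peptide from the same region, a consensus-motif match, and a
normalized count at or above the bait's median), mapped to
none/low/medium/high. The exact weighting used by the original
annotation service is not restated in the source work, so the four
equally weighted criteria are this package's own operationalisation of
the same evidence types.

Library coverage from naive (unchallenged) library sequencing is the
fraction of designed peptides observed in the union of samples; with
two or more samples a two-parameter saturating exponential
$C(k) = C_{max}(1 - e^{-bk})$ is fitted to the accumulation curve and
$C_{max}$ (capped at the design size) gives the estimated maximum
coverage. The functional form is the simplest saturating model for an
accumulation curve and is isolated in `estimate_coverage()`.

## The phosphomimetic enrichment score

For one bait and one phosphosite, every phosphomimetic peptide
covering the site is paired with its wild-type partner, one datapoint
per overlapping peptide per replicate. With normalized counts
$nc^{wt}_i$ and $nc^{pm}_i$ over $n$ datapoints,

$$
\mathrm{PES} \;=\; \sum_{i=1}^{n} \frac{nc^{pm}_i}{nc^{wt}_i + nc^{pm}_i}
\;-\; \sum_{i=1}^{n} \frac{nc^{wt}_i}{nc^{wt}_i + nc^{pm}_i},
$$

bounded by $\pm n$, positive when the phosphomimetic member is
preferentially enriched. Datapoints with both counts zero are
undefined under the formula and carry no information; they are
excluded before scoring, which also means $n$ (and the bound) refers
to the retained datapoints. The sum is over $n$ datapoints — an
$i = 0 \ldots n$ indexing would contradict the stated $\pm n$ bound,
so the $n$-datapoint reading is used. Each datapoint's contribution is
invariant to rescaling both counts, and swapping the wild-type and
phosphomimetic vectors negates the score exactly.

Significance comes from a two-sided Mann–Whitney test comparing the
wild-type and phosphomimetic count vectors: the exact null
distribution when both groups have at most 10 observations and the
data are tie-free, otherwise the normal approximation with mid-ranks,
tie-corrected variance and continuity correction. The test is
delegated to `stats::wilcox.test()`, whose exact/approximate switching
matches this rule; the test suite verifies the exact branch against a
full permutation enumeration for group sizes up to 6. Sites are
classified *enabling* (PES $\ge$ 2, $p \le 0.01$), *disabling*
(PES $\le -2$, $p \le 0.01$) or *not significant*; a stringent mode
($p \le 0.001$) is exposed via the same arguments. Raw p-values drive
the classification, matching the reference analysis; an optional
Benjamini–Hochberg column is available (`adjust = TRUE`) but is not
used for classification.

## Orthogonal affinity validation

`read_affinity_panel()` ships a 32-triplet benchmark panel: K_D values
for wild-type, glutamate and phosphorylated versions of the same
peptide against a panel of bait domains, with the matching PES and
p-value from the phage data. K_D cells may be numeric (micromolar), an
upper bound `"<x"`, or `"n.b."` (no detectable binding); bounds
propagate directionally through fold-change computations, with
`"n.b."` counted as an unbounded loss of affinity.

`concordance()` asks whether the phage-derived call predicts the
measured effect of phosphorylation: a record passes at $p \le 0.01$
and $|\mathrm{PES}| \ge 2$, and a passing record agrees when the PES
sign matches an at-least-twofold K_D change in the same direction
(enabling = tighter binding of the modified peptide). For baits probed
through two binding pockets only the major pocket is representative,
since it dominates the phage selection. On the shipped panel this
yields 18 passing pairs of 28 representative records, 14 of them in
agreement (78%).

Two rank correlations summarise the panel. The wild-type/
phosphomimetic versus wild-type/phosphorylated fold-change correlation
uses signed $\log_2$ K_D ratios over rows with finite values on both
axes; the PES versus phosphorylation fold-change correlation uses
representative rows only. Both are computed from the panel's
printed-precision K_D values; rank correlations are sensitive to
rounding when fold changes are close, so small differences from values
computed on unrounded instrument output are expected.

## FP curve models

All concentrations are handled in micromolar; probe amounts quoted in
nM must be converted by the caller (readers do not guess units).

**Saturation.** With total protein $P$, total probe $L$ and probe
dissociation constant $K_d$, the bound-probe concentration under the
1:1 ligand-depletion ("quadratic") model is
$[PL] = \tfrac{1}{2}\big( (P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL} \big)$,
and the signal is linear in the bound fraction. Initial guesses take
the signal extremes for the free/bound plateaus and the half-signal
concentration for $K_d$; fitting uses Levenberg–Marquardt
(`minpack.lm`), is deterministic given the data, and flags estimates
at the parameter bound.

**Displacement.** The competitor series is fitted with a descending
logistic in concentration with the Hill slope fixed at 1 by default
(the mechanistically expected value for 1:1 competition) or free; the
IC50 is the total competitor concentration at half-maximal signal
change. A curve whose displacement amplitude at the highest competitor
concentration is under 20% of the reference amplitude is flagged "no
binding" and no IC50 is reported — the original work reports "n.b."
without a numeric criterion, so the 20% threshold is this package's
explicit choice. When the free-probe signal is supplied the amplitude
is referenced to it; otherwise to the observed top plateau.

**IC50 → K_i.** The conversion uses the exact competitive-equilibrium
analysis: at zero competitor $[PL]_0$ follows the quadratic model; at
the IC50, $[PL] = [PL]_0/2$, the free species follow from the mass
balances, and $K_i = [P]_{50}[I]_{50}/[PI]_{50}$. Rather than trusting
the published algebra, the package carries a numeric three-species
equilibrium solver (`solve_competitive_equilibrium()`, monotone root
bracketing on free protein) and the test suite requires the closed
form to match it across a 125-point grid to well under 1% — in
practice the two agree to numerical precision, confirming the exact
analysis uses free (not total) species in the denominator. IC50 values
below the theoretical minimum (the bound-competitor concentration at
complete displacement) are rejected as input errors.

**Active fraction.** Displacement amplitudes can shift between protein
preparations; `back_calculate_active_fraction()` refits the saturation
model with $K_d$ fixed and a single multiplicative active-concentration
parameter in $(0, 1.5]$, reproducing the amplitude-normalisation step
of the FP workflow.

## The simulator and what passing tests mean

The simulator generates every input the analysis consumes, with all
randomness behind one explicit seed (fixed seed, byte-identical
output):

* **Proteomes** — random sequences with near-natural residue
  frequencies, one disordered region per protein, phosphosites drawn
  per S/T residue at a configurable density, and Beta-distributed
  quality scores (localization $\mathrm{Beta}(8,2)$, functional
  $\mathrm{Beta}(2,2)$), so the design filter keeps a realistic
  minority of sites.
* **Selections** — serial panning as per-round multiplicative fitness
  with multinomial resampling at the sequencing depth: a pair's
  enrichment factor applies to both members, and the phosphomimetic
  member is additionally multiplied by its site's `pm_preference`
  (1 = no effect). Defaults (2 rounds, mirroring the two sequenced
  selection days; depth $10^5$; 3 replicates; per-pair enrichment
  drawn log-uniformly between 2 and 8; preference 4 for affected
  sites) give strong-effect sites roughly a 16-fold count ratio after
  two rounds, comparable to a clearly phospho-modulated interaction.
* **FP plates** — saturation signals from the quadratic model,
  displacement signals from the numeric equilibrium solver, plus
  Gaussian noise in mP.

`simulate_fixture()` writes a complete miniature study and stamps it
with expected per-site results computed by a deliberately plain
base-R reference implementation of the scoring path
(normalize → merge → pair → PES → Mann–Whitney), kept separate from
the dplyr pipeline so the two routes are independent.

Calibration checks in the test suite use a 200-protein null fixture
(no preference anywhere; the fraction of sites called modulated at
$p \le 0.01$, $|\mathrm{PES}| \ge 2$ must stay at or below 2%, and the
mean PES near 0) and a 40-protein power fixture (preference 4; at
least 90% of affected sites with $n \ge 6$ datapoints must be called
with the correct sign). Sites covered by a single peptide pair
($n = 3$ datapoints with 3 replicates) cannot reach $p \le 0.01$ under
the exact test — the smallest attainable two-sided p is 0.1 — which is
the design rationale for tiling sites onto several overlapping
peptides.

The simulator does **not** emulate sequencing errors, phage display
bias, amplification (growth-rate) bias, stop-codon suppression or
kinase specificity. Passing tests therefore demonstrate correctness of
the computational pipeline under the stated sampling model, not
robustness to those experimental artefacts; on real data the
confidence-level and replicate structure carry that burden.

## Known limitations

* Glutamate is an imperfect phosphate mimic: obligate phospho-binders
  (14-3-3, polo-box and similar domains) require the phosphate moiety
  and are expected to produce false negatives in the enabling
  direction regardless of analysis quality.
* The concordance correlations computed from printed-precision K_D
  values can differ in the second decimal from values computed on raw
  instrument output (see above).
* Coverage extrapolation assumes exchangeable naive aliquots; strongly
  unequal sequencing depths between aliquots will bias $C_{max}$.
* The fold-change convention (enabling = variant binds tighter) and
  the 20% no-binding threshold are package choices and should be kept
  fixed within a study.
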