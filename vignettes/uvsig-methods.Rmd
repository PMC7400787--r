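---
title: "Methods: UV signature enrichment and hydrophobicity drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UV signature enrichment and hydrophobicity drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvsig)
```

## Scope

`uvsig` quantifies ultraviolet (UV) mutagenesis in somatic variant sets and
traces its biochemical consequence — a drift of the encoded proteome toward
hydrophobicity — through four connected analyses:

1. a **UV mutational signature enrichment score (UVMSE)** computed per sample
   from trinucleotide-context counts around each substitution;
2. a deterministic **in-silico mutagenesis simulator** over all 4096
   hexanucleotide (two-codon) stretches;
3. a **neopeptide hydrophobicity** analysis over the 8–10-mer windows the
   MHC class I pathway presents;
4. **cohort stratification** statistics (ROC threshold, Fisher odds ratios,
   Kaplan–Meier / log-rank) relating the score to immunotherapy outcome.

A seeded synthetic-fixture layer generates references, variant sets,
transcriptomes and outcome cohorts with the statistical structure these
methods assume, so everything is testable offline.

## The signature and its companion tables

A *signature channel* is a single-base substitution together with its
immediate 5' and 3' flanking bases. Strand-resolved, there are
4 × 2 × 3 × 4 × 2 = 192 channels (each pyrimidine-reference channel plus its
purine-reference reverse complement). The bundled UV signature
(`uv_signature_file()`) is a **synthetic stand-in**, constructed — not
fitted — from the qualitative physics of UV mutagenesis: C>T transitions at
dipyrimidine contexts (a 5'-pyrimidine neighbour) dominate, with roughly 95%
of the probability mass on C>T channels; purine-reference channels carry a
quarter of the weight of their complements, reflecting the transcriptional
strand bias of lesion repair; and the single published anchor, the TCC>TTC
channel at probability 0.2887, is pinned exactly. The file header and
`data-raw/make_uv_signature.R` document the construction. Quantities that
depend on the *shape* of the full signature (the per-iteration hydropathy
delta, stop-codon gains) therefore differ numerically from results computed
with the original published table, while quantities anchored to the pinned
channel or to the codon table alone reproduce at the tolerances stated in the
tests.

The codon-usage table is the standard human table in per-mille units; the
loader rescales any consistent unit by its total. The hydropathy scale is
Kyte–Doolittle (arbitrary units, AU; positive = hydrophobic). Translated stop
codons are scored at 0 AU by default — they are tracked as a census rather
than as hydropathy, since a premature stop's biological effect (truncation,
nonsense-mediated decay) is not a hydropathy effect; the value is
configurable via `load_hydropathy_scale(stop_value = )`.

## In-silico mutagenesis over hexanucleotide stretches

Six-nucleotide stretches represent two in-frame codons and are the shortest
unit on which the context-dependent signature can be evaluated at every
position of a codon in any reading frame. Each stretch `s` carries prior mass
`P(codon1) × P(codon2)`; positions 2–5 are mutable (terminal positions lack a
flank), giving 4096 × 4 × 3 = 49,152 single-mutant transitions.

One iteration — one dose of UV exposure — treats the signature probability
`q(s→m)` of each transition as a per-opportunity rate: mass `p(s)·q(s→m)`
moves from `s` to the mutant `m`, unselected mass stays on `s`, and at most
one substitution occurs per stretch per cycle. This reproduces the one-cycle
arithmetic of the worked example exactly (the TCCGAG → TTCGAG transition
contributes `0.0007 × 0.2887 × (+3.6)` AU) and makes multi-cycle evolution a
well-defined Markov chain: iteration `k+1` starts from the mass the previous
cycle left. The chain is run with a precomputed sparse transition matrix and
is deterministic; a hard error is raised if any stretch's total outgoing
probability exceeds 1, which would make the per-opportunity reading
incoherent.

Choices worth making explicit:

* **Renormalization**: signature probabilities are *not* renormalized over
  the channels applicable to a given stretch. The simplest reading — raw
  per-opportunity rates — is the one that reproduces the single-iteration
  arithmetic, and it keeps the dose interpretation linear.
* **Reciprocal strand**: by default a substitution is looked up only as
  written on the stretch; `include_reciprocal = TRUE` also credits the
  complement-strand channel, the variant used for sensitivity analysis.
* **Censuses**: the amino-acid census is emitted as probability mass per
  codon slot (with a mass × 4096 pseudo-count attached), and stop-codon gain
  is reported relative to the iteration-0 stop mass.
* **5-mer reduction**: `stretch_length = 5` (one codon plus one flanking base
  each side, uniform flank prior) reproduces the hydrophobicity drift on the
  smaller state space, a robustness check on the hexamer construction.

With the bundled tables the baseline exome hydropathy (mass-weighted sum
over all stretches) is −0.7188 AU, one iteration adds +0.1002 AU, and the
expected hydropathy increases monotonically over at least 100 iterations
while stop-codon mass grows by ~30% after one cycle and ~445% after twenty.

## The UVMSE score

For each filtered substitution a 41-nt reference window (20 nt either side,
clipped at contig ends) is extracted. For channel `m` with folded context
motif (e.g. TCC for the TCC>TTC channel) and substitution class `b` (the
folded ref>alt pair, e.g. C>T, counting G>A as its reverse complement):

* `mut_m` — variants matching `m` or its reverse complement;
* `con_m` — occurrences of the motif or its reverse complement in the
  reference windows of class-`b` variants;
* `mut_b` — all class-`b` variants;
* `con_b` — occurrences of the reference base or its complement in those
  windows.

The per-channel enrichment is the fold-excess
`E_m = (mut_m · con_b) / (mut_b · con_m)`, and the score is the
signature-weighted sum `UVMSE = Σ_m p_m · E_m` over all 192 channels. Under
context-independent mutagenesis each ratio cancels in expectation and the
score is ~1; signature-driven mutagenesis inflates exactly the channels the
signature weights.

Conventions, each of which the tests pin down: counts are aggregated over
all of a sample's windows before any ratio is formed (the score is
per-sample, not per-window-averaged); overlapping windows are counted in
full; the focal base's own motif occurrence is included (the window is the
*reference* copy); the substitution class is the folded ref>alt *pair* — for
a C>T channel the denominator counts C>T and G>A mutations, i.e. analogous
substitutions in other contexts — and its context totals are taken over that
class's windows; degenerate denominators yield `E_m = 0` (conservative for
short panels, and the affected channels are listed); QUAL ≥ 50 and depth ≥
100 are kept, missing values pass; BED region input is 0-based half-open,
VCF/FASTA coordinates 1-based inclusive; multi-nucleotide substitutions are
decomposed into component SNVs (UV's CC>TT contributes two channel hits) and
indels are dropped with a count. The per-sample UV-weighted mutation load is
`n_variants_used × UVMSE`, using the post-filter count (both counts are in
the log).

## Neopeptide hydrophobicity

A coding variant applied to a CDS yields before/after peptides (translation
stops at the first stop codon; a length-changing edit shifts the frame and is
translated to the first downstream stop). All 8-, 9- and 10-mer windows
containing a changed residue are enumerated, clipped at the termini, and
paired with the same-coordinate windows of the unmutated peptide; an interior
missense far from the termini yields 8+9+10 = 27 pairs, each carrying the
same residue swap, so the neopeptide total equals 27 × the full-length delta
there. Per-pair deltas are *summed* (not averaged) per mutation and per
sample. Expression weighting is linear in the transcript's fraction of total
expression — the simplest normalization consistent with "weighted by
expression" — and a zero-expression transcript contributes nothing.
Genome-to-transcript projection is out of scope: the variant→CDS map is an
explicit input.

## Cohort stratification

TMB categories use the clinical bounds low 1–5, intermediate 6–19, high ≥ 20
mutations/Mb (values < 1 fold into low). The UVMSE dichotomization threshold
is chosen by maximizing Youden's J on the ROC curve (via pROC), with
`score ≥ threshold` defining UV-high; "maximizes the area under the ROC
curve" does not by itself define a threshold rule, so J — the standard
operating point — is adopted and documented. The reference clinical
threshold 0.7917 (and the whole-exome variant 1.642) are shipped as
documented defaults, not claimed reproducible, since they derive from
cohorts this package does not ship. Response uses the RECIST dichotomy CR/PR
vs SD/PD. The odds ratio is the cross-product `(a·d)/(b·c)` with a log-OR
normal CI (Haldane correction on zero cells, flagged) and the exact
Fisher p; survival uses Kaplan–Meier medians ("not reached" reported as NA)
and the Mantel–Cox log-rank test with standard right-censoring. The
stratified report pools low and intermediate TMB — the comparison of
interest is high vs the rest — and skips strata with fewer than two patients
or a single UV group, with a note. Multivariate models are deliberately not
implemented; the tidy cohort table can be exported for external fitting.

## Synthetic fixtures: what they emulate, and what they do not

* `synth_reference`: iid bases at a requested GC fraction. No repeats,
  isochores or chromatin structure.
* `synth_variants`: with probability `f` a variant's context is drawn from
  the signature (channel → uniformly chosen matching reference position),
  otherwise uniform; QUAL/DP are sampled above the default filters so filter
  tests are explicit. Draws are coupled across `f` at a fixed seed (common
  random numbers): both candidates are realized per slot and `f` selects,
  which makes score monotonicity in `f` structural rather than seed-lucky.
  No clonality, sequencing error or caller artifacts.
* `synth_transcriptome`: start codon + usage-weighted non-stop codons +
  terminal stop; gamma-distributed expression. No splicing, UTRs or paralogy.
* `synth_cohort`: exponential survival with group-specific medians, uniform
  censoring over a follow-up window, response probabilities planted per
  UV-group × TMB-stratum (effect only in low/intermediate TMB, matching the
  clinical finding being modelled; the planted rates default to the reported
  45% vs 14% and 58% vs 57%). Simulated UVMSE scores are Gaussian around
  group means straddling the 0.7917 threshold.

Passing tests on these fixtures demonstrate that the estimators recover
known structure under the stated generative models — not that real tumor
data satisfy those models. In particular the null calibration (`E_m ≈ 1`)
holds for uniform placement on iid sequence; real genomes have context
composition that the windowed normalization is designed to absorb, but
panel footprints with extreme composition can still push individual channels
to their degenerate-zero fallback.

## Numerical and scale choices

Problem sizes used by the test-suite and the acceptance script — 100
simulator iterations, 20 null seeds × 500 variants on a 30 kb reference,
400-patient planted cohorts — were chosen as the smallest sizes at which the
Monte-Carlo checks have clear resolution. Probability mass is conserved to
< 1e−9 per iteration (observed: exact to machine precision); signature
validation requires unit total within 1e−6 and rejects duplicates, absent
channels and negative mass by name; all accumulation is in double precision.
Determinism: the simulator has no randomness; every generator takes an
explicit seed and restores the caller's RNG state.

## Known limitations

* The bundled signature is a constructed stand-in anchored at one published
  probability; analyses whose numbers depend on the full published profile
  will differ quantitatively (direction and orders of magnitude are stable
  under the construction's assumptions).
* The codon table's per-mille rounding propagates ~0.04% relative error into
  baseline quantities (e.g. the TCCGAG prior 0.00070064 vs 0.00070092
  computed from unnormalized per-mille values).
* Peptide handling of frameshifts is minimal (translate to first stop);
  nonsense-mediated decay and MHC binding affinity are out of scope.
* The UVMSE engine scores any loaded 192-channel signature, but no other
  signature table is bundled.
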