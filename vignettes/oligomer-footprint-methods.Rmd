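---
title: "Methods: oligomeric footprint mapping, occupancy modelling and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oligomeric footprint mapping, occupancy modelling and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and procedures:
what is computed, under which assumptions, which parameters matter,
and where the design was genuinely open. It states no empirical
result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The oligomer footprint model

Archaeal histones of the HMfA/HMfB family bind DNA as a tetramer that
protects a minimal footprint and then oligomerize by dimer addition.
The package encodes this as

$$L(r) = f_0 + s\,(r - 1), \qquad f_0 = 60\ \mathrm{bp},\ s = 30\ \mathrm{bp},$$

where the oligomer rank $r$ is 1 for the tetramer, 2 for the hexamer
(90 bp), 3 for the octamer (120 bp) and 4 for the decamer (150 bp).
MNase digestion of chromatinized cells therefore yields a
fragment-length ladder with 30 bp rungs starting at 60 bp; an
empty-vector (EV) control strain shows the nuclease's smooth
background length distribution with no rungs. Fragments are binned
into size classes $c \pm 5$ bp, $c \in \{60, 90, 120, 150\}$, for
class-resolved analyses; a width is assigned a rank only when it lies
within 5 bp of some $L(r)$, and ranks are capped at $r_{\max} = 4$
(the largest rung routinely resolved on gels and in sequencing).

## Coordinates, coverage, and normalization

All internal coordinates are 0-based half-open, converted at I/O
boundaries only. Bacterial and archaeal chromosomes are circular by
default; a fragment or window running past the contig end wraps
across the origin so that total coverage mass is conserved and the
origin shows no artificial depletion. Coverage is the full-span
per-base overlap count of fragments (midpoint-based counting is not
used anywhere).

Occupancy is the histone-strain coverage divided by the pseudocounted
EV coverage pooled over all fragment sizes,

$$O(x) = \frac{c_{\mathrm{strain}}(x)}{c_{\mathrm{EV}}(x) + 1},$$

which keeps zero-coverage control regions analyzable and cancels the
shared AT cutting bias. Both tracks can optionally be scaled to
fragments-per-million first (`scale_libraries`); the default is off,
appropriate when strain and control libraries come from one matched
sequencing design, and all downstream rank statistics are invariant
to that monotone rescaling anyway.

## The synthetic study

The generator produces every input the pipeline consumes, with the
planted structure that each downstream stage is supposed to recover.
Its defaults are the package's reference study conditions; all are
exposed in `sim_config()`.

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 200 kb | desk-scale chromosome, circular |
| `gc_background` / `gc_promoter` | 0.50 / 0.30 | background vs promoter GC; promoters are AT-rich |
| `n_genes` × `gene_length` | 100 × 1 kb | non-overlapping transcripts with a 100 bp promoter upstream of the TSS |
| `utr_length` | 50 bp | TSS → start-codon offset |
| `beta_gc` | 16 | nucleation weight: sites drawn ∝ exp(β·GC61) |
| `density` | 8 particles/kb | target particle density |
| `f0`, `step`, `r_max` | 60, 30, 4 | footprint model |
| `p_extend`, `alpha` | 0.6, 0.8 | extension probability `p0(1 − α·AT_flank)` per attempt |
| `sigma` | 2 bp | digestion end jitter (rounded Normal) |
| `w_at` | 0.7 | probability an end snaps to the nearest A/T base; also scales EV cut bias |
| `mu` | 20 | fragments per particle (Poisson) |
| `gamma` | 1 | repression coupling, log2FC = −γ·z(O_TSS) |
| `phi`, `n_replicates` | 0.2, 5 | NB dispersion and replicates of the count simulation |
| `n_compendium` | 50 | comparisons, one planted at ρ ≈ 0.5 |

Placement is sequential rejection sampling: tetramer centers are
drawn with probability proportional to `exp(beta_gc · GC61)` (GC
fraction of the 61 bp window at the site), overlapping draws are
rejected, and sampling stops at the target density (with a warning if
it is unattainable). Each particle then makes `r_max − 1` extension
attempts; an attempt picks a side uniformly and succeeds with
probability `p_extend · (1 − alpha · AT_flank)` where `AT_flank` is
the AT fraction of the adjacent 30 bp; a collision with a neighbour
ends extension permanently. A failed probability draw does *not* end
extension — only collisions do — so all four rungs carry visible mass
at the defaults.

Two default values deserve comment. `utr_length = 50` separates the
TSS window from the 51 bp start-codon control window; without it the
control window would coincide with the TSS window and the control
analysis would be vacuous. `beta_gc = 16` was calibrated once against
the generator's own design requirement that per-window occupancy–GC
Spearman correlation exceed 0.3 at the defaults: at 8 particles/kb
roughly 60% of the genome is occupied, so sequence preference
partially saturates, and weaker weights leave the planted preference
below that bar.

The digest emits `Poisson(mu)` fragments per particle, jitters each
end by a rounded `Normal(0, sigma)`, snaps ends to the nearest A/T
base with probability `w_at` (the nuclease's preference), and clips
lengths at 20 bp. The EV library has the same cut bias (start
positions weighted `1 + w_at · AT61`) but smooth Gamma-shaped lengths
over 20–160 bp — bias without footprint structure. The ~30 bp
band seen in some exponential-phase digests is deliberately not
simulated; it appears in EV controls too and is likely an artefact of
digestion or library construction rather than histone protection.

Expression coupling: baseline log2 expression is Normal(8, 1); the
binding strain's true log2 fold change is `−gamma` times the
standardized true TSS ± 25 bp occupancy, plus — for a random 10% of
genes — a systemic shift shared with a non-binding control strain
(this exercises the exclusion rule), plus Normal(0, 0.25) noise.
Counts are negative binomial; the DE table is estimated with a
log-ratio of replicate means and BH-adjusted two-sample t p-values, a
deliberate surrogate for a count GLM since the pipeline consumes DE
tables agnostically. Seeds fan out per stage by a deterministic hash
of the stage name, so changing one stage's seed leaves the others
bit-identical.

What the simulation does *not* emulate: mappability variation,
replication-associated copy-number gradients along the ori–ter axis,
transcription-coupled remodelling, GC-skewed codon structure, or any
real promoter sequence grammar. Passing tests therefore show that the
estimators recover the stated generative structure at realistic noise
— not that real libraries satisfy these models.

## Footprint calling

Coverage is smoothed by a discrete Fourier low-pass filter keeping
the lowest `ceiling(kappa · N)` frequency components (conjugates
included, mean preserved). Local maxima of the smoothed track above
its `q`-quantile are candidate calls; neighbouring maxima whose
separating dip stays above `merge_frac` of the lower peak are treated
as one footprint; surviving dips bound each call; the width is the
extent above half the peak height within those bounds; the dyad is
the midpoint of that extent; the score combines normalized height
with closeness of the width to the nearest $L(r)$; remaining overlaps
are resolved greedily by descending score with leftmost-center
tie-break, so final calls never overlap.

Defaults: `kappa = 0.1`, `q = 0.3`, `merge_frac = 0.85`, all surfaced
in the pipeline configuration. The choice differs from the ~2%
component retention common in nucleosome-calling practice for
eukaryotic MNase data, deliberately. A brick-wall filter at
`kappa = 0.02` has a 50 bp pass-band: at 8 particles/kb, where
neighbouring footprints are frequently separated by gaps of only a
few bp, it merges adjacent particles and costs roughly a third of the
true footprints. With 2 bp end jitter the informative scale of a
footprint edge is a few bp, so the pass-band is set at the jitter
scale (10 bp at `kappa = 0.1`); the Gibbs ripple this admits is
handled explicitly by the dip-merging rule: ripple dips are shallow
(≳ 85% of the peak) while genuine inter-particle dips at gaps of
≥ 3 bp fall well below that, which is what `merge_frac = 0.85`
separates. The dyad is the half-height-extent midpoint rather than
the argmax because the smoothed footprints are flat-topped and the
argmax is ripple-sensitive. At intermediate pass-bands
(`kappa ≈ 0.03–0.05`) the ripple's twin maxima straddle the true
center — a configuration to avoid, which is why `kappa` should be
moved in decisive steps if tuned at all.

For the extension–flank analysis, every ranked call contributes one
tetramer record. The flanks of an unextended (rank 1) call are the
30 bp outside each edge — sequence that blocked or never hosted an
extension; for an extended call the flanks at decision time lie
inside the final footprint, so the outer 30 bp at each end of the
call are used. Using a fixed core centered on the call instead
provably cancels the signal, because beyond an extended call's edge
lies sequence that blocked *further* extension and carries the
opposite bias.

## Sequence model

K-mer counts (k = 1..4, 340 features, forward strand, no
reverse-complement collapsing) are computed in odd windows centered
on genome positions, the window width paired to the size class
(60→61, 90→91, 120→121 bp); windows containing N are dropped and
reported. The LASSO is fit by `glmnet` on features standardized
internally, with coefficients reported on the count scale. Training
uses only the contiguous genome prefix `[0, floor(L/6))` — for the
*E. coli* chromosome, positions 0–773,608 — and the penalty is chosen
by 10-fold cross-validation over contiguous blocks *within* that
prefix, to limit spatial leakage from the autocorrelated response.
Training positions are strided (default every 10 bp) to keep the
design desk-scale; evaluation may be run at any resolution on the
held-out remainder. The response is raw normalized occupancy by
default with a log2 option. Univariate "most informative k-mer"
rankings are Spearman correlations of each feature with the response,
reported alongside model coefficients since the two rankings answer
different questions.

A known desk-scale limitation, measured by the test suite: at the
default density and extension parameters only ~9% of particles reach
rank 3, so the 120 ± 5 bp class covers ~9% of bases, and the
correlation between any sequence score and realized 120-class
occupancy is near zero — placement stochasticity dominates. The
model's machinery is instead validated by a noiseless planted
five-k-mer response (held-out ρ > 0.99 with exact support recovery)
and by the pooled/60 bp-class analyses, where G and C top the
univariate ranking whenever the GC preference is planted. On real
deeply-sequenced genome-scale data the 120-class analysis is the
interesting one; on a 200 kb simulation it is information-starved,
and the suite reports the measured value honestly rather than
asserting an unreachable bar.

Read-internal profiles are computed from fragments of one *exact*
length only (a 61 bp fragment does not contribute to the 60 bp
profile), as position-by-base frequencies divided by genome-wide base
composition. The dyad-symmetry score is the mean absolute difference
between each enrichment cell and its reverse-complement mirror; 0 is
perfect symmetry, and the sampling-noise floor scales as
$\sqrt{3/n}$ for $n$ fragments at uniform composition.

## Transcription linkage

The exclusion rule removes genes significantly changed in the same
direction in both the binding and the non-binding strain (these
respond to histone expression, not to binding); remaining genes are
grouped up/down/unchanged at `padj < 0.05` by the binding-strain
table. Five windows are scored per gene and size class: the TSS
base, TSS ± 25 bp, the annotated promoter, the gene body (whole
annotated transcript), and the 51 bp control window centered on the
start codon — its width matching the TSS ± 25 bp window by design.
Group comparisons use the two-sided Mann–Whitney rank-sum test
(occupancy distributions are far from normal; the test is exposed in
config), suppressed below 3 genes per group.

Compendium similarity is the raw dot product of log2-fold-change
vectors over shared genes — not cosine, though cosine is exposed,
since raw dot products are the field's convention for this comparison
— with the Spearman correlation of the paired vectors reported
alongside, and genes missing from a comparison dropped rather than
zero-filled (the shared-gene count is reported). The up/down split
restricts the query vector to positive or negative entries; by
linearity the two component similarities sum to the full one.

NAP Δ-occupancy takes, for each protein-bound region, the mean
occupancy inside minus the mean in the unbound gap immediately
downstream, downstream meaning increasing genome coordinate (the
direction is not otherwise specified by the protein's biology); on a
circular contig the last region wraps to the first, on a linear one
its gap runs to the contig end and is skipped only if empty. The Δ
set is summarized by a two-sided Wilcoxon signed-rank test.
Regional analyses use non-overlapping 200-gene blocks (independence
over resolution; the step is configurable), stratified by whether
transcription is codirectional with replication — replication
direction being away from the configured origin toward the terminus
on each replichore — and the 500-gene-span, 20-gene-step moving
window provides the positional GC–occupancy correlation profile.

## Numerical and degenerate-input conventions

TSS ties (equal read support) break toward the smallest coordinate.
All-zero support keeps the first position with a warning. Peak
plateaus take the leftmost run as the maximum. Zero-variance inputs
to rank correlations are flagged and return `NA` rather than an
error; an all-zero Δ set makes the signed-rank test undefined and is
flagged. Fragment-length histogram rungs are called against a
running-median background (ratio 1.5, ±15 bp), with the histogram's
edge bins excluded (one-sided background; the ≥ 20 bp length clip
piles up there) and twin maxima within 10 bp consolidated to the
higher — a sparse top rung can split under counting noise.

## Problem sizes

The test suite runs the full chain at the 200 kb reference
conditions once (cached across tests), the seed-stability check of
the repression sign across 20 seeds, and everything else at 20–50 kb;
oracle comparisons (coverage, windows, k-mer counts, NAP Δ) use
random instances of ≤ 10 kb against brute-force reimplementations.
The acceptance script simulates 200,000-fragment libraries. These
sizes were chosen so the planted effects sit comfortably above their
detection thresholds while a full run stays in the minutes range on
one core.
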