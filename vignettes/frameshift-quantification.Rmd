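---
title: "Quantifying +1 programmed ribosomal frameshifting from footprint phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying +1 programmed ribosomal frameshifting from footprint phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshift)
```

## The model

A +1 programmed frameshift (PRF) gene consists of an upstream ORF
(ORF1) initiated at an AUG and an overlapping downstream ORF (ORF2) in
the +1 frame. At a heptameric shift site — CTT-AGG-C for Ty1-type
sites — the P site holds the CTT codon, the slowly decoded AGG codon
occupies the A site, and a fraction $p$ of ribosomes slips one
nucleotide 3′, resuming with GGC in the +1 frame. Everything the
package computes follows from this picture.

**Coordinates and phase.** Positions are 0-based half-open throughout
(BED-native); 1-based numbering is display only. The sub-codon phase of
position $x$ relative to a frame anchor $a$ is $(x - a) \bmod 3$;
phases 0/1/2 correspond to the display frames 1/2/3 used in
frame-phasing figures. Sequences are held in the DNA alphabet; U is
normalized to T on input and restored on request at output. A shift
site is addressed by the first nucleotide of its P-site codon, so the
heptamer occupies $[q, q+7)$, the zero-frame A-site codon starts at
$q+3$, and the post-shift A-site codon (the `a1` codon) at $q+4$ —
which is why an in-frame fusion construct is obtained by deleting the
single nucleotide at $q+3$, and why translation through the shift
equals standard translation of that deletion sequence. This identity is
exercised as a property test over the whole synthetic family corpus.

**A-site assignment.** Ribosome footprints of a fixed length have a
fixed offset from their 5′ end to the first nucleotide of the A-site
codon. The defaults (28-nt fragments, +15 offset) are the standard
high-phasing choice for yeast data; both the length set and per-length
offsets are arguments of `select_and_offset()`. Offset positions
falling off the transcript are dropped and counted. Offset calibration
itself (e.g. from metagene profiles) is out of scope: the offset is an
input.

**The efficiency estimator.** With an A-site track $w(x)$,

$$\hat{E} = 100 \times
  \frac{\sum_{x \in \mathrm{ORF2},\ \phi_2(x) = 0} w(x) \,/\, C_2}
       {\sum_{x \in \mathrm{ORF1},\ \phi_1(x) \in \{0,1\}} w(x) \,/\, C_1}$$

where $\phi_1$ is phase relative to the ORF1 start, $\phi_2$ phase
relative to the ORF2 window anchor (the `a1` codon, so that
$\phi_2 = 0$ is the +1 frame relative to ORF1), and $C_1, C_2$ are
codon counts. ORF1 collects phases 0 *and* 1 because ribosomes that
shifted inside ORF1 still initiated on ORF1: both populations belong in
the denominator. Conventions the estimator fixes (the underlying texts
are silent on them): the ORF1 codon count excludes the stop codon
(termination is not elongation); the ORF2 window is inclusive of the
`a1` codon, while reads with the A site on the zero-frame AGG codon
belong to ORF1 — mirroring the A-site hand-off at the shift site; and
any internal ORF a user wishes to exclude from the ORF2 density is
excluded by choosing the window regions, not by a hidden rule.
Uncertainty comes from `bootstrap_ci()`: multinomial resampling of read
weights (equivalent to resampling reads with replacement), percentile
intervals, fixed seed, and an explicit count of degenerate replicates
with empty ORF1.

**Reporter arithmetic.** For dual-luciferase constructs,
`percent_frameshift_reporter()` computes
$100 \times \overline{(d/u)}_{\mathrm{test}} / \overline{(d/u)}_{\mathrm{control}}$,
with the downstream cistron chosen by an orientation flag and
per-replicate ratios retained for external statistics (a *t* test on
replicates is deliberately left to standard tools).

## The comparative decision rule

`classify_homolog()` formalizes the manual inspection used to call
frameshift requirement in homolog families. Relative to the annotated
main-ORF AUG, the maximal N-terminal extension runs from the bracketing
stop (the first in-frame stop 5′ of the AUG) to the AUG. The call is

* `requires_fs` — the extension has no in-frame ATG of its own; an
  ATG-initiated upstream ORF overlapping the extension in the shifted
  frame carries a catalog heptamer; and the +1 frame is open from that
  site to the main-ORF stop (the 5′-most qualifying site is reported
  when several exist);
* `no_fs` — the extension carries an in-frame ATG giving an
  uninterrupted ORF;
* `ambiguous` — anything else (e.g. a site ablated to CTA-AGG-C).

One frame-indexing convention is fixed here once: indexing frames by
position mod 3, a ribosome at codon $q$ of ORF1 resumes at $q + 1$
after the shift, so the extension frame is (ORF1 frame + 1) mod 3 and
candidate ORF1 frames are (extension frame − 1) mod 3. The extension
ATG scan covers the whole extension; narrowing it by conservation
context (e.g. to positions 5′ of the first absolutely conserved
residue) would need alignment data that a single query lacks, so it is
not part of the rule. The stop set is fixed at TAA/TAG/TGA (yeast
nuclear code); catalog patterns support IUPAC degeneracy but default to
the five exact heptamers (Ty1/ABP140, EST3, Ty3, OAZ1, and the
CTT-CGG-C variant). Real families may use conservation evidence beyond
this rule, so agreement with published manual calls is not claimed —
the guarantee tested is exact recovery of construction labels on
synthetic families.

Conservation statistics follow the usual logo conventions:
`project_to_reference()` drops reference-gap columns so numbering
matches reference residues; `conservation_counts()` calls a column
conserved when the modal residue reaches a threshold fraction with gaps
counting as mismatches (a species missing the residue cannot support
conservation); `synonymous_frame_signature()` flags codon columns whose
amino acid is shared (threshold defaults to 1.0 — the published
analyses eyeball this pattern, so the strictest rule is the default)
while at least one row differs from the reference at the nucleotide
level. `neighbor_joining()` implements classical NJ (Q criterion,
Studier–Keppler updates) on uncorrected p-distances, with
lexicographic tie-breaking for determinism and negative branch lengths
clamped to zero; on additive matrices it provably recovers the
generating tree, which the tests verify exactly up to 8 leaves against
randomly generated trees and against an independent implementation
(`ape::nj`). Multiple-substitution distance corrections and bootstrap
support are out of scope.

## The synthetic generators

`make_template_transcript()` builds a miniature dual-ORF locus with
every architecture element in known positions: leader (20 nt, with an
upstream in-frame stop), ORF1 of 200 sense codons with the CTT-AGG-C
heptamer at codon 60, a +1-frame stop bracketing the extension directly
after the ORF1 start codon, an open +1 frame through a 150-codon ORF2
window, and an annotated "main ORF" AUG in the +1 frame downstream of
the ORF1 stop. The scale is a deliberate compromise: ORF1 sizes of real
+1 PRF genes range from tens of codons to the ~440 codons of Ty1 *gag*;
200/150 codons keep single-codon features (pause peaks, the window
anchor) at the percent level of the densities so that the estimator's
structural accuracy — not locus-specific edge effects — is what the
tests measure. Filler nucleotides are sampled under rejection so no
stop invades the two watched frames, no ATG appears outside the two
start codons, and no stray catalog heptamer arises; `fused` variants
delete the nucleotide 3′ of the P-site codon, `ablated` variants mutate
CTT to CTA.

`simulate_footprints()` draws, for each A-site codon on the two
ribosome paths (all initiating ribosomes through ORF1 frame 0; a
fraction `p_fs` continuing in the +1 frame from the `a1` codon),
a gamma–Poisson read count — negative binomial with shape
`dispersion`, the standard overdispersion model for per-codon
ribo-seq counts; shape 10 is the default, a moderate level typical of
codon-resolution data, and `Inf` gives Poisson. Each read's recorded
position equals the true A-site position with probability `fidelity`
(default 0.91, matching the in-frame fractions reported for
high-quality yeast datasets), otherwise it moves one nucleotide left or
right with equal probability — a symmetric two-sided error model;
real libraries have asymmetric error profiles, which is deliberately
not modeled because the symmetric version already produces the
estimator's leakage bias. Pause multipliers default to ×5 at the
zero-frame AGG codon and ×3 at the post-shift GGC codon, echoing the
visible pause peaks at real shift sites. One seed drives the entire
simulation; identical parameters and seed give byte-identical output.

Because the generative model is explicit, the estimator's expectation
has a closed form: `expected_efficiency()` spreads each path codon's
expected read mass over recorded positions
($f$, $(1-f)/2$, $(1-f)/2$) and evaluates the estimator's region/phase
sums on that expected track (the ratio of expectations, accurate to
$O(1/\text{reads})$). At $f = 1$ the expectation equals the true
$100\,p$ up to small geometric terms (the pause peaks and the
ORF1/ORF2 overlap bookkeeping contribute fractions of a point at these
region sizes); at $f < 1$ it quantifies the upward leakage bias —
ORF1-frame reads mis-recorded into the +1 frame inflate the ORF2
density. The acceptance checks hold the simulation to this oracle:
mean recovery within 1.5 percentage points of truth at perfect
fidelity (20 seeds, depth 1000 reads/codon, efficiencies 5–40%), and
agreement with the closed form within 3 Monte-Carlo standard errors at
fidelity 0.91.

`simulate_homolog_family()` evolves homologs from the shared template
by i.i.d. substitutions (default rate 0.03 per site, a within-genus
level that leaves architecture recognizable) with the
architecture-defining positions frozen; proposals that break an
architecture invariant are rejected and resampled, with the count
reported. Eight designated +1-frame codons (4-fold degenerate Thr, Ala,
Gly) receive only synonymous third-position substitutions, planting the
protein-level conservation signature in the +1 frame. The generator
emulates substitution-only divergence — no indels (except the known
fusion deletion), no rate heterogeneity, no recombination — so passing
tests demonstrate correctness of the detection logic, not robustness to
the full messiness of real homolog retrieval and alignment.

## Numerical choices and degenerate inputs

* Zero-weight regions give `NA` phase fractions with a warning rather
  than an error; a zero ORF1 density makes the efficiency undefined and
  is an error.
* Bootstrap replicates with empty ORF1 are excluded from the
  percentiles and counted in the result.
* Multi-mapped reads are counted at the weight given in the footprint
  table; fractional weights pass through all stages unchanged, and the
  estimator is invariant under positive rescaling of all weights.
* NJ ties on the Q criterion take the lexicographically smallest pair;
  conservation ties between equally frequent residues take the first in
  byte order via `which.max`.
* Translation without an in-frame stop returns the truncated protein
  with a warning and a `truncated` attribute rather than failing.
* `find_orfs()` reports every ATG–stop span (nested starts included),
  stop codon inside the interval, so its output is a superset any
  caller can filter.

## Problem sizes in the checks

The test-suite and acceptance-script simulations use the template
geometry above at depths of 1000 reads/codon (10⁴ for the
frame-fraction check), 20 seeds per grid point, families of 12–20
homologs, and 18 random additive matrices of 3–8 taxa — sizes at which
every stochastic guarantee has comfortable Monte-Carlo margin while the
whole surface runs in well under a minute.

## Known limitations

* The efficiency estimator inherits the leakage bias of real phasing
  data; the package quantifies it (`expected_efficiency()`) but does
  not de-bias the estimate, since doing so requires trusting the
  fidelity estimate itself.
* The homolog decision rule uses no conservation context; published
  manual calls on real families may differ for individual species.
* p-distances underestimate divergence at large distances; the NJ
  guarantees here concern additive inputs, not statistical consistency
  on real alignments.
* The simulators do not model fragment-length mixtures, ligation or
  nuclease bias, rRNA contamination, or initiation/termination peaks
  beyond the configurable pause multipliers.
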