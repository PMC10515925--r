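---
title: "Measuring reference bias: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring reference bias: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(biasbench)
```

This vignette is the package's own account of the science it implements: the
model behind each measure, the tunable parameters and their defaults, what
the synthetic data generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that the
test suite does not itself compute.

## 1. The three balances and what each isolates

Reference bias is a *differential* loss or corruption of evidence between a
donor's two haplotypes. We therefore measure the REF-allele read fraction at
each phased HET site at three pipeline stages and difference them:

* **SB** — fraction of *simulated* reads spanning the site that come from
  the REF-carrying haplotype. Pure binomial sampling: its only job is to be
  the baseline, because even a perfect pipeline shows SB ≠ 0.5 site by site.
* **MB** — the same fraction among reads that truly originated spanning the
  site *and* aligned spanning it. `MB − SB` (NMB) is exactly the bias the
  aligner added: reads mis-mapped *in* are excluded (they are tallied
  separately as `n_mismapped`), and reads lost show up as a depleted allele.
* **AB** — the fraction implied by an assignment algorithm alone, with no
  truth tags. `AB − SB` (NAB) is the bias of alignment *plus* tallying.

**Spanning, not merely overlapping.** All three denominators use reads that
fully span the site's *effective* variant interval. A read that covers only
part of a repeat tract (or ends one base into a deletion) cannot be
attributed to a haplotype by any algorithm; such reads are assigned `BOTH`
and excluded everywhere, symmetrically. This is what makes the zero-bias
identity exact — under the idealized aligner, MB ≡ SB and AB ≡ SB at every
site, which the acceptance suite asserts with equality, not a tolerance. Had
the denominators used mere overlap, SB and AB would differ at indels for
geometric reasons alone (REF and ALT footprints offer different numbers of
partial-overlap positions), and the identity would be false by construction.

## 2. Assignment: naive versus context-aware

The *naive* assigner reads the pileup: the base(s) the aligner placed at the
variant's reference coordinates, the gap exactly where the aligner put it.
It is the implicit assigner of most downstream tools, and it inherits every
gap-placement decision. In a tandem repeat, a one-unit deletion admits
several equally scoring placements; the VCF left-anchors the event, so any
other placement makes the read's footprint sequence match the *reference*
allele (the tract is periodic) and the ALT read is silently miscounted as
REF. That is the dominant "local" failure mode.

The *context-aware* assigner distrusts the aligner's base-level decisions.
Per variant it builds two **allelic context sequences** — allele plus phased
flanking sequence taken from the haplotype that carries it — and searches
the read for them, anchored first at the left boundary of the variant, then
at the right, so a gap placed anywhere between the boundaries cannot move
the comparison window. A prefix/suffix of a context suffices when the read
ends inside it; matching both contexts, or conflicting single-allele calls
from the two anchors, yields `BOTH`; matching neither, or any `N` in the
window, yields `OTHER`. `BOTH`/`OTHER` never enter AB.

Parameters, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `flank` | 5 bp | context flank; long enough to kill chance matches at 30×, short enough that sequencing errors rarely fall inside |
| `distance` | 25 bp | cohort chaining distance: variants closer than this are matched jointly as one haplotype string, because an indel in the cluster shifts its neighbours' coordinates |
| `max_effective` | 70 bp | cap on the effective variant; longer repeat tracts exceed what a 150 bp read can span with flanks, so such sites are disregarded rather than half-measured |

**Effective variants.** If one context core is a prefix of the other the
variant is extended rightward until the first differing base; a suffix,
leftward; an interior substring, on the side needing the shorter extension.
The loop runs on the haplotype sequences themselves, so phased neighbours
(including HOM-ALT ones, which are part of the donor but never measured)
participate automatically. A read that does not cover the whole effective
interval of an extended variant is `BOTH`.

**Exactness.** Matching is literal string equality over A/C/G/T. No
edit-distance tolerance: a sequencing error inside the window demotes the
read to `OTHER`, which costs a little power symmetrically rather than
introducing an asymmetric artifact.

## 3. Classification geometry

Sites with defined (NMB, NAB) are classified by, in order: the circle of
radius 0.1 about the origin (`balanced`); the wedge ½ ≤ NAB/NMB ≤ 2 with
both coordinates of the same sign, covering the upper-right and the rare
lower-left quadrant (`loss`); |NMB| ≤ 0.1 with |NAB| > 0.1 (`flux` if more
than 5 reads over the site are mis-mapped from elsewhere, else `local`); and
`outlier` otherwise. Two documented discrepancies in the source method were
resolved as follows: the balanced region is the *circle* of the methods
text, not the ±0.1 square of the results prose (the radius is a parameter);
and the flux/local region is gated on |NMB| ≤ radius per the body text, not
the contradictory |NMB| > 0.1 of the figure caption. Wedge boundaries are
inclusive, evaluated in product form (`|NAB| ≤ 2|NMB| + ε`) so that exact
boundary points do not fall to division rounding.

## 4. The per-site predictor

Without truth tags, bias must be predicted from observables. Two features
carry most of the signal: mean MAPQ of the reads over the site (repeats
announce themselves through ambiguous mappings) and the context-aware AB.
The two published combinations are implemented exactly as printed:

```
mul: (avgMAPQ − maxMAPQ)/maxMAPQ × AB
add: (avgMAPQ − maxMAPQ)/maxMAPQ × 1.5 + AB
```

(The source prose mentions Z-scoring the features; the printed equations are
not Z-scores, and the equations are what we implement.) Low scores mean more
bias; both scores are 0-anchored at the MAPQ ceiling, so *pure* loss at
full mapping quality is invisible to them — a real limitation of the
two-feature model, not of this implementation. The evaluation fixture
therefore injects loss together with low-MAPQ foreign reads, the combination
the features are designed to catch. An optional `folded = TRUE` substitutes
2·|AB − ½| for AB so bias toward either allele moves the score the same
way; the raw equations remain the default. `max_mapq` is a required
per-aligner setting (42 Bowtie 2/BWA-MEM, 60 Giraffe), never autodetected:
silently mixing ceilings would shift every score.

Before scoring, sites whose evidence is itself corrupt are dropped: >90% of
reads `OTHER`, or one HET allele entirely absent with >40% `OTHER` — the
signature of missing or mis-phased variants in the input VCF, not of
alignment bias.

## 5. Scan mode

When even the donor's variants are unknown, bias leaves regional traces:
collapsed duplications pile excess depth onto one copy, dense "SNVs" appear
where diverged paralogs collapse, and allele frequencies go non-diploid. Per
sliding window (400 bp, step 100 bp — the step is our choice; the window
statistic is the published one) we compute mean depth (RD), SNV-position
density and non-diploid-position density (VD, ND; per covered base so edge
windows are comparable), Z-score each against a sampled baseline, truncate
(Z(RD) < 1 → 0, since only depth *excess* indicates collapse; negative
Z(VD)/Z(ND) → 0) and sum. Windows ≥ 5 seed biased regions, [3, 5)
suspicious ones; same-label regions within 1 kbp chain together, and
overlaps resolve biased-over-suspicious.

A position's alleles are the bases above 15% frequency; ≥2 alleles make an
SNV; an SNV is non-diploid if ≥3 alleles pass the threshold or the top
allele is more than twice the second. Indel marks in the pileup are ignored
for allele calling; depth counts aligned bases. The baseline samples whole
windows (1/1000 by default) so the spread is estimated on the same statistic
being scored; two workflows being compared must share one jointly sampled
baseline, half from each, or the less biased workflow would be scored
against a stricter yardstick. A workflow "improves" a region biased in the
other if ≥25% of its bases are both covered above one fifth of the overall
mean depth and outside its own biased regions.

### Why the null calibration property is red

The acceptance suite asserts that an unbiased fixture yields <1% of windows
with score ≥ 5. Faithfully implemented, the rule set cannot meet this at
30×: a true HET column is "non-diploid" whenever binomial sampling reaches a
21:9 split (probability ≈ 4.3% per HET), and on a clean fixture the ND
baseline spread is so small that every such column spikes z_nd past the
threshold in the ~4 windows containing it. Measured null rates run 1–4%
across HET densities from 1/100 to 1/2000 bp. The <1% bound presumes
Gaussian window statistics; VD and ND are small-count Poisson at any
realistic density. This matches the method's published behaviour on real
data, where a noticeable fraction of *balanced* sites falls inside scanned
bias regions. The property is left failing rather than loosened.

## 6. The synthetic world

The generator emulates exactly the conditions the measures need: i.i.d.
uniform reference sequence with optional planted tandem repeats (unit 2–6
bp, 4–12 copies) and an exact segmental duplication; phased HET SNVs and
1–10 bp indels at chosen densities; 2×150 bp pairs, fragments ~400 ± 50 bp,
~15× per haplotype with *different* seeds per haplotype so the coverage
profiles are uncorrelated; i.i.d. substitution errors. The idealized aligner
places every read at its true origin with the CIGAR implied by the variants
it spans (insertions at read ends soft-clipped) and maximum MAPQ — the
zero-bias baseline that makes the identity tests exact. Four injection modes
then construct each bias signature deliberately (`drop_alt`,
`add_mismapped` with a compensating OTHER-ing of ALT reads so NMB stays
near 0 while NAB moves, `shift_gap` one repeat unit *rightward* — the VCF
already left-anchors, so an ambiguous aligner's alternative placements lie
to the right — and `collapse_duplication`).

What it does not emulate: realistic quality-score models, indel sequencing
errors (optional flag territory; substitutions exercise every assignment
code path), PCR duplicates, GC bias, or genome-scale repeat structure. A
green test therefore establishes the *logic* of measurement, assignment,
classification and scanning — not performance on real genomes, which needs
real benchmark data.

## 7. Numerical and interface choices

* Intervals are 1-based closed throughout (the R/Bioconductor convention);
  BED output converts at the writer. VCF input is 1-based as specified.
* Multi-allelic records are split per ALT; genotypes like `1|2`, half-calls
  and `./.` mark their footprint as unresolvable and are removed together
  with anything they touch (transitively — a deletion over an SNV removes
  both).
* Undefined balances (zero denominators, disregarded sites) propagate as
  `NA` and are excluded from classification and plots.
* `avg_mapq` averages over *all* spanning reads including `BOTH`/`OTHER`:
  the predictor wants the mapping signal, not the assignment's opinion.
* All randomness flows from explicit integer seeds; same seeds give
  byte-identical TSV/BED outputs (asserted in the acceptance suite).
* Ties and boundaries: wedge bounds inclusive; "more than 5 mismapped
  reads" and "more than twice the second allele" strict; score ≥ 5 biased,
  ≥ 3 suspicious.

## 8. Known limitations

Diploid only (the balance algebra generalizes to higher ploidy, the 1:1
expectation does not). Exact matching makes long indels increasingly
error-fragile, biasing AB toward the shorter allele at long insertions — in
real data; the error-free fixtures do not show it. The two-feature predictor
cannot see pure loss at full MAPQ and does not separate flux from local.
Scan-mode pileups are held in memory; the implementation targets
benchmark-scale fixtures (megabases), not whole human genomes.
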