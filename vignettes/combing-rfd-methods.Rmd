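---
title: "Methods: single-molecule RFD profiling and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule RFD profiling and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combRFD)
```

## The measurement model

A dual-pulse combing experiment labels asynchronously cycling cells with
IdU for one pulse (20 min by default) and CldU for a second, stretches the
DNA, and maps individual fibres onto a reference locus with FISH anchors.
On an oriented fibre, the order of the two analogs along a replication
signal gives the direction of the fork that made it: IdU then CldU reading
left to right is a rightward fork, the converse a leftward fork.

### Track grammar

`classify_structures()` reads a fibre's ordered tracks as a chain of *fork
junctions*:

* adjacent IdU→CldU = rightward fork junction; CldU→IdU = leftward;
* a track shared by a leftward junction on its left and a rightward one on
  its right (the central IdU of CldU–IdU–CldU) is an **initiation**,
  anchored at the track centre — the midpoint between the diverging forks;
* the symmetric CldU of IdU–CldU–IdU is a **termination**;
* when an origin fired before the first pulse, the central IdU is split in
  two by an unlabelled gap (CldU–IdU…IdU–CldU); the initiation anchor is
  the gap midpoint. Terminations split symmetrically
  (IdU–CldU…CldU–IdU);
* a lone *intact* CldU track is an initiation that fired during the second
  pulse; a lone IdU track — or a lone CldU with a broken end — is
  direction-ambiguous and left `unoriented`.

Two design choices deserve comment.

**Junctions, not greedy scanning.** An alternative is to scan left to
right and greedily consume maximal patterns. That parse is not symmetric
under end-to-end reflection of the fibre: CldU–IdU–CldU–IdU would parse as
an initiation plus an unoriented leftover IdU, while its mirror image
would parse as a termination plus a leftover. Reflection symmetry is not
cosmetic — a combed molecule has no intrinsic left end, so any asymmetry
of the parser is an artefact. The junction grammar is symmetric by
construction and is also the physically complete reading: in
CldU–IdU–CldU–IdU three forks are visible and the chain carries *both* an
initiation (shared IdU) and a termination (shared CldU). A consequence is
that consecutive events can share a track, so structure rows returned by
`classify_structures()` may overlap by one track in alternating chains.

**Broken lone CldU tracks are unoriented.** A CldU track cut by a physical
fibre break could be the surviving half of an elongating fork whose IdU
went with the lost fragment; calling it an initiation would plant a false
leftward half-segment. Only unbroken signals are allowed to orient DNA.
In simulations this single rule is worth ~0.1 of round-trip rank
correlation, because fragment ends cut through elongating forks
constantly.

The only tunable here is `max_fork_gap` (default 3 kb): the largest
unlabelled gap across which an IdU and a CldU track are still considered
one fork. Microscopy produces small detection dropouts, but no quantified
value exists, so the limit is explicit and configurable. Same-analog
*event* gaps (the split initiation/termination patterns) are deliberately
not bounded by it: diverging or converging forks imply the event wherever
the midpoint falls.

### Orientation: the midpoint rule

`orient_fiber()` assigns direction maximally but honestly. Within a chain
every track and internal gap takes its fork's direction, event-bearing
tracks and gaps being split at the anchor. An unlabelled interval between
chains is split at its midpoint, each half inheriting the direction of the
adjacent fork. At fibre ends the same rule applies, and the *outer* half
of the end gap stays unassigned: beyond the midpoint the DNA could equally
have been replicated by an unseen neighbouring fork. A broken track end
coincides with the fibre boundary, so there is no extension at a break at
all. For a fully oriented fibre with intact ends, the oriented segments
therefore tile exactly the span between the first and last end-gap
midpoints — the partition property asserted in the test suite — not the
full molecule.

Anchors and midpoints are integer bp, rounded down (0-based, half-open
coordinates throughout, BED convention). Under reflection this floor
introduces at most 1 bp of asymmetry for odd-sum coordinates; the property
tests use even coordinates so the symmetry checks are exact.

## Profiles

`rfd_profile()` bins oriented segments over the locus: per bin the summed
rightward and leftward bp, and RFD = (R − L)/(R + L) as a ratio of sums
(not a mean of per-bp ratios, which would weight sparse positions up).
Uncovered bins are `NA`, never 0 — an RFD of 0 means balanced replication,
which is information, not absence. Exports omit `NA` bins.

`oem_profile()` needs no extra parameters: at each inter-window boundary
OEM is the drop in normalised leftward coverage, identically
(rfd(i+1) − rfd(i))/2 where both windows are defined. The default window
everywhere is 10 kb, the standard grain for RFD work on loci of hundreds
of kb.

`call_zones()` is an explicit, automated stand-in for the manual zone
annotation that is customary in this field: maximal runs of boundaries
with OEM ≥ `threshold` (default 0.1) are IZs, ≤ −threshold TZs, with
`min_run` (default 1) and `merge_gap` (default 0) to require run length
and to bridge single sub-threshold boundaries inside broad zones. Zone
intervals extend half a window beyond their first and last boundary, so
adjacent IZ/TZ calls never overlap. On sparse single-molecule OEM
(hundreds of fibres) the defaults overcall: the analyses in the test suite
use `min_run = 2, merge_gap = 1`, which suppressed single-boundary noise
runs at 1000-fibre depth without moving any zone centre.

## Fork speed

For an elongating fork with both tracks intact, speed is
(IdU + CldU length)/(2 × pulse) and the fork position the centre of the
combined span; with one track interrupted by a fibre break, the intact
track alone over one pulse, positioned at its centre; with both broken, no
measurement. The pulse duration is a parameter (default 20 min per
analog). Inputs are bp, outputs kb/min with 1 kb = 1000 bp; conversion
from micrometres of fluorescence to kb (the combing stretching factor) is
upstream of this package.

## OK-seq-style population RFD

`okseq_rfd()` accepts strand-oriented read intervals. The strand→direction
convention is an explicit flag: simulated/`direct` BED files carry the
fork direction on the strand, while real Okazaki-fragment libraries map
fragments on the strand *opposite* to fork movement (`convention =
"okseq"`, the default for BAM input). Counting is read-bp overlap by
default, to match the combing coverage definition; `count_mode = "reads"`
counts midpoints instead, since "coverage per direction" admits both
readings.

`subsample_rfd()` draws `n` reads (default 2500) without replacement,
`draws` times (default 100), from one RNG stream seeded once, draws taken
sequentially — a rerun with the same seed is bit-identical, which is the
reproducibility contract the tests assert. `binned_spearman()` is the
rank correlation over the bins defined in both profiles, with mid-ranked
ties.

## Fork-travel kinetics

All closed form, kept at full precision; rounding is half-up, only at
presentation, at the precision of the printed unit. From doubling time T
and S-phase fraction s: S duration = s·T. A fork born at the start of
quarter q travels d(q) = (1 − (q−1)/4)·sT·v. With quarter firing
fractions f(q), the timing-weighted mean travel is Σ d(q)f(q). For two
zones a distance ℓ apart, converging forks "meet" at
dIZ1/(dIZ1 + dIZ2)·ℓ from the 5′ zone, and the fraction of rightward
forks able to reach the 3′ zone is f_S1(source)·f_S4(target)·100 — the
source must fire at the very start of S and the target at the very end,
the two being independent. The distance-feasibility premise (an S1-born
fork covers ℓ by the end of S3, 0.75·sT·v ≥ ℓ) is reported as a boolean
diagnostic beside the percentage, not folded into it.

A caveat the simulator makes concrete: the meeting-point formula weights
the *whole-remaining-S* travel distances and is therefore not the expected
first-passage meeting position of two forks with those firing-time
distributions. The physical mean meeting point is
(E[t2 − t1] + ℓ/vL)/(1/vR + 1/vL), which depends only on the marginal mean
firing times and, for the default two-zone model, sits ~50 kb 3′-ward of
the formula's estimate. The simulation round-trip test asserts the called
TZ against the simulator's own terminations (they agree to a bin) and
records the formula comparison separately — no choice of firing-time
coupling can reconcile the two, since the discrepancy is a property of the
means.

## The simulator

`locus_model()` emulates the replication program this methodology is used
to study: delimited initiation zones with per-cell firing probability
(efficiency), positions uniform over the zone width, and quarter-resolved
firing times (quarter drawn from the zone's distribution, then uniform
within the quarter); plus dispersed licensed origins (Poisson per Mb,
uniform firing times over S) that fire only if a fork does not reach them
first — passive replication, computed exactly by processing candidates in
firing order. Forks run at constant per-direction velocities (optionally a
per-cell lognormal multiplier) until they merge; merge points are solved
in closed form, so per-cell direction and timing maps are exact piecewise
functions, and pulse labelling inverts them analytically. Boundary forks
entering from outside the locus guarantee complete replication by the end
of S without influencing the interior.

The default model (`ccser1_model()`) is a 661-kb locus with efficient
zones at 20 kb and 641 kb — 621 kb apart, matching the two-zone analysis
in the kinetics tables — velocities 1.9/1.8 kb/min, S = 465 min, and the
measured quarter distributions (5′ zone early: 26.3/53.2/17.6/2.9%;
3′ zone late: 5.7/20.1/41.0/33.2%).

**Firing-time coupling.** The quarter fractions are population marginals
and say nothing about the joint distribution within a cell. With fully
independent draws, the spread of the firing-time difference makes the
fork-meeting distribution ~130 kb wide, the RFD descent never exceeds the
0.1 OEM threshold, and no TZ is callable at any depth — unlike the sharp
TZ these experiments actually show. Replication timing is strongly
correlated cell-wide, so by default each cell draws one S-progression
quantile shared by all zones (`timing_coupling = 1`, comonotone; 0 gives
independence; dispersed origins always fire independently). This sharpens
the TZ to ~45 kb while leaving each zone's marginal distribution exactly
as specified.

**Fibre extraction.** `emit_fibers()` draws one cell per fibre, a pulse
onset uniform over S, and a lognormal fragment length (mean 95 kb, the
scale of combed molecules in this kind of experiment; sdlog 0.35,
configurable — the real length distribution shape is not known). Fragments
land uniformly among positions *overlapping* the locus and may overhang
its ends, as combed molecules do: truncating fragments at the locus
bounds would suppress the short-lived forks that run off the locus edges
and visibly bias edge RFD toward the opposing long-range fork. Tracks cut
by a fragment end are flagged broken on that side; coordinates are
floored to bp, so recovered speeds are exact to 1 bp per pulse
(5 × 10⁻⁵ kb/min), the tolerance the tests use for "exact".

**Reads.** `emit_reads()` samples read positions uniformly over the locus
in a pool of simulated cells and assigns each read the direction of the
fork that replicated its midpoint in its cell.

**What the simulator does not emulate:** chromatin-scale replication
timing structure beyond S quarters, fork stalling and speed variation
along a molecule, sister-fork correlations, combing stretch error, and
analog detection noise (false/missed track calls). Passing the round-trip
tests therefore shows the *analysis* is correct and unbiased under the
stated generative model, not that real microscopy annotation is
error-free.

**Detection-limit regime.** `dispersed_model()` has no zones and a
licensed-origin rate of 32/Mb/cell, calibrated once so that realized
(non-passively-replicated) initiations are ~5.3/Mb ≈ one event per two
mean-length fibres. In this regime individual initiations remain callable
on fibres while the expected RFD is flat everywhere, so any zone call is a
sampling artefact; the test suite samples 12,000 fibres, a depth chosen by
a noise-floor calculation (per-boundary OEM sd ~3σ below the 0.1
threshold across ~65 boundaries) so that the absence of called IZs
reflects the model and not luck.

## Problem sizes and seeds

The test suite simulates 1000 fibres for the two-zone round trip (about
160 of which carry tracks — the informative fraction is roughly the 40-min
pulse window over the 465-min S phase), 12,000 for the detection-limit
property, 20,000 reads with 100 × 2500-read subsamples, and 10,000 random
fibres for the partition/mirror properties. All stochastic tests fix their
seeds; every simulation function takes an explicit `seed` and restores the
caller's RNG state.

## Known limitations

* Zone calling is a threshold caller, not a segmentation model; no
  significance is attached to calls.
* The reach/meeting kinetics assume constant velocity and fully efficient
  zones, as stated for the printed analyses they reproduce.
* RFD from a few hundred tracks carries visible sampling noise; the
  subsampling ensemble exists precisely to quantify how much of a
  combing-vs-population discrepancy that noise explains.
* BigWig export requires chromosome sizes (`write_bigwig`); bedGraph is
  the canonical output.
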