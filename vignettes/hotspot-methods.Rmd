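---
title: "Detecting and predicting phosphorylation hotspots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and predicting phosphorylation hotspots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotter)
```

## The model

Many phosphorylation sites (P-sites) do not act as isolated, position-exact
switches: they occur in dense clusters — *hotspots* — whose combined negative
charge modulates the local electrostatic surface of the protein.  Within a
hotspot the exact position of any single site matters little, which defeats
motif- and profile-based single-site predictors: the flanking sequence of a
clustered site contains other P-sites, so no coherent positional profile can
be extracted.  This package therefore treats the hotspot *region* as the unit
of prediction and uses its amino-acid *composition*, not a positional motif.

The workflow has four stages.

**1. Hotspot detection.**  A hotspot is a maximal run of at least
`min_sites = 4` experimentally observed P-sites on one protein, in which
every pair of neighboring sites is at most `max_gap = 10` residues apart
(a gap of exactly 10 qualifies).  The run core is padded into a window of at
least `window_length = 17` residues with at least `min_flank = 3` residues
beyond the terminal sites.  When the flank rule alone does not reach 17
residues, the window is centered on the core midpoint; at half-integer
midpoints the more N-terminal start is taken, and windows that would cross a
protein terminus are shifted inward, so the 17-residue length is preserved
wherever the protein allows.  These tie-break rules are frozen because the
packaged reference windows are reproduced exactly by them.

**2. Spacing statistics.**  For every site sharing a continuously
peptide-covered segment with another site, `d_N` is the distance to the
closest other site in that segment.  Restricting to covered segments avoids
spuriously long distances across unobserved sequence.  Two nulls calibrate
the observed distribution: *P-flag randomization* reassigns each residue
type's flags uniformly among that type's positions in the same region
(testing whether spacing merely reflects where S/T/Y sit), and *sequence
randomization* shuffles the region's residues outright (destroying the S/T/Y
positional preferences as well).  Distributions are compared with a Pearson
chi-squared test of homogeneity on unit bins `1..25` plus an open tail; bins
whose expected count falls below 5 are merged into a neighbor beforehand,
the standard validity rule; the distance statistic itself prescribes no binning.

**3. Composition encoding and classification.**  Each 17-residue window is
encoded as 420 features: the 20 monomer frequencies (alphabetical order)
followed by the 400 *directed* adjacent-dimer frequencies (lexicographic
order), every count divided by the window length `L` — so the monomer block
sums to 1 and the dimer block to `(L − 1)/L`.  Direction matters: each
residue is paired only with its C-terminal neighbor, retaining a residue of
order information on top of pure composition.  Windows containing ambiguity
codes (X, B, Z, U, ...) are excluded from encoding and scanning, with a count
reported, since the encoding is undefined there.

Positive examples are all step-1 17-mers of every hotspot window (365 from
the 79 packaged reference windows).  Negative examples tile the covered
regions outside hotspot windows into *non-overlapping* 17-mers — a deliberate
asymmetry with the step-1 positive segmentation, which keeps negative
windows independent of one another — and must pass per-type S/T/Y frequency floors: each negative
contains serine, threonine and tyrosine at least at the minimum frequency
observed among the positives, so the classifier cannot win by merely
counting phosphorylatable residues, and is less prone to detecting generic
disorder.  Negatives may contain isolated P-sites; only clustering
distinguishes the classes.  The candidate pool is then downsampled to an
8:1 negative:positive ratio.

The classifier is a soft-margin SVM with RBF kernel
`K(x, y) = exp(−γ‖x − y‖²)`.  The default operating point is `C = 2⁰`,
`γ = 2²`, `j = 2³`; the full exhaustive grid
(`C = 2⁻¹⁰..2²⁴`, `γ = 2⁻¹⁰..2⁶`, `j = 2⁻²..2⁴`, 4,165 combinations) is
available through `grid_search()`.  The positive-class error weight `j` and
the 8:1 false-positive:false-negative cost ratio are composed
multiplicatively into per-class error weights (`positive = j`,
`negative = cost_ratio`); this composition is the documented, configurable
choice —
note that at the defaults the two knobs cancel to a symmetric weighting,
which the grid over `j` can undo.  Decision scores are raw margin distances
(no probability calibration) so that the thresholds 0 (training) and 1
(proteome scanning) keep their meaning.

Because adjacent positive windows share 16 of 17 residues, naive
cross-validation would leak.  Folds therefore partition *hotspots*, never
windows: all windows of one hotspot stay on one side of every train/test
split (`make_group_folds()` asserts this).  This is licensed by the low
mutual similarity of the reference windows — no two share a segment longer
than seven residues (`longest_shared_segment()`).  Negative regions are
allocated greedily so each fold keeps close to the global 8:1 ratio.

**4. Proteome scanning.**  Every 17-mer of every protein is scored.  A
residue is called positive when covered by at least one window scoring above
the threshold — positive predictions take precedence at the 16 residues
where adjacent windows disagree.  Maximal runs of consecutive positive
window starts span `[first start, last start + 17)`; neighboring runs whose
start positions differ by at most 17 are merged, iterated to a fixpoint
(a single left-to-right pass closes the relation, since merging never moves
the growing run's last start).  Each merged run must finally contain at
least 4 S/T/Y residues forming a gap-≤10 run — the experimental hotspot
criterion applied to all S/T/Y residues, since predictions carry no
site-level calls.  Reported coordinates are the merged run spans, not
re-padded windows.

**Disorder overlap.**  Hotspots preferentially sit in intrinsically
disordered regions.  `count_overlaps()` counts a hotspot as overlapping when
it shares at least 3 consecutive residues with a disorder interval of length
≥ 17 on the same protein; the interval-side count can differ (one hotspot
may hit two separated intervals).  The null redistributes the hotspots:
uniformly chosen protein, then uniformly chosen start, placements within a
repeat non-overlapping (rejection sampling, 1,000 tries per hotspot),
repeated 10 times.  Protein choice is uniform over proteins, not
length-weighted; the two-step draw (protein, then start) is the documented
default, and length-weighting is an easy variant for sensitivity analysis.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `window_length` | 17 aa | composition window and minimum hotspot length |
| `min_sites` | 4 | sites needed to form a hotspot |
| `max_gap` | 10 aa | maximum neighbor spacing inside a run |
| `min_flank` | 3 aa | padding beyond terminal sites |
| `neg_pos_ratio` | 8 | negative:positive training ratio |
| `C`, `gamma`, `j` | 1, 4, 8 | default RBF-SVM operating point |
| `cost_ratio` | 8 | FP:FN cost multiplier |
| `score_threshold_train` | 0 | CV decision threshold |
| `score_threshold_scan` | 1 | stricter proteome-scan threshold |

## The synthetic benchmark

`simulate_dataset()` generates the seeded datasets on which every stage is
tested without downloads.  The default `simulation_spec()` emulates the
structure the method assumes, and its values were fixed once as the
package's benchmark conditions:

* 200 proteins, log-normal lengths (median ≈ 300 residues), background
  composition from a typical-proteome frequency table (a fixture choice,
  not an organism claim);
* 50 planted hotspot segments of 17–40 residues.  Most (80%) follow an
  SR-rich theme — elevated S/R/P with explicit RS/SR/SP dimer bias matching
  the serine/arginine-rich splicing-factor windows that dominate the
  experimental set — while a 20% minority follows a T/Y-driven theme with
  ordinary serine content.  The mixture matters: the real reference windows
  are not uniformly SR-rich, and it is the occasional low-S window that
  keeps the per-type frequency floors of the positive set low.  A
  single-theme generator produces unrealistically strict floors and starves
  the negative pool;
* 4–8 sites per planted hotspot, placed on S/T/Y positions with a
  categorical gap distribution over 1..10 whose mode is 2, reproducing the
  short-gap preference of real clustered sites;
* isolated background sites at rate 0.005 per S/T/Y (a spurious 4-site
  cluster is then vanishingly unlikely);
* random covered segments (≈ 70% of each protein, mean segment ≈ 150
  residues) — a simulation of partial peptide coverage, not an in-silico
  digestion; planted hotspot windows are always covered, as experimentally
  observed hotspots are by definition;
* disorder intervals placed over planted hotspots with probability 0.7 plus
  sparse background intervals, so the directional overlap contrast is
  testable.

What passing on this benchmark does **not** show: performance on real
proteomes (real hotspots are more heterogeneous than the two-theme
mixture), or robustness to mass-spectrometry artifacts such as site
mislocalization and ambiguous phosphopeptides.

## Numerical choices and degenerate inputs

* All coordinates are 0-based with half-open intervals; conversion to
  1-based inclusive coordinates happens only in the GFF3 writer.  The
  packaged reference table is demonstrably 0-based (its N-terminal windows
  start at 0).
* Nearest-neighbor ties (equal N- and C-side distance) leave `d_N`
  unchanged; no partner annotation is kept, so no tie-break is needed.
* Proteins with a single site, and site pairs split across coverage gaps,
  contribute no distance.
* Proteins shorter than 17 residues yield a truncated, flagged window in
  padding and an empty track in scanning.
* Empty site sets, empty FASTA files, and empty hotspot sets produce empty
  outputs with warnings, not errors.
* libsvm orients decision values toward the class of the first training
  row; `train_svm()` detects and fixes the orientation so positive scores
  always mean "hotspot".
* Randomized steps consume the session RNG; every user-facing entry point
  accepts or documents a seed, and the same seed reproduces a simulated
  dataset byte for byte.

## Problem sizes used in the test suite

The suite and the acceptance script run entirely on generated data: oracle
equivalence on 500–1,000 random instances per operation, the classifier
benchmark on the default 200-protein/50-hotspot simulation (about 60,000
scan windows, roughly half a minute end to end), the homogeneity-test
calibration on 1,000 null draws of two 250-count samples, and the
randomization nulls on 10–20 repeats.  These sizes were chosen as the
smallest at which the checked contrasts are comfortably larger than their
sampling noise.

## Known limitations

* The proteome-scan consolidation merges runs to a fixpoint; a single
  pass over neighboring runs is a conceivable alternative, and the closure
  is the deterministic choice adopted here.
* The S/T/Y content filter evaluates all S/T/Y residues strictly inside a
  predicted run; flank context is deliberately excluded.
* P-flag randomization preserves counts per residue type (a pS flag stays
  on an S position); this is the conservative null that retains the
  S/T-vs-Y kinase distinction, which the spacing analysis treats
  separately.
* Real-proteome performance figures are outside the test surface: they
  would require organism-scale site, coverage, and proteome data.  The
  classifier is instead validated by parameter recovery on the synthetic
  benchmark.
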