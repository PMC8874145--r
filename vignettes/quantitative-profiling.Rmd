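---
title: "Quantitative surface-antigen profiling: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative surface-antigen profiling: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcflow)
```

## The measurement problem

Flow cytometry reports fluorescence, not molecule counts. When a target
antibody is conjugated to phycoerythrin (PE) at a 1:1 ratio, the PE
fluorescence of a cell is proportional to the number of bound antibodies,
and calibration beads carrying four known quantities of PE molecules per
bead let us convert fluorescence into antibody binding capacity (ABC) —
antibodies bound per cell. `abcflow` implements the full desk-side half of
that workflow: reading and annotating FCS files driven by a plate-layout
table, compensation, hierarchical template gating of 27 blood leukocyte
subsets across an innate and an adaptive tube, the bead calibration and ABC
conversion, background cutoffs from fluorescence-minus-one (FMO) controls,
per-subset statistics, antibody titration analytics, and cross-laboratory
reproducibility summaries.

Because instrument data cannot be shipped with a package, a synthetic event
generator stands in for acquisition. It is a first-class module: the
statistical structure it produces is exactly the structure the pipeline
assumes, which is what makes every downstream stage testable with known
ground truth.

## The synthetic event model

Each tube is a finite mixture of populations. Event counts per population
are multinomial in the specified fractions. Fluorescence channels are
log-normal in linear space with the location parameter equal to the
population median — so a generated median is directly comparable to a
specified one, with no bias correction. The default fluorescence CV is
0.20. Scatter channels are normal with CV 0.05, truncated at zero. `FSC-H`
is derived from `FSC-A` with a multiplicative noise of CV 0.02, so genuine
single cells sit well inside the default singlet ratio band (0.85–1.15);
optional doublets are built by summing two events' signals while keeping
one event's `FSC-H`, which pushes them out of the band. The doublet
fraction defaults to 0 and is configurable.

Marker medians default to 100 (negative), 10,000 (positive) and 60,000
(bright, used for the HLA-DR-high dendritic-cell gate) linear units. The
100-fold negative/positive separation corresponds to a cleanly resolved
backbone stain; with CV 0.20 the two log-normal components are about 11
standard deviations apart on the log scale, so template gates at the
geometric midpoint (1,000) misclassify a negligible fraction of events.
This is deliberate: the synthetic tubes validate the *logic* of the gating
trees (tree structure, disjointness, count conservation, threshold
orientation), not their robustness to smeared real-world populations.
Passing the ≥99 % accuracy checks therefore says the template implements
the intended phenotype definitions; it says nothing about performance on
dim or continuous markers, spreading error, or instrument drift.

Tube composition defaults reflect typical whole blood: granulocyte-heavy
innate tubes (45 % neutrophils, 3 % eosinophils, 1 % basophils),
monocytes at 10 % split across classical/intermediate/nonclassical, rare
ILC populations at 0.2–0.3 %, and lymphocyte-dominated adaptive tubes.
Non-leaf fillers (debris, CD45-negative events, lineage-excluded cells)
are included so that exclusion gates are actually exercised.

All randomness flows from one explicit seed per generator call; the
session RNG state is saved and restored, and identical seeds give
bit-identical tables.

## Gating

The two built-in templates encode the subset definitions of the panels:
the innate tree resolves neutrophils, eosinophils, basophils, the three
monocyte subsets, myeloid and plasmacytoid dendritic cells, ILC-1/2/3 and
NK cells (12 leaves); the adaptive tree resolves TCRγδ⁺ T cells, the
CD4 and CD8 naive/CM/EM/TEMRA quadrants, Treg, Tfh, and the four IgD/CD27
B-cell quadrants (15 leaves; 27 in total).

Gate geometries are one-sided thresholds, rectangles, a ratio band
(doublet exclusion on FSC-A/FSC-H, default 0.85–1.15), and an OR of
thresholds (NK cells: CD56⁺ and/or CD16⁺). Cut values live in a JSON
template (shipped in `inst/extdata/`) whose defaults are the same
conventions the generator uses: marker cut 1,000 (the geometric midpoint
of 100 and 10,000), HLA-DR-bright cut 25,000, side-scatter strata at
40,000 / 100,000 / 180,000, debris cut at FSC-A 30,000.

Two semantics choices matter:

* **Evaluation scale.** All gate geometries are monotone region tests, so
  thresholding the linear value against a linear cut is identical to
  thresholding the arcsinh-transformed value against the transformed cut.
  Gates are therefore evaluated on the compensated linear scale with cuts
  stated in linear units; `transform_spec()`/`apply_transform()` (arcsinh,
  default cofactor 150) exist for display and for any future density-based
  gate fitting. Quantitation (medians, ABC) always uses compensated linear
  values, so it is invariant to the display transform by construction.
* **Sibling capture.** Children of a node are evaluated in order with
  first-match capture. For geometrically disjoint siblings (all the
  quadrant splits) the order is irrelevant — asserted by a permutation
  test. Where the published strategy gates sequentially (Tfh captured
  before Treg before the CD45RA/CD27 quadrants), the template encodes that
  order, and every event still maps to at most one leaf.

Events failing an ancestor gate are unassigned, never errors. Per-node
counts satisfy `n(node) = Σ n(children) + n(stopping at node)` at every
internal node.

`validate_template()` supports the reduced-panel case in which an
instrument lacks the CD56 detection channel: NK gating degrades to its
CD16 alternative (flagged `leaf_degraded`), while ILC-1 — defined purely
negatively (CRTH2⁻CD117⁻) and only trustworthy when CD56⁺CD16⁻ NK cells
can be excluded — is declared unavailable through the template's
`channel_dependencies`.

## Calibration and quantitation conventions

* **Bead peaks.** Four clusters on log10 PE found by 1-D k-means (Lloyd)
  with quantile-based initial centers — deterministic and order-invariant.
  Adjacent cluster medians closer than 0.3 log10 units (2-fold) are
  reported as unresolvable rather than silently merged.
* **Calibration fit.** Ordinary least squares of log10(lot level) on
  log10(peak median). Regressing ABC on fluorescence means conversion
  needs no inversion; using all four peaks absorbs the difference between
  two-point and four-point fitting conventions. R² below 0.99 warns.
* **Conversion.** `ABC = 10^(slope·log10 F + intercept)` for `F > 0`.
  Compensation legitimately produces non-positive fluorescence; those
  events map to ABC 0 and are flagged below detection instead of being
  dropped, so subset counts (and the 66-event rule) are unaffected.
* **Quantiles.** One convention everywhere: linear interpolation between
  order statistics (R's type 7) for medians, quartiles, the 90th-percentile
  FMO cutoff and the 84.13th percentile in the robust SD. The tests verify
  every quantile against an independent sort-and-interpolate oracle.
* **Background cutoffs.** Per subset and per tube: the 90th percentile of
  the subset's ABC in the FMO control. Cutoffs are not pooled across
  donors or laboratories, matching the per-experiment FMO wells. Subsets
  with fewer than 66 events are omitted; 66 is retained.
* **Resolution summary.** `summarize_resolution()` reports median, min and
  max over a cutoff table. Applied to the package's reference table of 27
  subset cutoffs this gives 396 / 229 / 786 ABC units — the panel's
  headline sensitivity: expression above roughly 400 ABC is quantifiable
  on essentially every subset.

## Titration

The titration module models the standard barcoded mixture: five cell
lines and peripheral blood, each assigned one of three intensities
(medians 100 / 3,000 / 60,000) on two tracking-dye channels, mixed at
equal rates; blood is further split by scatter into lymphocytes,
monocytes and granulocytes. Demultiplexing regions are half-open
rectangles `[median/3, median·3)` around each level — events in the gaps
stay unassigned rather than being pulled to the nearest region, trading a
sliver of yield for purity.

Simulated binding follows a one-site law plus linear nonspecific term,
`bound(c) = bmax·c/(kd + c) + ns·c`, over a two-fold dilution series from
1/5 of stock down to 1/2560 (the last step at or above 1/3200). The
defaults — `bmax` 50,000 ABC on granulocytes, `kd` at the 1/100 stock
fraction, a `bmax`-0 mouse line as universal negative — give curves that
saturate inside the tested range. The Langmuir form is a test oracle and
generator, not the selection mechanism.

The Stain Index is `(median_pos − median_neg) / (2·rSD_neg)` with the
robust SD (84.13th percentile minus median of the negative); the exact
published robust variant differs between sources, so the classical-SD
version is available by argument. Titer selection offers three policies:
`saturation` (default) takes the most dilute step whose positive median is
at least 90 % of the curve maximum, stepping one further if the negative
cell line exceeds twice its FMO level there; `max-SI` takes the Stain
Index maximum; `max-SI-minus-one` takes one step more dilute than the SI
maximum.

Clone benchmarking compares per-subset median ABC across clones against
the per-subset across-clone median and flags deviations beyond 1.5-fold in
either direction — the pattern by which an epitope-shifted clone stands
out on a subset group while agreeing elsewhere.

## Reproducibility summaries

`cv_summary()` aggregates (marker, population, donor, lab) median-ABC
records: the intra-lab CV is the CV across donors within each lab,
averaged over labs with at least two donors; the inter-lab CV pools all
donor-lab values. Sample (n−1) SD is used, and CVs are scale-invariant by
construction. Groupings with fewer than two values are reported undefined
rather than zero. The aggregation across markers/subsets into a single
mean CV is left to the caller, since more than one reasonable weighting
exists.

## Protocol arithmetic and annotation

The experiment master table (EMT, CSV/TSV) maps wells to reagents and
drives two things. First, the printable protocol: per well, PE reagent
plus diluent to 10 µl, 40 µl of cell suspension (2×10⁶ cells) for 50 µl,
then 25 µl of backbone antibody mix for 75 µl; master-mix totals scale
linearly with well count times a configurable pipetting overage (default
10 %). Regenerating a protocol from the same EMT with the same injected
timestamp is byte-identical. Second, batch annotation: acquisition-default
file names (`Specimen_001_A1_A01_001.fcs`) are parsed for their well, the
matching EMT row's identifiers are written into the FCS TEXT segment
under `ABCF_`-prefixed keywords (avoiding vendor-keyword collisions), and
files are renamed `<experiment>_<plate>_<well>_<CD>_<clone>.fcs`.
Annotation is idempotent — an already-annotated file is recognized by its
`ABCF_WELL` keyword, keywords are overwritten rather than duplicated, and
the DATA segment is carried over byte-identically. Nonconforming names
are skipped with a logged warning, never aborting the batch.

FCS support is written into the package (3.0 emitted with little-endian
float32 data; 2.0/3.0/3.1 with float, double or unsigned-integer data
accepted), with delimiter escaping per the format definition. Spreadsheet
EMTs should be exported to CSV/TSV.

## Problem sizes and numerical choices

The shipped tests run the generator at 5,000–200,000 events per tube:
60,000 for routine gating-accuracy checks, 200,000 for the headline
partition/accuracy test, 20,000 for bead and titration tubes, sizes at
which the binomial and median sampling errors quoted in the tests are
comfortably below the asserted tolerances. Calibration recovery is
asserted to ±0.02 on the slope at 20,000 bead events (observed error is
about 0.001), end-to-end ABC recovery to 5 % at a true ABC of 10,000
(observed well under 1 %). Degenerate inputs have defined behavior
throughout: empty tubes round-trip with their channel header, an
all-debris tube yields zero in every leaf, zero-spread negatives give an
undefined (not infinite) Stain Index, empty CV groupings are undefined
(not zero), and a zero denominator in fold changes is flagged.

## Known limitations

The generator does not simulate spreading error, autofluorescence
heterogeneity, time drift, or acquisition anomalies, and population
separations default to optimistic; conclusions about gate robustness on
real data cannot be drawn from the synthetic checks. Gate cuts are fixed
template values — no density-based auto-thresholding, and no
clustering-based gating. Quantitation is PE-only under the 1:1
conjugation premise; multi-fluorophore quantitation and MESF conversion
are out of scope. Donor-level biology (actual ABC levels of real markers,
real inter-site CVs) requires instrument data and is deliberately not
claimed by any test here.
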