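---
title: "Methods: local Gi* segregation scores from tract polygons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local Gi* segregation scores from tract polygons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

For each census tract the package reports the standardized local Getis-Ord
Gi* statistic of a population group's share, computed within a larger
reference unit of $n$ tracts. Writing $x_j$ for the group proportion of
tract $j$, $\bar{x}$ for the unit mean, $s = \sqrt{\sum_j x_j^2/n -
\bar{x}^2}$ for the *population* standard deviation, and $w_{ij}$ for the
weights row of focal tract $i$ (row sum $W_i$, squared sum $S1_i$):

$$
G_i^* \;=\; \frac{\sum_j w_{ij} x_j - \bar{x}\,W_i}
{s\,\sqrt{\dfrac{n\,S1_i - W_i^2}{n-1}}}.
$$

This is the Ord–Getis standardized "star" form: the focal tract is included
in its own neighborhood and in $\bar{x}$ and $s$. Weights are binary
contiguity (queen: any shared boundary point; rook: a positive-length
shared edge), self-included and row-standardized, so a tract with $k$
neighbors carries $k+1$ equal weights of $1/(k+1)$, giving $W_i = 1$ and
$S1_i = 1/(k+1)$ exactly. The result is a Z-score under the usual
normal-approximation reading: positive where the focal neighborhood is
overrepresented relative to the unit, negative where underrepresented.

Assumptions worth keeping in mind: proportions are treated as fixed
quantities (no sampling error from the survey estimates themselves), the
normality of the score is asymptotic in $n$, and scores of neighboring
tracts are strongly dependent by construction — the statistic is a
descriptive local measure, not a family of independent hypothesis tests.

## Reference units

Each tract is assigned one larger unit. If a CBSA layer is supplied, the
tract joins the CBSA polygon containing its *representative interior
point*; otherwise (or for tracts outside every CBSA polygon) it joins the
county given lexically by the first five digits of its 11-digit FIPS
identifier. Two open choices were settled as follows:

* **Join predicate.** "Falls within" is operationalized as
  representative-point-in-polygon rather than full polygon containment,
  because tract boundaries track CBSA boundaries imperfectly in real data
  and containment would spuriously demote sliver-crossing tracts to their
  county. The representative point is constructed deterministically (widest
  interior interval of a horizontal scanline placed strictly between vertex
  y-levels), so it is always inside the polygon — concave tracts whose
  centroid falls outside are handled — and runs are reproducible.
* **Unit-restricted contiguity.** The contiguity graph is rebuilt inside
  each unit, so a tract's geometric neighbors across a unit boundary never
  contribute to its score or its reported neighbor count. This matches the
  split-per-unit computation implied by the indicator code for "connected
  to every other tract in the unit", at the cost that border tracts lose
  cross-border neighbors; building one national graph first and subsetting
  would differ for exactly those tracts.

## Contiguity detection

Adjacency is decided geometrically from ring boundaries: two polygons are
queen neighbors if they share a snapped vertex, have positive-length
collinear edge overlap, or touch in a T-junction (a vertex of one lying on
an edge of the other); they are rook neighbors iff their total collinear
overlap length strictly exceeds `snap_tolerance`. With the default
tolerance of 0 any positive-length shared segment counts as an edge and a
corner-only contact never does — the dominant software convention; rook
implementations genuinely vary here, which is why the threshold is exposed
as a parameter. `snap_tolerance > 0` additionally rounds coordinates onto a
grid of that pitch before testing, bridging sliver gaps in digitized
shapefiles; synthetic fixtures need no snapping. Collinearity tests use a
relative epsilon of $10^{-9}$ times the coordinate scale. Candidate pairs
are pre-filtered by a bounding-box sweep, so cost is near-linear on
tract-like data; correctness is checked in the test suite against an
$O(N^2)$ all-pairs segment-intersection oracle.

## Degenerate tracts and numerical edge cases

Cells where the statistic is undefined receive a reserved code, applied in
a fixed precedence order (unit-level before tract-level): single-tract unit
(-99), zero focal population (-100), no target population in the unit
(-199), focal tract adjacent to every other member (-299), all members
islands (-399). The precedence is a package decision — the codes' source
defines no ordering — chosen so that the most structural explanation wins.

Three further cases the code table does not cover:

* **Zero-population tracts** are coded -100 and then removed entirely from
  the unit: from $x$, $\bar{x}$, $s$, $n$, and from every other tract's
  weights row (rows are re-standardized over the remaining members). A 0/0
  proportion cannot enter the mean; whether the original workflow also
  purged them from neighbors' rows is unknown, so this is documented as a
  choice. If the removal leaves a tract adjacent to all remaining members,
  that tract is coded -299.
* **Zero variance** ($s = 0$ with a nonzero group total, e.g. perfectly
  identical compositions) has no reserved code; inventing one would
  misrepresent the published code table, so the cell is written as a
  missing value and a warning is raised.
* **The fully-connected limit.** When a focal row spans the whole unit with
  equal weights, $n\,S1_i - W_i^2 = 0$ and the formula is 0/0 — but its
  numerator is then *exactly* zero, since the neighborhood average over the
  whole unit is the unit mean. `gi_star_unit()` returns 0 for this limiting
  case (guarded at relative tolerance $10^{-9}$); the pipeline codes such
  tracts -299 before scoring, so the convention only surfaces when the core
  function is called directly. A single island inside an otherwise
  connected unit is *not* degenerate: it is scored with the self-only
  weights row $\{w_{ii}=1\}$.

## Output conventions

The result table is always one row per input tract, sorted by FIPS, with
columns `FIPS_ID` then `{group}_Gstat`, `{group}_n_neigh` per group — nine
columns for the default four groups. `n_neigh` is the within-unit neighbor
count excluding self (self-inclusion is a weighting device, not a
neighbor), identical across groups. CSV output prints Z-scores with 6
decimals (beyond statistical meaning; keeps files diff-able), codes as bare
ASCII integers, and `FIPS_ID` in the leading-zero-stripped numeric dialect
unless `pad_fips = TRUE`; internally identifiers are always the zero-padded
11-character string, which lexical county extraction requires.

## The synthetic world

`make_lattice()` builds rectangular grids of unit-square tracts with
plausibly minted identifiers (state 17, county 031 by default) so fixtures
exercise the same FIPS validation as real data. `make_population()` draws
seeded counts with a per-tract total of 1000 — a typical census-tract
population — under a baseline composition of 55% nhWhite, 18% nhBlack, 7%
nhAsian, 15% Hispanic (a realistic mid-size-metro mix; generic group sets
split 90% evenly). `planted_cluster` gives the target group share
`p_in = 0.8` inside a designated block and `p_out = 0.1` outside —
a strong, unambiguous segregation signal — splitting the remainder among
the other groups so group sums never exceed totals. Each indicator code has
a minimal dedicated fixture (1×1 lattice; a gutted tract; an emptied group
column; a 2×2 queen lattice; separated squares).

What the generator does *not* emulate: irregular tract shapes and areas,
coastline slivers and snapping noise, heavy-tailed tract populations,
survey sampling error, and realistic spatial autocorrelation structure
beyond a single planted block. A green test therefore establishes that the
statistic, weights, codes and schema are computed correctly — not that any
substantive segregation estimate for real geography is reproduced.

## Limitations

Coordinates are treated as planar; adjacency of polygons in geographic
coordinates is fine (touching is touching), but `snap_tolerance` is then in
degrees. Shapefile support covers the type-5 Polygon subset with one
attribute column — enough to round-trip tract layers, not a general reader.
No permutation p-values, multiple-testing correction, or the
focal-excluded (non-star) Gi variant. The pipeline is single-threaded;
national-scale runs work but are not optimized beyond the bounding-box
sweep.
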