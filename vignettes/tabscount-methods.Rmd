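---
title: "Counting conformational states with torsion angular bin strings"
author: "tabscount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting conformational states with torsion angular bin strings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabscount)
```

## The model

A small molecule's conformational flexibility is dominated by rotations
about its rotatable bonds.  `tabscount` discretizes each rotatable torsion
into a small number of angular bins taken from a torsion-pattern library,
so that a conformer is represented by a *torsion angular bin string*: a
string of $N$ integers ("bits"), where bit $i$ takes a value in
$\{1, \dots, m_i\}$ and $m_i$ is the multiplicity (bin count) of the
pattern matched to torsion $i$.  An arbitrary such string is a *raw* bin
string; the set $S$ of all raw strings has cardinality
$M = |S| = \prod_{i=1}^{N} m_i$.

Molecular graphs usually have topological symmetries: permutations of the
atom numbering that preserve element types and connectivity.  Each such
symmetry induces a permutation of the bits (always exchanging bits of
equal multiplicity), and the set of induced permutations forms a finite
group $G$.  Two raw strings related by an element of $G$ describe the same
physical torsional state under different atom numberings, so a
conformational state (a TABS) is an *orbit* of raw strings under $G$; the
lexicographically smallest orbit member is the canonical label.  The
number of distinct states, nTABS, is the number of orbits, and by
Burnside's (Cauchy–Frobenius) lemma

$$ \mathrm{nTABS} \;=\; \frac{1}{|G|} \sum_{g \in G} |\mathrm{Fix}(g)|, $$

where $\mathrm{Fix}(g)$ is the set of raw strings fixed by $g$.  A string
is fixed by $g$ exactly when it is constant on every cycle of $g$, so
$|\mathrm{Fix}(g)|$ is the product over cycles of the common multiplicity
of the bits in the cycle — an $O(N)$ computation.  The whole count
therefore costs $O(|G|\,N)$, replacing the exponential
enumerate-and-deduplicate approach ($O(|G|\,N\,M)$ for $|G| > 1$), which
survives in the package only as the brute-force oracle `nTabsNaive()`.
The final division is asserted to be exact; a remainder can only arise
from a corrupted (non-closed) group and is reported as such.  All
cardinalities use exact arbitrary-precision integers (`bigInteger()`),
because $M$ and nTABS overflow doubles for flexible molecules.

```{r fig-example}
sys <- TabsSystem(c(3, 3), SymmetryGroup(list(c(2L, 1L)), nBits = 2))
as.character(cardinality(sys))   # M = 9
as.character(nTabsBurnside(sys)) # 6 orbits: unordered pairs with repetition
```

## From a molecule to a bit system

`tabsSystemFromMolecule()` runs the perception pipeline:

1. **Rotatable torsions.**  A bond qualifies when it is not in a ring and
   each bond atom has at least one non-hydrogen neighbor besides the
   other.  Ring bonds are detected as non-bridges of the graph.
2. **Pattern matching.**  Each bond is matched against the torsion
   library in priority order (file order breaks ties); the first matching
   pattern fixes the bit's multiplicity and bin boundaries.  A catch-all
   generic pattern terminates the library so every rotatable bond is
   assigned.
3. **Symmetry.**  Atom automorphisms are enumerated by backtracking
   seeded with canonical-rank classes (Morgan-style refinement over
   element, charge, aromaticity, implicit-H count and degree; atoms may
   only map within their class).  Each automorphism is projected to a
   permutation of the torsion bonds; duplicates are removed and the
   *image* group is used as $G$.  Using the image group rather than the
   atom group is deliberate: Burnside's lemma applies to the group
   actually acting on $S$, and the deduplicated image is the cheaper,
   cleaner choice (the count is identical either way when duplicates are
   tallied consistently).

Stereochemistry is ignored throughout — the symmetry is graph-topological
— so enantiomeric torsional states may share a label.  The automorphism
search is capped (default $10^5$ elements) and exceeding the cap is a
hard error, never a silent truncation.

## Angular bins and the rotor period

Angles follow the IUPAC sign convention in degrees, normalized to
$(-180, 180]$.  Bins are half-open $(\mathrm{lower}, \mathrm{upper}]$
intervals; with boundaries $b_1 < \dots < b_k$, bin $j < k$ covers
$(b_j, b_{j+1}]$ and bin $k$ wraps around the ends of the interval.
Boundary values are therefore deterministic, and no smoothing or peak
snapping is applied: a conformer straddling a boundary lands exactly where
the half-open convention puts it.

Each pattern also carries a rotor *period* (a divisor of 360, default
360): the angle is folded into $(-\mathrm{period}/2, \mathrm{period}/2]$
before binning.  The period exists because some rotors are locally
symmetric — rotating a phenyl ring by 180° produces an indistinguishable
structure, and the two topologically equivalent ortho carbons that could
serve as the dihedral reference atom give angles differing by exactly
180°.  Folding such rotors (period 180 for the shipped aromatic patterns)
makes bin values independent of the reference-atom choice, which is what
guarantees that symmetric relabelings of a molecule leave its TABS
unchanged.  Rotors whose local symmetry is not captured by the library's
periods (for instance a *tert*-butyl group's three-fold degeneracy) are
the library author's responsibility, exactly as the full published
torsion libraries fold such degeneracies into their multiplicities.

The shipped library is a small curated stand-in — amide (2 bins,
cis/trans), aromatic–aromatic and sp3–aromatic (2 bins over a 180°
period), conjugated sp2–sp2 (2 bins, s-cis/s-trans), sp3–sp3 (3 bins at
$-120/0/120$, the gauche−/gauche+/anti minima) and a generic 3-bin
fallback — not a reproduction of the CSD-derived profiles.  User
libraries in the same JSON schema (`readTorsionLibrary()`) can replace it
wholesale; JSON is used rather than YAML because this R stack ships no
YAML parser.  Substructure queries are attribute-based (element set,
aromaticity, charge, a required neighbor with a given bond order) rather
than full SMARTS, which no installed R package provides; the matcher is
deliberately small and auditable.

## Determinism choices

* **Action convention.**  $g \cdot s$ places the value of bit $i$ at
  position $g(i)$.  Orbit counting is convention-independent, but
  canonical labels are not, so the convention is fixed and tested.
* **Bit order.**  Bonds are sorted by the canonical-rank pair of their
  atoms (index pairs break exact ties), making the string layout
  reproducible across atom relabelings.
* **Reference quadruple.**  On each side of a torsion bond, the heavy
  neighbor with the smallest canonical rank (then smallest index) is the
  reference atom.
* **Group closure.**  `SymmetryGroup()` always closes its generators
  under composition (bounded, default $10^6$), because a non-closed set
  silently corrupts the Burnside sum; validity re-verifies closure.
* **Degenerate geometry.**  A dihedral with three collinear atoms is an
  error, not an arbitrary bin.

## Comparing TABS with continuous metrics

For a conformer ensemble, every unordered pair is labeled *same* or
*different* twice: by TABS equality (the condition, i.e. ground truth)
and by a thresholded continuous metric (the prediction) — similarity
metrics predict "same" above the threshold, distances below.  From the
confusion matrix,

$$ \mathrm{PPV} = \frac{TP}{TP+FP}, \qquad
   \mathrm{NPV} = \frac{TN}{TN+FN}, $$

with undefined values (zero denominators) reported as missing, never as 0
or 1.  `sweepThresholds()` scans a grid (default 101 points over the
observed range) and `optimalThreshold()` selects the threshold maximizing
$\min(\mathrm{PPV}, \mathrm{NPV})$ — the symmetric scalar reading of
"optimizing for maximal values" of both; product and fixed-NPV criteria
are available as options, and ties break toward the stricter "same" call
(larger threshold for similarities, smaller for distances).  Molecules are
grouped by flexibility as low (nTABS $< 500$), medium
($500 \le$ nTABS $< 10{,}000$) or high (nTABS $\ge 10{,}000$).

The built-in RMSD adapter is symmetry-aware: it minimizes the Kabsch
superposition RMSD over all automorphism-induced atom mappings, since a
symmetry-naive RMSD would call topologically identical conformers
different while TABS calls them the same.  Shape-overlap scorers are not
reimplemented; external scores enter as a CSV pair table
(`readPairScores()`).

## What the synthetic generators emulate

`randomTabsSystem()` draws abstract bit systems (defaults $N \le 6$,
$m_i \le 4$, up to a few multiplicity-respecting generators) — small
enough that the exponential enumeration oracle stays exact, which is the
point: every Burnside result can be cross-checked against brute force.
`syntheticEnsemble()` samples raw strings uniformly from $S$ and draws
pair scores from two normal distributions (defaults: mean 0.95, sd 0.02
for equal-TABS pairs; mean 0.65, sd 0.08 for unequal — a clearly but not
perfectly separated similarity metric, roughly what a well-behaved shape
score looks like on a rigid molecule).  These exercise the counting and
categorization machinery, *not* conformer geometry: a green test
establishes the algebra and the pipeline, but says nothing about any
particular published torsion library or external benchmark, whose
reproduction requires data this package deliberately does not ship.  The
handful of 3D fixtures (`butaneConformer()`,
`diphenylethaneConformer()`) are built analytically from internal
coordinates with idealized bond lengths and angles; they have exact
torsions but are not energy-minimized structures.

## Known limitations

* Symmetries act as bit permutations only; a hypothetical symmetry that
  relabels bin values *within* a bit (a dihedral read from the opposite
  end mapping an angle to its negative) is out of scope.
* Aromaticity in SDF input is taken from bond type 4; kekulized input is
  accepted at face value, which can split aromatic symmetry classes.
* The SMILES reader covers the organic subset, brackets, charges, rings
  and branches, ignores stereo markers, and is not a full SMILES
  implementation.
* Local rotor degeneracies beyond the shipped 180° folds must be encoded
  by the library author.
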