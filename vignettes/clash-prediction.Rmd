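---
title: "Predicting steric clashes of amino acid substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting steric clashes of amino acid substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotaclash)
```

## The model

`rotaclash` treats a substitution as structurally tolerated if at least
one *common* conformation of the new side chain can be placed at the
site without a van der Waals clash. Side-chain conformational space is
discretized into rotamers — modal combinations of the χ dihedrals —
drawn from a backbone-dependent library conditioned on the site's (φ, ψ)
torsions. The backbone and all other residues are held rigid: the method
asks whether the *existing* structure can host the new side chain, not
whether the structure could relax to accommodate it.

The per-atom-pair test is

$$c = r_1 + r_2 - d - d_\mathrm{allowed},$$

a hard-sphere overlap with a tolerance. Three refinements:

* **Hydrogen-bond capable pairs.** When both elements are N or O, the
  radius sum is replaced by 2.5 Å. No donor/acceptor geometry is
  checked; any N/O–N/O pair gets the shorter limit. This over-includes
  hydrogen bonds, but over-inclusion only *relaxes* the test, which
  matches the intent (an H-bonded pair may approach closer than the vdW
  sum).
* **Cysteine pairs.** If both atoms belong to cysteine side chains (Cβ
  or Sγ of distinct residues, including the case where the substitution
  itself introduces the cysteine), the pair may be a disulfide, for
  which atom-level overlap is the wrong test. The criterion becomes a
  minimum Cα–Cα distance of 4 Å.
* **Cβ is never tested.** Rotamer atoms are enumerated strictly after
  Cβ, so Ala (side chain = Cβ) can never clash; Cβ's position is fixed
  by the backbone, not by the rotamer, so a Cβ conflict would indict the
  structure rather than the substitution.

### The decision cascade

1. *Glycine rule*: Gly fits everywhere (it removes atoms).
2. *Accessibility rule*: if the original side chain has ≥ 3 heavy atoms
   and relative accessibility ≥ 0.5, all substitutions fit. An exposed,
   reasonably long side chain demonstrates open space around the site.
3. *Smaller rule*: a target with fewer side-chain heavy atoms than the
   original fits — except the β-branched targets Val, Leu, Ile and Thr,
   whose bulk sits close to the backbone where "smaller" does not imply
   "fits"; they proceed to rotamer testing. Size is operationalized as
   heavy-atom count because it is the only measure that is
   well-defined, monotone under atom removal, and independent of
   conformation.
4. *Alanine direct placement*: a substitution to Ala that reaches this
   point (only possible at Gly sites) has no testable atoms and fits.
5. *Rotamer testing*: candidates in decreasing frequency order, stop at
   the first that fits; if none fits, the verdict is **clash** and the
   conflicts of the least-clashing rotamer (ties to the more frequent)
   are reported.

Rule precedence (Gly before accessibility before smaller) is fixed: Gly
is unconditional, and the accessibility rule is cheaper and strictly
more permissive than the smaller rule where both apply. Verdicts decided
by rules 1–4 never touch the clash engine, which the test suite audits
via the recorded `decision_path`.

### The neighbor search

Candidate clash partners are all atoms within a cutoff of the site's Cα
— polymer, ligands and cofactors alike (waters are removed at parse
time). The cutoff is constructed, not tuned: the Cα→Nη distance of an
ideal arginine with every χ at 180° (7.31 Å, the longest reach any
buildable side chain can attain; Nη2 is the far nitrogen since Nη1's
fixed dihedral folds it slightly back), plus the nitrogen van der Waals
radius 1.64 Å, plus the largest tabulated radius and d_allowed. The sum
is provably at least the distance at which any buildable atom could
still produce c > 0, so the cutoff can never exclude a true clash
partner; the test suite verifies this against a brute-force all-pairs
oracle on randomized structures. The query itself is a vectorized radius
scan over the coordinate array — with one query per substitution site
and sites queried once per batch, an O(N) scan has the same cost profile
as a spatial-index lookup without a tree-build step.

Only the substituted residue's own atoms are excluded from the
environment (its side chain is conceptually removed; its backbone
anchors the rotamer). The adjacent residues' backbone atoms are *not*
excluded, which is the main source of over-prediction near the backbone:
rotamers that graze the preceding carbonyl are discarded even where a
real structure would tolerate marginal strain.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `d_allowed` | 0.4 | Å | tolerated overlap before a contact is a clash; raising it is strictly more permissive (a monotonicity the suite checks end-to-end) |
| `hbond_radius_sum` | 2.5 | Å | replacement radius sum for N/O–N/O pairs |
| `cys_ca_min` | 4.0 | Å | minimum Cα–Cα distance for Cys–Cys side-chain contacts |
| `nitrogen_vdw` | 1.64 | Å | nitrogen radius term in the search-cutoff construction |
| `accessibility_threshold` | 0.5 | fraction | relative accessibility at which rule 2 fires |
| `min_sidechain_length` | 3 | heavy atoms | minimum original side-chain length for rule 2 |
| `branched_exceptions` | Val, Leu, Ile, Thr | — | targets exempt from the smaller rule |
| `min_frequency` | 0 | fraction | rotamer frequency floor (0 keeps every library entry; widening the list can only add fit opportunities) |
| SASA `probe` / `n_points` | 1.4 / 960 | Å / points | water probe and quadrature resolution |

### Data tables and their provenance

* **Van der Waals radii** (`inst/extdata/vdw_radii.tsv`): one radius per
  element, Chothia/Tsai protein family (N 1.64, O 1.42, S 1.77, Se 1.90,
  fallback 1.80). For carbon the carbonyl/aromatic value 1.76 Å is used
  rather than the sp³ value (1.87–1.88). The choice was measured, not
  assumed: in a well-packed reference structure (bio3d's bundled
  lysozyme example) the closest native γ-atom-to-backbone-carbonyl
  contacts sit near 3.2 Å; an sp³ carbon radius would set the C–C clash
  threshold at ≈ 3.35 Å and flag native packing as clashing, whereas
  1.76 Å sets it at 3.12 Å. An element-level table cannot distinguish
  atom types, so the value that keeps observed packing legal is the
  defensible single choice. The table is a plain-text file and can be
  overridden via `clash_params(radii = default_radii(path))`.
* **Maximum side-chain accessibility**
  (`inst/extdata/max_sidechain_asa.tsv`): computed with the package's
  own SASA implementation on extended Gly-X-Gly tripeptides (all
  χ = 180°, probe 1.4 Å, 960 points). Self-consistency matters more than
  the absolute scale here: the only consumer is the ≥ 0.5 threshold, and
  numerator and denominator come from the same SASA machinery and radii.
* **Ideal side-chain geometry**
  (`inst/extdata/sidechain_geometry.tsv`): bond lengths and angles from
  standard ideal-geometry compilations; each atom is placed by
  natural-extension from its three ancestors, with ring and branch
  dihedrals fixed (rings planar, carboxylates symmetric, branch offsets
  ±120°). χ angles beyond those the library parameterizes are fixed at
  ideal values. Cβ is always rebuilt from the backbone triad at the
  L-configuration improper (C–N–Cα–Cβ = +122.55°), so Gly sites can host
  any rotamer and the replacement side chain has a defined direction
  even when the original Cβ deviates.
* **Embedded rotamer library**
  (`inst/extdata/rotamers_minimal.tsv`): canonical χ modes with
  approximate literature frequencies, in two coarse 30° backbone bins
  (α-helix and β-sheet regions). Queries outside those bins, or at sites
  with undefined φ/ψ (termini, chain breaks), fall back to a
  backbone-independent marginal aggregated across bins. This keeps the
  predictor exercisable with zero downloads; a full-resolution
  backbone-dependent library in the same column format
  (`res phi psi freq chi1..chi4`) can be supplied to
  `load_rotamer_library()` (native 10° binning).

## Numerical choices

* **Binning** is half-open `[lo, hi)` on (−180°, 180°], with +180°
  wrapped into the first bin, so every torsion maps to exactly one bin.
* **Ties.** Rotamer lists sort by descending frequency, then ascending
  χ₁. Equal-occupancy altlocs resolve to "A", then lexicographically.
  The least-clashing rotamer reported for a clash verdict breaks ties
  toward the more frequent (earlier) candidate.
* **Degenerate inputs.** Collinear points make torsions undefined
  (error, or NA propagated at chain termini/breaks, where a break is a
  consecutive Cα–Cα distance > 4.5 Å); Gly has no relative accessibility
  (callers must not ask); an empty neighborhood fits vacuously;
  zero-occupancy atoms are retained (no filter is applied).
* **SASA quadrature.** Golden-spiral point sets are deterministic and
  quasi-uniform. Convergence is measured against each atom's full sphere
  area: halving the spacing moves per-atom SASA by < 1 % of the sphere
  area. The world-frame grid is not rotation-covariant, so SASA is
  rotation-invariant only to quadrature accuracy (torsions and built
  geometry are exact to 1e−6); the accessibility rule consumes a 0.5
  threshold, far above this noise.
* **Rounding.** Scores are computed at full precision; display rounding
  is half-up to 2 decimals, the convention of published performance
  tables. A score with a zero denominator is undefined (NA), never 0.

## What the synthetic fixtures do and do not show

The generators produce structures with *known ground truth*:

* `make_helix(n, phi, psi)` — ideal polyalanine (or any residue name)
  chains; torsion recovery is exact by construction.
* `make_extended_residue(res)` — extended Gly-X-Gly tripeptides; the
  accessibility references.
* `make_cage(gap)` — a residue enclosed by a spherical carbon shell
  (HETATM records, so the ligand-clash path runs by default): below the
  clash threshold every ≥ 2-atom side chain must fail; beyond the search
  cutoff everything must fit; verdicts are monotone in the gap.
* `make_blob(seed)` — seeded random atom environments for
  oracle-equivalence sweeps against the brute-force all-pairs
  implementation.

These fixtures validate the machinery — geometry, search, overlap rules,
cascade logic — under conditions where the correct answer is derivable.
They do *not* emulate real packing statistics, crystallographic error,
alternate conformations under strain, or compensating rearrangements;
passing them shows the method computes what it claims, not that the
binary verdict is biologically correct in any given protein. The test
suite's problem sizes (helices of 6–20 residues, 100 random
environments of 35–40 atoms, 960-point SASA) were chosen as the smallest
sizes at which each property is non-trivially exercised.

For a real-structure spot check with a locally downloaded PDB file, a
known benchmark case is the SH2 domain of SH2D1A (PDB 1D4W): Leu98→Glu
is accommodated while Leu98→Arg clashes against the Ile84/Tyr29 pocket —
`clash_scan("1d4w.pdb", "A:L98E\nA:L98R\n")` reproduces both verdicts
and lists the pocket residues among the clash partners.

## Known limitations

* Rigid backbone: proline substitutions (which re-shape the backbone)
  are systematically over-predicted as clashes and carry a warning;
  strained-but-tolerated variants near the backbone may also be called
  clashes because adjacent backbone atoms are legitimate partners.
* Binary output: no clash severity and no stability estimate; a *fits*
  verdict does not imply the variant is functionally neutral, only that
  space exists for some common rotamer.
* Element-level radii cannot express atom-type differences (sp³ vs
  carbonyl carbon); the single carbon value is a compromise documented
  above.
* The minimal embedded library trades coverage for self-containment;
  rare rotamers absent from it can turn a borderline *fits* into
  *clash* (never the reverse — widening the list is monotone).
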