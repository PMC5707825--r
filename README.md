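# rotaclash

Rotamer-based steric clash prediction for amino acid substitutions in
protein structures.

## The problem

A missense variant replaces one side chain with another inside a folded
protein. If no plausible conformation of the new side chain fits into the
space the structure offers, the substitution forces local or global
rearrangement and is very likely harmful. `rotaclash` answers, for each
substitution, the binary question: *can the new side chain be
accommodated, or does every common conformation collide with the
surrounding atoms?* It is aimed at structural bioinformaticians and
protein engineers triaging variant lists (including NGS-scale ones)
against a PDB structure, and at method developers who need a transparent,
fully scriptable clash test.

## The method

For a substitution at a site with backbone torsions (φ, ψ):

1. **Fast assumptions.** Glycine fits everywhere. If the original side
   chain is at least 3 heavy atoms long and its relative solvent
   accessibility — side-chain SASA divided by the residue type's maximum
   side-chain SASA — is ≥ 0.5, every substitution fits. A substitution to
   a smaller side chain (by heavy-atom count) fits, unless the target is
   short-but-branched (Val, Leu, Ile, Thr), which must still be tested.
2. **Rotamer fitting.** Otherwise, the backbone-dependent rotamer library
   is queried at (φ, ψ) and each candidate rotamer is built from ideal
   internal coordinates onto the site's own backbone (Cβ placed at ideal
   L-configuration geometry) in decreasing order of frequency. Every
   side-chain atom after Cβ is tested against every surrounding atom
   (ligands and cofactors included; waters and hydrogens removed) with
   the overlap score

   c = r₁ + r₂ − d − d_allowed

   where r are van der Waals radii, d the interatomic distance and
   d_allowed = 0.4 Å the tolerated overlap. For hydrogen-bond-capable
   pairs (N/O with N/O) the radius sum is replaced by 2.5 Å; contacts
   between two cysteine side chains use a minimum Cα–Cα distance of 4 Å
   (disulfide geometry) instead. A rotamer with any c > 0 is discarded;
   the search stops at the first fitting rotamer. If none fits, the
   substitution is predicted to cause a **clash**.

Surrounding atoms are collected within a provably sufficient radius of
the site's Cα: the reach of a fully extended arginine plus the nitrogen
van der Waals radius (1.64 Å), the largest tabulated radius and
d_allowed.

Performance against labelled variants is scored with confusion-matrix
measures (accuracy, PPV, NPV, sensitivity, specificity, MCC) with
*clash* as the positive class.

## Worked example

Everything below runs offline: structures come from the package's
synthetic-fixture generators.

```r
library(rotaclash)

h <- make_helix(12, res_type = "LEU")         # exposed 12-residue helix
pdb <- tempfile(fileext = ".pdb"); write_pdb(h, pdb)
rep <- clash_scan(pdb, "A:L6R\nA:L6G\n")
rep[, c("position", "from_aa", "to_aa", "verdict", "decision_path",
        "fitting_rotamer_chis")]
#>  position from_aa to_aa verdict decision_path fitting_rotamer_chis
#>         6       L     R    fits   rotamer_fit     -177,180,180,180
#>         6       L     G    fits  glycine_rule
```

Leu6 → Arg fits: the second-most-frequent arginine rotamer
(χ = −177, 180, 180, 180) can be built without any positive overlap, so
the search stopped there. Leu6 → Gly is decided without any geometry at
all (glycine is allowed at every position).

The same substitution inside an enclosed site is rejected:

```r
cage <- make_cage(2.0)   # a residue walled in by a 2 A shell of C atoms
p <- predict_substitution(cage, variant("A", 1, to_aa = "W"))
p
#> A:1 A -> W : clash (no_rotamer_fits)
#>   148 clashing pair(s), worst overlap 2.5 A
```

Every tryptophan rotamer collides with the shell (the report lists the
conflicts of the least-clashing one), so the verdict is *clash* with
decision path `no_rotamer_fits`.

A shell command-line interface with the same semantics is installed as
`exec/rotaclash` inside the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "rotaclash", package = "rotaclash"))')" \
  --structure protein.pdb --variants variants.txt --out report.tsv
```

Variant lines are one per line: `123` (all 19 substitutions at position
123), `A:123`, `A:L123R`, or `L123R`.

## Limitations

- The backbone is held fixed; substitutions to proline, which bend the
  backbone in reality, are over-predicted as clashes and carry a warning.
- Verdicts are binary: no clash severity, no ΔΔG.
- The embedded rotamer library is minimal (canonical χ modes in coarse
  backbone bins); for production use load a full-resolution
  backbone-dependent library with `load_rotamer_library()`.

See `vignettes/clash-prediction.Rmd` for the full method description,
parameter choices and design rationale.
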