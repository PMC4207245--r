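---
title: "Alpha-helix wheels, hydrophobic moments, and backbone validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-helix wheels, hydrophobic moments, and backbone validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmundson)
```

## What the package computes

An alpha helix places successive residues about 100° apart when viewed down
its axis (3.6 residues per turn), so projecting a sequence onto a circle —
the Edmundson wheel — shows which residues share a face. Antimicrobial
peptides are typically *amphipathic*: hydrophobic residues cluster on one
face and charged residues on the other, and this segregation is what lets
them partition into bacterial membranes. The package quantifies and draws
this, and it also tests whether a claimed helix actually *is* one, using
backbone geometry alone.

Four quantities drive everything:

* **Wheel position.** Residue $k$ sits at angle
  $\theta_k = 90^\circ - 100^\circ\,(k-1)$ on a circle of radius 5 (drawing
  units), so residue 1 is at $(0, 5)$ and residues $k$ and $k+18$ coincide
  ($18 \times 100^\circ$ is five full turns).
* **Hydrophobic moment.** With $h(r_k)$ the hydrophobicity of residue $k$
  and $\hat u_k$ the unit vector from the wheel centre to its position,
  $\vec\mu = \sum_k \hat u_k\, h(r_k)$. This is the raw vector sum, not
  divided by length; `mean_magnitude` exposes $|\vec\mu|/n$ as a derived
  convenience. A large $|\vec\mu|$ means amphipathicity.
* **RPNR**, the ratio of positive to negative residues:
  $n_{pos}/(n_{pos}+n_{neg})$ with $n_{pos}$ counting Lys and Arg and
  $n_{neg}$ counting Asp and Glu. It is 1 for an all-cationic hydrophilic
  face and undefined (`NA`) when the peptide has no charged residues at
  all. Unlike a "charge moment" (a charge-weighted vector sum over wheel
  positions), RPNR cannot be fooled by moving a cationic residue across the
  wheel and substituting an anionic one at a position that leaves the
  vector sum unchanged: the composition changes, so the ratio changes.
* **The distance property.** In a genuine helix, the distance between the
  C$\alpha$ atoms of residues $i$ and $i+4$ is (almost) equal to the
  distance between their carbonyl oxygens:
  $\delta = |D(C\alpha_i/C\alpha_{i+4}) - D(O_i/O_{i+4})| \approx 0$. The
  helix-defining hydrogen bond puts $O(i)$ within about 3.6 Å of
  $N(i+4)$; where that distance is violated, the residue is not really
  helical no matter what the PDB HELIX record says.

## The hydrophobicity scale and colours

The default scale (`hydrophobicity_scale()`) is a Jones-type dimensionless
scale; its sign structure drives the wheel colouring: positive values
(hydrophobic, including His at 0.333 and Pro at 0.239) are red; among the
negative-valued residues, Lys/Arg are dark blue (cationic), Asp/Glu medium
blue (anionic), and Asn/Gln light blue (amides). His is *not* counted as
charged in RPNR, consistent with its positive (hydrophobic) scale value.
Custom scales load from two-column `AAA value` text via `read_scale()`; all
20 residues are required so that classification stays total.

```{r}
w <- wheel_layout(">KR-12\nKRIVQRIKDFLR")
glance(w)
rpnr("KRIVQRIKDFLR")
```

## Validating helices from backbone geometry

`measure_pairs()` enumerates every $(i, i+4)$ pair (author residue
numbering, per chain), records `d_hbond`, `d_ca`, `d_o` and `delta`, and
labels a pair *in-helix* only when the whole interval $[i, i+4]$ lies
inside a single HELIX annotation; pairs straddling an annotation boundary
count as non-helix, since no annotation vouches for the full turn.
`correct_helices()` rejects a residue $i$ whose measured $O(i)$–$N(i{+}4)$
distance exceeds the 3.6 Å cutoff and re-annotates the surviving runs of
at least 5 consecutive residues (a shorter run cannot contain a single
$i,i{+}4$ hydrogen bond). A residue whose partner cannot be measured — the
last four residues of a chain have no $i+4$ — is retained: only a measured
violation is evidence of mis-annotation. The correction can therefore trim
mis-annotated helix termini, the most common defect in deposited HELIX
records, and never flags an ideal helix.

The rejection rule removes *pairs*, and removing pairs does not
mechanically lower a mean; the guarantee that correction reduces the mean
$\delta$ is an empirical property of the defect it targets, in which a few
displaced residues both break their hydrogen bonds and carry large
$\delta$. The test suite exercises exactly that regime (ideal helices with
two residues rigidly displaced by 5 Å). Under heavy *global* coordinate
noise every pair degrades equally, survivors are arbitrary, and the
corrected mean can go either way — that regime is not a mis-annotated
helix and is not part of the correction's contract.

## The synthetic helix generator

`build_ideal_helix()` constructs backbone N, CA, C, O coordinates by
sequential internal-to-Cartesian placement with fixed torsions
$\varphi=-57^\circ$, $\psi=-47^\circ$, $\omega=180^\circ$ and standard bond
lengths (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å). It builds
from internal coordinates rather than a parametric spiral because the
distance property involves carbonyl oxygens, which a Cα-only spiral lacks;
the helical twist (~100°/residue) and rise (~1.5 Å/residue) are then
*emergent* from the torsions rather than parameters, and the test suite
verifies them. The torsions are exposed for perturbation studies;
`noise_sd` adds i.i.d. Gaussian jitter per coordinate under a mandatory
seed.

What the generator emulates: the local covalent geometry and hydrogen-bond
pattern that the distance property rests on, plus coordinate uncertainty
(noise) and mis-annotation (displaced residues). What it does not emulate:
side chains, crystal contacts, bent or kinked helices, B-factor-dependent
coordinate error, or the sequence composition biases of real proteins.
Passing tests on synthetic data therefore demonstrate the geometry and the
machinery, not the field-wide statistics of deposited structures; the
checks against named high-resolution PDB entries exist for that and
require downloading those entries.

```{r}
h <- build_ideal_helix(12)
measure_pair(h, "A", 3)
```

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| wheel radius | 5 | drawing units | conventional wheel size; scales the picture only |
| angular step | 100 | degrees/residue | 3.6 residues per helical turn |
| H-bond cutoff | 3.6 | Å | typical O–N hydrogen-bond distance requirement; no angle term is used, distance only |
| minimum corrected run | 5 | residues | shortest span containing one $i,i{+}4$ bond |
| `noise_sd` | 0 | Å | ideal geometry unless perturbation is requested |
| scale | Jones-type table | — | sign structure defines the red/blue colouring |

Reported tables round distances to 1 decimal (Å); the printed `delta`
column is recomputed from the *rounded* `d_ca` and `d_o` so the table is
internally consistent. Internal computation is full precision. Summary
statistics use the population standard deviation (divide by $n$); with
hundreds of pairs the choice is immaterial, but it is fixed for
reproducibility.

## Numerical choices and degenerate inputs

* Moment arrows shorter than $10^{-9}$ are treated as zero and omitted
  from renders (an 18-mer homopolymer's moment is zero to rounding).
* Residue identity is (chain, author number, insertion code); pairing uses
  author-number arithmetic, so numbering gaps skip pairs rather than
  guessing. Residues with insertion codes or non-standard names are
  reported but excluded from pairing.
* Alternate locations resolve to the blank/'A' conformer; only the first
  MODEL of an NMR-style file is read.
* RPNR on a charge-free peptide returns `NA` with a warning rather than 0:
  "no charged residues" and "balanced charges" must not collapse.
* An empty pair selection yields `n_pairs = 0` with `NA` statistics.

## Problem sizes

The test and acceptance workloads use 20 ideal helices of 12–30 residues
(~330 pairs), 10 mixed clean/noisy fixtures, 10 mis-annotation fixtures,
and 100 random sequences for the moment oracle; these sizes make every
distributional comparison stable across seeds while keeping a full run in
well under a minute.

## Known limitations

* Helix definitions come from HELIX records, user spans, or the
  hydrogen-bond correction — there is no DSSP-style assignment from
  $\varphi/\psi$ and no energy-based hydrogen-bond model.
* The hydrophobic moment is computed for the idealized wheel geometry; a
  peptide's real conformation (and hence its effective moment) depends on
  solvent, which is out of scope.
* TikZ and PyMOL outputs are minimal deterministic dialects defined by
  this package and covered by golden-file tests; visual styling is not
  contractual.
* mmCIF input is not supported; fixed-column PDB only.
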