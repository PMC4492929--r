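---
title: "Scoring binding free energy changes upon point mutation: the model behind saambe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring binding free energy changes upon point mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saambe)
```

## The problem

A single amino acid substitution at or near a protein-protein interface can
strengthen, weaken or abolish binding. The quantity of interest is the change
in binding free energy,

$$\Delta\Delta G \;=\; \Delta G_{bind}^{MT} - \Delta G_{bind}^{WT}
\quad \text{(kcal/mol, positive = binding destabilized)},$$

measured experimentally by calorimetry or surface plasmon resonance and
needed computationally at proteome scale, where rigorous free energy
perturbation is far too slow. `saambe` implements a fast scoring approach:
a weighted linear combination of MM/PBSA-style energy components and
knowledge-based structure-derived terms, with weights fitted by multiple
linear regression against experimental $\Delta\Delta G$ values.

## The model

Every energy-like quantity $E$ enters through the rigid-body double
difference

$$\Delta\Delta E = (E_{AB}^{MT} - E_A^{MT} - E_B^{MT}) -
                   (E_{AB}^{WT} - E_A^{WT} - E_B^{WT}),$$

where $AB$ is the complex and $A$, $B$ are the unbound partners whose
coordinates are taken unchanged from the complex (no binding-induced
conformational change is modeled explicitly). The score is

$$\Delta\Delta G = w_0 + w_1\,\Delta IE + w_2\,\Delta\Delta EE +
w_3\,\Delta\Delta VE + w_4\,\Delta\Delta SP + w_5\,\Delta\Delta SN +
w_6\,\Delta\Delta S + w_7\,\Delta\Delta HYDR + w_8\,\Delta HB +
w_9\,\mathrm{Interface}^{MT} + w_{10}\,\frac{\Delta\Delta SASA}{\mathrm{Interface}^{MT}}.$$

The first five terms are the MM/PBSA block: internal energy (complexes only
-- the rigid-body double difference of internal energy is identically zero,
so the complex difference is used even though this is, strictly speaking,
not a thermodynamically meaningful quantity), Coulomb, van der Waals, and
polar/nonpolar solvation. Force-field minimization and Poisson-Boltzmann
solving are out of scope here: `IE`, `VE`, `SP` and normally `EE` are
**imported** per case from a components TSV (`load_energy_components()`).
Two exceptions:

* the nonpolar solvation term is linear in total SASA, with its slope
  absorbed into $w_5$ and its offset into $w_0$, so the feature reduces to
  the double difference of total SASA, which the package computes itself;
* `coulomb_ee()` offers a deliberately coarse internal stand-in for the
  Coulomb component -- formal charges (Asp/Glu $-1$ at the carboxylate-oxygen
  midpoint, Lys $+1$ at N$\zeta$, Arg $+1$ at C$\zeta$, His $+1$ at the
  ND1/NE2 midpoint) at a uniform dielectric of 7, pair distances clamped at
  1 Å. Imported values always take precedence.

The knowledge-based block is computed entirely from the coordinates:

* **Rotamer entropy** $S = \sum_j \ln[\,\mathrm{rSASA}_j (R_j - 1) + 1\,]$,
  with $R_j$ the maximum side-chain rotamer count of the residue type: a
  fully exposed residue samples all its rotamers, a buried one is frozen.
  rSASA is clipped to $[0,1]$ so the logarithm's argument never drops
  below 1 (the clip also bounds the hydrophobicity term; behavior above
  rSASA = 1 is otherwise undefined).
* **Hydrophobicity** $HYDR = \sum_j H_j \cdot \mathrm{rSASA}_j$ on the
  Wimley-White scale: exposure-weighted so that buried residues contribute
  nothing.
* **Hydrogen bonds**: an (H, O) pair closer than 2.4 Å, excluding
  C$\alpha$/C$\beta$ hydrogens (names HA*/HB*), with both residues in the
  polar (S, T, N, Q, Y) or charged (R, H, K, D, E) set. Nitrogen acceptors
  and bond geometry are intentionally ignored; any oxygen of an eligible
  residue (backbone carbonyl included) can accept; intra-residue and
  covalent (< 1.2 Å) pairs never count. The balance
  $\Delta HB$ credits inter-partner bonds gained by the mutant and debits
  intra-monomer bonds (which stabilize the unbound state). Hydrogens are
  required; a heavy-atom proxy mode (donor N/O to acceptor O under 3.4 Å)
  exists for hydrogen-free inputs and is flagged as a deviation.
* **Interface area**, reported with the positive buried-area convention
  $\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB)$. The literal
  "complex minus parts" difference is negative; the sign is flipped so a
  positive interface weight penalizes large interfaces consistently.
  $\Delta\Delta SASA$ is the double difference of total SASA, and the last
  feature normalizes it by the mutant interface (defined as 0, with a
  warning, when the partners do not touch).

### Surface areas

SASA is computed by Shrake-Rupley quadrature on the heavy atoms: each atom
inflated by a 1.4 Å probe, sampled with a deterministic Saff-Kuijlaars
spiral point set (960 points/atom by default; fully reproducible, no RNG),
a point counting as accessible when outside every neighboring inflated
sphere. Radii are a bundled NACCESS/Chothia-style element table
(C 1.87, N 1.65, O 1.40, S 1.85, P 1.80 Å); unknown elements are an error,
never a silent default. Relative SASA divides by a bundled Tien-style
theoretical maximum per residue type and is not clipped on output. At 960
points the per-atom quadrature deviation from a 10,000-point reference is
well under 2% of a full probe sphere; tests assert this against an
independent Fibonacci-lattice quadrature.

### Interface location classes

A mutation site is classified from its relative accessibility in the
monomer (rSASAm) and complex (rSASAc) states:

| class | meaning | rSASAm | rSASAc | ΔrSASA |
|-------|-----------------------|--------|--------|--------|
| COR | interface core | > 25% | < 25% | > 0 |
| SUP | interface support | < 25% | < 25% | > 0 |
| RIM | interface rim | any | > 25% | > 0 |
| INT | interior, off-interface | any | < 25% | = 0 |
| SUR | surface, off-interface | any | > 25% | = 0 |

Boundary policy: values exactly at 0.25 join the "> 25%" branch; "= 0"
means $|\Delta rSASA| \le 10^{-6}$. Rigid-body splitting guarantees
$\Delta rSASA \ge 0$; any residual combination returns `"unclassifiable"`
rather than a silent default.

## The small/large-effect classifier

Experimental $|\Delta\Delta G|$ splits roughly evenly at 1 kcal/mol, which
motivates two separate weight sets. Four flags describe a mutation: WT
residue type, MT residue type, WT site location, MT site location. Each
flag value carries an empirical probability of a large effect
($|\Delta\Delta G| \ge 1$, boundary inclusive). The tables are refined one
pass by *alteration*: each record's magnitude is reweighted by how strongly
the other three flags support its observed class,

$$|\Delta\Delta G|^{altered}_{(i)} =
\begin{cases}
\tfrac{2}{3}\sum_{j \ne i} P_j \cdot |\Delta\Delta G|, & |\Delta\Delta G| < 1\\[2pt]
\tfrac{2}{3}\sum_{j \ne i} (1 - P_j) \cdot |\Delta\Delta G|, & |\Delta\Delta G| \ge 1
\end{cases}$$

(all-0.5 probabilities change nothing), and flag dimension $i$'s table is
rebuilt from its own altered values. How the four per-flag altered
datasets should merge into one final table is genuinely open; this package
recomputes each dimension from its own altered set in a single pass, with
no fixed-point iteration -- the bundled tables are the defaults for
prediction, so the choice only affects table-rebuilding workflows. A prediction routes on the consensus
$P = \tfrac14 \sum_{i} P_i$: the large-effect weight set iff $P \ge 0.5$.
Rows with no data are absent and raise an error on lookup -- never a
silent 0.5.

```{r classifier}
consensus_probability(mutation_annotation("Q", "P", "COR", "SUP"))[c("p", "subset")]
```

## Weight fitting, validation, dielectric scan

`fit_weights()` is ordinary least squares with intercept (QR via `lm()`),
reporting the Pearson correlation of fitted vs experimental values and
two-sided t-test p-values per coefficient; rank deficiency is an error
naming the collinear terms. `cross_validate()` does k-fold (default 5)
validation with fold sizes differing by at most one, seeded (default
20150706) and reproducible. `trim_2sd()` refits after dropping points
beyond twice the residual SD, a single pass; an exactly linear input
(residual SD at floating-point noise) drops nothing, and identical
predictions are a degenerate-input error.

Three weight sets are bundled (`saambe_weights("tdb")`, `"tdb_small"`,
`"tdb_large"`), fitted on the full training database and on its small- and
large-effect halves. Terms absent from a published column are exact zeros.
The published slope/y-intercept metadata of the experimental-vs-predicted
line is stored verbatim but never applied, as its intended use is not
specified.

`scan_dielectrics()` re-fits the score restricted to the
dielectric-dependent terms (`dd_ee`, `dd_ve`, `dd_sp`) over a grid of
per-class dielectric constants -- charged 5..15, polar 3..13, other 3..13,
step 2 (216 combinations). Note that the adopted optimum (9, 8, 7) is not
itself a node of that grid in the polar direction: the polar grid holds
only odd values. The scan therefore also reports a continuous argmax,
obtained by fitting a parabola through the best node and its two neighbors
**in the 1/ε coordinate** (energies vary as 1/ε, so the correlation
surface is approximately symmetric there; interpolating in ε itself
biases the vertex upward by about half a grid step). This is the numerical
analogue of reading the optimum off a contour map of the sampled surface.

## Evaluation

Predictions are benchmarked with a four-outcome scheme: true positive when
both $|\Delta\Delta G_{calc}|$ and $|\Delta\Delta G_{exp}|$ are at least
1.5 kcal/mol with matching signs; false positive when a predicted change
$\ge 1.5$ meets a measured $< 0.5$; true negative when both are $< 0.5$;
false negative when a predicted $< 0.5$ meets a measured $\ge 1.5$. The
middle band (0.5-1.5 on either axis) and large pairs of opposite sign fall
in no cell and are excluded as `unclassified` -- which is why benchmark
counts total far below the dataset size. The sign of zero counts as
positive. Six summary metrics follow; the Matthews correlation coefficient
uses the conventional numerator $tp \cdot tn - fp \cdot fn$ (the
alternative "+" form is inconsistent with the published metric values,
which only the conventional form reproduces).

```{r roc}
unlist(roc_metrics(list(tp = 320, tn = 239, fp = 5, fn = 47)))
```

## Dataset curation

SKEMPI-style tables of repeated measurements are curated per complex and
mutation: exact duplicates collapse; groups whose spread (max - min) is
below 1.5 kcal/mol fuse to their mean; wider groups are deleted outright
(a spread of exactly 1.5 is deleted -- the stated "< 1.5 fuse" / "> 1.5
delete" rules leave the boundary open and the conservative side is taken).
Mutations in structurally disordered segments are removed. Every action is
logged, and curation is idempotent.

## What the synthetic generators emulate -- and what they do not

`make_toy_complex()` builds two extended chains facing each other across a
gap, with stylized side chains carrying correctly named functional atoms
(OD1/OD2, NZ, OG...), optional polar hydrogens, an optionally planted
Ser-Asp hydrogen bond at an exact H...O distance, and mutants derived by
naive side-chain relabeling (truncation to C$\beta$ -- explicitly
non-physical, fixtures only). Geometry is jittered by ±0.02 Å from a local
seeded RNG (global RNG state untouched), and inter-residue heavy-atom
clashes under 1.5 Å are an error. These toys exercise every structural
code path but are not proteins: no secondary structure, no realistic
packing, no rotamers. Passing tests demonstrate correctness of the
*computations*, not predictive accuracy on real complexes, which depends
on externally produced minimized structures and energy components.

`simulate_dataset()` draws independent Gaussian features and generates
$\Delta\Delta G$ from a known weight set plus Gaussian noise. Default
spreads are matched once to the magnitudes the published weights act on
(energy terms a few kcal/mol, interface areas 1600 ± 400 Å², the
normalized area ratio ±0.05, noise 0.5 kcal/mol); they make no claim to
reproduce the real training database's covariance -- features are
independent here, which real energy terms are not. With these defaults the
analytic correlation $\sqrt{V_s/(V_s+\sigma^2)} \approx 0.955$ and OLS at
$n = 1000$ recovers every weight within a few standard errors.

`make_dielectric_scan_data()` plants a recoverable dielectric optimum. Two
design points matter. First, a pure $1/\varepsilon$ mixture is
unidentifiable along the overall-scale ray (each feature's regression
coefficient absorbs a common rescaling of all three constants), so the
solvation feature follows a Born-like $1/\varepsilon - 1/80$ dependence
plus an ε-independent reaction-field component, anchoring the scale the
way a fixed solvent dielectric does physically. Second, the surface is
shallow near its maximum, so the defaults (n = 800 cases, residual noise
0.1 kcal/mol) are chosen so the interpolated argmax is stable; at higher
noise the best grid node is still adjacent to the truth but the refined
optimum wobbles beyond rounding distance.

## Numerical choices and limitations

* Problem sizes in tests and the acceptance script (toy complexes of tens
  of atoms, simulations of 800-1000 cases, a 216-point scan) are the
  package's chosen desk-scale study conditions; they run in seconds.
* Altloc resolution keeps the highest occupancy, ties alphabetically;
  waters are always excluded from the working model (counted separately);
  non-canonical ATOM residues are rejected because the constant tables
  cover only the 20 canonical types.
* Mutant structures are inputs: side-chain rebuilding and minimization are
  upstream of this package by design.
* Published headline correlations on the real training database are not
  reproducible here without that database and its externally computed
  energy components; the regression machinery is instead validated by
  exact noiseless recovery and by recovery-within-standard-errors on
  simulated data.
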