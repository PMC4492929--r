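# saambe

Predicting the change in protein–protein binding free energy (ΔΔG,
kcal/mol) caused by a single amino acid substitution, from the 3D structure
of the complex. The package is aimed at structural bioinformaticians who
need fast, interpretable ΔΔG estimates at scale — mutation-effect screening,
interface hot-spot analysis, benchmarking — rather than expensive free
energy perturbation.

## The model

Every energy-like term enters through the rigid-body double difference

    ΔΔE = (E_AB^MT − E_A^MT − E_B^MT) − (E_AB^WT − E_A^WT − E_B^WT)

(unbound monomers taken unchanged from the complex), and the score is a
weighted linear combination

    ΔΔG = w0 + w1·ΔIE + w2·ΔΔEE + w3·ΔΔVE + w4·ΔΔSP + w5·ΔΔSN
             + w6·ΔΔS + w7·ΔΔHYDR + w8·ΔHB
             + w9·Interface^MT + w10·ΔΔSASA/Interface^MT

MM/PBSA components (internal, Coulomb, van der Waals, polar solvation) are
imported per case from a TSV produced by external minimization/PB software;
everything knowledge-based — Shrake–Rupley solvent accessible surface
areas, rotamer entropy `S = Σ ln[rSASA·(R−1)+1]`, Wimley–White
hydrophobicity `Σ H·rSASA`, hydrogen-bond balance (H⋯O < 2.4 Å between
polar/charged residues), interface areas and the five-way interface
location classes (COR/SUP/RIM/INT/SUR from monomer/complex relative SASA)
— is computed from the coordinates by this package. A probability
classifier over four mutation "flags" (WT/MT residue type, WT/MT site
location) routes each case to weight sets fitted on small-effect
(|ΔΔG| < 1 kcal/mol) or large-effect mutations; the three published weight
sets are bundled. Weight fitting (OLS), 5-fold cross-validation, ±2SD
outlier trimming, a per-residue-class dielectric-constant scan harness,
SKEMPI-style dataset curation, and confusion-matrix benchmarking (accuracy,
sensitivity, specificity, precision, NPV, MCC) are included, plus
deterministic toy-complex and simulated-dataset generators so the whole
pipeline is testable without external data.

## Worked example

A deterministic toy complex (two five-residue chains facing across an
interface) with an Asp→Ala mutation on chain A:

```r
library(saambe)
mut  <- mutation_descriptor("A", 3, "D", "A")
case <- make_toy_case("ASDKG", "GSETA", mut, gap = 13, hydrogens = TRUE)

terms <- assemble_terms(case, ee_fallback = TRUE)
round(unclass(terms), 4)
#>                   d_ie                  dd_ee                  dd_ve
#>                     NA               -11.5708                     NA
#>                  dd_sp                  dd_sn                   dd_s
#>                     NA                22.3809                 0.2007
#>                dd_hydr                   d_hb           interface_mt
#>                 0.1253                 0.0000                78.6868
#> dd_sasa_over_interface
#>                 0.2844
```

`d_ie`, `dd_ve`, `dd_sp` are `NA` because no energy-components file was
supplied (they are imported quantities); `dd_ee` here comes from the
internal uniform-dielectric Coulomb fallback. Removing the charged Asp
leaves a positive `dd_sn` (the mutant buries less surface) and a positive
`interface_mt` of ~79 Å² for this small toy interface.

The classifier, with the bundled probability tables:

```r
consensus_probability(mutation_annotation("D", "A", "COR", "COR"))[c("p", "subset")]
#> $p
#> [1] 0.5475
#> $subset
#> [1] "large"
```

so this mutation would be scored with the large-effect weight set
(P ≥ 0.5). Benchmark metrics from a confusion table:

```r
unlist(roc_metrics(list(tp = 320, tn = 239, fp = 5, fn = 47)))
#>    accuracy sensitivity specificity   precision         npv         mcc
#>   0.9149918   0.8719346   0.9795082   0.9846154   0.8356643   0.8362002
```

A command-line front end mirrors the R API
(`exec/saambe features|sasa|predict|classify|fit|evaluate|curate|simulate|scan`):

```sh
exec/saambe classify --mutation Q>P --loc-wt COR --loc-mt SUP
# P = 0.5550 -> large effect
exec/saambe sasa --pdb complex.pdb --chains-a A --chains-b B --out profile.tsv
```

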