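# oligoshift

Tools for determining and engineering the **oligomeric state of homomeric
enzyme assemblies** — dimers, dimer-of-dimers tetramers, and D3 hexamers of
the kind formed by form II RuBisCO. The package is aimed at structural
biologists and protein engineers who assign solution assembly states from
SEC-SAXS(-MALS) data and design interface mutations that shift a homomer
from one state to another.

## What it computes

**State classification.** Candidate assemblies are scored against an
experimental scattering curve with the orientationally averaged Debye sum

    I(q) = sum_i sum_j f_i f_j sin(q r_ij) / (q r_ij),

with constant per-residue (or per-atom) electron-count form factors. The
radius of gyration comes from a Guinier fit, I(q) = I(0) exp(-q² Rg²/3),
on a deterministic low-q window kept inside the validity limit q·Rg ≤ 1.5.
Each candidate is compared by the scale-optimal fit quality

    chi = sqrt( sum_i [ (I_exp(q_i) - c·I_model(q_i)) / sigma_i ]² / (N-1) ),

and the state call is the candidate with minimal chi, optionally checked
against the subunit count implied by a measured molecular mass
(`round(mass / subunit_mass)`).

**Interface analysis.** Contacts, hydrogen bonds (donor/acceptor N/O pairs
within 3.6 Å, distance-only), and salt bridges (charged-group pairs within
4.0 Å) across a stated chain partition; interface residues by two criteria
— any heavy atom within 5.5 Å of the opposite group, or a side chain
pointing at the opposite group within 9 Å.

**2-to-6 design screen.** Given a template multimer and a candidate homolog
subunit, the screen finds interfacial positions where the two sequences
differ, enumerates all 2^k mutation combinations, rebuilds each mutant under
the template symmetry, scores it over 50 side-chain-perturbed samples with a
transparent surrogate interaction score, and selects among the top-5
finalists by interface hydrogen-bond count.

**Kinetics.** Derived quantities from measured RuBisCO parameters via the
specificity relation S_C/O = (kcat_C/K_C)/(kcat_O/K_O): the oxygenase
turnover kcat_O = kcat_C·K_O/(S_C/O·K_C), fold changes, and percent
decreases against a reference enzyme.

**Synthetic data.** Seeded generators for coarse bead assemblies with exact
C2 / tetramer / D3 geometry, noisy SAXS profiles, and homolog pairs with
planted interface differences, so the entire pipeline is testable offline.

## Worked example

Classify a noisy synthetic hexamer curve against dimer / tetramer / hexamer
candidates, then derive kinetics from a measured parameter table:

```r
library(oligoshift)

q <- seq(0.01, 0.46, length.out = 150)
cands <- sapply(c(dimer = "C2", tetramer = "dimer_of_dimers", hexamer = "D3"),
                function(pg) make_assembly(synthetic_spec(point_group = pg,
                                                          seed = 5))$assembly,
                simplify = FALSE)
prof <- make_noisy_profile(cands$hexamer, q, noise_rel = 0.02, seed = 42)

guinier_fit(prof)
#> <guinier_fit> Rg = 21.80 A, I0 = 5.688e+08, 20 points, q_max = 0.0674 (qRg = 1.47), R^2 = 0.9881

sub_mass <- theoretical_mass(chain_sequence(cands$hexamer, "A"))
classify_oligomer(prof, cands, measured_mass = 6 * sub_mass, subunit_mass = sub_mass)
#> <oligomer_call> best model: hexamer
#>   dimer        chi = 30.72
#>   tetramer     chi = 22.51
#>   hexamer      chi = 1.005
#>   mass-implied subunits: 6 (consistent with best model: TRUE)
```

The chi ≈ 1 for the generating model says the residuals match the stated 2%
noise; the dimer and tetramer are rejected by an order of magnitude. The
Guinier Rg (about 22 Å) is the scattering-weighted size of the coarse
hexamer.

```r
tsv <- system.file("extdata", "gallionella_kinetics.tsv", package = "oligoshift")
kinetics_table(read_kinetics(tsv), reference = "wild-type")[,
  c("enzyme", "state", "kcat_o", "s_co_fold", "k_o_fold", "kcat_c_decrease_pct")]
#> # A tibble: 3 x 6
#>   enzyme    state kcat_o s_co_fold k_o_fold kcat_c_decrease_pct
#>   <chr>     <chr>  <dbl>     <dbl>    <dbl>               <dbl>
#> 1 wild-type L6      0.38      1        1                      0
#> 2 R98A      L2      0.39      1.17     1.68                  29
#> 3 R131A     L2      0.49      1.13     2.15                  22
```

Here `kcat_o` is derived from the printed means of the other four
parameters; the fold changes say the dimer-forming point mutants trade a
20-30% slower carboxylation for a markedly weaker oxygen affinity (1.7-2.2x
higher K_O), i.e. a higher specificity factor.

Result objects have broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()` methods; a thin command-line wrapper with `simulate`,
`classify`, `design`, `kinetics` and `seq` subcommands lives at
`inst/cli/oligoshift.R`.

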