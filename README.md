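# dsmkit

Design and validation toolkit for double-site saturation-mutagenesis (DSM)
biosensor libraries built on chemically induced dimerization (CID)
scaffolds such as the plant abscisic-acid receptor PYR1. When a ligand
binds PYR1's pocket, the receptor gains a surface that recruits the PP2C
phosphatase HAB1; reprogramming the pocket by mutagenesis turns this
ligand-gated dimerization into a general biosensor platform. `dsmkit`
covers the computational side of that engineering cycle:

- **Library design** (`contact_positions()`, `build_allele_sets()`,
  `enumerate_singles()`, `enumerate_doubles()`, `partition_by_proximity()`,
  `library_report()`): propose pocket positions from a receptor–ligand
  structure by a heavy-atom distance cutoff, attach per-position allele
  sets (all amino acids except the wild type, Cys and Pro by default, with
  stability-based restriction and explicit overrides), and enumerate the
  exact single/double mutant space. With per-position set sizes
  *a₁ … a_k*, the design holds Σaᵢ singles and
  (Σaᵢ)² − Σaᵢ² ⁄ 2 doubles; doubles whose positions are separated by
  fewer than 8 residues are *proximal* and need a dedicated double-mutant
  oligo, the rest arise from two sequential single-oligo rounds of nicking
  mutagenesis.
- **Oligo pools** (`design_oligo()`, `design_oligos()`, `apply_oligo()`,
  `melting_temperature()`, `export_pools()`): one oligo per single and per
  proximal double — highest-usage replacement codon, homology arms grown
  until their nearest-neighbor melting temperature (unified NN
  thermodynamics) reaches the arm criterion, plus an in-silico application
  oracle that verifies each oligo reproduces exactly its intended protein
  variant.
- **Sequencing QC** (`align_read()`, `call_variants()`,
  `completeness_report()`): classify amplicon reads against the designed
  space (wildtype / designed single / designed double / undesigned /
  discarded) and measure library completeness — the fraction of designed
  variants observed at a read-count threshold.
- **Sensor characterization** (`fit_4pl()`, `estimate_lod()`,
  `selectivity_matrix()`): four-parameter logistic fits
  *y = bottom + (top − bottom)/(1 + (EC50/x)^h)* with asymptotic 95%
  confidence intervals on log₁₀EC50; immunoassay limits of detection by
  the blank + 3×SD rule on a low-linear-range calibration; and
  fold-selectivity matrices (EC50_off / EC50_on, censored entries
  propagated as bounds, "selective" = all folds ≥ 10).
- **Ligand-panel similarity** (`fingerprint_panel()`, `tanimoto()`,
  `similarity_matrix()`, `cluster_panel()`): atom-pair fingerprints,
  Tanimoto coefficients |A∩B|/|A∪B|, and average-linkage clustering on
  1 − T with deterministic leaf order, exportable as Newick.
- **Synthetic data** (`make_reference()`, `simulate_reads()`,
  `simulate_curve()`, `simulate_blanks()`): seeded generators for toy
  genes, error-bearing amplicon reads with truth tables, noisy
  dose-response curves and blank replicates, so the whole pipeline is
  testable end to end without any external data.

The package bundles a documented **synthetic reconstruction** of the
19-position PYR1 pocket design (`pyr1_design()`, `pyr1_reference_cds()`)
that reproduces the published library totals — 301 single mutants, 6,291
proximal double mutants, 37,797 single+double nonsynonymous variants —
from 15 unrestricted positions (17 alleles each), four restricted
positions (62/81/87/110) and a variant-level curation list. See the
methods vignette (`vignettes/dsm-pipeline.Rmd`) for exactly which parts
are published constraints and which are reconstruction choices.

## Worked example

```r
library(dsmkit)

design <- pyr1_design()
library_report(design)
#>   n_positions n_singles n_doubles n_proximal n_distal n_total
#> 1          19       301     37496       6291    31205   37797
```

301 singles and 37,496 doubles make 37,797 designed protein variants;
6,291 doubles are proximal (positions fewer than 8 residues apart) and get
their own oligo pool. Designing the single-mutant pool on the bundled
synthetic PYR1 CDS:

```r
oligos <- design_oligos(design, pyr1_reference_cds(), pools = "single")
nrow(oligos)
#> [1] 301
oligos[1, c("name", "sequence", "arm5_tm", "arm3_tm")]
#>   name  sequence                                        arm5_tm arm3_tm
#> 1 K59A  TTGATAAACCACAAACTTATGCTCATTTTATTAAATCTTGTTCTGT    60.6    61.7
```

Each oligo is 5′ arm + mutant codon + 3′ arm; both arms reach the 60 °C
arm criterion. `apply_oligo()` + `translate_cds()` verify the edit in
silico. Characterizing a sensor from a (here simulated) dose–response
series:

```r
d <- simulate_curve(ec50 = 36e-9, hill = 1, bottom = 0, top = 1,
                    noise_sd = 0.03, seed = 42)
fit_4pl(d)
#> <dr_fit> EC50 3.15e-08 [2.52e-08, 3.94e-08], hill 0.87,
#>          bottom -0.0178, top 0.997 (n = 24)
```

The true EC50 (36 nM) lies inside the fitted 95% interval. An
ELISA-style limit of detection from a calibration line (concentrations in
pM) and six blank wells:

```r
estimate_lod(cal, blanks, range = unique(cal$concentration))
#> <lod_result> LOD 433 (threshold 0.06777 = blank 0.04983 + 3 x SD 0.005981;
#>              slope 0.31)
```

i.e. the concentration whose predicted signal equals blank mean + 3×SD.
Selectivity from two measured EC50s (43 nM on-target diazinon, 1.1 µM
off-target azinphos):

```r
sel <- selectivity_matrix(
  data.frame(receptor = "DIAZI", ligand = c("diazinon", "azinphos"),
             ec50 = c(43e-9, 1.1e-6)),
  on_target = c(DIAZI = "diazinon"))
glance(sel)
#>   receptor min_fold selective
#> 1 DIAZI        25.6 TRUE
```

A 25.6-fold margin clears the ≥10-fold bar for a selective sensor.

## Command line

A thin wrapper binds the stages into reproducible runs driven by a YAML
config (`subcommand: design | oligos | simulate | qc | fit | lod |
selectivity | panel | contacts`); every run writes a JSON manifest of all
resolved parameters:

```sh
inst/exec/dsmkit config.yaml coverage=50 out_dir=results/qc
```
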