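---
title: "Designing and validating double-site mutagenesis biosensor libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating double-site mutagenesis biosensor libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmkit)
```

## The engineering problem

PYR1 is a plant abscisic-acid receptor that, upon binding its ligand,
forms a tight complex with the PP2C phosphatase HAB1. This chemically
induced dimerization (CID) can be rewired: mutating the ligand-binding
pocket changes which small molecule triggers the PYR1–HAB1 interaction,
so a single scaffold can be evolved into sensors for cannabinoids,
organophosphate pesticides and other ligands, read out through
two-hybrid growth, transcriptional circuits, split luciferase, or
ELISA-like immunoassays.

The computational work around such a campaign falls into five parts, one
module each: defining the mutant space (`R/design.R`, `R/pyr1.R`),
realizing it as mutagenic oligo pools (`R/oligo.R`, `R/codon.R`,
`R/tm.R`), verifying the built library by sequencing (`R/qc.R`),
quantifying evolved sensors (`R/doseresp.R`, `R/lod.R`,
`R/selectivity.R`), and relating the ligands screened (`R/ligpanel.R`).
A seeded generator suite (`R/simulate.R`) makes every stage testable
without external data.

## The mutant space model

A design is an ordered set of positions, each with a wild-type residue
and an allele set. The default allele set is the 20 standard amino acids
minus the wild type and minus a global exclusion set, `{C, P}` by
default: cysteines risk spurious disulfides and proline breaks
secondary structure, so neither is a useful pocket substitution. With
per-position set sizes $a_1, \dots, a_k$ the design contains
$\sum_i a_i$ singles and $\tfrac{1}{2}\big[(\sum_i a_i)^2 - \sum_i
a_i^2\big]$ doubles (all cross-position pairs). Both enumerations are
exact, deterministically ordered (position, then amino acid), and tested
against a brute-force `expand.grid` oracle on small designs.

Nicking mutagenesis (NM) installs mutations from single-stranded oligos
whose homology arms must anneal to unmodified template. Two mutations
closer together than an arm's footprint cannot be installed
sequentially, so doubles are partitioned by the rule

> proximal ⇔ |i − j| < window, with window = 8 residues,

and proximal doubles get a dedicated double-mutant oligo while distal
doubles arise from two sequential single-oligo rounds. The strict
inequality (positions *fewer than* 8 residues apart; separation of
exactly 8 is distal) matches the NM construction constraint and is the
reading under which the bundled reconstruction reproduces the published
pool sizes exactly; the window is a parameter throughout.

Candidate positions can be proposed from a receptor–ligand complex
structure: `contact_positions()` returns every protein residue with at
least one heavy atom within a cutoff (default 4.5 Å — a conventional
heavy-atom "close contact" radius) of any ligand heavy atom. Hydrogens
are ignored, alternate-location B records are dropped, and the result is
independent of atom order; an offset maps author numbering onto
reference numbering.

## The bundled PYR1 design is a reconstruction

The published PYR1 pocket library targets 19 positions: fifteen
(59, 83, 89, 92, 94, 108, 117, 120, 122, 141, 159, 160, 163, 164, 167)
mutate to all amino acids except Cys/Pro — 17 alleles each — and four
stability-sensitive positions (62, 81, 87, 110) are restricted to
smaller subsets. The original per-position design file is not
redistributed here, so `pyr1_design()` rebuilds a design from the
published summary constraints, and it is important to be explicit about
which parts are constrained and which are choices:

* **Restricted subset sizes.** 301 single mutants with 15 × 17 = 255
  unrestricted singles forces the four restricted sizes to sum to 46.
  Requiring the proximal-double count (window rule above) to equal the
  published 6,291 pins the sizes to (11, 14, 11, 10) at positions
  (62, 81, 87, 110) — the balanced integer solution found by exhaustive
  search. Under the inclusive window reading no size assignment
  reproduces 6,291 at all, which is why the strict rule is the default.
* **Restricted subset identities.** Not derivable from totals. The
  reconstruction takes the top-k substitutions by BLOSUM62 similarity to
  the wild type (ties broken alphabetically, Cys/Pro excluded) — a
  deterministic, conservative stand-in for the original
  stability-guided curation.
* **Variant-level curation.** No per-position design can reach the
  published total of 37,797 single+double nonsynonymous variants: with
  301 singles, full pairing gives ≈ 42.9k doubles whatever the size
  split (again exhaustive search), so roughly 5.4k specific double
  combinations must have been removed by manual curation. The
  reconstruction therefore carries an explicit excluded-doubles list —
  5,368 distal doubles, chosen deterministically (evenly spaced in the
  canonical enumeration) — so that `library_report()` computes 301 /
  6,291 / 37,797 from the design object rather than asserting them.
  The *identities* of the curated doubles are a synthetic placeholder.
* **Reference CDS.** `pyr1_reference_cds()` back-translates the
  191-residue receptor sequence with the bundled yeast codon-usage
  table, demoting codons where needed so no 15-mer repeats; it is a
  synthetic stand-in for the physical plasmid, encoding exactly the
  right protein with unambiguous ≥15 nt homology arms.

Counts computed from the reconstruction (totals, pool sizes, oligo
counts) therefore match the published library; per-variant identities at
restricted positions and in the curated set do not claim to.

The published library also quotes 42,743 "total mutants" alongside the
37,797 nonsynonymous ones; the relation (presumably DNA-level or
synonymous variants) is not stated, so the report exposes a separate
optional DNA-level count rather than guessing.

## Oligo design

Each designed single (and each proximal double) gets one oligo: 5′ arm +
replacement codon(s) (+ intervening reference sequence for proximal
pairs) + 3′ arm, on the sense strand. The replacement codon is the
highest-usage codon for the target amino acid in the host usage table
(S. cerevisiae bundled — the screening host), ties alphabetical; one
codon per substitution keeps one oligo per designed mutant.

Arms start at 15 nt and grow outward until their duplex melting
temperature reaches 60 °C, capped at 40 nt (90 nt total oligo). Tm is
unified nearest-neighbor thermodynamics with terminal initiation terms,
the entropic salt correction $0.368\,(N{-}1)\ln[\mathrm{Na}^+]$, and the
strand-concentration term $R\ln(C_T/4)$. The default evaluates arms at
the parameter set's 1 M NaCl standard state (salt correction zero):
evaluated at typical PCR salt instead, AT-rich arms on a yeast-codon CDS
cannot reach 60 °C within the length budget at all, so the standard
state is the coherent default for this arm criterion; all three
concentrations (salt, strand) remain parameters of `oligo_params()`.
On the bundled PYR1 CDS the longest arm needed is 24 nt and the longest
oligo 66 nt.

`apply_oligo()` is the verification oracle: both arms must match the
reference exactly once (guaranteed by the generators' unique-15-mer
constraint), the edited span replaces the reference span, and the
translated product must differ from the reference protein at exactly the
intended positions. The test suite runs this round trip exhaustively
over toy libraries and over the PYR1 single pool.

## Sequencing QC

Reads are treated as full-length amplicons over the designed region.
Classification is at the protein level: translate, diff against the
reference, and look the substitution set up in the designed space —
wild type (no amino-acid change; synonymous codon changes are ignored),
designed single/double, otherwise undesigned (including >2 changes).
Reads with any indel are discarded with reason `indel` (in an amplicon
library these are synthesis/sequencing artifacts, and the simulator's
substitution-only error model keeps this rule separately testable);
reads shorter than half the reference are discarded as `partial`.
Alignment is affine-gap global (match 2, mismatch −3, gap open 10,
extend 0.5); as an optimization the batch caller compares equal-length
reads positionally and reserves the aligner for length-discordant reads,
which are the only ones that can carry gaps.

Completeness is the fraction of designed variants with at least
`min_reads` supporting reads (default 1: the validation question is
presence/absence). It is monotone non-increasing in `min_reads`,
invariant to read order, and on error-free full-coverage simulations
equals 1 exactly; withholding a fraction of variants in the simulator
reproduces `1 − f` exactly when `f × n` is an integer.

## Dose–response, LOD, selectivity

`fit_4pl()` fits the variable-slope logistic
$y = b + (t - b)/(1 + (\mathrm{EC50}/x)^h)$ by Levenberg–Marquardt least
squares with EC50 parameterized as $\log_{10}$EC50 (positivity for
free), from a 3 × 3 multi-start grid (EC50 at the quartiles of the
tested log-range; slopes −1, 0.8, 2 so both orientations are reachable);
the best converged start by RSS wins. Replicates enter as individual
points. After fitting, orientation is normalized to bottom ≤ top by the
exact reparameterization (swap asymptotes, negate slope), which leaves
the curve unchanged. The 95% CI is asymptotic on log₁₀EC50 with a
t(n−4) quantile — commercial packages use related but not identical
interval machinery, so printed intervals from other software are
expected to agree only approximately. A warning flags dose-mean
non-monotonicity beyond 3 residual SDs. On 200 seeded synthetic
datasets (8 half-log concentrations, triplicates, 5% Gaussian noise —
the suite's standing recovery study) the median |log₁₀(EC50̂/EC50)| is
≈ 0.04 and interval coverage ≈ 0.93.

`estimate_lod()` implements the immunoassay rule: regress response on
log₁₀(concentration) over the low linear range, and report the
concentration whose predicted signal equals blank mean + 3 × blank SD.
The automatic range is the largest contiguous low-concentration window
of ≥3 points with window R² ≥ 0.98 and mean response under half the
observed maximum — a heuristic that can admit a shoulder point on
gently saturating data, which is why an explicit `range` always
overrides it. Non-positive (or numerically zero) slope is an error;
an LOD outside the regression range is flagged as extrapolated.

`selectivity_matrix()` is arithmetic on fitted EC50s: per receptor,
fold = EC50_off / EC50_on against the declared on-target ligand;
censored entries ("no response up to the top tested concentration")
propagate as `> bound/EC50_on`; a receptor is selective when every
off-target fold is ≥ 10. Folds are invariant under global response
rescaling because they depend only on EC50 ratios.

## Ligand panels

Fingerprints default to sparse atom-pair descriptor sets, with a folded
1024-bit variant as the alternative scheme; the scheme id travels with
every result because descriptor settings change similarity values.
Tanimoto is computed here (set arithmetic), and cross-checked in the
tests against an independent fingerprint engine on the same molecules.
Clustering is average-linkage agglomeration on 1 − T; ligand ids are
sorted before clustering so the tree is invariant to input order with
lexicographic tie-breaking. Trees export as Newick, matrices as TSV,
heatmaps via `autoplot()`.

## What the simulators do and do not emulate

`make_reference()` (random CDS, start codon, no internal stops, unique
15-mers), `simulate_reads()` (per-variant coverage, iid per-base
substitution errors, withheld fraction, truth table),
`simulate_curve()` and `simulate_blanks()` (4PL + Gaussian noise) are
fully deterministic at a fixed seed, with the seed echoed in output
headers. They emulate the *structure* of real data, not its
pathologies: no indel or context-dependent sequencing errors, no
coverage skew (a log-normal option exists for stress tests), no plate
effects or heteroscedastic assay noise. Green tests on these
simulations certify the pipeline's logic — enumeration, realization,
calling, fitting — not robustness to every artifact of a real
sequencing run or plate reader.

Standing problem sizes in the suite: toy libraries of 3–5 positions
(up to ~2,900 doubles) at 30× coverage, and 200-dataset recovery
studies for the 4PL machinery; the full 19-position design is exercised
for its counts and its 301-oligo single pool.

## Known limitations

* Restricted-subset and curated-double *identities* in `pyr1_design()`
  are reconstruction choices (see above); analyses that depend on which
  specific alleles are present at positions 62/81/87/110 should load
  the real design table via `design_from_allele_table()` instead.
* The QC module assumes merged, full-length amplicon reads: no
  paired-end merging, UMIs, or quality recalibration.
* Oligos are not screened for secondary structure or synthesis
  constraints beyond length; degenerate-codon designs are out of scope.
* ΔΔG values are consumed as an external table; no stability
  computation is performed.
* Tm is a duplex model used as an arm-sizing criterion, not a
  hybridization simulation of the nicking reaction.
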