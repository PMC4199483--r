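---
title: "Gene-based pleiotropy discovery with CCA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based pleiotropy discovery with CCA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocca)
```

## The model

`pleiocca` asks a multivariate question: is a block of SNP dosages `X`
(n samples × q SNPs, additive 0/1/2 coding) jointly associated with a set
of phenotypes `Y` (n × p)? Canonical correlation analysis supplies the
statistic: the canonical correlations r₁ ≥ … ≥ r_c, c = min(p, q), are the
singular values of the whitened cross-covariance of `X` and `Y`, and all of
them are tested at once through Wilks' Lambda, Λ = ∏(1 − rⱼ²), transformed
to Rao's approximately F-distributed statistic with df₁ = pq and
df₂ = wt − pq/2 + 1, where w = n − (p + q + 3)/2 and
t = √((p²q² − 4)/(p² + q² − 5)), taking t = 1 when p² + q² ≤ 5. For
p = q = 1 the procedure collapses exactly to the simple-regression F-test
— the test suite asserts this equivalence to 10⁻¹⁰ relative error — and
for min(p, q) ≤ 2 the F approximation is exact, which is why the
permutation cross-check at (p, q) = (2, 3) is so tight.

Assumptions worth keeping in mind: phenotypes are treated as multivariate
Gaussian after standardisation (heavy-tailed traits inflate type-I error);
samples are exchangeable (no relatedness or population-structure
correction is applied inside the test); and n must comfortably exceed
p + q (the code refuses n ≤ p + q + 1, and the GA assigns worst fitness to
subsets that violate it).

### Log-scale p-values

Cohort-scale associations can fall far below the smallest positive double
(2.22×10⁻³⁰⁸). All p-values are therefore computed and carried as log10
values via the log-space F and chi-square tail routines; ranking,
thresholding and Fisher combination all operate on that scale. The rule
tables additionally include a linear-scale column for human consumption,
clamped to 0 below the double floor — the clamp is a formatting decision,
never a computational one.

## Preprocessing

*Genotype QC* removes samples with call rate < 90%, then SNPs with exact
conditional Hardy–Weinberg p < 10⁻⁷ or minor allele frequency < 1%. The
HWE test enumerates the conditional distribution of heterozygote counts
given the allele count (two-sided, summing all outcomes no more probable
than the observed one); a 1-df chi-square variant is available through
`qc_config(hwe_test = "chisq")`.

*Phenotype imputation* is k-nearest-neighbour with k = 5: a missing cell
(i, j) becomes the mean of phenotype j over the k samples closest to i,
with distances computed on provisionally standardised columns (so no
trait dominates by scale), over the phenotypes observed in both samples,
excluding column j itself. We use the root-mean-square form of the
Euclidean distance so candidates with different overlap sizes are
comparable. Imputation precedes the mean-0/SD-1 normalisation that CCA
requires.

*SNP-to-gene assignment* maps every SNP to the gene minimising the gap (in
bases) to the gene interval on the same chromosome; a SNP inside an
interval has distance 0. BED intervals are 0-based half-open and VCF
positions 1-based; the conversion lives in one place
(`assign_snps_to_genes()`). Equidistant ties resolve to the smaller start
coordinate, then the lexicographically smaller name, which makes the
assignment invariant to gene-file ordering. Both intronic and exonic SNPs
are assigned and no distance cap is applied by default (`max_distance` is
exposed for users who want one).

*LD pruning* is two-stage and per block. First a greedy scan in genomic
order drops any SNP whose squared dosage correlation with an
already-retained SNP strictly exceeds 0.64 (the earlier SNP wins — keeping
the scan order fixed makes pruning deterministic and idempotent). Then
variance inflation factors VIFⱼ = 1/(1 − R²ⱼ), with R²ⱼ from regressing
SNP j on the other retained SNPs, are computed iteratively and the
arg-max SNP dropped (ties to the later position) while any VIF exceeds 2.
The VIF bound guarantees full column rank, so the CCA whitening step is
well-posed for every block the pipeline produces. r² is computed on
dosages (composite LD), matching the additive coding used throughout;
missing dosages are mean-imputed per SNP before any correlation is taken,
and that imputation is flagged in the QC report rather than hidden.

## Subset search

Which phenotypes belong with a gene (and which genes with a phenotype) is
a combinatorial question; hill-climbing is easily trapped by one strong
marginal association, so the search uses a binary genetic algorithm.
Chromosomes are bit vectors over the candidate universe; fitness is
−log10 of the Rao p-value of the induced rule. Selection is rank-weighted
roulette, crossover single-point, elitism keeps the top E individuals
(making the best fitness non-decreasing — asserted per run), and mutation
redraws each bit with probability 1/L (L the universe size), setting it to
1 with probability 1/(1 + zero-to-one ratio). The same ratio biases the
initial population; with a ratio of 50, initial chromosomes select ~2% of
items, which keeps candidate rules small and n ≫ p + q. Chromosomes with
no set bits or more than `k_max` bits are penalised with worst fitness
rather than repaired — repair operators would couple bits and complicate
the determinism contract. All fitness evaluations are memoised by subset.

The cohort-scale presets are: population 100, elitism 20, ratio 50 for the
per-gene phenotype search; population 600, elitism 35, ratio 700 for the
per-phenotype gene search; population 1000, elitism 100 for the joint
mode. The generation count is capped at 100 with early stopping after 20
stagnant generations — a run-length control we chose and exposed in
`ga_config()`, since convergence at these population sizes is typically
much faster on planted-signal data.

For joint gene-set/phenotype-set rules, two populations coevolve
cooperatively: each individual is evaluated against the best individual of
the other population from the previous generation (generation 0 pairs
with a random *admissible* individual — one whose subset is non-empty and
within `k_max`; pairing against an inadmissible partner would blank out
the fitness signal for the whole generation). Random pairing is available
behind `pairing = "random"`. All rules evaluated anywhere during the run
are collected, deduplicated and ranked, so the output is a rule list
rather than a single winner. When several genes are selected, their pruned
blocks are concatenated and VIF-pruned again jointly before the CCA — the
pooling scheme is recorded in the run manifest.

## Multiple-testing correction

A GA evaluates only a sliver of the rule space, but it *could* have
proposed any subset within its size bounds, so the family-wise correction
divides α by the full count of candidate rules on each side:
Σₖ C(n, k) over the allowed subset sizes k, for genes and phenotypes
separately, multiplied together. The counts are computed exactly with a
small base-10⁷ big-integer arithmetic (multiply/divide by machine
integers along the C(n, k+1) = C(n, k)(n−k)/(k+1) recurrence) and
cross-checked against a log-sum-exp of log-gamma terms; the two routes
must agree to 10⁻⁹ in log10 or the function aborts. At the scale of 3648
genes and 82 phenotypes the spaces reach 10⁷² rules and thresholds near
10⁻⁷⁵ — far beyond linear-scale floats, which is the second reason
everything stays in log10. Subset-size bounds default to the largest rule
sizes the search modes permit (24 phenotypes or 29 genes in the
single-sided modes, 22 genes × 9 phenotypes in the joint mode), with
"multiple" spaces starting at size 2 — a rule must combine at least two
items — and the gene-side single-phenotype space starting at 1.

Fisher's combined probability, −2Σln pᵢ against χ²(2k), is reported beside
each CCA p-value as the natural "no pleiotropy, just accumulation"
comparator. Plain Fisher is the default; a Brown-style adjustment that
rescales the χ² mean/variance from the phenotype correlation matrix
(Kost–McDermott covariance polynomial) is available through the
`correlation` argument for positively correlated traits, and is
deliberately kept out of the headline outputs because the plain version is
the transparent baseline.

## The synthetic generator

No suitable cohort (genotypes + dozens of phenotypes) is publicly
deposited, so the generator emulates the relevant *structure*: gene-sized
SNP blocks with tunable within-gene LD, a phenotype panel with a specified
correlation matrix, planted gene→phenotype-set effects in SD-per-allele
units, and missing-completely-at-random entries (default 1.4% of phenotype
cells, matching the per-phenotype missingness scale of cohort phenotype
panels; genotype missingness defaults to 0 and is configurable).

LD is modelled with a single equicorrelated latent Gaussian per gene:
each haplotype's allele indicators arise by thresholding correlated
normals at the MAF quantile. Thresholding attenuates correlation, so the
latent correlation ρ is calibrated by solving (1-D Gaussian quadrature +
`uniroot`) for the value at which the mean pairwise squared
allele-indicator correlation over the gene's sampled MAFs equals the
requested `target_ld`. Two caveats follow from the model, not the code:
with heterogeneous MAFs the attainable pairwise r² is bounded above (the
classic allele-frequency constraint on r²), so high `target_ld` combined
with a wide `maf_range` saturates below the target; and one ρ per gene
cannot produce block-diagonal or distance-decaying LD. Both are
acceptable here because the purpose of the LD knob is to exercise the
r²/VIF pruning path, not to mimic recombination; the generator makes no
attempt at recombination maps, population structure, or array
ascertainment.

What passing tests on this generator do show: the test statistics hold
their nominal null behaviour, the pruning bounds are enforced, and the
search recovers effects planted under the generator's assumptions. What
they cannot show: robustness to non-Gaussian phenotypes, informative
missingness, relatedness, or realistic haplotype structure.

## Numerical choices

- Canonical correlations come from QR decompositions of the centred
  matrices followed by an SVD of Q₁ᵀQ₂ — never from explicit covariance
  inversion; correlations are clipped to [0, 1 − 10⁻¹²] before Λ so a
  numerically perfect correlation cannot zero the product.
- VIFs are read off the inverse correlation matrix, falling back to
  per-column least squares (rank-revealing, reporting ∞ for exact
  collinearity) when the matrix is numerically singular.
- The exact HWE enumeration works in log-factorials and normalises within
  the conditional distribution; the "≤ observed probability" comparison
  uses a 1 + 10⁻⁹ relative tolerance so ties are counted.
- Determinism: generation and search run under an isolated RNG scope
  (`withr::with_seed`) keyed by the caller's seed; per-gene and
  per-phenotype GA runs derive their seeds from the pipeline seed by
  offset, so end-to-end outputs are byte-identical across runs.
- Degenerate inputs fail loudly and early: constant phenotype columns,
  all-missing columns, rank-deficient blocks, subsets too large for n —
  each names the offending column or quantity.

## Test and verification scale

The suite verifies behaviour at sizes chosen to give tight statistical
bands while keeping a full run in tens of seconds: generator calibration
at n = 5000, planted-slope recovery at n = 2000, type-I error over 2000
null simulations at (n, p, q) = (200, 3, 5), permutation agreement over
100 datasets × 2000 permutations at (60, 2, 3), and search recovery on a
500-sample, 6-gene × 8-phenotype dataset with a planted (1-gene,
2-phenotype) rule at 0.4 SD/allele — conditions under which the planted
rule is the exhaustive-scan optimum, so heuristic and oracle can be
compared exactly. The GA configurations in those tests are scaled to the
small universes (population 40–60, ≤ 60 generations) rather than the
cohort presets, whose chromosome lengths assume thousands of genes.

## Known limitations

- Power drops for very long genes (many SNPs surviving pruning) because
  df₁ = pq grows while the planted signal stays put; this is a property of
  the omnibus Wilks test, not of the implementation.
- Only the overall test is performed; per-component (sequential) canonical
  significance is out of scope, as are kernel, sparse and Bayesian CCA
  variants.
- The search-space Bonferroni is deliberately conservative: it counts
  every rule the optimiser could propose, so genuine but modest
  multivariate signals will often rank highly yet fall short of the
  threshold. Ranking, not the flag, is the primary output.
- FDR and permutation-based family-wise corrections are not provided.
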