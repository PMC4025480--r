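---
title: "Methods: linkage maps, recombination rates and QTL from low-coverage RIL genotyping"
author: "rilmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage maps, recombination rates and QTL from low-coverage RIL genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rilmap)
```

# The study design

`rilmap` analyses selfed recombinant inbred line (RIL) panels genotyped by
restriction-fragment sequencing at low per-site coverage. The reference
design is an F8 panel: two inbred parents (labelled IM and PR throughout)
are crossed, a single F1 is self-fertilised, and each line is propagated by
single-seed descent for six further generations. After 7 selfing rounds the
expected residual heterozygosity per line is $(1/2)^7 \approx 0.8\%$, and
the discordance $R$ between two loci with meiotic recombination fraction
$r$ converges to the Haldane–Waddington limit

$$ R = \frac{2r}{1 + 2r}, $$

the map-expansion relation every downstream distance estimate inverts.

# The simulator and what it does (not) emulate

`simulate_pedigree()` draws, for every meiosis, a Poisson number of
crossovers with mean equal to the chromosome's genetic length in Morgans
and places them uniformly along the physical axis, so genetic distance is
proportional to physical distance within a chromosome and there is **no
crossover interference** — the assumption under which the Haldane map
function used downstream is exact. Inside a declared inversion interval, a
meiosis in an individual heterozygous across the whole interval yields no
crossovers (suppression is absolute by default; `inversion_leak` relaxes
it). An inductive consequence worth knowing: haplotypes never acquire
junctions inside an inversion, so every RIL is genotypically constant
across it.

`simulate_reads()` places SNPs uniformly at a chosen density and draws
per-RIL depth as independent Poisson counts per SNP; each read samples one
haplotype uniformly and flips with the per-base error probability. The real
depth distribution of restriction-fragment libraries is overdispersed and
clustered on fragments; Poisson per-line depth is our modelling choice (the
published data constrain only the median total depth per SNP, ~338 across
~480 lines, which the defaults match: 500 lines × 0.7 reads). The
simulator does not model FASTQ-level artefacts, alignment error, indels or
repeat mismapping.

`simulate_phenotypes()` emits replicate values
$y = \mu + \sum_k a_k x_k + u_{\text{RIL}} + g_{\text{grow-up}} +
m_{\text{method}} + e$, with QTL coded $x \in \{+1, -1, 0\}$ for
IM/IM, PR/PR, IM/PR, effects $a_k$ in within-RIL SD units, RIL deviates
correlated across traits through a shared polygenic factor, and, when
`skew_transform = TRUE`, the raw value $\exp(y) - 1$ — right-skewed, always
$> -1$, and exactly linearised by the $\log(x+1)$ transform the analysis
applies. Defaults ($V_{\text{ril}} = V_{\text{error}} = 1$, 3 grow-ups,
3 replicates, effects ~0.5 SD) reproduce the low-power regime typical of
secondary-metabolite QTL studies.

# Window genotyping

Per-SNP genotypes from allele depths use fixed frequency thresholds (IM/IM
above 0.9, PR/PR below 0.1, IM/PR otherwise; no call without reads). The
five-criterion SNP filter follows the printed bounds, reading "between" as
inclusive; criterion 4's alternative-base frequency is read-weighted across
all RILs by default with a RIL-weighted switch. The neighbor-consistency
filter compares each SNP's calls against all other SNPs within 50 kb in the
same line, skipping missing and heterozygous cells, and excludes SNPs
disagreeing more than half the time — all SNPs are judged against the
original call set, so the filter is order-independent.

The window caller aggregates calls in contiguous 50-kb tiles from scaffold
coordinate 0 (the final partial tile is kept). A heterozygous SNP call
contributes half an IM allele to the window frequency $p$; the marker-level
thresholds are strict inequalities exactly as printed, so $p = 0.9$ falls
in the missing band. The mapping subset keeps the 100 most completely
genotyped lines (ties by id) and markers called in at least 75% of them.

**Known limitation — junction censoring.** When a line's covered SNPs are
spread across a window, a crossover inside the window produces an
intermediate $p$ and the window is called missing (or heterozygous). With
adjacent-pair distance estimation (below) that junction is then not counted
anywhere, so maps built from *saturating* coverage shrink markedly; with
sparse coverage (roughly one informative site per window) window calls
behave like point genotypes and lengths are recovered. A multipoint hidden
Markov treatment would recover censored junctions across missing cells, but
multipoint likelihood mapping is out of scope here. Map-recovery tests
therefore use error-free midpoint genotype matrices
(`true_genotype_matrix()`), which isolate the mapping stage from this
caller property.

# Map construction

Pairwise linkage uses only homozygous cells — at under 1% residual
heterozygosity the information lost is negligible and $\hat R = k/n$ stays
binomial. The LOD against free recombination has the closed form
$k \log_{10}\hat R + (n-k)\log_{10}(1-\hat R) + n \log_{10} 2$ (equal to
$n\log_{10}2$ at $k = 0$, zero at $\hat R = 0.5$). Grouping is
single-linkage at $\hat R \le 0.15$; groups are numbered by size. Scaffolds
whose markers land in different groups are broken into maximal same-group
runs of consecutive windows.

Ordering minimises the sum of adjacent recombination fractions (SARF).
Markers within a scaffold fragment are frozen in physical order and treated
as rigid, flippable blocks; block order and orientations come from greedy
nearest-neighbour construction from 20 random starts, each refined by
2-opt reversal moves to a local optimum, with undefined pairs costed at
0.5. On instances with up to ~7 free blocks the optimiser provably matches
exhaustive search (tested); the metaheuristic the original analysis used
(ant-colony optimisation) is replaced because the objective, not the
search algorithm, is the substance. Two caveats are inherent to
SARF-minimisation with noisy $\hat R$: junctions are chosen partly because
their estimates are low, deflating inter-block distances slightly, and the
order inside a fully suppressed inversion is arbitrary (all internal
$\hat R = 0$).

Distances: adjacent $\hat R$ is mapped to meiotic $r = \hat R / (2(1 -
\hat R))$ (capped at 0.49) and then to $d = -50\ln(1-2r)$ cM, accumulated
from zero.

**Known bias — finite selfing generations.** The $R = 2r/(1+2r)$ inverse
assumes infinite selfing. An exact two-locus recursion for selfed lineages
shows F8 discordance is ~5% below the limit at 0.5-2.5 cM spacings (ratio
0.947-0.955), so F8 map lengths estimated with the infinite-selfing
correction are systematically ~5% short. We keep the standard correction —
it is what `riself`-type analyses use — and document the size of the bias
instead. A second, statistical limit matters for recovery experiments: a
100-cM chromosome in 100 lines contains only ~200 observable junctions, so
*any* junction-based length estimate carries a ~7% sampling SD; per-chromosome
length recovery inside ±10% is therefore not reliably attainable at that
panel size, while 300+ lines bring the SD down to ~4%.

# Recombination rates and the block bootstrap

Per-scaffold rates divide the map span between a scaffold's outermost
markers by the physical span between its outermost window edges (unbroken
scaffolds with ≥ 2 markers only). Because genetic span runs
marker-to-marker while physical span runs edge-to-edge, a scaffold with $w$
windows loses about $1/w$ of its genetic span at the margins; rate studies
that need unbiased scaffold rates should place point markers at scaffold
ends (`point_genotype_matrix()`), which makes the two spans commensurate.
Global summaries: mapped rate = mapped cM / mapped Mb (a ratio of sums,
hence length-weighted and aggregation-consistent with the per-scaffold
table), unmapped rate = leftover cM / leftover Mb, genome-wide rate = total
cM / genome Mb.

Chromosome and global confidence intervals use a circular block bootstrap
over scaffolds in genome order: block lengths are geometric with mean 3 on
support $\{1, 2, \dots\}$ (the zero-support variant would allow empty
blocks), blocks wrap so every scaffold has equal inclusion probability, and
each replicate is truncated to the original scaffold count; the interval is
the central 95% percentile range of replicate ratio-of-sums rates
(one-sided options exposed). Blocked resampling accommodates spatial
correlation of rates among neighbouring scaffolds. Percentile intervals on
a few dozen noisy scaffold rates undercover mildly (coverage ~91-93% in our
calibration at ~120 scaffolds per genome) — a property of the interval
type, worth remembering when reading the bounds.

# Inversion detection

Suppressed blocks are formalised as maximal runs of consecutive map markers
with genetic span ≤ `eps_cM` (default 1.0), at least `min_markers` (20)
markers, and summed scaffold extents of at least `min_bp` (2 Mb) — gates
calibrated to the smallest block a dense RIL map is expected to resolve
(tens of markers over ~3 Mb). Physical spans sum per-scaffold marker
extents because inter-scaffold gaps are unknown ("at least" semantics).
The map-gap signature (the cM jump flanking a block) is reported alongside.
With noisy single-SNP markers the 1-cM gate is brittle — a single miscalled
cell inside a block adds ~1 cM at $n = 100$ — so sparse-coverage analyses
may need `eps_cM` of a few median marker spacings. There is no numeric
criterion in the original analysis (blocks were read off heatmaps); the
gates are this package's convention.

# QTL mapping

Traits are analysed as $\log(x+1)$ of raw concentrations. The nested ANOVA
fits grow-up and quantification method as fixed factors and RIL (nested in
grow-up) as random; variance components come from expected mean squares
with the unbalanced-design coefficient
$k = (N - \sum_g \sum_i n_{gi}^2 / n_g)/\mathrm{df}_{\mathrm{RIL}}$,
truncating negative among-RIL estimates at zero. On balanced designs this
method-of-moments estimator coincides with REML (tested against `lme4`).
RIL means are residuals from the fixed-effect fit averaged per line; the
within-RIL SD, $\sqrt{V_\mathrm{error}}$, is the effect-size unit.

Missing (and residual heterozygous) genotypes are imputed 32 times from the
two-state Markov chain along each linkage group whose step probabilities
are the selfed-RIL discordances implied by map distances; sampling
conditions on the nearest flanking observed markers using the composite
flip probability $Q(t,u) = \tfrac12(1 - \prod_s (1-2q_s))$. With no missing
data every imputation equals the input, and the combined LOD is *exactly*
the single-regression LOD (asserted to 1e-10). Each scan regresses RIL
means on the genotype code (IM = +1, PR = -1), giving the
regression (Haley–Knott) form $\mathrm{LOD} = (n/2)\log_{10}
(\mathrm{RSS}_0/\mathrm{RSS}_1)$; with complete imputed genotypes this
equals the normal-model interval-mapping LOD at marker positions. The
imputation grid is the observed markers only — at ~0.5-cM spacing a
pseudomarker grid adds nothing. Imputations are combined as
$\log_{10}\overline{10^{\mathrm{LOD}}}$ with a numerically stable
log-sum-exp. Genome-wide thresholds permute RIL mean phenotypes against
intact genotype rows (1000 permutations; 5% and 10% quantiles of the
per-permutation maxima); QTL p-values are the fraction of permutation
maxima at or above the observed peak. Conditional scans (`add_qtl()`)
include model-QTL genotypes as covariates in both null and alternative
regressions. Support intervals take the outermost positions within a
1.8-LOD drop of the peak. Effects are reported as the full IM/IM − PR/PR
class difference in within-RIL SD units (twice the additive effect $a$),
labelled as such; percent variance uses sums of squares from the linear
model with the QTL as predictor.

# Numerical conventions and degenerate inputs

Coordinates are 0-based half-open everywhere internally, 1-based only in
VCF. Genotypes are integer-coded (0 missing, 1 IM, 2 PR, 3 HET). Strict vs
inclusive thresholds follow the printed wording (depth and frequency bounds
inclusive, call thresholds strict). Ties: mapping-set RIL selection breaks
ties by id; co-locating markers keep input order; group numbering is by
size then first marker. Perfect-fit LODs are capped via a relative floor on
RSS (`.Machine$double.eps`); undefined pairwise estimates (fewer than 2
informative lines) are flagged, cost 0.5 during ordering, and are excluded
from grouping. Empty filters, all-missing markers, single-scaffold
chromosomes and flat LOD profiles return flagged results rather than
errors; `transform_trait()` accepts any value where $\log(x+1)$ is defined
so skew-simulated panels round-trip. Every stochastic routine requires an
explicit integer seed and identical seeds give byte-identical output.

# Problem sizes used in the test-suite experiments

The packaged experiments run at sizes chosen to keep the suite fast while
leaving the statistical claims testable: map recovery uses 14 chromosomes ×
100 cM with ~1-cM marker spacing and 100 lines; the selfing-correction
check uses 5000 lines and 12 selfing generations (numerically the
infinite-selfing limit); bootstrap coverage uses 200 replicate genomes of
~120 scaffolds (0.375 Mb each, point markers every ~125 kb, 1000 bootstrap
replicates); inversion recovery uses 100 genomes with three 2.9-4.1 Mb
inversions at ~20 markers/Mb; null QTL calibration uses 200 scans of 169
phenotyped lines with 1000 permutations each over ~90 markers with 10%
missing cells and 8 imputations. What passing these tests shows — and does
not show — about real data follows from the simulator's scope above: no
interference, no clustered coverage, no alignment artefacts, and phenotypes
that really are Gaussian on the transformed scale.
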