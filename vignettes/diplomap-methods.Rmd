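---
title: "Population-pileup diplotyping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-pileup diplotyping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In a three-generation cross between two diverged taxa (here called Bv and
Bb after the *Bombina variegata* x *B. bombina* design the package is built
around), every F2 individual carries zero, one or two Bv haplotypes at each
captured locus. Targeted-enrichment data summarised as per-position read
counts (the PoPoolation2 "sync" dialect) are an awkward substrate for
genotype calling: coverage is strongly peaked at the bait region and decays
toward the locus ends, and mis-mapped reads from elsewhere in a repetitive
genome ("overmerging") pile onto the reference and create consistently
heterozygous-looking sites in every sample. Calling genotypes position by
position and reconciling them afterwards discards information and forces
arbitrary filters. `diplomap` instead treats the whole locus as one
non-recombining marker and infers a single three-state diplotype per sample
-- BbHOM, HET or BvHOM -- directly from the raw count matrix, with
ln-likelihood support.

## The polarization heuristic

Counts are organised as 6 x n matrices (states A, C, G, T, N, DEL over the n
reference positions). For the two F0 grandparents the counts are converted
to per-column frequencies; the difference (Bv minus Bb) is a signed matrix
whose positive entries mark states associated with the Bv grandparent. Each
column i is weighted by `1 - Sig(i)`, where `Sig(i)` is the p-value of the
multinomial likelihood-ratio G-test that the two grandparental count columns
come from a common distribution (df = observed pooled states minus one; the
chi-square approximation is used, with weight 0 whenever the test is
undefined). The result is the weighted polarized matrix `M_p`.

Each sample's count matrix is multiplied elementwise by `M_p`; the summed
positive and (absolute) negative entries, divided by the number of
informative columns (weight > 0), give a Bv score and a Bb score. The
normalisation by informative-column count is a deliberate choice -- the
source description of "means of the positive and negative entries" does not
fix a denominator -- because it makes scores proportional to coverage
(low-coverage samples sit near the origin and are visually and
algorithmically down-weighted) while staying comparable across loci of
different lengths.

Under the null (no divergence) the LRT p-value is uniform, so individual
column weights do not vanish; robustness comes from the polarized entries
themselves being near zero at undiverged columns, not from the weights
alone.

## Clustering

Samples fall into arcs of constant diplotype in the (Bv, Bb) score plane, so
the clustering is one-dimensional on the angle (0 degrees = pure Bv axis),
weighted by radius. Angles are binned at 0.05 degrees (weight-preserving,
keeps the optimisation exact up to bin width and deterministic), and an
exact dynamic-programming weighted 1-D k-means is solved for k = 1..6. k is
chosen by a BIC score, `n log(WSS/n + 1) + 2 k log(n)`, whose one-degree
variance floor stops the criterion from rewarding the subdivision of
already-tight clusters. More than three clusters are allowed and expected
when additional haplotypes segregate. Samples with radius below 5% of the
locus maximum are excluded from cluster statistics but still receive
likelihood calls. A locus where every radius is zero is flagged
`no_variants`.

After the first pass, `M_p` is re-estimated once from the pooled raw counts
of the two clusters nearest the axes (the purest individuals of each taxon,
at far higher combined coverage than two F0 samples), and scoring plus
clustering is repeated once. Ties in angle are broken toward the larger
pooled depth.

## The Mendelian likelihood

Each cluster's pooled counts are reduced to a strict majority consensus: a
state is called only when its count strictly exceeds half the column depth;
ties and N-majorities become NOCALL (N depth influences column totals but N
is never an ancestry state). The deduplicated consensuses are the candidate
haplotypes.

For a candidate pair (hap_bv, hap_bb) and a sample, columns where either
haplotype is NOCALL are masked. Per unmasked column the expected read
distribution is a mixture over the carried haplotypes with a symmetric error
model: a read matches its source state with probability `1 - epsilon` and is
any one of the other five states with probability `epsilon/5`. Homozygotes
are point masses; HET mixes the two haplotypes with an admixture coefficient
`alpha` that models enrichment bias (baits derived from one taxon capture
that taxon's fragments slightly better). The HET log-likelihood is maximised
over `alpha` -- a concave 1-D problem solved with `stats::optimize()`
(Brent's method, golden-section plus parabolic interpolation, tolerance
1e-8) on an aggregated form of the objective that depends on the counts only
through "matches hap_bv" / "matches hap_bb" / "other" totals.

**Admixture bounds.** The default bounds are `[0.1, 0.9]`, and this is a
load-bearing choice. If `alpha` may approach 0 or 1, the HET model converges
on the homozygote model (the per-read Kullback-Leibler distance between
HET at `alpha = 1 - 1e-3` and BvHOM is about 3e-4 at `epsilon = 0.005`), so
a handful of sequencing-error reads landing on the opposite taxon state
flips true homozygotes to HET and homozygote supports collapse to fractions
of a ln-unit. Bounded at 0.9, a homozygote's matching reads each contribute
about 0.105 ln-units of separation, supports are two orders of magnitude
above the 10 ln-unit convention, and calls are stable. The bounds comfortably
contain realistic enrichment bias (the package's simulator uses 0.55, and
observed conspecific:heterospecific mapping ratios in capture data are near
1.1); both bounds are user-configurable for systems with more extreme bias.

The ML taxon pair maximises the summed best-state log-likelihood over all
samples; orientation follows cluster geometry (the member from the cluster
nearer the Bv axis is labelled Bv; exact angle ties are evaluated in both
orientations). Pair support is the gap to the second-best pair. After pair
selection the haplotypes are refined once: all samples called BvHOM are
pooled and their strict majority consensus replaces hap_bv (same for Bb),
followed by one re-calling pass. The refinement is a single pass by design;
iterating it invites oscillation on loci with genuine extra haplotypes, and
one pass already moves the estimate from a ~40x cluster pool to the full
homozygote pool.

F0/F1 calls are compared with the expected pattern (grandsire BvHOM,
granddam BbHOM, all F1 HET). Violations flag the locus -- they do not drop
it -- which reproduces the manual-rescoring queue of the original workflow;
`rescore_with_whitelist()` then applies the identical likelihood machinery
restricted to hand-annotated variant columns.

MISSING is returned when every column is masked or the sample has no reads
on unmasked columns. In the Lep-MAP3 posterior output MISSING becomes a
uniform all-ones vector (the tool's no-information convention); the source
material does not state how missing calls were encoded, so this choice is
flagged here.

## Downstream statistics

**Segregation distortion.** Per locus and family, non-missing F2 calls are
tested against 1:2:1 (`chi2 = sum (obs - exp)^2 / exp`, df 2; missing calls
are excluded rather than imputed). Two thresholds are reported: a lower
Bonferroni threshold dividing alpha = 0.05 by 24 chromosome arms (for df 2
the critical value has the closed form `-2 ln(alpha/24)` = 12.35), and an
upper Benjamini-Hochberg step-up applied jointly across all locus x family
p-values.

**Bin reduction.** Within each bin (loci sharing a cM position), pairwise
diplotype differences are counted over F2 individuals, skipping pairs with a
MISSING member. While the maximum exceeds 3, the locus with the largest
summed differences is removed (greedy; the observed cases need a single
removal, the loop generalises), then one survivor is drawn uniformly under
the user's seed.

**Sex-determining region.** The sex-homozygote bias
`b = (N[male BbHOM] + N[female BvHOM]) / N[HOM]` is 0.5 at autosomal loci
and 0 at the SD locus, because the heterogametic F1 parent's sex chromosomes
are taxon-labelled by the cross direction. The attached test is the exact
one-sided lower-tail binomial probability (the SD signal is exclusively a
deficit); samples with uncertain or unknown sex are excluded throughout. The
scan reports the global minimum and the contiguous interval (default
b < 0.05) around it.

**Heterogamety.** Clusters are ranked by male proportion and
`pMaleInMaleClusters` is the mean over the minimal prefix holding more than
half of all males (female analog symmetric). Outliers (> 0.9 by default,
against an autosomal mode of 0.5) near the b minimum mark candidate
sex-linked-haplotype loci. One subtlety the package handles explicitly:
in clean data, ordinary diplotype clusters near the SD region are themselves
sex-pure, so outliers can appear in either statistic under either system;
the outlier pattern alone cannot separate XY from ZW. The deciding evidence
-- the same evidence the original study used -- is which F0 grandparent is
heterozygous for the diverged sex-limited haplotype. The package measures
this as each F0's angular deviation off its own axis at the candidate loci
(grandsire off 0 degrees implies the haplotype rides his Y: XY; granddam
off 90 degrees: ZW; minimum deviation 5 degrees, and one side must exceed
twice the other). When F0 angles are not available the strictly one-sided
outlier rule is applied, and otherwise the verdict is `inconclusive` --
which is also the honest answer for a cross without any diverged sex-linked
haplotype in range.

## The simulator

`sim_config()` encodes the study conditions as defaults: mean locus length
673 bp; between-taxon divergence d_xy lognormal with mean 0.0202 and mode
0.013 (meanlog -4.0487, sdlog 0.5419 solve those two constraints); two F2
families of 80 and 82; mean peak coverage 147x with a trapezoid profile flat
over the central 250 bp (the 2x-tiled bait span) decaying linearly to 10% at
the termini; sequencing error 0.005; capture bias 0.55 toward Bv reads in
heterozygotes; 20% of loci overmerged. Gametes recombine between adjacent
loci of a linkage group at the inverse-Kosambi fraction of their cM gap
(`r = 0.5 tanh(2d)`), matching the mapping function of the study's map; no
additional crossover interference is modelled. With an SD locus configured,
sex follows transmission of the heterogametic F1 parent's sex chromosome,
which enforces the defining constraint (no male BbHOM, no female BvHOM at
the SD locus) without any rejection step. An optional diverged sex-linked
haplotype (default divergence 0.04, "strongly diverged") rides the
heterogametic F0's sex chromosome at a configurable offset from the SD
locus, with recombination between the two loci in both F0 and F1 meioses.

Overmerging is modelled as a terminal pileup: contaminant reads carrying a
locus-unrelated paralog haplotype accumulate over a contiguous block (10% of
positions by default) at one randomly chosen end of the locus, at half peak
coverage, in every sample. This is the structure targeted-capture data
actually show -- off-target reads accumulate at reference ends, where true
coverage is lowest -- and it is what produces "consistently heterozygous"
sites. Because the contamination is shared, the grandparental LRT finds no
taxon signal at purely contaminated columns (weight near 0 for scoring), and
the pooled-cluster consensuses either agree on the contaminant state or
NOCALL it, so the likelihood masks it. Uniform mid-locus contamination
colliding with a diagnostic state is a different and harsher process that no
per-sample likelihood on raw counts could disambiguate from genuine
heterozygosity; it is deliberately not the default model.

What the simulator does not emulate: indel/structural variation (whole-locus
deletions and duplications were handled by the manual rescoring path in the
original workflow), within-taxon standing variation beyond the single
optional sex-linked haplotype, per-sample library-size variation, duplicate
reads, and mapping reference errors. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated noise processes,
not performance on arbitrary real libraries.

## Numerical and scale choices

Test and acceptance runs use deliberately desk-scale problem sizes: the
study-like recovery check runs 12 loci x 167 samples at 147x (about 2,000 F2
calls), truth-level statistics (b, segregation ratios, cluster-sex baselines)
use 10,000 F2 where a tight standard error matters, and the brute-force
oracle comparison uses 50 loci of 8 samples x 30 columns so that an
exhaustive pairs x states x admixture-grid search stays exact and fast.
Likelihood ties in `which.max` resolve to the first state in (BbHOM, HET,
BvHOM) order; bin-reduction ties on summed differences resolve to the
lexicographically first locus; all random draws (bin survivor picks,
simulations) flow from explicit integer seeds through a local RNG that
restores global state.

## Known limitations

The three-state model collapses within-taxon variation onto the best
taxon-haplotype pair; loci where that variation dominates are exactly the
flagged queue. The b-profile scan assumes sexed F2; with many uncertain
sexes its power drops roughly with the square root of the sexed homozygote
count. The heterogamety verdict requires a diverged sex-linked haplotype
within recombination range of the SD locus -- absent one, `inconclusive` is
the designed outcome. Supports are ln-likelihood gaps under the stated error
model and are not calibrated posterior probabilities.
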