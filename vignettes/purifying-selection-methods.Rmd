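---
title: "Models and methods: purifying-selection contrasts between reproductive modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: purifying-selection contrasts between reproductive modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the design

Loss of sex and recombination is expected to weaken purifying selection
and let slightly deleterious mutations accumulate ("mutational
meltdown"). `purisel` implements the comparative test of that prediction
on a paired phylogenetic design: several independently derived asexual
lineages, each matched with a close sexual relative from the same
taxonomic group, analysed over a set of single-copy orthologous
protein-coding genes on a fixed species tree (optionally with one
outgroup). Three complementary signals are measured per gene:

1. **Nonsynonymous accumulation** -- per-branch dN/dS under a free-ratio
   codon model; less effective purifying selection raises terminal-branch
   dN/dS.
2. **Deleteriousness of replacements** -- hydrophobicity change between
   the reconstructed ancestral and the observed derived amino acid on
   terminal branches.
3. **Selection on synonymous usage** -- codon-usage bias (Wright's Nc)
   and its composition-corrected deviation (CDC).

Mode effects are tested by permutation ANOVA across genes, modes and
groups, and by per-group paired Wilcoxon signed-rank tests with
Delta(sex − asex) reporting.

## The codon substitution model

The substitution process is MG94 x HKY over the 61 sense codons of the
universal code. For codons $i \ne j$ differing at exactly one position
(and $j$ not a stop),

$$q_{ij} = \pi_j \,\kappa^{\mathbb{1}[\text{transition}]}\,
\omega^{\mathbb{1}[\text{nonsynonymous}]},$$

zero otherwise; $\pi$ comes from the F3x4 construction (positional
nucleotide frequencies multiplied per codon and renormalized over sense
codons). Each branch's generator is rescaled so that one unit of branch
length equals one expected substitution per codon *under that branch's
own* $\omega$; this makes branch length and $\omega$ cleanly separable
and matches the simulator's convention, so parameter recovery is
unbiased by construction. dN and dS follow the flux convention
$dN = t\,\rho_N/(3 L_N)$, $dS = t\,\rho_S/(3 L_S)$, where $\rho_N$ is
the nonsynonymous fraction of equilibrium substitution flux at the
fitted $\omega$ and $L_N = \rho_N(\omega = 1)$ the neutral site
proportion; the ratio $dN/dS$ recovers the fitted $\omega$ exactly
wherever $dS > 0$.

The likelihood is Felsenstein pruning over sites with per-pattern
scaling; codons containing `N` or gaps contribute partial likelihood 1
in every state (the permissive missing-data convention). Transition
matrices come from eigendecomposition of the symmetrized reversible
generator, which is exact for this model class; likelihood values are
invariant to root placement.

## Fitting strategy and numerical choices

Fitting is two-stage, mirroring the common practice of estimating
branch lengths first and branch-specific rates second:

* **Stage 1 (shared ratio)**: $\kappa$, a single tree-wide $\omega$, and
  all branch lengths are optimized jointly -- Brent line searches per
  branch (using inside/outside partial likelihoods so only one branch's
  transition matrix is rebuilt per evaluation) alternating with
  Nelder-Mead over $(\log\kappa, \log\omega)$. Three deterministic
  starting pairs $(\kappa, \omega) \in \{(2, 0.2), (1, 0.05), (4, 0.5)\}$
  are screened coarsely and the best refined; a deterministic grid was
  preferred over random multistarts so that fits are exactly
  reproducible and do not consume the caller's RNG stream.
* **Stage 2 (free ratio)**: each branch's $(\log t, \log\omega)$ is
  refined by nested Brent searches on local, self-expanding brackets,
  sweeping all branches until the log-likelihood gain of a full sweep
  falls below $10^{-2}$ (at most 8 sweeps), with one $\kappa$
  re-optimization after the first sweep. Sweep gains fall roughly
  geometrically; below a gain of $10^{-2}$ the per-branch $\omega$
  estimates move by $\sim 10^{-3}$, which is far inside the sampling
  noise of any gene-sized alignment, so a tighter cutoff only adds
  sweeps without changing any reported quantity.

$\omega$ is bounded to $[10^{-4}, 20]$ and branch lengths to
$[10^{-9}, 20]$. Branches with $dS$ numerically zero report $\omega$ as
missing and are excluded downstream; $dS > 3$ raises a saturation flag
(not an exclusion). On branches carrying very few substitutions the ML
$\omega$ is weakly identified and right-skewed (occasionally hitting the
upper bound); this is why all mode comparisons use terminal branches
only and why genes are screened (below) before the statistics.

**Positive-selection screening.** A gene is dropped when some branch has
fitted $\omega > 1$ *with likelihood-ratio support*: the branch is
refit with $\omega$ capped at 1 and the gene is flagged when
$2\Delta\log L > 2.71$ (one-sided $\chi^2_1$ at 5%). This mirrors the
practice of excluding loci with episodic positive selection before
asking about purifying selection.

**Branch filtering.** The comparable response set keeps terminal
branches with defined $\omega \le 1$ and $dS > 0$, dropping internal
branches (not attributable to either mode in a paired design) and
outgroup branches.

## Ancestral reconstruction and hydrophobicity scoring

Marginal posterior codon distributions for every internal node are
computed by the inside/outside form of pruning under the fitted
free-ratio model; the reported state is the argmax codon, translated to
an amino acid. Reconstruction is at the codon level (then translated)
rather than at the amino-acid level: the codon model is the fitted
object, and collapsing to amino acids first would discard the
synonymous information that anchors branch lengths. When an outgroup is
present the pipeline roots the tree on it before fitting, which fixes
the node set used for reconstruction; marginal posteriors at internal
nodes are root-invariant under this reversible model.

A transition record is emitted for every site on a terminal branch
where the tip amino acid differs from the parent node's reconstruction,
provided the parent posterior reaches the threshold (default 0.5;
lower-confidence sites are skipped and counted). Under the synthetic
study conditions about 95% of true terminal nonsynonymous events are
recovered at this default; demanding 0.95 posterior instead drops
recall to roughly 0.75-0.78 because genuinely uncertain sites are
skipped -- the threshold trades precision against recall and is a
user-facing parameter.

Replacements are scored with a symmetric 20 x 20 hydrophobicity score:
$HS(a,b) = \mathrm{round}\!\left(100 - 100\,|h(a) - h(b)| / (\max h -
\min h)\right)$ on the Kyte-Doolittle hydropathy scale, so 100 means
identical hydrophobicity and lower scores mean stronger physicochemical
change; scores below 90 are labelled "dissimilar". The matrix is a
pluggable TSV input, and the scale name travels in the output metadata,
because the score semantics ("lower = stronger change", threshold 90)
matter more than the particular published scale. Mode comparison of HS
uses a paired sign-flip permutation test on per-species means (a
deliberate simplification of mixed-model alternatives; with eight
groups the flip null is enumerated exactly).

## Codon-usage statistics

**Nc** (effective number of codons) uses Wright's homozygosity
estimator per amino-acid family, $\hat F = (n\sum p_i^2 - 1)/(n-1)$ for
families with $n \ge 2$ observations, class means over degeneracy
classes (2-fold: 9 amino acids; 3-fold: Ile; 4-fold: 5; 6-fold: Leu,
Ser, Arg), and $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 +
3/\bar F_6$, capped at 61. A missing 3-fold class is imputed as
$(\bar F_2 + \bar F_4)/2$ (the codonW-compatible rule); a missing 2-,
4- or 6-fold class yields a missing value.

**CDC** compares observed codon frequencies with the usage expected
from positional GC and purine contents alone. Each position's
nucleotide distribution is factorized as $P(G) = gc \cdot pur$,
$P(C) = gc(1 - pur)$, $P(A) = (1-gc)\,pur$, $P(T) = (1-gc)(1-pur)$ --
the minimal-assumption construction from exactly those two observed
quantities -- codon expectations are position products, stops dropped
and the vector renormalized; CDC is one minus the cosine similarity of
observed and expected vectors, clipped to $[0, 1]$. Both statistics are
computed on curated alignment sequences with gaps removed per species,
i.e. on the same material the divergence analyses see.

## Permutation and rank statistics

The permutation ANOVA fits `value ~ gene + mode + group + mode:group`
with sequential (type I) sums of squares in that fixed order and builds
each term's null by permuting the response wholesale (the
exchangeable-null construction; Freedman-Lane residual permutation is
available as an option), with add-one p-values
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$ and the default 5,000
replicates. Observed F statistics are checked against R's sequential
`aov` in the test suite; the permutation engine evaluates all permuted
responses against pre-computed orthonormal bases of the nested model
sequence, so the 5,000-replicate default costs well under a second.

The Wilcoxon signed-rank test discards zero differences, mid-ranks
ties, and for up to 15 nonzero pairs computes the exact two-sided
p-value from the full distribution of $V$ over all $2^n$ sign
assignments (by convolution on doubled ranks, identical to complete
enumeration and correct under ties); larger samples use the normal
approximation with continuity and tie corrections. No multiple-testing
correction is applied across groups by default, matching the
raw-per-group reporting convention of this analysis style.

## The synthetic-data generator

The generator exists so every stage is testable without external data.
It simulates each gene's codon sequence along the packaged 17-taxon
design (eight sexual/asexual pairs as cherries on a comb backbone plus
one outgroup; topology and branch lengths are synthetic stand-ins for
that sampling design, not estimates for real taxa) under the same MG94
process the estimator assumes. Defaults define the study conditions:

* baseline $\omega = 0.03$ on every branch -- the strong-purifying
  regime typical of conserved single-copy orthologues;
* $\kappa = 2$, a routine transition/transversion ratio;
* GC3-rich positional composition (GC3 = 0.70) so Nc and CDC have
  signal to detect;
* 99 genes x 300 codons, the scale of a curated orthologue set (gene
  length chosen so a full-study simulation stays desk-sized);
* terminal branch lengths 0.26-0.34 expected substitutions per codon,
  internal stems 0.04-0.06, outgroup 0.55 -- deep splits with
  substantial synonymous divergence but below saturation;
* a meltdown factor $\lambda \ge 1$ multiplying $\omega$ on asexual
  terminal branches ($\lambda = 1$ reproduces the null scenario
  byte-for-byte).

The default mode is Gillespie event simulation per branch, which yields
true per-branch synonymous/nonsynonymous event counts for the truth
tables that parameter-recovery tests consume; exact transition-kernel
sampling is retained as a cross-check mode (used, e.g., for the
equilibrium-convergence test, where a very long branch would make event
simulation wasteful). Per-gene RNG streams are derived as
`(seed + gene_index * 1000003) mod (2^31 - 1)`, so genes are
independent and individually reproducible.

What the generator does **not** emulate: assembly artifacts, paralogy,
alignment error, indels (simulated alignments are gap-free), among-site
rate heterogeneity, and any biological covariates of asexuality beyond
the branch-wise $\omega$ elevation. Passing tests therefore demonstrate
correctness of the estimators and statistics under the assumed model,
and calibrated behaviour at realistic sizes -- not robustness to the
model violations real transcriptome data carry.

## Verification summary

The test suite pins, among others: the pruning likelihood against
brute-force enumeration over internal states on all tree shapes with up
to 4 tips (tolerance $10^{-8}$); Nc's closed-form boundary values 20
and 61; CDC's self-consistency zero; exact signed-rank p-values against
complete sign enumeration up to $n = 12$; the nominal size of the
permutation ANOVA's mode term over 200 null simulations; recovery of
simulated dN/dS (median branch $\hat\omega \in [0.07, 0.13]$ for data
simulated at $\omega = 0.1$ with 2,000 codons on 16 tips; terminal-mean
$\hat\omega \in [0.9, 1.1]$ over 20 neutral genes of 300 codons); and
detection of a 3-fold asexual $\omega$ elevation in at least 90% of 20
simulated genes, with the majority of groups showing negative
Delta(sex − asex). The neutrality calibration averages *terminal*
branches because internal branches -- excluded from every downstream
statistic -- carry too few substitutions at these gene lengths for
their ratio estimates to have a stable mean (their median is ~1, their
mean is not; see the fitting notes above).

## Known limitations

* One $\omega$ per branch and site-homogeneous rates: no branch-site or
  Gamma models; genuine rate heterogeneity maps into averaged branch
  estimates.
* The HS matrix is a one-dimensional hydrophobicity summary, not a
  structure- or context-aware deleteriousness predictor.
* The CDC expectation assumes positional independence of GC and purine
  content; sequences violating that factorization shift the baseline.
* The paired permutation test on species means replaces a mixed model;
  with few groups its resolution is limited by $2^G$ sign flips.
* Free-ratio $\omega$ on data-poor branches is weakly identified; use
  the exclusion flags rather than raw internal-branch values.
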