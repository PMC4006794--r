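---
title: "Methods: population genetics of regulatory indel polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of regulatory indel polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

regindel analyses insertion/deletion polymorphism in population
resequencing alignments of regulatory DNA — the setting in which a large
deletion that removes a transcription-factor binding site segregates at
appreciable frequency, and one wants to know whether the carrier
haplotype class shows the signature of selection, how the deletion is
distributed geographically, and whether it shifts a measurable embryonic
phenotype. This vignette documents the models, conventions and design
choices behind each stage.

## Alignments, variant calling and coordinates

The input is a multiple-sequence alignment of haploid, phased sequences
(inbred or isogenic lines), with `-` for deleted bases and `N` for
missing data; IUPAC ambiguity codes are converted to `N` on read because
an ambiguous base in an inbred-line Sanger read carries no reliable
haplotype information. All internal coordinates are 0-based and
half-open (BED convention); 1-based inclusive coordinates appear only in
rendered reports. This makes span arithmetic (overlap, removal,
truncation) unambiguous.

Every alignment column with two or more nucleotide states among the
non-gap, non-missing characters is a SNP. An indel *event* is a maximal
run of identical gap placement: all rows sharing a gap run with the same
start and end are carriers of one biallelic presence/absence marker,
regardless of the run's length — a 72-bp deletion is one event, exactly
as a 1-bp deletion is. Overlapping but non-identical runs are distinct
events. This convention is what makes indel-class segregating-site
counts small integers comparable across regions.

All SNP-class statistics use *complete deletion*: any column containing
`-` or `N` in any row is excluded, and the number of retained columns is
the per-site denominator. This matches the default behaviour of the
classic desktop tools for this analysis; pairwise deletion would retain
more data but make per-site denominators column-specific. Indel-class
statistics reuse the same formulas with each event as one biallelic
site and the *same* retained-column normalization as the SNP analysis of
that region, so the two classes are on a common per-site scale.

## Diversity statistics

For a sample of $n$ sequences and $L$ retained sites:

* $\pi$ — mean pairwise difference per site over all $n(n-1)/2$ pairs;
* $\theta_W = S / (a_n L)$ with $a_n = \sum_{i=1}^{n-1} 1/i$;
* Tajima's $D$ — $(\pi_{tot} - S/a_1)$ normalized by the 1989 variance
  constants $e_1 S + e_2 S(S-1)$;
* Fu & Li's $D^*$ and $F^*$ — the no-outgroup, singleton-based
  statistics, using the corrected variance constants (the versions the
  standard desktop implementation uses). Mutation counts $\eta$ enter
  the formulas; for biallelic data $\eta = S$;
* $K$ and $Hd$ — distinct haplotypes over retained columns and
  $\frac{n}{n-1}(1 - \sum p_i^2)$;
* $D_{xy}$ — mean between-class pairwise difference per site, computed
  after complete deletion on the *pooled* alignment.

Statistics undefined at $S = 0$ (the $D$-family) propagate as missing
values — a monomorphic region has an empty cell, not a zero. Columns
with more than two states count toward $S$ but are excluded from
pairwise LD, which needs the biallelic 2×2 table; they are flagged in
the variant table. Group-private variants track the pooled minor state,
with exact 50/50 ties broken by lexicographic nucleotide order for
determinism.

Sliding windows are laid out on alignment coordinates — gap columns
count toward window positioning but not toward the site denominator —
so window x-axes remain interpretable against annotation even across a
large deletion. A window with zero retained sites is reported missing,
not zero.

## Linkage disequilibrium

Sequences are haploid phased haplotypes, so $D = p_{AB} - p_A p_B$ and
$r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))$ are computed directly from
gamete counts; no genotype-phasing EM is needed or implemented. The LD
profile pairs a focal deletion's presence/absence vector against every
biallelic SNP in the region; rows missing at either marker are dropped
pairwise, so the effective sample size can vary per record. Records
that are monomorphic after missing-data removal are flagged undefined
rather than zero. Perfect coupling and repulsion ($r^2 = 1$) are
flagged explicitly because clade-marking variants are the expected
signature around a young deletion haplotype. No minor-allele-frequency
filter is applied by default.

## The coalescent null and Hudson's haplotype test

The simulator draws a standard Kingman genealogy: while $k$ lineages
remain, the waiting time to the next coalescence is
$\mathrm{Exp}(k(k-1)/2)$ and the merging pair is uniform. Time is in
units of $2N$ generations, so $E[T_2] = 1$ and the expected total tree
length is $2 a_n$ — the classic `ms` simulator's $4N$ units are half
these, and the conversion is made explicitly wherever results are
compared, to avoid silent factor-2 errors. Mutations are placed under
infinite sites, either exactly $S$ of them (each independently on a
branch chosen proportionally to length — the fixed-$S$ conditioning
used by the haplotype test) or at rate $\theta/2$ per unit branch
length, which makes the expected pairwise difference equal $\theta$.

Hudson's haplotype test asks: in a neutral sample of size $n$ with $S$
segregating sites and no recombination, how often does there exist a
subset of at least $i$ chromosomes segregating at no more than $j$
sites? The observed data define $(n, S, i, j)$ and satisfy the
condition by construction; the Monte-Carlo p-value is the fraction of
replicates that also satisfy it. Because the published description of
the subset criterion is terse, both readings are implemented: the
default any-subset statistic, and a stricter largest-identical-class
variant. The subset search exploits the fact that an optimal subset is
always a union of identical-haplotype classes (adding a duplicate row
never adds a segregating site), so with $k$ distinct haplotypes
($k \le S+1$ under infinite sites) the search over $2^k - 1$ subsets is
exact whenever $2^k \le 8192$, and falls back to greedy growth from
each haplotype class above that — a lower bound on the optimum,
validated against exhaustive row-subset enumeration for $n \le 8$ in the
test suite. The null has no recombination, growth or structure, because
the test conditions only on $(n, S)$.

## PWM scanning

Count matrices become log2-odds weights via
$\log_2\frac{(c_{bk} + q)/(\sum_b c_{bk} + 4q)}{\pi_b}$ with
pseudocount $q = 0.8$ and uniform background by default. Raw log-odds
scores (not 0–100 rescaled scores) are reported, matching the
fixed-cutoff convention ("score above 6") used in binding-site surveys
of this kind; because the exact matrix version behind any particular
published score is generally unrecoverable, both the pseudocount and
the background are exposed and printed scores are treated as
matrix-version dependent. Scanning reports every window at or above
threshold on both strands, minus-strand hits scored on the reverse
complement but reported in forward coordinates; windows containing `N`
are skipped (conservative) rather than scored with background odds.
Predicted sites are classified against a deletion span as removed
(fully inside), truncated (overlapping a boundary — the biologically
interesting half-site case), or intact. The shipped example matrix is
synthetic (an A/T-rich zinc-finger-style profile) and is labelled as
such; it is a stand-in for database matrices the package does not
redistribute.

## Clines, F_ST and the sign test

Cline fitting is ordinary least squares of carrier frequency on decimal
latitude (degree-minute strings are parsed as degrees + minutes/60).
Frequency-scale OLS is the primary method because it is the analysis
whose printed slope the package reproduces; a count-weighted logistic
alternative is available behind a flag for users who prefer it.
Pairwise $F_{ST}$ defaults to the Hudson-style estimator
$1 - H_w/H_b$ with sample-size-corrected within-population
heterozygosity, because the choice of estimator was genuinely open; the
Weir–Cockerham $\theta$ is exposed as an option and negative estimates
are floored at zero for reporting with the raw value retained. The
sign test is the exact two-sided binomial tail,
$\min(1,\; 2 P(X \ge \max(k, n-k)))$.

## Stripe-boundary geometry and contrasts

Embryo landmarks are converted to relative positions by scalar
projection of each boundary landmark onto the unit anterior-posterior
axis, divided by tip-to-tip length. Projection, not raw Euclidean
distance from the tip, is the primary mode: the two differ for
off-axis landmarks, and projection is isometry-invariant, bounded, and
independent of the perpendicular offset of the measurement guideline (a
raw-distance mode is kept behind a flag). Positions are clipped to
[0, 1] with clips counted, and within-stripe ordering violations are
flagged rather than dropped.

The ordinal dorsal/ventral orientation score is removed by per-boundary
OLS residualization (treated as a linear term; the alternative ordinal
coding was not identifiable from four levels), and genotype contrasts
are then fitted per boundary on *line-level means* with the line-mean
developmental stage as a covariate. Line means are a transparent,
testable alternative to a full mixed model with line variance
components, which is out of scope here; with few lines per class the
line is the correct unit of inference, and the line-mean analysis keeps
the per-boundary p-values exact under normality. The 14 boundary tests
use a Bonferroni cutoff of $\alpha/14$ (0.0036 at $\alpha = 0.05$).

## Synthetic data: what it emulates, what it does not

`synth_population_alignment` is a stylized two-class generator, not one
joint genealogy: the wild-type class descends from a standard
coalescent at per-site $\theta$; the carrier class from an independent
coalescent whose times are scaled by the `diversity_reduction` factor
$f$ (a recent-subclade surrogate for a sweep, chosen because it
reproduces the observable signature — carrier-class $\pi$ reduced to a
fraction $f$ of wild type — with one interpretable knob); stem
mutations shared by all carriers sit in perfect coupling with the
deletion, giving the elevated-$r^2$ LD profile; and carriers are gapped
across the deletion span. Defaults (18 wild-type and 16 carrier
chromosomes, $\theta = 0.005$/site, a 72-bp deletion, $f = 0.3$) mirror
the resequencing design and the observed 25–100% carrier diversity
reduction this class contrast is built to detect. The generator does
not model recombination, so it cannot produce the
recombination-imported variation real carrier haplotypes show; passing
tests demonstrate the statistics and their calibration, not robustness
to intra-locus recombination.

`synth_cline` draws binomial counts around a planted
frequency-latitude line (defaults: the ten survey latitudes, 38
chromosomes per population, slope −0.006/degree). `synth_embryos`
plants a stripe template (seven 4%-width stripes spanning 35–85% egg
length), adds orientation, stage, line and landmark-noise effects, and
lays landmarks on a randomly rotated, translated and scaled axis with
perpendicular offsets. Noise defaults were fixed once at values
realistic for visual landmarking: 0.01 embryo-lengths measurement
noise, 0.005 between-line SD (measurement noise dominates line
variation for boundary positions), 0.004/unit orientation effect,
0.005/unit stage effect. With 30 embryos per class over 5 lines these
defaults give a correctly calibrated null (~5% of boundaries at
p < 0.05) and high power for a 3-standard-deviation planted shift under
the 14-test Bonferroni cutoff.

## Numerical conventions and problem sizes

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; generators are pure functions of (parameters,
seed). Undefined statistics are `NA` end to end, never zero. Monte
Carlo checks in the test suite and the acceptance script use 1 500 to
2 000 coalescent replicates, 200 to 500 synthetic datasets for
parameter-recovery checks, and 100 to 200 datasets for stripe-pipeline
calibration — sizes at which the three-standard-error acceptance bands
are a small fraction of the quantities checked. The Hudson test is run
at 2 000 replicates per configuration in the acceptance script; its
exact-search threshold ($2^k \le 8192$) covers every configuration used
there.

## Known limitations

* The coalescent null ignores recombination; for regions with
  appreciable internal recombination the haplotype test is
  conservative in some configurations and anticonservative in others.
* Fu & Li's outgroup-based $D$ and $F$ are not implemented (no
  outgroup in the inputs), only $D^*$/$F^*$.
* PWM scores are matrix-version dependent and have no p-value
  calibration here.
* The stripe analysis aggregates to line means; variance-component
  estimates and least-squares means from a full mixed model are out of
  scope.
* The per-row reference population of the shipped cline table's
  pairwise $F_{ST}$ column is taken to be the southernmost population;
  this is documented as an assumption and not asserted in tests.
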