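---
title: "Evaluating reference-panel bias in ancient-DNA imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reference-panel bias in ancient-DNA imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoimpute)
```

## The question this package answers

Low-coverage ancient genomes can be imputed against a modern reference
panel, and the genotype concordance of the result is often reassuringly
high. Concordance, however, is computed only over the sites that were
imputed confidently — and which sites those are, and which genotypes they
received, depends on the composition of the panel. When the panel is
dominated by one or two population components, the imputed genome drifts
toward them: downstream PCA, ancestry and runs-of-homozygosity analyses
then tell a subtly different story than the true genome would.
`paleoimpute` provides a fully seeded simulation of this situation with
known truth, an internal imputer, and the evaluation metrics needed to
measure both accuracy and drift.

## The generative model

### Panel

`simulate_panel()` draws, per site, an ancestral allele frequency
$p \sim U(0.05, 0.95)$ and, per population group $g$, a
Balding–Nichols frequency

$$ f_g \sim \mathrm{Beta}\!\left(p\,\frac{1-F}{F},\; (1-p)\,\frac{1-F}{F}\right), $$

so that $E[f_g] = p$ and $\mathrm{Var}[f_g] = F\,p(1-p)$ with $F$ the
group's drift parameter. Haplotypes are Bernoulli$(f_g)$ draws; each
diploid donor contributes two independent haplotypes (the panel is used
phased, so within-donor correlation would be irrelevant to the imputer).
The unit tests verify that the Hudson FST estimator recovers the nominal
$F$ on generated matrices.

This deliberately replaces coalescent simulation: the bias phenomenon
needs structured groups with distinct frequency spectra, not realistic
genealogies. The cost of the simplification is the absence of
linkage-disequilibrium blocks — a point we return to under *Limitations*.

Default values describe the motivating system: 51 diploid donors
(19 EUW European wild boar, 25 EUD European domestic, 4 BLW Balkan wild
boar, 3 NEW Near Eastern wild boar), 5,000 biallelic SNPs at one site per
500 bp (the marker density of a dense whole-genome call set), drift
$F = 0.15$ per group — within the range separating wild-boar and domestic
pig populations.

Half of all sites are assigned a deamination-prone allele pair (C/T or
G/A), the rest the four other pairs. No published figure pins down the
damage-prone fraction of segregating sites; one half gives the
deamination filter realistic bite while leaving a damage-free comparison
set.

### Targets and reads

`simulate_admixed_target()` builds each haploid copy as an ancestry
mosaic: segment lengths are exponential on the genetic map (rate
`switch_rate_per_cm`), each segment's group is drawn from the target's
ancestry proportions, and alleles within a segment are Bernoulli draws
from the group's panel frequency ("frequency-conditional copying"). The
default admixture is ~46% European / ~54% Near Eastern — the kind of
mixed-ancestry individual for which panel bias matters most. The default switch rate of 1 per Morgan gives realistic
long tracts; note that over a short simulated region that means a haploid
copy is often a single segment, so tests that need a realized mixture
close to its expectation use denser switching and longer regions.

`simulate_reads()` gives every site a Poisson(λ) read count; each read
copies one of the two true alleles uniformly, flips to the other allele
with probability ε (default $10^{-3}$, i.e. Phred-30 bases after quality
trimming), and is assigned a uniform strand. Deamination then converts
C→T on + strand reads at C/T sites and G→A on − strand reads at G/A
sites, each with probability δ (default 0.1 — a conventional
mid-range per-site damage rate for screened ancient libraries; per-sample
damage rates are rarely tabulated). `downsample_pileups()` thins reads
binomially onto the 0.5–2× evaluation grid.

### Genotype calling and quality

`genotype_likelihoods()` is the standard biallelic diploid model:
$P(\mathrm{obs}\mid a) = 1-\varepsilon$ for a matching allele,
$\varepsilon$ otherwise, and heterozygotes emit each allele with
probability one half. Call quality is a **site-level variant confidence**:
for sites whose likelihood argmax is a variant genotype, the Phred-scaled
posterior of hom-ref; for hom-ref argmax sites, the Phred-scaled posterior
of being variant. We chose this over the flat-prior single-sample GQ
because GQ is bounded by roughly 3 Phred per read — under a 25/30
threshold no site could ever be emitted at 0.5–2×, whereas site-level
variant quality lets a single Phred-30 alternate read clear the bar,
which is how low-coverage variant calling actually behaves. The
thresholds themselves (emit 25, filter 30) follow low-coverage aDNA
practice. A consequence worth knowing: at depth 1 a true heterozygote is
called as a confident homozygote for whichever allele was read — the
classic low-coverage bias that the two-step pipeline later corrects.

### Deamination filter

At C/T SNPs any called genotype containing T, and at G/A SNPs any
containing A, could be a damage artifact and is excluded; likelihood ties
count as damaged (conservative). Methods 1–2 drop such sites from the
target; Method 3 keeps them as no-calls (`./.`) so the target retains one
row per panel site. The same rule is applied to the gold standard and to
the evaluated imputed output: damage-explicable genotypes are excluded
from *all* further analyses, so every comparison is made on the same
footing.

## The imputer

The hidden state is an ordered pair of panel haplotypes; each haploid
copy switches donors independently between adjacent sites with
probability $1 - \exp(-4 N_e d / K)$, where $d$ is the genetic interval
in Morgans, $N_e = 20{,}000$ by default and $K$ the number of panel
haplotypes; the new donor is uniform over $K$. Emissions mix a
per-haplotype miscopy rate $\theta$ (default $10^{-3}$) with the site's
normalized genotype likelihoods; sites without data are flat. The
factorized transition makes a forward–backward pass $O(S K^2)$; the C++
kernel stores scaled forward matrices and accumulates genotype posteriors
on the backward sweep, including the site's own likelihood term, so the
reported GP is the exact posterior $P(g \mid \text{reads, panel})$. The
test suite checks it against two independent oracles: a naive dense
$K^2 \times K^2$ matrix recursion and true path enumeration, both to
$10^{-8}$ or better, and verifies that forward and backward total
log-likelihoods agree.

Genetic distances default to a uniform 1 cM/Mb map; `build_map()`
constructs binned maps from recombination frequencies via the Haldane
formula $d = -50 \ln(1 - 2r)$ cM with 1 Mb bins and linear interpolation
inside a bin (a step function would also be defensible; linear is chosen
because the imputer consumes interval differences, which a step function
would concentrate at bin edges). Plink-dialect map files round-trip.

### Pipelines, methods, filters

* **Methods.** Method 1 anchors the HMM on called variant sites only;
  Method 2 on all confidently called sites including hom-ref; Method 3
  on exactly the panel's sites with uncallable positions missing.
  Observed genotypes enter as hard calls (degenerate likelihood
  triplets), mirroring tools that consume a called VCF.
* **One-step vs two-step.** The two-step pipeline first runs the HMM on
  the observed sites with their *soft* likelihoods, then removes calls
  whose refined maximum genotype probability is below 0.99 before the
  full pass. At 0.5× this removes mostly the single-read homozygote
  errors, which is why it improves concordance so consistently.
* **Imputation-score filter.** Retained sites must have an imputation
  score of 1. With a positive miscopy rate the maximum GP is bounded by
  $(1-\theta)^2 < 1$, so a literal score-of-1 cutoff would retain
  nothing; since imputation tools report genotype probabilities at about
  two decimals, the filter thresholds the score rounded to two decimals
  (score 1 ⇔ max GP ≥ 0.995). An INFO-style dosage-variance score is
  available as an alternative (`score_filter(mode = "dosage_variance")`).

## Evaluation metrics

`concordance()` classifies every imputed genotype against the
deamination-filtered gold standard: *correct*, *incorrect genotype*
(site present, genotype differs) or *incorrect position* (site absent
from the standard — counted as an error by construction even though some
such calls may be right in reality; that is what the class name means).
The three counts always sum to the imputed total. Information content is
the ratio of imputed to gold-standard genotype counts.
`stratified_concordance()` repeats this per MAF bin — the overlapping
set `<0.05`, `0.05–0.1`, `0.1–0.3`, `>0.05`, `>0.3`, `No MAF`, of which
the four narrow bins partition [0, 0.5] — per chromosome (with a
standard-deviation uniformity summary), and for sites whose *gold
standard* genotype is heterozygous (truth-conditioning; conditioning on
the imputed genotype would mix error classes into the stratum
definition).

`affinity_profile()` operationalizes "presence/absence" reference
affinity: a group supports a genotype if at least one of its diploid
panel donors carries it, and each evaluated genotype gets a support
pattern such as `EUD; EUW`. Pattern distributions are compared in
aggregate (not site-by-site) between each imputed class and the
gold-standard baseline via total-variation distance. Under a skewed
panel the incorrect-genotype class concentrates sharply on
majority-*only* patterns — genotypes the minority group does not carry —
which is the cleanest single-number signature of the drift (the mass of
patterns that merely *contain* the majority barely moves, because almost
every common genotype is carried by the majority too).

`ancestry_props()` is a supervised surrogate for model-based admixture:
it fits observed dosages to $2\sum_g w_g f_g$ by least squares with the
weights on the probability simplex, solved exactly by active-set subset
enumeration (deterministic, and exact for the handful of groups a panel
has). `bias_shift()` reports the per-group difference between the
imputed and true ancestry estimates, plus a PCA displacement: principal
components are computed on the panel donors' frequency-standardized
genotypes and the two samples are *projected* onto them — the samples
are not included in the decomposition, avoiding the shrinkage of the
sample toward the panel cloud that inclusion would cause.

`detect_roh()` implements the plink-style window scan with the
parameterization used for ancient pigs: 100-SNP windows homozygous at
≤2 heterozygous and ≤1 missing calls, a per-SNP hit fraction of 0.05
(the wrapped tool's default, since no published value overrides it),
runs of ≥100 SNPs and ≥10 kb, split at >10 kb gaps. Length classes are
[0, 500), [500, 1000), [1000, ∞) kb — boundaries left-closed as a
convention — each with
count, total kb and Froh (total kb over assayed genome length; both
call sets share the denominator, so comparisons do not depend on it).

## What the simulations show — and what they cannot

Under the default study conditions (skewed panel, 50/50 admixed target,
1× coverage) the package reproduces, qualitatively and reproducibly, the
phenomena that motivate it: imputed ancestry shifts toward the panel's
majority component while a balanced panel shows no systematic shift;
imputed genotypes produce large runs of homozygosity where the truth has
none (score-confident sites are overwhelmingly homozygous, and the true
genomes here carry no inbreeding at all); the two-step pipeline beats
the one-step pipeline at 0.5×; heterozygote concordance is far below
overall concordance; and rare-variant (MAF < 0.05) concordance is high
even while those same sites drive the ancestry drift.

Two caveats keep these results in proportion. First, the generator's
haplotypes are independent across sites: there are no LD blocks, so
panel size does not improve accuracy the way it does on real data
(haplotype-sharing is the mechanism, and it is absent by design); the
package asserts only that accuracy does not *degrade* with panel size.
Second, absolute concordance values at desk scale (~0.73–0.80 at 1× with
small panels) sit below what large real panels achieve; directions and
contrasts, not absolute levels, are the reproducible quantities here.
The test suite and `scripts/acceptance.R` therefore check directional
and structural properties at fixed seeds — problem sizes of 2,000–5,000
sites and 20 replicates, chosen so the full evaluation remains a
minutes-scale desk computation.

## Numerical and degenerate-input behaviour

* Forward–backward uses per-site rescaling; a zero forward mass (all
  emission mass excluded) raises an error rather than returning NaNs.
* Likelihood ties in calling resolve to the first genotype (hom-ref
  first) for determinism; the deamination filter treats ties
  conservatively as damaged.
* λ = 0 coverage yields valid empty pileups; depth-0 sites are missing
  genotypes; an all-missing target refuses to impute.
* All simulators take explicit integer seeds and restore the caller's
  RNG state; identical configuration and seed give bit-identical output,
  which the experiment driver verifies by writing byte-identical report
  tables.
* `two_step_prefilter()` errors if the GP filter would remove every
  observed genotype; `panel_qc()` errors if no site survives QC.

## Limitations

Beyond the absence of LD discussed above: indels and multi-allelic sites
are out of scope; the panel is generated phased (statistical phasing is
not modelled); fragment-length and library-preparation effects are not
modelled; the imputer runs whole-chromosome passes (no windowing); and
only single-sample imputation is implemented — joint imputation of
multiple targets is a different design with its own biases.
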