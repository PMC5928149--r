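---
title: "Compositional co-occurrence networks: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional co-occurrence networks: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(microcooc)
```

## Why a compositional estimator

Amplicon counts are closed: each sample's reads sum to the sequencing depth,
so the observed abundances are fractions on the simplex. Closure induces
negative dependence among fractions even when the underlying (absolute)
"basis" abundances are independent — correlations computed directly on
relative abundances are biased toward spurious negativity, and the bias grows
as the number of taxa shrinks. The package therefore estimates correlations
among the *basis* abundances from log-ratio statistics, which are invariant
to closure.

```{r compositional-bias}
sp <- basis_spec(5, seed = 7)             # five independent OTUs
ds <- simulate_counts(sp, n_samples = 200, depth = 2000)
rel <- ds$counts / rowSums(ds$counts)
naive <- cor(rel)
mean(naive[upper.tri(naive)])             # naive Pearson: clearly negative
fit <- sparcc(as_otu_table(ds), seed = 7)
mean(fit$rho[upper.tri(fit$rho)])         # log-ratio estimator: near zero
```

## The estimator

For fractions $f_i$, the variation matrix $t_{ij} = \mathrm{Var}[\log(f_i/f_j)]$
satisfies $t_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$
under a log-normal basis model, where $\omega_i$ is the basis log-variance.
If most $\rho_{ij}$ are near zero (sparsity), summing row $i$ over the
non-excluded partners $I_i$ gives the linear system
$\sum_{j \in I_i} t_{ij} \approx |I_i|\,\omega_i + \sum_{j \in I_i} \omega_j$,
solved exactly by QR; the decomposition is then inverted for $\hat\rho$ and
clipped to $[-1, 1]$.

Settings, all exposed as arguments of `sparcc()`:

* **Fraction resampling** — per sample, fractions are drawn from the
  Dirichlet posterior with a symmetric unit prior (counts + 1). The prior
  guarantees strictly positive fractions (log-ratios always defined) and the
  resampling propagates counting noise. Default 20 resamples, aggregated by
  the element-wise median; these are the long-standing defaults of the
  method's reference implementation, kept for comparability.
* **Iterative exclusion** — after each solve, the single strongest pair with
  $|\hat\rho|$ above the exclusion threshold (default 0.1) is removed from
  the sparsity system and $\omega$ re-solved, up to 10 iterations. Excluding
  one pair per iteration, strongest first, is a deterministic tie-break
  (ties broken by scan order, which is fixed by the OTU ordering).
* **Flooring** — non-positive solved $\omega_i$ are floored at $10^{-6}$
  before the square root, keeping $\hat\rho$ defined on degenerate inputs
  (e.g. an all-zero variation matrix). At least 4 OTUs are required: the
  sparsity system is degenerate below that, and smaller tables are rejected
  with a clear error. If exclusions ever make the system rank-deficient,
  the solver signals it and the exclusion loop keeps the last valid
  estimate.
* **Unbiased variances** — all sample variances use the $n-1$ denominator;
  the choice is immaterial at study scale but is fixed for reproducibility.

## Pseudo p-values

Each permuted dataset shuffles every OTU's counts independently across
samples, which destroys all between-OTU dependence while preserving each
OTU's marginal distribution; the full inference (including resampling and
exclusion) is re-run per permutation. The two-sided pseudo p-value is the
plain proportion of permutations with $|\rho_\mathrm{perm}| \ge
|\rho_\mathrm{obs}|$ — deliberately *not* the $(k+1)/(B+1)$ variant, so a
pair never exceeded in $B$ permutations reports $p = 0$. Whether to permute
whole samples or each OTU independently is a genuine design fork; the
per-OTU shuffle is the stronger null (it also breaks dependence on sample
covariates) and is what the reference tool does, so it is used here and
recorded in the fit's `params`. The PERMANOVA wrapper, by contrast, reports
the conventional $(k+1)/(B+1)$ permutation p-value of distance-based ANOVA;
the two conventions coexist deliberately and are both documented where they
apply.

## Network construction and descriptors

A pair becomes a link iff $p \le 0.05$ (inclusive) **and** $|\rho| > 0.5$
(strict). Strict-versus-inclusive matters at the boundary: a pair at exactly
$\rho = 0.5$ is excluded, one at exactly $p = 0.05$ is included. Networks
keep their full node universe, so per-stage networks restricted to the union
of all linked OTUs are directly comparable; isolated nodes count toward $N$
but not $N_C$.

Two descriptor conventions deserve a note because the field uses both:

* **Mean degree** is $2L/N_C$ — averaged over *connected* nodes, not the
  whole universe. With a fixed 66-node universe and stage-specific link
  sets, averaging over all of $N$ would conflate connectivity with universe
  size; $2L/N_C$ is also the only reading consistent with reporting both
  quantities separately.
* **Subnetworks** are connected components with at least one link; isolated
  nodes are not subnetworks.

Role classification is a strict signed majority: more negative than positive
links → competitive, the reverse → cooperative, exact non-zero ties →
`mixed` (an explicit label rather than a silent coin flip), degree zero →
neutral. Hubs are *all* nodes attaining the maximum degree — ties are real
in small networks and are reported as such. Presentation rounding is half
away from zero at 3 decimals and is applied only in `descriptor_table()`;
stored values keep full precision.

## The synthetic generator

`basis_spec()` plants a small set of strong target correlations
($0.5 \le |\rho| \le 1$; weaker targets are indistinguishable from the null
at desk scale and are rejected) in an otherwise-identity correlation matrix.
The completed matrix is repaired to the nearest positive semi-definite
matrix by clipping negative eigenvalues at zero and re-normalizing to unit
diagonal; if the repair moves a planted entry by more than 0.05 the
specification is declared infeasible and rejected — planting, e.g., a
$(+0.9, +0.9, -0.9)$ triangle fails loudly instead of silently simulating
something else.

`simulate_counts()` draws per-sample basis log-abundances from a
multivariate normal with that correlation structure, exponentiates, closes
to fractions, and draws reads multinomially at a fixed depth — exactly the
generative regime the log-ratio estimator assumes. Defaults: per-OTU log
means uniform on $[1, 4]$ (roughly a 20-fold abundance gradient, a modest
version of real amplicon unevenness) and a common log standard deviation of
1 (order-of-magnitude fluctuations across samples, typical of host-
associated communities). The pre-closure log-abundances and expected
fractions are kept in the returned object so tests can check the generator
independently of the estimator. `spike_isolate()` multiplies one OTU's
expected fraction by a fold factor and re-closes before re-drawing counts,
mirroring how an over-represented isolate in an inoculum displaces the rest
of the community; with the dataset's own seed and fold 1 it reproduces the
original counts bit for bit.

What the generator does **not** emulate: sequencing error and chimeras
(no read-level data), taxonomic structure, zero-inflation beyond what the
multinomial produces, temporal dynamics of recolonization, or uneven
per-sample depths. Tests passing on this generator therefore validate the
estimator's statistical behavior under its own model class — they do not
certify performance on real data whose noise process is unknown.

## Validation scale and known limitations

The validation suite runs at desk scale: 50 OTUs, 500 samples, depth 5,000
for recovery; 20 OTUs for null calibration and p-value uniformity (200
permutations); 200 random graphs (≤ 12 nodes) against a brute-force
descriptor oracle; 500 null PERMANOVA runs. These sizes were chosen so the
whole suite stays comfortably interactive while keeping Monte-Carlo noise
well below the tolerances tested.

The main known limitation is **attenuation of strong correlations for rare
OTUs**. Count noise adds roughly $2/\bar c$ to the log-fraction variance of
an OTU averaging $\bar c$ reads per sample; this inflates the inferred
$\omega$ and shrinks $|\hat\rho|$ by
$\sqrt{\omega_i\omega_j / ((\omega_i+\nu_i)(\omega_j+\nu_j))}$. With the
default abundance gradient, a planted $\rho = 0.8$ pair is typically
estimated around 0.70–0.75 at depth 5,000, and replicates whose planted
OTUs land at the rare end of the gradient can miss a ±0.15 recovery band.
This is a property of the estimator class, not of the implementation — the
estimate on noiseless closed fractions is within 0.01 of truth — and it is
the reason strong-correlation thresholds on real data should be read as
conservative. `scripts/acceptance.R` recomputes the recovery rate and the
mean planted-pair estimate on every run rather than asserting a fixed
number.

Out of scope by design: alternative inference backends (naive Pearson
exists only as a test foil), phylogeny-aware beta diversity (no tree is
built), jackknifed ordination confidence, and centrality measures beyond
degree — degree is the only centrality the role classification needs.
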