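---
title: "Measuring asymmetric rate acceleration after gene duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring asymmetric rate acceleration after gene duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

After a gene duplicates, do both copies keep evolving at the ancestral
rate, or does one copy accelerate? `dupaccel` measures this with the
*sextuplet* design: one duplication event represented by six coding
sequences — both paralogs in each of two closely related ingroup species
(for example mouse and rat), plus a single-copy ortholog in each of two
outgroup species (for example dog and cow). Because the outgroups diverged
before the duplication, their branches estimate the *preduplication* rate
of the very same gene, and the ingroup branches estimate the
*postduplication* rates of each copy separately.

The fixed tree is `(((M1,R1),(M2,R2)),C,D)`: `M1`/`M2` are the two
paralogs in species M, `R1`/`R2` their orthologs in sister species R,
`C` and `D` the outgroups. Its nine branches fall into five rate classes:

| class | branches | meaning |
|---|---|---|
| `preD` | `C`, `D`, stem | preduplication evolution |
| `ipostD1`, `ipostD2` | the two internal branches | initial postduplication period of each copy |
| `rpostD1`, `rpostD2` | `M1`+`R1`, `M2`+`R2` | recent postduplication period of each copy |

## The model

Substitution follows a Goldman–Yang-style codon model over the 61 sense
codons of the standard code. Codons exchange by single-nucleotide steps;
the rate from codon *i* to *j* is proportional to the target frequency
π<sub>j</sub>, multiplied by κ for transitions and by ω for
nonsynonymous changes. Each branch class has its own ω; κ and π are
shared across the tree because they describe mutational, not selective,
properties. Rate matrices are rescaled so branch lengths are expected
substitutions per codon, and per-branch `dn` and `ds` are obtained by
splitting each branch length into its nonsynonymous and synonymous flux,
each normalised by the neutral (ω = 1) flux at the same κ and π. This
makes `dn/ds` on a branch equal its class ω *exactly*, a closed-form
identity the test suite checks to 1e-10.

Likelihoods are computed by Felsenstein pruning with column pattern
compression and per-column scaling; alignment gaps are treated as missing
data. `P(t) = exp(Qt)` comes from an eigendecomposition of the
symmetrised matrix `diag(√π) Q diag(1/√π)`, which is numerically stable
for reversible chains. The optimiser maximises over log-transformed
branch lengths, κ, and the class ω values with L-BFGS-B, with a small
number of deterministically jittered restarts; the objective is a
compiled (RcppArmadillo) pruning kernel, with a pure-R implementation
kept as the reference that the tests compare against, including against
brute-force enumeration over internal states on small trees.

Codon frequencies default to F3x4 — position-specific nucleotide
frequencies estimated from the alignment, floored at 1e-8 and
renormalised — a standard compromise between the 60-parameter empirical
codon distribution and unrealistic uniform frequencies.

## The statistics

Writing ω̂ for the fitted class values:

- `delta_f = max(ω̂_rpostD1, ω̂_rpostD2) − ω̂_preD` — acceleration of the
  faster copy,
- `delta_s = min(ω̂_rpostD1, ω̂_rpostD2) − ω̂_preD` — acceleration of the
  slower copy,
- `delta_if`, `delta_is` — the same contrasts for the initial internal
  branches, paired with whichever copy is recently fast or slow.

The max/min construction is label-free: relabelling copy 1 and copy 2
leaves every delta unchanged (a tested invariant). A finding of
*asymmetric* acceleration is `delta_f > 0` with `delta_s ≈ 0`.

A cheaper pairwise design needs no joint fit: `O = dn/ds(C–D)` estimates
the preduplication rate, `P1 = dn/ds(M1–R1)` and `P2 = dn/ds(M2–R2)` the
two recent rates, and the duplication age is the mean of `ds(M1–M2)` and
`ds(R1–R2)`. Pairwise `dn/ds` is available both by two-sequence ML under
the same codon model and by Nei–Gojobori (NG86) counting with
Jukes–Cantor correction; the two agree within a few percent at moderate
divergence. NG86 counts synonymous sites excluding mutations to stop
codons from the opportunity denominator, and averages substitution
pathways that avoid stop codons; saturated comparisons (raw difference
proportion ≥ 3/4) are flagged rather than raised.

## Set construction and filtering

`find_sextuplets()` scans a homology table for the strict pattern — one
dog and one cow ortholog, each one-to-one with both ingroup paralogs, and
a one-to-one dog–cow relation. Families with more than two paralogs go to
`decompose_family()`, which dates events by pairwise `ds`: the
smallest-`ds` pair is the most recent duplication; one member of each
resolved pair is removed at random (seed-scoped, reproducible) and the
step repeats, yielding `k − 1` ranked sets from `k` paralogs. Ties in
`ds` are broken lexicographically and logged. `filter_ds()` then drops
any set with a pairwise `ds` above a threshold (default 1.0, strict
inequality), guarding against synonymous saturation.

Two diagnostics protect the inference. Gene conversion between paralogs
homogenises them within one species, so a converted set shows a paralog
`ds` in one species far below the shared duplication age;
`gene_conversion_check()` correlates `ds(M1–M2)` with `ds(R1–R2)` across
sets and flags sets falling below half the major-axis prediction.
Synteny decides which copy occupies the ancestral position:
`classify_old_new()` calls the copy whose flanking neighbours contain
orthologs of the outgroup gene's neighbours the *original*, the other the
*novel* copy; adjacent (tandem) paralogs and ambiguous cases are set
aside. `novel_fast_test()` is a one-sided exact binomial test of whether
the faster-evolving copy is the novel copy more often than chance
(p = 1/2). An exact binomial is used deliberately: the observation per
duplication is a single Bernoulli outcome, so no 2×2 contingency
structure exists that would call for a different exact test.

## The simulator

`simulation_scenario()`/`simulate_sextuplet()` draw root codons from the
stationary distribution and evolve them down the sextuplet tree with
per-class ω. The defaults encode the asymmetric-acceleration regime the
package is designed to detect: ω = 0.10 before duplication, recent
postduplication ω = 0.25 for one copy and 0.10 for the other (so true
`delta_f` = 0.15, `delta_s` = 0), initial postduplication ω = 0.40 on
both internal branches, κ = 2.5, paralog synonymous depth 0.3, outgroup
depth 0.15, 500 codons. Branch lengths are solved from synonymous-depth
targets by inverting the flux decomposition, so scenarios are specified
in `ds` units. The simulator deliberately omits indels, alignment error,
rate variation among sites, selection on codon usage, and lineage
sorting; fixtures for gene conversion (`apply_gene_conversion()`),
multi-duplication families (`simulate_family()`), homology tables and
synteny neighbourhoods carry machine-readable truth labels instead.

## Reproducibility and limitations

Every stochastic step takes an explicit seed; the pipeline derives one
sub-seed per set from its master seed and restores the caller's RNG
state afterwards. Known limitations: ω is constant across sites within a
class, so site-specific positive selection is diluted; the pairwise
design cannot estimate the internal-branch contrasts; NG86 becomes
biased as divergence grows; and the synteny classifier depends on
neighbourhood conservation, so rearranged regions stay unresolved.
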