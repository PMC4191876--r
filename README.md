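# coevosite

Evolutionary correlations between regulatory sites in aligned 3'UTRs.

miRNA seed matches are short, weakly conserved, and densely packed in
3'UTRs. `coevosite` asks two questions about them: is an individual site
conserved *beyond* the background of its own UTR, and did two sites evolve
*together* rather than independently — across the same 3'UTR, across genes
of the same protein complex or pathway, or between miRNA families. Both
signals are easily faked by phylogeny (related species share sites by
ancestry) and by UTR-level heterogeneity, so the package is built around a
background model that accounts for both, plus matched-control machinery for
everything the model cannot capture. It is aimed at computational
biologists working with reference-anchored multiple alignments (MAF),
TargetScan-style seed families, and curated gene sets.

## The model

The background is a Markov random field on the species phylogeny with
hidden ancestral nodes. A configuration `x` of presence/absence states over
all nodes has weight

    W(x) = exp( Σ_edges β_e·1[x_u = x_v] + Σ_nodes h_v·x_v )

where the agreement couplings `β_e` play the branch-length role and the
per-node fields `h_v` let the equilibrium presence probability decay along
the tree, as background K-mer conservation does in real alignments.
Parameters are fitted per gene class so that the model reproduces the
empirical per-species and per-species-pair K-mer conservation frequencies.

A site's conservation score σ tilts all nodes toward presence
(`exp(σ·Σ_v x_v)`, hidden ancestors integrated out exactly by sum-product
message passing); its maximum-likelihood value and the log-likelihood ratio
`D` against σ = 0 measure preferential conservation. A pair of sites is
coupled through `exp(J·Σ_v x_v y_v)` on the composite state; the
log-likelihood ratio `ΔL` of the joint fit `(σ₁, σ₂, J)` against the two
independent fits measures evolutionary correlation, with the sign of `Ĵ`
giving its direction. Enrichment of correlated pairs over
conservation-matched, biased-bootstrap-resampled control seed pairs is
tested with Poisson statistics, and positive-versus-negative excess with
the Skellam distribution.

## A worked example

```r
library(coevosite)

# a 10-species background model with conservation decaying from the reference
tree <- random_phylogeny(10, seed = 42)
round(model_marginals(tree)$p_s, 2)
#>  sp2  sp3  sp4  sp5  sp6  sp7  sp8  sp9 sp10
#> 0.06 0.73 0.07 0.08 0.03 0.65 0.62 0.10 0.86

# score one site: present in 6 of 9 non-reference species
pat <- conservation_pattern(
  c(sp1 = 1, sp2 = 1, sp3 = 1, sp4 = 1, sp5 = 0, sp6 = 1,
    sp7 = 1, sp8 = 0, sp9 = 1, sp10 = 0))
fit <- fit_sigma(tree, pat)
#> sigma_hat = 1.57, D = 4.71

# a coupled pair: sampled at J = 2.5, then re-inferred
pp <- sample_pattern_pairs(tree, tree, -1, -1, J = 2.5, n = 1, seed = 7)[[1]]
pair <- fit_pair(tree, tree, pp$x, pp$y)
#> J_hat = 10.00, deltaL = 2.51, sign = positive
```

The site's `sigma_hat = 1.57` says this pattern is about `e^1.57 ≈ 4.8`-fold
more retained per node than background 7-mers of its gene class would
predict, and `D = 4.71` is the log-likelihood support for that tilt. The
pair's `deltaL = 2.51` exceeds the default correlation cutoff of 2, so the
pair is called positively correlated; here the two sampled patterns happen
to coincide exactly, which pushes `Ĵ` to its search bound — the reason
analyses downstream read `ΔL` and the sign rather than the magnitude of
`Ĵ`.

The full pipeline (stitch MAF → scan seeds → fit background → score sites
and pairs → controls → enrichment) runs from a YAML config:

```r
run_pipeline(list(paths = list(), seed = 1, out_dir = "run",
                  params = list(n_classes = 2, n_bins = 4,
                                n_controls = 200, n_ctrl = 25, B = 50),
                  simulate = list()))   # synthetic bundle, no downloads
```

or from the shell via `exec/coevosite <stage ...> --config run.yaml`. On
the default synthetic bundle the planted close-pair category comes out
Poisson-enriched (observed 7 correlated pairs against a control mean of
0.67, `p ≈ 6.7e-06` in the run above), while distant, unplanted categories
stay at their control level.

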