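# superexon

Superstatistical analysis of exon-length series in R.

## The problem

The exons of a chromosome, ordered by genomic position, define a discrete
"time series" of lengths l(t) in base pairs. Coding regions show
short-range correlations, and the marginal length distribution — peaked
near 10² bp with a heavy power-law tail — is far from any single
equilibrium law. Superstatistics models this as a superposition of local
equilibria: within a stretch of the chromosome, lengths follow a simple
conditional law with local mean ξ; ξ itself fluctuates slowly, persisting
over a long scale T while lengths decorrelate over a short relaxation
scale t₁ ≪ T. The marginal is then the mixture

    p(l) = ∫ f(l | ξ) p(ξ) dξ.

Two pairings close this integral exactly:

| local law f(l|ξ)            | mixing law p(ξ)            | marginal            |
|-----------------------------|----------------------------|---------------------|
| gamma (shape k, mean ξ)     | inverse gamma (μ, ω)       | **q-Gamma**         |
| inverse gamma (α, mean ξ)   | gamma (δ, ω)               | **inverse q-Gamma** |

with q-Gamma `p(l) = A (l/σ)^a exp_q(−l/σ)` and inverse q-Gamma
`p(l) = A (l/σ)^(−α−2) exp_q(−σ/l)`, where
`exp_q(−u) = [1 + (q−1)u]^(−1/(q−1))` is the Tsallis q-exponential. The
entropic index q > 1 measures how broadly ξ fluctuates; q → 1 recovers
the classical gamma / inverse gamma. The closed-form mappings are
`a = k−1, q = 1 + 1/(k+μ), σ = ω/(k(k+μ))` and
`q = 1 + 1/(α+δ+1), σ = αω(α+δ+1)`, validated in the tests against
numerical quadrature of the mixture integral.

The package is for researchers who want to run this analysis end to end
on a genome annotation (or on synthetic data with known truth):
timescale extraction from the autocorrelation, windowed local and mixing
fits, Levenberg–Marquardt marginal fits, and Bayesian model comparison
between the two families via nested-sampling evidences and the Jeffreys
scale.

## Worked example

Generate a synthetic chromosome with the full superstatistical structure
(gamma local law k = 0.5, inverse-gamma mixing μ = 15, ω = 4000,
persistence T = 121, relaxation t₁ = 1.3), then run the pipeline:

```r
library(superexon)

cfg <- synthetic_config("gamma_local_invgamma_mixing", local_shape = 0.5,
                        mixing = list(mu = 15, omega = 4000),
                        T_true = 121, t1_true = 1.3, n = 1e5, seed = 42)
g <- generate_series(cfg)
g$series
#> exon_series: synthetic, n = 100000 exons, lengths 1-9145 bp (median 126)
g$truth$marginal
#> q-Gamma params: a = -0.5, sigma = 516.1 bp, q = 1.065, A = 0.001066 (constrained)

report <- run_chromosome(g$series, run_config(seed = 42))
report
#> chromosome_report: synthetic (100000 exons, status ok)
#> timescale_fit: t1 = 1.099, t2 = 148.7, ratio t2/t1 = 135.3 (scales separated), rss = 0.00908
#>   q-Gamma fit:          q = 1.0825
#>   inverse q-Gamma fit:  q = 1.0825
```

Reading the output: the autocorrelation separates a short relaxation
scale (t₁ ≈ 1.1 exons) from a long persistence scale (t₂ ≈ 149), ratio
135 ≫ 10, so the superstatistical premise holds for this series; the
fitted entropic index q ≈ 1.08 sits near the generator's mixture-implied
q = 1.0645 (the median over ten seeds lands within ±0.02; a single seed
fluctuates a bit more). For real data, build the series with
`parse_exons()` + `build_series()` from a GFF3 file instead of the
generator, and add `run_evidence = TRUE` to compare the two families by
Bayes factor:

```r
recs   <- parse_exons("annotation.gff3", chromosome_filter = "chr1")
series <- build_series(recs, "chr1")
report <- run_chromosome(series, run_config(run_evidence = TRUE, seed = 1))
```

The `analysis/` directory holds the narrative workflow
(`01_simulate.R` … `05_bayes.R`: simulate → timescales → local/mixing
fits → marginal fits → Bayes comparison), each a thin driver over the
package functions that prints what it finds and writes its tables under
`results/`. `analysis/06_real_data.R` documents the manual NCBI fetch
recipe for running on current genome annotations (network required,
annotation-version drift expected).

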