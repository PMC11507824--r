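#!/usr/bin/env Rscript
# Fit the q-Gamma and inverse q-Gamma marginals to each chromosome's binned
# length density (linear box scale, Levenberg-Marquardt, constrained
# normalization) and compare the recovered entropic index with the
# generator's ground truth.

suppressPackageStartupMessages(library(superexon))
truth <- jsonlite::read_json("results/synthetic/ground_truth.json")
files <- Sys.glob("results/synthetic/chr*.tsv")
rows <- list()
for (f in files) {
  nm <- sub("[.]tsv$", "", basename(f))
  s <- read_series(f, chromosome = nm)
  d <- binned_density(s)
  write_density(d, sprintf("results/density_%s.tsv", nm))
  fq <- fit_marginal(d, "q_gamma")
  fi <- fit_marginal(d, "inv_q_gamma")
  q_true <- truth[[nm]]$q
  cat(sprintf("%s: q_G = %.4f, q_IG = %.4f (generator marginal q = %.4f)\n",
              nm, fq$params$q, fi$params$q, q_true))
  rows[[nm]] <- data.frame(
    chromosome = nm, q_true = q_true,
    q_G = fq$params$q, a_G = fq$params$a, sigma_G = fq$params$sigma,
    rss_G = fq$rss,
    q_IG = fi$params$q, alpha_IG = fi$params$alpha,
    sigma_IG = fi$params$sigma, rss_IG = fi$rss)
}
tab <- do.call(rbind, rows)
write.table(tab, "results/marginal_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

gamma_chrs <- tab[startsWith(tab$chromosome, "chr") & tab$chromosome != "chr_inv", ]
cat(sprintf("\nmean q_G over gamma-flavour chromosomes: %.4f +/- %.4f (truth %.4f)\n",
            mean(gamma_chrs$q_G), sd(gamma_chrs$q_G) / sqrt(nrow(gamma_chrs)),
            gamma_chrs$q_true[1]))
cat("tables written to results/marginal_fits.tsv and results/density_*.tsv\n")
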