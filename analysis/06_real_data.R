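#!/usr/bin/env Rscript
# Optional, network-dependent: run the pipeline on a real genome annotation.
#
# This script is NOT part of the offline analysis; it documents the manual
# fetch recipe and runs only if you have already downloaded an annotation.
# Current annotation releases drift from older ones, so recovered numbers
# (e.g. melon chromosome 1: t1 ~ 1.27, t2 ~ 121, per-chromosome evidences,
# genus-mean entropic indices q_G ~ 1.17, q_IG ~ 1.09 for Cucumis) are soft
# reference points, not fixed targets.
#
# Fetch recipe (melon shown; any of the five cucurbit species works):
#   1. Find the current RefSeq assembly, e.g. via NCBI datasets:
#        datasets download genome taxon "Cucumis melo" --include gff3
#      or download the *_genomic.gff.gz directly from
#        https://ftp.ncbi.nlm.nih.gov/genomes/refseq/plant/Cucumis_melo/
#   2. gunzip the GFF3 and pass its path plus a chromosome id below.
#
# Usage:
#   Rscript analysis/06_real_data.R <annotation.gff3> <chromosome_id>

suppressPackageStartupMessages(library(superexon))
args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2) {
  cat("No annotation supplied; see the fetch recipe in this script's header.\n")
  quit(status = 0)
}
recs <- parse_exons(args[1], chromosome_filter = args[2])
s <- build_series(recs, args[2])
cat(sprintf("%s: %d exons\n", args[2], length(s)))
rep <- run_chromosome(s, run_config(run_evidence = TRUE, nlive = 100, seed = 1))
print(rep)
dir.create("results", showWarnings = FALSE)
report_to_json(rep, sprintf("results/real_%s.json", args[2]))
cat(sprintf("report written to results/real_%s.json\n", args[2]))
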