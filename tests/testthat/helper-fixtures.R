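# Shared fixtures, built in code.

# three exons on one chromosome: lengths 100, 150, 11
gff3_lines <- function(chrom = "T1") {
  c("##gff-version 3",
    sprintf("%s\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1", chrom),
    sprintf("%s\tsrc\texon\t301\t450\t.\t+\t.\tParent=g1", chrom),
    sprintf("%s\tsrc\texon\t460\t470\t.\t-\t.\tParent=g2", chrom))
}

# exact two-exponential correlogram, no noise
exact_correlogram <- function(a, b, t1, t2, tau_max = 600) {
  tau <- 0:tau_max
  structure(list(lags = tau, values = a * exp(-tau / t1) + b * exp(-tau / t2)),
            class = "correlogram")
}

quiet <- function(expr) suppressWarnings(expr)
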