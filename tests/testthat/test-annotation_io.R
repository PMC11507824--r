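test_that("GFF3 exons parse with inclusive-coordinate lengths", {
  recs <- parse_exons(gff3_lines())
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$length, c(100L, 150L, 11L))
  expect_equal(recs$strand, c("+", "+", "-"))
  expect_equal(recs$gene_id, c("g1", "g1", "g2"))
})

test_that("filtering to an absent chromosome is an empty-input error", {
  expect_error(parse_exons(gff3_lines(), chromosome_filter = "T2"),
               class = "superexon_empty_input")
})

test_that("malformed lines raise parse errors naming the line", {
  bad <- c(gff3_lines(), "T1\tsrc\texon\t500\t400\t.\t+\t.\tID=x")
  expect_error(parse_exons(bad), "line 5", class = "superexon_parse_error")
  short <- c("##gff-version 3", "T1\tsrc\texon")
  expect_error(parse_exons(short), "line 2", class = "superexon_parse_error")
  nonnum <- c("T1\tsrc\texon\tabc\t200\t.\t+\t.\tID=x")
  expect_error(parse_exons(nonnum), "line 1", class = "superexon_parse_error")
})

test_that("series construction orders by start with stable tie-breaks", {
  recs <- parse_exons(gff3_lines())
  s <- build_series(recs, "T1")
  expect_s3_class(s, "exon_series")
  expect_equal(s$lengths, c(100L, 150L, 11L))
  expect_equal(s$indices, 1:3)
  # same start: smaller end first
  ties <- data.frame(chromosome = "c", start = c(10L, 10L), end = c(30L, 19L),
                     strand = "+", gene_id = NA_character_)
  expect_equal(build_series(ties, "c")$lengths, c(10L, 21L))
  expect_error(build_series(recs, "nope"), class = "superexon_empty_input")
})

test_that("input order does not matter under by_start ordering", {
  set.seed(41)
  recs <- parse_exons(gff3_lines())
  for (i in 1:5) {
    perm <- recs[sample(nrow(recs)), ]
    expect_equal(build_series(perm, "T1"), build_series(recs, "T1"))
  }
})

test_that("dedup collapses exact-duplicate intervals only", {
  recs <- rbind(parse_exons(gff3_lines()), parse_exons(gff3_lines())[1, ])
  expect_equal(length(build_series(recs, "T1")$lengths), 4L)
  expect_equal(length(build_series(recs, "T1", dedup = TRUE)$lengths), 3L)
})

test_that("series TSV round-trips a large synthetic series exactly", {
  set.seed(7)
  s <- exon_series(sample(1:5000, 10000, replace = TRUE), chromosome = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(s, path)
  r <- read_series(path, chromosome = "rt")
  expect_identical(r$lengths, s$lengths)
  expect_identical(r$indices, s$indices)
})

test_that("series validation rejects non-positive or fractional lengths", {
  expect_error(exon_series(c(10, 0, 5)), class = "superexon_validation_error")
  expect_error(exon_series(c(10.5, 3)), class = "superexon_validation_error")
  expect_error(exon_series(numeric(0)), class = "superexon_empty_input")
})
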