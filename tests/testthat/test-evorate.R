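# miRNA sequence divergence from alignment blocks; rate-table I/O.

iv <- function(id = "mir1", chrom = "chr1", start = 100, end = 122,
               strand = "+") {
  tibble::tibble(id = id, chrom = chrom, start = start, end = end,
                 strand = strand)
}

test_that("divergence is 0 on identity and 1 on full mismatch", {
  ref <- paste(rep("A", 22), collapse = "")
  blocks <- toy_block("chr1", 100, ref, ref)
  r <- mirna_divergence(blocks, iv())
  expect_equal(r$rate, 0)
  expect_equal(r$n_sites, 22)
  expect_equal(r$status, "ok")
  all_mm <- toy_block("chr1", 100, ref, paste(rep("G", 22), collapse = ""))
  expect_equal(mirna_divergence(all_mm, iv())$rate, 1)
})

test_that("gap columns are excluded from numerator and denominator", {
  # 23-column block over a 22-nt interval: 2 substitutions, 1 query gap
  ref <- paste(c(rep("A", 10), "C", rep("A", 12)), collapse = "")   # 23 ungapped
  qry <- paste(c(rep("A", 3), "G", rep("A", 6), "-", rep("A", 7), "G",
                 rep("A", 4)), collapse = "")
  stopifnot(nchar(ref) == 23, nchar(qry) == 23)
  blocks <- toy_block("chr1", 100, ref, qry)
  r <- mirna_divergence(blocks, iv(start = 100, end = 122))
  expect_equal(r$n_sites, 21)
  expect_equal(r$n_subs, 2)
  expect_equal(r$rate, 2 / 21)
})

test_that("reference gaps do not consume reference coordinates", {
  # insertion in query: ref gap column sits between positions
  blocks <- toy_block("chr1", 100, "AAAA-AAAA", "AAAATAAAA")
  blocks$ref_end <- 108
  r <- mirna_divergence(blocks, iv(start = 100, end = 108))
  expect_equal(r$n_sites, 8)
  expect_equal(r$rate, 0)
})

test_that("comparison is case-insensitive", {
  blocks <- toy_block("chr1", 100, "ACGTacgt", "acgtACGT")
  r <- mirna_divergence(blocks, iv(start = 100, end = 108))
  expect_equal(r$rate, 0)
})

test_that("missing or sparse alignment is flagged, not guessed", {
  blocks <- toy_block("chr2", 100, "AAAA", "AAAA")
  r <- mirna_divergence(blocks, iv())
  expect_equal(r$status, "no_alignment")
  expect_true(is.na(r$rate))
  # covers 8 of 22 positions -> low coverage at the default 0.5 threshold
  part <- toy_block("chr1", 100, "AAAAAAAA", "AAAAAAAA")
  r2 <- mirna_divergence(part, iv())
  expect_equal(r2$status, "low_coverage")
  expect_equal(r2$aligned_fraction, 8 / 22)
})

test_that("divergence is invariant under reverse-complementing the alignment", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  rc <- function(s) chartr("ACGT-", "TGCA-", paste(rev(strsplit(s, "")[[1]]),
                                                   collapse = ""))
  for (i in 1:5) {
    ref <- paste(sample(bases, 30, TRUE), collapse = "")
    qry <- paste(ifelse(runif(30) < 0.2, sample(bases, 30, TRUE),
                        strsplit(ref, "")[[1]]), collapse = "")
    fwd <- mirna_divergence(toy_block("chr1", 50, ref, qry),
                            iv(start = 50, end = 80))
    rev <- mirna_divergence(toy_block("chr1", 50, rc(ref), rc(qry)),
                            iv(start = 50, end = 80, strand = "-"))
    expect_equal(rev$rate, fwd$rate)
    expect_equal(rev$n_sites, fwd$n_sites)
  }
})

test_that("overlapping blocks warn and the first block wins", {
  b1 <- toy_block("chr1", 100, "AAAAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAAAAAA")
  b2 <- toy_block("chr1", 110, "AAAAAAAAAAAAAAAAAAAAAA", "GGGGGGGGGGGGGGGGGGGGGG")
  expect_warning(r <- mirna_divergence(rbind(b1, b2), iv()), "first block wins")
  expect_equal(r$rate, 0)  # positions 100..121 all resolved by block 1
})

test_that("mean divergence converges to the substitution probability", {
  n_iv <- 300; width <- 80; p <- 0.05
  cfg <- synthetic_config(n_tf = 2, n_mirna = 2, n_gene = 2, n_tf_gene = 1,
                          n_tf_mirna = 1, n_mirna_target = 1,
                          subst_prob = p, gap_prob = 0.02,
                          interval_width = width, seed = 6)
  ivs <- tibble::tibble(id = sprintf("m%03d", seq_len(n_iv)),
                        chrom = paste0("chr", (seq_len(n_iv) - 1) %% 5 + 1),
                        start = 1000 + 1000 * ((seq_len(n_iv) - 1) %/% 5),
                        end = 1000 + 1000 * ((seq_len(n_iv) - 1) %/% 5) + width,
                        strand = "+")
  dt <- divergence_table(generate_alignments(ivs, cfg), ivs)
  se <- sqrt(p * (1 - p) / (n_iv * width))
  expect_lt(abs(mean(dt$rate) - p), 3 * se)
  # and is exactly zero when nothing is substituted
  cfg0 <- synthetic_config(n_tf = 2, n_mirna = 2, n_gene = 2, n_tf_gene = 1,
                           n_tf_mirna = 1, n_mirna_target = 1,
                           subst_prob = 0, gap_prob = 0, seed = 6)
  dt0 <- divergence_table(generate_alignments(ivs[1:20, ], cfg0), ivs[1:20, ])
  expect_true(all(dt0$rate == 0))
})

test_that("AXT blocks round-trip through write and read", {
  set.seed(12)
  cfg <- synthetic_config(n_tf = 2, n_mirna = 2, n_gene = 2, n_tf_gene = 1,
                          n_tf_mirna = 1, n_mirna_target = 1, seed = 2)
  ivs <- iv(id = c("m1", "m2"), chrom = c("chr1", "chr2"),
            start = c(100, 200), end = c(180, 280))
  blocks <- generate_alignments(ivs, cfg)
  path <- withr::local_tempfile(fileext = ".axt")
  write_axt(blocks, path)
  back <- read_axt(path)
  expect_equal(as.data.frame(back), as.data.frame(blocks))
})

test_that("rate tables round-trip and invalid tables are rejected", {
  rates <- c(g1 = 0.05, g2 = 0.10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rates, path)
  expect_equal(load_rate_table(path), rates)
  writeLines(c("id\trate", "g1\t-0.1"), path)
  expect_error(load_rate_table(path), "negative")
  writeLines(c("id\trate", "g1\t0.1", "g1\t0.2"), path)
  expect_error(load_rate_table(path), "duplicate")
  writeLines(c("id\trate", "g1\tfast"), path)
  expect_error(load_rate_table(path), "non-numeric")
})

test_that("BED intervals round-trip with 0-based half-open coordinates", {
  ivs <- tibble::tibble(id = c("mir-a", "mir-b"), chrom = c("chr1", "chr3"),
                        start = c(999L, 5000L), end = c(1079L, 5080L),
                        strand = c("+", "-"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed6(ivs, path)
  back <- read_bed6(path)
  expect_equal(as.data.frame(back[, c("id", "chrom", "start", "end", "strand")]),
               as.data.frame(ivs))
})
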