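# Evolutionary rates: miRNA sequence divergence from pairwise alignment
# blocks, and ingestion of protein dN tables.
#
# Divergence is the raw per-aligned-site substitution proportion over
# the alignment columns falling inside a miRNA's genomic interval:
# columns with a gap in either sequence are excluded from numerator and
# denominator. No multiple-hit correction is applied by default; the
# primate-scale distances this targets are small enough that the raw
# proportion and a Jukes-Cantor correction are nearly identical
# (a `jukes_cantor` switch is provided anyway).

#' Read pairwise alignment blocks in AXT format
#'
#' AXT summary lines carry 1-based inclusive reference coordinates;
#' internally the package is 0-based half-open, so `ref_start` in the
#' result is `start - 1`. Comment lines (`#`) and blank lines are
#' skipped.
#'
#' @param path path to an uncompressed AXT file.
#' @return tibble with `ref_chrom`, `ref_start` (0-based), `ref_end`
#'   (half-open), `ref_aln`, `query_aln`.
#' @export
read_axt <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[cumsum(nzchar(lines)) > 0 | nzchar(lines)]  # keep structure
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0) {
    stop_fmt("malformed AXT in %s: %d non-blank lines, expected multiples of 3",
             path, length(lines))
  }
  idx <- seq(1, length(lines), by = 3)
  blocks <- lapply(idx, function(i) {
    hdr <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(hdr) < 9) stop_fmt("malformed AXT header at line %d of %s", i, path)
    ref_aln <- lines[i + 1]; query_aln <- lines[i + 2]
    if (nchar(ref_aln) != nchar(query_aln)) {
      stop_fmt("AXT block %s: sequence lines of unequal length", hdr[1])
    }
    start1 <- as.integer(hdr[3]); end1 <- as.integer(hdr[4])
    ungapped <- nchar(gsub("-", "", ref_aln))
    if (ungapped != end1 - start1 + 1) {
      stop_fmt("AXT block %s: ungapped reference length %d does not span %d-%d",
               hdr[1], ungapped, start1, end1)
    }
    list(ref_chrom = hdr[2], ref_start = start1 - 1L, ref_end = end1,
         ref_aln = ref_aln, query_aln = query_aln)
  })
  tibble::tibble(
    ref_chrom = vapply(blocks, `[[`, character(1), "ref_chrom"),
    ref_start = vapply(blocks, function(b) as.integer(b$ref_start), integer(1)),
    ref_end = vapply(blocks, function(b) as.integer(b$ref_end), integer(1)),
    ref_aln = vapply(blocks, `[[`, character(1), "ref_aln"),
    query_aln = vapply(blocks, `[[`, character(1), "query_aln"))
}

#' Write alignment blocks in AXT format
#' @param blocks tibble as returned by [read_axt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_axt <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    writeLines(c(
      sprintf("%d %s %d %d query %d %d + 1000", i - 1L, b$ref_chrom,
              b$ref_start + 1L, b$ref_end, 1L,
              nchar(gsub("-", "", b$query_aln))),
      b$ref_aln, b$query_aln, ""), con)
  }
  invisible(path)
}

#' Read miRNA genomic intervals from a BED6 file
#'
#' Parsed through `rtracklayer`; coordinates are returned 0-based
#' half-open, matching BED's native convention.
#'
#' @param path path to a BED file with at least name and strand columns.
#' @return tibble with `id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || any(is.na(nm))) stop_fmt("BED file %s lacks interval names", path)
  tibble::tibble(
    id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)))
}

#' Write intervals as BED6
#' @param intervals tibble with `id`, `chrom`, `start` (0-based), `end`,
#'   `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(intervals, path) {
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   intervals$id, 0L,
                   ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "+"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# per-column reference coordinates of a block; NA at reference gaps
block_ref_positions <- function(ref_aln, ref_start) {
  chars <- strsplit(ref_aln, "")[[1]]
  pos <- rep(NA_integer_, length(chars))
  ungapped <- chars != "-"
  pos[ungapped] <- ref_start + seq_len(sum(ungapped)) - 1L
  list(chars = chars, pos = pos)
}

#' miRNA sequence divergence over one genomic interval
#'
#' Scans the alignment columns whose reference coordinate falls in
#' `[start, end)`. A column counts as an aligned site when both species
#' have a base there (no gap); it counts as a substitution when the two
#' bases differ case-insensitively. Divergence = substitutions / aligned
#' sites. When overlapping blocks cover the same reference position the
#' first block wins (with a warning); best-chain pairwise alignments are
#' non-overlapping in practice.
#'
#' @param blocks alignment blocks tibble (see [read_axt()]).
#' @param interval one-row tibble or list with `id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param min_fraction minimum aligned-site fraction of the interval
#'   length below which the estimate is flagged `low_coverage` (default
#'   0.5); flagged rates are excluded from analyses by default.
#' @param jukes_cantor apply the Jukes-Cantor multiple-hit correction
#'   \eqn{-\frac{3}{4}\log(1 - \frac{4}{3}\hat p)} (default FALSE).
#' @return list with `id`, `rate` (NA when undefined), `n_subs`,
#'   `n_sites`, `aligned_fraction`, `status` one of `ok`,
#'   `low_coverage`, `no_alignment`.
#' @export
mirna_divergence <- function(blocks, interval, min_fraction = 0.5,
                             jukes_cantor = FALSE) {
  if (interval$start < 0 || interval$start >= interval$end) {
    stop_fmt("invalid interval for %s", interval$id)
  }
  len <- interval$end - interval$start
  hits <- blocks[blocks$ref_chrom == interval$chrom &
                   blocks$ref_end > interval$start &
                   blocks$ref_start < interval$end, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(id = interval$id, rate = NA_real_, n_subs = 0L, n_sites = 0L,
                aligned_fraction = 0, status = "no_alignment"))
  }
  seen <- integer(0)
  n_subs <- 0L; n_sites <- 0L
  overlap_warned <- FALSE
  for (i in seq_len(nrow(hits))) {
    bp <- block_ref_positions(hits$ref_aln[i], hits$ref_start[i])
    qchars <- strsplit(hits$query_aln[i], "")[[1]]
    in_iv <- !is.na(bp$pos) & bp$pos >= interval$start & bp$pos < interval$end
    dup <- in_iv & bp$pos %in% seen
    if (any(dup)) {
      if (!overlap_warned) {
        warn_fmt("overlapping alignment blocks at %s for %s; first block wins",
                 interval$chrom, interval$id)
        overlap_warned <- TRUE
      }
      in_iv <- in_iv & !dup
    }
    seen <- c(seen, bp$pos[in_iv])
    aligned <- in_iv & qchars != "-"
    n_sites <- n_sites + sum(aligned)
    n_subs <- n_subs + sum(aligned &
                             toupper(bp$chars) != toupper(qchars))
  }
  frac <- n_sites / len
  if (n_sites == 0) {
    return(list(id = interval$id, rate = NA_real_, n_subs = 0L, n_sites = 0L,
                aligned_fraction = 0, status = "no_alignment"))
  }
  p <- n_subs / n_sites
  if (jukes_cantor) {
    p <- if (p >= 0.75) NA_real_ else -0.75 * log1p(-4 * p / 3)
  }
  list(id = interval$id, rate = p, n_subs = as.integer(n_subs),
       n_sites = as.integer(n_sites), aligned_fraction = frac,
       status = if (frac < min_fraction) "low_coverage" else "ok")
}

#' Divergence for a set of miRNA intervals
#'
#' @inheritParams mirna_divergence
#' @param intervals tibble of intervals (see [read_bed6()]).
#' @return tibble with one row per interval: `id`, `rate`, `n_subs`,
#'   `n_sites`, `aligned_fraction`, `status`.
#' @export
divergence_table <- function(blocks, intervals, min_fraction = 0.5,
                             jukes_cantor = FALSE) {
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    tibble::as_tibble(mirna_divergence(blocks, intervals[i, ],
                                       min_fraction = min_fraction,
                                       jukes_cantor = jukes_cantor))
  })
  do.call(rbind, rows)
}

#' Load a two-column rate table (id, rate)
#'
#' @param path TSV path with header `id rate`.
#' @return named numeric vector (a rate table); duplicate ids, negative
#'   or non-numeric rates are errors.
#' @export
load_rate_table <- function(path) {
  df <- read_tsv_plain(path, c("id", "rate"))
  rate <- suppressWarnings(as.numeric(df$rate))
  if (anyNA(rate)) {
    stop_fmt("non-numeric rate for id '%s' in %s", df$id[which(is.na(rate))[1]], path)
  }
  if (any(rate < 0)) {
    stop_fmt("negative rate for id '%s' in %s", df$id[which(rate < 0)[1]], path)
  }
  if (anyDuplicated(df$id)) {
    stop_fmt("duplicate id '%s' in %s", df$id[which(duplicated(df$id))[1]], path)
  }
  stats::setNames(rate, df$id)
}

#' Write a rate table as two-column TSV
#' @param rates named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  write_tsv_plain(data.frame(id = names(rates), rate = unname(rates)), path)
}
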