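#' Simulate paired-end read alignments from a donor genome
#'
#' Fragments are drawn uniformly along each donor chromosome; the two reads
#' are the outermost `read_len` bases of the fragment, sequenced towards each
#' other. `insert_mean`/`insert_sd` parameterize the insert size as it is
#' measured downstream: the distance between the innermost aligned positions
#' of the two reads, so a concordant library yields insert lengths averaging
#' `insert_mean` and pairs spanning a deletion of size `d` average
#' `insert_mean + d`. Reads are mapped back to the
#' reference analytically through the donor-to-reference block map, so the
#' emitted coordinates and strands are exactly what a perfect aligner of
#' uniquely mapping reads would report. A read that straddles a rearrangement
#' junction is emitted unmapped (such reads are only informative for
#' split-read methods).
#'
#' @param donor A `donor_genome` from [apply_svs()], or a plain `DNAStringSet`
#'   (treated as an unrearranged donor identical to the reference).
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Insert-size (fragment-length) distribution in bp;
#'   `insert_mean` must exceed `2 * read_len`.
#' @param coverage Haploid fold-coverage; the number of pairs per chromosome is
#'   `round(coverage * chrom_len / (2 * read_len))`.
#' @param seed Integer seed.
#' @param mapq Mapping quality assigned to mapped reads.
#' @param base_quality Phred base quality assigned to every read.
#' @param low_quality_frac Fraction of pairs downgraded to `low_quality_phred`
#'   (to exercise quality-tier logic).
#' @param low_quality_phred Phred value used for downgraded pairs.
#' @return A tibble with one row per pair: `qname`, and per read `chrom`,
#'   `start`, `end`, `strand`, `mapped`, `mapq`, `baseq` (suffix `1` = the
#'   fragment's leftmost read on the donor, sequenced forward).
#' @export
simulate_read_pairs <- function(donor, read_len = 100, insert_mean = 300,
                                insert_sd = 30, coverage = 30, seed = 1,
                                mapq = 60, base_quality = 40,
                                low_quality_frac = 0, low_quality_phred = 15) {
  if (coverage <= 0) abort("`coverage` must be positive")
  if (insert_mean <= 2 * read_len) abort("`insert_mean` must exceed 2 * read_len")
  if (inherits(donor, "DNAStringSet")) {
    donor <- apply_svs(donor)
  }
  if (!inherits(donor, "donor_genome")) abort("`donor` must be a donor_genome")
  set.seed(seed)
  bm <- donor$block_map
  out <- list()
  for (chrom in names(donor$donor)) {
    L <- Biostrings::width(donor$donor)[names(donor$donor) == chrom]
    n <- round(coverage * L / (2 * read_len))
    if (n < 1) next
    inner <- pmax(1L, as.integer(round(rnorm(n, insert_mean, insert_sd))))
    f <- pmin(inner + 2L * read_len - 1L, L)
    s <- 1L + as.integer(floor(runif(n) * (L - f + 1)))
    r1 <- map_donor_interval(bm, chrom, s, s + read_len - 1L, "+")
    r2 <- map_donor_interval(bm, chrom, s + f - read_len, s + f - 1L, "-")
    q <- rep(base_quality, n)
    if (low_quality_frac > 0) {
      q[runif(n) < low_quality_frac] <- low_quality_phred
    }
    out[[chrom]] <- tibble(
      qname = sprintf("frag_%s_%06d", chrom, seq_len(n)),
      chrom1 = r1$chrom, start1 = r1$start, end1 = r1$end,
      strand1 = r1$strand, mapped1 = r1$mapped,
      chrom2 = r2$chrom, start2 = r2$start, end2 = r2$end,
      strand2 = r2$strand, mapped2 = r2$mapped,
      mapq1 = ifelse(r1$mapped, mapq, 0L), mapq2 = ifelse(r2$mapped, mapq, 0L),
      baseq1 = q, baseq2 = q
    )
  }
  bind_rows(out)
}

# Map donor intervals [s, e] on `chrom` to reference coordinates via the block
# map. `strand` is the orientation of the read on the donor. Intervals that
# cross a block boundary are returned unmapped.
map_donor_interval <- function(block_map, chrom, s, e, strand) {
  bm <- block_map[block_map$donor_chrom == chrom, ]
  bm <- bm[order(bm$donor_start), ]
  idx <- findInterval(s, bm$donor_start)
  ok <- idx >= 1 & e <= bm$donor_end[pmax(idx, 1L)]
  idx[!ok] <- NA_integer_
  ref_chrom <- bm$ref_chrom[idx]
  blk_plus <- !is.na(idx) & bm$strand[idx] == "+"
  off_s <- s - bm$donor_start[idx]
  off_e <- e - bm$donor_start[idx]
  start <- ifelse(blk_plus, bm$ref_start[idx] + off_s, bm$ref_end[idx] - off_e)
  end <- ifelse(blk_plus, bm$ref_start[idx] + off_e, bm$ref_end[idx] - off_s)
  out_strand <- ifelse(blk_plus, strand,
                       ifelse(strand == "+", "-", "+"))
  tibble(
    chrom = ifelse(ok, ref_chrom, NA_character_),
    start = as.integer(ifelse(ok, start, NA)),
    end = as.integer(ifelse(ok, end, NA)),
    strand = ifelse(ok, out_strand, NA_character_),
    mapped = ok
  )
}

#' Write simulated pairs as a SAM file
#'
#' Emits a coordinate-unsorted SAM with proper pairing flags; reads are written
#' with fully matched CIGARs and uniform base-quality strings, which is all
#' downstream analysis consumes. Sort/convert with samtools or
#' [Rsamtools::asBam()] as needed.
#'
#' @param pairs Pair tibble from [simulate_read_pairs()].
#' @param path Output path (`.sam`).
#' @param reference `DNAStringSet` (for `@SQ` header lines).
#' @export
write_sam <- function(pairs, path, reference) {
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                Biostrings::width(reference))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted", sq)
  rl1 <- ifelse(pairs$mapped1, pairs$end1 - pairs$start1 + 1L, 100L)
  rl2 <- ifelse(pairs$mapped2, pairs$end2 - pairs$start2 + 1L, 100L)
  flag_of <- function(mapped, strand, m_mapped, m_strand, first) {
    1L +
      ifelse(mapped, 0L, 4L) +
      ifelse(m_mapped, 0L, 8L) +
      ifelse(mapped & strand == "-", 16L, 0L) +
      ifelse(m_mapped & m_strand == "-", 32L, 0L) +
      ifelse(first, 64L, 128L)
  }
  line_of <- function(mapped, chrom, start, strand, mapq, baseq, rl, flag) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            pairs$qname, flag,
            ifelse(mapped, chrom, "*"),
            ifelse(mapped, start, 0L),
            ifelse(mapped, mapq, 0L),
            ifelse(mapped, paste0(rl, "M"), "*"),
            strrep("N", rl),
            strrep(vapply(baseq + 33L, function(q) rawToChar(as.raw(q)), ""), rl))
  }
  l1 <- line_of(pairs$mapped1, pairs$chrom1, pairs$start1, pairs$strand1,
                pairs$mapq1, pairs$baseq1, rl1,
                flag_of(pairs$mapped1, pairs$strand1, pairs$mapped2,
                        pairs$strand2, TRUE))
  l2 <- line_of(pairs$mapped2, pairs$chrom2, pairs$start2, pairs$strand2,
                pairs$mapq2, pairs$baseq2, rl2,
                flag_of(pairs$mapped2, pairs$strand2, pairs$mapped1,
                        pairs$strand1, FALSE))
  writeLines(c(hdr, rbind(l1, l2)), path)
  invisible(path)
}

#' Read paired alignments from SAM/BAM into a pair table
#'
#' Loads primary alignments and joins mates by read name (triage): pairs with
#' both ends mapped become mapped-pair records; exactly one end mapped gives a
#' `ONE_END` record and neither end an `ORPHAN` record (category is filled in
#' here; mapped pairs are categorised later by [classify_pairs()]).
#'
#' @param path A `.sam` or `.bam` file.
#' @return Pair tibble in the [simulate_read_pairs()] schema plus a `category`
#'   column (`NA` for mapped pairs).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "strand", "mapq", "qual"),
    flag = flags
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  baseq <- vapply(as.character(b$qual), function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_integer_)
    min(utf8ToInt(q)) - 33L
  }, integer(1), USE.NAMES = FALSE)
  mapped <- bitwAnd(b$flag, 4L) == 0L
  reads <- tibble(
    qname = b$qname,
    first = bitwAnd(b$flag, 64L) > 0L,
    mapped = mapped,
    chrom = as.character(b$rname),
    start = b$pos,
    end = b$pos + ifelse(is.na(b$qwidth), 1L, b$qwidth) - 1L,
    strand = ifelse(!mapped, NA_character_,
                    ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+")),
    mapq = ifelse(is.na(b$mapq), 0L, b$mapq),
    baseq = ifelse(is.na(baseq), 0L, baseq)
  )
  triage_pairs(reads)
}

#' Join per-read records into pair records
#'
#' @param reads Tibble with columns `qname`, `first`, `mapped`, `chrom`,
#'   `start`, `end`, `strand`, `mapq`, `baseq` (one row per primary alignment).
#' @return Pair tibble; `category` is `ONE_END`/`ORPHAN` for incompletely
#'   mapped pairs and `NA` for mapped pairs.
#' @export
triage_pairs <- function(reads) {
  r1 <- reads[reads$first, ]
  r2 <- reads[!reads$first, ]
  names(r2) <- paste0(names(r2), "_m")
  j <- dplyr::inner_join(r1, r2, by = c(qname = "qname_m"))
  pairs <- tibble(
    qname = j$qname,
    chrom1 = j$chrom, start1 = j$start, end1 = j$end, strand1 = j$strand,
    mapped1 = j$mapped,
    chrom2 = j$chrom_m, start2 = j$start_m, end2 = j$end_m, strand2 = j$strand_m,
    mapped2 = j$mapped_m,
    mapq1 = j$mapq, mapq2 = j$mapq_m, baseq1 = j$baseq, baseq2 = j$baseq_m
  )
  pairs$category <- dplyr::case_when(
    pairs$mapped1 & pairs$mapped2 ~ NA_character_,
    pairs$mapped1 | pairs$mapped2 ~ "ONE_END",
    TRUE ~ "ORPHAN"
  )
  pairs
}

#' Expand a pair table into one row per mapped read
#'
#' Used by the read-depth module, which counts every mapped read including the
#' anchored end of one-end-anchored pairs.
#'
#' @param pairs Pair tibble.
#' @return Tibble with `qname`, `chrom`, `start`, `end`, `strand`.
#' @export
reads_from_pairs <- function(pairs) {
  r1 <- pairs[pairs$mapped1, c("qname", "chrom1", "start1", "end1", "strand1")]
  r2 <- pairs[pairs$mapped2, c("qname", "chrom2", "start2", "end2", "strand2")]
  names(r1) <- names(r2) <- c("qname", "chrom", "start", "end", "strand")
  bind_rows(r1, r2)
}

#' Write the planted-SV truth table
#'
#' @param donor A `donor_genome`.
#' @param path Output TSV path.
#' @export
write_truth <- function(donor, path) {
  readr::write_tsv(donor$truth, path)
  invisible(path)
}
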