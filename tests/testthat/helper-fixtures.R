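# Shared in-code fixtures; everything is generated at test time.

# Minimal hand-built pair record(s); defaults describe a concordant pair.
make_pair <- function(qname = "p1", chrom1 = "chr1", start1 = 1000, end1 = 1099,
                      strand1 = "+", chrom2 = "chr1", start2 = 1300, end2 = 1399,
                      strand2 = "-", mapped1 = TRUE, mapped2 = TRUE,
                      mapq1 = 60, mapq2 = 60, baseq1 = 40, baseq2 = 40) {
  tibble::tibble(
    qname = qname, chrom1 = chrom1, start1 = as.integer(start1),
    end1 = as.integer(end1), strand1 = strand1, mapped1 = mapped1,
    chrom2 = chrom2, start2 = as.integer(start2), end2 = as.integer(end2),
    strand2 = strand2, mapped2 = mapped2,
    mapq1 = as.integer(mapq1), mapq2 = as.integer(mapq2),
    baseq1 = as.integer(baseq1), baseq2 = as.integer(baseq2)
  )
}

# Fixed insert model with known cut-offs (no estimation noise).
make_model <- function(lc = 200, uc = 400, alpha = 0.01) {
  structure(
    tibble::tibble(library = "lib1", alpha = alpha, lc = lc, uc = uc,
                   median_l = (lc + uc) / 2, mean_l = (lc + uc) / 2,
                   sd_l = (uc - lc) / (2 * qnorm(1 - alpha / 2)),
                   n_obs = 10000L, low_n = FALSE),
    class = c("insert_model", "tbl_df", "tbl", "data.frame")
  )
}

# Window tibble wrapping a plain y signal (one window per value, 100 bp grid).
make_signal_windows <- function(y, chrom = "chr1", window_size = 100,
                                masked = FALSE) {
  n <- length(y)
  tibble::tibble(
    chrom = chrom,
    start = seq_len(n) * window_size - window_size + 1L,
    end = seq_len(n) * window_size,
    r = 30L, gc = 0.5, gc_bin = 50L,
    masked = rep_len(masked, n), r_adj = 30, y = y
  )
}

# Brute-force transitive-closure clustering oracle over the pairwise relation
# |dx1| <= d & |dx2| <= d (independent of the sweep implementation).
oracle_closure <- function(x1, x2, d) {
  n <- length(x1)
  adj <- outer(x1, x1, function(a, b) abs(a - b) <= d) &
    outer(x2, x2, function(a, b) abs(a - b) <= d)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# Canonical partition representation for comparing clusterings.
partition_sets <- function(ids, labels) {
  unname(lapply(split(ids, labels), function(x) sort(x)))
}

# Synthetic cluster row with explicit breakpoint intervals (for interpreter
# and filter tests); intervals are half-open [lo, hi).
make_cluster <- function(id, category, chromA, bpA_lo, bpA_hi, chromB, bpB_lo,
                         bpB_hi, s = 10, strand_config = "fr", somatic = FALSE,
                         unreliable = FALSE, q_best = 40) {
  tibble::tibble(
    cluster_id = id, category = category, strand_config = strand_config,
    chrom_1 = chromA, x1_min = as.integer(bpA_lo), x1_max = as.integer(bpA_lo),
    strand_s1 = "+",
    chrom_2 = chromB, x2_min = as.integer(bpB_lo), x2_max = as.integer(bpB_lo),
    strand_s2 = "-",
    s = as.integer(s), q_best = as.integer(q_best),
    members = list(sprintf("%s_m%d", id, seq_len(s))),
    x1s = list(rep(as.integer(bpA_lo), s)), x2s = list(rep(as.integer(bpB_lo), s)),
    chromA = chromA, bpA_lo = as.integer(bpA_lo), bpA_hi = as.integer(bpA_hi),
    chromB = chromB, bpB_lo = as.integer(bpB_lo), bpB_hi = as.integer(bpB_hi),
    unreliable = unreliable, somatic = somatic
  )
}

# Segments tiling [1, n_bp] with given states; bounds is a matrix-like list of
# c(start, end, state) triples.
make_segments <- function(chrom, ...) {
  rows <- list(...)
  tibble::tibble(
    chrom = chrom,
    start = vapply(rows, function(r) as.integer(r[[1]]), 1L),
    end = vapply(rows, function(r) as.integer(r[[2]]), 1L),
    n_windows = (vapply(rows, function(r) as.integer(r[[2]]), 1L) -
                   vapply(rows, function(r) as.integer(r[[1]]), 1L) + 1L) %/% 100L,
    mean_y = vapply(rows, function(r)
      switch(r[[3]], GAIN = 2, LOSS = -2, 0), 1.0),
    state = vapply(rows, function(r) r[[3]], "")
  )
}

# BED writer whose tempdir lives as long as the calling test.
write_bed <- function(lines, name = "track.bed", env = parent.frame()) {
  path <- file.path(withr::local_tempdir(.local_envir = env), name)
  writeLines(lines, path)
  path
}

# A minimal call row with explicit breakpoint intervals.
make_call <- function(id, sv_class, bp1 = c(1000, 1400), bp2 = c(5000, 5400),
                      chrom = "chr1") {
  tibble::tibble(
    call_id = id, sv_class = sv_class,
    reported_type = pairsv:::reported_type_of(sv_class),
    source_chrom = chrom, source_lo = bp1[1], source_hi = bp2[2],
    insert_chrom = NA_character_, insert_lo = NA_integer_,
    insert_hi = NA_integer_, orientation = "direct",
    cluster_ids = list(id), s_total = 5L, rd_state = NA_character_,
    somatic = FALSE, unreliable = FALSE,
    bp1_chrom = chrom, bp1_lo = as.integer(bp1[1]), bp1_hi = as.integer(bp1[2]),
    bp2_chrom = chrom, bp2_lo = as.integer(bp2[1]), bp2_hi = as.integer(bp2[2])
  )
}

# The standard multi-class planted-SV scenario used by end-to-end checks.
eleven_class_specs <- function() {
  dplyr::bind_rows(
    sv_spec("DEL",             "chr1",  20000,  26000),
    sv_spec("DUP_TANDEM",      "chr1",  40000,  46000),
    sv_spec("INV",             "chr1",  60000,  66000),
    sv_spec("GAIN_INTRA",      "chr1",  80000,  86000, "chr1", 100000),
    sv_spec("GAIN_INTRA_INV",  "chr1", 112000, 118000, "chr1", 130000),
    sv_spec("TRANS_INTRA",     "chr1", 142000, 148000, "chr1", 160000),
    sv_spec("TRANS_INTRA_INV", "chr2",  20000,  26000, "chr2",  40000),
    sv_spec("GAIN_INTER",      "chr2",  60000,  66000, "chr1", 172000),
    sv_spec("GAIN_INTER_INV",  "chr2",  80000,  86000, "chr1", 180000),
    sv_spec("TRANS_INTER",     "chr2", 100000, 106000, "chr1", 188000),
    sv_spec("TRANS_INTER_INV", "chr2", 120000, 126000, "chr1", 194000)
  )
}
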