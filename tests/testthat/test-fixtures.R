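test_that("simulated references track the requested GC profile", {
  ref <- simulate_reference(1, 100000, gc = 0.5, seed = 7)
  gc <- Biostrings::letterFrequency(ref[[1]], "GC", as.prob = TRUE)[1]
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)

  at_only <- simulate_reference(1, 1000, gc = 0, seed = 1)
  expect_equal(
    sum(Biostrings::letterFrequency(at_only[[1]], c("G", "C"))), 0
  )

  again <- simulate_reference(1, 100000, gc = 0.5, seed = 7)
  expect_identical(as.character(ref), as.character(again))

  # positional profile is tracked per kb
  grad <- simulate_reference(1, 50000,
                             gc = function(pos) ifelse(pos <= 25000, 0.3, 0.7),
                             seed = 3)
  lo <- Biostrings::letterFrequency(
    Biostrings::subseq(grad[[1]], 1, 25000), "GC", as.prob = TRUE)[1]
  hi <- Biostrings::letterFrequency(
    Biostrings::subseq(grad[[1]], 25001, 50000), "GC", as.prob = TRUE)[1]
  expect_lt(abs(lo - 0.3), 0.05)
  expect_lt(abs(hi - 0.7), 0.05)

  expect_error(simulate_reference(1, -5), "positive")
})

test_that("applying SVs conserves donor length exactly", {
  ref <- simulate_reference(1, 100000, gc = 0.5, seed = 2)
  del <- apply_svs(ref, sv_spec("DEL", "chr1", 40001, 45000))
  expect_equal(sum(Biostrings::width(del$donor)), 95000)

  dup <- apply_svs(ref, sv_spec("DUP_TANDEM", "chr1", 40001, 42000))
  expect_equal(sum(Biostrings::width(dup$donor)), 102000)

  inv <- apply_svs(ref, sv_spec("INV", "chr1", 40001, 43000))
  expect_equal(sum(Biostrings::width(inv$donor)), 100000)
  seg <- Biostrings::subseq(inv$donor[[1]], 40001, 43000)
  expect_identical(
    as.character(seg),
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(ref[[1]], 40001, 43000)))
  )

  # cut-paste moves, copy-paste duplicates, across chromosomes too
  ref2 <- simulate_reference(2, 50000, gc = 0.5, seed = 4)
  tr <- apply_svs(ref2, sv_spec("TRANS_INTER", "chr2", 10001, 15000,
                                "chr1", 30000))
  expect_equal(Biostrings::width(tr$donor), c(55000, 45000))
  cp <- apply_svs(ref2, sv_spec("GAIN_INTER_INV", "chr2", 10001, 15000,
                                "chr1", 30000))
  expect_equal(Biostrings::width(cp$donor), c(55000, 50000))

  expect_error(
    apply_svs(ref, dplyr::bind_rows(sv_spec("DEL", "chr1", 1000, 3000),
                                    sv_spec("DEL", "chr1", 2500, 4000))),
    "overlap"
  )
  expect_error(sv_spec("DEL", "chr1", 5000, 4000), "source_start")
  expect_error(sv_spec("GAIN_INTRA", "chr1", 1000, 2000), "insertion")
  expect_error(sv_spec("GAIN_INTRA", "chr1", 1000, 2000, "chr1", 1500),
               "inside")
})

test_that("simulated libraries are concordant at the modelled rate", {
  ref <- simulate_reference(1, 100000, gc = 0.5, seed = 5)
  pairs <- simulate_read_pairs(ref, read_len = 100, insert_mean = 300,
                               insert_sd = 30, coverage = 30, seed = 6)
  expect_equal(nrow(pairs), round(30 * 100000 / 200))
  model <- estimate_insert_model(pairs, alpha = 0.01)
  cls <- classify_pairs(pairs, model)
  anom <- sum(cls$category %in% c("DISTANCE", "ORDER", "ORI", "CHRPOS",
                                  "CHRPOSORI"))
  mapped <- sum(cls$mapped1 & cls$mapped2)
  expect_lte(anom / mapped, 0.01)  # only the discordant tail can be anomalous
  conc <- sum(cls$category == "CONCORDANT")
  expect_gte(conc / mapped, 0.985)

  # insert length averages the nominal insert size
  l <- insert_lengths(pairs)
  l <- l[!is.na(l)]
  expect_lt(abs(mean(l) - 300), 3 * 30 / sqrt(length(l)) + 1)

  expect_error(simulate_read_pairs(ref, coverage = 0), "coverage")
  expect_error(simulate_read_pairs(ref, read_len = 200, insert_mean = 300),
               "insert_mean")
})

test_that("pairs spanning a deletion stretch by the deletion size", {
  ref <- simulate_reference(1, 60000, gc = 0.5, seed = 8)
  d <- 5000
  donor <- apply_svs(ref, sv_spec("DEL", "chr1", 30001, 30000 + d))
  pairs <- simulate_read_pairs(donor, coverage = 40, seed = 9)
  model <- estimate_insert_model(pairs)
  cls <- classify_pairs(pairs, model)
  span <- cls[cls$category == "DISTANCE" & cls$l > d / 2, ]
  expect_gt(nrow(span), 5)
  expect_lt(abs(mean(span$l) - (300 + d)), 3 * 30 / sqrt(nrow(span)) + 1)
})

test_that("pairs straddling an inversion junction map to one strand", {
  ref <- simulate_reference(1, 60000, gc = 0.5, seed = 10)
  donor <- apply_svs(ref, sv_spec("INV", "chr1", 30001, 36000))
  pairs <- simulate_read_pairs(donor, coverage = 40, seed = 11)
  model <- estimate_insert_model(pairs)
  cls <- classify_pairs(pairs, model)
  ori <- cls[cls$category == "ORI", ]
  expect_gt(nrow(ori), 10)
  expect_true(all(ori$strand1 == ori$strand2))
  # straddlers anchor near the two junctions
  expect_true(all(
    pmin(abs(ori$start1 - 30000), abs(ori$start1 - 36000)) < 500
  ))
})

test_that("simulation is deterministic under a fixed seed", {
  ref <- simulate_reference(1, 20000, gc = 0.4, seed = 12)
  donor <- apply_svs(ref, sv_spec("DEL", "chr1", 8001, 10000))
  p1 <- simulate_read_pairs(donor, coverage = 10, seed = 13)
  p2 <- simulate_read_pairs(donor, coverage = 10, seed = 13)
  expect_identical(p1, p2)
  p3 <- simulate_read_pairs(donor, coverage = 10, seed = 14)
  expect_false(identical(p1, p3))
})

test_that("SAM round-trip preserves pair records and triage classes", {
  skip_if_not_installed("Rsamtools")
  ref <- simulate_reference(1, 30000, gc = 0.5, seed = 15)
  donor <- apply_svs(ref, sv_spec("DEL", "chr1", 12001, 15000))
  pairs <- simulate_read_pairs(donor, coverage = 8, seed = 16)
  sam <- file.path(withr::local_tempdir(), "toy.sam")
  write_sam(pairs, sam, ref)
  back <- read_alignments(sam)
  expect_equal(nrow(back), nrow(pairs))
  back <- back[match(pairs$qname, back$qname), ]
  for (col in c("chrom1", "start1", "end1", "strand1", "mapped1",
                "chrom2", "start2", "end2", "strand2", "mapped2")) {
    expect_equal(back[[col]], pairs[[col]], info = col)
  }
  # triage classes: one-end pairs at junction boundaries survive the trip
  n_one_end <- sum(xor(pairs$mapped1, pairs$mapped2))
  expect_equal(sum(back$category == "ONE_END", na.rm = TRUE), n_one_end)
})

test_that("planted SV classes produce their expected anomaly signatures", {
  ref <- simulate_reference(2, 60000, gc = 0.5, seed = 17)
  cases <- list(
    list(sv_spec("DEL", "chr1", 25001, 30000), "DISTANCE"),
    list(sv_spec("DUP_TANDEM", "chr1", 25001, 30000), "ORDER"),
    list(sv_spec("INV", "chr1", 25001, 30000), "ORI"),
    list(sv_spec("GAIN_INTER", "chr2", 25001, 30000, "chr1", 40000), "CHRPOS"),
    list(sv_spec("GAIN_INTER_INV", "chr2", 25001, 30000, "chr1", 40000),
         "CHRPOSORI")
  )
  for (cs in cases) {
    donor <- apply_svs(ref, cs[[1]])
    pairs <- simulate_read_pairs(donor, coverage = 20, seed = 18)
    cls <- classify_pairs(pairs, estimate_insert_model(pairs))
    counts <- count_categories(cls)
    n <- counts$n[counts$category == cs[[2]]]
    expect_gt(n, 10, label = paste(cs[[1]]$sv_class[1], "signature count"))
    expect_equal(
      strsplit(donor$truth$expected_categories, ",")[[1]][1],
      cs[[2]]
    )
  }
})
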