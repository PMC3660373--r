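test_that("breakpoint matching is padded interval overlap", {
  expect_true(match_breakpoints(c(100, 400), c(350, 600)))
  expect_false(match_breakpoints(c(100, 200), c(300, 400)))
  expect_true(match_breakpoints(c(100, 200), c(210, 300), tolerance = 20))
  expect_false(match_breakpoints(c(100, 200), c(241, 300), tolerance = 20))
})

# noiseless hand-built scenario pieces -------------------------------------
neutral_chr <- function(chrom, len = 2e5) {
  make_segments(chrom, list(1, len, "NEUTRAL"))
}

test_that("single clusters resolve by their depth state", {
  del_cl <- make_cluster("c1", "DISTANCE", "chr1", 19900, 20300,
                         "chr1", 25700, 26100)
  seg_loss <- make_segments("chr1", list(1, 20000, "NEUTRAL"),
                            list(20001, 26000, "LOSS"),
                            list(26001, 2e5, "NEUTRAL"))
  calls <- define_svs(del_cl, seg_loss)
  expect_equal(calls$sv_class, "DEL")
  expect_equal(calls$reported_type, "deletion")
  expect_equal(calls$rd_state, "LOSS")

  # without the loss it is only a putative deletion
  calls2 <- define_svs(del_cl, neutral_chr("chr1"))
  expect_equal(calls2$sv_class, "PUTATIVE_DELETION")

  dup_cl <- make_cluster("c2", "ORDER", "chr1", 39700, 40100,
                         "chr1", 45900, 46300)
  seg_gain <- make_segments("chr1", list(1, 40000, "NEUTRAL"),
                            list(40001, 46000, "GAIN"),
                            list(46001, 2e5, "NEUTRAL"))
  expect_equal(define_svs(dup_cl, seg_gain)$sv_class, "DUP_TANDEM")
  expect_equal(define_svs(dup_cl, neutral_chr("chr1"))$sv_class, "UNDEFINED")

  # unreliable clusters (mutually overlapping intervals) are demoted
  bad <- make_cluster("c3", "DISTANCE", "chr1", 1000, 1400, "chr1", 1200, 1600,
                      unreliable = TRUE)
  out <- define_svs(bad, seg_loss)
  expect_equal(out$sv_class, "UNDEFINED")
  expect_true(out$unreliable)
})

test_that("cluster combinations resolve copy-paste, cut-paste and inversions", {
  # geometry: source [a, b] = [80000, 86000], insertion point p = 100000
  seg_gain <- make_segments("chr1", list(1, 80000, "NEUTRAL"),
                            list(80001, 86000, "GAIN"),
                            list(86001, 2e5, "NEUTRAL"))
  dist <- make_cluster("d1", "DISTANCE", "chr1", 85900, 86300,
                       "chr1", 99700, 100100)
  ord <- make_cluster("o1", "ORDER", "chr1", 79700, 80100,
                      "chr1", 99900, 100300)
  calls <- define_svs(dplyr::bind_rows(dist, ord), seg_gain)
  expect_equal(calls$sv_class, "GAIN_INTRA")
  expect_equal(calls$orientation, "direct")
  expect_lte(calls$source_lo, 80001)
  expect_gte(calls$source_hi, 86000)
  expect_true(calls$insert_lo <= 100000 && calls$insert_hi >= 100000)
  expect_setequal(calls$cluster_ids[[1]], c("d1", "o1"))

  # same two clusters without the gain stay separate (putative + undefined)
  calls_n <- define_svs(dplyr::bind_rows(dist, ord), neutral_chr("chr1"))
  expect_setequal(calls_n$sv_class, c("PUTATIVE_DELETION", "UNDEFINED"))

  # adding the excision distance cluster with neutral depth: cut-paste
  exc <- make_cluster("d2", "DISTANCE", "chr1", 79800, 80200,
                      "chr1", 85800, 86200, s = 12)
  calls_t <- define_svs(dplyr::bind_rows(dist, ord, exc), neutral_chr("chr1"))
  expect_equal(calls_t$sv_class, "TRANS_INTRA")
  expect_equal(length(calls_t$cluster_ids[[1]]), 3)

  # inverted copy: forward-ORI + reverse-ORI sharing the insertion locus
  ff <- make_cluster("f1", "ORI", "chr1", 85900, 86300, "chr1", 99700, 100100,
                     strand_config = "ff")
  rr <- make_cluster("r1", "ORI", "chr1", 79700, 80100, "chr1", 99900, 100300,
                     strand_config = "rr")
  calls_i <- define_svs(dplyr::bind_rows(ff, rr), seg_gain)
  expect_equal(calls_i$sv_class, "GAIN_INTRA_INV")
  expect_equal(calls_i$orientation, "inverted")

  # matching on both sides with neutral depth is an inversion
  ff2 <- make_cluster("f2", "ORI", "chr1", 59900, 60300, "chr1", 65900, 66300,
                      strand_config = "ff")
  rr2 <- make_cluster("r2", "ORI", "chr1", 59700, 60100, "chr1", 65700, 66100,
                      strand_config = "rr")
  calls_v <- define_svs(dplyr::bind_rows(ff2, rr2), neutral_chr("chr1"))
  expect_equal(calls_v$sv_class, "INV")
  expect_equal(calls_v$rd_state, "NEUTRAL")

  # inter-chromosomal copy-paste from two same-category clusters
  seg2 <- dplyr::bind_rows(
    neutral_chr("chr1"),
    make_segments("chr2", list(1, 60000, "NEUTRAL"),
                  list(60001, 66000, "GAIN"), list(66001, 2e5, "NEUTRAL"))
  )
  cp1 <- make_cluster("x1", "CHRPOSORI", "chr1", 171900, 172300,
                      "chr2", 65900, 66300, strand_config = "ff")
  cp2 <- make_cluster("x2", "CHRPOSORI", "chr1", 171700, 172100,
                      "chr2", 59700, 60100, strand_config = "rr")
  calls_x <- define_svs(dplyr::bind_rows(cp1, cp2), seg2)
  expect_equal(calls_x$sv_class, "GAIN_INTER_INV")
  expect_equal(calls_x$source_chrom, "chr2")
  expect_equal(calls_x$insert_chrom, "chr1")
})

test_that("every input cluster lands in exactly one call", {
  set.seed(61)
  cls <- dplyr::bind_rows(
    make_cluster("a", "DISTANCE", "chr1", 10000, 10400, "chr1", 15000, 15400),
    make_cluster("b", "ORDER", "chr1", 30000, 30400, "chr1", 35000, 35400),
    make_cluster("c", "ORI", "chr1", 50000, 50400, "chr1", 55000, 55400,
                 strand_config = "ff"),
    make_cluster("d", "CHRPOS", "chr1", 70000, 70400, "chr2", 5000, 5400)
  )
  calls <- define_svs(cls, neutral_chr("chr1"))
  used <- unlist(calls$cluster_ids)
  expect_setequal(used, cls$cluster_id)
  expect_false(any(duplicated(used)))
  # balanced calls never carry a non-neutral source state; unbalanced always do
  expect_true(all(is.na(calls$rd_state) |
                    calls$rd_state == "NEUTRAL" |
                    calls$sv_class %in% c("DEL", "DUP_TANDEM", "GAIN_INTRA",
                                          "GAIN_INTRA_INV", "GAIN_INTER",
                                          "GAIN_INTER_INV")))
})

test_that("somatic subtraction removes clusters shared with the normal", {
  m <- make_model(lc = 200, uc = 400)  # D = 200
  tum <- dplyr::bind_rows(
    make_cluster("t1", "DISTANCE", "chr1", 10000, 10400, "chr1", 15000, 15400),
    make_cluster("t2", "DISTANCE", "chr1", 50000, 50400, "chr1", 56000, 56400)
  )
  # one normal pair co-locating with t1's anchors
  normal_shared <- make_pair(
    qname = "n1", start1 = 9950, end1 = 10049, strand1 = "+",
    start2 = 14990, end2 = 15089, strand2 = "-"
  ) |> dplyr::mutate(category = "DISTANCE", l = NA_integer_)
  som <- subtract_shared(tum, normal_shared, m)
  expect_equal(som$cluster_id, "t2")
  expect_true(all(som$somatic))

  # a normal pair beyond the bound does not subtract
  normal_far <- dplyr::mutate(normal_shared,
                              start1 = start1 + 2 * 200 + 10,
                              end1 = end1 + 2 * 200 + 10,
                              start2 = start2 + 2 * 200 + 10,
                              end2 = end2 + 2 * 200 + 10)
  som2 <- subtract_shared(tum, normal_far, m)
  expect_setequal(som2$cluster_id, c("t1", "t2"))

  # wrong category never subtracts
  normal_cat <- dplyr::mutate(normal_shared, category = "ORDER",
                              strand1 = "-", strand2 = "+")
  expect_equal(nrow(subtract_shared(tum, normal_cat, m)), 2)
})
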