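flat_ref <- function(len = 20000, seed = 51, n_chroms = 1) {
  simulate_reference(n_chroms, len, gc = 0.5, seed = seed)
}

test_that("reads are assigned to the window holding most of their bases", {
  ref <- flat_ref(1000)
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(61L, 41L, 51L, 10L),
    end = c(120L, 100L, 110L, 29L),
    qname = sprintf("r%d", 1:4), strand = "+"
  )
  # window grid of 100 bp: read 1 has 40/20 split -> window 1; read 2 fully in
  # window 1; read 3 is exactly 50/50 -> left window; read 4 fully in window 1
  w <- suppressWarnings(bin_reads(reads, ref, window_size = 100))
  expect_equal(w$r[1], 4L)
  expect_equal(sum(w$r), nrow(reads))

  # a read mostly in the second window goes there
  r2 <- tibble::tibble(chrom = "chr1", start = 81L, end = 140L,
                       qname = "x", strand = "+")
  w2 <- suppressWarnings(bin_reads(r2, ref, window_size = 100))
  expect_equal(w2$r[2], 1L)
  expect_equal(w2$r[1], 0L)
})

test_that("binning conserves reads and matches the direct-count oracle", {
  ref <- flat_ref(20000)
  pairs <- simulate_read_pairs(ref, coverage = 30, seed = 52)
  reads <- reads_from_pairs(pairs)
  w <- suppressWarnings(bin_reads(reads, ref, window_size = 100))
  expect_equal(sum(w$r), nrow(reads))
  # direct-count oracle: per-read midpoint-majority assignment, re-derived
  mid_win <- function(s, e) {
    cand <- unique(c((s - 1) %/% 100, (e - 1) %/% 100))
    ov <- vapply(cand, function(k) {
      min(e, (k + 1) * 100) - max(s, k * 100 + 1) + 1
    }, 1)
    cand[which.max(ov)]  # which.max takes the first (leftmost) on ties
  }
  oracle <- table(mapply(mid_win, reads$start, reads$end))
  got <- w$r[match(as.integer(names(oracle)), (w$start - 1) %/% 100)]
  expect_equal(got, as.integer(oracle))
  # ~ coverage * window / read_len reads per window on average
  expect_lt(abs(mean(w$r) - 30), 1)
})

test_that("GC normalization flattens an engineered GC depth bias", {
  # two GC strata; high-GC windows get double depth
  ref <- simulate_reference(
    1, 100000,
    gc = function(pos) ifelse(((pos - 1) %/% 1000) %% 2 == 0, 0.30, 0.60),
    seed = 53
  )
  w <- tibble::tibble(chrom = "chr1")
  base <- suppressWarnings(
    bin_reads(simulate_read_pairs(ref, coverage = 30, seed = 54), ref)
  )
  set.seed(55)
  boost <- base$gc_bin >= 45
  base$r <- base$r + ifelse(boost, rpois(nrow(base), base$r), 0L)
  norm <- gc_normalize(base, min_bin_windows = 20)
  med_by_bin <- norm[!norm$masked, ] |>
    dplyr::group_by(gc_bin) |>
    dplyr::summarise(med = median(r_adj), n = dplyr::n()) |>
    dplyr::filter(n >= 50)
  overall <- median(norm$r_adj[!norm$masked])
  expect_true(all(abs(med_by_bin$med / overall - 1) <= 0.05))
  # idempotent on an already flat signal
  again <- gc_normalize(dplyr::mutate(norm, r = r_adj), min_bin_windows = 20)
  expect_equal(again$r_adj[!again$masked], norm$r_adj[!norm$masked],
               tolerance = 1e-8)
})

test_that("normalization handles degenerate windows", {
  w <- make_signal_windows(rep(0, 100))[, 1:7]
  w$r <- 10L
  w1 <- gc_normalize(w, min_bin_windows = 10)
  expect_equal(w1$r_adj, rep(10, 100))  # single GC bin: identity
  w$r[1] <- 0L
  expect_equal(gc_normalize(w, min_bin_windows = 10)$r_adj[1], 0)
  w$r <- 0L
  expect_error(gc_normalize(w), "zero depth")
})

test_that("the square-root transform centers typical windows at zero", {
  w <- make_signal_windows(rep(0, 50))[, 1:7]
  w$r <- 36L
  w <- gc_normalize(w, min_bin_windows = 1)
  w$r_adj[1] <- 0  # homozygous-deletion window at median depth 36
  t <- transform_depth(w)
  expect_equal(t$y[1], -6)
  expect_equal(t$y[2], 0)
})

test_that("segmentation recovers planted steps and honours state thresholds", {
  # constant signal: one neutral segment
  flat <- make_signal_windows(rep(0, 5000))
  seg <- segment_depth(flat)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "NEUTRAL")
  expect_equal(seg$start, 1L)
  expect_equal(seg$end, 5000L * 100L)

  # noisy step is recovered within +/- 2 windows
  set.seed(56)
  y <- c(rnorm(2000, 0, 0.3), rnorm(50, -1.5, 0.3), rnorm(2000, 0, 0.3))
  seg <- segment_depth(make_signal_windows(y))
  loss <- seg[seg$state == "LOSS", ]
  expect_equal(nrow(loss), 1)
  expect_lt(abs(loss$start - (2000 * 100 + 1)), 2 * 100 + 1)
  expect_lt(abs(loss$end - 2050 * 100), 2 * 100 + 1)
  expect_true(all(seg$start[-1] == head(seg$end, -1) + 1))  # tiling

  # two adjacent steps of opposite sign stay separate
  set.seed(57)
  y2 <- c(rnorm(500, 0, 0.3), rnorm(50, 1.5, 0.3), rnorm(50, -1.5, 0.3),
          rnorm(500, 0, 0.3))
  seg2 <- segment_depth(make_signal_windows(y2))
  expect_equal(sum(seg2$state == "GAIN"), 1)
  expect_equal(sum(seg2$state == "LOSS"), 1)

  # state calling is monotone in the segment mean
  y3 <- c(rep(0.39, 200), rep(0.41, 200), rep(-0.39, 200), rep(-0.41, 200))
  seg3 <- segment_depth(make_signal_windows(y3))
  expect_equal(seg3$state[order(seg3$start)],
               c("NEUTRAL", "GAIN", "NEUTRAL", "LOSS"))
})

test_that("masked windows are excluded but the tiling is preserved", {
  set.seed(58)
  y <- c(rnorm(300, 0, 0.2), rnorm(100, -2, 0.2), rnorm(300, 0, 0.2))
  w <- make_signal_windows(y)
  w$masked[350:360] <- TRUE
  w$y[350:360] <- NA
  seg <- segment_depth(w)
  expect_true(all(seg$start[-1] == head(seg$end, -1) + 1))
  expect_equal(sum(seg$state == "LOSS"), 1)
  expect_equal(min(seg$start), 1L)
  expect_equal(max(seg$end), 700L * 100L)
})

test_that("single-copy loss and gain at 30x cross the state thresholds", {
  set.seed(59)
  r <- c(rpois(3000, 30), rpois(80, 15), rpois(3000, 30), rpois(80, 45),
         rpois(3000, 30))
  w <- make_signal_windows(rep(0, length(r)))[, 1:7]
  w$r <- as.integer(r)
  w <- transform_depth(gc_normalize(w, min_bin_windows = 1))
  seg <- segment_depth(w)
  expect_equal(sum(seg$state == "LOSS"), 1)
  expect_equal(sum(seg$state == "GAIN"), 1)
  expect_lt(seg$mean_y[seg$state == "LOSS"], -0.4)
  expect_gt(seg$mean_y[seg$state == "GAIN"], 0.4)
})
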