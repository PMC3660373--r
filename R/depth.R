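#' Bin reads into fixed windows with GC annotation
#'
#' Divides each chromosome into non-overlapping windows of `window_size` bp and
#' assigns every mapped read (including the anchored end of one-end-anchored
#' pairs) to the window where the highest fraction of its bases falls; an exact
#' 50/50 split goes to the left window. Window GC content is annotated from the
#' reference at 1% resolution; windows that are mostly ambiguous bases (> 50%
#' `N`) are masked.
#'
#' @param reads Per-read tibble from [reads_from_pairs()] (columns `chrom`,
#'   `start`, `end`), or a pair tibble (expanded automatically).
#' @param reference `DNAStringSet` with the reference sequences.
#' @param window_size Window size in bp (default 100).
#' @return Tibble of windows: `chrom`, `start`, `end`, `r` (read count), `gc`
#'   (fraction), `gc_bin` (integer percent), `masked`.
#' @export
bin_reads <- function(reads, reference, window_size = 100) {
  if (all(c("chrom1", "chrom2") %in% names(reads))) {
    reads <- reads_from_pairs(reads)
  }
  if (window_size <= max(reads$end - reads$start + 1, 0)) {
    warn("window_size <= read length: window assignment becomes ambiguity-prone")
  }
  windows <- lapply(names(reference), function(chrom) {
    L <- Biostrings::width(reference)[names(reference) == chrom]
    start <- seq.int(1L, L, by = window_size)
    end <- pmin(start + window_size - 1L, L)
    v <- Biostrings::Views(reference[[chrom]], start = start, end = end)
    fr <- Biostrings::letterFrequency(v, c("GC", "N"))
    w <- end - start + 1L
    gc <- fr[, "G|C"] / w
    tibble(
      chrom = chrom, start = start, end = end,
      gc = gc, gc_bin = as.integer(round(100 * gc)),
      masked = fr[, "N"] / w > 0.5
    )
  })
  windows <- bind_rows(windows)

  reads <- reads[reads$chrom %in% names(reference), ]
  ws <- window_size
  s <- reads$start
  e <- reads$end
  w_s <- (s - 1L) %/% ws
  w_e <- (e - 1L) %/% ws
  ov1 <- (w_s + 1L) * ws - s + 1L            # bases in the first window
  ov2 <- e - (w_s + 1L) * ws                 # bases in the second window
  win <- ifelse(
    w_e == w_s, w_s,
    ifelse(w_e == w_s + 1L, ifelse(ov1 >= ov2, w_s, w_s + 1L),
           ifelse(ov1 >= ws, w_s, w_s + 1L))  # >2 windows: first full window
  )
  key <- paste(reads$chrom, win, sep = "\r")
  tb <- table(key)
  wkey <- paste(windows$chrom, (windows$start - 1L) %/% ws, sep = "\r")
  windows$r <- as.integer(tb[wkey])
  windows$r[is.na(windows$r)] <- 0L
  windows[, c("chrom", "start", "end", "r", "gc", "gc_bin", "masked")]
}

#' GC-normalize window counts
#'
#' Adjusts each window count by the ratio of the global median count to the
#' median count of windows sharing its GC bin: `r_adj = r * m / m_gc`.
#' GC bins with a zero median or occupied by fewer than `min_bin_windows`
#' windows are masked (their medians are unstable) and excluded from
#' segmentation.
#'
#' @param windows Window tibble from [bin_reads()].
#' @param min_bin_windows Minimum windows per GC bin (default 50).
#' @return `windows` with `r_adj` (NA on masked windows).
#' @export
gc_normalize <- function(windows, min_bin_windows = 50) {
  use <- !windows$masked
  if (!any(use) || all(windows$r[use] == 0)) {
    abort("all windows have zero depth; cannot GC-normalize")
  }
  m <- median(windows$r[use])
  stats <- windows[use, ] %>%
    group_by(.data$gc_bin) %>%
    summarise(m_gc = median(.data$r), n_bin = dplyr::n(), .groups = "drop")
  i <- match(windows$gc_bin, stats$gc_bin)
  m_gc <- stats$m_gc[i]
  n_bin <- stats$n_bin[i]
  bad <- is.na(m_gc) | m_gc == 0 | n_bin < min_bin_windows
  windows$masked <- windows$masked | bad
  windows$r_adj <- ifelse(windows$masked, NA_real_, windows$r * m / m_gc)
  windows
}

#' Variance-stabilize the normalized depth signal
#'
#' Square-root transform with the global median as the shift towards zero:
#' `y = sqrt(r_adj) - sqrt(median(r_adj))`. Diploid-typical windows then
#' center on `y ~ 0`, and copy-number gains/losses shift `y` up/down with
#' roughly constant variance.
#'
#' @param windows GC-normalized window tibble.
#' @return `windows` with `y`.
#' @export
transform_depth <- function(windows) {
  med <- median(windows$r_adj[!windows$masked])
  windows$y <- sqrt(windows$r_adj) - sqrt(med)
  windows
}

#' Segment the depth signal into gain/loss/neutral regions
#'
#' Fits a piecewise-constant model per chromosome by bottom-up backward
#' elimination: every inter-window boundary starts as a candidate breakpoint
#' and the weakest (smallest mean-difference t-like score between the adjacent
#' segments, with a robust global noise scale) is removed until all remaining
#' breakpoints score at least `crit`. Masked windows are excluded from the fit;
#' segments tile the chromosome (segment bounds extend to the midpoint gaps
#' over masked runs). Segment state is `GAIN` when the segment mean of `y`
#' exceeds `gain_threshold`, `LOSS` below `loss_threshold`, else `NEUTRAL`.
#'
#' @param windows Transformed window tibble (column `y`).
#' @param crit Breakpoint retention score (default 5, calibrated on
#'   synthetic step signals; larger is more conservative).
#' @param gain_threshold,loss_threshold State thresholds on mean `y`
#'   (defaults +0.4 / -0.4).
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_windows`, `mean_y`,
#'   `state`.
#' @export
segment_depth <- function(windows, crit = 5, gain_threshold = 0.4,
                          loss_threshold = -0.4) {
  out <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$start), ]
    use <- which(!w$masked & !is.na(w$y))
    if (!length(use)) return(NULL)
    y <- w$y[use]
    cp <- be_changepoints(y, crit)          # segment ends, indices into y
    seg_end_i <- use[cp]
    seg_start_i <- use[c(1L, head(cp, -1L) + 1L)]
    # tile the chromosome: extend first/last to bounds, meet at mask gaps
    starts <- w$start[seg_start_i]
    ends <- w$end[seg_end_i]
    starts[1] <- w$start[1]
    ends[length(ends)] <- w$end[nrow(w)]
    if (length(starts) > 1) {
      gaps <- starts[-1] - ends[-length(ends)] - 1L
      mid <- ends[-length(ends)] + gaps %/% 2L
      ends[-length(ends)] <- mid
      starts[-1] <- mid + 1L
    }
    mean_y <- vapply(seq_along(cp), function(i) {
      mean(y[(c(0L, cp)[i] + 1L):cp[i]])
    }, numeric(1))
    tibble(
      chrom = w$chrom[1], start = starts, end = ends,
      n_windows = diff(c(0L, cp)), mean_y = mean_y,
      state = dplyr::case_when(
        mean_y > gain_threshold ~ "GAIN",
        mean_y < loss_threshold ~ "LOSS",
        TRUE ~ "NEUTRAL"
      )
    )
  })
  bind_rows(out)
}

# Bottom-up backward elimination of changepoints. Returns the sorted indices of
# segment ends (last index always included). Score between adjacent segments =
# |mean1 - mean2| / (sigma * sqrt(1/n1 + 1/n2)) with sigma estimated robustly
# from first differences.
be_changepoints <- function(y, crit) {
  n <- length(y)
  if (n < 2) return(n)
  sigma <- mad(diff(y)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) {
    sigma <- sd(diff(y)) / sqrt(2)
    if (!is.finite(sigma) || sigma <= 0) {
      # (near-)noiseless signal: keep exact jumps only
      cp <- which(diff(y) != 0)
      return(unique(c(cp, n)))
    }
  }
  cnt <- rep(1L, n)
  sm <- y
  nxt <- c(seq_len(n - 1L) + 1L, 0L)
  prv <- c(0L, seq_len(n - 1L))
  score <- rep(Inf, n)
  sc <- function(i, j) {
    abs(sm[i] / cnt[i] - sm[j] / cnt[j]) /
      (sigma * sqrt(1 / cnt[i] + 1 / cnt[j]))
  }
  for (i in seq_len(n - 1L)) score[i] <- sc(i, i + 1L)
  repeat {
    b <- which.min(score)
    if (score[b] >= crit) break
    j <- nxt[b]
    cnt[b] <- cnt[b] + cnt[j]
    sm[b] <- sm[b] + sm[j]
    nxt[b] <- nxt[j]
    if (nxt[b] > 0L) prv[nxt[b]] <- b
    score[j] <- Inf
    score[b] <- if (nxt[b] > 0L) sc(b, nxt[b]) else Inf
    if (prv[b] > 0L) score[prv[b]] <- sc(prv[b], b)
  }
  ends <- integer(0)
  i <- 1L
  while (i > 0L) {
    ends <- c(ends, i + cnt[i] - 1L)
    i <- nxt[i]
  }
  ends
}

#' Write depth results (per-window signal and per-segment calls)
#'
#' Emits a BedGraph-style per-window track of the transformed signal and a
#' BED-style segment file with state and mean signal (0-based half-open
#' coordinates, per those formats).
#'
#' @param windows Transformed window tibble.
#' @param segments Segment tibble.
#' @param dir Output directory (created if needed).
#' @export
write_depth <- function(windows, segments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- windows[!windows$masked, ]
  readr::write_tsv(
    tibble(chrom = w$chrom, start = w$start - 1L, end = w$end,
           y = round(w$y, 4)),
    file.path(dir, "depth_signal.bedgraph"), col_names = FALSE
  )
  readr::write_tsv(
    tibble(chrom = segments$chrom, start = segments$start - 1L,
           end = segments$end, state = segments$state,
           mean_y = round(segments$mean_y, 4)),
    file.path(dir, "depth_segments.bed"), col_names = FALSE
  )
  invisible(dir)
}
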