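#' Do two breakpoint intervals match?
#'
#' "Equal" breakpoints are realized as interval overlap after symmetric padding
#' by `tolerance`: prediction intervals already encode the positional
#' uncertainty, so the default tolerance is 0 (raw overlap).
#'
#' @param a,b Length-2 numeric vectors `c(lo, hi)` of half-open intervals on
#'   the same chromosome.
#' @param tolerance Padding in bp.
#' @return `TRUE` iff the padded intervals overlap.
#' @export
match_breakpoints <- function(a, b, tolerance = 0) {
  bp_overlap(a[1], a[2], b[1], b[2], tolerance)
}

bp_overlap <- function(lo1, hi1, lo2, hi2, tol = 0) {
  (lo1 - tol) < (hi2 + tol) & (lo2 - tol) < (hi1 + tol)
}

# Fraction of [lo, hi) covered by segments in `state` on `chrom`; segments
# tile each chromosome, so bp overlap is well defined.
rd_state_fraction <- function(segments, chrom, lo, hi, state) {
  s <- segments[segments$chrom == chrom & segments$state == state, ]
  if (!nrow(s)) return(0)
  ov <- pmax(0, pmin(s$end + 1, hi) - pmax(s$start, lo))
  sum(ov) / max(hi - lo, 1)
}

# RD support predicate: the candidate region must span at least `min_windows`
# windows and have >= `min_fraction` of its length in segments of the required
# state. Returns "yes", "no" or "short" (region too small for RD evidence).
rd_support <- function(segments, chrom, lo, hi, state, window_size = 100,
                       min_windows = 3, min_fraction = 0.5) {
  if ((hi - lo) < min_windows * window_size) return("short")
  if (rd_state_fraction(segments, chrom, lo, hi, state) >= min_fraction)
    "yes" else "no"
}

#' Subtract clusters shared with a matched normal sample
#'
#' A tumour cluster is removed when at least one anomalous pair of the same
#' category in the normal sample would have joined it under the clustering
#' distance bound (i.e. the normal pair's two anchors lie within `D` of some
#' member pair's anchors). Raw normal pairs are used rather than normal
#' clusters: a single supporting read pair in the normal already indicates the
#' event is germline, which is stricter than cluster-versus-cluster matching
#' and reduces false somatic calls. Surviving clusters are flagged somatic.
#'
#' @param tumour_clusters Cluster tibble from [cluster_pairs()].
#' @param normal_pairs Classified pair tibble for the matched normal (same
#'   insert-model convention as the tumour).
#' @param model An `insert_model` (distance bound).
#' @param d Distance bound override.
#' @return The somatic subset of `tumour_clusters`, with `somatic = TRUE`.
#' @export
subtract_shared <- function(tumour_clusters, normal_pairs, model, d = NULL) {
  if (is.null(d)) d <- model_cutoffs(model)$d
  na <- pair_anchors(normal_pairs)
  keep <- vapply(seq_len(nrow(tumour_clusters)), function(i) {
    cl <- tumour_clusters[i, ]
    cand <- na[na$category == cl$category &
                 na$strand_config == cl$strand_config &
                 na$chrom_1 == cl$chrom_1 & na$chrom_2 == cl$chrom_2, ]
    if (!nrow(cand)) return(TRUE)
    x1 <- cl$x1s[[1]]
    x2 <- cl$x2s[[1]]
    for (k in seq_len(nrow(cand))) {
      if (any(abs(cand$x_1[k] - x1) <= d & abs(cand$x_2[k] - x2) <= d)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- tumour_clusters[keep, ]
  out$somatic <- rep(TRUE, nrow(out))
  out
}

#' Define structural variants from clusters and depth segments
#'
#' Applies the combination rule table. Multi-cluster combinations are matched
#' first, greedily by descending total support, so that clusters belonging to a
#' copy-paste or cut-paste event are not mis-read as simple deletions:
#'
#' * copy-paste gains: two clusters sharing exactly one breakpoint locus (the
#'   insertion point) whose other two breakpoints delimit a source region with
#'   a `GAIN` depth state — `DISTANCE`+`ORDER` (same chromosome, direct),
#'   forward-`ORI`+reverse-`ORI` (same chromosome, inverted), two `CHRPOS`
#'   (other chromosome, direct) or two `CHRPOSORI` (other chromosome,
#'   inverted);
#' * cut-paste translocations: the same two-cluster insertion signatures with a
#'   `NEUTRAL` source region plus a `DISTANCE` cluster matching the two source
#'   junctions (the excision);
#' * inversions: a forward-`ORI` and a reverse-`ORI` cluster whose breakpoint
#'   predictions match on both sides, with `NEUTRAL` depth over the span;
#' * then single clusters: a `DISTANCE` cluster over a `LOSS` segment is a
#'   deletion (`DEL`); an `ORDER` cluster over a `GAIN` is a tandem duplication
#'   (`DUP_TANDEM`); remaining `DISTANCE` clusters with neither a loss nor a
#'   combination are `PUTATIVE_DELETION`; anything else is `UNDEFINED` and is
#'   routed to the repeat filter.
#'
#' Copy/cut calls record both the source (copied/excised) region and the
#' insertion point. Single-cluster calls whose two breakpoint intervals
#' mutually overlap are demoted to `UNDEFINED` and flagged unreliable.
#'
#' @param clusters Breakpoint-predicted (and optionally somatic-subtracted,
#'   confidence-annotated) cluster tibble.
#' @param segments Depth segments from [segment_depth()].
#' @param window_size Depth window size used (for the minimum-region rule).
#' @param tolerance Breakpoint matching tolerance in bp (default 100, about
#'   three insert-size standard deviations at the default library). The
#'   prediction-interval formula assumes supporting fragments no longer than
#'   the upper cut-off, but categories without an insert-length cap (order,
#'   orientation and inter-chromosomal pairs) occasionally contain a
#'   tail-length fragment that shifts one interval edge past the junction by
#'   up to the tail excess; the tolerance absorbs this when deciding whether
#'   two clusters point at the same locus.
#' @return Tibble of SV calls: `call_id`, `sv_class`, `reported_type`, source
#'   region, insertion point, `orientation`, supporting `cluster_ids`
#'   (list-column), `s_total`, `rd_state`, `somatic`, `unreliable`, and the
#'   two primary breakpoint intervals (`bp1_*`, `bp2_*`) used by the filter.
#' @export
define_svs <- function(clusters, segments, window_size = 100, tolerance = 100) {
  cl <- clusters
  n <- nrow(cl)
  if (!n) return(empty_svcalls())
  if (!"somatic" %in% names(cl)) cl$somatic <- FALSE
  used <- rep(FALSE, n)
  calls <- list()

  iv <- function(i, side) {
    if (side == "A") c(cl$bpA_lo[i], cl$bpA_hi[i]) else c(cl$bpB_lo[i], cl$bpB_hi[i])
  }
  chrom_of <- function(i, side) if (side == "A") cl$chromA[i] else cl$chromB[i]

  # which sides of clusters i and j match (same chromosome + interval overlap)
  side_matches <- function(i, j) {
    m <- list()
    for (si in c("A", "B")) for (sj in c("A", "B")) {
      if (chrom_of(i, si) == chrom_of(j, sj) &&
          bp_overlap(iv(i, si)[1], iv(i, si)[2], iv(j, sj)[1], iv(j, sj)[2],
                     tolerance)) {
        m[[length(m) + 1L]] <- c(si, sj)
      }
    }
    m
  }

  # ---- enumerate multi-cluster candidates --------------------------------
  pair_combo <- function(i, j, kind) {
    m <- side_matches(i, j)
    if (kind == "inv") {
      # both sides must match pairwise (A-A & B-B after coordinate ordering)
      both <- any(vapply(m, function(x) all(x == c("A", "A")), TRUE)) &&
        any(vapply(m, function(x) all(x == c("B", "B")), TRUE))
      if (!both) return(NULL)
      lo <- min(cl$bpA_lo[c(i, j)])
      hi <- max(cl$bpB_hi[c(i, j)])
      return(list(type = "inv", members = c(i, j),
                  source_chrom = cl$chromA[i], source_lo = lo, source_hi = hi,
                  insert_chrom = NA, insert_lo = NA, insert_hi = NA))
    }
    if (length(m) != 1L) return(NULL)   # exactly one shared locus
    si <- m[[1]][1]; sj <- m[[1]][2]
    oi <- setdiff(c("A", "B"), si); oj <- setdiff(c("A", "B"), sj)
    if (chrom_of(i, oi) != chrom_of(j, oj)) return(NULL)  # source on one chrom
    ins_iv <- range(c(iv(i, si), iv(j, sj)))
    src <- range(c(iv(i, oi), iv(j, oj)))
    if (kind == "inter" && chrom_of(i, si) == chrom_of(i, oi)) return(NULL)
    if (kind == "intra" && chrom_of(i, si) != chrom_of(i, oi)) return(NULL)
    list(type = "insertion", members = c(i, j),
         source_chrom = chrom_of(i, oi), source_lo = src[1], source_hi = src[2],
         src_iv_1 = iv(i, oi), src_iv_2 = iv(j, oj),
         insert_chrom = chrom_of(i, si), insert_lo = ins_iv[1],
         insert_hi = ins_iv[2])
  }

  cands <- list()
  add_cand <- function(x, class_direct, class_inv, inverted) {
    if (is.null(x)) return()
    x$class <- if (inverted) class_inv else class_direct
    x$s_total <- sum(cl$s[x$members])
    cands[[length(cands) + 1L]] <<- x
  }
  idx <- seq_len(n)
  dist_i <- idx[cl$category == "DISTANCE"]
  order_i <- idx[cl$category == "ORDER"]
  ori_f <- idx[cl$category == "ORI" & cl$strand_config == "ff"]
  ori_r <- idx[cl$category == "ORI" & cl$strand_config == "rr"]
  chrpos_i <- idx[cl$category == "CHRPOS"]
  chrposori_i <- idx[cl$category == "CHRPOSORI"]

  for (i in dist_i) for (j in order_i) {
    add_cand(pair_combo(i, j, "intra"), "GAIN_INTRA", NULL, FALSE)
  }
  for (i in ori_f) for (j in ori_r) {
    add_cand(pair_combo(i, j, "inv"), "INV_CAND", NULL, FALSE)
    add_cand(pair_combo(i, j, "intra"), NULL, "GAIN_INTRA_INV", TRUE)
  }
  combn2 <- function(v) if (length(v) < 2) list() else
    utils::combn(v, 2, simplify = FALSE)
  for (p in combn2(chrpos_i)) {
    add_cand(pair_combo(p[1], p[2], "inter"), "GAIN_INTER", NULL, FALSE)
  }
  for (p in combn2(chrposori_i)) {
    add_cand(pair_combo(p[1], p[2], "inter"), NULL, "GAIN_INTER_INV", TRUE)
  }

  # cut-paste triples: an insertion pair + a DISTANCE cluster matching the two
  # source junctions
  base <- cands
  for (x in base) {
    if (x$type != "insertion") next
    for (k in dist_i) {
      if (k %in% x$members) next
      if (cl$chromA[k] != x$source_chrom || cl$chromB[k] != x$source_chrom) next
      m1 <- bp_overlap(cl$bpA_lo[k], cl$bpA_hi[k], x$src_iv_1[1], x$src_iv_1[2],
                       tolerance) ||
        bp_overlap(cl$bpA_lo[k], cl$bpA_hi[k], x$src_iv_2[1], x$src_iv_2[2],
                   tolerance)
      m2 <- bp_overlap(cl$bpB_lo[k], cl$bpB_hi[k], x$src_iv_1[1], x$src_iv_1[2],
                       tolerance) ||
        bp_overlap(cl$bpB_lo[k], cl$bpB_hi[k], x$src_iv_2[1], x$src_iv_2[2],
                   tolerance)
      if (m1 && m2) {
        t <- x
        t$type <- "cutpaste"
        t$members <- c(x$members, k)
        t$class <- switch(x$class,
          GAIN_INTRA = "TRANS_INTRA", GAIN_INTRA_INV = "TRANS_INTRA_INV",
          GAIN_INTER = "TRANS_INTER", GAIN_INTER_INV = "TRANS_INTER_INV",
          x$class)
        t$s_total <- sum(cl$s[t$members])
        cands[[length(cands) + 1L]] <- t
      }
    }
  }

  # ---- greedy acceptance by descending total support ---------------------
  if (length(cands)) {
    ord <- order(-vapply(cands, function(x) x$s_total, numeric(1)),
                 vapply(cands, function(x) min(x$members), numeric(1)))
    for (x in cands[ord]) {
      if (any(used[x$members])) next
      if (x$type == "inv") {
        st <- rd_support(segments, x$source_chrom, x$source_lo, x$source_hi,
                         "NEUTRAL", window_size)
        if (st == "no") next
        cls <- "INV"
        rd <- "NEUTRAL"
      } else if (x$type == "insertion") {
        st <- rd_support(segments, x$source_chrom, x$source_lo, x$source_hi,
                         "GAIN", window_size)
        if (st != "yes") next
        cls <- x$class
        rd <- "GAIN"
      } else { # cutpaste
        st <- rd_support(segments, x$source_chrom, x$source_lo, x$source_hi,
                         "NEUTRAL", window_size)
        if (st == "no") next
        cls <- x$class
        rd <- "NEUTRAL"
      }
      used[x$members] <- TRUE
      lead <- x$members[which.max(cl$s[x$members])]
      calls[[length(calls) + 1L]] <- tibble(
        sv_class = cls,
        source_chrom = x$source_chrom,
        source_lo = as.integer(x$source_lo), source_hi = as.integer(x$source_hi),
        insert_chrom = as.character(x$insert_chrom),
        insert_lo = as.integer(x$insert_lo), insert_hi = as.integer(x$insert_hi),
        orientation = if (cls == "INV" || grepl("_INV$", cls)) "inverted" else "direct",
        cluster_ids = list(cl$cluster_id[x$members]),
        s_total = sum(cl$s[x$members]),
        rd_state = rd,
        somatic = all(cl$somatic[x$members]),
        unreliable = FALSE,
        bp1_chrom = cl$chromA[lead], bp1_lo = cl$bpA_lo[lead],
        bp1_hi = cl$bpA_hi[lead],
        bp2_chrom = cl$chromB[lead], bp2_lo = cl$bpB_lo[lead],
        bp2_hi = cl$bpB_hi[lead]
      )
    }
  }

  # ---- single-cluster rules ----------------------------------------------
  for (i in idx[!used]) {
    cat_i <- cl$category[i]
    unreli <- isTRUE(cl$unreliable[i])
    cls <- "UNDEFINED"
    rd <- NA_character_
    if (!unreli && cat_i == "DISTANCE") {
      st <- rd_support(segments, cl$chromA[i], cl$bpA_lo[i], cl$bpB_hi[i],
                       "LOSS", window_size)
      cls <- if (st == "yes") "DEL" else "PUTATIVE_DELETION"
      rd <- if (st == "yes") "LOSS" else NA_character_
    } else if (!unreli && cat_i == "ORDER") {
      st <- rd_support(segments, cl$chromA[i], cl$bpA_lo[i], cl$bpB_hi[i],
                       "GAIN", window_size)
      if (st == "yes") {
        cls <- "DUP_TANDEM"
        rd <- "GAIN"
      }
    }
    calls[[length(calls) + 1L]] <- tibble(
      sv_class = cls,
      source_chrom = cl$chromA[i],
      source_lo = cl$bpA_lo[i], source_hi = cl$bpB_hi[i],
      insert_chrom = NA_character_, insert_lo = NA_integer_,
      insert_hi = NA_integer_,
      orientation = "direct",
      cluster_ids = list(cl$cluster_id[i]),
      s_total = cl$s[i],
      rd_state = rd,
      somatic = cl$somatic[i],
      unreliable = unreli,
      bp1_chrom = cl$chromA[i], bp1_lo = cl$bpA_lo[i], bp1_hi = cl$bpA_hi[i],
      bp2_chrom = cl$chromB[i], bp2_lo = cl$bpB_lo[i], bp2_hi = cl$bpB_hi[i]
    )
  }

  out <- bind_rows(calls)
  out$reported_type <- reported_type_of(out$sv_class)
  out <- out %>%
    arrange(.data$source_chrom, .data$source_lo) %>%
    mutate(call_id = sprintf("sv%04d", row_number())) %>%
    select("call_id", "sv_class", "reported_type", dplyr::everything())
  out
}

empty_svcalls <- function() {
  tibble(
    call_id = character(0), sv_class = character(0), reported_type = character(0),
    source_chrom = character(0), source_lo = integer(0), source_hi = integer(0),
    insert_chrom = character(0), insert_lo = integer(0), insert_hi = integer(0),
    orientation = character(0), cluster_ids = list(), s_total = integer(0),
    rd_state = character(0), somatic = logical(0), unreliable = logical(0),
    bp1_chrom = character(0), bp1_lo = integer(0), bp1_hi = integer(0),
    bp2_chrom = character(0), bp2_lo = integer(0), bp2_hi = integer(0)
  )
}
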