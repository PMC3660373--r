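#' Cluster anomalous read pairs
#'
#' Groups same-category anomalous pairs that point to the same rearrangement.
#' Two pairs co-cluster when both of their side anchors (the rightmost aligned
#' position of the read on each side) lie within the distance bound `D` of
#' each other; clusters are the transitive closure (single linkage) of this
#' relation, computed with a coordinate-sorted sweep plus union-find so the
#' result is independent of input order and agrees exactly with a brute-force
#' closure. Opposite-strand categories (`DISTANCE`, `ORDER`, `CHRPOS`) are
#' clustered on their forward-read and reverse-read anchors; same-strand
#' categories (`ORI`, `CHRPOSORI`) cluster forward-forward and reverse-reverse
#' pairs separately on their two coordinate-ordered sides. Every pair belongs
#' to at most one cluster and only clusters with at least `min_support` pairs
#' are emitted.
#'
#' The default bound is `D = UC - LC`; under a Normal insert distribution this
#' equals twice the `1 - alpha/2` Normal quantile times the insert-size
#' standard deviation.
#'
#' @param pairs Classified pair tibble (only anomalous categories are used).
#' @param model An `insert_model` (provides `D` and `UC`).
#' @param d Distance bound override in bp (default `UC - LC`).
#' @param min_support Minimum supporting pairs per emitted cluster (default 2).
#' @return Tibble of clusters: `cluster_id`, `category`, `strand_config`,
#'   side-1/2 chromosome, anchor extrema and strand, `s` (support), member
#'   read names (list-column), and the best per-pair base-quality floor
#'   `q_best`.
#' @export
cluster_pairs <- function(pairs, model, d = NULL, min_support = 2) {
  cut <- model_cutoffs(model)
  if (is.null(d)) d <- cut$d
  anchors <- pair_anchors(pairs)
  if (!nrow(anchors)) return(empty_clusters())
  groups <- split(
    anchors,
    paste(anchors$category, anchors$strand_config, anchors$chrom_1,
          anchors$chrom_2, sep = "\r")
  )
  out <- list()
  for (g in groups) {
    memb <- closure_cluster(g$x_1, g$x_2, d)
    g$.memb <- memb
    cl <- g %>%
      group_by(.data$.memb) %>%
      summarise(
        category = first(.data$category),
        strand_config = first(.data$strand_config),
        chrom_1 = first(.data$chrom_1),
        x1_min = min(.data$x_1), x1_max = max(.data$x_1),
        strand_s1 = first(.data$strand_s1),
        chrom_2 = first(.data$chrom_2),
        x2_min = min(.data$x_2), x2_max = max(.data$x_2),
        strand_s2 = first(.data$strand_s2),
        s = dplyr::n(),
        q_best = max(.data$baseq_min),
        members = list(sort(.data$qname)),
        x1s = list(.data$x_1), x2s = list(.data$x_2),
        .groups = "drop"
      ) %>%
      select(-".memb")
    out[[length(out) + 1L]] <- cl[cl$s >= min_support, ]
  }
  res <- bind_rows(out)
  if (!nrow(res)) return(empty_clusters())
  res <- res %>%
    arrange(.data$category, .data$chrom_1, .data$x1_min, .data$chrom_2,
            .data$x2_min) %>%
    mutate(cluster_id = sprintf("c%04d", row_number())) %>%
    select("cluster_id", dplyr::everything())
  res
}

empty_clusters <- function() {
  tibble(
    cluster_id = character(0), category = character(0),
    strand_config = character(0),
    chrom_1 = character(0), x1_min = integer(0), x1_max = integer(0),
    strand_s1 = character(0),
    chrom_2 = character(0), x2_min = integer(0), x2_max = integer(0),
    strand_s2 = character(0),
    s = integer(0), q_best = integer(0), members = list(),
    x1s = list(), x2s = list()
  )
}

# Transitive closure of {|dx1| <= d & |dx2| <= d} by sorted sweep + union-find.
closure_cluster <- function(x1, x2, d) {
  n <- length(x1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(x1, x2)
  for (a in seq_len(n)) {
    i <- ord[a]
    b <- a - 1L
    while (b >= 1L && x1[i] - x1[ord[b]] <= d) {
      j <- ord[b]
      if (abs(x2[i] - x2[j]) <= d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      b <- b - 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Predict breakpoint intervals for clusters
#'
#' For a side supported by forward-strand reads the junction must lie right of
#' every read end but within one upper cut-off of the earliest: the interval is
#' `[max(x), min(x) + UC)`. For a reverse-supported side it is mirrored:
#' `(max(x) - UC, min(x)]`. Interval width therefore shrinks (weakly) as
#' support grows. Intervals are clipped at chromosome bounds when lengths are
#' supplied, and sides are then ordered so `bpA` is the lower genomic
#' coordinate. Clusters whose two intervals overlap each other are flagged
#' `unreliable` (kept, but such calls are typically discarded).
#'
#' @param clusters Cluster tibble from [cluster_pairs()].
#' @param model An `insert_model`.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return `clusters` with columns `chromA`, `bpA_lo`, `bpA_hi`, `chromB`,
#'   `bpB_lo`, `bpB_hi` (half-open `[lo, hi)` intervals) and `unreliable`.
#' @export
predict_breakpoints <- function(clusters, model, chrom_lengths = NULL) {
  if (!nrow(clusters)) {
    clusters[c("chromA", "chromB")] <- character(0)
    clusters[c("bpA_lo", "bpA_hi", "bpB_lo", "bpB_hi")] <- integer(0)
    clusters$unreliable <- logical(0)
    return(clusters)
  }
  uc <- ceiling(model_cutoffs(model)$uc)
  side_interval <- function(xmin, xmax, strand) {
    # forward-supported: [max(x), min(x) + UC); reverse: (max(x) - UC, min(x)]
    lo <- ifelse(strand == "+", xmax, xmax - uc + 1L)
    hi <- ifelse(strand == "+", xmin + uc, xmin + 1L)
    list(lo = as.integer(lo), hi = as.integer(pmax(hi, lo + 1L)))
  }
  s1 <- side_interval(clusters$x1_min, clusters$x1_max, clusters$strand_s1)
  s2 <- side_interval(clusters$x2_min, clusters$x2_max, clusters$strand_s2)
  if (!is.null(chrom_lengths)) {
    clip <- function(v, chrom, upper) {
      lim <- unname(chrom_lengths[chrom]) + 1L
      v <- pmax(v, if (upper) 2L else 1L)
      pmin(v, ifelse(is.na(lim), v, if (upper) lim else lim - 1L))
    }
    s1$lo <- clip(s1$lo, clusters$chrom_1, FALSE)
    s1$hi <- clip(s1$hi, clusters$chrom_1, TRUE)
    s2$lo <- clip(s2$lo, clusters$chrom_2, FALSE)
    s2$hi <- clip(s2$hi, clusters$chrom_2, TRUE)
  }
  a_first <- clusters$chrom_1 < clusters$chrom_2 |
    (clusters$chrom_1 == clusters$chrom_2 & s1$lo <= s2$lo)
  clusters$chromA <- ifelse(a_first, clusters$chrom_1, clusters$chrom_2)
  clusters$bpA_lo <- ifelse(a_first, s1$lo, s2$lo)
  clusters$bpA_hi <- ifelse(a_first, s1$hi, s2$hi)
  clusters$chromB <- ifelse(a_first, clusters$chrom_2, clusters$chrom_1)
  clusters$bpB_lo <- ifelse(a_first, s2$lo, s1$lo)
  clusters$bpB_hi <- ifelse(a_first, s2$hi, s1$hi)
  clusters$unreliable <- clusters$chromA == clusters$chromB &
    clusters$bpA_lo < clusters$bpB_hi & clusters$bpB_lo < clusters$bpA_hi
  clusters
}

#' Annotate cluster confidence tiers
#'
#' Adds the three reliability tiers used to stratify breakpoint predictions:
#'
#' * `q_tier`: 1 when at least one member pair has both reads at phred >= 30
#'   (>= 99.9% base-call accuracy), 2 when at least one reaches phred >= 20
#'   (99%) without reaching tier 1, else `"lower"`.
#' * `support_tier`: `"special"` when the supporting-pair count `S` is
#'   significantly larger than the mean coverage (one-sided Poisson tail
#'   `P(X >= S) < 1e-4` at rate `mean_coverage`), else `"high"` for S >= 10,
#'   `"medium"` for S in 5..9, `"low"` below.
#' * `length_tier`: from the variant span (outer distance `bpB_hi - bpA_lo`)
#'   for intra-chromosomal clusters: `"high"` for 1 kb..1 Mb, `"medium"` for
#'   500 bp..1 kb, `"special"` outside those bins; `"n/a"` for
#'   inter-chromosomal (`CHRPOS`/`CHRPOSORI`) clusters, whose two sides do not
#'   define a length.
#'
#' @param clusters Breakpoint-predicted cluster tibble.
#' @param mean_coverage Mean sequence coverage (fold).
#' @return `clusters` with `q_tier`, `support_tier` and `length_tier`.
#' @export
annotate_confidence <- function(clusters, mean_coverage) {
  if (!nrow(clusters)) {
    clusters[c("q_tier", "support_tier", "length_tier")] <- character(0)
    return(clusters)
  }
  clusters$q_tier <- dplyr::case_when(
    clusters$q_best >= 30 ~ "1",
    clusters$q_best >= 20 ~ "2",
    TRUE ~ "lower"
  )
  special <- ppois(clusters$s - 1, mean_coverage, lower.tail = FALSE) < 1e-4
  clusters$support_tier <- dplyr::case_when(
    special ~ "special",
    clusters$s >= 10 ~ "high",
    clusters$s >= 5 ~ "medium",
    TRUE ~ "low"
  )
  span <- ifelse(clusters$chromA == clusters$chromB,
                 clusters$bpB_hi - clusters$bpA_lo, NA_integer_)
  clusters$length_tier <- dplyr::case_when(
    is.na(span) ~ "n/a",
    span >= 1000 & span < 1e6 ~ "high",
    span >= 500 & span < 1000 ~ "medium",
    TRUE ~ "special"
  )
  clusters
}

#' Write clusters as a tab-separated file
#'
#' @param clusters Annotated cluster tibble.
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  out <- clusters
  out$members <- vapply(out$members, paste, "", collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}
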