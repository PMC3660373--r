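#' Classify read pairs into concordant and anomaly categories
#'
#' Assigns every mapped pair exactly one category from the geometry of its two
#' alignments and the insert-size model:
#'
#' * `CONCORDANT` — same chromosome, leftmost read forward / rightmost reverse,
#'   insert length `l` within `[LC, UC]`;
#' * `DISTANCE` — same configuration with `l > UC` (stretched insert);
#' * `INSERT_DISCARDED` — same configuration with `l < LC`; indicative of small
#'   insertions, which paired reads cannot size reliably, so these pairs are
#'   set aside and not used further;
#' * `ORDER` — same chromosome, right orientation but wrong order (leftmost
#'   read reverse, rightmost forward);
#' * `ORI` — same chromosome, both reads on the same strand;
#' * `CHRPOS` — different chromosomes, opposite strands;
#' * `CHRPOSORI` — different chromosomes, same strand.
#'
#' Pairs where either end has mapping quality below `mapq_floor` are marked
#' `MAPQ_FILTERED` and excluded from downstream analysis (multi-mappers at
#' mapping quality 0 generate spurious anomaly signal). `ONE_END`/`ORPHAN`
#' rows from triage pass through unchanged. In mate-pair mode both strands are
#' flipped before classification (the two chemistries differ only by this
#' convention).
#'
#' @param pairs Pair tibble from [simulate_read_pairs()], [read_alignments()]
#'   or [triage_pairs()].
#' @param model An `insert_model`; per-library cut-offs are used when both the
#'   pairs and the model carry libraries.
#' @param library_type `"paired_end"` (default) or `"mate_pair"`.
#' @param mapq_floor Minimum mapping quality for both ends (default 1).
#' @return `pairs` with columns `l` (insert length, `NA` when undefined) and
#'   `category`.
#' @export
classify_pairs <- function(pairs, model, library_type = c("paired_end", "mate_pair"),
                           mapq_floor = 1) {
  library_type <- match.arg(library_type)
  if (library_type == "mate_pair") {
    flip <- function(s) ifelse(s == "+", "-", "+")
    pairs$strand1 <- flip(pairs$strand1)
    pairs$strand2 <- flip(pairs$strand2)
  }
  has_lib <- "library" %in% names(pairs) && length(unique(model$library)) > 1
  lib <- if (has_lib) pairs$library else rep(model$library[1], nrow(pairs))
  i <- match(lib, model$library)
  if (anyNA(i)) abort("pair library without an insert model")
  lc <- model$lc[i]
  uc <- model$uc[i]

  o <- orient_pairs(pairs)
  mapped_pair <- pairs$mapped1 & pairs$mapped2
  prior <- if ("category" %in% names(pairs)) pairs$category else
    ifelse(mapped_pair, NA_character_,
           ifelse(pairs$mapped1 | pairs$mapped2, "ONE_END", "ORPHAN"))
  same_chrom <- o$applicable
  l <- ifelse(same_chrom & o$opposite & o$left_fwd,
              o$inner_r - o$inner_l, NA_integer_)
  mapq_ok <- pairs$mapq1 >= mapq_floor & pairs$mapq2 >= mapq_floor

  category <- dplyr::case_when(
    !mapped_pair ~ prior,
    !mapq_ok ~ "MAPQ_FILTERED",
    same_chrom & o$opposite & o$left_fwd & l > uc ~ "DISTANCE",
    same_chrom & o$opposite & o$left_fwd & l < lc ~ "INSERT_DISCARDED",
    same_chrom & o$opposite & o$left_fwd ~ "CONCORDANT",
    same_chrom & o$opposite ~ "ORDER",
    same_chrom ~ "ORI",
    o$opposite ~ "CHRPOS",
    TRUE ~ "CHRPOSORI"
  )
  pairs$l <- as.integer(l)
  pairs$category <- category
  pairs
}

#' Tally pair categories
#'
#' @param pairs Classified pair tibble.
#' @return Tibble of `category` counts in canonical order.
#' @export
count_categories <- function(pairs) {
  tb <- table(factor(pairs$category, levels = RP_CATEGORIES))
  tibble(category = names(tb), n = as.integer(tb))
}

# Anchor geometry for clustering. For each anomalous pair, the clustering
# anchors are the rightmost aligned positions of the two reads. Sides are
# fixed deterministically:
#  - opposite-strand categories (DISTANCE/ORDER/CHRPOS): side F = the
#    forward-strand read, side R = the reverse-strand read;
#  - same-strand categories (ORI/CHRPOSORI): side A = the read with the lower
#    (chromosome, start) key, side B the other; both sides share the pair's
#    strand, and forward-pair clusters are kept apart from reverse-pair ones.
# Returns one row per pair: chrom/anchor/strand for side 1 and side 2 plus the
# grouping key.
pair_anchors <- function(pairs) {
  stopifnot("category" %in% names(pairs))
  p <- pairs[pairs$category %in% ANOMALOUS_CATEGORIES, ]
  if (!nrow(p)) {
    return(tibble(
      qname = character(0), category = character(0), strand_config = character(0),
      chrom_1 = character(0), x_1 = integer(0), strand_s1 = character(0),
      chrom_2 = character(0), x_2 = integer(0), strand_s2 = character(0),
      baseq_min = integer(0)
    ))
  }
  opp <- p$strand1 != p$strand2
  # side order: opposite-strand -> (forward read, reverse read);
  # same-strand -> lower (chrom, start) first
  one_first <- ifelse(opp, p$strand1 == "+",
                      ifelse(p$chrom1 != p$chrom2, p$chrom1 < p$chrom2,
                             p$start1 <= p$start2))
  tibble(
    qname = p$qname,
    category = p$category,
    strand_config = ifelse(opp, "fr", ifelse(p$strand1 == "+", "ff", "rr")),
    chrom_1 = ifelse(one_first, p$chrom1, p$chrom2),
    x_1 = as.integer(ifelse(one_first, p$end1, p$end2)),
    strand_s1 = ifelse(one_first, p$strand1, p$strand2),
    chrom_2 = ifelse(one_first, p$chrom2, p$chrom1),
    x_2 = as.integer(ifelse(one_first, p$end2, p$end1)),
    strand_s2 = ifelse(one_first, p$strand2, p$strand1),
    baseq_min = as.integer(pmin(p$baseq1, p$baseq2))
  )
}
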