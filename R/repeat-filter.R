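#' Load repeat-annotation tracks
#'
#' Reads the three BED-like tracks used by the call filter: segmental
#' duplications (SD), simple sequence repeats (SSR), and transposable elements
#' (TE) with a per-element identity. BED coordinates are 0-based half-open and
#' are converted to the package's 1-based convention on load. The TE identity
#' is taken from the track's score-like 4th/5th column: with
#' `te_identity = "milli_divergence"` (RepeatMasker-style) the value is a
#' divergence in units of 1/1000 and identity is `1 - value/1000`; with
#' `"identity"` the column is a plain fraction in `[0, 1]`. Elements with
#' identity above `te_min_identity` form the low-divergence TE set used for
#' filtering.
#'
#' @param sd_path,ssr_path,te_path BED files (at least chrom/start/end; the TE
#'   track needs a 4th column `name` and 5th column carrying divergence or
#'   identity). `NULL` tracks are treated as empty.
#' @param te_identity Dialect of the TE identity column (see above).
#' @param te_min_identity Identity threshold for the low-divergence set
#'   (default 0.9).
#' @return A list of class `repeat_annotation` with `GRanges` per track
#'   (`sd`, `ssr`, `te`, and `te_lowdiv`), the TE ranges carrying an
#'   `identity` metadata column.
#' @export
load_repeat_tracks <- function(sd_path = NULL, ssr_path = NULL, te_path = NULL,
                               te_identity = c("milli_divergence", "identity"),
                               te_min_identity = 0.9) {
  te_identity <- match.arg(te_identity)
  sd <- read_bed_track(sd_path)
  ssr <- read_bed_track(ssr_path)
  te <- read_bed_track(te_path, min_cols = if (is.null(te_path)) 3L else 5L)
  if (length(te)) {
    v <- as.numeric(S4Vectors::mcols(te)$score)
    ident <- if (te_identity == "milli_divergence") 1 - v / 1000 else v
    if (any(is.na(ident) | ident < 0 | ident > 1)) {
      abort("TE identity column outside [0, 1] after conversion")
    }
    S4Vectors::mcols(te)$identity <- ident
  } else {
    S4Vectors::mcols(te)$identity <- numeric(0)
  }
  structure(
    list(sd = sd, ssr = ssr, te = te,
         te_lowdiv = te[S4Vectors::mcols(te)$identity > te_min_identity]),
    class = "repeat_annotation"
  )
}

read_bed_track <- function(path, min_cols = 3L) {
  if (is.null(path)) return(GenomicRanges::GRanges())
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < min_cols)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d in %s: expected >= %d columns",
                  which(keep)[bad[1]], path, min_cols))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end) || any(end < start)) {
    bad <- which(is.na(start) | is.na(end) | end < start)[1]
    abort(sprintf("malformed BED line %d in %s: bad coordinates",
                  which(keep)[bad], path))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (min_cols >= 5L) {
    S4Vectors::mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
    S4Vectors::mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
    if (anyNA(S4Vectors::mcols(gr)$score)) {
      abort(sprintf("malformed BED line in %s: non-numeric score column", path))
    }
  }
  gr
}

# GRanges of the two breakpoint intervals of each call (2 ranges per call,
# call index in mcols$i). Intervals are half-open [lo, hi).
call_breakpoint_ranges <- function(calls) {
  GenomicRanges::GRanges(
    c(calls$bp1_chrom, calls$bp2_chrom),
    IRanges::IRanges(c(calls$bp1_lo, calls$bp2_lo),
                     c(calls$bp1_hi - 1L, calls$bp2_hi - 1L)),
    i = rep(seq_len(nrow(calls)), 2)
  )
}

#' Filter non-defined calls against repeat annotation (cascade)
#'
#' Calls that are supported by read depth or by a combination of clusters
#' (every class other than `PUTATIVE_DELETION`/`UNDEFINED`) always pass.
#' Filter-eligible calls are routed down a cascade on their two predicted
#' breakpoint intervals: a call with either interval intersecting a segmental
#' duplication goes to `in_sd`; of the rest, those hitting a simple repeat go
#' to `in_ssr`; of the rest, those hitting a low-divergence transposable
#' element (> 90% identity by default) go to `in_te`; the remainder pass. The
#' intersection test uses the whole predicted interval, since the true
#' junction is only localized to it. Passing calls are annotated with the
#' highest identity of any TE overlapping a breakpoint (`te_identity`, `NA`
#' when none).
#'
#' @param calls SV-call tibble from [define_svs()].
#' @param annotation A `repeat_annotation` from [load_repeat_tracks()].
#' @return `calls` with columns `filter_verdict` (`passed`, `in_sd`, `in_ssr`,
#'   `in_te`) and `te_identity`.
#' @export
final_count_down <- function(calls, annotation) {
  stopifnot(inherits(annotation, "repeat_annotation"))
  if (!nrow(calls)) {
    calls$filter_verdict <- character(0)
    calls$te_identity <- numeric(0)
    return(calls)
  }
  eligible <- calls$sv_class %in% c("PUTATIVE_DELETION", "UNDEFINED")
  bp <- call_breakpoint_ranges(calls)
  hits_track <- function(gr) {
    h <- GenomicRanges::findOverlaps(bp, gr)
    idx <- unique(S4Vectors::mcols(bp)$i[S4Vectors::queryHits(h)])
    seq_len(nrow(calls)) %in% idx
  }
  in_sd <- hits_track(annotation$sd)
  in_ssr <- hits_track(annotation$ssr)
  in_te <- hits_track(annotation$te_lowdiv)
  verdict <- dplyr::case_when(
    !eligible ~ "passed",
    in_sd ~ "in_sd",
    in_ssr ~ "in_ssr",
    in_te ~ "in_te",
    TRUE ~ "passed"
  )
  te_ident <- rep(NA_real_, nrow(calls))
  if (length(annotation$te)) {
    h <- GenomicRanges::findOverlaps(bp, annotation$te)
    if (length(h)) {
      ids <- S4Vectors::mcols(annotation$te)$identity[S4Vectors::subjectHits(h)]
      ci <- S4Vectors::mcols(bp)$i[S4Vectors::queryHits(h)]
      agg <- tapply(ids, ci, max)
      te_ident[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  calls$filter_verdict <- verdict
  calls$te_identity <- ifelse(verdict == "passed", te_ident, NA_real_)
  calls
}
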