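#' Insert lengths of properly oriented pairs
#'
#' The insert length is `l = right - left`, the distance between the innermost
#' aligned positions of the two reads: the end of the leftmost (forward) read
#' and the start of the rightmost (reverse) read. Defined only for same
#' chromosome pairs mapped leftmost-forward / rightmost-reverse; other pairs
#' get `NA`.
#'
#' @param pairs Pair tibble (both ends mapped rows are considered).
#' @return Integer vector of insert lengths, `NA` where not applicable.
#' @export
insert_lengths <- function(pairs) {
  o <- orient_pairs(pairs)
  ifelse(o$applicable & o$opposite & o$left_fwd,
         o$inner_r - o$inner_l, NA_integer_)
}

# Shared orientation geometry: identify the leftmost/rightmost read of each
# mapped pair. Ties on the leftmost coordinate are resolved as right order.
orient_pairs <- function(pairs) {
  applicable <- pairs$mapped1 & pairs$mapped2 & pairs$chrom1 == pairs$chrom2
  applicable[is.na(applicable)] <- FALSE
  one_left <- pairs$start1 <= pairs$start2
  one_left[!applicable] <- TRUE
  l_start <- ifelse(one_left, pairs$start1, pairs$start2)
  l_end <- ifelse(one_left, pairs$end1, pairs$end2)
  l_strand <- ifelse(one_left, pairs$strand1, pairs$strand2)
  r_start <- ifelse(one_left, pairs$start2, pairs$start1)
  r_strand <- ifelse(one_left, pairs$strand2, pairs$strand1)
  list(
    applicable = applicable,
    opposite = pairs$strand1 != pairs$strand2,
    left_fwd = l_strand == "+",
    inner_l = l_end,
    inner_r = r_start,
    left_start = l_start,
    right_start = r_start,
    right_strand = r_strand
  )
}

#' Estimate the empirical insert-size model
#'
#' Computes the empirical distribution of the insert length `L` from properly
#' oriented pairs and derives the concordance cut-offs `LC`/`UC` as its
#' `alpha/2` and `1 - alpha/2` percentiles (linear interpolation between order
#' statistics). Under a Normal insert distribution with `alpha = 0.01` these
#' sit 2.58 standard deviations from the mean. When a `library` column is
#' present the model is estimated per library, else globally.
#'
#' @param x Pair tibble, or a numeric vector of insert lengths.
#' @param alpha Assumed maximum discordant fraction, in (0, 1); default 0.01.
#' @param min_obs Observation floor below which the model is flagged
#'   low-confidence (warning state).
#' @param max_obs Subsample cap per library (first `max_obs` lengths).
#' @return An object of class `insert_model`; a tibble with one row per
#'   library: `library`, `alpha`, `lc`, `uc`, `median_l`, `mean_l`, `sd_l`,
#'   `n_obs`, `low_n`.
#' @examples
#' m <- estimate_insert_model(rnorm(5000, 300, 30))
#' @export
estimate_insert_model <- function(x, alpha = 0.01, min_obs = 1000,
                                  max_obs = 1e6) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (is.data.frame(x)) {
    lens <- insert_lengths(x)
    lib <- if ("library" %in% names(x)) x$library else rep("lib1", nrow(x))
    keep <- !is.na(lens)
    lens <- lens[keep]
    lib <- lib[keep]
  } else {
    lens <- as.numeric(x)
    lens <- lens[!is.na(lens)]
    lib <- rep("lib1", length(lens))
  }
  if (!length(lens)) abort("no usable insert lengths")
  rows <- lapply(split(lens, lib), function(l) {
    l <- head(l, max_obs)
    qs <- quantile(l, c(alpha / 2, 1 - alpha / 2), type = 7, names = FALSE)
    tibble(
      alpha = alpha, lc = qs[1], uc = qs[2],
      median_l = median(l), mean_l = mean(l),
      sd_l = if (length(l) > 1) sd(l) else 0,
      n_obs = length(l), low_n = length(l) < min_obs
    )
  })
  out <- bind_rows(rows, .id = "library")
  if (any(out$low_n)) {
    warn(paste0("insert model estimated from fewer than ", min_obs,
                " pairs for: ",
                paste(out$library[out$low_n], collapse = ", ")))
  }
  structure(out, class = c("insert_model", class(out)))
}

#' @export
print.insert_model <- function(x, ...) {
  cat("<insert_model> alpha =", x$alpha[1], "\n")
  print(as_tibble(x), ...)
  invisible(x)
}

# Cut-offs for one library (first library by default); returns list(lc, uc, d)
# where d = uc - lc is the clustering distance bound.
model_cutoffs <- function(model, library = NULL) {
  stopifnot(inherits(model, "insert_model"))
  i <- if (is.null(library)) 1L else match(library, model$library)
  if (is.na(i)) abort(paste0("no insert model for library ", library))
  list(lc = model$lc[i], uc = model$uc[i], d = model$uc[i] - model$lc[i])
}

#' Serialize an insert-size model to a JSON report
#'
#' @param model An `insert_model`.
#' @param path Output path.
#' @export
write_insert_model <- function(model, path) {
  jsonlite::write_json(as.list(as_tibble(model)), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.insert_model <- function(x, ...) as_tibble(x)

#' @export
glance.insert_model <- function(x, ...) {
  tibble(
    n_libraries = nrow(x), alpha = x$alpha[1],
    n_obs = sum(x$n_obs), low_n = any(x$low_n)
  )
}
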