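#' Simulate a reference genome
#'
#' Draws independent bases with a target GC composition, one sequence per
#' chromosome. The GC profile may be a single fraction applied everywhere or a
#' function of position returning the local GC fraction (evaluated per base).
#'
#' @param n_chroms Number of chromosomes to emit (named `chr1`, `chr2`, ...).
#' @param length Chromosome length in bp (recycled across chromosomes).
#' @param gc GC fraction in `[0, 1]`, or a function `f(pos)` mapping 1-based
#'   positions to GC fractions.
#' @param seed Integer seed; the same seed always yields the same sequences.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @examples
#' ref <- simulate_reference(1, 10000, gc = 0.5, seed = 1)
#' @export
simulate_reference <- function(n_chroms = 1, length = 100000, gc = 0.5,
                               seed = 1) {
  if (any(length <= 0)) abort("chromosome `length` must be positive")
  lens <- rep_len(as.integer(length), n_chroms)
  set.seed(seed)
  seqs <- lapply(lens, function(L) {
    p_gc <- if (is.function(gc)) gc(seq_len(L)) else rep(gc, L)
    if (any(p_gc < 0 | p_gc > 1)) abort("`gc` must be within [0, 1]")
    is_gc <- runif(L) < p_gc
    half <- runif(L) < 0.5
    base <- ifelse(is_gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
    paste(base, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- paste0("chr", seq_len(n_chroms))
  out
}

#' Build a table of structural-variant specifications
#'
#' Convenience constructor for the planted-SV table consumed by [apply_svs()].
#' Eleven classes are supported: deletion (`DEL`), tandem duplication
#' (`DUP_TANDEM`), in-place inversion (`INV`), copy-paste gains inserted on the
#' same (`GAIN_INTRA`, `GAIN_INTRA_INV`) or a different chromosome
#' (`GAIN_INTER`, `GAIN_INTER_INV`), and cut-paste translocations
#' (`TRANS_INTRA`, `TRANS_INTRA_INV`, `TRANS_INTER`, `TRANS_INTER_INV`).
#' `*_INV` classes insert the moved/copied segment in inverted orientation.
#'
#' @param sv_class Character vector of class names (see above).
#' @param source_chrom,source_start,source_end Source segment (1-based,
#'   inclusive).
#' @param insert_chrom,insert_pos Insertion point for classes that move or copy
#'   material: the segment is spliced in immediately after `insert_pos`.
#' @return A tibble with one row per SV.
#' @export
sv_spec <- function(sv_class, source_chrom, source_start, source_end,
                    insert_chrom = NA_character_, insert_pos = NA_integer_) {
  out <- tibble(
    sv_class = as.character(sv_class),
    source_chrom = as.character(source_chrom),
    source_start = as.integer(source_start),
    source_end = as.integer(source_end),
    insert_chrom = as.character(insert_chrom),
    insert_pos = as.integer(insert_pos)
  )
  validate_sv_specs(out)
  out
}

validate_sv_specs <- function(specs) {
  bad <- setdiff(specs$sv_class, SV_CLASSES)
  if (length(bad)) abort(paste0("unknown sv_class: ", paste(bad, collapse = ", ")))
  if (any(specs$source_start >= specs$source_end)) {
    abort("source_start must be < source_end")
  }
  needs_ins <- specs$sv_class %in% SV_CLASSES_WITH_INSERTION
  if (any(needs_ins & (is.na(specs$insert_chrom) | is.na(specs$insert_pos)))) {
    abort("insertion fields required for copy/cut classes")
  }
  if (any(!needs_ins & !is.na(specs$insert_pos))) {
    abort("insertion fields only allowed for copy/cut classes")
  }
  # non-overlap on the source genome, and insertion points outside sources
  by_chr <- split(specs, specs$source_chrom)
  for (s in by_chr) {
    s <- s[order(s$source_start), ]
    if (nrow(s) > 1 && any(s$source_start[-1] <= s$source_end[-nrow(s)])) {
      abort("SV source regions overlap")
    }
  }
  ins <- specs[needs_ins, ]
  if (nrow(ins)) {
    for (i in seq_len(nrow(ins))) {
      hit <- specs$source_chrom == ins$insert_chrom[i] &
        specs$source_start <= ins$insert_pos[i] &
        specs$source_end >= ins$insert_pos[i]
      if (any(hit)) abort("insertion point falls inside an SV source region")
    }
  }
  invisible(specs)
}

#' Apply structural variants to a reference
#'
#' Rearranges the reference according to `specs`, producing donor sequences
#' plus an exact donor-to-reference block map (used to place simulated reads
#' analytically, with no aligner) and a truth table recording the planted
#' junctions and the read-pair anomaly categories each class is expected to
#' generate.
#'
#' @param reference A [Biostrings::DNAStringSet] from [simulate_reference()].
#' @param specs SV table from [sv_spec()]; may have zero rows.
#' @return A list of class `donor_genome`: `donor` (DNAStringSet), `block_map`
#'   (tibble mapping donor intervals to reference intervals and strands),
#'   `truth` (tibble), `reference`.
#' @export
apply_svs <- function(reference, specs = sv_spec(character(0), character(0),
                                                 integer(0), integer(0))) {
  validate_sv_specs(specs)
  chroms <- names(reference)
  ref_len <- setNames(Biostrings::width(reference), chroms)
  if (!all(specs$source_chrom %in% chroms)) abort("unknown source chromosome")

  needs_ins <- specs$sv_class %in% SV_CLASSES_WITH_INSERTION
  inverted <- grepl("_INV$", specs$sv_class) & specs$sv_class != "INV"
  keeps_source <- !(specs$sv_class %in%
    c("DEL", "TRANS_INTRA", "TRANS_INTRA_INV", "TRANS_INTER", "TRANS_INTER_INV"))

  # per-chromosome events
  removals <- specs[specs$sv_class %in%
    c("DEL", "TRANS_INTRA", "TRANS_INTRA_INV", "TRANS_INTER", "TRANS_INTER_INV"), ]
  inversions <- specs[specs$sv_class == "INV", ]
  ins <- specs[needs_ins, ]
  ins_strand <- ifelse(inverted[needs_ins], "-", "+")
  tandem <- specs[specs$sv_class == "DUP_TANDEM", ]

  insert_events <- bind_rows(
    tibble(chrom = character(0), pos = integer(0), src_chrom = character(0),
           src_start = integer(0), src_end = integer(0), strand = character(0)),
    if (nrow(ins)) tibble(
      chrom = ins$insert_chrom, pos = ins$insert_pos,
      src_chrom = ins$source_chrom, src_start = ins$source_start,
      src_end = ins$source_end, strand = ins_strand
    ),
    if (nrow(tandem)) tibble(
      chrom = tandem$source_chrom, pos = tandem$source_end,
      src_chrom = tandem$source_chrom, src_start = tandem$source_start,
      src_end = tandem$source_end, strand = "+"
    )
  )

  block_map <- list()
  donor_seqs <- character(length(chroms))
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    L <- ref_len[[chrom]]
    ev <- bind_rows(
      {
        r <- removals[removals$source_chrom == chrom, ]
        if (nrow(r)) tibble(kind = "remove", pos = r$source_start,
                            end = r$source_end, src_chrom = NA, src_start = NA,
                            src_end = NA, strand = NA)
      },
      {
        r <- inversions[inversions$source_chrom == chrom, ]
        if (nrow(r)) tibble(kind = "invert", pos = r$source_start,
                            end = r$source_end, src_chrom = NA, src_start = NA,
                            src_end = NA, strand = NA)
      },
      {
        r <- insert_events[insert_events$chrom == chrom, ]
        if (nrow(r))
          tibble(kind = "insert", pos = r$pos, end = r$pos,
                 src_chrom = r$src_chrom, src_start = r$src_start,
                 src_end = r$src_end, strand = r$strand)
      }
    )
    blocks <- list()
    emit <- function(src_chrom, s, e, strand) {
      if (e >= s) blocks[[length(blocks) + 1L]] <<-
          list(ref_chrom = src_chrom, ref_start = s, ref_end = e, strand = strand)
    }
    cur <- 1L
    if (!is.null(ev) && nrow(ev)) {
      # insertion after pos sorts after a removal/inversion starting at pos + 1
      ev <- ev[order(ev$pos + ifelse(ev$kind == "insert", 0.5, 0)), ]
      for (k in seq_len(nrow(ev))) {
        if (ev$kind[k] == "remove") {
          emit(chrom, cur, ev$pos[k] - 1L, "+")
          cur <- ev$end[k] + 1L
        } else if (ev$kind[k] == "invert") {
          emit(chrom, cur, ev$pos[k] - 1L, "+")
          emit(chrom, ev$pos[k], ev$end[k], "-")
          cur <- ev$end[k] + 1L
        } else {
          emit(chrom, cur, ev$pos[k], "+")
          emit(ev$src_chrom[k], ev$src_start[k], ev$src_end[k], ev$strand[k])
          cur <- ev$pos[k] + 1L
        }
      }
    }
    emit(chrom, cur, L, "+")
    bm <- bind_rows(lapply(blocks, as_tibble))
    w <- bm$ref_end - bm$ref_start + 1L
    bm$donor_chrom <- chrom
    bm$donor_end <- cumsum(w)
    bm$donor_start <- bm$donor_end - w + 1L
    block_map[[ci]] <- bm
    pieces <- lapply(seq_len(nrow(bm)), function(i) {
      s <- Biostrings::subseq(reference[[bm$ref_chrom[i]]],
                              bm$ref_start[i], bm$ref_end[i])
      if (bm$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    })
    donor_seqs[ci] <- paste(unlist(pieces), collapse = "")
  }
  donor <- Biostrings::DNAStringSet(donor_seqs)
  names(donor) <- chroms

  truth <- specs %>%
    mutate(
      expected_categories = dplyr::case_when(
        sv_class == "DEL" ~ "DISTANCE",
        sv_class == "DUP_TANDEM" ~ "ORDER",
        sv_class == "INV" ~ "ORI,ORI",
        sv_class == "GAIN_INTRA" ~ "DISTANCE,ORDER",
        sv_class == "GAIN_INTRA_INV" ~ "ORI,ORI",
        sv_class == "GAIN_INTER" ~ "CHRPOS,CHRPOS",
        sv_class == "GAIN_INTER_INV" ~ "CHRPOSORI,CHRPOSORI",
        sv_class == "TRANS_INTRA" ~ "DISTANCE,DISTANCE,ORDER",
        sv_class == "TRANS_INTRA_INV" ~ "DISTANCE,ORI,ORI",
        sv_class == "TRANS_INTER" ~ "DISTANCE,CHRPOS,CHRPOS",
        sv_class == "TRANS_INTER_INV" ~ "DISTANCE,CHRPOSORI,CHRPOSORI"
      )
    )

  structure(
    list(donor = donor, block_map = bind_rows(block_map), truth = truth,
         reference = reference),
    class = "donor_genome"
  )
}

#' @export
print.donor_genome <- function(x, ...) {
  cat("<donor_genome> ", length(x$donor), " chromosome(s), ",
      nrow(x$truth), " planted SV(s)\n", sep = "")
  invisible(x)
}

#' Write sequences to a FASTA file
#'
#' @param x A `DNAStringSet` or `donor_genome` (writes the donor).
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "donor_genome")) x <- x$donor
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
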