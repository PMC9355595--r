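# Degradome (PARE) support: per-transcript 5'-end tag profiles, the
# five-category classification of a predicted cleavage site relative to the
# transcript's signal distribution, and prediction-guided target validation.

#' Build a per-transcript degradome profile
#'
#' Sums degradome tag counts per 1-based 5'-end position on one transcript.
#'
#' @param tags data.frame with columns `transcript_id`, `position`, `count`
#'   (1-based 5'-end coordinates).
#' @param transcript_id transcript to profile.
#' @param transcript_length transcript length in nt.
#' @return object of class `degradome_profile`: integer count vector of
#'   length `transcript_length` plus the transcript id.
#' @export
build_profile <- function(tags, transcript_id, transcript_length) {
  stopifnot(transcript_length >= 1)
  sel <- tags[tags$transcript_id == transcript_id, , drop = FALSE]
  counts <- numeric(transcript_length)
  if (nrow(sel)) {
    bad <- sel$position < 1 | sel$position > transcript_length
    if (any(bad)) {
      stop("degradome position out of range for ", transcript_id, ": ",
           paste(utils::head(sel$position[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    tab <- tapply(sel$count, sel$position, sum)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  structure(list(transcript_id = transcript_id, counts = counts),
            class = "degradome_profile")
}

#' @export
print.degradome_profile <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat("degradome profile for ", x$transcript_id, ": length ",
      length(x$counts), ", ", nz, " nonzero positions, total ",
      sum(x$counts), " tags\n", sep = "")
  invisible(x)
}

#' Classify a cleavage site into degradome categories 0--4
#'
#' With `s` the tag count at the queried position, `M` the transcript-wide
#' maximum and `med` the median of nonzero counts: category 4 if `s == 1`
#' (single read); else 0 if `s` is the unique maximum; 1 if `s` equals a
#' maximum attained at more than one position; 2 if `med < s < M`; 3 if
#' `1 < s <= med`. A zero count (or an all-zero profile) yields no call
#' (`NA`). The median is taken over nonzero positions only, since degradome
#' profiles are sparse.
#'
#' @param profile a `degradome_profile`.
#' @param position 1-based transcript coordinate.
#' @return integer category 0--4, or `NA_integer_` for no call.
#' @export
classify_category <- function(profile, position) {
  counts <- profile$counts
  stopifnot(position >= 1, position <= length(counts))
  s <- counts[position]
  if (s == 0 || all(counts == 0)) return(NA_integer_)
  if (s == 1) return(4L)
  M <- max(counts)
  med <- stats::median(counts[counts > 0])
  if (s == M) {
    if (sum(counts == M) == 1L) return(0L) else return(1L)
  }
  if (s > med) return(2L)
  3L
}

#' Validate predicted target sites against degradome profiles
#'
#' For every predicted site, looks up the degradome signal at the cleavage
#' position (the transcript coordinate paired with miRNA position 10),
#' classifies the site into categories 0--4, and keeps the site when the
#' category is at most `keep_max_category`, the duplex score is at most
#' `max_score`, and the duplex has no mismatch at miRNA positions 10--11
#' (the `c5` column of the prediction table). With `tolerance > 0` the
#' strongest signal within that many nucleotides of the expected position is
#' used instead of a strict position match.
#'
#' @param predictions prediction table from [predict_targets()].
#' @param profiles named list of `degradome_profile` objects (names =
#'   transcript ids).
#' @param keep_max_category maximal category kept as a true target
#'   (default 2).
#' @param max_score maximal duplex score kept (default 4).
#' @param tolerance cleavage-position tolerance in nt (default 0, strict).
#' @return data.frame of cleavage calls: `mirna_id`, `transcript_id`,
#'   `cleave_site`, `score`, `site_count`, `max_count`, `median_nonzero`,
#'   `category`, `kept`, `missing_profile`.
#' @export
validate_targets <- function(predictions, profiles, keep_max_category = 2L,
                             max_score = 4, tolerance = 0L) {
  n <- nrow(predictions)
  out <- data.frame(
    mirna_id = predictions$mirna_id,
    transcript_id = predictions$transcript_id,
    cleave_site = predictions$cleave_site,
    score = predictions$score,
    site_count = NA_real_, max_count = NA_real_, median_nonzero = NA_real_,
    category = NA_integer_, kept = FALSE,
    missing_profile = FALSE, stringsAsFactors = FALSE)
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    tid <- predictions$transcript_id[i]
    prof <- profiles[[tid]]
    if (is.null(prof)) { out$missing_profile[i] <- TRUE; next }
    pos <- predictions$cleave_site[i]
    if (is.na(pos)) next
    if (tolerance > 0) {
      lo <- max(1L, pos - tolerance)
      hi <- min(length(prof$counts), pos + tolerance)
      win <- lo:hi
      pos <- win[which.max(prof$counts[win])]
      out$cleave_site[i] <- pos
    }
    out$site_count[i] <- prof$counts[pos]
    out$max_count[i] <- max(prof$counts)
    nz <- prof$counts[prof$counts > 0]
    out$median_nonzero[i] <- if (length(nz)) stats::median(nz) else NA_real_
    out$category[i] <- classify_category(prof, pos)
    no_cleavage_mm <- if ("c5" %in% names(predictions)) predictions$c5[i] else TRUE
    out$kept[i] <- !is.na(out$category[i]) &&
      out$category[i] <= keep_max_category &&
      predictions$score[i] <= max_score && isTRUE(no_cleavage_mm)
  }
  out
}
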