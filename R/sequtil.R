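RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide sequence to the RNA or DNA alphabet
#'
#' Sequences are uppercased and T/U interconverted. Conversion is lossless:
#' the two alphabets differ only in the T/U letter.
#'
#' @param x character vector of sequences.
#' @param alphabet `"RNA"` (default) or `"DNA"`.
#' @return character vector in the requested alphabet.
#' @export
normalize_seq <- function(x, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  if (alphabet == "RNA") gsub("T", "U", x, fixed = TRUE)
  else gsub("U", "T", x, fixed = TRUE)
}

check_seq_alphabet <- function(x, ids = NULL, extra = "N") {
  ok <- grepl(paste0("^[ACGTU", paste(extra, collapse = ""), "]*$"), toupper(x))
  if (!all(ok)) {
    bad <- if (is.null(ids)) which(!ok) else ids[!ok]
    stop("malformed sequence characters in record(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Records are read with \pkg{Biostrings} and normalized to the requested
#' alphabet (uppercase, T/U interconverted). Duplicate ids are an error.
#'
#' @param path file path.
#' @param alphabet `"RNA"` (default) or `"DNA"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_seq(as.character(ss), alphabet)
  check_seq_alphabet(seqs, ids)
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' Sequences are written in the DNA alphabet (U converted to T), the common
#' dialect of miRNA and transcript FASTA files, regardless of the internal
#' RNA representation.
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("all records must be named", call. = FALSE)
  }
  if (anyDuplicated(names(records))) {
    stop("duplicate FASTA id(s): ",
         paste(unique(names(records)[duplicated(names(records))]),
               collapse = ", "), call. = FALSE)
  }
  ss <- Biostrings::BStringSet(normalize_seq(records, "DNA"))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement an RNA sequence
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements (RNA alphabet).
#' @export
rev_comp_rna <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  vapply(strsplit(normalize_seq(x, "RNA"), ""), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, character(1))
}

TAG_FLAGS <- c("low_quality", "high_n", "adapter5_contaminated",
               "no_adapter3", "polya")

#' Filter small-RNA tags
#'
#' Removes reads carrying any quality defect flag (any base below Q20, more
#' than 5\% N, contaminated 5' adapter, missing 3' adapter, polyA tail), then
#' removes sequences outside the 18--30 nt small-RNA length window, and
#' finally deduplicates identical sequences summing their per-library counts.
#'
#' @param tags data.frame with a `sequence` column, one or more count columns
#'   (all numeric columns are treated as per-library counts), and optional
#'   logical flag columns `low_quality`, `high_n`, `adapter5_contaminated`,
#'   `no_adapter3`, `polya`. Missing flag columns are treated as all-FALSE.
#' @param min_len,max_len retained length window, default 18--30 nt.
#' @return data.frame of unique clean tags (RNA alphabet) with summed counts.
#' @export
filter_tags <- function(tags, min_len = 18L, max_len = 30L) {
  if (nrow(tags) == 0) return(tags[, c("sequence", count_cols(tags)), drop = FALSE])
  seqs <- normalize_seq(tags$sequence, "RNA")
  check_seq_alphabet(seqs, rownames(tags))
  flagged <- rep(FALSE, nrow(tags))
  for (f in TAG_FLAGS) {
    if (f %in% names(tags)) flagged <- flagged | isTRUE_vec(tags[[f]])
  }
  len <- nchar(seqs)
  keep <- !flagged & len >= min_len & len <= max_len & !grepl("N", seqs)
  cc <- count_cols(tags)
  kept <- data.frame(sequence = seqs[keep], stringsAsFactors = FALSE)
  for (col in cc) kept[[col]] <- tags[[col]][keep]
  if (nrow(kept) == 0) return(kept)
  agg <- stats::aggregate(kept[cc], by = list(sequence = kept$sequence), FUN = sum)
  agg <- agg[order(agg$sequence), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

count_cols <- function(tags) {
  cand <- setdiff(names(tags), c("sequence", TAG_FLAGS))
  cand[vapply(tags[cand], is.numeric, logical(1))]
}

#' Flag reads in a FASTQ file by basic quality metrics
#'
#' A minimal quality flagger for testing the tag filter: marks reads with any
#' base below the Phred quality floor as `low_quality` and reads whose N
#' fraction exceeds `max_n_frac` as `high_n`. Adapter-related defects are not
#' detectable from sequence alone and must be supplied externally.
#'
#' @param path FASTQ file (Phred+33).
#' @param min_q per-base quality floor (default 20).
#' @param max_n_frac maximal tolerated fraction of N bases (default 0.05).
#' @return data.frame: sequence, count (=1 per read), low_quality, high_n.
#' @export
flag_fastq <- function(path, min_q = 20L, max_n_frac = 0.05) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ file", call. = FALSE)
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  minq <- vapply(quals, function(q) {
    if (nchar(q) == 0) return(Inf)
    min(utf8ToInt(q)) - 33L
  }, numeric(1), USE.NAMES = FALSE)
  nfrac <- vapply(seqs, function(s) {
    lengths(regmatches(s, gregexpr("N", toupper(s)))) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(sequence = normalize_seq(seqs, "RNA"),
             count = 1L,
             low_quality = minq < min_q,
             high_n = nfrac > max_n_frac,
             stringsAsFactors = FALSE)
}

# Longest common exact substring length between two sequences (small inputs).
longest_common_substring <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  na <- length(x); nb <- length(y)
  if (na == 0 || nb == 0) return(0L)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_i <- x[i] == y
    cur[1] <- as.integer(match_i[1])
    if (nb > 1) {
      for (j in 2:nb) cur[j] <- if (match_i[j]) prev[j - 1] + 1L else 0L
    }
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# Minimal ungapped mismatch distance over all relative offsets; unaligned
# bases of the shorter sequence count as mismatches.
ungapped_mismatches <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  na <- length(x); nb <- length(y)
  short <- min(na, nb)
  best <- Inf
  for (off in seq(-(nb - 1), na - 1)) {
    ia <- max(1, 1 + off):min(na, nb + off)
    ib <- ia - off
    ov <- length(ia)
    mm <- sum(x[ia] != y[ib]) + (short - ov)
    best <- min(best, mm)
  }
  best
}

#' Assign a clean tag to a known miRNA family
#'
#' A tag joins the family of a known mature miRNA if the best ungapped
#' alignment has at most one mismatch, or if the two sequences share an exact
#' block of at least `min_overlap` nucleotides. Among several qualifying
#' knowns, ties are broken by fewest mismatches, then longest exact overlap,
#' then lexicographic family id.
#'
#' @param tag tag sequence (RNA or DNA; normalized internally).
#' @param known data.frame with columns `id`, `family`, `sequence`.
#' @param max_mismatch maximal ungapped mismatch count (default 1).
#' @param min_overlap minimal exact overlap (default 16 nt).
#' @return family id (character) or `NA_character_` if no known qualifies.
#' @export
assign_family <- function(tag, known, max_mismatch = 1L, min_overlap = 16L) {
  tag <- normalize_seq(tag, "RNA")
  if (nrow(known) == 0) return(NA_character_)
  ks <- normalize_seq(known$sequence, "RNA")
  mm <- vapply(ks, ungapped_mismatches, numeric(1), a = tag, USE.NAMES = FALSE)
  ov <- vapply(ks, longest_common_substring, integer(1), a = tag, USE.NAMES = FALSE)
  qual <- mm <= max_mismatch | ov >= min_overlap
  if (!any(qual)) return(NA_character_)
  idx <- which(qual)
  ord <- order(mm[idx], -ov[idx], known$family[idx])
  known$family[idx[ord[1]]]
}
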