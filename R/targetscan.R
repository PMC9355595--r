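# Plant miRNA target prediction: duplex alignment of a mature miRNA
# (5'->3') against a transcript window (read 3'->5'), positional pairing
# states, a mismatch score with G:U wobbles at half weight, a duplex
# binding-energy ratio, and the six-part screening rule used for
# cleavage-competent plant targets.

# Pairing classes, indexed by (miRNA base, target base), bases coded
# A=1, C=2, G=3, U=4: 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch.
PAIR_CLASS <- local({
  m <- matrix(2L, 4, 4)
  m[1, 4] <- m[4, 1] <- m[3, 2] <- m[2, 3] <- 0L
  m[3, 4] <- m[4, 3] <- 1L
  m
})
PAIR_CLASS_VEC <- as.integer(PAIR_CLASS) # index (m-1)*4 + t

base_codes <- function(seq) {
  codes <- match(strsplit(normalize_seq(seq, "RNA"), "")[[1]], RNA_BASES)
  if (anyNA(codes)) stop("sequence contains non-ACGU characters", call. = FALSE)
  codes
}

# Stacking-free per-pair binding energies (arbitrary units): a paired G or C
# on the miRNA side contributes -3, a paired A or U -2, a G:U wobble -1,
# mismatches and gaps 0. Used only as a ratio against the perfect duplex.
pair_energy <- function(state, mirna_code) {
  ifelse(state == 0L, ifelse(mirna_code %in% c(2L, 3L), -3, -2),
         ifelse(state == 1L, -1, 0))
}

perfect_energy <- function(mirna_code) {
  sum(ifelse(mirna_code %in% c(2L, 3L), -3, -2))
}

STATE_LABELS <- c(`0` = "WC", `1` = "GU", `2` = "MM")
STATE_CHARS <- c(WC = "|", GU = "o", MM = "x", GAP = "-")

# Enumerate the (window offset) pairing layout for one gap placement.
# Returns paired miRNA positions and their 1-based window offsets, plus the
# gap descriptor. g = 0..L for a target bulge (W = L+1; bulge after miRNA
# position g), g = 1..L for an unpaired miRNA base (W = L-1).
gap_layout <- function(L, W, g) {
  if (W == L) {
    list(mirna = seq_len(L), window = L + 1L - seq_len(L), gap = NULL)
  } else if (W == L + 1L) {
    i <- seq_len(L)
    win <- ifelse(i <= g, L + 2L - i, L + 1L - i)
    list(mirna = i, window = win,
         gap = list(type = "bulge", after = g, window_pos = L + 1L - g))
  } else if (W == L - 1L) {
    i <- setdiff(seq_len(L), g)
    win <- ifelse(i < g, L - i, L + 1L - i)
    list(mirna = i, window = win, gap = list(type = "mirna_gap", at = g))
  } else stop("unsupported window length", call. = FALSE)
}

#' Align a miRNA against a transcript window
#'
#' Pairs the miRNA 5'->3' against the window read 3'->5' and labels every
#' position Watson--Crick (`WC`), G:U wobble (`GU`), mismatch (`MM`) or gap
#' (`GAP`). The window may be one nucleotide longer (a bulged target base) or
#' shorter (an unpaired miRNA base) than the miRNA when `max_gaps = 1`; the
#' single gap is placed to maximize the Watson--Crick pair count, ties going
#' to the leftmost placement. The alignment score is
#' `#MM + 0.5 * #GU + #GAP`.
#'
#' @param mirna mature miRNA sequence (5'->3'; RNA or DNA letters).
#' @param window transcript window sequence (5'->3' transcript sense).
#' @param max_gaps maximal number of gaps (0 or 1; default 1).
#' @return an object of class `duplex_alignment`: pairing states, per-state
#'   miRNA and window coordinates, score, Watson--Crick count, binding
#'   energies, and a one-line duplex string (`|` WC, `o` GU, `x` MM, `-` gap).
#' @export
align_duplex <- function(mirna, window, max_gaps = 1L) {
  mc <- base_codes(mirna)
  wc_ <- base_codes(window)
  L <- length(mc); W <- length(wc_)
  if (L == 0) stop("empty miRNA", call. = FALSE)
  if (abs(W - L) > max_gaps) {
    stop("window length ", W, " incompatible with miRNA length ", L,
         " at max_gaps = ", max_gaps, call. = FALSE)
  }
  gs <- if (W == L) NA_integer_ else if (W == L + 1L) 0:L else seq_len(L)
  best <- NULL
  for (g in gs) {
    lay <- gap_layout(L, W, if (is.na(g)) 0L else g)
    st <- PAIR_CLASS_VEC[(mc[lay$mirna] - 1L) * 4L + wc_[lay$window]]
    nwc <- sum(st == 0L)
    if (is.null(best) || nwc > best$nwc) {
      best <- list(g = g, lay = lay, st = st, nwc = nwc)
    }
  }
  lay <- best$lay; st <- best$st
  # Full state sequence in duplex order (miRNA 5'->3'), with the gap state
  # inserted where it occurs.
  states <- STATE_LABELS[as.character(st)]
  mirna_pos <- lay$mirna
  window_pos <- lay$window
  if (!is.null(lay$gap)) {
    if (lay$gap$type == "bulge") {
      at <- lay$gap$after
      states <- append(states, "GAP", after = at)
      mirna_pos <- append(mirna_pos, NA_integer_, after = at)
      window_pos <- append(window_pos, lay$gap$window_pos, after = at)
    } else {
      at <- lay$gap$at
      states <- append(states, "GAP", after = at - 1L)
      mirna_pos <- append(mirna_pos, at, after = at - 1L)
      window_pos <- append(window_pos, NA_integer_, after = at - 1L)
    }
  }
  # Effective per-miRNA-position states for the positional rules: a gap
  # (either kind) counts as a mismatch at the adjacent miRNA position.
  eff <- rep("MM", L)
  eff[lay$mirna] <- STATE_LABELS[as.character(st)]
  if (!is.null(lay$gap) && lay$gap$type == "bulge") {
    eff[min(lay$gap$after + 1L, L)] <- "MM"
  }
  score <- sum(states == "MM") + 0.5 * sum(states == "GU") + sum(states == "GAP")
  paired <- !is.na(mirna_pos) & states != "GAP"
  energy <- sum(pair_energy(st, mc[lay$mirna]))
  structure(list(
    mirna = normalize_seq(mirna, "RNA"),
    window = normalize_seq(window, "RNA"),
    states = states, mirna_pos = mirna_pos, window_pos = window_pos,
    eff = eff, score = score, wc_count = best$nwc,
    energy = energy, perfect_energy = perfect_energy(mc),
    duplex = paste(STATE_CHARS[states], collapse = "")
  ), class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex alignment (", length(x$eff), "-nt miRNA, score ", x$score,
      ", MFE ratio ", round(mfe_ratio(x), 1), "%)\n", sep = "")
  cat("miRNA 5'-", x$mirna, "-3'\n         ", x$duplex, "\n", sep = "")
  invisible(x)
}

#' Duplex binding-energy ratio
#'
#' Ratio (percent) of the duplex binding energy to the energy of the perfect
#' Watson--Crick duplex of the same miRNA, under the stacking-free per-pair
#' model (G/C pair -3, A/U pair -2, G:U wobble -1, mismatch/gap 0). The
#' perfect duplex scores 100; defects reduce the ratio towards 0.
#'
#' @param duplex a `duplex_alignment`.
#' @return percentage in `[0, 100]`.
#' @export
mfe_ratio <- function(duplex) {
  if (duplex$perfect_energy == 0) stop("degenerate duplex: zero perfect energy",
                                       call. = FALSE)
  100 * duplex$energy / duplex$perfect_energy
}

#' Apply the six target-screening criteria to a duplex
#'
#' The criteria, applied conjunctively with miRNA positions counted 1-based
#' from the 5' end and gaps counting as mismatches for positional rules:
#' (1) binding-energy ratio of the duplex to its perfect counterpart at least
#' `mfe_min` percent; (2) weighted mismatch score (`MM` = 1, `GU` = 0.5,
#' gap = 1) at most `max_score`; (3) at most `max_adjacent` adjacent-mismatch
#' pairs over the whole duplex; (4) no two consecutive mismatches within
#' miRNA positions 2--12; (5) no mismatch at miRNA positions 10--11 (the
#' cleavage-defining pair); (6) weighted mismatches within positions 2--12 at
#' most `seed_weight_max`.
#'
#' @param duplex a `duplex_alignment`.
#' @param mfe_min criterion-1 threshold, percent (default 74).
#' @param max_score criterion-2 threshold (default 4).
#' @param max_adjacent criterion-3 threshold (default 2).
#' @param seed_weight_max criterion-6 threshold (default 2.5).
#' @return list of class `criteria_verdict` with logicals `c1`..`c6` and
#'   `pass` (the conjunction).
#' @export
apply_criteria <- function(duplex, mfe_min = 74, max_score = 4,
                           max_adjacent = 2, seed_weight_max = 2.5) {
  L <- length(duplex$eff)
  mm_like <- duplex$states %in% c("MM", "GAP")
  eff_mm <- duplex$eff == "MM"
  seed <- 2:min(12L, L)
  c1 <- mfe_ratio(duplex) >= mfe_min
  c2 <- duplex$score <= max_score
  c3 <- sum(mm_like[-1] & mm_like[-length(mm_like)]) <= max_adjacent
  pairs_in_seed <- seed[-length(seed)]
  c4 <- !any(eff_mm[pairs_in_seed] & eff_mm[pairs_in_seed + 1L])
  c5 <- if (L >= 11) !eff_mm[10] && !eff_mm[11] else TRUE
  c6 <- sum(eff_mm[seed] + 0.5 * (duplex$eff[seed] == "GU")) <= seed_weight_max
  v <- list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6)
  v$pass <- all(unlist(v))
  class(v) <- "criteria_verdict"
  v
}

#' @export
print.criteria_verdict <- function(x, ...) {
  cat("criteria:", paste0("c", 1:6, "=", substr(unlist(x[1:6]), 1, 1),
                          collapse = " "),
      if (x$pass) "-> PASS" else "-> fail", "\n")
  invisible(x)
}

# Transcript coordinate paired with a given miRNA position, or NA.
paired_transcript_pos <- function(duplex, start, mirna_position = 10L) {
  i <- which(!is.na(duplex$mirna_pos) & duplex$mirna_pos == mirna_position &
               duplex$states != "GAP")
  if (length(i) == 0) return(NA_integer_)
  start - 1L + duplex$window_pos[i[1]]
}

# Vectorized single-pair scan: returns candidate starts per window length
# whose best-placement alignment has score <= max_score. Candidates are then
# re-aligned through align_duplex() for the full verdict.
scan_candidates <- function(mc, tc, max_gaps, max_score) {
  L <- length(mc); N <- length(tc)
  out <- list()
  Ws <- L + (-max_gaps:max_gaps)
  Ws <- Ws[Ws >= 1 & Ws <= N]
  for (W in Ws) {
    starts <- seq_len(N - W + 1L)
    nS <- length(starts)
    gs <- if (W == L) 0L else if (W == L + 1L) 0:L else seq_len(L)
    best_wc <- rep(-1L, nS); best_g <- rep(NA_integer_, nS)
    layouts <- lapply(gs, function(g) gap_layout(L, W, g))
    cls_list <- vector("list", length(gs))
    for (k in seq_along(gs)) {
      lay <- layouts[[k]]
      ti <- outer(lay$window, starts - 1L, "+")
      cls <- matrix(PAIR_CLASS_VEC[(mc[lay$mirna] - 1L) * 4L + tc[ti]],
                    nrow = length(lay$mirna))
      cls_list[[k]] <- cls
      nwc <- .colSums(cls == 0L, nrow(cls), nS)
      better <- nwc > best_wc
      best_wc[better] <- nwc[better]
      best_g[better] <- k
    }
    ngap <- as.integer(W != L)
    score <- rep(NA_real_, nS)
    for (k in unique(best_g)) {
      sel <- which(best_g == k)
      cls <- cls_list[[k]][, sel, drop = FALSE]
      score[sel] <- .colSums(cls == 2L, nrow(cls), length(sel)) +
        0.5 * .colSums(cls == 1L, nrow(cls), length(sel)) + ngap
    }
    cand <- starts[score <= max_score]
    if (length(cand)) out[[as.character(W)]] <- cand
  }
  out
}

#' Predict miRNA target sites on transcripts
#'
#' Scans every transcript window compatible with the miRNA length (plus or
#' minus `max_gaps`) at step 1, aligns the duplex, applies the six screening
#' criteria, and reports all passing sites. Overlapping passing windows of
#' the same miRNA--transcript pair are collapsed to the best-scoring one
#' (ties: lowest score, then smallest start).
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param max_gaps maximal gaps per duplex (0 or 1; default 1; 0 gives a
#'   pure ungapped scan).
#' @param collapse collapse overlapping passing windows (default TRUE).
#' @param mfe_min,max_score,max_adjacent,seed_weight_max criteria thresholds,
#'   see [apply_criteria()].
#' @return data.frame: `mirna_id`, `transcript_id`, `start`, `end`, `score`,
#'   `mfe_ratio`, `c1`..`c6`, `pass`, `cleave_site` (transcript coordinate
#'   paired with miRNA position 10), `duplex`.
#' @export
predict_targets <- function(mirnas, transcripts, max_gaps = 1L,
                            collapse = TRUE, mfe_min = 74, max_score = 4,
                            max_adjacent = 2, seed_weight_max = 2.5) {
  stopifnot(length(mirnas) > 0, length(transcripts) > 0,
            !is.null(names(mirnas)), !is.null(names(transcripts)))
  rows <- list()
  for (mid in names(mirnas)) {
    mc <- base_codes(mirnas[[mid]])
    for (tid in names(transcripts)) {
      tseq <- normalize_seq(transcripts[[tid]], "RNA")
      tc <- base_codes(tseq)
      if (length(tc) < length(mc) - max_gaps) next
      cand <- scan_candidates(mc, tc, max_gaps, max_score)
      for (W in names(cand)) {
        Wn <- as.integer(W)
        for (s in cand[[W]]) {
          d <- align_duplex(mirnas[[mid]], substr(tseq, s, s + Wn - 1L),
                            max_gaps = max_gaps)
          v <- apply_criteria(d, mfe_min, max_score, max_adjacent,
                              seed_weight_max)
          if (!v$pass) next
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = mid, transcript_id = tid,
            start = s, end = s + Wn - 1L,
            score = d$score, mfe_ratio = mfe_ratio(d),
            c1 = v$c1, c2 = v$c2, c3 = v$c3, c4 = v$c4, c5 = v$c5, c6 = v$c6,
            pass = v$pass,
            cleave_site = paired_transcript_pos(d, s, 10L),
            duplex = d$duplex, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      mfe_ratio = numeric(), c1 = logical(), c2 = logical(),
                      c3 = logical(), c4 = logical(), c5 = logical(),
                      c6 = logical(), pass = logical(),
                      cleave_site = integer(), duplex = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  if (collapse) res <- collapse_overlaps(res)
  rownames(res) <- NULL
  res
}

# Collapse chains of mutually overlapping windows per (miRNA, transcript)
# to the single best window: lowest score, then smallest start.
collapse_overlaps <- function(res) {
  key <- paste(res$mirna_id, res$transcript_id, sep = "\r")
  keep <- logical(nrow(res))
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(res$start[idx], res$end[idx])]
    group <- integer(length(idx)); gid <- 0L; reach <- -Inf
    for (j in seq_along(idx)) {
      if (res$start[idx[j]] > reach) { gid <- gid + 1L; reach <- res$end[idx[j]] }
      else reach <- max(reach, res$end[idx[j]])
      group[j] <- gid
    }
    for (g in unique(group)) {
      gi <- idx[group == g]
      best <- gi[order(res$score[gi], res$start[gi])][1]
      keep[best] <- TRUE
    }
  }
  res[keep, , drop = FALSE]
}
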