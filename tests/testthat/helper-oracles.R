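# Independent brute-force oracles, written with naive per-element loops and
# string lookups, deliberately sharing no code with the package internals.

ORACLE_PAIRS <- c(AU = "WC", UA = "WC", GC = "WC", CG = "WC",
                  GU = "GU", UG = "GU")

oracle_class <- function(m, t) {
  cls <- ORACLE_PAIRS[paste0(m, t)]
  ifelse(is.na(cls), "MM", cls)
}

oracle_pair_energy <- function(m, cls) {
  if (cls == "WC") { if (m %in% c("G", "C")) -3 else -2 }
  else if (cls == "GU") -1 else 0
}

# Align one window against a miRNA, enumerating every legal single-gap
# placement; best placement = most WC pairs, first (leftmost) on ties.
oracle_align <- function(mb, wb) {
  L <- length(mb); W <- length(wb)
  rw <- rev(wb)
  layouts <- list()
  if (W == L) {
    layouts[[1]] <- list(mpos = 1:L, rpos = 1:L, gap = NULL)
  } else if (W == L + 1) {
    for (g in 0:L) {
      rpos <- ifelse(1:L <= g, 1:L, (1:L) + 1)
      layouts[[length(layouts) + 1]] <-
        list(mpos = 1:L, rpos = rpos, gap = list(kind = "bulge", g = g))
    }
  } else if (W == L - 1) {
    for (g in 1:L) {
      mpos <- setdiff(1:L, g)
      rpos <- ifelse(mpos < g, mpos, mpos - 1)
      layouts[[length(layouts) + 1]] <-
        list(mpos = mpos, rpos = rpos, gap = list(kind = "unpaired", g = g))
    }
  } else stop("bad window")
  best <- NULL
  for (lay in layouts) {
    cls <- oracle_class(mb[lay$mpos], rw[lay$rpos])
    if (is.null(best) || sum(cls == "WC") > best$nwc) {
      best <- list(lay = lay, cls = cls, nwc = sum(cls == "WC"))
    }
  }
  lay <- best$lay; cls <- best$cls
  # per-miRNA-position states with gap folded in as MM
  eff <- rep("MM", L)
  eff[lay$mpos] <- cls
  full <- character(0)
  if (is.null(lay$gap)) {
    full <- cls
  } else if (lay$gap$kind == "bulge") {
    g <- lay$gap$g
    full <- append(cls, "GAP", after = g)
    eff[min(g + 1, L)] <- "MM"
  } else {
    g <- lay$gap$g
    full <- append(cls, "GAP", after = g - 1)
  }
  ngap <- sum(full == "GAP")
  score <- sum(full == "MM") + 0.5 * sum(full == "GU") + ngap
  energy <- 0
  for (i in seq_along(lay$mpos)) {
    energy <- energy + oracle_pair_energy(mb[lay$mpos[i]], cls[i])
  }
  perfect <- sum(sapply(mb, function(b) if (b %in% c("G", "C")) -3 else -2))
  list(full = full, eff = eff, score = score,
       ratio = 100 * energy / perfect)
}

oracle_verdict <- function(al, mfe_min = 74, max_score = 4) {
  L <- length(al$eff)
  mm_full <- al$full %in% c("MM", "GAP")
  adj <- 0
  for (i in seq_len(length(mm_full) - 1)) {
    if (mm_full[i] && mm_full[i + 1]) adj <- adj + 1
  }
  mm <- al$eff == "MM"
  c4 <- TRUE
  for (i in 2:11) if (mm[i] && mm[i + 1]) c4 <- FALSE
  w26 <- sum(mm[2:12]) + 0.5 * sum(al$eff[2:12] == "GU")
  all(c(al$ratio >= mfe_min, al$score <= max_score, adj <= 2, c4,
        !mm[10] && !mm[11], w26 <= 2.5))
}

# Exhaustive window scan applying the six criteria literally; returns
# passing windows collapsed like the scanner (overlap chains -> lowest
# score, then smallest start).
oracle_scan <- function(mirna, transcript, max_gaps = 0) {
  mb <- strsplit(chartr("Tt", "Uu", toupper(mirna)), "")[[1]]
  tb <- strsplit(chartr("Tt", "Uu", toupper(transcript)), "")[[1]]
  L <- length(mb); N <- length(tb)
  hits <- NULL
  for (W in (L - max_gaps):(L + max_gaps)) {
    if (W < 1 || W > N) next
    for (s in 1:(N - W + 1)) {
      al <- oracle_align(mb, tb[s:(s + W - 1)])
      if (al$score > max_score_for_speed()) next
      if (oracle_verdict(al)) {
        hits <- rbind(hits, data.frame(start = s, end = s + W - 1,
                                       score = al$score))
      }
    }
  }
  if (is.null(hits)) return(data.frame(start = integer(), end = integer(),
                                       score = numeric()))
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  out <- NULL
  i <- 1
  while (i <= nrow(hits)) {
    j <- i; reach <- hits$end[i]
    while (j < nrow(hits) && hits$start[j + 1] <= reach) {
      j <- j + 1
      reach <- max(reach, hits$end[j])
    }
    grp <- hits[i:j, , drop = FALSE]
    best <- grp[order(grp$score, grp$start), , drop = FALSE][1, ]
    out <- rbind(out, best)
    i <- j + 1
  }
  rownames(out) <- NULL
  out
}

# criterion 2 (score <= 4) is part of the verdict; skipping high-score
# windows early only saves time and cannot change the passing set.
max_score_for_speed <- function() 4

# O(n^3) topological overlap by the explicit triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

# Exhaustive hypergeometric upper tail by complete enumeration of draws.
oracle_hypergeom <- function(N, n, M, m) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(M)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= m)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

random_rna_string <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
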