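mk_window <- function(mirna, mismatch = integer(), gu = integer()) {
  b <- strsplit(mirna, "")[[1]]
  L <- length(b)
  w <- strsplit(rev_comp_rna(mirna), "")[[1]]
  for (p in mismatch) w[L + 1 - p] <- b[p]
  for (p in gu) w[L + 1 - p] <- switch(b[p], G = "U", U = "G",
                                       stop("need G/U base"))
  paste(w, collapse = "")
}

MIR <- "UGACAGAAGAGAGUGAGCACA" # 21 nt, mixed composition

test_that("a perfect duplex is all Watson-Crick with score 0 and ratio 100", {
  d <- align_duplex(MIR, mk_window(MIR))
  expect_true(all(d$states == "WC"))
  expect_equal(d$score, 0)
  expect_equal(mfe_ratio(d), 100)
  v <- apply_criteria(d)
  expect_true(v$pass)
  expect_true(all(unlist(v[paste0("c", 1:6)])))
})

test_that("G:U wobbles score half a mismatch", {
  # one wobble, no other defect: the score printed for validated
  # high-confidence sites (e.g. an ARF-family target at score 0.5)
  d <- align_duplex(MIR, mk_window(MIR, gu = 15))
  expect_equal(d$score, 0.5)
  expect_equal(sum(d$states == "GU"), 1)
  # MM at 1 and 21 plus GU at 15 -> 2.5
  d2 <- align_duplex(MIR, mk_window(MIR, mismatch = c(1, 21), gu = 15))
  expect_equal(d2$score, 2.5)
})

test_that("the energy ratio follows the per-pair model", {
  # 20-nt all-G/C miRNA: perfect energy 60; one mismatch loses 3 -> 95%
  m <- strrep("GC", 10)
  d <- align_duplex(m, mk_window(m, mismatch = 5))
  expect_equal(mfe_ratio(d), 100 * 57 / 60)
  # ratio exactly at the 74% boundary satisfies criterion 1 (>=)
  # miRNA: 8 G + 13 U -> perfect 50; five mismatches at 3 G and 2 U
  # positions lose 13 -> 37/50 = 74%
  m2 <- paste0(strrep("G", 8), strrep("U", 13))
  d2 <- align_duplex(m2, mk_window(m2, mismatch = c(1, 2, 3, 9, 10)))
  expect_equal(mfe_ratio(d2), 74)
  expect_true(apply_criteria(d2)$c1)
})

test_that("energy ratio is monotone and score additive under extra defects", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_rna_string(21)
    defects <- sample(21, 3)
    d0 <- align_duplex(m, mk_window(m, mismatch = defects[1]))
    d1 <- align_duplex(m, mk_window(m, mismatch = defects))
    expect_gte(mfe_ratio(d0), mfe_ratio(d1))
    expect_lte(d0$score, d1$score)
    # permuting defect positions leaves the score unchanged
    d2 <- align_duplex(m, mk_window(m, mismatch = sample(21, 3)))
    expect_equal(d1$score, d2$score)
  }
})

test_that("positional criteria catch cleavage-region and seed defects", {
  # single mismatch opposite position 10 -> criterion 5 fails, rest pass
  d <- align_duplex(MIR, mk_window(MIR, mismatch = 10))
  v <- apply_criteria(d)
  expect_false(v$c5)
  expect_true(all(unlist(v[c("c1", "c2", "c3", "c4", "c6")])))
  expect_false(v$pass)
  # adjacent mismatches at 3-4 (inside 2-12) -> criterion 4 fails while
  # 2 and 6 still pass
  d2 <- align_duplex(MIR, mk_window(MIR, mismatch = c(3, 4)))
  v2 <- apply_criteria(d2)
  expect_false(v2$c4)
  expect_true(v2$c2)
  expect_true(v2$c6)
  # three adjacent pairs duplex-wide -> criterion 3
  d3 <- align_duplex(MIR, mk_window(MIR, mismatch = 14:17))
  v3 <- apply_criteria(d3)
  expect_false(v3$c3)
  expect_true(v3$c4)
  # weighted seed mismatches above 2.5 -> criterion 6
  d4 <- align_duplex(MIR, mk_window(MIR, mismatch = c(2, 5, 8)))
  v4 <- apply_criteria(d4)
  expect_false(v4$c6)
  expect_true(v4$c2)
})

test_that("single-gap alignments are placed to maximize pairing", {
  w <- mk_window(MIR)
  # bulged target base: insert an extra base mid-window
  wb <- paste0(substr(w, 1, 10), "A", substr(w, 11, 21))
  d <- align_duplex(MIR, wb, max_gaps = 1)
  expect_equal(sum(d$states == "GAP"), 1)
  expect_equal(length(d$states), 22)
  expect_equal(d$score, 1)
  # unpaired miRNA base: delete one window base
  wd <- paste0(substr(w, 1, 10), substr(w, 12, 21))
  d2 <- align_duplex(MIR, wd, max_gaps = 1)
  expect_equal(sum(d2$states == "GAP"), 1)
  expect_equal(length(d2$states), 21)
  # window length outside miRNA +/- max_gaps errors
  expect_error(align_duplex(MIR, substr(w, 1, 18), max_gaps = 1),
               "incompatible")
})

test_that("an embedded perfect site is reported exactly once at its position", {
  set.seed(11)
  tx <- random_rna_string(400)
  site <- mk_window(MIR)
  tx2 <- paste0(substr(tx, 1, 150), site, substr(tx, 151, 400))
  p <- predict_targets(c(mir = MIR), c(t1 = tx2), max_gaps = 0)
  expect_equal(nrow(p), 1)
  expect_equal(p$start, 151)
  expect_equal(p$end, 171)
  expect_equal(p$score, 0)
  # cleavage site pairs miRNA position 10: start + 21 - 10
  expect_equal(p$cleave_site, 151 + 21 - 10)
  expect_equal(p$duplex, strrep("|", 21))
})

test_that("scanning agrees with the brute-force oracle on random pairs", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_rna_string(21)
    tx <- random_rna_string(400)
    # plant one perturbed site so passing windows actually occur
    site <- mk_window(m, mismatch = sample(c(1, 13:21), sample(0:2, 1)))
    pos <- sample(50, 1) * 5
    tx <- paste0(substr(tx, 1, pos), site, substr(tx, pos + 1, 400))
    p <- predict_targets(c(m = m), c(t = tx), max_gaps = 0)
    o <- oracle_scan(m, tx, max_gaps = 0)
    expect_equal(nrow(p), nrow(o))
    if (nrow(o)) {
      expect_equal(p$start, o$start)
      expect_equal(p$end, o$end)
      expect_equal(p$score, o$score)
    }
  }
})

test_that("gapped scanning agrees with the brute-force oracle", {
  set.seed(202)
  for (i in 1:8) {
    m <- random_rna_string(21)
    tx <- random_rna_string(250)
    site <- mk_window(m, gu = intersect(sample(21, 2),
                                        which(strsplit(m, "")[[1]] %in% c("G", "U"))))
    pos <- sample(40, 1) * 5
    tx <- paste0(substr(tx, 1, pos), site, substr(tx, pos + 1, 250))
    p <- predict_targets(c(m = m), c(t = tx), max_gaps = 1)
    o <- oracle_scan(m, tx, max_gaps = 1)
    expect_equal(p$start, o$start)
    expect_equal(p$end, o$end)
    expect_equal(p$score, o$score)
  }
})

test_that("overlapping passing windows collapse to the best-scoring site", {
  df <- data.frame(
    mirna_id = "m", transcript_id = "t",
    start = c(10L, 12L, 100L), end = c(30L, 32L, 120L),
    score = c(1, 0.5, 2), mfe_ratio = 90,
    c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = TRUE, c5 = TRUE, c6 = TRUE,
    pass = TRUE, cleave_site = c(21L, 23L, 111L), duplex = "x",
    stringsAsFactors = FALSE)
  res <- mirnet:::collapse_overlaps(df)
  expect_equal(nrow(res), 2)
  expect_equal(res$start, c(12L, 100L))
})
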