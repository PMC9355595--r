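profile_from <- function(counts, id = "tx", len = length(counts)) {
  pos <- which(counts > 0)
  build_profile(data.frame(transcript_id = id, position = pos,
                           count = counts[pos]), id, len)
}

test_that("profiles sum tag counts per 5'-end position", {
  empty <- build_profile(data.frame(transcript_id = character(),
                                    position = integer(),
                                    count = integer()), "tx", 100)
  expect_true(all(empty$counts == 0))
  tags <- data.frame(transcript_id = c("tx", "tx", "other"),
                     position = c(802, 802, 10),
                     count = c(3, 4, 9))
  p <- build_profile(tags, "tx", 1000)
  expect_equal(p$counts[802], 7)
  expect_equal(sum(p$counts), 7)
  expect_error(build_profile(data.frame(transcript_id = "tx",
                                        position = 2000, count = 1),
                             "tx", 1000), "out of range")
})

test_that("all five categories classify as defined", {
  base <- numeric(500)
  # unique maximum
  p0 <- base; p0[100] <- 50; p0[c(7, 33, 210)] <- c(7, 3, 2)
  expect_equal(classify_category(profile_from(p0), 100), 0L)
  # tied maximum
  p1 <- base; p1[c(100, 200)] <- 50; p1[7] <- 3
  expect_equal(classify_category(profile_from(p1), 100), 1L)
  # above the nonzero median but below the maximum
  p2 <- base; p2[100] <- 10; p2[200] <- 50; p2[c(1, 2, 3)] <- c(2, 2, 2)
  expect_equal(classify_category(profile_from(p2), 100), 2L)
  # above 1, at or below the median
  p3 <- base; p3[100] <- 2; p3[200] <- 50; p3[c(1, 2, 3)] <- c(9, 9, 9)
  expect_equal(classify_category(profile_from(p3), 100), 3L)
  # single read
  p4 <- base; p4[100] <- 1; p4[200] <- 50
  expect_equal(classify_category(profile_from(p4), 100), 4L)
  # zero count -> no call
  expect_true(is.na(classify_category(profile_from(p0), 101)))
})

test_that("category is monotone in the site count", {
  base <- numeric(300); base[c(10, 20, 30)] <- c(50, 9, 3)
  cats <- sapply(c(2, 5, 20, 50, 60), function(s) {
    p <- base; p[100] <- s
    classify_category(profile_from(p), 100)
  })
  expect_true(all(diff(cats) <= 0))
})

test_that("scaling counts preserves categories 0-3 while the single-read rule is count-based", {
  base <- numeric(300); base[100] <- 10; base[200] <- 50; base[1:3] <- 2
  for (pos in c(100, 200)) {
    c1 <- classify_category(profile_from(base), pos)
    c2 <- classify_category(profile_from(base * 3), pos)
    expect_equal(c1, c2)
  }
  single <- numeric(300); single[100] <- 1; single[200] <- 5
  expect_equal(classify_category(profile_from(single), 100), 4L)
  expect_false(classify_category(profile_from(single * 3), 100) == 4L)
})

test_that("validation keeps only low-category, low-score, cleavage-clean calls", {
  preds <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4"),
    transcript_id = c("t1", "t2", "t3", "t_missing"),
    start = 1L, end = 21L, score = c(0.5, 2, 1, 0),
    c5 = c(TRUE, TRUE, TRUE, TRUE),
    cleave_site = c(100L, 100L, 100L, 100L),
    stringsAsFactors = FALSE)
  mk <- function(s) { v <- numeric(300); v[100] <- s; v[200] <- 50
                      v[1:4] <- c(2, 2, 3, 3); v }
  profiles <- list(t1 = profile_from(mk(80), "t1"),   # unique max, cat 0
                   t2 = profile_from(mk(10), "t2"),   # cat 2
                   t3 = profile_from(mk(1), "t3"))    # single read, cat 4
  calls <- validate_targets(preds, profiles)
  expect_equal(calls$category, c(0L, 2L, 4L, NA_integer_))
  expect_equal(calls$kept, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(calls$missing_profile[4])
  # every call corresponds to an input prediction (no invented pairs)
  expect_true(all(paste(calls$mirna_id, calls$transcript_id) %in%
                  paste(preds$mirna_id, preds$transcript_id)))
  # a cleavage-region mismatch disqualifies even a category-0 site
  preds$c5[1] <- FALSE
  expect_false(validate_targets(preds, profiles)$kept[1])
  # keep-threshold is configurable
  expect_true(validate_targets(preds, profiles,
                               keep_max_category = 4)$kept[3])
})

test_that("a +/-1 nt tolerance window rescues shifted peaks when enabled", {
  preds <- data.frame(mirna_id = "m", transcript_id = "t",
                      start = 1L, end = 21L, score = 1, c5 = TRUE,
                      cleave_site = 100L, stringsAsFactors = FALSE)
  v <- numeric(300); v[101] <- 60; v[5] <- 2
  profiles <- list(t = profile_from(v, "t"))
  strict <- validate_targets(preds, profiles)
  expect_false(strict$kept[1])
  loose <- validate_targets(preds, profiles, tolerance = 1)
  expect_true(loose$kept[1])
  expect_equal(loose$cleave_site[1], 101L)
})

test_that("simulated degradome tags land exactly on planted cleavage sites", {
  cfg <- sim_config(seed = 4, degradome_noise_rate = 0,
                    degradome_peak_height = 50L)
  sites <- simulate_target_sites(cfg)
  deg <- simulate_degradome(sites$truth, sites$transcripts, cfg)
  expect_setequal(paste(deg$transcript_id, deg$position),
                  paste(sites$truth$transcript_id, sites$truth$cleave_site))
  expect_true(all(deg$count == 50))
  # with noise, planted peaks stay the transcript-wide unique maximum
  cfg2 <- sim_config(seed = 4, degradome_noise_rate = 0.2)
  deg2 <- simulate_degradome(sites$truth, sites$transcripts, cfg2)
  for (i in sample(nrow(sites$truth), 10)) {
    tid <- sites$truth$transcript_id[i]
    prof <- build_profile(deg2, tid, nchar(sites$transcripts[[tid]]))
    expect_equal(classify_category(prof, sites$truth$cleave_site[i]), 0L)
  }
})
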