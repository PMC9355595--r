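test_that("the expression filter applies the value/fraction/SD rules", {
  set.seed(5)
  vals <- matrix(5 + rnorm(120, sd = 0.5), 10, 12)
  # rows 1-4 pass; 5-7 fail the >=2-in-70% rule; 8-10 fail the SD rule
  vals[5, ] <- c(rep(5, 7), rep(0.5, 5))   # 58% above 2
  vals[6, ] <- 1.5                          # never above 2
  vals[7, ] <- c(rep(3, 8), rep(1, 4))     # 67% above 2
  vals[8, ] <- 5                            # SD 0
  vals[9, ] <- 5 + rep(c(-0.1, 0.1), 6)    # SD ~0.1
  vals[10, ] <- 2.0 + rep(c(-0.2, 0.2), 6) # SD ~0.2
  dimnames(vals) <- list(paste0("g", 1:10), paste0("s", 1:12))
  em <- expr_matrix(vals, stage = rep(letters[1:4], each = 3),
                    units = "FPKM")
  kept <- filter_expressed(em)
  expect_setequal(rownames(kept$values), paste0("g", 1:4))
  # boundary: >= 2 in exactly 75% of samples with SD 0.3 is kept
  b <- matrix(c(rep(2, 9), rep(1, 3)), 1, 12,
              dimnames = list("gb", paste0("s", 1:12)))
  b[1, 1] <- 3.2 # lift SD above 0.25 without dropping below the floor
  emb <- expr_matrix(b, stage = rep(letters[1:4], each = 3), units = "FPKM")
  expect_equal(nrow(filter_expressed(emb)$values), 1)
})

test_that("soft-thresholded adjacency transforms correlations", {
  x <- rbind(a = 1:10, b = (1:10) * 2 + 3, c = c(5, 2, 8, 1, 9, 4, 7, 3, 6, 5))
  a <- adjacency(x, beta = 9)
  expect_equal(a["a", "b"], 1)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(diag(a), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(a))
  # |r| = 0.5 at beta 9
  r <- 0.5
  expect_equal(r^9, 0.001953125)
})

test_that("the TOM matches its closed forms and the triple-loop oracle", {
  # 2-node network: TOM equals the adjacency
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom(a2)["x", "y"], 0.4)
  # 3-node clique at full adjacency: TOM 1 everywhere
  a3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(tom(a3) - 1) < 1e-12))
  # random instances against the O(n^3) loop
  set.seed(8)
  for (n in c(10, 30)) {
    r <- matrix(runif(n * n), n)
    a <- (r + t(r)) / 2; diag(a) <- 1
    dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
    t1 <- tom(a)
    expect_lt(max(abs(t1 - oracle_tom(a))), 1e-12)
    expect_true(isSymmetric(unname(t1)))
    expect_true(all(t1 >= 0 & t1 <= 1 + 1e-12))
  }
  expect_error(tom(matrix(c(1, 0.2, 0.8, 1), 2)), "symmetric")
})

planted_block_matrix <- function(n_per = 60, n_noise = 30, n_samples = 20,
                                 seed = 3) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  x <- rbind(
    t(replicate(n_per, f1 + 0.2 * rnorm(n_samples))),
    t(replicate(n_per, f2 + 0.2 * rnorm(n_samples))),
    matrix(rnorm(n_noise * n_samples), n_noise))
  rownames(x) <- c(paste0("a", 1:n_per), paste0("b", 1:n_per),
                   paste0("n", 1:n_noise))
  x
}

test_that("planted blocks are detected and noise pools into grey", {
  x <- planted_block_matrix()
  tm <- tom(adjacency(x, 6))
  det <- detect_modules(tm, min_module_size = 30)
  labs <- det$labels
  mods <- setdiff(unique(labs), "grey")
  expect_equal(length(mods), 2)
  expect_equal(length(unique(labs[paste0("a", 1:60)])), 1)
  expect_equal(length(unique(labs[paste0("b", 1:60)])), 1)
  # labels come from the fixed palette in size order
  expect_setequal(mods, c("turquoise", "blue"))
  # pure noise -> everything grey
  set.seed(9)
  noise <- matrix(rnorm(40 * 15), 40,
                  dimnames = list(paste0("g", 1:40), NULL))
  det2 <- detect_modules(tom(adjacency(noise, 6)), min_module_size = 10)
  expect_true(all(det2$labels == "grey"))
})

test_that("eigengenes are the standardized first principal component", {
  prof <- sin(1:12)
  x <- matrix(rep(prof, 5), 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  eg <- eigengene(x)
  expect_equal(sd(eg), 1)
  expect_equal(abs(cor(eg, prof)), 1)
  # orientation: members correlate positively
  expect_gt(cor(x[1, ], eg), 0)
  # variance explained is 1 for identical members
  xs <- t(scale(t(x)))
  expect_equal(mean(cor(t(xs), eg)^2), 1)
})

test_that("module merging joins similar eigengenes iteratively", {
  set.seed(12)
  f <- rnorm(20)
  mk <- function(base, n, noise) t(replicate(n, base + noise * rnorm(20)))
  x <- rbind(mk(f, 30, 0.1), mk(f + 0.25 * rnorm(20), 30, 0.1),
             mk(rnorm(20), 30, 0.1))
  rownames(x) <- paste0("g", 1:90)
  labels <- setNames(rep(c("red", "blue", "green"), each = 30),
                     rownames(x))
  merged <- merge_modules(labels, x, merge_similarity = 0.8)
  expect_equal(length(unique(merged[1:60])), 1)
  expect_equal(length(unique(merged)), 2)
  # dissimilar modules stay apart
  merged2 <- merge_modules(labels, x, merge_similarity = 0.999)
  expect_equal(length(unique(merged2)), 3)
})

test_that("module-trait correlation reproduces exact endpoints", {
  x <- planted_block_matrix()
  tm <- tom(adjacency(x, 6))
  det <- detect_modules(tm, min_module_size = 30)
  eg <- module_eigengenes(det$labels, x)
  trait <- eg[, 1]
  mt <- module_trait(eg, trait)
  expect_equal(mt$r[1], 1)
  expect_lt(mt$p[1], 1e-12)
  mt2 <- module_trait(eg, -trait)
  expect_equal(mt2$r[1], -1)
})

test_that("hub selection takes the top kME members with a floor of one", {
  set.seed(14)
  f <- rnorm(30)
  x <- t(sapply(seq_len(1000), function(i) {
    w <- if (i == 1) 0.02 else runif(1, 0.3, 1)
    f + w * rnorm(30)
  }))
  rownames(x) <- sprintf("g%04d", 1:1000)
  labels <- setNames(rep("blue", 1000), rownames(x))
  eg <- module_eigengenes(labels, x)
  hubs <- select_hubs(labels, x, "blue", eg)
  expect_equal(nrow(hubs), 1)            # ceil(0.001 * 1000)
  expect_equal(hubs$id, "g0001")
  # a 50-member module still returns one hub
  small <- labels[1:50]
  eg50 <- module_eigengenes(small, x[1:50, ])
  expect_equal(nrow(select_hubs(small, x[1:50, ], "blue", eg50)), 1)
})

test_that("the pipeline is deterministic for a fixed input", {
  x <- planted_block_matrix()
  n1 <- coexpr_network(x, beta = 6, min_module_size = 30)
  n2 <- coexpr_network(x, beta = 6, min_module_size = 30)
  expect_identical(n1$labels, n2$labels)
  expect_identical(n1$eigengenes, n2$eigengenes)
})

test_that("dendrograms export as readable Newick", {
  x <- planted_block_matrix(n_per = 10, n_noise = 5)
  det <- detect_modules(tom(adjacency(x, 6)), min_module_size = 5)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(det$dendro, f)
  tree <- ape::read.tree(f)
  expect_equal(sort(tree$tip.label), sort(rownames(x)))
})
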