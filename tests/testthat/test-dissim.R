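test_that("Bray-Curtis matches closed forms and stays in [0, 1]", {
  m <- rbind(a = c(3, 1, 0), b = c(3, 1, 0), c = c(0, 0, 5))
  d <- as.matrix(bray_curtis(m, pre_transform = "none"))
  expect_equal(d["a", "b"], 0)       # identical rows
  expect_equal(d["a", "c"], 1)       # disjoint support
  expect_equal(as.numeric(bray_curtis(rbind(c(6, 2), c(2, 2)),
                                      pre_transform = "none")),
               1 / 3)
  withr::with_seed(8, {
    mm <- matrix(rpois(60, 3), 10, 6)
  })
  dd <- bray_curtis(mm)
  expect_true(all(dd >= 0 & dd <= 1))
  # fourth-root pre-transform is applied elementwise before the index
  expect_equal(as.matrix(dd), as.matrix(bray_curtis(mm^0.25,
                                                    pre_transform = "none")))
  expect_warning(bray_curtis(rbind(c(0, 0), c(0, 0)), "none"), "All-zero")
})

test_that("Bray-Curtis agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(13, m <- matrix(rpois(80, 4), 10, 8))
  expect_equal(as.matrix(bray_curtis(m, pre_transform = "none")),
               as.matrix(vegan::vegdist(m, "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("ANOSIM R: complete separation gives 1, random labels near 0", {
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 50), 10))
  })
  D <- dist(x)
  g <- rep(c("a", "b"), each = 10)
  out <- anosim(D, g, n_perm = 99, seed = 1)
  expect_equal(out$R, 1)
  expect_lte(out$p_value, 0.05)

  withr::with_seed(3, {
    rs <- replicate(40, {
      gg <- sample(g)
      anosim(D, gg, n_perm = 0 + 9, seed = 1)$R
    })
  })
  expect_lt(abs(mean(rs)), 0.1)  # E[R] ~ 0 under the null
})

test_that("one-way R matches the rank-formula oracle and vegan", {
  withr::with_seed(9, x <- matrix(rnorm(36), 12, 3))
  D <- dist(x)
  g <- rep(c("a", "b", "c"), each = 4)
  ours <- anosim(D, g, n_perm = 99, seed = 4)
  expect_equal(ours$R, anosim_r_oracle(D, g), tolerance = 1e-12)
  skip_if_not_installed("vegan")
  vg <- vegan::anosim(D, g, permutations = 99)
  expect_equal(ours$R, unname(vg$statistic), tolerance = 1e-12)
})

test_that("exact enumeration on n = 6 equals the full label enumeration", {
  withr::with_seed(17, x <- matrix(rnorm(12), 6, 2))
  D <- dist(x)
  g <- rep(c("a", "b"), each = 3)
  out <- anosim(D, g, exact = TRUE)
  # independent oracle: enumerate all 6!/(3!3!) = 20 assignments directly
  combos <- combn(6, 3)
  rs <- apply(combos, 2, function(idx)
    anosim_r_oracle(D, ifelse(seq_len(6) %in% idx, "a", "b")))
  expect_equal(out$n_perm, 20)
  expect_equal(out$p_value, mean(rs >= out$R - 1e-12))
})

test_that("crossed ANOSIM reduces to one-way with a single block level and
           detects within-block separation", {
  withr::with_seed(22, x <- matrix(rnorm(40), 20, 2))
  D <- dist(x)
  g <- rep(c("in", "out"), 10)
  one <- anosim(D, g, n_perm = 199, seed = 6)
  crossed <- anosim(D, g, block = factor(rep("all", 20)), n_perm = 199,
                    seed = 6)
  expect_equal(one$R[1], crossed$R[1], tolerance = 1e-12)

  # zone effect only inside block B: crossed test re-ranks within blocks
  withr::with_seed(23, {
    blk <- rep(c("A", "B"), each = 10)
    zone <- rep(rep(c("in", "out"), each = 5), 2)
    y <- matrix(rnorm(40), 20, 2)
    y[blk == "B" & zone == "in", ] <- y[blk == "B" & zone == "in", ] + 8
  })
  res <- anosim(dist(y), zone, block = blk, n_perm = 199, seed = 7)
  expect_gt(res$R[res$factor == "grouping"], 0.2)
  expect_lte(res$p_value[res$factor == "grouping"], 0.05)

  # empty cells in the crossed design are named
  expect_error(anosim(D, factor(c(rep("a", 10), rep("b", 10))),
                      block = factor(c(rep("x", 10), rep("y", 10)))),
               "Empty cell")
})

test_that("permutation streams are reproducible by seed", {
  withr::with_seed(31, x <- matrix(rnorm(30), 15, 2))
  D <- dist(x)
  g <- rep(c("a", "b", "c"), 5)
  p1 <- anosim(D, g, n_perm = 99, seed = 11)$p_value
  p2 <- anosim(D, g, n_perm = 99, seed = 11)$p_value
  expect_identical(p1, p2)
})
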