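toy_matrix <- function() {
  m <- rbind(gA = c(1, 2, 3, 4,  5, 5,  0.2, 0.4,  9, 9,  1, 1),
             gB = c(2, 2, 2, 2,  8, 8,  8, 8,      2, 2,  0, 0),
             gC = c(0, 0, 0, 0,  0, 0,  0, 0,      0, 0,  0, 0))
  colnames(m) <- c("M1_1", "M1_2", "M1_3", "M1_4", "M2_1", "M2_2",
                   "M3_1", "M3_2", "M4_1", "M4_2", "carcass_1", "carcass_2")
  m
}

test_that("replicate averaging is the arithmetic mean and errors on missing tissues", {
  m <- toy_matrix()
  avg <- average_replicates(m)
  expect_equal(unname(avg["gA", "M1"]), 2.5)     # mean of 1,2,3,4
  expect_equal(unname(avg["gB", "M2"]), 8)       # identical replicates
  expect_equal(unname(avg["gA", "carcass"]), 1)
  expect_error(average_replicates(m[, 1:4]), "M2")
  # single replicate is itself
  expect_equal(unname(average_replicates(m[, c(1, 5, 7, 9, 11), drop = FALSE])["gA", "M1"]), 1)
})

test_that("presence is strictly greater than the threshold", {
  avg <- rbind(g1 = c(1, 1.01, 0, 5, 2))
  colnames(avg) <- MIDGUT_TISSUES
  p <- presence_calls(avg)
  expect_equal(unname(p[1, ]), c(FALSE, TRUE, FALSE, TRUE, TRUE))
  zero <- presence_calls(rbind(g = c(0, 0, 0, 0, 0)))
  expect_false(any(zero))
})

test_that("overlap partition enumerates the 15 presence patterns and conserves the total", {
  p <- rbind(A = c(TRUE, FALSE, FALSE, FALSE),
             B = c(TRUE, TRUE, FALSE, FALSE),
             C = c(TRUE, TRUE, TRUE, TRUE),
             D = c(FALSE, FALSE, FALSE, FALSE))
  colnames(p) <- c("M1", "M2", "M3", "M4")
  v <- overlap_partition(p)
  expect_length(v, 15)
  expect_equal(unname(v[["M1"]]), 1)
  expect_equal(unname(v[["M1&M2"]]), 1)
  expect_equal(unname(v[["M1&M2&M3&M4"]]), 1)
  expect_equal(sum(v), 3)  # D absent everywhere is not counted
  expect_equal(sum(v != 0), 3)
  # empty presence: all 15 cells are zero
  v0 <- overlap_partition(p[0, , drop = FALSE])
  expect_true(all(v0 == 0))
  expect_error(overlap_partition(p, tissues = c("M1", "M9")), "M9")
  # conservation on simulated data
  sim <- small_sim(300, 5)
  pres <- presence_calls(average_replicates(sim$expression))
  v1 <- overlap_partition(pres)
  expect_equal(sum(v1), sum(rowSums(pres[, c("M1", "M2", "M3", "M4")]) > 0))
})

test_that("top_n takes the highest-expressed genes with a deterministic tie rule", {
  avg <- cbind(M1 = c(a = 5, b = 3, c = 3, d = 1, e = 9))
  expect_equal(top_n(avg, "M1", 1), "e")
  expect_equal(top_n(avg, "M1", nrow(avg)), c("e", "a", "b", "c", "d"))
  # tie at the boundary: lexicographically smaller ID admitted
  expect_equal(top_n(avg, "M1", 3), c("e", "a", "b"))
  # monotone nesting under the tie rule
  for (n in 1:4) expect_true(all(top_n(avg, "M1", n) %in% top_n(avg, "M1", n + 1)))
  expect_error(top_n(avg, "M1", 6), "exceeds")
  # every member outranks every non-member
  sim <- small_sim(300, 5)
  means <- average_replicates(sim$expression)
  grp <- top_n(means, "M3", 50)
  expect_gte(min(means[grp, "M3"]), max(means[setdiff(rownames(means), grp), "M3"]))
})

test_that("pca_summary matches closed-form eigenstructure and drops flat genes", {
  # samples on a line in gene space: PC1 carries all variance
  line <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  colnames(line) <- paste0("M1_", 1:4)
  pc <- pca_summary(line)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
  expect_true(all(diff(pc$explained) <= 1e-12))

  # two scaled variables with known correlation: eigenvalues of the
  # correlation matrix are 1 +- r
  set.seed(4)
  x <- rnorm(200); y <- 0.6 * x + rnorm(200, sd = sqrt(1 - 0.36))
  m <- rbind(gx = x, gy = y)
  colnames(m) <- paste0("M1_", seq_len(200))
  pc2 <- pca_summary(m)
  r <- stats::cor(x, y)
  expect_equal(pc2$explained, c(1 + r, 1 - r) / 2, tolerance = 1e-10)

  flat <- rbind(g1 = c(1, 2, 3, 4), g0 = c(7, 7, 7, 7))
  colnames(flat) <- paste0("M1_", 1:4)
  expect_equal(pca_summary(flat)$dropped, "g0")
  expect_error(pca_summary(flat[, 1, drop = FALSE]), "2 samples")
  # explained variance invariant under sample reordering
  sim <- small_sim(300, 5)
  ex <- sim$expression
  p1 <- pca_summary(ex)$explained
  p2 <- pca_summary(ex[, sample(ncol(ex))])$explained
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("one-way ANOVA matches the hand decomposition and base aov", {
  m <- rbind(g = c(0, 1, 2, 3, 5, 5, 9, 9))
  colnames(m) <- c("M1_1", "M1_2", "M2_1", "M2_2", "M3_1", "M3_2", "M4_1", "M4_2")
  # groups (0,1) vs (2,3): SS_between = 4, SS_within = 1, df (1, 2) -> F = 8
  two <- anova_by_region(m[, 1:4, drop = FALSE], tissues = c("M1", "M2"),
                         log_transform = FALSE)
  expect_equal(two$F, 8)
  expect_equal(c(two$df1, two$df2), c(1, 2))
  expect_equal(two$p, stats::pf(8, 1, 2, lower.tail = FALSE))

  # agreement with base aov on all four groups
  full <- anova_by_region(m, log_transform = FALSE)
  vals <- as.numeric(m)
  g <- factor(sub("_[0-9]+$", "", colnames(m)), levels = c("M1", "M2", "M3", "M4"))
  ref <- summary(stats::aov(vals ~ g))[[1]]
  expect_equal(full$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(full$p, ref$`Pr(>F)`[1], tolerance = 1e-12)

  # shift invariance
  shifted <- anova_by_region(m + 100, log_transform = FALSE)
  expect_equal(shifted$F, full$F, tolerance = 1e-9)

  # identical group means -> F = 0; all-constant -> F = 0, p = 1
  flat <- rbind(g = c(1, 3, 1, 3, 1, 3, 1, 3))
  colnames(flat) <- colnames(m)
  expect_equal(anova_by_region(flat, log_transform = FALSE)$F, 0)
  const <- rbind(g = rep(2, 8))
  colnames(const) <- colnames(m)
  res <- anova_by_region(const, log_transform = FALSE)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(anova_by_region(m, tissues = "M1"), "2 groups")
})
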