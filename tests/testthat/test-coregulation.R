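fc_from_matrix <- function(m) {
  colnames(m) <- paste0("cond_", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(protein = paste0("P", seq_len(nrow(m))),
                   position = seq_len(nrow(m))),
    tibble::as_tibble(as.data.frame(m)))
}

test_that("regulation filter needs |log2FC| > 1 in at least 3 conditions", {
  m <- rbind(c(1.2, -1.5, 2.0, 0.1),   # 3 qualifying -> kept
             c(1.5, -1.5, 0.9, 0.2),   # 2 qualifying -> dropped
             c(0, 0, 0, 0),            # all zero -> dropped
             c(1.0, 1.0, 1.0, 1.0))    # exactly 1 is not > 1 -> dropped
  kept <- filter_regulated(fc_from_matrix(m))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$position, 1)
  expect_warning(filter_regulated(fc_from_matrix(m[3:4, , drop = FALSE])),
                 "empty")
})

test_that("correlations: self 1, negation -1, low overlap and constants to 0", {
  base <- c(1.5, -2, 3, 0.5, -1, 2.2)
  m <- rbind(base, -base, rep(1, 6))
  expect_warning(cc <- correlation_matrix(fc_from_matrix(m)), "constant")
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc[1, 2], -1)
  expect_equal(cc[1, 3], 0)  # constant row
  expect_equal(cc, t(cc))
  # insufficient overlap -> 0
  m2 <- rbind(c(1, 2, 3, NA, NA, NA), c(1.1, 2.2, 2.9, NA, NA, NA),
              c(NA, NA, NA, 1, 2, 3))
  cc2 <- correlation_matrix(fc_from_matrix(m2), min_overlap = 4)
  expect_equal(cc2[1, 2], 0)
  expect_equal(cc2[1, 3], 0)
})

test_that("two planted co-regulated sites correlate above 0.9", {
  sim <- make_fc_matrix(n_sites = 2, n_conditions = 40, n_clusters = 1,
                        signal_sd = 1, noise_sd = 0.1, seed = 41)
  cc <- correlation_matrix(sim$fc)
  expect_gt(cc[1, 2], 0.9)
})

test_that("block-structured correlations cut into the planted clusters", {
  # two perfectly correlated blocks, anti-correlated across blocks
  base <- c(2, -1, 1.5, -2, 1, -1.5, 2.5, -0.5)
  m <- rbind(base, base, base, -base, -base)
  cc <- suppressWarnings(correlation_matrix(fc_from_matrix(m)))
  cl <- cluster_sites(cc, cut_height = mean(range(hclust(
    dist(cc), method = "ward.D2")$height)))
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:5])), 1)
  # cut at 0: every site with a distinct profile is its own cluster
  sim0 <- make_fc_matrix(n_sites = 8, n_clusters = 2, noise_sd = 0.5, seed = 44)
  cc0 <- correlation_matrix(sim0$fc)
  expect_equal(cluster_sites(cc0, cut_height = 0)$n_clusters, 8)
  # cut above the root: single cluster with a warning
  expect_warning(one <- cluster_sites(cc, cut_height = 1e6), "root")
  expect_equal(one$n_clusters, 1)
})

test_that("cluster labels are invariant to row permutation up to renaming", {
  sim <- make_fc_matrix(n_sites = 30, n_clusters = 3, seed = 42)
  cc <- correlation_matrix(sim$fc)
  cl1 <- cluster_sites(cc, n_clusters = 3)
  set.seed(43)
  perm <- sample(nrow(cc))
  cl2 <- cluster_sites(cc[perm, perm], n_clusters = 3)
  expect_equal(mclust::adjustedRandIndex(cl1$labels[rownames(cc)[perm]],
                                         cl2$labels), 1)
})

test_that("planted 3-cluster matrices are recovered with ARI >= 0.9", {
  for (seed in 1:20) {
    sim <- make_fc_matrix(n_sites = 60, n_conditions = 50, n_clusters = 3,
                          signal_sd = 2, noise_sd = 0.2, seed = seed)
    reg <- filter_regulated(sim$fc)
    cc <- correlation_matrix(reg)
    cl <- cluster_sites(cc, n_clusters = 3)
    ari <- mclust::adjustedRandIndex(cl$labels, sim$labels[names(cl$labels)])
    expect_gte(ari, 0.9)
  }
})

test_that("the condition Z-test matches its null and shifted closed forms", {
  # null: cluster mean equal to background mean -> z = 0, p = 0.5
  m <- rbind(c(1, 1), c(-1, -1), c(3, 3), c(-3, -3))
  fc <- fc_from_matrix(m)
  labels <- stats::setNames(c(1L, 1L, 2L, 2L), paste0("P", 1:4, "_", 1:4))
  ct <- cluster_condition_test(fc, labels)
  r1 <- ct[ct$cluster == 1 & ct$condition == "cond_1", ]
  expect_equal(r1$z, 0)
  expect_equal(r1$p_value, 0.5)
  expect_equal(abs(r1$signed_log10_p), -log10(0.5), tolerance = 1e-12)

  # planted shift of +3 sd_bg / sqrt(n) with the cluster excluded from the
  # background: z = 3 exactly, one-sided p = pnorm(-3)
  bg <- c(-2, -1, 0, 1, 2)
  s_bg <- sd(bg)
  delta <- 3 * s_bg / sqrt(2)
  col <- c(bg, mean(bg) + delta - 0.01, mean(bg) + delta + 0.01)
  fc2 <- fc_from_matrix(cbind(col, col))
  labels2 <- stats::setNames(c(rep(1L, 5), 2L, 2L),
                             paste0("P", 1:7, "_", 1:7))
  ct2 <- cluster_condition_test(fc2, labels2,
                                exclude_cluster_from_background = TRUE)
  r2 <- ct2[ct2$cluster == 2 & ct2$condition == "cond_1", ]
  expect_equal(r2$z, 3, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.0013498980316301035, tolerance = 1e-9)
  expect_gt(r2$signed_log10_p, 0)

  # an all-missing condition gives NA
  m3 <- cbind(c(1, 2, 3, 4), NA_real_)
  ct3 <- cluster_condition_test(fc_from_matrix(m3),
                                stats::setNames(c(1L, 1L, 2L, 2L),
                                                paste0("P", 1:4, "_", 1:4)))
  expect_true(all(is.na(ct3$p_value[ct3$condition == "cond_2"])))
})

test_that("hypergeometric over-representation matches exact enumeration", {
  population <- c(letters[1:15], paste0("x", 1:5))
  ann <- list(T1 = c("a", "b", "c", "e", "f"))
  # selection of 5 containing 4 of the 5 term members
  res <- over_representation(c("a", "b", "c", "e", "d"), ann, population)
  expected <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(res$p_value, expected, tolerance = 1e-12)
  # selection = population -> p = 1 for every term
  all_sel <- over_representation(population, ann, population)
  expect_equal(all_sel$p_value, 1)
  expect_error(over_representation(character(0), ann, population), "empty")
  # zero-membership terms are skipped
  res2 <- over_representation(c("a", "b"), list(T0 = c("zz"), T1 = ann$T1),
                              population)
  expect_false("T0" %in% res2$term)
  expect_true(all(res2$q_value >= res2$p_value - 1e-12))
})
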