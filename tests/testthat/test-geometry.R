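test_that("kabsch recovers planted rigid motions to numerical precision", {
  for (seed in 1:100) {
    set.seed(seed)
    p <- matrix(rnorm(45), 15, 3)
    tf0 <- complexforge:::random_rigid_motion()
    q <- apply_transform(tf0, p)
    tf <- kabsch(p, q)
    expect_lt(tf$rmsd, 1e-6)
    expect_lt(max(abs(tf$rotation - tf0$rotation)), 1e-6)
    expect_lt(max(abs(tf$translation - tf0$translation)), 1e-6)
  }
})

test_that("kabsch transform is proper (no reflection) and validates input", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "3 matched points")
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch(line, line), "collinear")
  # mirror image of a chiral set: rotation stays proper, rmsd > 0
  set.seed(1)
  p <- matrix(rnorm(30), 10, 3)
  q <- p %*% diag(c(-1, 1, 1))
  tf <- kabsch(p, q)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-8)
  expect_gt(tf$rmsd, 0.1)
  # identical sets: identity rotation, rmsd 0
  tf_id <- kabsch(p, p)
  expect_lt(tf_id$rmsd, 1e-10)
  expect_equal(tf_id$rotation, diag(3), tolerance = 1e-10)
})

test_that("kabsch rmsd is invariant under a rigid motion of both sets", {
  set.seed(2)
  p <- matrix(rnorm(36), 12, 3)
  q <- p + matrix(rnorm(36, sd = 0.5), 12, 3)
  base <- kabsch(p, q)$rmsd
  for (seed in 1:20) {
    set.seed(seed)
    m <- complexforge:::random_rigid_motion()
    expect_equal(kabsch(apply_transform(m, p), apply_transform(m, q))$rmsd,
                 base, tolerance = 1e-9)
  }
})

test_that("d0 follows the closed form with a 0.5 A floor", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(100), 3.652, tolerance = 1e-3)
  expect_equal(tm_d0(21), 0.5)
  expect_equal(tm_d0(10), 0.5)
})

test_that("tm_score is exact for self and rigid copies, low for scrambled", {
  set.seed(3)
  hel <- complexforge:::helix_chain(30, "A", 90)
  ca <- as.matrix(hel[hel$elety == "CA", c("x", "y", "z")])
  expect_equal(tm_score(ca, ca)$tm_score, 1.0)
  moved <- apply_transform(complexforge:::random_rigid_motion(), ca)
  expect_equal(tm_score(moved, ca)$tm_score, 1.0, tolerance = 1e-9)
  scrambled <- ca[sample(nrow(ca)), ]
  expect_lt(tm_score(scrambled, ca)$tm_score, 0.2)
})

test_that("tm_score is bracketed by the whole-chain Kabsch fit and 1", {
  # the full-length seed is the plain Kabsch superposition, so the iterative
  # search can only improve on its score; 1 bounds it from above
  d0 <- tm_d0(20)
  for (seed in 1:20) {
    set.seed(seed)
    ref <- matrix(rnorm(60, sd = 4), 20, 3)
    mob <- apply_transform(complexforge:::random_rigid_motion(),
                           ref + matrix(rnorm(60, sd = 1), 20, 3))
    tf <- kabsch(mob, ref)
    d <- sqrt(rowSums((apply_transform(tf, mob) - ref)^2))
    lower <- mean(1 / (1 + (d / d0)^2))
    tm <- tm_score(mob, ref)$tm_score
    expect_gte(tm + 1e-9, lower)
    expect_lte(tm, 1)
  }
})

test_that("tm_score does not exceed a dense rotation-grid optimum by more than grid error", {
  # coarse SO(3) grid with centroid translation gives a lower bound on the
  # true optimum; the iterative search must at least reach it
  grid_tm <- function(mob, ref, d0, step = 30) {
    ang <- seq(0, 330, by = step) * pi / 180
    half <- seq(0, 150, by = step) * pi / 180
    best <- 0
    cm <- colMeans(mob); cr <- colMeans(ref)
    mc <- sweep(mob, 2, cm)
    for (a in ang) for (b in half) for (g in ang) {
      rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
      ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
      rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
      r <- rz1 %*% ry %*% rz2
      d <- sqrt(rowSums((sweep(mc %*% t(r), 2, cr, "+") - ref)^2))
      best <- max(best, mean(1 / (1 + (d / d0)^2)))
    }
    best
  }
  for (seed in 1:3) {
    set.seed(seed)
    ref <- matrix(rnorm(36, sd = 3), 12, 3)
    mob <- apply_transform(complexforge:::random_rigid_motion(),
                           ref + matrix(rnorm(36, sd = 0.8), 12, 3))
    d0 <- tm_d0(12)
    expect_gte(tm_score(mob, ref)$tm_score + 1e-9, grid_tm(mob, ref, d0))
  }
})

test_that("assembly_rmsd recovers identity and is invariant to copy permutation", {
  cx <- make_complex(n_chains = 4, seed = 5)
  id_map <- cx$chain_map
  r <- assembly_rmsd(cx$complex, cx$complex, model_map = id_map,
                     reference_map = id_map)
  expect_lt(r$rmsd, 1e-9)
  expect_equal(r$tm_score, 1.0, tolerance = 1e-9)

  # two identical copies of one protein: swapping labels must not change rmsd
  cx2 <- make_complex(n_chains = 3, seed = 6)
  dup_map <- tibble::tibble(chain = c("A", "B", "C"),
                            protein = c("P1", "P1", "P2"))
  swapped <- dup_map; swapped$chain <- c("B", "A", "C")
  r1 <- assembly_rmsd(cx2$complex, cx2$complex, dup_map, dup_map)
  r2 <- assembly_rmsd(cx2$complex, cx2$complex, swapped, dup_map)
  expect_equal(r1$rmsd, r2$rmsd, tolerance = 1e-9)
  expect_error(
    assembly_rmsd(cx2$complex, cx2$complex,
                  model_map = tibble::tibble(chain = "A", protein = "QX"),
                  reference_map = dup_map),
    "no chains match")
})
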