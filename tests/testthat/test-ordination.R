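test_that("Bray-Curtis matches hand computations and boundary cases", {
  x <- rbind(a = c(0.6, 0.4, 0), b = c(0.2, 0.4, 0.4))
  expect_equal(bray_curtis(x)["a", "b"], 0.4)  # 1 - 2*(0.2+0.4)/2
  same <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 0))), "all-zero")
})

test_that("Bray-Curtis is a bounded symmetric dissimilarity on random tables", {
  set.seed(14)
  for (rep in 1:5) {
    x <- matrix(stats::rexp(60), 6, 10,
                dimnames = list(sprintf("s%d", 1:6), sprintf("t%d", 1:10)))
    x <- x / rowSums(x)
    d <- bray_curtis(x)
    validate_distance_matrix(d)
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("PCoA reconstructs Euclidean-embeddable input exactly", {
  set.seed(21)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:7), sprintf("s%d", 1:7))
  ord <- strainniche::pcoa(d, k = 3)
  rec <- as.matrix(dist(ord$scores))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  # asking for more axes than exist degrades gracefully with a warning
  expect_warning(strainniche::pcoa(d, k = 6), "positive axes")
})

test_that("PCoA matches classical MDS and drops degenerate axes", {
  # 3 collinear points, spacing 1-1-2
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ord <- suppressWarnings(strainniche::pcoa(d, k = 2))
  # axis 1 reproduces the spacing up to sign/translation; axis 2 is gone
  expect_equal(ncol(ord$scores), 1L)
  s <- sort(ord$scores[, 1])
  expect_equal(unname(diff(s)), c(1, 1), tolerance = 1e-8)
  # independent oracle: stats::cmdscale on a random Euclidean matrix
  set.seed(5)
  pts <- matrix(rnorm(12), 6, 2)
  dd <- as.matrix(dist(pts))
  dimnames(dd) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  o2 <- strainniche::pcoa(dd, k = 2)
  cs <- stats::cmdscale(dd, k = 2)
  expect_equal(abs(unname(o2$scores)), abs(unname(cs)), tolerance = 1e-8)
  # all-zero distances -> all-zero scores
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  oz <- strainniche::pcoa(z, k = 2)
  expect_true(all(oz$scores == 0))
})

test_that("PCoA eigenvalue sum equals the trace of the Gower matrix", {
  d <- random_dm(8, seed = 33, max_d = 0.8)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  ord <- suppressWarnings(strainniche::pcoa(d, k = n - 1))
  ev_all <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev_all), sum(diag(B)), tolerance = 1e-8)
  expect_equal(ord$eigenvalues, ev_all[ev_all > 1e-9 * max(abs(ev_all))],
               tolerance = 1e-8)
})

test_that("frequency correction divides scores by the group size", {
  scores <- matrix(c(7.34, 1.0), 2, 1,
                   dimnames = list(c("c1", "h1"), "PC1"))
  ord <- structure(list(eigenvalues = 1, scores = scores,
                        corrected = FALSE, divisor = NULL),
                   class = "pcoa_result")
  out <- frequency_correct(ord, c(c1 = "cat", h1 = "human"),
                           group_sizes = c(cat = 367, human = 1))
  expect_equal(out$scores["c1", "PC1"], 7.34 / 367)
  expect_equal(out$scores["c1", "PC1"], 0.02)
  expect_equal(out$scores["h1", "PC1"], 1.0)  # size-1 group unchanged
  expect_true(out$corrected)
  # double application is guarded
  expect_error(frequency_correct(out, c(c1 = "cat", h1 = "human")),
               "already")
  # unknown group errors
  expect_error(frequency_correct(ord, c(c1 = "cat", h1 = "mouse"),
                                 group_sizes = c(cat = 367)), "unknown")
})

test_that("frequency correction preserves within-group score order", {
  d <- random_dm(9, seed = 9, max_d = 0.9)
  ord <- strainniche::pcoa(d, k = 2)
  grp <- stats::setNames(rep(c("a", "b", "c"), each = 3), rownames(d))
  out <- frequency_correct(ord, grp)
  for (g in c("a", "b", "c")) {
    idx <- names(grp)[grp == g]
    expect_equal(order(out$scores[idx, 1]), order(ord$scores[idx, 1]))
  }
})

test_that("taxon positions are abundance-weighted mean sample scores", {
  scores <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
                   dimnames = list(c("s1", "s2", "s3"), c("PC1", "PC2")))
  ord <- structure(list(eigenvalues = c(2, 1), scores = scores,
                        corrected = FALSE, divisor = NULL),
                   class = "pcoa_result")
  ab <- matrix(c(1, 0, 0,     # t1 only in s1
                 0.5, 0.5, 0, # t2 equal in s1, s2
                 0.5, 0.3, 0.2,
                 0, 0, 0),    # t4 absent everywhere
               3, 4, dimnames = list(c("s1", "s2", "s3"),
                                     c("t1", "t2", "t3", "t4")))
  pos <- feature_positions(ord, ab)
  expect_equal(pos["t1", ], scores["s1", ])
  expect_equal(unname(pos["t2", ]), c(1.5, 15))
  w <- c(0.5, 0.3, 0.2)
  expect_equal(unname(pos["t3", ]), unname(colSums(scores * w) / sum(w)))
  expect_true(all(is.na(pos["t4", ])))
})

test_that("PERMANOVA handles the exact separation and flat cases", {
  b <- matrix(1, 6, 6); b[1:3, 1:3] <- 0; b[4:6, 4:6] <- 0; diag(b) <- 0
  dimnames(b) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  grp <- rep(c("x", "y"), each = 3)
  res <- permanova(b, grp, permutations = 99, seed = 1)
  expect_equal(res$R2, 1)
  flat <- matrix(0.5, 6, 6); diag(flat) <- 0
  dimnames(flat) <- dimnames(b)
  res2 <- permanova(flat, grp, permutations = 99, seed = 1)
  expect_equal(res2$p, 1)  # every permutation gives the same F
  expect_error(permanova(b, rep("x", 6), permutations = 99, seed = 1),
               "2 groups")
})

test_that("PERMANOVA R2 equals the brute-force oracle and vegan", {
  d <- random_dm(8, seed = 12)
  grp <- rep(c("x", "y"), 4)
  res <- permanova(d, grp, permutations = 99, seed = 3)
  expect_equal(res$R2, oracle_permanova_r2(d, grp), tolerance = 1e-10)
  av <- vegan::adonis2(stats::as.dist(d) ~ g,
                       data = data.frame(g = grp), permutations = 99)
  expect_equal(res$R2, av$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_F, av$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA p-values are reproducible and seed-dependent", {
  d <- random_dm(10, seed = 4)
  grp <- rep(c("x", "y"), 5)
  p1 <- permanova(d, grp, permutations = 199, seed = 10)$p
  p2 <- permanova(d, grp, permutations = 199, seed = 10)$p
  expect_identical(p1, p2)
})
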