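# Distance matrix with two planted host blocks: all within-host distances
# d_w, all between-host distances d_b.
block_dm <- function(n_a, n_b, d_w, d_b, hosts = c("cat", "dog")) {
  n <- n_a + n_b
  ids <- sprintf("s%02d", seq_len(n))
  host <- stats::setNames(rep(hosts, c(n_a, n_b)), ids)
  m <- matrix(d_b, n, n, dimnames = list(ids, ids))
  m[seq_len(n_a), seq_len(n_a)] <- d_w
  m[(n_a + 1):n, (n_a + 1):n] <- d_w
  diag(m) <- 0
  list(dm = m, host = host)
}

test_that("eligibility applies the sharing and sample-count rules", {
  inv <- list(
    ok        = c(dog = 25, cat = 5),            # eligible
    onehost   = c(dog = 19),                     # single host, total < 20
    small5    = c(dog = 30, cat = 4, human = 0), # only one host >= 5
    twosmall  = c(dog = 10, cat = 9),            # total 19 < 20
    threeway  = c(dog = 10, cat = 5, human = 5)  # eligible
  )
  res <- eligible_sgbs(inv)
  got <- stats::setNames(res$eligible, res$sgb_id)
  expect_true(got[["ok"]])
  expect_true(got[["threeway"]])
  expect_false(got[["onehost"]])
  expect_false(got[["small5"]])
  expect_false(got[["twosmall"]])
  expect_match(res$reason[res$sgb_id == "small5"], "2 hosts")
  expect_match(res$reason[res$sgb_id == "onehost"], "shared")
})

test_that("host score equals the hand-computed median contrast", {
  b <- block_dm(5, 5, d_w = 0.01, d_b = 0.10)
  expect_equal(host_coherence_score(b$dm, b$host, "cat"), 1 - 0.01 / 0.10)
  expect_equal(host_coherence_score(b$dm, b$host, "dog"), 0.9)
})

test_that("no host structure and inverted structure both give 0", {
  flat <- block_dm(5, 5, d_w = 0.2, d_b = 0.2)
  expect_equal(host_coherence_score(flat$dm, flat$host, "cat"), 0)
  inv <- block_dm(5, 5, d_w = 0.2, d_b = 0.1)  # within larger than between
  expect_equal(host_coherence_score(inv$dm, inv$host, "cat"), 0)
  zero <- block_dm(5, 5, d_w = 0, d_b = 0)     # median(B) = 0
  expect_equal(host_coherence_score(zero$dm, zero$host, "cat"), 0)
})

test_that("host score preconditions and saturation rule hold", {
  b <- block_dm(4, 6, d_w = 0.01, d_b = 0.1)
  expect_error(host_coherence_score(b$dm, b$host, "cat"), "need >= 5")
  # saturate > 50% of cat's pairs -> undefined
  b2 <- block_dm(5, 5, d_w = 0.01, d_b = 0.1)
  dm <- b2$dm
  cat_ids <- names(b2$host)[b2$host == "cat"]
  dog_ids <- names(b2$host)[b2$host == "dog"]
  dm[cat_ids, dog_ids] <- NA_real_  # 25 of 35 relevant pairs saturated
  dm[dog_ids, cat_ids] <- NA_real_
  expect_true(is.na(host_coherence_score(dm, b2$host, "cat")))
})

test_that("SGB score is the unweighted mean of defined host scores", {
  # the three published worked examples, printed at 3 decimals
  expect_lt(abs(mean_coherence(c(0.763, 0.876, 0.909)) - 0.850), 0.002)
  expect_lt(abs(mean_coherence(c(0.00, 0.554, 0.00)) - 0.185), 0.002)
  expect_lt(abs(mean_coherence(c(0.00, 0.623, 0.093)) - 0.238), 0.002)
  expect_equal(mean_coherence(c(0.5, NA, 0.7)), 0.6)
  expect_true(is.na(mean_coherence(c(NA_real_, NA_real_))))
})

test_that("coherence_score aggregates host scores and reports eligibility", {
  b <- block_dm(12, 12, d_w = 0.01, d_b = 0.10)
  res <- coherence_score(b$dm, b$host, sgb_id = "SGBtest")
  expect_s3_class(res, "coherence_result")
  expect_equal(unname(res$host_scores[c("cat", "dog")]), c(0.9, 0.9))
  expect_equal(res$mean_score, 0.9)
  expect_true(res$eligible)
  tab <- coherence_table(res)
  expect_equal(tab$mean_score, 0.9)
  expect_equal(tab$n_cat, 12L)
})

test_that("hosts below the strain minimum feed B pools but get no score", {
  b <- block_dm(10, 3, d_w = 0.01, d_b = 0.10)
  res <- coherence_score(b$dm, b$host)
  expect_equal(names(res$host_scores), "cat")
  expect_equal(unname(res$host_scores), 0.9)  # dog strains still in cat's B
  # no host reaching the minimum is an error
  tiny <- block_dm(3, 3, d_w = 0.01, d_b = 0.1)
  expect_error(coherence_score(tiny$dm, tiny$host), "no host")
})

test_that("scores are invariant to rescaling all distances", {
  set.seed(8)
  sim <- simulate_strain_set(n_per_host = 6, L = 600, t_w = 0.02, t_b = 0.05,
                             seed = 31)
  dm <- k2p_distance_matrix(sim$alignment, min_sites = 10)
  host <- host_labels(sim$alignment)
  r1 <- coherence_score(dm, host, min_total = 10)
  for (k in c(0.5, 3, 100)) {
    rk <- coherence_score(dm * k, host, min_total = 10)
    expect_equal(rk$host_scores, r1$host_scores, tolerance = 1e-12)
    expect_equal(rk$mean_score, r1$mean_score, tolerance = 1e-12)
  }
})

test_that("permuted labels on fully mixed data give near-zero coherence", {
  # one mixed pool of strains, labels assigned at random 200 times
  sim <- simulate_strain_set(n_per_host = 10, L = 1000, t_w = 0.05, t_b = 0,
                             seed = 55)
  dm <- k2p_distance_matrix(sim$alignment, min_sites = 10)
  ids <- rownames(dm)
  set.seed(77)
  cvals <- replicate(200, {
    host <- stats::setNames(sample(rep(c("cat", "dog", "human"), each = 10)), ids)
    coherence_score(dm, host)$mean_score
  })
  expect_lte(mean(cvals), 0.05)
})

test_that("coherence is monotone in the between-host branch length", {
  t_bs <- c(0, 0.02, 0.05, 0.1, 0.2)
  cs <- vapply(seq_along(t_bs), function(i) {
    sim <- simulate_strain_set(n_per_host = 8, L = 2000, t_w = 0.02,
                               t_b = t_bs[i], seed = 400 + i)
    dm <- k2p_distance_matrix(sim$alignment, min_sites = 10)
    coherence_score(dm, host_labels(sim$alignment))$mean_score
  }, numeric(1))
  # allow tiny stochastic wobble between adjacent grid points
  expect_true(all(diff(cs) > -0.03))
  expect_lt(cs[1], 0.1)
  expect_gt(cs[5], 0.7)
})
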