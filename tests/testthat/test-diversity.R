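test_that("exact Raup-Crick matches brute-force hypergeometric enumeration", {
  # no shared taxa, 5+5 from a pool of 20: S_RC = 0.5 * P(X = 0)
  expect_equal(raup_crick_exact(5, 5, 20, 0),
               0.5 * choose(15, 5) / choose(20, 5))
  expect_equal(raup_crick_exact(5, 5, 20, 0), src_brute(5, 5, 20, 0))
  # mid case against direct pmf summation
  expect_equal(raup_crick_exact(7, 5, 20, 3), src_brute(7, 5, 20, 3))
  # maximal sharing with small richness vs pool -> near 1
  expect_gt(raup_crick_exact(10, 10, 100, 10), 1 - 1e-10)
  # saturated profiles: every null draw ties -> 0.5
  expect_equal(raup_crick_exact(20, 20, 20, 20), 0.5)
  # forced-overlap zero: P(X < 0) = 0 and P(X = 0) = 0
  expect_equal(raup_crick_exact(15, 15, 20, 10), src_brute(15, 15, 20, 10))
  expect_error(raup_crick_exact(5, 5, 20, 6), "infeasible")
  expect_error(raup_crick_exact(25, 5, 20, 2), "pool")
})

test_that("Monte-Carlo Raup-Crick converges to the closed form", {
  set.seed(8)
  for (rep in 1:12) {
    pool <- sample(15:40, 1)
    n_a <- sample(3:(pool - 2), 1)
    n_b <- sample(3:(pool - 2), 1)
    a <- integer(pool); a[sample.int(pool, n_a)] <- 1L
    b <- integer(pool); b[sample.int(pool, n_b)] <- 1L
    obs <- sum(a & b)
    exact <- raup_crick_exact(n_a, n_b, pool, obs)
    mc <- raup_crick(a, b, n_null = 1999, seed = 100 + rep)
    se <- sqrt(max(exact * (1 - exact), 1e-6) / 1999)
    expect_lt(abs(mc - exact), 3 * se + 1e-9)
  }
})

test_that("Raup-Crick is symmetric and validates its inputs", {
  a <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  b <- c(0, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(raup_crick(a, b, n_null = 999, seed = 5),
               raup_crick(b, a, n_null = 999, seed = 5))
  expect_error(raup_crick(a, b[1:5]), "equal length")
  expect_error(raup_crick(a, b, pool_size = 2), "pool")
  expect_error(raup_crick(a, b, n_null = 99), "999")
})

test_that("pairwise similarity matrix is well-formed and label-invariant", {
  m <- rbind(s1 = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
             s2 = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
             s3 = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  bm <- suppressWarnings(band_matrix(m, reactor = c("A", "A", "B"), day = c(1, 2, 1)))
  S <- pairwise_src(bm, n_null = 1999, seed = 3)
  expect_true(isSymmetric(unname(S)))
  expect_equal(diag(S), rep(1, 3), ignore_attr = TRUE)
  expect_gt(S[1, 2], 0.95)          # identical mid-richness profiles
  # reordering samples permutes the matrix consistently
  bm_rev <- suppressWarnings(band_matrix(m[3:1, ], reactor = c("B", "A", "A"),
                                         day = c(1, 2, 1)))
  S_rev <- pairwise_src(bm_rev, n_null = 1999, seed = 3)
  expect_equal(S_rev[rownames(S), colnames(S)], S)
  # single sample: 1 x 1 identity
  bm1 <- suppressWarnings(band_matrix(m[1, , drop = FALSE], "A", 1))
  expect_equal(unname(pairwise_src(bm1, n_null = 999, seed = 1)),
               matrix(1, 1, 1))
})

test_that("single linkage clusters identical profiles at height zero", {
  S <- diag(1, 4)
  S[1, 2] <- S[2, 1] <- 1        # identical pair
  S[3, 4] <- S[4, 3] <- 1        # identical pair
  S[1, 3] <- S[3, 1] <- S[1, 4] <- S[4, 1] <- 0.2
  S[2, 3] <- S[3, 2] <- S[2, 4] <- S[4, 2] <- 0.2
  hc <- single_linkage_cluster(S)
  expect_equal(hc$height[1:2], c(0, 0))
  expect_equal(hc$height[3], 0.8)
  expect_error(single_linkage_cluster(matrix(c(1, 0.3, 0.1, 1), 2, 2)),
               "symmetric")
})

test_that("single linkage reproduces the brute-force 3-sample chain", {
  # d(1,2) = 0.1, d(1,3) = 0.5, d(2,3) = 0.3: single linkage merges
  # {1,2} at 0.1 then {1,2},{3} at min(0.5, 0.3) = 0.3
  S <- diag(1, 3)
  S[1, 2] <- S[2, 1] <- 0.9
  S[1, 3] <- S[3, 1] <- 0.5
  S[2, 3] <- S[3, 2] <- 0.7
  hc <- single_linkage_cluster(S)
  expect_equal(hc$height, c(0.1, 0.3))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  # duplicating a sample leaves existing merge heights unchanged
  S4 <- rbind(cbind(S, S[, 1]), c(S[1, ], 1))
  hc4 <- single_linkage_cluster(S4)
  expect_true(all(c(0.1, 0.3) %in% round(hc4$height, 12)))
  # Newick export covers all labels
  hc$labels <- c("a", "b", "c")
  nwk <- dendrogram_newick(hc)
  expect_true(all(vapply(c("a", "b", "c"), grepl, logical(1), x = nwk)))
})

test_that("moving window flags stability, shifts and random drift", {
  pool <- 30
  stable_prof <- c(rep(1, 9), rep(0, pool - 9))
  m <- rbind(stable_prof, stable_prof, stable_prof)
  bm <- suppressWarnings(band_matrix(m, reactor = "R1", day = c(1, 10, 19)))
  mw <- moving_window(bm, n_null = 1999, seed = 2, pool_size = pool)
  expect_equal(nrow(mw), 2)
  expect_true(all(mw$S_RC > 0.95))
  expect_true(all(mw$flag == "stable"))
  # complete band replacement between days -> significant shift
  m2 <- rbind(c(rep(1, 8), rep(0, pool - 8)),
              c(rep(0, 8), rep(1, 8), rep(0, pool - 16)))
  bm2 <- suppressWarnings(band_matrix(m2, reactor = "R4", day = c(19, 28)))
  mw2 <- moving_window(bm2, n_null = 1999, seed = 2, pool_size = pool)
  expect_equal(nrow(mw2), 1)
  expect_lt(mw2$S_RC, 0.05)
  expect_equal(mw2$flag, "shift")
  bm_bad <- suppressWarnings(band_matrix(m, reactor = "R1", day = c(10, 1, 19)))
  expect_error(moving_window(bm_bad), "increasing")
})

test_that("Chao1 reproduces hand-computed values in both forms", {
  x <- c(1, 1, 2, 3, 4)                      # S = 5, F1 = 2, F2 = 1
  expect_equal(chao1(x, bias_corrected = FALSE)$estimate, 7)    # 5 + 4/2
  expect_equal(chao1(x)$estimate, 5.5)       # 5 + 2*1/(2*2)
  # no singletons: lower bound attained
  expect_equal(chao1(c(2, 3, 5))$estimate, 3)
  expect_equal(chao1(c(2, 3, 5))$se, 0)
  expect_error(chao1(integer(0)))
  expect_error(chao1(c(0, 0)))
  # estimator never drops below observed richness (randomized)
  set.seed(21)
  for (i in 1:15) {
    cnt <- rpois(12, 2)
    if (sum(cnt) == 0) next
    expect_gte(chao1(cnt)$estimate, sum(cnt > 0))
  }
})

test_that("Chao1 and ACE agree with the independent vegan implementation", {
  set.seed(31)
  for (i in 1:8) {
    cnt <- c(rep(1, sample(0:4, 1)), rep(2, sample(0:3, 1)),
             sample(1:30, sample(3:10, 1), replace = TRUE))
    v <- suppressWarnings(vegan::estimateR(cnt))
    expect_equal(chao1(cnt)$estimate, unname(v["S.chao1"]), tolerance = 1e-10)
    a <- suppressWarnings(ace(cnt))   # fallback branch tested separately
    if (is.null(a$fallback))
      expect_equal(a$estimate, unname(v["S.ACE"]), tolerance = 1e-8)
    expect_equal(chao1(cnt)$se, unname(v["se.chao1"]), tolerance = 0.15)
  }
})

test_that("ACE handles its edge cases per the standard formula", {
  # no rare class: estimator equals observed richness
  expect_equal(ace(c(12, 15, 30))$estimate, 3)
  # abundant-class passthrough: adding an abundant species adds exactly 1
  x <- c(1, 1, 2, 3, 12)
  expect_equal(ace(c(x, 50))$estimate, ace(x)$estimate + 1)
  # hand evaluation: rare = {1,1,2,3}, N_rare = 7, F1 = 2, C = 5/7,
  # sum k(k-1)F_k = 2 + 6 = 8, gamma2 = max(4/C * 8/42 - 1, 0)
  C <- 1 - 2 / 7
  g2 <- max((4 / C) * 8 / (7 * 6) - 1, 0)
  expect_equal(ace(x)$estimate, 1 + 4 / C + (2 / C) * g2, tolerance = 1e-12)
  expect_gt(ace(x)$se, 0)
  # all rare taxa singletons: coverage zero, falls back to Chao1
  expect_warning(a <- ace(c(1, 1, 1, 12, 15)), "falling back")
  expect_equal(a$estimate, chao1(c(1, 1, 1, 12, 15))$estimate)
})

test_that("rarefaction follows the hypergeometric expectation", {
  x <- c(5, 3, 2)
  rc <- rarefaction_curve(x, c(1, 5, 10))
  expect_equal(rc$expected_species[1], 1, tolerance = 1e-6)  # n = 1
  expect_equal(rc$expected_species[3], 3)                    # full depth
  # direct formula check at n = 5
  N <- 10
  direct <- sum(1 - choose(N - x, 5) / choose(N, 5))
  expect_equal(rc$expected_species[2], direct, tolerance = 1e-10)
  # Monte-Carlo subsampling oracle
  set.seed(12)
  units <- rep(seq_along(x), x)
  mc <- replicate(30000, length(unique(sample(units, 5))))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - rc$expected_species[2]), 3 * se)
  # curve is non-decreasing and concave in depth
  full <- rarefaction_curve(x, 1:10)$expected_species
  expect_true(all(diff(full) > -1e-12))
  expect_true(all(diff(diff(full)) < 1e-12))
  expect_error(rarefaction_curve(x, 11), "depth")
})

test_that("richness statistics are invariant to taxon relabeling", {
  set.seed(77)
  cnt <- c(1, 1, 1, 2, 2, 4, 9, 13)
  perm <- sample(length(cnt))
  expect_equal(chao1(cnt)$estimate, chao1(cnt[perm])$estimate)
  expect_equal(ace(cnt)$estimate, ace(cnt[perm])$estimate)
  expect_equal(rarefaction_curve(cnt, 10)$expected_species,
               rarefaction_curve(cnt[perm], 10)$expected_species)
})

test_that("band counts over the trailing days summarize correctly", {
  pool <- 9
  m <- matrix(1, nrow = 4, ncol = pool)
  bm <- band_matrix(m, reactor = "R1", day = c(46, 55, 64, 73))
  br <- band_richness(bm)
  expect_equal(br$mean_bands, 9)
  expect_equal(br$sd_bands, 0)
  # counts {9, 10, 9, 8} -> mean 9, sd sqrt(2/3)
  m2 <- matrix(0, nrow = 4, ncol = 10)
  for (i in 1:4) m2[i, seq_len(c(9, 10, 9, 8)[i])] <- 1
  bm2 <- band_matrix(m2, reactor = "R2", day = c(46, 55, 64, 73))
  br2 <- band_richness(bm2)
  expect_equal(br2$mean_bands, 9)
  expect_equal(br2$sd_bands, sqrt(2 / 3), tolerance = 1e-12)
  expect_error(band_richness(bm2, last_k_days = 5), "fewer")
})
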