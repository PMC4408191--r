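test_that("species-pool generator respects its spec and seed", {
  p1 <- gen_species_pool(pool_spec(seed = 9))
  expect_s3_class(p1, "species_pool")
  expect_equal(nrow(p1), 23)
  expect_true(all(p1$mu_max >= 0.9 & p1$mu_max <= 1.1))
  expect_true(all(p1$K_N >= 0.5 & p1$K_N <= 4))
  expect_true(all(p1$K_O >= 0.15 & p1$K_O <= 1.2))
  # bit-reproducible
  expect_identical(p1, gen_species_pool(pool_spec(seed = 9)))
  # single species edge
  expect_equal(nrow(gen_species_pool(pool_spec(n_species = 1))), 1)
  expect_error(pool_spec(K_N_range = c(2, 1)), "ranges")
  expect_error(pool_spec(tradeoff_rho = -2), "tradeoff_rho")
})

test_that("perfect trade-off reverses affinity ranks exactly", {
  p <- gen_species_pool(pool_spec(n_species = 12, tradeoff_rho = -1, seed = 2))
  expect_equal(rank(p$K_N), 13 - rank(p$K_O))
})

test_that("default pools have a non-degenerate competitive front", {
  # no species may dominate all others on both half-saturations
  for (s in 1:6) {
    p <- gen_species_pool(pool_spec(seed = s))
    best_both <- vapply(seq_len(nrow(p)), function(i)
      all(p$K_N[i] <= p$K_N[-i] + 1e-15) && all(p$K_O[i] <= p$K_O[-i] + 1e-15),
      logical(1))
    expect_false(any(best_both))
  }
})

test_that("trade-off induces stable consumption geometry along the front", {
  p <- gen_species_pool(pool_spec(seed = 3))
  # c_O/c_N must increase with K_O/K_N (species consume relatively more
  # of the resource they are worse at), the stability prerequisite
  expect_identical(order(p$c_O / p$c_N), order(p$K_O / p$K_N))
})

test_that("band-matrix generator produces the designed temporal structure", {
  # zero turnover, no attractor pull or noise: every profile = inoculum
  spec0 <- gel_spec(turnover_rate = 0, attractor_pull = 0, noise_rate = 0,
                    seed = 4)
  bm0 <- gen_band_matrix(spec0)
  expect_equal(nrow(bm0$presence), 36)
  expect_equal(nrow(unique(as.data.frame(bm0$presence))), 1)
  # generated object satisfies the band-matrix invariants
  bm <- gen_band_matrix(gel_spec(seed = 4))
  expect_true(all(bm$presence %in% 0:1))
  expect_identical(gen_band_matrix(gel_spec(seed = 4))$presence, bm$presence)
  expect_error(gel_spec(pool = 8, attractor_sizes = c(9, 7, 12, 6)),
               "smaller")
})

test_that("post-convergence samples cluster by treatment (pipeline oracle)", {
  pure_seeds <- 0
  for (s in 1:5) {
    bm <- gen_band_matrix(gel_spec(seed = s))
    post <- bm$samples$day > 28
    S <- pairwise_src(bm, n_null = 999, seed = 100 + s)
    hcp <- single_linkage_cluster(S[post, post])
    k4 <- stats::cutree(hcp, 4)
    pure <- all(apply(table(k4, bm$samples$reactor[post]), 1,
                      function(r) sum(r > 0) == 1))
    pure_seeds <- pure_seeds + pure
  }
  expect_gte(pure_seeds, 4)
})

test_that("clone-library generator produces skewed libraries at scale", {
  otus <- gen_otu_counts(seed = 5)
  expect_equal(dim(otus), c(25, 4))
  tot <- colSums(otus)
  expect_true(all(tot >= 37 & tot <= 42))
  # ~160 clones across 4 libraries, the reported library scale
  expect_true(sum(tot) > 140 && sum(tot) < 170)
  expect_identical(unclass(gen_otu_counts(seed = 5)),
                   unclass(gen_otu_counts(seed = 5)))
  expect_error(gen_otu_counts(k = 1.2), "k must")
})

test_that("skewed abundances leave estimated richness above observed", {
  hits <- 0
  for (s in 1:6) {
    otus <- gen_otu_counts(n_samples = 1, pool = 25, seed = s)
    ch <- chao1(otus[, 1])
    if (ch$estimate > ch$S_obs) hits <- hits + 1
  }
  expect_gte(hits, 5)   # singletons present in nearly every draw
})

test_that("near-even communities need no richness correction", {
  # k close to 1 concentrates clones on the first ranks: with a tiny
  # pool every taxon is abundant and Chao1 collapses to S_obs
  otus <- gen_otu_counts(n_samples = 1, n_clones_range = c(200, 200),
                         k = 0.9, pool = 3, seed = 2)
  ch <- chao1(otus[, 1])
  expect_equal(ch$estimate, ch$S_obs)
})

test_that("species table round-trips through CSV strictly", {
  p <- gen_species_pool(pool_spec(n_species = 5, seed = 1))
  f <- tempfile(fileext = ".csv")
  write_species_table(p, f)
  p2 <- read_species_table(f)
  expect_equal(as.data.frame(p2), as.data.frame(p), tolerance = 1e-12)
  # strict parsing: negative and missing entries rejected
  bad <- p; bad$mu_max[2] <- -1
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(bad), f2, row.names = FALSE)
  expect_error(read_species_table(f2), "positive")
  utils::write.csv(as.data.frame(p)[, -2], f2, row.names = FALSE)
  expect_error(read_species_table(f2), "lacks")
})

test_that("band matrix and OTU tables round-trip through disk", {
  bm <- gen_band_matrix(gel_spec(seed = 6))
  f <- tempfile(fileext = ".csv")
  write_band_matrix(bm, f)
  bm2 <- read_band_matrix(f)
  expect_equal(bm2$presence, bm$presence)
  expect_equal(bm2$samples, bm$samples)
  otus <- gen_otu_counts(seed = 3)
  f3 <- tempfile(fileext = ".csv")
  write_otu_table(otus, f3)
  expect_equal(unclass(read_otu_table(f3)), unclass(otus), ignore_attr = TRUE)
})
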