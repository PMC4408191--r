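test_that("growth rate is the Liebig minimum of two Monod terms", {
  sp <- one_species(mu_max = 1, K_N = 1, K_O = 0.5)
  # saturation limit
  expect_equal(growth_rate(sp, 1e9, 1e9), 1, tolerance = 1e-6)
  # half-saturation identity: R_N = K_N limits when oxygen saturates
  expect_equal(growth_rate(sp, 1, 1e9), 0.5, tolerance = 1e-6)
  # both terms evaluated by hand: N term 1/(1+1) = 0.5, O term
  # 0.5/(0.5+0.5) = 0.5 -> min is 0.5
  expect_equal(growth_rate(sp, 1, 0.5), 0.5)
  # oxygen term smaller: min picks it
  expect_equal(growth_rate(sp, 1, 0.1), 1 * 0.1 / 0.6)
  expect_error(growth_rate(sp, -1, 1), "non-negative")
})

test_that("growth rate is monotone in each resource and bounded by mu_max", {
  set.seed(41)
  for (i in 1:20) {
    sp <- one_species(mu_max = runif(1, 0.5, 2), K_N = runif(1, 0.1, 5),
                      K_O = runif(1, 0.1, 2))
    r <- sort(runif(2, 0, 10))
    expect_lte(growth_rate(sp, r[1], 3), growth_rate(sp, r[2], 3))
    expect_lte(growth_rate(sp, 3, r[1]), growth_rate(sp, 3, r[2]))
    expect_lt(growth_rate(sp, 1e6, 1e6), sp$mu_max)
  }
})

test_that("R* has its closed form and increases with the loss rate", {
  sp <- one_species(mu_max = 1, K_N = 0.5, K_O = 0.5, m = 0.5)
  expect_equal(r_star(sp, "N"), 0.5)          # m = mu_max/2 -> R* = K
  expect_equal(r_star(sp, "N", m = 0.2), 0.125)
  expect_error(r_star(sp, "N", m = 1.1), "no equilibrium")
  ms <- seq(0.05, 0.9, by = 0.05)
  rs <- vapply(ms, function(m) r_star(sp, "N", m = m), numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("ZNGI corner sits at (R*_N, R*_O) and growth there equals m", {
  sym <- one_species(K_N = 0.7, K_O = 0.7, m = 0.3)
  z <- zngi(sym)
  expect_equal(z$R_N_star, z$R_O_star)        # symmetric corner on 1:1 line
  asym <- one_species(mu_max = 1, K_N = 1, K_O = 0.1, m = 0.5)
  z2 <- zngi(asym)
  expect_equal(c(z2$R_N_star, z2$R_O_star), c(1.0, 0.1))
  expect_equal(growth_rate(asym, z2$R_N_star, 1e9), asym$m)
  expect_equal(growth_rate(asym, z2$R_N_star, z2$R_O_star), asym$m)
})

test_that("chemostat washes out every species when D exceeds mu_max", {
  pool <- stable_pair()
  out <- chemostat_outcome(pool, c(5, 5), D = 1.5, t_end = 2000)
  expect_length(out$survivors, 0)
  expect_equal(unname(out$equilibrium_R), c(5, 5), tolerance = 1e-6)
})

test_that("single ammonia-limited species draws resource down to R*", {
  sp <- one_species(mu_max = 1, K_N = 0.8, K_O = 0.05, m = 0.2)
  out <- chemostat_outcome(sp, c(10, 200), D = 0.2)
  expect_identical(out$survivors, "a")
  expect_equal(unname(out$equilibrium_R["R_N"]), r_star(sp, "N", m = 0.2),
               tolerance = 1e-6)
})

test_that("chemostat steady state closes the mass balance", {
  pool <- stable_pair()
  S <- c(6, 8)
  out <- chemostat_outcome(pool, S, D = 0.2)
  expect_true(out$converged)
  mu <- growth_rate(pool, out$equilibrium_R["R_N"], out$equilibrium_R["R_O"])
  up <- mu * out$biomasses
  expect_equal(0.2 * (S[1] - out$equilibrium_R["R_N"]),
               sum(pool$c_N * up), tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(0.2 * (S[2] - out$equilibrium_R["R_O"]),
               sum(pool$c_O * up), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("competitive exclusion follows the R* rule when one resource limits", {
  # oxygen in excess: only K_N differs, lower R*_N must win
  pool <- species_pool(c("lo", "hi"), mu_max = 1, K_N = c(0.5, 1),
                       K_O = 0.01, m = 0.2, c_N = 7, c_O = 25)
  out <- chemostat_outcome(pool, c(10, 500), D = 0.2)
  expect_identical(out$survivors, "lo")
  # and the outcome does not depend on community order
  out2 <- chemostat_outcome(pool[2:1, ], c(10, 500), D = 0.2)
  expect_identical(sort(out2$survivors), sort(out$survivors))
  expect_equal(out2$equilibrium_R, out$equilibrium_R, tolerance = 1e-6)
})

test_that("coexistence wedge geometry: symmetry, dominance, crossing point", {
  # mirror-image species -> wedge symmetric about the 1:1 supply ray
  mirror <- species_pool(c("p", "q"), mu_max = 1,
                         K_N = c(0.4, 1.2), K_O = c(1.2, 0.4), m = 0.2,
                         c_N = c(5, 12), c_O = c(12, 5))
  w <- coexistence_wedge(mirror[1, ], mirror[2, ])
  expect_true(w$crossing)
  expect_equal(unname(w$point["R_N"]), unname(w$point["R_O"]))
  expect_true(w$stable)
  # classification symmetric under coordinate swap
  s <- supply_point(c(2, 5), c(5, 2))
  cl <- classify_supply(w, s)
  expect_identical(sort(cl), sort(c("p", "q")))
  # strictly nested ZNGIs -> no crossing, dominant reported
  nest <- species_pool(c("win", "lose"), mu_max = 1, K_N = c(0.3, 1),
                       K_O = c(0.1, 0.5), m = 0.2, c_N = 7, c_O = 25)
  w2 <- coexistence_wedge(nest[1, ], nest[2, ])
  expect_false(w2$crossing)
  expect_identical(w2$dominant, "win")
  # identical corners degenerate
  w3 <- coexistence_wedge(mirror[1, ], mirror[1, ])
  expect_false(w3$crossing)
})

test_that("wedge classification matches the chemostat on a supply grid", {
  pool <- stable_pair()
  w <- coexistence_wedge(pool[1, ], pool[2, ])
  expect_true(w$crossing)
  X <- w$point
  grid <- expand.grid(S_N = X["R_N"] * c(2, 6, 18),
                      S_O = X["R_O"] * c(2, 6, 18))
  cl <- classify_supply(w, supply_point(grid$S_N, grid$S_O))
  hits <- 0
  for (i in seq_len(nrow(grid))) {
    out <- chemostat_outcome(pool, c(grid$S_N[i], grid$S_O[i]), D = 0.2)
    pred <- switch(cl[i], none = character(0),
                   coexist = c("ngl", "ogl"), bistable = NA, cl[i])
    if (!anyNA(pred) && identical(sort(out$survivors), sort(pred)))
      hits <- hits + 1
  }
  expect_gte(hits, 8)  # one boundary cell may disagree
})
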