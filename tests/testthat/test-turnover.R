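test_that("beta_sim follows min(b,c)/(min(b,c)+a) with NA for empty sides", {
  expect_equal(beta_sim(5, 0, 0), 0)        # identical communities
  expect_equal(beta_sim(3, 4, 0), 0)        # nested communities
  expect_equal(beta_sim(2, 1, 1), 1 / 3)
  expect_true(is.na(beta_sim(0, 0, 0)))     # both empty
  expect_true(is.na(beta_sim(0, 3, 0)))     # focal empty
  expect_equal(beta_sim(0, 2, 3), 1)        # fully distinct
  expect_error(beta_sim(-1, 0, 0), "non-negative")
  # adding a shared species strictly decreases turnover when min(b,c) > 0
  expect_lt(beta_sim(3, 2, 4), beta_sim(2, 2, 4))
})

test_that("beta_sim matches set arithmetic and vegan on random pairs", {
  set.seed(21)
  pool <- sprintf("sp%02d", 1:30)
  for (i in 1:200) {
    s1 <- sample(pool, rpois(1, 8))
    s2 <- sample(pool, rpois(1, 8))
    c1 <- as.numeric(pool %in% s1)
    c2 <- as.numeric(pool %in% s2)
    expect_identical(beta_sim_pair(c1, c2), beta_sim_oracle(s1, s2))
  }
  skip_if_not_installed("vegan")
  M <- matrix(rbinom(200, 1, 0.5), 10, 20)
  sim <- as.matrix(vegan::betadiver(M, "sim"))
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(beta_sim_pair(M[i, ], M[j, ]), sim[i, j], tolerance = 1e-12)
})

test_that("beta_rao decomposition matches the pooled/within formula", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2)
  # identical communities: pooling adds nothing
  expect_equal(beta_rao_pair(c(1, 1), c(1, 1), D, jost = FALSE), 0)
  expect_equal(beta_rao_pair(c(1, 1), c(1, 1), D, jost = TRUE), 0)
  # two singletons at d = 0.4, raw additive: Qa = 0, Qg = 0.2
  expect_equal(beta_rao_pair(c(1, 0), c(0, 1), D, jost = FALSE), 0.2)
  # symmetry
  expect_equal(beta_rao_pair(c(1, 0), c(0, 1), D),
               beta_rao_pair(c(0, 1), c(1, 0), D))
  expect_true(is.na(beta_rao_pair(c(0, 0), c(1, 1), D)))

  set.seed(31)
  tr <- random_trait_table(12)
  Dr <- gower_dist(tr)
  for (i in 1:100) {
    c1 <- rbinom(12, 1, 0.5); c2 <- rbinom(12, 1, 0.5)
    for (jost in c(TRUE, FALSE)) for (prop in c(TRUE, FALSE)) {
      got <- beta_rao_pair(c1, c2, Dr, jost = jost, proportional = prop)
      want <- beta_rao_oracle(c1, c2, Dr, jost = jost, proportional = prop)
      expect_equal(got, want, tolerance = 1e-12)
    }
    # corrected decomposition is non-negative
    if (sum(c1) && sum(c2))
      expect_gte(beta_rao_pair(c1, c2, Dr, jost = TRUE), -1e-12)
  }
})

test_that("NFN and MFD cross-community dissimilarities behave", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2)
  expect_equal(nfn_pair(c(1, 0), c(1, 0), D), 0)
  expect_equal(mfd_pair(c(1, 0), c(1, 0), D), 0)
  expect_equal(nfn_pair(c(1, 0), c(0, 1), D), 0.4)
  expect_equal(mfd_pair(c(1, 0), c(0, 1), D), 0.4)
  expect_true(is.na(nfn_pair(c(0, 0), c(1, 0), D)))

  set.seed(41)
  tr <- random_trait_table(10)
  Dr <- gower_dist(tr)
  for (i in 1:100) {
    c1 <- rbinom(10, 1, 0.5); c2 <- rbinom(10, 1, 0.5)
    if (!sum(c1) || !sum(c2)) next
    nfn <- nfn_pair(c1, c2, Dr)
    mfd <- mfd_pair(c1, c2, Dr)
    expect_equal(nfn, nfn_oracle(c1, c2, Dr), tolerance = 1e-12)
    expect_equal(mfd, mfd_oracle(c1, c2, Dr), tolerance = 1e-12)
    expect_gte(mfd, nfn - 1e-12)   # nearest <= mean
  }
})

test_that("moving-window fields average pairwise values over neighbours", {
  set.seed(51)
  tr <- random_trait_table(8)
  D <- gower_dist(tr)

  # spatially constant atlas: zero turnover for sim/rao/nfn, and MFD equals
  # the within-community mean pairwise distance
  grid <- make_grid(4)
  M <- matrix(rep(c(1, 1, 0, 1, 0, 0, 1, 1), each = 16), 16,
              dimnames = list(grid$cell_id, rownames(tr$data)))
  atl <- bd_atlas(grid, M, "p1", 10)
  for (meas in c("sim", "rao", "nfn")) {
    f <- neighborhood_turnover(atl, D, meas)
    expect_equal(f$value, rep(0, 16), tolerance = 1e-12)
  }
  fm <- neighborhood_turnover(atl, D, "mfd")
  idx <- which(M[1, ] > 0)
  expect_equal(fm$value, rep(mean(D[idx, idx]), 16), tolerance = 1e-12)

  # 2x2 tiling of four disjoint equal-richness communities: every Moore
  # neighbour pair shares no species (a = 0), so beta_sim == 1 everywhere
  tile <- (grid$easting / 10) %% 2 + 2 * ((grid$northing / 10) %% 2)
  M2 <- sapply(0:3, function(k) as.numeric(tile == k))
  M2 <- cbind(M2, M2)  # two species per community
  colnames(M2) <- sprintf("s%d", 1:8)
  rownames(M2) <- grid$cell_id
  atl2 <- bd_atlas(grid, M2, "p1", 10)
  f2 <- neighborhood_turnover(atl2, measure = "sim")
  expect_equal(f2$value, rep(1, 16))

  # vectorized fields equal per-pair scalar computation on a random atlas
  atl3 <- random_atlas(5, 8, prob = 0.45)
  for (meas in c("sim", "rao", "nfn", "mfd")) {
    f3 <- neighborhood_turnover(atl3, D, meas)
    for (ci in c(1, 7, 13, 25)) {
      nbr <- moore_neighbors(atl3, atl3$grid$cell_id[ci])$neighbors
      vals <- vapply(nbr, function(nb) {
        c1 <- atl3$presence[ci, ]
        c2 <- atl3$presence[nb, ]
        switch(meas, sim = beta_sim_pair(c1, c2),
               rao = beta_rao_pair(c1, c2, D),
               nfn = nfn_pair(c1, c2, D),
               mfd = mfd_pair(c1, c2, D))
      }, numeric(1))
      want <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      expect_equal(f3$value[ci], want, tolerance = 1e-12)
    }
  }

  # a focal square with no species gets NA, not 0
  M4 <- matrix(1, 16, 2, dimnames = list(grid$cell_id, c("s1", "s2")))
  M4[6, ] <- 0
  f4 <- neighborhood_turnover(bd_atlas(grid, M4, "p1", 10), measure = "sim")
  expect_true(is.na(f4$value[6]))
})

test_that("delta fields subtract later minus earlier with NA propagation", {
  grid <- make_grid(3)
  t1 <- as_field(grid, c(0.6, rep(0.5, 7), NA), measure = "sim")
  t2 <- as_field(grid, c(0.4, rep(0.5, 7), 0.3), measure = "sim")
  d <- delta_field(t1, t2)
  expect_equal(d$value[1], -0.2)           # homogenization is negative
  expect_equal(d$value[2:8], rep(0, 7))
  expect_true(is.na(d$value[9]))
  expect_equal(attr(d, "measure"), "delta_sim")
  t3 <- as_field(grid, 1:9, measure = "rao")
  expect_error(delta_field(t1, t3))
})
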