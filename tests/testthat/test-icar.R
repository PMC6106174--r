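# small helper: standardized covariate tables + response field on a grid
make_spec_inputs <- function(g = 6, seed = 1) {
  set.seed(seed)
  grid <- make_grid(g)
  n <- nrow(grid)
  biotic <- data.frame(cell_id = grid$cell_id, SR = rnorm(n),
                       RaoQ = rnorm(n), MBV = rnorm(n))
  climate <- data.frame(cell_id = grid$cell_id,
                        matrix(rnorm(n * 15), n,
                               dimnames = list(NULL,
                                               c("Min.temp", "Drought",
                                                 "GDD", "varT", "varD",
                                                 "varG", "autoT", "autoD",
                                                 "autoG", "LTTT", "LTTD",
                                                 "LTTG", "FtailT", "FtailD",
                                                 "FtailG"))))
  resp <- as_field(grid, rnorm(n))
  list(grid = grid, biotic = biotic, climate = climate, resp = resp)
}

test_that("design matrices match the three covariate-set models", {
  inp <- make_spec_inputs()
  full <- build_design("full", inp$resp, inp$biotic, inp$climate)
  biot <- build_design("biotic", inp$resp, inp$biotic)
  clim <- build_design("climate", inp$resp, climate = inp$climate)
  expect_equal(ncol(full$X), 20)
  expect_equal(ncol(biot$X), 5)
  expect_equal(ncol(clim$X), 17)
  expect_equal(colnames(biot$X), c("Lat", "Long", "SR", "RaoQ", "MBV"))
  # standardization
  expect_true(all(abs(colMeans(full$X)) < 1e-12))
  expect_true(all(abs(apply(full$X, 2, sd) - 1) < 1e-12))
  # constant column is an error
  bad <- inp$biotic
  bad$MBV <- 1
  expect_error(build_design("biotic", inp$resp, bad), "constant covariate")
  # rao_on_sim takes the single taxonomic-change covariate
  ros <- build_design("rao_on_sim", inp$resp,
                      covariate = as_field(inp$grid, rnorm(36)))
  expect_equal(colnames(ros$X), "delta_sim")
})

test_that("ICAR structure is scaled to unit generalized variance", {
  grid <- make_grid(5)
  str <- betadrift:::icar_structure(grid, 10)
  Q <- str$Q
  expect_equal(Q, t(Q))
  expect_equal(unname(rowSums(Q)), rep(0, 25), tolerance = 1e-10)
  # geometric mean of marginal variances (pseudo-inverse diagonal) is 1
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-8
  mv <- rowSums(sweep(eg$vectors[, pos]^2, 2, eg$values[pos], "/"))
  expect_equal(exp(mean(log(mv))), 1, tolerance = 1e-8)
})

test_that("spatial full conditional matches a dense-matrix oracle", {
  set.seed(131)
  grid <- make_grid(7)[1:49, ][1:49 <= 49, ]  # 49 cells (< 50)
  str <- betadrift:::icar_structure(grid, 10)
  r <- rnorm(49)
  for (tp in c(0.5, 2, 10)) for (te in c(0.3, 4)) {
    got <- betadrift:::icar_phi_mean(str$eig, tp, te, r)
    want <- solve(tp * str$Q + te * diag(49), te * r)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # Gaussian deviance against a dnorm oracle
  y <- rnorm(20); mu <- rnorm(20); te <- 2.5
  expect_equal(betadrift:::gaussian_deviance(y, mu, te),
               -2 * sum(dnorm(y, mu, 1 / sqrt(te), log = TRUE)),
               tolerance = 1e-10)
})

test_that("with the spatial term removed the fit matches the conjugate
           Bayesian linear regression", {
  set.seed(141)
  grid <- make_grid(6)
  n <- 36
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  X <- scale(X)
  y <- 0.8 * X[, 1] - 0.4 * X[, 2] + rnorm(n, 0, 0.5)
  resp <- as_field(grid, y)
  biot <- data.frame(cell_id = grid$cell_id, SR = X[, 1], RaoQ = X[, 2],
                     MBV = rnorm(n))
  spec <- build_design("biotic", resp, biot)
  tau_eps <- 4
  fit <- fit_icar(spec, n_iter = 6000, n_burn = 1000, seed = 5,
                  fix_tau_phi = Inf, fix_tau_eps = tau_eps)
  # closed-form posterior: N(A^-1 tau X'y, A^-1), A = tau X'X + 0.001 I
  Xf <- cbind(1, spec$X)
  A <- tau_eps * crossprod(Xf) + 0.001 * diag(ncol(Xf))
  m <- solve(A, tau_eps * crossprod(Xf, spec$y))
  post_sd <- sqrt(diag(solve(A)))
  mc_se <- apply(fit$beta, 2, sd) / sqrt(nrow(fit$beta) / 10)  # autocorr slack
  expect_true(all(abs(colMeans(fit$beta) - as.numeric(m)) <
                    4 * pmax(mc_se, 1e-4)))
  expect_equal(unname(apply(fit$beta, 2, sd)), unname(post_sd),
               tolerance = 0.1)
})

test_that("the sampler is seed-reproducible and DIC behaves", {
  inp <- make_spec_inputs(seed = 9)
  spec <- build_design("biotic", inp$resp, inp$biotic)
  f1 <- suppressWarnings(fit_icar(spec, n_iter = 400, n_burn = 100,
                                  seed = 42))
  f2 <- suppressWarnings(fit_icar(spec, n_iter = 400, n_burn = 100,
                                  seed = 42))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$dic, f2$dic)
  expect_error(dic(f1)["DIC"], NA)
  # pD is positive on a well-identified fit (enough cells that the noise
  # and spatial precisions separate)
  set.seed(4)
  grid10 <- make_grid(10)
  biot10 <- data.frame(cell_id = grid10$cell_id, SR = rnorm(100),
                       RaoQ = rnorm(100), MBV = rnorm(100))
  y <- 0.5 * scale(biot10$SR)[, 1] + rnorm(100, 0, 0.5)
  spec2 <- build_design("biotic", as_field(grid10, y), biot10)
  f3 <- suppressWarnings(fit_icar(spec2, n_iter = 2000, n_burn = 500,
                                  seed = 2))
  expect_gt(f3$pd, 0)
  # model ranking table
  cmp <- compare_models(list(a = f1, b = f3, c = f2))
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$dDIC[1], 0)
  expect_true(all(diff(cmp$DIC) >= 0))
})

test_that("the rao-on-sim regression recovers a planted slope", {
  set.seed(151)
  grid <- make_grid(8)
  n <- 64
  dsim <- rnorm(n, 0, 0.1)
  drao <- 2 * dsim + rnorm(n, 0, 0.02)
  fit <- regress_rao_on_sim(as_field(grid, drao, "delta_rao"),
                            as_field(grid, dsim, "delta_sim"),
                            n_iter = 1500, n_burn = 500, seed = 1)
  # coefficients are on the standardized covariate scale; back-transform
  slope_native <- fit$slope$median / sd(dsim)
  expect_equal(slope_native, 2, tolerance = 0.1)
  expect_true(fit$slope$substantial)
})
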