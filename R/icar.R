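# connected components of an adjacency list (BFS); returns integer labels
graph_components <- function(nb) {
  n <- length(nb)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

# Intrinsic-CAR structure matrix Q = D - W on the Moore graph of a cell
# table, rescaled per connected component so the geometric mean of the
# marginal variances (diagonal of the generalized inverse) equals 1.
# Returns list(Q, comp, eig) with eig the eigendecomposition of the scaled
# matrix, reused by the sampler.
icar_structure <- function(cells, cell_size, scale = TRUE) {
  nb <- neighbor_index(cells, cell_size)
  if (any(lengths(nb) == 0))
    stop("isolated cell in adjacency graph; apply exclusions first")
  n <- nrow(cells)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) Q[i, nb[[i]]] <- -1
  diag(Q) <- lengths(nb)
  comp <- graph_components(nb)
  if (scale) {
    for (k in seq_len(max(comp))) {
      idx <- which(comp == k)
      eg <- eigen(Q[idx, idx], symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      mvar <- rowSums(sweep(eg$vectors[, pos, drop = FALSE]^2, 2,
                            eg$values[pos], "/"))
      gv <- exp(mean(log(mvar)))
      Q[idx, idx] <- Q[idx, idx] * gv
    }
  }
  eig <- eigen(Q, symmetric = TRUE)
  list(Q = Q, comp = comp, eig = eig)
}

# mean of the full conditional of the spatial effects:
# (tau_phi Q + tau_eps I)^{-1} tau_eps r, in the eigenbasis of Q
icar_phi_mean <- function(eig, tau_phi, tau_eps, r) {
  d <- tau_phi * pmax(eig$values, 0) + tau_eps
  as.numeric(eig$vectors %*% ((tau_eps * crossprod(eig$vectors, r)) / d))
}

# Gaussian deviance -2 log L for the observation model y ~ N(mu, 1/tau_eps)
gaussian_deviance <- function(y, mu, tau_eps) {
  n <- length(y)
  n * log(2 * pi) - n * log(tau_eps) + tau_eps * sum((y - mu)^2)
}

#' Build a regression design for one covariate-set model
#'
#' Assembles the response and the covariate columns of one of the three
#' multimodel-inference specifications, plus the single-covariate
#' `rao_on_sim` regression:
#' * `biotic`: Lat, Long, SR, RaoQ, MBV (5 columns);
#' * `climate`: Lat, Long + the 15 climate covariates (17 columns);
#' * `full`: all of the above (20 columns);
#' * `rao_on_sim`: the change in taxonomic turnover only (1 column).
#'
#' Latitude and longitude are the cell northing and easting.  Every
#' covariate column is centred and scaled to unit variance; the response is
#' left on its own scale.  Cells with any missing value are dropped with a
#' message.
#'
#' @param model_id one of `"full"`, `"biotic"`, `"climate"`,
#'   `"rao_on_sim"`.
#' @param response a `bd_field` (typically a change field from
#'   [delta_field()]).
#' @param biotic data.frame from [biotic_covariates()].
#' @param climate data.frame from [climate_covariates()].
#' @param covariate for `rao_on_sim`: the `bd_field` of Delta beta_sim.
#' @return An object of class `bd_modelspec`: list with `y`, `X`
#'   (standardized covariate matrix), `cells` (grid rows used),
#'   `cell_size`, `model_id`.
#' @export
build_design <- function(model_id = c("full", "biotic", "climate",
                                      "rao_on_sim"),
                         response, biotic = NULL, climate = NULL,
                         covariate = NULL) {
  model_id <- match.arg(model_id)
  df <- data.frame(cell_id = response$cell_id,
                   easting = response$easting,
                   northing = response$northing,
                   y = response$value, stringsAsFactors = FALSE)
  df$Lat <- df$northing
  df$Long <- df$easting
  if (model_id == "rao_on_sim") {
    stopifnot(!is.null(covariate),
              identical(covariate$cell_id, response$cell_id))
    df$delta_sim <- covariate$value
    cols <- "delta_sim"
  } else {
    biotic_cols <- c("SR", "RaoQ", "MBV")
    climate_cols <- c("Min.temp", "Drought", "GDD", "varT", "varD", "varG",
                      "autoT", "autoD", "autoG", "LTTT", "LTTD", "LTTG",
                      "FtailT", "FtailD", "FtailG")
    if (model_id %in% c("full", "biotic")) {
      stopifnot(!is.null(biotic))
      df <- merge(df, biotic, by = "cell_id", all.x = TRUE, sort = FALSE)
    }
    if (model_id %in% c("full", "climate")) {
      stopifnot(!is.null(climate))
      df <- merge(df, climate, by = "cell_id", all.x = TRUE, sort = FALSE)
    }
    cols <- switch(model_id,
                   biotic = c("Lat", "Long", biotic_cols),
                   climate = c("Lat", "Long", climate_cols),
                   full = c("Lat", "Long", biotic_cols, climate_cols))
  }
  df <- df[order(match(df$cell_id, response$cell_id)), ]
  keep <- stats::complete.cases(df[c("y", cols)])
  if (!all(keep))
    message(sum(!keep), " cell(s) dropped for missing values")
  df <- df[keep, , drop = FALSE]
  X <- as.matrix(df[cols])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column: ", paste(cols[sds == 0], collapse = ", "))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  cells <- data.frame(cell_id = df$cell_id, easting = df$easting,
                      northing = df$northing, stringsAsFactors = FALSE)
  structure(list(y = df$y, X = X, cells = cells,
                 cell_size = attr(response, "cell_size"),
                 model_id = model_id),
            class = "bd_modelspec")
}

#' Fit an intrinsic-CAR Gaussian regression by Gibbs sampling
#'
#' Model: y = intercept + X beta + phi + eps, with iid Gaussian noise
#' eps ~ N(0, 1/tau_eps) and an intrinsic conditional autoregressive prior
#' on the spatial effects phi over the Moore adjacency graph of the cells.
#' The ICAR structure matrix is rescaled to generalized marginal variance 1
#' (per connected component) and phi is recentred to sum to zero within
#' each component every sweep.  Regression coefficients get independent
#' N(0, 1/0.001) priors; both precisions get Gamma(shape, rate) hyperpriors
#' (default Gamma(1, 0.005)).  All full conditionals are conjugate; the
#' phi update is performed in the eigenbasis of the structure matrix, so
#' one dense eigendecomposition per graph is the only expensive step.
#'
#' @param spec a `bd_modelspec` from [build_design()].
#' @param n_iter total Gibbs sweeps (default 6000).
#' @param n_burn discarded burn-in sweeps (default 1000).
#' @param seed optional RNG seed.
#' @param priors list overriding `beta_prec`, `tau_phi_shape`,
#'   `tau_phi_rate`, `tau_eps_shape`, `tau_eps_rate`.
#' @param fix_tau_phi,fix_tau_eps optionally hold a precision fixed
#'   (useful for limit checks; `fix_tau_phi = Inf` removes the spatial
#'   term entirely).
#' @param thin_phi keep every `thin_phi`-th phi sample (default 10).
#' @return An object of class `bd_icar`: posterior samples (`beta`,
#'   `tau_phi`, `tau_eps`, thinned `phi`), coefficient `summary` (median
#'   and 95% credible interval), `dic`, `pd`, the posterior mean `phi_mean`
#'   and sampler settings.  A split-chain R-hat above 1.1 on any
#'   coefficient triggers a warning.
#' @export
fit_icar <- function(spec, n_iter = 6000, n_burn = 1000, seed = NULL,
                     priors = list(), fix_tau_phi = NULL,
                     fix_tau_eps = NULL, thin_phi = 10L) {
  stopifnot(inherits(spec, "bd_modelspec"), n_iter > n_burn)
  pr <- utils::modifyList(list(beta_prec = 0.001, tau_phi_shape = 1,
                               tau_phi_rate = 0.005, tau_eps_shape = 1,
                               tau_eps_rate = 0.005), priors)
  if (!is.null(seed)) set.seed(seed)
  y <- spec$y
  n <- length(y)
  Xf <- cbind("(Intercept)" = 1, spec$X)
  p <- ncol(Xf)
  str <- icar_structure(spec$cells, spec$cell_size)
  eig <- str$eig
  comp <- str$comp
  ncomp <- max(comp)
  lam <- pmax(eig$values, 0)
  XtX <- crossprod(Xf)
  no_spatial <- identical(fix_tau_phi, Inf)

  beta <- rep(0, p)
  phi <- rep(0, n)
  tau_phi <- if (is.null(fix_tau_phi)) 1 else fix_tau_phi
  tau_eps <- if (is.null(fix_tau_eps)) 1 / stats::var(y) else fix_tau_eps

  n_keep <- n_iter - n_burn
  beta_s <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(Xf)))
  tau_phi_s <- tau_eps_s <- dev_s <- numeric(n_keep)
  phi_keep <- matrix(NA_real_, ceiling(n_keep / thin_phi), n)
  phi_sum <- rep(0, n)

  for (it in seq_len(n_iter)) {
    ## beta | .
    A <- tau_eps * XtX
    diag(A) <- diag(A) + pr$beta_prec
    ch <- chol(A)
    m <- backsolve(ch, backsolve(ch, tau_eps * crossprod(Xf, y - phi),
                                 transpose = TRUE))
    beta <- as.numeric(m + backsolve(ch, stats::rnorm(p)))
    mu_fix <- as.numeric(Xf %*% beta)
    ## phi | .
    if (no_spatial) {
      phi <- rep(0, n)
    } else {
      r <- y - mu_fix
      d <- tau_phi * lam + tau_eps
      z <- (tau_eps * crossprod(eig$vectors, r)) / d +
        stats::rnorm(n) / sqrt(d)
      phi <- as.numeric(eig$vectors %*% z)
      phi <- phi - stats::ave(phi, comp)   # sum-to-zero per component
    }
    ## precisions | .
    if (is.null(fix_tau_phi) && !no_spatial) {
      quad <- as.numeric(crossprod(phi, str$Q %*% phi))
      tau_phi <- stats::rgamma(1, pr$tau_phi_shape + (n - ncomp) / 2,
                               pr$tau_phi_rate + quad / 2)
    }
    resid <- y - mu_fix - phi
    if (is.null(fix_tau_eps)) {
      tau_eps <- stats::rgamma(1, pr$tau_eps_shape + n / 2,
                               pr$tau_eps_rate + sum(resid^2) / 2)
    }
    if (it > n_burn) {
      k <- it - n_burn
      beta_s[k, ] <- beta
      tau_phi_s[k] <- tau_phi
      tau_eps_s[k] <- tau_eps
      dev_s[k] <- gaussian_deviance(y, mu_fix + phi, tau_eps)
      phi_sum <- phi_sum + phi
      if (k %% thin_phi == 1 || thin_phi == 1)
        phi_keep[(k - 1) %/% thin_phi + 1, ] <- phi
    }
  }
  phi_mean <- phi_sum / n_keep
  beta_mean <- colMeans(beta_s)
  dev_bar <- mean(dev_s)
  # plug-in precision on the log scale (the precision posterior is right-
  # skewed; the geometric mean matches the log-gamma parameterization)
  dev_hat <- gaussian_deviance(y, as.numeric(Xf %*% beta_mean) + phi_mean,
                               exp(mean(log(tau_eps_s))))
  pd <- dev_bar - dev_hat
  dic <- dev_bar + pd

  qs <- t(apply(beta_s, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  summary <- data.frame(coef = colnames(Xf), median = qs[, 1],
                        lower = qs[, 2], upper = qs[, 3],
                        row.names = NULL, stringsAsFactors = FALSE)
  rhat <- apply(beta_s, 2, split_rhat)
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("split-chain R-hat > 1.1 for: ",
            paste(colnames(Xf)[rhat > 1.1], collapse = ", "))
  structure(list(beta = beta_s, tau_phi = tau_phi_s, tau_eps = tau_eps_s,
                 phi = phi_keep, phi_mean = phi_mean, summary = summary,
                 dic = dic, pd = pd, deviance = dev_s, rhat = rhat,
                 model_id = spec$model_id, n_iter = n_iter, n_burn = n_burn,
                 seed = seed, priors = pr, comp = comp),
            class = "bd_icar")
}

# simple split-half R-hat for a single chain
split_rhat <- function(x) {
  m <- length(x) %/% 2
  a <- x[seq_len(m)]
  b <- x[(length(x) - m + 1):length(x)]
  W <- (stats::var(a) + stats::var(b)) / 2
  if (W == 0) return(NA_real_)
  B <- m * (mean(a) - mean(b))^2 / 2   # 2 half-chains
  varplus <- (m - 1) / m * W + B / m
  sqrt(varplus / W)
}

#' @export
print.bd_icar <- function(x, ...) {
  cat(sprintf("bd_icar fit (%s): DIC = %.2f, pD = %.1f, %d kept sweeps\n",
              x$model_id, x$dic, x$pd, nrow(x$beta)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Deviance information criterion of a fit
#'
#' DIC = Dbar + pD with pD = Dbar - D(posterior means), deviance from the
#' Gaussian likelihood.
#'
#' @param fit a `bd_icar`.
#' @return named numeric vector `c(DIC, pD)`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bd_icar"))
  if (nrow(fit$beta) < 100) stop("need at least 100 retained samples")
  c(DIC = fit$dic, pD = fit$pd)
}

#' Rank fitted models by DIC
#'
#' @param fits named list of `bd_icar` fits of the same response on the
#'   same cells.
#' @return data.frame sorted by DIC with a `dDIC` column relative to the
#'   best model.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  d <- vapply(fits, function(f) f$dic, numeric(1))
  pd <- vapply(fits, function(f) f$pd, numeric(1))
  out <- data.frame(model = names(fits), DIC = d, pD = pd,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$DIC), ]
  out$dDIC <- out$DIC - out$DIC[1]
  rownames(out) <- NULL
  out
}

#' Regress functional on taxonomic turnover change
#'
#' Single-covariate ICAR fit of Delta beta_rao on Delta beta_sim.  The
#' slope is reported as posterior median with 95% credible interval and
#' flagged `substantial` when the interval excludes zero.
#'
#' @param delta_rao,delta_sim `bd_field` change fields on the same grid.
#' @param ... passed to [fit_icar()].
#' @return the `bd_icar` fit with an extra `slope` element
#'   (median, lower, upper, substantial).
#' @export
regress_rao_on_sim <- function(delta_rao, delta_sim, ...) {
  spec <- build_design("rao_on_sim", response = delta_rao,
                       covariate = delta_sim)
  fit <- fit_icar(spec, ...)
  s <- fit$summary[fit$summary$coef == "delta_sim", ]
  fit$slope <- list(median = s$median, lower = s$lower, upper = s$upper,
                    substantial = s$lower > 0 || s$upper < 0)
  fit
}
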