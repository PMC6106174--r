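# evaluate code under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic study system
#'
#' Collects every tunable of the generator that emulates a two-period
#' gridded breeding atlas with mixed-type traits and 30 years of monthly
#' climate.  Occupancy follows a logistic (Gaussian-niche) response to a
#' smooth latent environmental surface with species optima spread along
#' it; a second period can be homogenized inside a rectangular sub-region
#' by pulling occupancy probabilities toward the local majority state;
#' traits can be coupled to the species optima to create non-null
#' functional structure; climate follows seasonal cycle + linear trend +
#' AR(1) noise with Student-t innovations.
#'
#' @param grid_size cells per side of the square lattice (>= 9; >= 27 so
#'   that both the 30 km and 90 km aggregations retain a workable grid).
#' @param n_species number of species in the pool.
#' @param seed master seed; all generator functions are pure functions of
#'   (config, seed).
#' @param cell_size lattice spacing in km (default 10).
#' @param homog_region rectangle `c(e_min, e_max, n_min, n_max)` in km
#'   within which period 2 is homogenized (NULL = whole grid).
#' @param homog_strength mixing weight in \[0, 1\] toward the neighbourhood
#'   majority state (0 = period 2 identical in law to period 1).
#' @param trait_coupling correlation in \[0, 1\] between coupled trait
#'   values and species environmental optima (0 = traits independent of
#'   ranges, the null-calibration regime).
#' @param trait_spec list of `list(name, kind, coupled, ...)` trait
#'   descriptors; defaults to an 8-trait avian-style set (body mass,
#'   clutch size, age at first breeding, development mode, nesting
#'   behaviour, migration, nest type, diet).
#' @param climate_spec per-attribute list (`tmean`, `tmin`, `precip`) of
#'   `trend` (units/yr), AR(1) coefficient `phi` in (-1, 1), innovation
#'   `sd`, and innovation `df` (Student-t, `Inf` = Gaussian).
#' @param n_years length of the climate record (default 30).
#' @param niche_width niche breadth on the standardized latent surface.
#' @param base_logit logit of occupancy probability at the niche optimum.
#' @return list of class `bd_simconfig`.
#' @export
sim_config <- function(grid_size = 27, n_species = 60, seed = 1,
                       cell_size = 10, homog_region = NULL,
                       homog_strength = 0, trait_coupling = 0,
                       trait_spec = NULL, climate_spec = NULL,
                       n_years = 30, niche_width = 1, base_logit = 2) {
  stopifnot(grid_size >= 9, n_species >= 2,
            homog_strength >= 0, homog_strength <= 1,
            trait_coupling >= 0, trait_coupling <= 1)
  default_climate <- list(
    tmean = list(trend = 0.02, phi = 0.3, sd = 0.6, df = Inf),
    tmin = list(trend = 0.02, phi = 0.3, sd = 0.8, df = Inf),
    precip = list(trend = 0, phi = 0.2, sd = 20, df = Inf))
  climate_spec <- utils::modifyList(default_climate,
                                    if (is.null(climate_spec)) list()
                                    else climate_spec)
  for (a in climate_spec)
    stopifnot(abs(a$phi) < 1, a$sd >= 0, is.infinite(a$df) || a$df > 2)
  if (is.null(trait_spec)) trait_spec <- default_trait_spec()
  structure(list(grid_size = as.integer(grid_size),
                 n_species = as.integer(n_species), seed = as.integer(seed),
                 cell_size = as.integer(cell_size),
                 homog_region = homog_region,
                 homog_strength = homog_strength,
                 trait_coupling = trait_coupling,
                 trait_spec = trait_spec, climate_spec = climate_spec,
                 n_years = as.integer(n_years),
                 niche_width = niche_width, base_logit = base_logit),
            class = "bd_simconfig")
}

default_trait_spec <- function() {
  list(
    list(name = "body_mass", kind = "continuous", meanlog = log(100),
         sdlog = 1, coupled = TRUE, log = TRUE),
    list(name = "clutch_size", kind = "continuous", meanlog = log(4),
         sdlog = 0.4, coupled = TRUE, log = FALSE),
    list(name = "age_first_breeding", kind = "ordinal", levels = 4,
         coupled = TRUE),
    list(name = "development", kind = "categorical",
         levels = c("altricial", "semialtricial", "precocial"),
         coupled = FALSE),
    list(name = "nesting", kind = "categorical",
         levels = c("solitary", "semicolonial", "colonial"),
         coupled = FALSE),
    list(name = "migration", kind = "categorical",
         levels = c("resident", "short_distance", "long_distance"),
         coupled = TRUE),
    list(name = "nest_type", kind = "binary_set",
         labels = c("ground", "hole", "open_arboreal", "closed_arboreal",
                    "ground_closed", "parasite"), p = 0.3, coupled = FALSE),
    list(name = "diet", kind = "binary_set",
         labels = c("seeds", "fruit", "invertebrates", "vertebrates",
                    "carrion", "plants"), p = 0.4, coupled = FALSE))
}

# smooth latent environmental surface + species optima, deterministic in
# cfg$seed (shared by the atlas and trait generators so traits can couple
# to ranges)
sim_latent <- function(cfg) {
  g <- cfg$grid_size
  cs <- cfg$cell_size
  coords <- expand.grid(easting = (0:(g - 1)) * cs,
                        northing = (0:(g - 1)) * cs)
  coords <- coords[order(coords$northing, coords$easting), ]
  xn <- coords$easting / ((g - 1) * cs)
  yn <- coords$northing / ((g - 1) * cs)
  with_seed(cfg$seed, {
    E <- 1.5 * (xn + yn - 1)
    for (j in 1:6) {
      kx <- sample(1:3, 1); ky <- sample(1:3, 1)
      E <- E + stats::rnorm(1, 0, 0.5) *
        cos(2 * pi * (kx * xn + ky * yn) + stats::runif(1, 0, 2 * pi))
    }
    E <- as.numeric(scale(E))
    optima <- seq(min(E), max(E), length.out = cfg$n_species) +
      stats::rnorm(cfg$n_species, 0, 0.1)
    list(coords = coords, E = E, optima = optima)
  })
}

# occupancy probability of every species in every cell
occ_prob <- function(cfg, lat) {
  P <- sapply(seq_len(cfg$n_species), function(k)
    stats::plogis(cfg$base_logit -
                    ((lat$E - lat$optima[k]) / cfg$niche_width)^2))
  colnames(P) <- sprintf("sp%03d", seq_len(cfg$n_species))
  P
}

region_mask <- function(cfg, coords) {
  if (is.null(cfg$homog_region)) return(rep(TRUE, nrow(coords)))
  r <- cfg$homog_region
  stopifnot(length(r) == 4)
  m <- coords$easting >= r[1] & coords$easting <= r[2] &
    coords$northing >= r[3] & coords$northing <= r[4]
  if (!any(m)) stop("homog_region lies outside the grid")
  m
}

#' Simulate a two-period atlas pair
#'
#' Period 1 presences are Bernoulli draws from the logistic-niche
#' occupancy probabilities.  Period 2 uses the same probabilities outside
#' the homogenization region; inside it, each species' probability is
#' mixed (weight `homog_strength`) toward its realized period-1
#' neighbourhood majority state, so locally common species expand and
#' locally rare species contract, which reduces taxonomic turnover there
#' in expectation.
#'
#' @param cfg a [sim_config()].
#' @return list with `atlas1`, `atlas2` (both `bd_atlas`, all-land grid)
#'   and `latent` (surface, optima, occupancy probabilities and the
#'   region mask) for ground-truth checks.
#' @export
simulate_atlas_pair <- function(cfg) {
  lat <- sim_latent(cfg)
  P1 <- occ_prob(cfg, lat)
  mask <- region_mask(cfg, lat$coords)
  n <- nrow(P1)
  grid <- data.frame(cell_id = sprintf("c%d_%d", lat$coords$easting,
                                       lat$coords$northing),
                     easting = lat$coords$easting,
                     northing = lat$coords$northing,
                     land_fraction = 1, stringsAsFactors = FALSE)
  nb <- neighbor_index(grid, cfg$cell_size)
  with_seed(cfg$seed + 1L, {
    M1 <- (matrix(stats::runif(length(P1)), n) < P1) + 0
    dimnames(M1) <- list(grid$cell_id, colnames(P1))
    # neighbourhood occupancy fraction per species, realized period 1
    frac <- matrix(0, n, ncol(M1))
    for (i in seq_len(n)) frac[i, ] <- colMeans(M1[nb[[i]], , drop = FALSE])
    maj <- ifelse(frac >= 0.5, 0.98, 0.02)
    P2 <- P1
    h <- cfg$homog_strength
    P2[mask, ] <- (1 - h) * P1[mask, ] + h * maj[mask, ]
    M2 <- (matrix(stats::runif(length(P2)), n) < P2) + 0
    dimnames(M2) <- dimnames(M1)
  })
  list(atlas1 = bd_atlas(grid, M1, "period1", cfg$cell_size),
       atlas2 = bd_atlas(grid, M2, "period2", cfg$cell_size),
       latent = c(lat, list(P1 = P1, P2 = P2, region = mask)))
}

#' Simulate a mixed-type trait table
#'
#' Continuous traits are lognormal, ordinal traits integer grades,
#' categorical traits have 3-6 levels and multi-label (`binary_set`)
#' traits independent label memberships.  Traits flagged `coupled` in the
#' trait spec draw their latent value with correlation `trait_coupling` to
#' the species' environmental optimum, creating real functional structure
#' along the occupancy gradient; at coupling 0 all traits are independent
#' of the ranges (the null-model calibration regime).
#'
#' @param cfg a [sim_config()].
#' @return a [bd_traits] for the species pool.
#' @export
simulate_traits <- function(cfg) {
  lat <- sim_latent(cfg)
  mu <- as.numeric(scale(lat$optima))
  ns <- cfg$n_species
  rho <- cfg$trait_coupling
  with_seed(cfg$seed + 2L, {
    latent_z <- function(coupled) {
      z <- stats::rnorm(ns)
      if (coupled && rho > 0) rho * mu + sqrt(1 - rho^2) * z else z
    }
    cols <- list()
    types <- character()
    logt <- character()
    for (tr in cfg$trait_spec) {
      z <- latent_z(isTRUE(tr$coupled))
      v <- switch(tr$kind,
        continuous = exp(tr$meanlog + tr$sdlog * z),
        ordinal = {
          br <- stats::qnorm(seq(0, 1, length.out = tr$levels + 1))
          as.integer(cut(z, br, labels = FALSE, include.lowest = TRUE))
        },
        categorical = {
          k <- length(tr$levels)
          br <- stats::qnorm(seq(0, 1, length.out = k + 1))
          tr$levels[cut(z, br, labels = FALSE, include.lowest = TRUE)]
        },
        binary_set = {
          B <- matrix(stats::runif(ns * length(tr$labels)) < tr$p,
                      ns, length(tr$labels))
          # guarantee one label per species
          none <- rowSums(B) == 0
          B[cbind(which(none), sample(length(tr$labels), sum(none),
                                      replace = TRUE))] <- TRUE
          apply(B, 1, function(b) paste(tr$labels[b], collapse = ";"))
        },
        stop("unknown trait kind '", tr$kind, "'"))
      cols[[tr$name]] <- v
      types[tr$name] <- tr$kind
      if (isTRUE(tr$log)) logt <- c(logt, tr$name)
    }
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    rownames(df) <- sprintf("sp%03d", seq_len(ns))
    bd_traits(df, types = types, log_traits = logt)
  })
}

# variance-standardized innovations: Student-t scaled to unit variance,
# Gaussian when df = Inf
rinnov <- function(n, df) {
  if (is.infinite(df)) stats::rnorm(n)
  else stats::rt(n, df) / sqrt(df / (df - 2))
}

#' Simulate monthly climate series for every grid cell
#'
#' Each attribute (monthly mean temperature, mean daily minimum, and
#' precipitation) follows seasonal cycle + linear year trend + AR(1) noise
#' with (optionally heavy-tailed) Student-t innovations, with the baseline
#' varying smoothly across the grid (cooler and wetter northward).
#'
#' @param cfg a [sim_config()] (`n_years >= 5`).
#' @param years calendar years (default `1961:(1960 + n_years)`).
#' @return data.frame with columns `cell_id,year,month,tmin_c,tmean_c,
#'   precip_mm`.
#' @export
simulate_climate <- function(cfg, years = NULL) {
  if (cfg$n_years < 5) stop("n_years must be >= 5")
  if (is.null(years)) years <- 1961:(1960 + cfg$n_years)
  lat <- sim_latent(cfg)
  n <- nrow(lat$coords)
  yn <- lat$coords$northing / max(1, max(lat$coords$northing))
  nT <- length(years) * 12
  month <- rep(1:12, length(years))
  yearv <- rep(years, each = 12)
  seas_t <- -6.5 * cos(2 * pi * (month - 0.5) / 12)
  seas_p <- 20 * cos(2 * pi * (month - 0.5) / 12)
  sp <- cfg$climate_spec
  ar_noise <- function(spec) {
    e <- matrix(rinnov(nT * n, spec$df) * spec$sd, nT, n)
    apply(e, 2, function(x)
      as.numeric(stats::filter(x, spec$phi, method = "recursive")))
  }
  with_seed(cfg$seed + 3L, {
    base_t <- 9 - 3 * yn
    base_p <- 70 + 30 * yn
    tmean <- outer(seas_t + sp$tmean$trend * (yearv - years[1]), rep(1, n)) +
      matrix(base_t, nT, n, byrow = TRUE) + ar_noise(sp$tmean)
    tmin <- tmean - 4 +
      outer((sp$tmin$trend - sp$tmean$trend) * (yearv - years[1]),
            rep(1, n)) + ar_noise(sp$tmin)
    precip <- outer(seas_p + sp$precip$trend * (yearv - years[1]),
                    rep(1, n)) +
      matrix(base_p, nT, n, byrow = TRUE) + ar_noise(sp$precip)
    precip <- pmax(precip, 0)
    cell_id <- sprintf("c%d_%d", lat$coords$easting, lat$coords$northing)
    data.frame(cell_id = rep(cell_id, each = nT),
               year = rep(yearv, n), month = rep(month, n),
               tmin_c = as.numeric(tmin), tmean_c = as.numeric(tmean),
               precip_mm = as.numeric(precip), stringsAsFactors = FALSE)
  })
}
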