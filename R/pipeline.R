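# block label shared by atlas and climate aggregation
block_coords <- function(easting, northing, e0, n0, cell_size, factor) {
  bi <- ((easting - e0) %/% cell_size) %/% factor
  bj <- ((northing - n0) %/% cell_size) %/% factor
  list(easting = e0 + bi * factor * cell_size,
       northing = n0 + bj * factor * cell_size)
}

# average monthly climate over block member cells
aggregate_climate <- function(climate, base_grid, e0, n0, cell_size,
                              factor) {
  i <- match(climate$cell_id, base_grid$cell_id)
  ok <- !is.na(i)
  climate <- climate[ok, , drop = FALSE]
  bc <- block_coords(base_grid$easting[i[ok]], base_grid$northing[i[ok]],
                     e0, n0, cell_size, factor)
  bid <- sprintf("c%d_%d", bc$easting, bc$northing)
  agg <- stats::aggregate(
    climate[c("tmin_c", "tmean_c", "precip_mm")],
    by = list(cell_id = bid, year = climate$year, month = climate$month),
    FUN = mean)
  agg[order(agg$cell_id, agg$year, agg$month), ]
}

#' Run the full homogenization analysis
#'
#' Orchestrates the end-to-end workflow: obtain (or simulate) the
#' two-period atlas, traits and climate; apply exclusions; for each
#' requested focal scale compute the taxonomic and functional turnover
#' fields and their change, run the trait-shuffle null test and classify
#' cells, derive the biotic and climate covariates, fit the three
#' covariate-set ICAR models per response plus the rao-on-sim regression,
#' and rank models by DIC.  Every stage output is written as plain CSV
#' (or JSON) into `out_dir` together with a `manifest.json` recording the
#' seed, configuration and summary numbers, which suffices to reproduce
#' every output exactly.
#'
#' @param config a list or path to a YAML file.  Recognised blocks:
#'   `seed`; `simulate` (arguments of [sim_config()]) or `inputs`
#'   (`atlas`, `period1`, `period2`, `traits`, `climate` CSV paths);
#'   `scales` (subset of `c(10, 30, 90)` in units of the base cell size);
#'   `null` (`n_reps`, `alpha`); `fit` (`enabled`, `n_iter`, `n_burn`,
#'   `models`, `responses`); `jost`, `proportional`, `lat`,
#'   `quantile_type`, `min_land`.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1, scales = c(10, 30, 90),
                   null = list(n_reps = 199, alpha = 0.05),
                   fit = list(enabled = TRUE, n_iter = 2000, n_burn = 500,
                              models = c("full", "biotic", "climate"),
                              responses = c("delta_sim", "delta_rao")),
                   jost = TRUE, proportional = FALSE, lat = 54,
                   quantile_type = 7, min_land = 0.5)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  ## --- stage: data ---------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                cfg$simulate))
    pair <- simulate_atlas_pair(sc)
    a1 <- pair$atlas1; a2 <- pair$atlas2
    traits <- simulate_traits(sc)
    climate <- simulate_climate(sc)
    write_atlas(a1, file.path(out_dir, "atlas_period1.csv"))
    write_atlas(a2, file.path(out_dir, "atlas_period2.csv"))
    tr_out <- cbind(species = traits$species, traits$data)
    utils::write.csv(tr_out, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(climate, file.path(out_dir, "climate.csv"),
                     row.names = FALSE)
    truth <- unclass(sc)
    truth$trait_spec <- NULL
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else if (!is.null(cfg$inputs)) {
    a1 <- read_atlas(cfg$inputs$atlas, cfg$inputs$period1)
    a2 <- read_atlas(cfg$inputs$atlas, cfg$inputs$period2)
    traits <- read_traits(cfg$inputs$traits)
    climate <- read_climate(cfg$inputs$climate)
  } else stop("config must contain a 'simulate' or 'inputs' block")

  base_cs <- a1$cell_size
  e0 <- min(a1$grid$easting); n0 <- min(a1$grid$northing)
  a1 <- apply_exclusions(a1, cfg$min_land)
  a2 <- apply_exclusions(a2, cfg$min_land)
  common <- intersect(a1$grid$cell_id, a2$grid$cell_id)
  a1 <- subset_atlas(a1, common)
  a2 <- subset_atlas(a2, common)
  dmat <- gower_dist(traits)
  manifest <- list(seed = cfg$seed, config = cfg,
                   package_version = as.character(
                     utils::packageVersion("betadrift")),
                   scales = list())

  for (scale_km in cfg$scales) {
    if (scale_km %% base_cs != 0)
      stop("scale ", scale_km, " km is not a multiple of the base cell size")
    factor <- as.integer(scale_km / base_cs)
    if (factor == 1L) {
      s1 <- a1; s2 <- a2
      clim_s <- climate
    } else {
      s1 <- aggregate(a1, factor, min_land = cfg$min_land)
      s2 <- aggregate(a2, factor, min_land = cfg$min_land)
      common <- intersect(s1$grid$cell_id, s2$grid$cell_id)
      s1 <- subset_atlas(s1, common)
      s2 <- subset_atlas(s2, common)
      clim_s <- aggregate_climate(climate, a1$grid, e0, n0, base_cs, factor)
    }
    tag <- sprintf("%dkm", s1$cell_size)
    ms <- manifest$scales[[tag]] <- list(n_cells = nrow(s1$grid))

    ## turnover fields and change
    fields <- list()
    for (meas in c("sim", "rao")) {
      t1 <- neighborhood_turnover(s1, dmat, meas, jost = cfg$jost,
                                  proportional = cfg$proportional)
      t2 <- neighborhood_turnover(s2, dmat, meas, jost = cfg$jost,
                                  proportional = cfg$proportional)
      d <- delta_field(t1, t2)
      fields[[meas]] <- list(t1 = t1, t2 = t2, delta = d)
      utils::write.csv(
        data.frame(site_id = t1$cell_id, easting_km = t1$easting,
                   northing_km = t1$northing, t1 = t1$value,
                   t2 = t2$value, delta = d$value),
        file.path(out_dir, sprintf("turnover_%s_%s.csv", tag, meas)),
        row.names = FALSE)
    }

    ## null test + classification
    nul <- null_delta_distribution(s1, s2, traits,
                                   n_reps = cfg$null$n_reps,
                                   seed = cfg$seed + 17L,
                                   jost = cfg$jost,
                                   proportional = cfg$proportional)
    cls <- classify_cells(fields$sim$delta, fields$rao$delta, nul$p,
                          alpha = cfg$null$alpha)
    utils::write.csv(
      data.frame(site_id = nul$cell_id, observed_delta_rao = nul$observed,
                 p = nul$p, category = as.character(cls$category)),
      file.path(out_dir, sprintf("nulltest_%s.csv", tag)),
      row.names = FALSE)
    utils::write.csv(as.data.frame(cls$counts),
                     file.path(out_dir, sprintf("counts_%s.csv", tag)),
                     row.names = FALSE)
    ms$rejection_fraction <- cls$rejection_fraction

    ## covariates
    biot <- biotic_covariates(s1, dmat)
    clim_cov <- climate_covariates(clim_s, lat = cfg$lat,
                                   quantile_type = cfg$quantile_type)
    utils::write.csv(biot, file.path(out_dir,
                                     sprintf("biotic_covariates_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(clim_cov,
                     file.path(out_dir,
                               sprintf("climate_covariates_%s.csv", tag)),
                     row.names = FALSE)

    ## models
    if (isTRUE(cfg$fit$enabled)) {
      for (resp_name in cfg$fit$responses) {
        resp <- fields[[sub("delta_", "", resp_name)]]$delta
        fits <- list()
        for (mid in cfg$fit$models) {
          spec <- build_design(mid, resp, biotic = biot,
                               climate = clim_cov)
          fits[[mid]] <- fit_icar(spec, n_iter = cfg$fit$n_iter,
                                  n_burn = cfg$fit$n_burn,
                                  seed = cfg$seed + 31L)
          utils::write.csv(
            fits[[mid]]$summary,
            file.path(out_dir, sprintf("coef_%s_%s_%s.csv", tag,
                                       resp_name, mid)),
            row.names = FALSE)
        }
        rank <- compare_models(fits)
        utils::write.csv(rank,
                         file.path(out_dir,
                                   sprintf("dic_ranking_%s_%s.csv", tag,
                                           resp_name)),
                         row.names = FALSE)
        ms[[paste0("dic_best_", resp_name)]] <- rank$model[1]
      }
      rs <- regress_rao_on_sim(fields$rao$delta, fields$sim$delta,
                               n_iter = cfg$fit$n_iter,
                               n_burn = cfg$fit$n_burn,
                               seed = cfg$seed + 43L)
      ms$rao_on_sim <- rs$slope
    }
    manifest$scales[[tag]] <- ms
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

# restrict an atlas to a set of cell ids (kept in grid order)
subset_atlas <- function(atlas, cell_ids) {
  keep <- atlas$grid$cell_id %in% cell_ids
  bd_atlas(atlas$grid[keep, , drop = FALSE],
           atlas$presence[keep, , drop = FALSE],
           atlas$period, atlas$cell_size)
}
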