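#' Occurrence atlas objects
#'
#' A `bd_atlas` bundles a regular grid of survey squares with a binary
#' site-by-species presence matrix for one census period.  Cells are
#' identified by the integer (easting, northing) of their lower-left corner
#' in km; the lattice spacing is `cell_size` km (10 for hectads, 30 or 90
#' after aggregation).
#'
#' @param grid data.frame with columns `cell_id`, `easting`, `northing`
#'   (km, lower-left corner) and `land_fraction` in \[0, 1\].
#' @param presence binary matrix, one row per grid cell (in grid order), one
#'   column per species.
#' @param period character label for the census period.
#' @param cell_size lattice spacing in km.
#' @return An object of class `bd_atlas`: a list with elements `grid`,
#'   `presence`, `species`, `period`, `cell_size`.
#' @export
bd_atlas <- function(grid, presence, period, cell_size) {
  stopifnot(is.data.frame(grid),
            all(c("cell_id", "easting", "northing", "land_fraction") %in%
                  names(grid)))
  if (anyDuplicated(grid$cell_id))
    stop("duplicate cell ids in grid")
  if (anyDuplicated(grid[c("easting", "northing")]))
    stop("duplicate cell coordinates in grid")
  if (any(grid$land_fraction < 0 | grid$land_fraction > 1))
    stop("land_fraction must lie in [0, 1]")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (any((grid$easting - min(grid$easting)) %% cell_size != 0) ||
      any((grid$northing - min(grid$northing)) %% cell_size != 0))
    stop("cell coordinates do not lie on a lattice of spacing cell_size")
  presence <- as.matrix(presence)
  if (nrow(presence) != nrow(grid))
    stop("presence must have one row per grid cell")
  if (!all(presence %in% c(0, 1)))
    stop("presence entries must be 0 or 1")
  if (is.null(colnames(presence)))
    stop("presence must have species column names")
  storage.mode(presence) <- "double"
  rownames(presence) <- grid$cell_id
  structure(list(grid = grid, presence = presence,
                 species = colnames(presence),
                 period = as.character(period),
                 cell_size = as.integer(cell_size)),
            class = "bd_atlas")
}

#' @export
print.bd_atlas <- function(x, ...) {
  cat(sprintf("bd_atlas: %d cells (%d km), %d species, period '%s'\n",
              nrow(x$grid), x$cell_size, length(x$species), x$period))
  invisible(x)
}

# index of the (up to 8) Moore neighbours of every cell: list of integer
# vectors into the grid rows
neighbor_index <- function(grid, cell_size) {
  key <- paste(grid$easting, grid$northing, sep = "_")
  off <- expand.grid(de = c(-1L, 0L, 1L), dn = c(-1L, 0L, 1L))
  off <- off[!(off$de == 0 & off$dn == 0), ]
  nb <- vector("list", nrow(grid))
  hits <- matrix(NA_integer_, nrow(grid), nrow(off))
  for (k in seq_len(nrow(off))) {
    kk <- paste(grid$easting + off$de[k] * cell_size,
                grid$northing + off$dn[k] * cell_size, sep = "_")
    hits[, k] <- match(kk, key)
  }
  for (i in seq_len(nrow(grid))) {
    h <- hits[i, ]
    nb[[i]] <- h[!is.na(h)]
  }
  names(nb) <- grid$cell_id
  nb
}

#' Moore neighbourhood of a grid cell
#'
#' Returns the surviving cells among the eight lattice-adjacent positions
#' (orthogonal and diagonal) around a focal cell.
#'
#' @param atlas a `bd_atlas`.
#' @param cell a cell id present in the atlas grid.
#' @return list with elements `focal` (the cell id) and `neighbors`
#'   (character vector of adjacent cell ids, possibly empty).
#' @export
moore_neighbors <- function(atlas, cell) {
  i <- match(cell, atlas$grid$cell_id)
  if (is.na(i)) stop("cell '", cell, "' not in grid")
  nb <- neighbor_index(atlas$grid, atlas$cell_size)[[i]]
  list(focal = cell, neighbors = atlas$grid$cell_id[nb])
}

#' Apply land and isolation exclusions
#'
#' Removes cells with less than `min_land` land cover, then repeatedly
#' removes cells left without any Moore neighbour until no further cell is
#' orphaned (fixed point).  The land rule is a strict `<`, so a cell with
#' exactly 50% land is retained under the default.
#'
#' @param atlas a `bd_atlas`.
#' @param min_land minimum land fraction retained (default 0.5).
#' @return the filtered `bd_atlas`.
#' @export
apply_exclusions <- function(atlas, min_land = 0.5) {
  keep <- atlas$grid$land_fraction >= min_land
  grid <- atlas$grid[keep, , drop = FALSE]
  pres <- atlas$presence[keep, , drop = FALSE]
  repeat {
    if (nrow(grid) == 0) stop("all cells excluded")
    nb <- neighbor_index(grid, atlas$cell_size)
    orphan <- lengths(nb) == 0
    if (!any(orphan)) break
    grid <- grid[!orphan, , drop = FALSE]
    pres <- pres[!orphan, , drop = FALSE]
  }
  if (nrow(grid) == 0) stop("all cells excluded")
  bd_atlas(grid, pres, atlas$period, atlas$cell_size)
}

#' Aggregate an atlas to a coarser focal-square size
#'
#' Groups cells into non-overlapping `factor` x `factor` blocks anchored at
#' the minimum easting/northing.  Block presence is the union (logical OR)
#' of member-cell presences; block land fraction is the mean over the full
#' block (members missing from the grid count as 0 land).  Exclusions are
#' re-applied at the new scale, so partial coastal blocks survive exactly
#' when their mean land fraction passes `min_land`.
#'
#' @param x a `bd_atlas`.
#' @param factor block edge length in cells: 3 (10 -> 30 km) or 9
#'   (10 -> 90 km).
#' @param min_land passed on to [apply_exclusions()].
#' @param ... ignored.
#' @return the aggregated `bd_atlas` with `cell_size * factor` spacing.
#' @export
aggregate.bd_atlas <- function(x, factor, min_land = 0.5, ...) {
  if (!factor %in% c(3L, 9L)) stop("factor must be 3 or 9")
  cs <- x$cell_size
  e0 <- min(x$grid$easting)
  n0 <- min(x$grid$northing)
  bi <- ((x$grid$easting - e0) %/% cs) %/% factor
  bj <- ((x$grid$northing - n0) %/% cs) %/% factor
  blk <- paste(bi, bj, sep = "_")
  ub <- unique(blk)
  m <- match(blk, ub)
  pres <- rowsum(x$presence, m, reorder = TRUE)
  pres <- (pres > 0) + 0
  land <- as.vector(rowsum(x$grid$land_fraction, m, reorder = TRUE)) / factor^2
  # rowsum(reorder = TRUE) sorts groups by the numeric index m, i.e. by
  # first appearance in ub; re-sort everything into (northing, easting) order
  ei <- as.integer(sub("_.*", "", ub))
  ni <- as.integer(sub(".*_", "", ub))
  o <- order(ni, ei)
  pres <- pres[o, , drop = FALSE]
  land <- land[o]
  grid <- data.frame(cell_id = sprintf("c%d_%d", e0 + ei[o] * factor * cs,
                                       n0 + ni[o] * factor * cs),
                     easting = e0 + ei[o] * factor * cs,
                     northing = n0 + ni[o] * factor * cs,
                     land_fraction = land,
                     stringsAsFactors = FALSE)
  out <- bd_atlas(grid, pres, x$period, cs * factor)
  apply_exclusions(out, min_land = min_land)
}

#' Read an occurrence atlas from CSV
#'
#' Accepts either a long table (`site_id,easting_km,northing_km,
#' land_fraction,species[,period][,presence]`, one row per occurrence) or a
#' wide site-by-species matrix (`site_id,easting_km,northing_km,
#' land_fraction` followed by one 0/1 column per species).  The dialect is
#' detected from the header.  Duplicate (site, species) records collapse to
#' a single presence with a warning; non-binary presence values and
#' duplicated site coordinates are hard errors naming the offending row.
#'
#' @param path CSV file.
#' @param period period label; in long format with a `period` column, rows
#'   of other periods are ignored (sites and the species pool are shared
#'   across periods so that paired atlases stay conformable).
#' @param cell_size lattice spacing in km (default 10).
#' @return a `bd_atlas`.
#' @export
read_atlas <- function(path, period, cell_size = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  base_cols <- c("site_id", "easting_km", "northing_km", "land_fraction")
  if (!all(base_cols %in% names(df)))
    stop("atlas CSV must contain columns ", paste(base_cols, collapse = ", "))
  long <- "species" %in% names(df)
  sites <- unique(df[base_cols])
  dup <- duplicated(sites[c("easting_km", "northing_km")])
  if (any(dup)) {
    bad <- which(paste(df$easting_km, df$northing_km) %in%
                   paste(sites$easting_km[dup], sites$northing_km[dup]))[1]
    stop("duplicate site coordinates (CSV row ", bad + 1, ")")
  }
  sites <- sites[order(sites$northing_km, sites$easting_km), ]
  grid <- data.frame(cell_id = sites$site_id,
                     easting = sites$easting_km,
                     northing = sites$northing_km,
                     land_fraction = sites$land_fraction,
                     stringsAsFactors = FALSE)
  if (long) {
    species <- sort(unique(df$species))
    if ("period" %in% names(df)) {
      if (!period %in% df$period)
        stop("unknown period label '", period, "'")
      rows <- df[df$period == period, , drop = FALSE]
    } else rows <- df
    if ("presence" %in% names(df)) {
      bad <- which(!rows$presence %in% c(0, 1))
      if (length(bad))
        stop("non-binary presence value (CSV row ",
             as.integer(rownames(rows)[bad[1]]) + 1, ")")
      rows <- rows[rows$presence == 1, , drop = FALSE]
    }
    key <- paste(rows$site_id, rows$species)
    if (anyDuplicated(key)) {
      warning("duplicate (site, species) records collapsed")
      rows <- rows[!duplicated(key), , drop = FALSE]
    }
    pres <- matrix(0, nrow(grid), length(species),
                   dimnames = list(grid$cell_id, species))
    pres[cbind(match(rows$site_id, grid$cell_id),
               match(rows$species, species))] <- 1
  } else {
    spcols <- setdiff(names(df), base_cols)
    if (!length(spcols)) stop("no species columns found")
    vals <- as.matrix(df[spcols])
    bad <- which(!vals %in% c(0, 1))
    if (length(bad))
      stop("non-binary presence value (CSV row ",
           (bad[1] - 1) %% nrow(df) + 2, ")")
    pres <- vals[match(grid$cell_id, df$site_id), sort(spcols), drop = FALSE]
    rownames(pres) <- grid$cell_id
  }
  bd_atlas(grid, pres, period, cell_size)
}

#' Write an atlas as a wide site-by-species CSV
#'
#' @param atlas a `bd_atlas`.
#' @param path output file.
#' @export
write_atlas <- function(atlas, path) {
  out <- data.frame(site_id = atlas$grid$cell_id,
                    easting_km = atlas$grid$easting,
                    northing_km = atlas$grid$northing,
                    land_fraction = atlas$grid$land_fraction,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(atlas$presence, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
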