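#' Per-cell species richness and functional alpha diversity
#'
#' Richness is the presence row sum; functional diversity is Rao's
#' quadratic entropy of the cell community (NA for an empty cell).  Both
#' are intended as covariates from the *earlier* census period.
#'
#' @param atlas a `bd_atlas`.
#' @param cell optional cell id; when NULL a vector over all cells is
#'   returned.
#' @return integer richness / numeric Rao Q, per cell.
#' @export
richness <- function(atlas, cell = NULL) {
  r <- rowSums(atlas$presence)
  if (is.null(cell)) return(r)
  i <- match(cell, atlas$grid$cell_id)
  if (is.na(i)) stop("cell '", cell, "' not in grid")
  r[[i]]
}

#' @rdname richness
#' @param dmat functional distance matrix matching the atlas species.
#' @export
rao_alpha <- function(atlas, cell = NULL, dmat) {
  dmat <- dmat[atlas$species, atlas$species]
  q <- apply(atlas$presence, 1, function(x)
    if (sum(x) == 0) NA_real_ else rao_q(x, dmat))
  if (is.null(cell)) return(q)
  i <- match(cell, atlas$grid$cell_id)
  if (is.na(i)) stop("cell '", cell, "' not in grid")
  q[[i]]
}

#' Mean binomial variance of local occupancy
#'
#' For each focal cell, considers every species present in the focal cell
#' or its surviving Moore neighbours and computes the binomial variance
#' n * p * q of its local occupancy, where n is the number of surrounding
#' window cells, p the fraction of those occupied and q = 1 - p.  The mean
#' over those species is returned.  The statistic peaks (n / 4 per
#' species) when occupancy fractions sit at 1/2 and vanishes when all
#' local species are ubiquitous or absent from the surroundings.
#'
#' By default (`include_focal = FALSE`) the focal cell contributes to
#' species membership but not to the occupancy fraction, which is computed
#' over the surrounding cells only; `include_focal = TRUE` counts the focal
#' cell in the window as well.
#'
#' @param atlas a post-exclusion `bd_atlas` at the working focal scale.
#' @param include_focal whether the focal cell enters the occupancy
#'   fraction.
#' @return numeric vector, one value per cell (NA where the window holds
#'   no species or no surviving neighbours).
#' @export
mean_binomial_variance <- function(atlas, include_focal = FALSE) {
  M <- atlas$presence
  nb <- neighbor_index(atlas$grid, atlas$cell_size)
  out <- rep(NA_real_, nrow(M))
  for (i in seq_len(nrow(M))) {
    w <- nb[[i]]
    if (!length(w)) next
    members <- colSums(M[c(i, w), , drop = FALSE]) > 0
    if (!any(members)) next
    if (include_focal) {
      n <- length(w) + 1L
      k <- colSums(M[c(i, w), members, drop = FALSE])
    } else {
      n <- length(w)
      k <- colSums(M[w, members, drop = FALSE])
    }
    p <- k / n
    out[i] <- mean(n * p * (1 - p))
  }
  names(out) <- atlas$grid$cell_id
  out
}

#' Biotic covariate table
#'
#' Combines earlier-period species richness (`SR`), earlier-period Rao Q
#' (`RaoQ`) and the mean binomial variance of local occupancy (`MBV`) into
#' one row per cell.
#'
#' @param atlas_early the earlier-period post-exclusion atlas.
#' @param dmat functional distance matrix.
#' @inheritParams mean_binomial_variance
#' @return data.frame with columns `cell_id`, `SR`, `RaoQ`, `MBV`.
#' @export
biotic_covariates <- function(atlas_early, dmat, include_focal = FALSE) {
  data.frame(cell_id = atlas_early$grid$cell_id,
             SR = richness(atlas_early),
             RaoQ = rao_alpha(atlas_early, dmat = dmat),
             MBV = mean_binomial_variance(atlas_early, include_focal),
             stringsAsFactors = FALSE, row.names = NULL)
}
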