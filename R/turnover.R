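#' Simpson-based taxonomic turnover
#'
#' beta_sim = min(b, c) / (min(b, c) + a), where a is the number of shared
#' species, b the number found only in the neighbouring community and c the
#' number found only in the focal community.  Insensitive to richness
#' gradients: nested communities (min(b, c) = 0 with a > 0) score 0.  When
#' one (or both) community is empty (a = 0 and min(b, c) = 0) the measure
#' is undefined and NA is returned.
#'
#' @param a,b,c non-negative integer counts; vectorized.
#' @return turnover in \[0, 1\], or NA.
#' @export
beta_sim <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0)) stop("counts must be non-negative")
  m <- pmin(b, c)
  out <- m / (m + a)
  out[a == 0 & m == 0] <- NA_real_
  out
}

# shared / only-in-2 / only-in-1 counts from two binary vectors
community_pair <- function(comm1, comm2) {
  p1 <- comm1 > 0
  p2 <- comm2 > 0
  c(a = sum(p1 & p2), b = sum(!p1 & p2), c = sum(p1 & !p2))
}

#' @rdname beta_sim
#' @param comm1,comm2 binary species vectors on a common species order
#'   (`comm1` is the focal community).
#' @export
beta_sim_pair <- function(comm1, comm2) {
  n <- community_pair(comm1, comm2)
  beta_sim(n[["a"]], n[["b"]], n[["c"]])
}

# equivalent-numbers (Jost) transform of a Rao Q value
rao_eqnum <- function(q) {
  if (any(q >= 1)) stop("Rao Q >= 1: distances must lie in [0, 1]")
  1 / (1 - q)
}

#' Rao quadratic entropy decomposition of functional turnover
#'
#' The gain in functional diversity when two communities are pooled:
#' beta_rao = Q_gamma - mean(Q_alpha), where Q_gamma is the Rao Q of the
#' pooled community with each community contributing weight 1/2 and
#' Q_alpha are the within-community values.  With `jost = TRUE` (default)
#' all Q values are first transformed to equivalent numbers, 1 / (1 - Q),
#' which guarantees a non-negative decomposition; `jost = FALSE` gives the
#' raw additive variant.  `proportional = TRUE` divides by the (transformed)
#' gamma value.
#'
#' @param comm1,comm2 binary species vectors aligned with `dmat`.
#' @param dmat functional distance matrix with entries in \[0, 1\].
#' @param jost apply the equivalent-numbers correction (default TRUE).
#' @param proportional return (gamma - alpha) / gamma instead of the
#'   additive difference.
#' @return functional turnover (NA if either community is empty).
#' @export
beta_rao_pair <- function(comm1, comm2, dmat, jost = TRUE,
                          proportional = FALSE) {
  s1 <- sum(comm1 > 0)
  s2 <- sum(comm2 > 0)
  if (s1 == 0 || s2 == 0) return(NA_real_)
  qa1 <- rao_q(comm1, dmat)
  qa2 <- rao_q(comm2, dmat)
  w <- (comm1 > 0) / (2 * s1) + (comm2 > 0) / (2 * s2)
  qg <- as.numeric(w %*% dmat %*% w)
  if (jost) {
    qa1 <- rao_eqnum(qa1); qa2 <- rao_eqnum(qa2); qg <- rao_eqnum(qg)
  }
  beta <- qg - (qa1 + qa2) / 2
  if (proportional) beta <- beta / qg
  beta
}

#' Nearest functional neighbour and mean functional dissimilarity
#'
#' Cross-community functional dissimilarities between two presence
#' communities: `mfd_pair` is the mean Gower distance over all
#' cross-community species pairs; `nfn_pair` averages, over the species of
#' each community, the distance to the functionally closest species of the
#' opposite community (mean of the two directional means).
#'
#' @inheritParams beta_rao_pair
#' @return dissimilarity (NA if either community is empty).
#' @export
nfn_pair <- function(comm1, comm2, dmat) {
  i <- which(comm1 > 0)
  j <- which(comm2 > 0)
  if (!length(i) || !length(j)) return(NA_real_)
  sub <- dmat[i, j, drop = FALSE]
  (mean(apply(sub, 1, min)) + mean(apply(sub, 2, min))) / 2
}

#' @rdname nfn_pair
#' @export
mfd_pair <- function(comm1, comm2, dmat) {
  i <- which(comm1 > 0)
  j <- which(comm2 > 0)
  if (!length(i) || !length(j)) return(NA_real_)
  mean(dmat[i, j])
}

# ordered (focal, neighbour) index pairs of an atlas grid
atlas_pairs <- function(atlas) {
  nb <- neighbor_index(atlas$grid, atlas$cell_size)
  f <- rep(seq_along(nb), lengths(nb))
  g <- unlist(nb, use.names = FALSE)
  list(f = f, g = g)
}

# per-pair measure values, vectorized over all (focal, neighbour) pairs.
# Empty communities on either side give NA for the pair.
pair_values <- function(M, S, pairs, measure, dmat = NULL, jost = TRUE,
                        proportional = FALSE) {
  f <- pairs$f; g <- pairs$g
  empty <- S[f] == 0 | S[g] == 0
  if (measure == "sim") {
    a <- rowSums(M[f, , drop = FALSE] * M[g, , drop = FALSE])
    b <- S[g] - a
    cc <- S[f] - a
    val <- beta_sim(a, b, cc)
  } else if (measure %in% c("rao", "mfd")) {
    MD <- M %*% dmat
    cross <- rowSums(MD[f, , drop = FALSE] * M[g, , drop = FALSE])
    if (measure == "mfd") {
      val <- cross / (S[f] * S[g])
    } else {
      qa <- rowSums(MD * M) / S^2   # NaN for empty cells, masked below
      qg <- qa[f] / 4 + qa[g] / 4 + cross / (2 * S[f] * S[g])
      if (jost) {
        qa <- 1 / (1 - qa)
        qg <- 1 / (1 - qg)
      }
      val <- qg - (qa[f] + qa[g]) / 2
      if (proportional) val <- val / qg
    }
  } else if (measure == "nfn") {
    val <- numeric(length(f))
    for (k in seq_along(f)) {
      val[k] <- if (empty[k]) NA_real_ else
        nfn_pair(M[f[k], ], M[g[k], ], dmat)
    }
  } else stop("unknown measure '", measure, "'")
  val[empty] <- NA_real_
  val
}

#' Neighbourhood turnover field via a moving window
#'
#' For every focal cell, computes the pairwise turnover against each of its
#' surviving Moore neighbours and averages over the available pairs (this
#' accommodates coastal cells with fewer than 8 neighbours).  Pairs where
#' either community is empty are dropped from the mean; a cell with no
#' valid pair gets NA.
#'
#' @param atlas a post-exclusion `bd_atlas`.
#' @param dmat functional distance matrix (required for measures other than
#'   `"sim"`), with species matching the atlas.
#' @param measure one of `"sim"`, `"rao"`, `"nfn"`, `"mfd"`.
#' @inheritParams beta_rao_pair
#' @return a `bd_field`: data.frame with columns `cell_id`, `easting`,
#'   `northing`, `value`, and attributes `measure`, `period`, `cell_size`.
#' @export
neighborhood_turnover <- function(atlas, dmat = NULL,
                                  measure = c("sim", "rao", "nfn", "mfd"),
                                  jost = TRUE, proportional = FALSE) {
  measure <- match.arg(measure)
  if (measure != "sim") {
    stopifnot(!is.null(dmat))
    dmat <- dmat[atlas$species, atlas$species]
  }
  M <- atlas$presence
  S <- rowSums(M)
  pairs <- atlas_pairs(atlas)
  val <- pair_values(M, S, pairs, measure, dmat, jost, proportional)
  agg <- tapply(val, factor(pairs$f, levels = seq_len(nrow(M))),
                function(v) if (all(is.na(v))) NA_real_ else
                  mean(v, na.rm = TRUE))
  out <- data.frame(cell_id = atlas$grid$cell_id,
                    easting = atlas$grid$easting,
                    northing = atlas$grid$northing,
                    value = as.numeric(agg),
                    stringsAsFactors = FALSE)
  structure(out, measure = measure, period = atlas$period,
            cell_size = atlas$cell_size,
            class = c("bd_field", "data.frame"))
}

#' Change in turnover between two periods
#'
#' Cellwise difference `period2 - period1` of two turnover fields on the
#' same grid and measure.  Negative values indicate homogenization
#' (reduced spatial turnover over time); NA propagates.
#'
#' @param t1,t2 `bd_field` objects from [neighborhood_turnover()] for the
#'   earlier and later period.
#' @return a `bd_field` whose `value` is the change, with attribute
#'   `measure` prefixed `"delta_"`.
#' @export
delta_field <- function(t1, t2) {
  stopifnot(identical(t1$cell_id, t2$cell_id),
            identical(attr(t1, "measure"), attr(t2, "measure")))
  out <- t1
  out$value <- t2$value - t1$value
  attr(out, "measure") <- paste0("delta_", attr(t1, "measure"))
  attr(out, "period") <- paste(attr(t1, "period"), attr(t2, "period"),
                               sep = " -> ")
  out
}
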