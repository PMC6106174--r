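#' Shuffle species labels over intact trait rows
#'
#' The constrained trait-level randomization: species names are permuted
#' against whole trait rows, so every row travels together and the trait
#' ranges and covariances of the table are preserved verbatim, while the
#' occurrence data (and hence richness, taxonomic turnover and the spatial
#' structure of distributions) are untouched.
#'
#' @param traits a [bd_traits] object.
#' @return a `bd_traits` with the same species in the same order, each now
#'   carrying the trait row of a randomly chosen species.
#' @export
shuffle_traits <- function(traits) {
  perm <- sample(length(traits$species))
  data <- traits$data[perm, , drop = FALSE]
  rownames(data) <- traits$species
  bd_traits(data, types = traits$types, log_traits = traits$log_traits)
}

#' Two-tailed permutation p-value
#'
#' Rank-based p with the (r + 1) / (n + 1) convention (never exactly 0) and
#' ties counted inclusively on both tails:
#' p = min(1, 2 * min(#\{null <= obs\} + 1, #\{null >= obs\} + 1) / (n + 1)).
#'
#' @param observed observed statistic (NA gives NA).
#' @param null vector of null statistics.
#' @return p-value in (0, 1\].
#' @export
two_tailed_p <- function(observed, null) {
  if (is.na(observed)) return(NA_real_)
  null <- null[!is.na(null)]
  if (!length(null)) stop("empty null distribution")
  r_low <- sum(null <= observed)
  r_high <- sum(null >= observed)
  min(1, 2 * min(r_low + 1, r_high + 1) / (length(null) + 1))
}

#' Null distribution of the change in functional turnover
#'
#' Builds the trait-shuffle null for Delta beta_rao: for each replicate one
#' species-label permutation is drawn and used for BOTH periods, the
#' neighbourhood beta_rao fields are recomputed, and their change is
#' recorded.  Internally a permutation of the trait rows is applied as the
#' corresponding symmetric permutation of the fixed Gower matrix, which is
#' algebraically identical and avoids recomputing distances.
#'
#' @param atlas1,atlas2 post-exclusion atlases on a common grid and species
#'   list (earlier and later period).
#' @param traits a [bd_traits] covering the atlas species.
#' @param n_reps number of shuffles (default 999).
#' @param seed optional RNG seed for reproducible shuffles.
#' @inheritParams beta_rao_pair
#' @return An object of class `bd_null`: list with `cell_id`, `grid`,
#'   `observed` (Delta beta_rao per cell), `null_deltas` (n_reps x n_cells),
#'   `p` (two-tailed per cell), `n_reps`, `seed`.
#' @export
null_delta_distribution <- function(atlas1, atlas2, traits, n_reps = 999,
                                    seed = NULL, jost = TRUE,
                                    proportional = FALSE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  stopifnot(identical(atlas1$grid$cell_id, atlas2$grid$cell_id),
            identical(atlas1$species, atlas2$species))
  D <- gower_dist(traits)[atlas1$species, atlas1$species]
  M1 <- atlas1$presence; S1 <- rowSums(M1)
  M2 <- atlas2$presence; S2 <- rowSums(M2)
  pairs <- atlas_pairs(atlas1)
  nlev <- factor(pairs$f, levels = seq_len(nrow(M1)))
  field <- function(M, S, Dm) {
    v <- pair_values(M, S, pairs, "rao", Dm, jost, proportional)
    as.numeric(tapply(v, nlev, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)))
  }
  observed <- field(M2, S2, D) - field(M1, S1, D)
  if (!is.null(seed)) set.seed(seed)
  ns <- length(atlas1$species)
  null_deltas <- matrix(NA_real_, n_reps, nrow(M1))
  for (r in seq_len(n_reps)) {
    perm <- sample(ns)
    Dp <- D[perm, perm]
    null_deltas[r, ] <- field(M2, S2, Dp) - field(M1, S1, Dp)
  }
  p <- vapply(seq_along(observed), function(i)
    two_tailed_p(observed[i], null_deltas[, i]), numeric(1))
  structure(list(cell_id = atlas1$grid$cell_id, grid = atlas1$grid,
                 observed = observed, null_deltas = null_deltas, p = p,
                 n_reps = n_reps, seed = seed),
            class = "bd_null")
}

#' @export
print.bd_null <- function(x, ...) {
  cat(sprintf(
    "bd_null: %d cells, %d shuffles; rejection at alpha=0.05: %.1f%%\n",
    length(x$cell_id), x$n_reps, 100 * mean(x$p < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Classify cells by homogenization outcome
#'
#' Cells where the trait-shuffle null is rejected (p < alpha) are labelled
#' by the sign pair of the taxonomic and functional changes:
#' Delta beta_sim < 0 is taxonomic homogenization (>= 0 differentiation),
#' Delta beta_rao < 0 functional homogenization (> 0 differentiation;
#' exactly 0 with a rejected null is degenerate and yields NA with a
#' warning).  Non-rejected cells are `null-consistent`.
#'
#' @param delta_sim,delta_rao `bd_field` objects (changes) on the same grid.
#' @param p per-cell two-tailed p-values (e.g. from
#'   [null_delta_distribution()]).
#' @param alpha significance level (default 0.05).
#' @return list with `category` (factor per cell), `counts` (2 x 2 table of
#'   rejected cells), and `rejection_fraction`.
#' @export
classify_cells <- function(delta_sim, delta_rao, p, alpha = 0.05) {
  stopifnot(identical(delta_sim$cell_id, delta_rao$cell_id),
            length(p) == nrow(delta_sim))
  tax <- ifelse(delta_sim$value < 0, "taxonomic homogenization",
                "taxonomic differentiation")
  fun <- ifelse(delta_rao$value < 0, "functional homogenization",
                ifelse(delta_rao$value > 0, "functional differentiation",
                       NA_character_))
  cat_lab <- rep(NA_character_, length(p))
  rejected <- !is.na(p) & p < alpha
  cat_lab[!is.na(p) & !rejected] <- "null-consistent"
  if (any(rejected & is.na(fun) & !is.na(delta_rao$value)))
    warning("rejected cell with Delta beta_rao exactly 0: category NA")
  ok <- rejected & !is.na(tax) & !is.na(fun)
  cat_lab[ok] <- paste(tax[ok], "+", fun[ok])
  levs <- c(outer(c("taxonomic homogenization", "taxonomic differentiation"),
                  c("functional homogenization", "functional differentiation"),
                  paste, sep = " + "))
  category <- factor(cat_lab, levels = c(sort(levs), "null-consistent"))
  counts <- table(
    factor(tax[ok], c("taxonomic homogenization",
                      "taxonomic differentiation")),
    factor(fun[ok], c("functional homogenization",
                      "functional differentiation")))
  names(dimnames(counts)) <- NULL
  list(category = category, counts = counts,
       rejection_fraction = mean(p[!is.na(p)] < alpha))
}
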