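#' Species trait tables with mixed variable types
#'
#' Wraps a species-by-trait data.frame together with the declared type of
#' each trait.  Supported kinds: `continuous`, `ordinal` (rank-scaled and
#' then treated as continuous), `categorical` (0/1 mismatch) and
#' `binary_set` (multi-label memberships such as diet categories, stored as
#' semicolon-delimited strings and compared by Jaccard mismatch).
#'
#' @param data data.frame with species as rownames (or a `species` column)
#'   and one column per trait; no missing values.
#' @param types named character vector giving the kind of every trait
#'   column; inferred when `NULL` (numeric -> continuous, ordered factor ->
#'   ordinal, strings containing ";" -> binary_set, otherwise categorical).
#' @param log_traits names of positive continuous traits (body-mass-like)
#'   to log-transform before range scaling.
#' @return An object of class `bd_traits`.
#' @export
bd_traits <- function(data, types = NULL, log_traits = character()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if ("species" %in% names(data)) {
    rownames(data) <- data$species
    data$species <- NULL
  }
  if (is.null(rownames(data)) || anyDuplicated(rownames(data)))
    stop("trait table needs unique species rownames (or a species column)")
  if (anyNA(data)) stop("trait table contains missing values")
  if (is.null(types)) {
    types <- vapply(data, function(x) {
      if (is.numeric(x)) "continuous"
      else if (is.ordered(x)) "ordinal"
      else if (any(grepl(";", as.character(x), fixed = TRUE))) "binary_set"
      else "categorical"
    }, character(1))
  }
  if (!all(names(data) %in% names(types)))
    stop("types must cover every trait column")
  types <- types[names(data)]
  ok <- types %in% c("continuous", "ordinal", "categorical", "binary_set")
  if (!all(ok)) stop("unknown trait kind: ", paste(types[!ok], collapse = ", "))
  if (!all(log_traits %in% names(data)))
    stop("log_traits not in trait table")
  structure(list(species = rownames(data), data = data, types = types,
                 log_traits = log_traits),
            class = "bd_traits")
}

#' @export
print.bd_traits <- function(x, ...) {
  cat(sprintf("bd_traits: %d species, %d traits (%s)\n",
              length(x$species), length(x$types),
              paste(sprintf("%s:%s", names(x$types), substr(x$types, 1, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a trait table from CSV
#'
#' Accepts a wide table (`species` column + one column per trait) or a long
#' table with exactly the columns `species,trait_name,value`.  Multi-label
#' values are semicolon-delimited.
#'
#' @inheritParams bd_traits
#' @param path CSV file.
#' @return a `bd_traits`.
#' @export
read_traits <- function(path, types = NULL, log_traits = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (identical(sort(names(df)), c("species", "trait_name", "value"))) {
    wide <- stats::reshape(df, idvar = "species", timevar = "trait_name",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    # restore numeric columns that survived the round trip as strings
    for (j in setdiff(names(wide), "species")) {
      v <- suppressWarnings(as.numeric(wide[[j]]))
      if (!anyNA(v)) wide[[j]] <- v
    }
    df <- wide
  }
  bd_traits(df, types = types, log_traits = log_traits)
}

# membership matrix of a semicolon-delimited multi-label column
set_membership <- function(x) {
  labs <- strsplit(as.character(x), ";", fixed = TRUE)
  labs <- lapply(labs, function(l) unique(trimws(l[nzchar(trimws(l))])))
  all_labs <- sort(unique(unlist(labs)))
  B <- matrix(0, length(x), length(all_labs),
              dimnames = list(NULL, all_labs))
  for (i in seq_along(labs)) B[i, labs[[i]]] <- 1
  B
}

#' Gower distance matrix over mixed traits
#'
#' Equal-weight Gower average of per-trait dissimilarities: continuous
#' (after optional log transform) and rank-scaled ordinal traits contribute
#' `|x_i - x_j| / range`; categorical traits contribute a 0/1 mismatch;
#' multi-label (`binary_set`) traits contribute one minus the Jaccard
#' similarity of the label sets (two empty sets count as identical).  A
#' zero-range continuous trait contributes 0 with a warning.
#'
#' @param traits a [bd_traits] object.
#' @return symmetric species-by-species matrix with entries in \[0, 1\] and
#'   zero diagonal.
#' @export
gower_dist <- function(traits) {
  stopifnot(inherits(traits, "bd_traits"))
  n <- length(traits$species)
  D <- matrix(0, n, n, dimnames = list(traits$species, traits$species))
  for (tr in names(traits$types)) {
    kind <- traits$types[[tr]]
    x <- traits$data[[tr]]
    if (kind %in% c("continuous", "ordinal")) {
      if (kind == "ordinal") {
        x <- rank(x, ties.method = "average")
      } else if (tr %in% traits$log_traits) {
        if (any(x <= 0)) stop("log-transformed trait '", tr, "' must be > 0")
        x <- log(x)
      }
      rng <- max(x) - min(x)
      if (rng == 0) {
        warning("trait '", tr, "' has zero range; contributes 0")
        next
      }
      D <- D + abs(outer(x, x, "-")) / rng
    } else if (kind == "categorical") {
      D <- D + (outer(as.character(x), as.character(x), "!=") + 0)
    } else {  # binary_set
      B <- set_membership(x)
      inter <- tcrossprod(B)
      sz <- rowSums(B)
      un <- outer(sz, sz, "+") - inter
      d <- 1 - inter / un
      d[un == 0] <- 0  # both sets empty: identical
      D <- D + d
    }
  }
  D <- D / length(traits$types)
  dimnames(D) <- list(traits$species, traits$species)
  D
}

#' Rao's quadratic entropy of a presence community
#'
#' Expected functional distance between two randomly drawn individuals,
#' with presence-absence weights p_i = 1/S for each of the S species
#' present: Q = sum_ij p_i p_j d_ij.
#'
#' @param community binary vector of presences; if named, aligned to
#'   `dmat` by species name, otherwise by position.
#' @param dmat symmetric functional distance matrix (e.g. [gower_dist()]).
#' @return Q, a non-negative scalar (0 for a single species).
#' @export
rao_q <- function(community, dmat) {
  idx <- which(community > 0)
  if (!length(idx)) stop("Rao Q undefined for an empty community")
  if (!is.null(names(community)) && !is.null(rownames(dmat)))
    idx <- match(names(community)[idx], rownames(dmat))
  S <- length(idx)
  sum(dmat[idx, idx]) / S^2
}
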