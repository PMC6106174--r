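# Fixtures built in code and independent brute-force oracles used across
# the suite.  Oracles deliberately use naive double loops / set arithmetic
# so they share no code path with the package implementations.

# full square grid, all land
make_grid <- function(g, cs = 10) {
  d <- expand.grid(easting = (0:(g - 1)) * cs, northing = (0:(g - 1)) * cs)
  d <- d[order(d$northing, d$easting), ]
  data.frame(cell_id = sprintf("c%d_%d", d$easting, d$northing),
             easting = d$easting, northing = d$northing,
             land_fraction = 1, stringsAsFactors = FALSE)
}

random_atlas <- function(g, ns, period = "p1", prob = 0.4, cs = 10) {
  grid <- make_grid(g, cs)
  M <- matrix(rbinom(nrow(grid) * ns, 1, prob), nrow(grid), ns,
              dimnames = list(grid$cell_id, sprintf("sp%02d", seq_len(ns))))
  bd_atlas(grid, M, period, cs)
}

random_trait_table <- function(ns) {
  df <- data.frame(
    mass = exp(rnorm(ns, 4, 1)),
    clutch = runif(ns, 1, 10),
    grade = sample(1:5, ns, replace = TRUE),
    colour = sample(c("red", "green", "blue", "grey"), ns, replace = TRUE),
    food = vapply(seq_len(ns), function(i)
      paste(sample(c("a", "b", "c", "d"), sample(1:3, 1)), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- sprintf("sp%02d", seq_len(ns))
  bd_traits(df, types = c(mass = "continuous", clutch = "continuous",
                          grade = "ordinal", colour = "categorical",
                          food = "binary_set"))
}

# --- oracles ----------------------------------------------------------

# Gower distance by per-pair, per-trait loop
gower_oracle <- function(traits) {
  dat <- traits$data
  ns <- nrow(dat)
  prep <- list()
  for (tr in names(traits$types)) {
    x <- dat[[tr]]
    kind <- traits$types[[tr]]
    if (kind == "ordinal") x <- rank(x, ties.method = "average")
    if (kind == "continuous" && tr %in% traits$log_traits) x <- log(x)
    prep[[tr]] <- x
  }
  D <- matrix(0, ns, ns, dimnames = list(rownames(dat), rownames(dat)))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    tot <- 0
    for (tr in names(traits$types)) {
      kind <- traits$types[[tr]]
      x <- prep[[tr]]
      if (kind %in% c("continuous", "ordinal")) {
        rng <- max(x) - min(x)
        if (rng > 0) tot <- tot + abs(x[i] - x[j]) / rng
      } else if (kind == "categorical") {
        tot <- tot + as.numeric(x[i] != x[j])
      } else {
        a <- strsplit(as.character(x[i]), ";")[[1]]
        b <- strsplit(as.character(x[j]), ";")[[1]]
        un <- length(union(a, b))
        if (un > 0) tot <- tot + 1 - length(intersect(a, b)) / un
      }
    }
    D[i, j] <- tot / length(traits$types)
  }
  D
}

# Rao Q by explicit double loop over present species
rao_oracle <- function(x, D) {
  idx <- which(x > 0)
  S <- length(idx)
  q <- 0
  for (i in idx) for (j in idx) q <- q + D[i, j] / S^2
  q
}

# pooled/within Rao decomposition by double loop over the pooled weights
beta_rao_oracle <- function(c1, c2, D, jost = TRUE, proportional = FALSE) {
  s1 <- sum(c1 > 0); s2 <- sum(c2 > 0)
  if (s1 == 0 || s2 == 0) return(NA_real_)
  w <- numeric(length(c1))
  for (i in seq_along(c1))
    w[i] <- (c1[i] > 0) / (2 * s1) + (c2[i] > 0) / (2 * s2)
  qg <- 0
  for (i in seq_along(w)) for (j in seq_along(w))
    qg <- qg + w[i] * w[j] * D[i, j]
  qa1 <- rao_oracle(c1, D); qa2 <- rao_oracle(c2, D)
  if (jost) { qa1 <- 1 / (1 - qa1); qa2 <- 1 / (1 - qa2); qg <- 1 / (1 - qg) }
  b <- qg - (qa1 + qa2) / 2
  if (proportional) b / qg else b
}

# beta_sim from raw species sets
beta_sim_oracle <- function(set1, set2) {
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set2, set1))
  cc <- length(setdiff(set1, set2))
  m <- min(b, cc)
  if (a == 0 && m == 0) return(NA_real_)
  m / (m + a)
}

nfn_oracle <- function(c1, c2, D) {
  i <- which(c1 > 0); j <- which(c2 > 0)
  if (!length(i) || !length(j)) return(NA_real_)
  m1 <- mean(vapply(i, function(k) min(D[k, j]), numeric(1)))
  m2 <- mean(vapply(j, function(k) min(D[i, k]), numeric(1)))
  (m1 + m2) / 2
}

mfd_oracle <- function(c1, c2, D) {
  i <- which(c1 > 0); j <- which(c2 > 0)
  if (!length(i) || !length(j)) return(NA_real_)
  tot <- 0
  for (k in i) for (l in j) tot <- tot + D[k, l]
  tot / (length(i) * length(j))
}

# wrap a numeric vector as a bd_field on a given grid
as_field <- function(grid, value, measure = "delta_sim", cs = 10) {
  structure(data.frame(cell_id = grid$cell_id, easting = grid$easting,
                       northing = grid$northing, value = value,
                       stringsAsFactors = FALSE),
            measure = measure, period = "p", cell_size = cs,
            class = c("bd_field", "data.frame"))
}
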