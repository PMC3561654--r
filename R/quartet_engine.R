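## Quartet inference: four-point condition on six pairwise distances, ordinary
## least-squares quartet edge lengths, middle-edge-fraction weights, and the
## pluggable quartet oracle used by the random walk.
##
## Topology indices are relative to the input order (W, X, Y, Z):
##   1 = WX|YZ, 2 = WY|XZ, 3 = WZ|XY  (the canonical order; ties pick the
## smallest index and carry zero weight since the fitted middle edge is 0).

#' Four-point quartet topology from six pairwise distances
#'
#' Compares `dWX + dYZ`, `dWY + dXZ` and `dWZ + dXY`; the pairing whose
#' within-pair sum is smallest wins. Ties are broken by the canonical order
#' `WX|YZ < WY|XZ < WZ|XY` and flagged via the `"tied"` attribute.
#'
#' @param dWX,dWY,dWZ,dXY,dXZ,dYZ finite nonnegative distances.
#' @return Integer 1, 2 or 3 (topology `WX|YZ`, `WY|XZ`, `WZ|XY`), with
#'   attribute `tied`.
#' @export
four_point <- function(dWX, dWY, dWZ, dXY, dXZ, dYZ) {
  s <- c(dWX + dYZ, dWY + dXZ, dWZ + dXY)
  stopifnot(all(is.finite(s)))
  top <- which.min(s)
  structure(as.integer(top), tied = sum(s == s[top]) > 1L)
}

#' Ordinary least-squares edge lengths of a quartet
#'
#' Closed-form OLS fit of the five-edge quartet tree to the six observed
#' distances, for a fixed topology. On additive input the fit is exact; when
#' the topology is the four-point winner the fitted middle edge is
#' nonnegative. External edges may come out negative on noisy input; they are
#' reported raw here and clamped only in [quartet_weight()].
#'
#' @inheritParams four_point
#' @param topology integer 1..3 as returned by [four_point()].
#' @return Named numeric `c(a, b, c, d, e)`: pendant edges of W, X, Y, Z and
#'   the middle edge, in the W,X,Y,Z order of the *input* (not reordered by
#'   topology).
#' @export
ols_quartet_lengths <- function(dWX, dWY, dWZ, dXY, dXZ, dYZ, topology) {
  ## reduce to topology 1 by swapping X with the taxon paired with W
  d <- c(dWX, dWY, dWZ, dXY, dXZ, dYZ)
  perm <- switch(topology,
                 c(1L, 2L, 3L, 4L, 5L, 6L),   # W X Y Z
                 c(2L, 1L, 3L, 4L, 6L, 5L),   # swap X,Y
                 c(3L, 2L, 1L, 6L, 5L, 4L))   # swap X,Z
  dd <- d[perm]
  e <- (dd[2] + dd[3] + dd[4] + dd[5]) / 4 - (dd[1] + dd[6]) / 2
  a <- (dd[1] + (dd[2] + dd[3]) / 2 - (dd[4] + dd[5]) / 2) / 2
  b <- (dd[1] + (dd[4] + dd[5]) / 2 - (dd[2] + dd[3]) / 2) / 2
  cc <- (dd[6] + (dd[2] + dd[4]) / 2 - (dd[3] + dd[5]) / 2) / 2
  ddl <- (dd[6] + (dd[3] + dd[5]) / 2 - (dd[2] + dd[4]) / 2) / 2
  ext <- switch(topology,
                c(a, b, cc, ddl),
                c(a, cc, b, ddl),
                c(a, cc, ddl, b))
  setNames(c(ext, e), c("a", "b", "c", "d", "e"))
}

#' Middle-edge-fraction quartet weight
#'
#' `w = e / (a + b + c + d + e)` with negative external lengths clamped to 0
#' before summing; a nonpositive middle edge, a nonpositive denominator or a
#' non-finite value yields weight 0. The result lies in `[0, 1]` and is
#' invariant under rescaling all six input distances.
#'
#' @param lengths numeric of length 5, `(a, b, c, d, e)` as from
#'   [ols_quartet_lengths()].
#' @return Weight in `[0, 1]`.
#' @export
quartet_weight <- function(lengths) {
  stopifnot(length(lengths) == 5L)
  e <- lengths[5L]
  if (!is.finite(e) || e <= 0) return(0)
  ext <- pmax(lengths[1:4], 0)
  den <- sum(ext) + e
  if (!is.finite(den) || den <= 0) return(0)
  min(1, max(0, unname(e / den)))
}

## vectorized weight for k quartets given 6 distance vectors and winner tops
quartet_weight_batch <- function(d1, d2, d3, d4, d5, d6, top) {
  ## d order: WX, WY, WZ, XY, XZ, YZ; permute per row so the winner is the
  ## "WX|YZ" frame, via subassignment (cheaper than ifelse in the hot path)
  i2 <- top == 2L; i3 <- top == 3L
  dd1 <- d1; dd1[i2] <- d2[i2]; dd1[i3] <- d3[i3]
  dd2 <- d2; dd2[i2] <- d1[i2]
  dd3 <- d3; dd3[i3] <- d1[i3]
  dd4 <- d4; dd4[i3] <- d6[i3]
  dd5 <- d5; dd5[i2] <- d6[i2]
  dd6 <- d6; dd6[i2] <- d5[i2]; dd6[i3] <- d4[i3]
  e <- (dd2 + dd3 + dd4 + dd5) / 4 - (dd1 + dd6) / 2
  a <- (dd1 + (dd2 + dd3) / 2 - (dd4 + dd5) / 2) / 2
  b <- (dd1 + (dd4 + dd5) / 2 - (dd2 + dd3) / 2) / 2
  cc <- (dd6 + (dd2 + dd4) / 2 - (dd3 + dd5) / 2) / 2
  dl <- (dd6 + (dd3 + dd5) / 2 - (dd2 + dd4) / 2) / 2
  den <- pmax(a, 0) + pmax(b, 0) + pmax(cc, 0) + pmax(dl, 0) + e
  w <- e / den
  w[e <= 0 | den <= 0 | !is.finite(w)] <- 0
  pmin(1, pmax(0, w))
}

## ---- oracles ----
##
## A quartet oracle is an environment of class "quartet_oracle" with fields
##   taxa        character vector defining taxon indices
##   kind        "distance" | "trees" | "noisy"
##   vote_batch  function(xi, R) for the walk's node queries: xi is the new
##               taxon's index, R a k x 3 matrix of representative indices
##               (one per direction). Returns list(dir, w): per-row direction
##               1..3 (NA = unresolvable/ABSENT) and weight.
##   query_idx   function(i, j, k, l) -> list(top, lengths, weight, tied) or
##               NULL (ABSENT), used by query_quartet().
## plus kind-specific state.

new_oracle <- function(kind, taxa) {
  o <- new.env(parent = emptyenv())
  o$kind <- kind
  o$taxa <- taxa
  class(o) <- c(paste0(kind, "_oracle"), "quartet_oracle", "environment")
  o
}

#' Distance-based quartet oracle over an alignment
#'
#' Answers quartet queries by the four-point condition on cached pairwise
#' distances, with OLS edge lengths and middle-edge-fraction weights.
#'
#' @param aln an `alignment` (or `NULL` with `model = "precomputed"`).
#' @param model,D,cap passed to [distance_cache()].
#' @return A `quartet_oracle`.
#' @export
distance_oracle <- function(aln = NULL, model = c("jc", "scoredist", "precomputed"),
                            D = NULL, cap = 10) {
  ca <- distance_cache(aln, model, D = D, cap = cap)
  o <- new_oracle("distance", ca$labels)
  o$cache <- ca
  o$query_idx <- function(i, j, k, l) {
    d <- cache_dist_many(ca, c(i, i, i, j, j, k), c(j, k, l, k, l, l))
    top <- four_point(d[1], d[2], d[3], d[4], d[5], d[6])
    len <- ols_quartet_lengths(d[1], d[2], d[3], d[4], d[5], d[6], top)
    list(top = as.integer(top), lengths = len,
         weight = if (isTRUE(attr(top, "tied"))) 0 else quartet_weight(len),
         tied = isTRUE(attr(top, "tied")))
  }
  o$vote_batch <- function(xi, R) {
    k <- nrow(R)
    iv <- c(rep.int(xi, 3L * k), R[, 1L], R[, 1L], R[, 2L])
    jv <- c(R[, 1L], R[, 2L], R[, 3L], R[, 2L], R[, 3L], R[, 3L])
    d <- cache_dist_many(ca, iv, jv)
    dWX <- d[seq_len(k)]; dWY <- d[k + seq_len(k)]; dWZ <- d[2L * k + seq_len(k)]
    dXY <- d[3L * k + seq_len(k)]; dXZ <- d[4L * k + seq_len(k)]
    dYZ <- d[5L * k + seq_len(k)]
    s1 <- dWX + dYZ; s2 <- dWY + dXZ; s3 <- dWZ + dXY
    top <- max.col(-cbind(s1, s2, s3), ties.method = "first")
    w <- quartet_weight_batch(dWX, dWY, dWZ, dXY, dXZ, dYZ, top)
    list(dir = top, w = w)
  }
  o
}

#' Majority quartet oracle over a collection of trees (supertree mode)
#'
#' Among input trees containing all four taxa, the induced topologies are
#' tallied; the majority topology is returned with weight
#' `sqrt(m / N)`, where `m` is the number of input trees inducing it and `N`
#' the total number of input trees. When no input tree contains all four
#' taxa the query is ABSENT. Majority ties are broken by the canonical
#' topology order and carry a tie flag.
#'
#' @param trees a list of `phylogeny` (or ape `phylo`) objects, possibly on
#'   different, overlapping taxon sets.
#' @return A `quartet_oracle`.
#' @export
tree_oracle <- function(trees) {
  stopifnot(length(trees) >= 1L)
  trees <- lapply(trees, as_phylogeny)
  taxa <- sort(unique(unlist(lapply(trees, taxa_labels))))
  n <- length(taxa)
  N <- length(trees)
  ## per-tree topological leaf distance matrices, NA rows for absent taxa
  mats <- lapply(trees, function(tr) {
    M <- matrix(NA_real_, n, n)
    D <- leaf_dist_matrix(tr, unit = TRUE)
    idx <- match(rownames(D), taxa)
    M[idx, idx] <- D
    M
  })
  o <- new_oracle("trees", taxa)
  o$trees <- trees
  tally4 <- function(i, j, k, l) {
    votes <- integer(3)
    for (M in mats) {
      s1 <- M[i, j] + M[k, l]; s2 <- M[i, k] + M[j, l]; s3 <- M[i, l] + M[j, k]
      if (is.na(s1)) next
      s <- c(s1, s2, s3)
      votes[which.min(s)] <- votes[which.min(s)] + 1L
    }
    votes
  }
  o$query_idx <- function(i, j, k, l) {
    votes <- tally4(i, j, k, l)
    if (sum(votes) == 0L) return(NULL)  # ABSENT
    top <- which.max(votes)
    list(top = top, lengths = NULL, weight = sqrt(votes[top] / N),
         tied = sum(votes == votes[top]) > 1L)
  }
  o$vote_batch <- function(xi, R) {
    k <- nrow(R)
    dir <- rep(NA_integer_, k); w <- numeric(k)
    for (q in seq_len(k)) {
      r <- o$query_idx(xi, R[q, 1L], R[q, 2L], R[q, 3L])
      if (is.null(r)) next
      dir[q] <- r$top; w[q] <- r$weight
    }
    list(dir = dir, w = w)
  }
  o
}

#' Noisy quartet oracle with independent errors (test model)
#'
#' Returns the topology induced by a known true tree with probability
#' `1 - p_err`, otherwise one of the two wrong topologies uniformly at
#' random. Weights are fixed at 1. This is the independent-error model used
#' to study the random walk in isolation from distance estimation.
#'
#' @param true_tree a `phylogeny` (or ape `phylo`).
#' @param p_err error probability in `[0, 2/3)`.
#' @return A `quartet_oracle`.
#' @export
noisy_oracle <- function(true_tree, p_err = 0) {
  stopifnot(p_err >= 0, p_err < 2 / 3)
  tr <- as_phylogeny(true_tree)
  D <- leaf_dist_matrix(tr, unit = TRUE)
  taxa <- rownames(D)
  o <- new_oracle("noisy", taxa)
  o$true_tree <- tr
  o$p_err <- p_err
  true_top <- function(i, j, k, l) {
    s <- c(D[i, j] + D[k, l], D[i, k] + D[j, l], D[i, l] + D[j, k])
    which.min(s)
  }
  o$query_idx <- function(i, j, k, l) {
    top <- true_top(i, j, k, l)
    if (p_err > 0 && runif(1) < p_err)
      top <- (top - 1L + sample.int(2L, 1L)) %% 3L + 1L
    list(top = as.integer(top), lengths = NULL, weight = 1, tied = FALSE)
  }
  o$vote_batch <- function(xi, R) {
    k <- nrow(R)
    s1 <- D[cbind(xi, R[, 1L])] + D[cbind(R[, 2L], R[, 3L])]
    s2 <- D[cbind(xi, R[, 2L])] + D[cbind(R[, 1L], R[, 3L])]
    s3 <- D[cbind(xi, R[, 3L])] + D[cbind(R[, 1L], R[, 2L])]
    top <- max.col(-cbind(s1, s2, s3), ties.method = "first")
    if (p_err > 0) {
      err <- runif(k) < p_err
      if (any(err)) {
        shift <- sample.int(2L, sum(err), replace = TRUE)
        top[err] <- (top[err] - 1L + shift) %% 3L + 1L
      }
    }
    list(dir = top, w = rep(1, k))
  }
  o
}

#' Ask a quartet oracle for the topology of four taxa
#'
#' @param oracle a `quartet_oracle`.
#' @param a,b,c,d taxon labels.
#' @return A `weighted_quartet`: list with `topology` (canonical key
#'   `"A,B|C,D"`), `lengths` (OLS `(a,b,c,d,e)` for distance oracles, else
#'   `NULL`), `weight`, and `tied`; or `NULL` when the query is ABSENT
#'   (tree-collection oracle only).
#' @export
query_quartet <- function(oracle, a, b, c, d) {
  stopifnot(inherits(oracle, "quartet_oracle"))
  labs <- c(a, b, c, d)
  idx <- match(labs, oracle$taxa)
  if (anyNA(idx)) stop("unknown taxon: ", paste(labs[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stop("quartet taxa must be distinct")
  r <- oracle$query_idx(idx[1L], idx[2L], idx[3L], idx[4L])
  if (is.null(r)) return(NULL)
  structure(list(topology = quartet_key(labs, r$top), lengths = r$lengths,
                 weight = r$weight, tied = r$tied),
            class = "weighted_quartet")
}

#' @export
print.weighted_quartet <- function(x, ...) {
  cat("quartet", x$topology, " weight", format(x$weight, digits = 4),
      if (isTRUE(x$tied)) "(tied)" else "", "\n")
  invisible(x)
}
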