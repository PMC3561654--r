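## Tree-comparison measures: Robinson-Foulds quality, quartet quality
## (exact enumeration or seeded Monte-Carlo sampling), and taxon coverage.

#' Robinson-Foulds quality
#'
#' Both trees are restricted to their shared taxa; the result is the
#' percentage of the reference tree's non-trivial splits found in the test
#' tree. The reference supplies the denominator, so partial test trees are
#' scored against ground truth on the taxa they share.
#'
#' @param T_test,T_ref `phylogeny` (or ape `phylo`) objects sharing at least
#'   4 taxa.
#' @return Percentage in `[0, 100]`.
#' @export
rf_quality <- function(T_test, T_ref) {
  T_test <- as_phylogeny(T_test); T_ref <- as_phylogeny(T_ref)
  shared <- intersect(taxa_labels(T_test), taxa_labels(T_ref))
  if (length(shared) < 4L) stop("need at least 4 shared taxa")
  if (length(shared) < n_leaves(T_test)) T_test <- restrict_taxa(T_test, shared)
  if (length(shared) < n_leaves(T_ref)) T_ref <- restrict_taxa(T_ref, shared)
  s_test <- names(splits(T_test))
  s_ref <- names(splits(T_ref))
  100 * length(intersect(s_test, s_ref)) / length(s_ref)
}

#' Quartet quality
#'
#' Percentage of four-taxon subsets of the shared taxa whose induced
#' topologies agree between the two trees. Exact mode enumerates all
#' `choose(m, 4)` quartets (allowed up to `exact_cap`); sampled mode draws
#' `n_samples` quartets uniformly with replacement and reports a Monte-Carlo
#' standard error in the `"se"` attribute.
#'
#' @inheritParams rf_quality
#' @param mode `"auto"` (exact when within the cap), `"exact"`, or
#'   `"sampled"`.
#' @param n_samples quartets drawn in sampled mode (default `1e5`).
#' @param exact_cap largest quartet count enumerated exactly (default `5e5`).
#' @return Percentage in `[0, 100]`; in sampled mode with attributes `se`
#'   (percentage points) and `n` (draws).
#' @export
quartet_quality <- function(T_test, T_ref, mode = c("auto", "exact", "sampled"),
                            n_samples = 1e5, exact_cap = 5e5) {
  mode <- match.arg(mode)
  T_test <- as_phylogeny(T_test); T_ref <- as_phylogeny(T_ref)
  shared <- sort(intersect(taxa_labels(T_test), taxa_labels(T_ref)))
  m <- length(shared)
  if (m < 4L) stop("need at least 4 shared taxa")
  n_quartets <- choose(m, 4)
  if (mode == "auto") mode <- if (n_quartets <= exact_cap) "exact" else "sampled"
  if (mode == "exact" && n_quartets > exact_cap)
    stop("choose(m, 4) = ", n_quartets, " exceeds the exact cap; use sampled mode")
  D1 <- leaf_dist_matrix(T_test, unit = TRUE)[shared, shared]
  D2 <- leaf_dist_matrix(T_ref, unit = TRUE)[shared, shared]
  if (mode == "exact") {
    Q <- t(combn(m, 4L))
  } else {
    Q <- matrix(0L, n_samples, 4L)
    need <- seq_len(n_samples)
    while (length(need) > 0L) {
      Q[need, ] <- sample.int(m, 4L * length(need), replace = TRUE)
      need <- need[apply(Q[need, , drop = FALSE], 1L, anyDuplicated) > 0L]
    }
  }
  t1 <- quartet_tops(D1, Q)
  t2 <- quartet_tops(D2, Q)
  agree <- mean(t1 == t2)
  if (mode == "exact") return(100 * agree)
  structure(100 * agree,
            se = 100 * sqrt(agree * (1 - agree) / nrow(Q)),
            n = nrow(Q))
}

## vectorized induced topologies for rows of quartet-index matrix Q against a
## topological (unit-length) leaf distance matrix: additive distances make
## the four-point comparison exact
quartet_tops <- function(D, Q) {
  s1 <- D[Q[, c(1, 2), drop = FALSE]] + D[Q[, c(3, 4), drop = FALSE]]
  s2 <- D[Q[, c(1, 3), drop = FALSE]] + D[Q[, c(2, 4), drop = FALSE]]
  s3 <- D[Q[, c(1, 4), drop = FALSE]] + D[Q[, c(2, 3), drop = FALSE]]
  max.col(-cbind(s1, s2, s3), ties.method = "first")
}

#' Taxon coverage
#'
#' @param x a `build_report` or a `phylogeny`.
#' @param full_taxa the complete taxon set (defaults to the report's own
#'   input set when `x` is a `build_report`).
#' @return Percentage of `full_taxa` present in the tree.
#' @export
coverage <- function(x, full_taxa = NULL) {
  if (inherits(x, "build_report")) {
    if (is.null(full_taxa)) return(x$coverage)
    x <- x$tree
  }
  x <- as_phylogeny(x)
  stopifnot(!is.null(full_taxa))
  100 * length(intersect(taxa_labels(x), full_taxa)) / length(full_taxa)
}

#' Compare two trees on all quality measures
#'
#' @inheritParams quartet_quality
#' @param full_taxa taxon set for the coverage figure (defaults to the
#'   reference tree's taxa).
#' @return A list with `rf_quality`, `quartet_quality` (with attributes in
#'   sampled mode), `shared_taxa` and `coverage`.
#' @export
compare_trees <- function(T_test, T_ref, mode = "auto", n_samples = 1e5,
                          full_taxa = NULL) {
  T_test <- as_phylogeny(T_test); T_ref <- as_phylogeny(T_ref)
  if (is.null(full_taxa)) full_taxa <- taxa_labels(T_ref)
  shared <- intersect(taxa_labels(T_test), taxa_labels(T_ref))
  list(rf_quality = rf_quality(T_test, T_ref),
       quartet_quality = quartet_quality(T_test, T_ref, mode = mode,
                                         n_samples = n_samples),
       shared_taxa = length(shared),
       coverage = coverage(T_test, full_taxa))
}
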