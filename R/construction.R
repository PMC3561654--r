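## End-to-end tree building: neighbour-joining guide tree on a random subset,
## randomized insertion order via the random walk, reinsertion rounds,
## optional forced insertion, and the supertree driver.

#' Neighbour joining
#'
#' Classic NJ agglomeration on a symmetric distance matrix (via [ape::nj()]),
#' returned as an unrooted `phylogeny` with branch lengths.
#'
#' @param D symmetric numeric matrix with zero diagonal and taxon dimnames.
#' @return A `phylogeny`.
#' @export
neighbour_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3L)
  if (is.null(rownames(D))) stop("distance matrix needs taxon dimnames")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  as_phylogeny(ape::nj(stats::as.dist(D)))
}

#' Guide-tree configuration
#'
#' The guide tree is built by neighbour joining on a uniformly sampled subset
#' of taxa. The fixed rule uses `min(size, max(4, floor(n/2)))` taxa; the
#' proportional rule uses `ceiling(c * n^(1/3))` (clamped to `[4, n]`),
#' which keeps guide-tree construction asymptotically negligible.
#'
#' @param size fixed guide size (default 200).
#' @param c when non-`NULL`, use the proportional rule with this constant
#'   (default constant 10 when `c = TRUE`).
#' @return A `guide_config` list.
#' @export
guide_config <- function(size = 200, c = NULL) {
  if (isTRUE(c)) c <- 10
  structure(list(size = size, c = c), class = "guide_config")
}

guide_size_for <- function(gcfg, n) {
  if (!is.null(gcfg$c)) {
    m <- ceiling(gcfg$c * n^(1 / 3))
  } else {
    m <- min(gcfg$size, max(4, floor(n / 2)))
  }
  as.integer(min(n, max(4, m)))
}

## distance matrix used for the guide tree, per oracle kind
oracle_guide_dists <- function(oracle, idx) {
  taxa <- oracle$taxa[idx]
  if (oracle$kind == "distance") {
    cache_dist_matrix(oracle$cache, idx)
  } else if (oracle$kind == "noisy") {
    D <- leaf_dist_matrix(oracle$true_tree,
                          unit = !any(!is.na(oracle$true_tree$edge_len[
                            phy_alive(oracle$true_tree)])))
    D[taxa, taxa]
  } else { # tree collection: path distances within the first input tree
    tr <- oracle$trees[[1L]]
    D <- leaf_dist_matrix(tr, unit = !any(!is.na(tr$edge_len[phy_alive(tr)])))
    D[taxa, taxa]
  }
}

## taxa eligible for the guide sample
oracle_guide_taxa <- function(oracle) {
  if (oracle$kind == "trees") intersect(oracle$taxa, taxa_labels(oracle$trees[[1L]]))
  else oracle$taxa
}

#' Build a phylogeny incrementally with the quartet random walk
#'
#' The pipeline: (1) sample a random guide subset and build its
#' neighbour-joining guide tree; (2) index it with a search tree; (3) insert
#' the remaining taxa in uniform random order via the (optionally repeated)
#' random walk, attaching each accepted taxon; (4) re-attempt still-unplaced
#' taxa for `rounds - 1` further rounds with fresh random orders; (5) when
#' `force_all`, place whatever remains by running the walk followed by a
#' forced descent.
#'
#' @param source an `alignment` (nucleotide by default) or a `quartet_oracle`.
#' @param cfg a [walk_config()].
#' @param guide a [guide_config()].
#' @param rounds total insertion rounds (default 3 = first pass plus two
#'   reinsertion rounds).
#' @param force_all insert every remaining taxon by forced descent after the
#'   last round (default `FALSE`).
#' @param model distance model when `source` is an alignment (`"jc"` or
#'   `"scoredist"`).
#' @param seed integer seed for all randomness of the build (guide sampling,
#'   insertion orders, representative choice, vote tie-breaks); `NULL` uses
#'   the ambient RNG state.
#' @return A `build_report`: list with `tree` (the `phylogeny`), `coverage`
#'   (percent of taxa placed), `placed`, `unplaced`, `forced`, per-round
#'   counts `rounds`, `guide_taxa`, and the configuration echo `config`.
#' @export
build_tree <- function(source, cfg = walk_config(), guide = guide_config(),
                       rounds = 3, force_all = FALSE,
                       model = c("jc", "scoredist"), seed = NULL) {
  if (inherits(source, "alignment")) {
    model <- match.arg(model)
    oracle <- distance_oracle(source, model)
  } else if (inherits(source, "quartet_oracle")) {
    oracle <- source
  } else stop("source must be an alignment or a quartet_oracle")
  stopifnot(rounds >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(oracle$taxa)
  if (n < 5L) stop("need at least 5 taxa")
  ## a full build eventually touches most pairs: for nucleotide alignments of
  ## a few hundred taxa or more, one BLAS pass over the one-hot encoding is
  ## cheaper than incremental memoization
  if (oracle$kind == "distance" && is.null(oracle$cache$D) &&
      oracle$cache$model == "jc" && n >= 300 && n <= 5000)
    cache_precompute_all(oracle$cache)

  guide_pool <- oracle_guide_taxa(oracle)
  m <- guide_size_for(guide, length(guide_pool))
  guide_taxa <- sort(sample(guide_pool, m))
  guide_idx <- match(guide_taxa, oracle$taxa)
  D <- oracle_guide_dists(oracle, guide_idx)
  gt <- neighbour_joining(D)
  ## the walk is purely topological; drop guide branch lengths
  gt$edge_len[] <- NA_real_
  st <- build_search_tree(gt)

  remaining <- setdiff(oracle$taxa, guide_taxa)
  placed <- character(0)
  forced <- character(0)
  round_log <- data.frame(round = integer(0), attempted = integer(0),
                          inserted = integer(0))
  for (rd in seq_len(rounds)) {
    if (length(remaining) == 0L) break
    order_rd <- sample(remaining)
    inserted <- character(0)
    for (x in order_rd) {
      res <- repeated_walk(x, st, oracle, cfg)
      if (res$accepted) {
        insert_at_leaf(st, res$terminal, x)
        inserted <- c(inserted, x)
      }
    }
    round_log <- rbind(round_log,
                       data.frame(round = rd, attempted = length(order_rd),
                                  inserted = length(inserted)))
    placed <- c(placed, inserted)
    remaining <- setdiff(remaining, inserted)
  }
  if (force_all && length(remaining) > 0L) {
    for (x in sample(remaining)) {
      res <- random_walk(x, st, oracle, cfg)
      leaf <- force_descent(x, st, oracle, cfg, from = res$terminal)
      insert_at_leaf(st, leaf, x)
      forced <- c(forced, x)
    }
    placed <- c(placed, forced)
    remaining <- character(0)
  }
  st_audit(st)
  all_placed <- c(guide_taxa, placed)
  structure(list(
    tree = st$T,
    coverage = 100 * length(all_placed) / n,
    placed = all_placed,
    unplaced = remaining,
    forced = forced,
    guide_taxa = guide_taxa,
    rounds = round_log,
    n_taxa = n,
    config = list(walk = cfg, guide = guide, rounds = rounds,
                  force_all = force_all, seed = seed)
  ), class = "build_report")
}

## attach taxon x at the phylogeny edge owned by search leaf `leaf` and keep
## the search tree in sync
insert_at_leaf <- function(st, leaf, x) {
  e <- st$region[[leaf]][1L]
  T2 <- attach_leaf(st$T, e, x)
  pl <- attr(T2, "placement")
  attr(T2, "placement") <- NULL
  st$T <- T2
  expand_leaf(st, leaf, pl)
  invisible(st)
}

#' @export
print.build_report <- function(x, ...) {
  cat("quartet random-walk build:", length(x$placed), "of", x$n_taxa,
      sprintf("taxa placed (coverage %.1f%%)\n", x$coverage))
  if (nrow(x$rounds) > 0) {
    for (i in seq_len(nrow(x$rounds)))
      cat(sprintf("  round %d: %d/%d inserted\n", x$rounds$round[i],
                  x$rounds$inserted[i], x$rounds$attempted[i]))
  }
  if (length(x$forced) > 0) cat("  forced:", length(x$forced), "taxa\n")
  if (length(x$unplaced) > 0) cat("  unplaced:", length(x$unplaced), "taxa\n")
  invisible(x)
}

#' Supertree construction from a collection of trees
#'
#' Builds a tree over the union of the input trees' taxon sets, answering
#' quartet queries by the majority topology among input trees (weighted by
#' the square root of the proportion of input trees carrying it). The guide
#' tree is neighbour joining on path distances measured in the first input
#' tree, over a random subset of its taxa.
#'
#' @param trees list of `phylogeny` or ape `phylo` objects with overlapping
#'   taxon sets.
#' @inheritParams build_tree
#' @return A `build_report`.
#' @export
supertree <- function(trees, cfg = walk_config(), guide = guide_config(),
                      rounds = 3, force_all = FALSE, seed = NULL) {
  stopifnot(length(trees) >= 2L)
  oracle <- tree_oracle(trees)
  if (length(oracle$taxa) < 5L) stop("union taxon set must have at least 5 taxa")
  build_tree(oracle, cfg = cfg, guide = guide, rounds = rounds,
             force_all = force_all, seed = seed)
}
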