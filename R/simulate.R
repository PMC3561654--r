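## Synthetic data: pure-birth (Yule) trees, branch-length perturbation and
## scaling, Jukes-Cantor sequence evolution with exponential rate variation
## across sites, and alignment bootstrap.

#' Simulate a pure-birth (Yule) tree
#'
#' Lineages split at rate 1 with exponential waiting times; the rooted tree's
#' height is normalized to 1 time unit and the tree is then unrooted. The
#' normalized rooted tree is kept in the `"rooted"` attribute (an ape
#' `phylo`) for diagnostics such as ultrametricity checks.
#'
#' @param n number of taxa (>= 3); leaves are labelled `t1 ... tn`.
#' @return A `phylogeny` with branch lengths (tree height 1).
#' @export
yule_tree <- function(n) {
  stopifnot(n >= 3)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n))
  depths <- ape::node.depth.edgelength(tr)
  h <- max(depths[seq_len(n)])
  tr$edge.length <- tr$edge.length / h
  T <- as_phylogeny(tr)
  attr(T, "rooted") <- tr
  T
}

#' Perturb and scale branch lengths
#'
#' Each branch is multiplied independently by a factor drawn uniformly from
#' `interval` (deviating the tree from ultrametricity), then all branches are
#' scaled by `kappa * f`. With the default calibration `kappa = 1/200`, the
#' scale factors `f` in `{25, 50, 100, 200}` map a height-1 tree to heights
#' `{0.125, 0.25, 0.5, 1.0}` substitutions/site.
#'
#' @param T a `phylogeny` with branch lengths.
#' @param interval length-2 perturbation interval (default `c(0.5, 2)`).
#' @param f overall scale factor (default 100).
#' @param kappa calibration constant converting the scale-factor grid to
#'   substitutions/site (default `1/200`).
#' @return The perturbed `phylogeny` (same topology).
#' @export
perturb_and_scale <- function(T, interval = c(0.5, 2), f = 100, kappa = 1 / 200) {
  stopifnot(inherits(T, "phylogeny"), length(interval) == 2L,
            interval[1] > 0, interval[1] <= interval[2], f > 0)
  alive <- phy_alive(T)
  if (anyNA(T$edge_len[alive])) stop("tree must have branch lengths")
  mult <- runif(length(alive), interval[1], interval[2])
  T$edge_len[alive] <- T$edge_len[alive] * mult * kappa * f
  attr(T, "rooted") <- NULL
  T
}

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' Each site gets a rate `r` (exponential with mean 1 by default, or fixed at
#' 1); the root state is uniform over `{A, C, G, T}` and along a branch of
#' length `b` each off-diagonal substitution has probability
#' `(1/4)(1 - exp(-(4/3) r b))`. The model is time-reversible, so the
#' (arbitrary) internal root does not affect the distribution. No indels are
#' introduced.
#'
#' @param T a `phylogeny` with branch lengths in substitutions/site.
#' @param length number of alignment columns.
#' @param rates `"exponential"` (mean-1 exponential rate per site) or
#'   `"constant"`.
#' @return A gap-free DNA `alignment` over the leaf taxa.
#' @export
evolve_jc <- function(T, length, rates = c("exponential", "constant")) {
  rates <- match.arg(rates)
  stopifnot(inherits(T, "phylogeny"), length >= 1)
  alive <- phy_alive(T)
  if (anyNA(T$edge_len[alive])) stop("tree must have branch lengths")
  r <- if (rates == "exponential") rexp(length) else rep(1, length)
  leaves <- phy_leaves(T)
  root <- setdiff(seq_len(T$n_nodes), leaves)[1L]
  states <- matrix(0L, T$n_nodes, length)
  states[root, ] <- sample.int(4L, length, replace = TRUE)
  ## preorder traversal from the root
  stack_v <- integer(T$n_nodes); stack_e <- integer(T$n_nodes)
  top <- 1L; stack_v[1L] <- root; stack_e[1L] <- 0L
  while (top > 0L) {
    v <- stack_v[top]; via <- stack_e[top]; top <- top - 1L
    for (e in T$adj[, v]) {
      if (e == 0L || e == via) next
      w <- phy_other_end(T, e, v)
      p_sub <- 0.75 * (1 - exp(-4 / 3 * r * T$edge_len[e]))
      change <- runif(length) < p_sub
      s <- states[v, ]
      if (any(change)) {
        shift <- 1L + as.integer(3 * runif(sum(change))) # uniform in {1,2,3}
        s[change] <- (s[change] - 1L + shift) %% 4L + 1L
      }
      states[w, ] <- s
      if (!phy_is_leaf(T, w)) { top <- top + 1L; stack_v[top] <- w; stack_e[top] <- e }
    }
  }
  mat <- states[leaves, , drop = FALSE]
  rownames(mat) <- T$label[leaves]
  structure(list(mat = mat, labels = T$label[leaves], alphabet = "dna",
                 symbols = .dna_symbols), class = "alignment")
}

#' Bootstrap an alignment by column resampling
#'
#' @param aln an `alignment`.
#' @return An `alignment` of the same dimensions whose columns are sampled
#'   uniformly with replacement from the original.
#' @export
bootstrap_alignment <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  L <- ncol(aln$mat)
  cols <- sample.int(L, L, replace = TRUE)
  out <- aln
  out$mat <- aln$mat[, cols, drop = FALSE]
  out
}

#' Simulation configuration for one grid cell
#'
#' @param n_taxa taxa per tree (>= 5).
#' @param interval branch perturbation interval.
#' @param f scale factor.
#' @param length alignment columns.
#' @param rates site-rate model.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa, interval = c(0.5, 2), f = 100, length = 1000,
                       rates = "exponential") {
  stopifnot(n_taxa >= 5, length >= 1)
  structure(list(n_taxa = n_taxa, interval = interval, f = f,
                 length = length, rates = rates), class = "sim_config")
}

#' Simulate a tree and alignment for one grid cell
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return A list with `tree` (the perturbed true `phylogeny`) and
#'   `alignment`.
#' @export
simulate_cell <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T0 <- yule_tree(cfg$n_taxa)
  T1 <- perturb_and_scale(T0, interval = cfg$interval, f = cfg$f)
  aln <- evolve_jc(T1, cfg$length, rates = cfg$rates)
  list(tree = T1, alignment = aln)
}

#' Coverage over the pure-birth simulation grid
#'
#' For every combination of scale factor and sequence length, simulates one
#' perturbed pure-birth tree with a Jukes-Cantor alignment, reconstructs it
#' with [build_tree()] under the default random-walk settings (5 quartets,
#' weighted majority, confidence threshold 30, 200-taxon neighbour-joining
#' guide, two reinsertion rounds), and reports the taxon coverage per cell
#' and its grand mean.
#'
#' @param n_taxa taxa per simulated tree (default 1000).
#' @param scales scale-factor grid (default `c(25, 50, 100, 200)`).
#' @param lengths sequence-length grid (default `c(250, 1000, 4000)`).
#' @param cfg walk configuration (default [walk_config()]).
#' @param guide guide configuration (default [guide_config()]).
#' @param rounds insertion rounds (default 3).
#' @param seed master seed; per-cell seeds are derived from it.
#' @param with_quality also compute RF quality of each reconstruction
#'   against the true tree (slower; default `FALSE`).
#' @param verbose print one line per cell.
#' @return A data.frame with one row per grid cell (`f`, `length`,
#'   `coverage`, optionally `rf`), with the grand mean coverage in the
#'   `"mean_coverage"` attribute.
#' @export
coverage_grid <- function(n_taxa = 1000, scales = c(25, 50, 100, 200),
                          lengths = c(250, 1000, 4000), cfg = walk_config(),
                          guide = guide_config(), rounds = 3, seed = 1,
                          with_quality = FALSE, verbose = FALSE) {
  set.seed(seed)
  cells <- expand.grid(f = scales, length = lengths)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  out <- cells
  out$coverage <- NA_real_
  if (with_quality) out$rf <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sim <- simulate_cell(sim_config(n_taxa, f = cells$f[i],
                                    length = cells$length[i]),
                         seed = cell_seeds[i])
    rep <- build_tree(sim$alignment, cfg = cfg, guide = guide, rounds = rounds)
    out$coverage[i] <- rep$coverage
    if (with_quality) out$rf[i] <- rf_quality(rep$tree, sim$tree)
    if (verbose)
      message(sprintf("f=%-4g len=%-5d coverage=%.1f%%", cells$f[i],
                      cells$length[i], rep$coverage))
  }
  attr(out, "mean_coverage") <- mean(out$coverage)
  out
}
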