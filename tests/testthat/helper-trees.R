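## Shared fixtures and independent oracles used across the suite.

## random unrooted binary topology with uniform branch lengths
random_tree <- function(n, lengths = TRUE) {
  tr <- ape::rtopology(n, rooted = FALSE)
  tr$tip.label <- paste0("t", seq_len(n))
  if (lengths) tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  else tr$edge.length <- NULL
  as_phylogeny(tr)
}

## independent split enumeration: for each internal edge of an ape tree,
## the tip set on one side, canonicalized like splits()
brute_splits <- function(T) {
  tr <- as_phylo(T)
  labs <- sort(tr$tip.label)
  bp <- ape::prop.part(tr)  # not used: prop.part needs rooted; do it by hand
  n <- ape::Ntip(tr)
  out <- character(0)
  for (i in seq_len(nrow(tr$edge))) {
    child <- tr$edge[i, 2L]
    if (child <= n) next
    tips <- tr$tip.label[unlist(phangorn::Descendants(tr, child, "tips"))]
    if (length(tips) < 2L || length(tips) > n - 2L) next
    blk <- if (labs[1L] %in% tips) sort(tips) else sort(setdiff(labs, tips))
    out <- c(out, paste(blk, collapse = ","))
  }
  unique(out)
}

## quartet topology by restriction: restrict the tree to the four taxa and
## read its single split
restriction_quartet <- function(T, taxa) {
  R <- restrict_taxa(T, taxa)
  sp <- splits(R)
  stopifnot(length(sp) == 1L)
  b1 <- sp[[1L]]$block1; b2 <- sp[[1L]]$block2
  paste0(paste(sort(b1), collapse = ","), "|", paste(sort(b2), collapse = ","))
}

## additive pairwise distances of a quartet tree with edge lengths
## (a, b, c, d, e) and topology WX|YZ, in the order WX, WY, WZ, XY, XZ, YZ
additive_quartet_dists <- function(a, b, c, d, e) {
  c(a + b, a + e + c, a + e + d, b + e + c, b + e + d, c + d)
}

## brute-force candidate pools: leaves of the phylogeny lying in each
## adjacency direction of node p, restricted to a set of region edges
brute_pools <- function(T, p, region) {
  in_reg <- logical(T$n_edges)
  in_reg[region] <- T$edge_alive[region]
  out <- vector("list", 3L)
  for (slot in 1:3) {
    e0 <- T$adj[slot, p]
    acc <- integer(0)
    if (e0 != 0L && in_reg[e0]) {
      seen_e <- e0
      frontier <- setdiff(T$edge_nodes[, e0], p)
      seen_n <- c(p, frontier)
      while (length(frontier) > 0L) {
        nxt <- integer(0)
        for (v in frontier) {
          for (e in T$adj[, v]) {
            if (e == 0L || !in_reg[e] || e %in% seen_e) next
            seen_e <- c(seen_e, e)
            w <- setdiff(T$edge_nodes[, e], v)
            if (!(w %in% seen_n)) { seen_n <- c(seen_n, w); nxt <- c(nxt, w) }
          }
        }
        frontier <- nxt
      }
      acc <- seen_n[seen_n != p & !is.na(T$label[seen_n])]
    }
    out[[slot]] <- sort(acc)
  }
  out
}

## JC pair simulation: two sequences at true distance t (rate-1 sites)
sim_jc_pair <- function(t, len) {
  p_sub <- 0.75 * (1 - exp(-4 / 3 * t))
  a <- sample.int(4L, len, replace = TRUE)
  b <- a
  hit <- runif(len) < p_sub
  shift <- 1L + as.integer(3 * runif(sum(hit)))
  b[hit] <- (b[hit] - 1L + shift) %% 4L + 1L
  syms <- c("A", "C", "G", "T")
  list(a = paste(syms[a], collapse = ""), b = paste(syms[b], collapse = ""))
}
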