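#' @importFrom stats runif rexp setNames
#' @importFrom utils combn
NULL

## Internal representation
##
## A phylogeny is an unrooted binary tree stored as a flat list:
##   adj        3 x node-capacity integer matrix of incident edge ids (0 = none)
##   edge_nodes 2 x edge-capacity integer matrix of endpoints (0 = dead edge)
##   edge_len   numeric per edge (NA when lengths are absent)
##   edge_alive logical per edge; subdivided edges are retired, never reused
##   label      character per node; NA for internal nodes (a node is a leaf
##              iff it carries a label)
##   n_nodes, n_edges  high-water marks for id allocation
## Node and edge ids are stable across insertions so that external indexes
## (the search tree) can reference them.

phy_empty <- function(node_cap, edge_cap) {
  structure(list(
    adj = matrix(0L, 3L, node_cap),
    edge_nodes = matrix(0L, 2L, edge_cap),
    edge_len = rep(NA_real_, edge_cap),
    edge_alive = logical(edge_cap),
    label = rep(NA_character_, node_cap),
    n_nodes = 0L,
    n_edges = 0L
  ), class = "phylogeny")
}

phy_grow <- function(T, extra_nodes, extra_edges) {
  nc <- ncol(T$adj); ec <- ncol(T$edge_nodes)
  if (T$n_nodes + extra_nodes > nc) {
    new_nc <- max(2L * nc, T$n_nodes + extra_nodes)
    adj <- matrix(0L, 3L, new_nc); adj[, seq_len(nc)] <- T$adj; T$adj <- adj
    T$label <- c(T$label, rep(NA_character_, new_nc - nc))
  }
  if (T$n_edges + extra_edges > ec) {
    new_ec <- max(2L * ec, T$n_edges + extra_edges)
    en <- matrix(0L, 2L, new_ec); en[, seq_len(ec)] <- T$edge_nodes; T$edge_nodes <- en
    T$edge_len <- c(T$edge_len, rep(NA_real_, new_ec - ec))
    T$edge_alive <- c(T$edge_alive, logical(new_ec - ec))
  }
  T
}

phy_add_node <- function(T, label = NA_character_) {
  T <- phy_grow(T, 1L, 0L)
  T$n_nodes <- T$n_nodes + 1L
  T$label[T$n_nodes] <- label
  T
}

## attaches edge id in the first free adjacency slot of both endpoints
phy_add_edge <- function(T, u, v, len = NA_real_) {
  T <- phy_grow(T, 0L, 1L)
  e <- T$n_edges + 1L
  T$n_edges <- e
  T$edge_nodes[, e] <- c(u, v)
  T$edge_len[e] <- len
  T$edge_alive[e] <- TRUE
  for (p in c(u, v)) {
    slot <- match(0L, T$adj[, p])
    if (is.na(slot)) stop("node ", p, " already has degree 3")
    T$adj[slot, p] <- e
  }
  T
}

phy_alive <- function(T) which(T$edge_alive[seq_len(T$n_edges)])

phy_degree <- function(T, v) sum(T$adj[, v] > 0L)

phy_other_end <- function(T, e, v) {
  en <- T$edge_nodes[, e]
  if (en[1L] == v) en[2L] else en[1L]
}

phy_leaves <- function(T) which(!is.na(T$label[seq_len(T$n_nodes)]))

phy_is_leaf <- function(T, v) !is.na(T$label[v])

#' Taxa present in a phylogeny
#'
#' @param T a `phylogeny` object.
#' @return Character vector of leaf labels (unsorted, in node-id order).
#' @export
taxa_labels <- function(T) {
  stopifnot(inherits(T, "phylogeny"))
  T$label[phy_leaves(T)]
}

#' Number of leaves of a phylogeny
#' @param T a `phylogeny` object.
#' @return Integer leaf count.
#' @export
n_leaves <- function(T) length(phy_leaves(T))

phy_node_of_label <- function(T, lab) {
  idx <- match(lab, T$label[seq_len(T$n_nodes)])
  if (anyNA(idx)) stop("unknown taxon: ", paste(lab[is.na(idx)], collapse = ", "))
  idx
}

phy_validate <- function(T) {
  leaves <- phy_leaves(T)
  L <- length(leaves)
  if (L < 3L) stop("phylogeny must have at least 3 leaves")
  if (anyDuplicated(T$label[leaves])) stop("duplicate leaf labels")
  deg <- colSums(T$adj[, seq_len(T$n_nodes), drop = FALSE] > 0L)
  if (any(deg[leaves] != 1L)) stop("leaf with degree != 1")
  internal <- setdiff(which(deg > 0L), leaves)
  if (any(deg[internal] != 3L)) stop("internal node with degree != 3")
  ne <- length(phy_alive(T))
  if (ne != 2L * L - 3L) stop("edge count ", ne, " != 2L-3 for L = ", L)
  invisible(T)
}

## ---- conversion to/from ape ----

#' Convert an ape `phylo` tree to a `phylogeny`
#'
#' The tree is unrooted first (a binary root is suppressed, its two incident
#' edges merged). Node labels (e.g. support values) are dropped with a warning.
#'
#' @param tr an [ape::read.tree()]-style `phylo` object.
#' @return A `phylogeny`.
#' @export
as_phylogeny <- function(tr) {
  if (inherits(tr, "phylogeny")) return(tr)
  stopifnot(inherits(tr, "phylo"))
  if (!is.null(tr$node.label) && any(nzchar(tr$node.label) & !is.na(tr$node.label))) {
    warning("internal node labels (e.g. support values) are ignored")
    tr$node.label <- NULL
  }
  if (ape::Ntip(tr) < 3L) stop("need at least 3 leaves")
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  L <- ape::Ntip(tr)
  nn <- tr$Nnode
  tab <- tabulate(c(tr$edge), nbins = L + nn)
  if (any(tab[seq_len(L)] != 1L)) stop("malformed tree: tip of degree != 1")
  if (any(tab[(L + 1L):(L + nn)] != 3L))
    stop("polytomies are not supported (beyond the unrooted trifurcation)")
  T <- phy_empty(L + nn, 2L * L - 3L)
  T$n_nodes <- L + nn
  T$label[seq_len(L)] <- tr$tip.label
  len <- if (is.null(tr$edge.length)) rep(NA_real_, nrow(tr$edge)) else tr$edge.length
  for (i in seq_len(nrow(tr$edge)))
    T <- phy_add_edge(T, tr$edge[i, 1L], tr$edge[i, 2L], len[i])
  phy_validate(T)
  T
}

#' Convert a `phylogeny` to an ape `phylo` tree
#'
#' @param T a `phylogeny`.
#' @return An unrooted `phylo` object (trifurcation at the basal node).
#' @export
as_phylo <- function(T) {
  stopifnot(inherits(T, "phylogeny"))
  leaves <- phy_leaves(T)
  L <- length(leaves)
  deg <- colSums(T$adj[, seq_len(T$n_nodes), drop = FALSE] > 0L)
  internal <- setdiff(which(deg == 3L), leaves)
  tip_id <- integer(T$n_nodes); tip_id[leaves] <- seq_len(L)
  int_id <- integer(T$n_nodes); int_id[internal] <- L + seq_along(internal)
  aid <- tip_id + int_id
  root <- if (length(internal) > 0L) internal[1L] else leaves[1L]
  ne <- 2L * L - 3L
  edge <- matrix(0L, ne, 2L); elen <- numeric(ne); k <- 0L
  # iterative DFS from root
  stack_v <- integer(ne + 1L); stack_e <- integer(ne + 1L); top <- 1L
  stack_v[1L] <- root; stack_e[1L] <- 0L
  while (top > 0L) {
    v <- stack_v[top]; via <- stack_e[top]; top <- top - 1L
    for (e in T$adj[, v]) {
      if (e == 0L || e == via) next
      w <- phy_other_end(T, e, v)
      k <- k + 1L
      edge[k, ] <- c(aid[v], aid[w]); elen[k] <- T$edge_len[e]
      if (!phy_is_leaf(T, w)) { top <- top + 1L; stack_v[top] <- w; stack_e[top] <- e }
    }
  }
  tr <- list(edge = edge[seq_len(k), , drop = FALSE], tip.label = T$label[leaves],
             Nnode = length(internal))
  if (!all(is.na(elen[seq_len(k)]))) tr$edge.length <- elen[seq_len(k)]
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

## ---- Newick I/O ----

#' Parse a Newick string into a phylogeny
#'
#' Rooted inputs are unrooted by suppressing the root. Polytomies other than
#' the outermost trifurcation of the standard unrooted representation are
#' rejected. Branch lengths are preserved when present; support values on
#' internal nodes are dropped with a warning.
#'
#' @param text a single Newick string (terminated by `;`).
#' @return A `phylogeny`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in Newick input")
  as_phylogeny(tr)
}

## smallest descendant label per direction, used for canonical output order
fmt_subtree <- function(T, v, via, with_lengths, digits) {
  if (phy_is_leaf(T, v)) {
    s <- T$label[v]
    if (with_lengths) s <- paste0(s, ":", format(T$edge_len[via], digits = digits))
    return(list(str = s, min = T$label[v]))
  }
  kids <- list()
  for (e in T$adj[, v]) {
    if (e == 0L || e == via) next
    kids[[length(kids) + 1L]] <- fmt_subtree(T, phy_other_end(T, e, v), e,
                                             with_lengths, digits)
  }
  mins <- vapply(kids, `[[`, "", "min")
  ord <- order(mins)
  s <- paste0("(", paste(vapply(kids[ord], `[[`, "", "str"), collapse = ","), ")")
  if (with_lengths && via > 0L)
    s <- paste0(s, ":", format(T$edge_len[via], digits = digits))
  list(str = s, min = min(mins))
}

#' Write a phylogeny as a canonical Newick string
#'
#' Output is deterministic for a fixed tree: the tree is printed from the
#' internal node adjacent to the lexicographically smallest taxon, with
#' children ordered by their smallest descendant label.
#'
#' @param T a `phylogeny`.
#' @param with_lengths emit branch lengths? Defaults to `TRUE` when the tree
#'   has any; trees without lengths are always printed topology-only.
#' @param digits significant digits for branch lengths.
#' @return A Newick string.
#' @export
format_newick <- function(T, with_lengths = NULL, digits = 10) {
  stopifnot(inherits(T, "phylogeny"))
  if (is.null(with_lengths))
    with_lengths <- any(!is.na(T$edge_len[phy_alive(T)]))
  labs <- taxa_labels(T)
  start_leaf <- phy_node_of_label(T, min(labs))
  root <- phy_other_end(T, T$adj[1L, start_leaf], start_leaf)
  if (phy_is_leaf(T, root)) { # 2-leaf degenerate never occurs (L >= 3)
    stop("degenerate phylogeny")
  }
  res <- fmt_subtree(T, root, 0L, with_lengths, digits)
  paste0(res$str, ";")
}

#' @export
print.phylogeny <- function(x, ...) {
  cat("phylogeny with", n_leaves(x), "leaves,", length(phy_alive(x)), "edges",
      if (any(!is.na(x$edge_len[phy_alive(x)]))) "(with branch lengths)" else
        "(topology only)", "\n")
  invisible(x)
}

## ---- splits ----

## DFS assigning, for every alive edge, the set of leaf labels on the far side
## (away from `root_leaf`). Returns a list indexed by edge id.
phy_edge_leafsets <- function(T) {
  leaves <- phy_leaves(T)
  root <- leaves[1L]
  sets <- vector("list", T$n_edges)
  rec <- function(v, via) {
    if (phy_is_leaf(T, v)) {
      sets[[via]] <<- T$label[v]
      return(T$label[v])
    }
    acc <- character(0)
    for (e in T$adj[, v]) {
      if (e == 0L || e == via) next
      acc <- c(acc, rec(phy_other_end(T, e, v), e))
    }
    if (via > 0L) sets[[via]] <<- acc
    acc
  }
  rec(phy_other_end(T, T$adj[1L, root], root), T$adj[1L, root])
  sets
}

split_key <- function(block, all_taxa) {
  # canonical key: the block containing the lexicographically smallest taxon
  if (min(all_taxa) %in% block) paste(sort(block), collapse = ",")
  else paste(sort(setdiff(all_taxa, block)), collapse = ",")
}

#' Non-trivial splits of a phylogeny
#'
#' One split (bipartition of the taxon set) per internal edge; a binary tree
#' on L leaves has exactly L - 3 of them.
#'
#' @param T a `phylogeny` with at least 4 leaves.
#' @return A named list of splits; each element is a list with components
#'   `block1` and `block2` (sorted character vectors, the block containing the
#'   lexicographically smallest taxon first). Names are canonical keys usable
#'   for set comparison.
#' @export
splits <- function(T) {
  stopifnot(inherits(T, "phylogeny"))
  if (n_leaves(T) < 4L) stop("splits need at least 4 leaves")
  all_taxa <- sort(taxa_labels(T))
  sets <- phy_edge_leafsets(T)
  out <- list()
  for (e in phy_alive(T)) {
    en <- T$edge_nodes[, e]
    if (phy_is_leaf(T, en[1L]) || phy_is_leaf(T, en[2L])) next
    far <- sets[[e]]
    b1 <- if (all_taxa[1L] %in% far) sort(far) else sort(setdiff(all_taxa, far))
    b2 <- setdiff(all_taxa, b1)
    out[[paste(b1, collapse = ",")]] <- list(block1 = b1, block2 = b2)
  }
  out
}

## ---- leaf path distances ----

## All-pairs leaf path-length matrix (labels as dimnames). unit = TRUE uses
## unit branch lengths (topological distances), which makes the four-point
## comparison exact for induced quartet topologies.
leaf_dist_matrix <- function(T, unit = FALSE) {
  tr <- as_phylo(T)
  if (unit || is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  D <- ape::dist.nodes(tr)[seq_len(ape::Ntip(tr)), seq_len(ape::Ntip(tr))]
  dimnames(D) <- list(tr$tip.label, tr$tip.label)
  D
}

#' Quartet topology induced by a tree on four taxa
#'
#' @param T a `phylogeny`.
#' @param taxa character vector of four leaf labels.
#' @return A canonical quartet key of the form `"A,B|C,D"`: taxa sorted within
#'   pairs, the pair containing the alphabetically smallest taxon first.
#' @export
induced_quartet <- function(T, taxa) {
  stopifnot(inherits(T, "phylogeny"), length(taxa) == 4L)
  nodes <- phy_node_of_label(T, taxa)
  # topological distances from each of the four taxa by BFS
  d <- matrix(0, 4L, 4L)
  for (i in 1:3) for (j in (i + 1L):4L) {
    d[i, j] <- d[j, i] <- phy_path_len(T, nodes[i], nodes[j], unit = TRUE)
  }
  top <- four_point(d[1, 2], d[1, 3], d[1, 4], d[2, 3], d[2, 4], d[3, 4])
  quartet_key(taxa, top)
}

## canonical quartet key from 4 taxa and topology index 1..3
## (1 = t1t2|t3t4, 2 = t1t3|t2t4, 3 = t1t4|t2t3)
quartet_key <- function(taxa, top) {
  pairs <- switch(top,
                  list(taxa[c(1, 2)], taxa[c(3, 4)]),
                  list(taxa[c(1, 3)], taxa[c(2, 4)]),
                  list(taxa[c(1, 4)], taxa[c(2, 3)]))
  p1 <- sort(pairs[[1L]]); p2 <- sort(pairs[[2L]])
  if (min(p2) < min(p1)) { tmp <- p1; p1 <- p2; p2 <- tmp }
  paste0(paste(p1, collapse = ","), "|", paste(p2, collapse = ","))
}

## path length between two nodes (tree BFS; O(n))
phy_path_len <- function(T, a, b, unit = FALSE) {
  if (a == b) return(0)
  n <- T$n_nodes
  dist <- rep(NA_real_, n)
  dist[a] <- 0
  queue <- integer(n); queue[1L] <- a; qh <- 1L; qt <- 1L
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    for (e in T$adj[, v]) {
      if (e == 0L) next
      w <- phy_other_end(T, e, v)
      if (!is.na(dist[w])) next
      step <- if (unit) 1 else T$edge_len[e]
      dist[w] <- dist[v] + step
      if (w == b) return(dist[w])
      queue[qt <- qt + 1L] <- w
    }
  }
  stop("nodes not connected")
}

## ---- attach & restrict ----

#' Attach a new leaf to an edge of a phylogeny
#'
#' The edge `(u, w)` is subdivided by a new internal node `m` and the new
#' taxon is attached to `m` by a pendant edge. When the tree carries branch
#' lengths, the two sub-edges share the original length according to
#' `split_fractions` and the pendant edge gets `pendant_length`.
#'
#' @param T a `phylogeny`.
#' @param edge id of an alive edge of `T`.
#' @param taxon new leaf label (must not already be present).
#' @param pendant_length length of the new pendant edge (`NA` when the tree is
#'   topology-only).
#' @param split_fractions length-2 nonnegative vector summing to 1; how the
#'   original edge length is divided between the `u`- and `w`-side sub-edges.
#' @return The enlarged `phylogeny`, with an attribute `"placement"`: a list
#'   with the ids of the new node (`m`), new leaf, the two sub-edges
#'   (`e_u`, `e_w`), the pendant edge, and the retired edge.
#' @export
attach_leaf <- function(T, edge, taxon, pendant_length = NA_real_,
                        split_fractions = c(0.5, 0.5)) {
  stopifnot(inherits(T, "phylogeny"))
  if (edge < 1L || edge > T$n_edges || !T$edge_alive[edge]) stop("edge not in tree")
  if (taxon %in% T$label[seq_len(T$n_nodes)]) stop("taxon already present: ", taxon)
  stopifnot(length(split_fractions) == 2L, all(split_fractions >= 0),
            abs(sum(split_fractions) - 1) < 1e-9)
  u <- T$edge_nodes[1L, edge]; w <- T$edge_nodes[2L, edge]
  old_len <- T$edge_len[edge]
  T <- phy_grow(T, 2L, 3L)
  T <- phy_add_node(T)              # m
  m <- T$n_nodes
  T <- phy_add_node(T, taxon)       # x
  x <- T$n_nodes
  # retire old edge, keeping adjacency slot positions of u and w stable
  T$edge_alive[edge] <- FALSE
  e_u <- T$n_edges + 1L; e_w <- T$n_edges + 2L; e_x <- T$n_edges + 3L
  T$n_edges <- T$n_edges + 3L
  T$edge_nodes[, e_u] <- c(u, m)
  T$edge_nodes[, e_w] <- c(m, w)
  T$edge_nodes[, e_x] <- c(m, x)
  T$edge_len[e_u] <- old_len * split_fractions[1L]
  T$edge_len[e_w] <- old_len * split_fractions[2L]
  T$edge_len[e_x] <- pendant_length
  T$edge_alive[c(e_u, e_w, e_x)] <- TRUE
  T$adj[match(edge, T$adj[, u]), u] <- e_u
  T$adj[match(edge, T$adj[, w]), w] <- e_w
  T$adj[, m] <- c(e_u, e_w, e_x)
  T$adj[1L, x] <- e_x
  attr(T, "placement") <- list(m = m, leaf = x, e_u = e_u, e_w = e_w,
                               pendant = e_x, old_edge = edge, u = u, w = w)
  T
}

#' Restrict a phylogeny to a subset of taxa
#'
#' Returns the binary topology induced on `S`; path lengths between retained
#' leaves are preserved when lengths are present (suppressed degree-2 nodes
#' merge their incident edge lengths additively).
#'
#' @param T a `phylogeny`.
#' @param S character vector of at least 3 leaf labels.
#' @return A `phylogeny` on the taxa in `S`.
#' @export
restrict_taxa <- function(T, S) {
  stopifnot(inherits(T, "phylogeny"))
  S <- unique(S)
  if (length(S) < 3L) stop("restriction needs at least 3 taxa")
  keep_nodes <- phy_node_of_label(T, S)
  n <- T$n_nodes
  # working adjacency as edge-id sets; prune then suppress
  deg <- colSums(T$adj[, seq_len(n), drop = FALSE] > 0L)
  alive_e <- T$edge_alive[seq_len(T$n_edges)]
  alive_n <- deg > 0L
  keep <- logical(n); keep[keep_nodes] <- TRUE
  adj <- T$adj[, seq_len(n), drop = FALSE]
  # iteratively remove unkept leaves / degree-1 internals
  repeat {
    drop <- which(alive_n & deg <= 1L & !keep)
    if (length(drop) == 0L) break
    for (v in drop) {
      alive_n[v] <- FALSE
      for (e in adj[, v]) {
        if (e == 0L || !alive_e[e]) next
        alive_e[e] <- FALSE
        o <- phy_other_end(T, e, v)
        adj[match(e, adj[, o]), o] <- 0L
        deg[o] <- deg[o] - 1L
      }
      adj[, v] <- 0L; deg[v] <- 0L
    }
  }
  # suppress degree-2 nodes: merge their two edges
  elen <- T$edge_len
  enodes <- T$edge_nodes
  repeat {
    v <- which(alive_n & deg == 2L & !keep)
    if (length(v) == 0L) break
    v <- v[1L]
    es <- adj[, v]; es <- es[es > 0L]
    a <- if (enodes[1L, es[1L]] == v) enodes[2L, es[1L]] else enodes[1L, es[1L]]
    b <- if (enodes[1L, es[2L]] == v) enodes[2L, es[2L]] else enodes[1L, es[2L]]
    # reuse es[1], retire es[2]
    enodes[, es[1L]] <- c(a, b)
    elen[es[1L]] <- elen[es[1L]] + elen[es[2L]]
    alive_e[es[2L]] <- FALSE
    adj[match(es[2L], adj[, b]), b] <- es[1L]
    adj[, v] <- 0L; alive_n[v] <- FALSE; deg[v] <- 0L
  }
  # compact into a fresh phylogeny
  nodes <- which(alive_n)
  L <- length(S)
  out <- phy_empty(length(nodes), 2L * L - 3L + 3L)
  id <- integer(n)
  for (v in nodes) { out <- phy_add_node(out, T$label[v]); id[v] <- out$n_nodes }
  seen <- logical(length(alive_e))
  for (v in nodes) for (e in adj[, v]) {
    if (e == 0L || seen[e]) next
    seen[e] <- TRUE
    out <- phy_add_edge(out, id[enodes[1L, e]], id[enodes[2L, e]], elen[e])
  }
  phy_validate(out)
  out
}
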