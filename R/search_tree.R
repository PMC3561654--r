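## Rooted ternary search tree over a phylogeny.
##
## A search node v owns a contiguous region r(v) of the phylogeny (a set of
## edge ids). Internal search nodes additionally hold a center s(v) — a
## phylogeny internal node inside r(v) — and up to three children, one per
## direction around s(v) that contains region edges. Search-tree leaves are
## in bijection with phylogeny edges. Each region has at most two boundary
## nodes (phylogeny nodes inside the region with incident edges outside it);
## this is maintained by always choosing the center on the path between the
## two boundary nodes when there are two.
##
## The structure is a mutable environment:
##   T          the phylogeny being indexed (updated in place on insertion)
##   kind       1 internal, 2 leaf (per search node id)
##   parent, depth, center
##   child      3 x cap matrix; column v slot s = child for the s-th
##              adjacency slot of center(v) (0 = empty direction)
##   region     list of edge-id vectors (retired edges may linger harmlessly;
##              they are unreachable through live adjacency)
##   ldir       list of 3-lists: phylogeny leaf ids per direction slot
##   bnodes     list of boundary-node vectors (length <= 2)
##   edge_leaf  phylogeny edge id -> search leaf id
##   center_of  phylogeny node id -> search node id it centers (0 = none)

st_new <- function(T, cap) {
  st <- new.env(parent = emptyenv())
  st$T <- T
  st$kind <- integer(cap)
  st$parent <- integer(cap)
  st$depth <- integer(cap)
  st$center <- integer(cap)
  st$child <- matrix(0L, 3L, cap)
  st$region <- vector("list", cap)
  st$ldir <- vector("list", cap)
  st$bnodes <- vector("list", cap)
  st$rver <- integer(cap)
  st$pcache <- new.env(parent = emptyenv(), size = 4096L)
  st$n_nodes <- 0L
  st$root <- 1L
  st$edge_leaf <- integer(ncol(T$edge_nodes))
  st$center_of <- integer(ncol(T$adj))
  class(st) <- c("search_tree", "environment")
  st
}

st_grow <- function(st, extra) {
  cap <- length(st$kind)
  if (st$n_nodes + extra <= cap) return(invisible(st))
  new_cap <- max(2L * cap, st$n_nodes + extra)
  pad <- new_cap - cap
  st$kind <- c(st$kind, integer(pad))
  st$parent <- c(st$parent, integer(pad))
  st$depth <- c(st$depth, integer(pad))
  st$center <- c(st$center, integer(pad))
  st$rver <- c(st$rver, integer(pad))
  ch <- matrix(0L, 3L, new_cap); ch[, seq_len(cap)] <- st$child; st$child <- ch
  length(st$region) <- new_cap
  length(st$ldir) <- new_cap
  length(st$bnodes) <- new_cap
  invisible(st)
}

st_alloc <- function(st) {
  st_grow(st, 1L)
  st$n_nodes <- st$n_nodes + 1L
  st$n_nodes
}

## grow index vectors keyed by phylogeny ids when the phylogeny grows
st_sync_caps <- function(st) {
  T <- st$T
  if (length(st$edge_leaf) < ncol(T$edge_nodes))
    st$edge_leaf <- c(st$edge_leaf,
                      integer(ncol(T$edge_nodes) - length(st$edge_leaf)))
  if (length(st$center_of) < ncol(T$adj))
    st$center_of <- c(st$center_of, integer(ncol(T$adj) - length(st$center_of)))
  invisible(st)
}

## ---- region decomposition helpers ----

## Orient a region (edge-id vector) from a start node: returns parent edge and
## parent node per region node, plus a preorder of nodes. Used for centroid
## computation and path finding. O(|region|).
region_orient <- function(T, region, start) {
  adj <- T$adj; en <- T$edge_nodes
  in_reg <- logical(T$n_edges)
  in_reg[region] <- T$edge_alive[region]
  n <- T$n_nodes
  par_edge <- integer(n); par_node <- integer(n)
  seen <- logical(n)
  order_nodes <- integer(length(region) + 1L)
  seen[start] <- TRUE
  order_nodes[1L] <- start
  qh <- 1L; qt <- 1L
  while (qh <= qt) {
    v <- order_nodes[qh]; qh <- qh + 1L
    for (e in adj[, v]) {
      if (e == 0L || !in_reg[e]) next
      w <- en[1L, e]; if (w == v) w <- en[2L, e]
      if (seen[w]) next
      seen[w] <- TRUE
      par_edge[w] <- e; par_node[w] <- v
      qt <- qt + 1L; order_nodes[qt] <- w
    }
  }
  list(order = order_nodes[seq_len(qt)], par_edge = par_edge,
       par_node = par_node, in_reg = in_reg)
}

#' Centroid of a region of a phylogeny
#'
#' Among the candidate nodes, returns the one minimizing the edge count of
#' its largest direction within the region (ties broken by smallest node id).
#' Used as the center of every search-tree node, which keeps the decomposition
#' depth logarithmic in the region size.
#'
#' @param T a `phylogeny`.
#' @param region integer vector of edge ids forming a contiguous region.
#' @param candidates optional integer vector of candidate nodes; defaults to
#'   all region nodes incident to at least two region edges.
#' @return A list with `node` (the centroid) and `max_part` (edge count of
#'   its largest direction).
#' @export
region_centroid <- function(T, region, candidates = NULL) {
  region <- region[T$edge_alive[region]]
  m <- length(region)
  stopifnot(m >= 1L)
  start <- T$edge_nodes[1L, region[1L]]
  ori <- region_orient(T, region, start)
  nodes <- ori$order
  ## edges below each node (within region), by reverse BFS order
  below <- integer(T$n_nodes)
  for (v in rev(nodes)) if (ori$par_edge[v] > 0L)
    below[ori$par_node[v]] <- below[ori$par_node[v]] + below[v] + 1L
  ## region degree
  rdeg <- integer(T$n_nodes)
  ends <- T$edge_nodes[, region, drop = FALSE]
  tab <- tabulate(c(ends), nbins = T$n_nodes)
  rdeg[seq_along(tab)] <- tab
  if (is.null(candidates)) candidates <- nodes[rdeg[nodes] >= 2L]
  stopifnot(length(candidates) >= 1L)
  best <- 0L; best_part <- .Machine$integer.max
  for (v in sort(candidates)) {
    parts <- integer(0)
    for (e in T$adj[, v]) {
      if (e == 0L || !ori$in_reg[e]) next
      w <- phy_other_end(T, e, v)
      down <- ori$par_node[w] == v && ori$par_edge[w] == e
      ## a child direction holds the child's subtree plus the connecting edge;
      ## the upward direction holds everything not below v
      parts <- c(parts, if (down) below[w] + 1L else m - below[v])
    }
    mp <- max(parts)
    if (mp < best_part) { best_part <- mp; best <- v }
  }
  list(node = best, max_part = best_part)
}

## path (as node vector) between nodes a and b inside the region
region_path <- function(T, region, a, b) {
  ori <- region_orient(T, region, a)
  path <- integer(0)
  v <- b
  while (v != a) {
    path <- c(path, v)
    v <- ori$par_node[v]
    if (v == 0L) stop("boundary nodes not connected inside region")
  }
  c(path, a)
}

## flood-fill the region from center: label every region node and edge with
## the adjacency slot (1..3) of the center edge it lies behind.
region_directions <- function(T, region, center) {
  adj <- T$adj; en <- T$edge_nodes
  region <- region[T$edge_alive[region]]
  in_reg <- logical(T$n_edges)
  in_reg[region] <- TRUE
  edge_slot <- integer(T$n_edges)
  node_slot <- integer(T$n_nodes)
  node_slot[center] <- -1L
  stack_v <- integer(length(region) + 3L)
  for (slot in 1:3) {
    e0 <- adj[slot, center]
    if (e0 == 0L || !in_reg[e0]) next
    edge_slot[e0] <- slot
    w0 <- en[1L, e0]; if (w0 == center) w0 <- en[2L, e0]
    if (node_slot[w0] != 0L) next  # parallel path cannot occur in a tree
    node_slot[w0] <- slot
    top <- 1L; stack_v[1L] <- w0
    while (top > 0L) {
      v <- stack_v[top]; top <- top - 1L
      for (e in adj[, v]) {
        if (e == 0L || !in_reg[e] || edge_slot[e] != 0L) next
        edge_slot[e] <- slot
        w <- en[1L, e]; if (w == v) w <- en[2L, e]
        if (node_slot[w] == 0L) { node_slot[w] <- slot; top <- top + 1L; stack_v[top] <- w }
      }
    }
  }
  list(edge_slot = edge_slot, node_slot = node_slot, region = region)
}

## ---- construction ----

#' Build the ternary search tree of a phylogeny
#'
#' Recursively decomposes the phylogeny into contiguous regions: each search
#' node's center is the centroid of its region (restricted to the path
#' between the region's two boundary nodes when both exist, which keeps every
#' boundary set at size at most 2); single-edge regions become search-tree
#' leaves, in bijection with the phylogeny's edges.
#'
#' @param T a `phylogeny` with at least 4 leaves.
#' @return A mutable `search_tree` environment (it carries its own copy of
#'   `T`, which subsequent insertions update in place).
#' @export
build_search_tree <- function(T) {
  stopifnot(inherits(T, "phylogeny"))
  if (n_leaves(T) < 4L) stop("search tree needs at least 4 leaves")
  phy_validate(T)
  st <- st_new(T, 4L * n_leaves(T))
  build_region(st, phy_alive(T), integer(0), 0L, 0L)
  st_audit(st)
  st
}

## recursive decomposition; returns the new search node id
build_region <- function(st, region, bnodes, parent, depth) {
  T <- st$T
  region <- region[T$edge_alive[region]]
  v <- st_alloc(st)
  st$parent[v] <- parent
  st$depth[v] <- depth
  st$region[[v]] <- region
  st$bnodes[[v]] <- bnodes
  if (length(region) == 1L) {
    st$kind[v] <- 2L
    st$edge_leaf[region] <- v
    return(v)
  }
  st$kind[v] <- 1L
  candidates <- if (length(bnodes) == 2L)
    region_path(T, region, bnodes[1L], bnodes[2L]) else NULL
  if (!is.null(candidates)) {
    ## keep only candidates with >= 2 incident region edges
    in_reg <- logical(T$n_edges); in_reg[region] <- TRUE
    rdeg <- vapply(candidates, function(p) {
      es <- T$adj[, p]; es <- es[es > 0L]; sum(in_reg[es])
    }, 0L)
    candidates <- candidates[rdeg >= 2L]
  }
  cen <- region_centroid(T, region, candidates)$node
  st$center[v] <- cen
  st$center_of[cen] <- v
  dirs <- region_directions(T, region, cen)
  for (slot in 1:3) {
    sub <- dirs$region[dirs$edge_slot[dirs$region] == slot]
    if (length(sub) == 0L) next
    sub_nodes_b <- bnodes[bnodes != cen & dirs$node_slot[bnodes] == slot]
    child_b <- c(cen, sub_nodes_b)
    stopifnot(length(child_b) <= 2L)  # boundary-size invariant
    ch <- build_region(st, sub, child_b, v, depth + 1L)
    st$child[slot, v] <- ch
  }
  ## leaves per direction slot
  reg_nodes <- which(dirs$node_slot > 0L)
  st$ldir[[v]] <- lapply(1:3, function(slot) {
    nd <- reg_nodes[dirs$node_slot[reg_nodes] == slot]
    nd[!is.na(T$label[nd])]
  })
  v
}

## ---- queries ----

#' Depth statistics of a search tree
#' @param st a `search_tree`.
#' @return A list with `max_depth`, `n_leaves`, `n_internal`.
#' @export
st_stats <- function(st) {
  n <- st$n_nodes
  list(max_depth = max(st$depth[seq_len(n)]),
       n_leaves = sum(st$kind[seq_len(n)] == 2L),
       n_internal = sum(st$kind[seq_len(n)] == 1L))
}

## consistency audit: bijection leaves <-> alive edges, boundary sizes
st_audit <- function(st) {
  T <- st$T
  alive <- phy_alive(T)
  leaves <- which(st$kind[seq_len(st$n_nodes)] == 2L)
  mapped <- st$edge_leaf[alive]
  if (any(mapped == 0L)) stop("edge without a search leaf")
  if (length(unique(mapped)) != length(alive) || length(leaves) != length(alive))
    stop("search leaves are not in bijection with phylogeny edges")
  for (v in which(st$kind[seq_len(st$n_nodes)] == 1L))
    if (length(st$bnodes[[v]]) > 2L) stop("boundary set larger than 2")
  invisible(TRUE)
}

## Pools of candidate representatives around phylogeny node p, one pool per
## adjacency slot of p. The search climbs ancestors of `vstart` until every
## direction pool reaches `min_pool` leaves or the root region is used
## (biased quartet choice). Returns list(pools = list of 3 leaf-id vectors,
## level = the search node whose region was used).
## ancestor-or-self test on the search tree
st_is_ancestor <- function(st, anc, v) {
  da <- st$depth[anc]
  while (st$depth[v] > da) v <- st$parent[v]
  v == anc
}

## Pools of candidate representatives around internal phylogeny node p for a
## query positioned at search node vstart, under the biased-choice climb.
##
## Every internal phylogeny node is the center of exactly one search node
## (edges incident to a node are only separated by splitting at that node),
## so for any level strictly below center_of[p] the region lies entirely in
## one direction of p and at least one pool is empty: the first level that
## can satisfy the rule is center_of[p], whose per-direction pools are the
## precomputed ldir leaf lists. Climbing further, each ancestor level adds
## exactly the leaves of that ancestor's sibling child regions, and they all
## lie in a single direction from p (behind the ancestor's center), found by
## walking the search tree from a search leaf up to the chain. No region
## traversal is needed at query time.
st_pools <- function(st, vstart, p, min_pool) {
  c_sid <- st$center_of[p]
  if (c_sid == 0L) stop("pools are defined around internal (center) nodes")
  ldir <- st$ldir
  parent <- st$parent
  pools <- ldir[[c_sid]]
  levels <- c_sid
  qdir <- NA_integer_
  ## lowest admissible level: vstart when it sits above c_sid, else c_sid
  first <- if (st_is_ancestor(st, vstart, c_sid)) vstart else c_sid
  dfirst <- st$depth[first]
  y <- c_sid
  repeat {
    if (st$depth[y] <= dfirst && all(lengths(pools) >= min_pool)) break
    yn <- parent[y]
    if (yn == 0L) break
    slot_chain <- match(y, st$child[, yn])
    dirp <- chain_direction(st, st$center[yn], levels, qdir, c_sid)
    for (s in (1:3)[-slot_chain]) {
      add <- ldir[[yn]][[s]]
      if (length(add)) pools[[dirp]] <- c(pools[[dirp]], add)
    }
    levels <- c(levels, yn)
    qdir <- c(qdir, dirp)
    y <- yn
  }
  list(pools = pools, level = y, levels = levels)
}

## Direction from p (center of levels[1]) in which the center q of the next
## chain level lies: walk up from the search leaf of one of q's region edges
## until the chain is met; meeting it at the base gives the child slot, and
## meeting it higher means q lies behind that level's own addition direction.
chain_direction <- function(st, q, levels, qdir, c_sid) {
  parent <- st$parent
  for (e in st$T$adj[, q]) {
    if (e == 0L) next
    v <- st$edge_leaf[e]
    if (v == 0L) next
    prev <- 0L
    while (v != 0L) {
      j <- match(v, levels)
      if (!is.na(j)) {
        if (j == 1L) return(match(prev, st$child[, c_sid]))
        return(qdir[j])
      }
      prev <- v
      v <- parent[v]
    }
  }
  stop("internal error: chain direction not found")
}

#' Sample a representative taxon for a direction around a search node
#'
#' Implements the biased choice of quartets: the candidate pool for each of
#' the three directions around the node's center is restricted to the region
#' of the lowest ancestor at which every direction holds at least
#' `min_pool` candidate leaves (falling back to the whole phylogeny at the
#' root). The representative is sampled uniformly from the pool.
#'
#' @param st a `search_tree`.
#' @param v a search node id (internal).
#' @param direction 1, 2 or 3 (adjacency slot of the node's center).
#' @param min_pool minimum pool size per direction (the bias rule constant;
#'   default 20).
#' @return A taxon label.
#' @export
representatives <- function(st, v, direction, min_pool = 20) {
  stopifnot(st$kind[v] == 1L, direction %in% 1:3)
  res <- st_pools(st, v, st$center[v], min_pool)
  pool <- res$pools[[direction]]
  if (length(pool) == 0L) stop("no candidate leaves in direction ", direction)
  st$T$label[pool[sample.int(length(pool), 1L)]]
}

## pool sizes per direction at a node (exposed for tests)
st_pool_sizes <- function(st, v, min_pool = 20) {
  res <- st_pools(st, v, st$center[v], min_pool)
  lengths(res$pools)
}

## ---- incremental update ----

#' Expand a search-tree leaf after a leaf insertion in the phylogeny
#'
#' After [attach_leaf()] subdivides the phylogeny edge owned by search leaf
#' `leaf_id`, the leaf becomes an internal search node centered on the new
#' phylogeny node, with one child leaf per new edge; all ancestor regions are
#' enlarged accordingly and the edge-to-leaf index is updated.
#'
#' @param st a `search_tree` whose phylogeny was updated in place.
#' @param leaf_id the search leaf owning the subdivided edge.
#' @param placement the `"placement"` attribute returned by [attach_leaf()].
#' @return The search tree, invisibly (modified in place).
#' @export
expand_leaf <- function(st, leaf_id, placement) {
  T <- st$T
  pl <- placement
  if (st$kind[leaf_id] != 2L || st$region[[leaf_id]][1L] != pl$old_edge)
    stop("stale search leaf: edge no longer matches")
  st_sync_caps(st)
  m <- pl$m
  new_edges <- c(pl$e_u, pl$e_w, pl$pendant)
  ## the leaf becomes internal, centered on m
  st$kind[leaf_id] <- 1L
  st$center[leaf_id] <- m
  st$center_of[m] <- leaf_id
  st$region[[leaf_id]] <- new_edges
  st$bnodes[[leaf_id]] <-
    c(pl$u, pl$w)[c(!phy_is_leaf(T, pl$u), !phy_is_leaf(T, pl$w))]
  ldir <- vector("list", 3L)
  for (slot in 1:3) {
    e <- T$adj[slot, m]
    o <- phy_other_end(T, e, m)
    ch <- st_alloc(st)
    st$kind[ch] <- 2L
    st$parent[ch] <- leaf_id
    st$depth[ch] <- st$depth[leaf_id] + 1L
    st$region[[ch]] <- e
    st$bnodes[[ch]] <- c(m, o)[c(TRUE, !phy_is_leaf(T, o))]
    st$child[slot, leaf_id] <- ch
    st$edge_leaf[e] <- ch
    ldir[[slot]] <- if (phy_is_leaf(T, o)) o else integer(0)
  }
  st$ldir[[leaf_id]] <- ldir
  st$rver[leaf_id] <- st$rver[leaf_id] + 1L
  ## fix direction-edge references of centers at the old endpoints: adjacency
  ## slots were kept stable by attach_leaf, so child slots still align.
  ## enlarge ancestor regions and leaf-direction lists
  x <- pl$leaf
  ch <- leaf_id
  a <- st$parent[leaf_id]
  while (a != 0L) {
    st$region[[a]] <- c(st$region[[a]], new_edges)
    st$rver[a] <- st$rver[a] + 1L
    slot <- match(ch, st$child[, a])
    st$ldir[[a]][[slot]] <- c(st$ldir[[a]][[slot]], x)
    ch <- a
    a <- st$parent[a]
  }
  invisible(st)
}

#' @export
print.search_tree <- function(x, ...) {
  s <- st_stats(x)
  cat("search tree:", s$n_internal, "internal nodes,", s$n_leaves,
      "leaves, max depth", s$max_depth, "\n")
  invisible(x)
}

## indented text dump (diagnostics)
st_dump <- function(st, v = st$root, indent = 0) {
  pad <- strrep("  ", indent)
  if (st$kind[v] == 2L) {
    e <- st$region[[v]][1L]
    cat(pad, "leaf sid=", v, " edge=", e, "\n", sep = "")
  } else {
    cat(pad, "node sid=", v, " center=", st$center[v], " |region|=",
        sum(st$T$edge_alive[st$region[[v]]]), " bnodes=",
        paste(st$bnodes[[v]], collapse = ","), "\n", sep = "")
    for (slot in 1:3) if (st$child[slot, v] != 0L)
      st_dump(st, st$child[slot, v], indent + 1L)
  }
  invisible(NULL)
}
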