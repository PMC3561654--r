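## The error-tolerant random walk over the search tree.
##
## At an internal search node the walk first checks the (at most two)
## boundaries of the current region: a node query at each boundary node whose
## winning direction points outside the region sends the walk to the parent.
## Otherwise a node query at the region's center picks the child to descend
## into. At a search-tree leaf (a phylogeny edge), confirmation queries at the
## edge's internal endpoints increment a counter when they point back at the
## edge and decrement it otherwise; the walk moves up only at counter zero and
## the taxon is accepted once the counter reaches the confidence threshold.

#' Random-walk configuration
#'
#' @param k quartet queries per node query (default 5).
#' @param voting `"wm"` (weighted majority: weights of quartets pointing in
#'   the same direction are summed and the largest total wins) or `"wta"`
#'   (winner takes all: the single highest-weight quartet decides).
#' @param ell confidence threshold: number of trailing steps the walk must
#'   spend at a leaf before the taxon is inserted there (default 30).
#' @param step_budget maximum steps per walk; defaults to
#'   `ceiling(6 * log2(max(n_edges, 2))) + ell`, set at walk time when `NULL`.
#' @param repeats independent walks per taxon; the taxon is accepted only if
#'   all walks accept at the same leaf (default 1; 2 reproduces the
#'   repeated-walk variant).
#' @param min_pool minimum representative pool size per direction for the
#'   biased quartet choice (default 20).
#' @param early_accept accept as soon as the leaf counter reaches `ell`
#'   (default); when `FALSE` only the literal trailing-window rule at budget
#'   exhaustion applies.
#' @return A `walk_config` list.
#' @export
walk_config <- function(k = 5, voting = c("wm", "wta"), ell = 30,
                        step_budget = NULL, repeats = 1, min_pool = 20,
                        early_accept = TRUE) {
  voting <- match.arg(voting)
  stopifnot(k >= 1, ell >= 0, repeats >= 1, min_pool >= 1)
  if (!is.null(step_budget)) stopifnot(step_budget > ell)
  structure(list(k = as.integer(k), voting = voting, ell = as.integer(ell),
                 step_budget = step_budget, repeats = as.integer(repeats),
                 min_pool = as.integer(min_pool),
                 early_accept = isTRUE(early_accept)),
            class = "walk_config")
}

cfg_budget <- function(cfg, st) {
  if (!is.null(cfg$step_budget)) return(as.integer(cfg$step_budget))
  ne <- length(phy_alive(st$T))
  as.integer(ceiling(6 * log2(max(ne, 2))) + cfg$ell)
}

## sample that never interprets a length-1 pool as 1:n
sample_pool <- function(pool, k) {
  if (length(pool) == 1L) rep.int(pool, k) else sample(pool, k, replace = TRUE)
}

## One node query: k quartet queries q(x, a1, a2, a3) with representatives
## drawn from the three pools, aggregated by the voting scheme.
## pools: list of 3 integer vectors of phylogeny leaf node ids (slot-aligned).
## Returns list(slot, totals): winning adjacency slot (1..3) and the per-slot
## vote totals.
vote_at_node <- function(st, oracle, xi, pool_idx, cfg) {
  k <- cfg$k
  if (any(lengths(pool_idx) == 0L))
    stop("internal error: empty representative pool")
  R <- cbind(sample_pool(pool_idx[[1L]], k),
             sample_pool(pool_idx[[2L]], k),
             sample_pool(pool_idx[[3L]], k))
  ## forbid exact repeats of a taxon triple within one vote (best effort)
  for (attempt in 1:10) {
    key <- (R[, 1L] * 2^21 + R[, 2L]) * 2^21 + R[, 3L]
    dup <- duplicated(key)
    if (!any(dup)) break
    if (all(lengths(pool_idx) == 1L)) { R <- R[!dup, , drop = FALSE]; break }
    nd <- sum(dup)
    R[dup, ] <- cbind(sample_pool(pool_idx[[1L]], nd),
                      sample_pool(pool_idx[[2L]], nd),
                      sample_pool(pool_idx[[3L]], nd))
  }
  res <- oracle$vote_batch(xi, R)
  ## ABSENT answers: up to 10 resamples, then zero-weight abstention
  for (attempt in 1:10) {
    ab <- which(is.na(res$dir))
    if (length(ab) == 0L) break
    R2 <- cbind(sample_pool(pool_idx[[1L]], length(ab)),
                sample_pool(pool_idx[[2L]], length(ab)),
                sample_pool(pool_idx[[3L]], length(ab)))
    r2 <- oracle$vote_batch(xi, R2)
    res$dir[ab] <- r2$dir
    res$w[ab] <- r2$w
  }
  keep <- !is.na(res$dir)
  totals <- numeric(3)
  if (cfg$voting == "wm") {
    for (d in 1:3) totals[d] <- sum(res$w[keep & res$dir == d])
    top <- max(totals)
    if (top <= 0) return(list(slot = sample.int(3L, 1L), totals = totals))
    cand <- which(totals == top)
  } else { # winner takes all
    if (!any(keep) || max(res$w[keep]) <= 0)
      return(list(slot = sample.int(3L, 1L), totals = totals))
    wk <- ifelse(keep, res$w, -Inf)
    top <- max(wk)
    cand <- unique(res$dir[wk == top])
    totals[cand] <- top
  }
  slot <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  list(slot = slot, totals = totals)
}

## Pools around phylogeny node p for a walk positioned at search node v,
## mapped to oracle taxon indices. Two cache layers: a per-walk memo (the
## tree cannot change during a walk) and a cross-walk cache on the search
## tree, validated against the region version stamps of every level the
## bias-rule climb inspected (insertions bump the stamps of all regions they
## enlarge, invalidating exactly the affected pools).
walk_pools <- function(st, v, p, cfg, memo, oracle) {
  key <- paste0(v, ".", p)
  got <- memo[[key]]
  if (!is.null(got)) return(got)
  cached <- st$pcache[[key]]
  if (!is.null(cached) && identical(st$rver[cached$levels], cached$vers)) {
    memo[[key]] <- cached$idx
    return(cached$idx)
  }
  res <- st_pools(st, v, p, cfg$min_pool)
  pool_idx <- lapply(res$pools, function(pp) {
    if (length(pp) == 0L) return(integer(0))
    idx <- match(st$T$label[pp], oracle$taxa)
    idx[!is.na(idx)]
  })
  st$pcache[[key]] <- list(idx = pool_idx, levels = res$levels,
                           vers = st$rver[res$levels])
  memo[[key]] <- pool_idx
  pool_idx
}

#' Node query at an internal search node
#'
#' Asks `k` quartet queries pairing the new taxon with one representative per
#' direction around the node's center and aggregates them by the configured
#' voting scheme.
#'
#' @param x new taxon label (not yet in the phylogeny).
#' @param st a `search_tree`.
#' @param v internal search node id.
#' @param oracle a `quartet_oracle` containing `x`.
#' @param cfg a [walk_config()].
#' @return A list with `direction` (winning adjacency slot 1..3 of the
#'   center), `child` (the corresponding child search node, 0 when that
#'   direction holds no region edges — evidence the taxon lies outside the
#'   region), and `totals` (per-direction vote totals).
#' @export
node_vote <- function(x, st, v, oracle, cfg = walk_config()) {
  stopifnot(st$kind[v] == 1L)
  xi <- match(x, oracle$taxa)
  if (is.na(xi)) stop("unknown taxon: ", x)
  memo <- new.env(parent = emptyenv())
  pools <- walk_pools(st, v, st$center[v], cfg, memo, oracle)
  r <- vote_at_node(st, oracle, xi, pools, cfg)
  list(direction = r$slot, child = st$child[r$slot, v], totals = r$totals)
}

## boundary check at internal search node v; TRUE = move up.
## A node query is asked at each boundary node; if its winning direction
## leaves the region, the walk retreats to the parent.
boundary_says_up <- function(st, v, xi, oracle, cfg, memo) {
  bs <- st$bnodes[[v]]
  if (length(bs) == 0L) return(FALSE)
  region <- st$region[[v]]
  T <- st$T
  for (b in bs) {
    pools <- walk_pools(st, v, b, cfg, memo, oracle)
    r <- vote_at_node(st, oracle, xi, pools, cfg)
    e_win <- T$adj[r$slot, b]
    if (!(e_win %in% region)) return(TRUE)
  }
  FALSE
}

#' Boundary check at an internal search node
#'
#' @inheritParams node_vote
#' @param v internal, non-root search node id (the root has no boundary and
#'   always stays).
#' @return `"stay"` or `"up"`.
#' @export
boundary_check <- function(x, st, v, oracle, cfg = walk_config()) {
  stopifnot(st$kind[v] == 1L)
  xi <- match(x, oracle$taxa)
  if (is.na(xi)) stop("unknown taxon: ", x)
  memo <- new.env(parent = emptyenv())
  if (boundary_says_up(st, v, xi, oracle, cfg, memo)) "up" else "stay"
}

## leaf confirmation: node queries at the internal endpoints of the leaf's
## edge; confirmed iff every performed query points back at the edge.
leaf_confirms <- function(st, v, xi, oracle, cfg, memo) {
  T <- st$T
  e <- st$region[[v]][1L]
  for (p in T$edge_nodes[, e]) {
    if (phy_is_leaf(T, p)) next
    pools <- walk_pools(st, v, p, cfg, memo, oracle)
    r <- vote_at_node(st, oracle, xi, pools, cfg)
    if (T$adj[r$slot, p] != e) return(FALSE)
  }
  TRUE
}

#' Run the random walk for one new taxon
#'
#' Starts at the search-tree root. At an internal node the boundary check may
#' send the walk to the parent; otherwise a node query at the center chooses
#' the child (a vote for a direction without region edges also retreats).
#' At a leaf, confirmation queries drive a counter: the walk is accepted at
#' the leaf when the counter reaches the confidence threshold `ell`, and
#' retreats when a disconfirming query finds the counter at zero. A walk that
#' exhausts its step budget is accepted only if it sits at a leaf where it
#' spent the entire trailing window of `ell` steps.
#'
#' @inheritParams node_vote
#' @return A `walk_result`: list with `terminal` (search node id), `accepted`,
#'   `steps`, and `trace` (node id per step).
#' @export
random_walk <- function(x, st, oracle, cfg = walk_config()) {
  xi <- match(x, oracle$taxa)
  if (is.na(xi)) stop("unknown taxon: ", x)
  if (x %in% taxa_labels(st$T)) stop("taxon already in the phylogeny: ", x)
  budget <- cfg_budget(cfg, st)
  memo <- new.env(parent = emptyenv())
  cur <- st$root
  counter <- 0L
  trace <- integer(budget)
  steps <- 0L
  accepted <- FALSE
  while (steps < budget) {
    steps <- steps + 1L
    if (st$kind[cur] == 1L) {
      if (boundary_says_up(st, cur, xi, oracle, cfg, memo)) {
        cur <- st$parent[cur]
        counter <- 0L
      } else {
        pools <- walk_pools(st, cur, st$center[cur], cfg, memo, oracle)
        r <- vote_at_node(st, oracle, xi, pools, cfg)
        ch <- st$child[r$slot, cur]
        cur <- if (ch != 0L) ch else if (st$parent[cur] != 0L) st$parent[cur] else cur
        counter <- 0L
      }
    } else {
      if (leaf_confirms(st, cur, xi, oracle, cfg, memo)) {
        counter <- counter + 1L
        if (cfg$early_accept && counter >= cfg$ell) {
          trace[steps] <- cur
          accepted <- TRUE
          break
        }
      } else if (counter == 0L) {
        cur <- st$parent[cur]
      } else {
        counter <- counter - 1L
      }
    }
    trace[steps] <- cur
  }
  trace <- trace[seq_len(steps)]
  if (!accepted) {
    accepted <- st$kind[cur] == 2L && steps >= cfg$ell &&
      all(trace[(steps - cfg$ell + 1L):steps] == cur)
  }
  structure(list(terminal = cur, accepted = accepted, steps = steps,
                 trace = trace), class = "walk_result")
}

#' Repeat the random walk and require agreement
#'
#' Runs `cfg$repeats` independent walks; the taxon is accepted only when all
#' of them are accepted at the same search leaf.
#'
#' @inheritParams node_vote
#' @return A `walk_result` (the last walk, with `accepted` reflecting the
#'   agreement rule).
#' @export
repeated_walk <- function(x, st, oracle, cfg = walk_config()) {
  res <- random_walk(x, st, oracle, cfg)
  if (cfg$repeats == 1L) return(res)
  for (i in seq_len(cfg$repeats - 1L)) {
    res2 <- random_walk(x, st, oracle, cfg)
    if (!(res$accepted && res2$accepted && res2$terminal == res$terminal)) {
      res2$accepted <- FALSE
      return(res2)
    }
    res <- res2
  }
  res
}

#' Forced descent to a leaf
#'
#' From a walk's terminal node, descends using center node queries only (no
#' boundary checks, no backtracking): among directions that hold region
#' edges, the one with the highest vote total is taken. Always ends at a
#' search leaf.
#'
#' @inheritParams node_vote
#' @param from search node id to start from (e.g. a walk's terminal node).
#' @return The reached search leaf id.
#' @export
force_descent <- function(x, st, oracle, cfg = walk_config(), from = st$root) {
  xi <- match(x, oracle$taxa)
  if (is.na(xi)) stop("unknown taxon: ", x)
  memo <- new.env(parent = emptyenv())
  cur <- from
  while (st$kind[cur] == 1L) {
    pools <- walk_pools(st, cur, st$center[cur], cfg, memo, oracle)
    r <- vote_at_node(st, oracle, xi, pools, cfg)
    kids <- st$child[, cur]
    if (kids[r$slot] != 0L) {
      cur <- kids[r$slot]
    } else {
      ## restrict to directions that actually hold region edges
      ok <- which(kids != 0L)
      best <- ok[which.max(r$totals[ok])]
      cur <- kids[best]
    }
  }
  cur
}
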