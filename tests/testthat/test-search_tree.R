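test_that("the search tree of a 4-leaf tree covers all five edges", {
  T <- parse_newick("(A,B,(C,D));")
  st <- build_search_tree(T)
  s <- st_stats(st)
  expect_equal(s$n_leaves, 5L)
  ## a 4-leaf tree decomposes with two internal search nodes (one per
  ## internal phylogeny node; each centers exactly one node)
  expect_equal(s$n_internal, 2L)
  expect_error(build_search_tree(parse_newick("(A,B,C);")), "at least 4")
})

test_that("search leaves are in bijection with phylogeny edges", {
  set.seed(2)
  for (n in c(10, 40, 80)) {
    T <- random_tree(n, lengths = FALSE)
    st <- build_search_tree(T)
    expect_equal(st_stats(st)$n_leaves, 2L * n - 3L)
    expect_silent(quartetwalk:::st_audit(st))
  }
})

test_that("centroid decomposition keeps the depth logarithmic", {
  set.seed(6)
  for (i in 1:8) {
    T <- random_tree(500, lengths = FALSE)
    st <- build_search_tree(T)
    ne <- 2L * 500L - 3L
    expect_lte(st_stats(st)$max_depth, 2 * log2(ne) + 4)
  }
})

test_that("region_centroid agrees with exhaustive minimization", {
  set.seed(13)
  for (i in 1:10) {
    T <- random_tree(20, lengths = FALSE)
    region <- quartetwalk:::phy_alive(T)
    m <- length(region)
    leaves <- quartetwalk:::phy_leaves(T)
    internal <- setdiff(seq_len(T$n_nodes), leaves)
    ## brute force: direction sizes by component flood for every candidate
    best <- NULL; best_part <- Inf
    for (v in sort(internal)) {
      parts <- lengths(lapply(brute_pools(T, v, region), function(x) x))
      ## count edges, not leaves: recompute via flood edge counts
      sizes <- integer(0)
      for (slot in 1:3) {
        e0 <- T$adj[slot, v]
        if (e0 == 0L) next
        ## edges in this direction = m minus edges in the other directions;
        ## flood by removing v: use distances through e0
        cnt <- 0L
        seen_e <- e0; frontier <- setdiff(T$edge_nodes[, e0], v)
        while (length(frontier) > 0L) {
          nxt <- integer(0)
          for (u in frontier) for (e in T$adj[, u]) {
            if (e == 0L || e %in% seen_e) next
            seen_e <- c(seen_e, e)
            nxt <- c(nxt, setdiff(T$edge_nodes[, e], u))
          }
          frontier <- nxt
        }
        sizes <- c(sizes, length(seen_e))
      }
      if (max(sizes) < best_part) { best_part <- max(sizes); best <- v }
    }
    got <- region_centroid(T, region)
    expect_equal(got$node, best)
    expect_equal(got$max_part, best_part)
  }
  ## path-like region: the middle node of a 7-edge path
  cat7 <- parse_newick("(A,(B,(C,(D,(E,(F,(G,H)))))));")
  expect_true(region_centroid(cat7, quartetwalk:::phy_alive(cat7))$max_part <=
                ceiling((2 * 8 - 3) / 2) + 1)
})

test_that("boundary sets never exceed two nodes", {
  set.seed(91)
  for (i in 1:6) {
    T <- random_tree(60, lengths = FALSE)
    st <- build_search_tree(T)
    for (v in seq_len(st$n_nodes))
      expect_lte(length(st$bnodes[[v]]), 2L)
  }
})

test_that("representative pools match brute-force leaf enumeration", {
  set.seed(37)
  for (i in 1:5) {
    T <- random_tree(50, lengths = FALSE)
    st <- build_search_tree(T)
    internals <- which(st$kind[seq_len(st$n_nodes)] == 1L)
    for (v in sample(internals, 10)) {
      p <- st$center[v]
      for (mp in c(1L, 20L)) {
        res <- quartetwalk:::st_pools(st, v, p, mp)
        expected <- brute_pools(st$T, p, st$region[[res$level]])
        for (slot in 1:3)
          expect_setequal(res$pools[[slot]], expected[[slot]])
        ## the rule: every pool at the chosen level reaches the minimum, or
        ## the level is the root
        sizes <- lengths(res$pools)
        expect_true(all(sizes >= mp) || res$level == st$root)
        ## and the level below (on the climb path) fails the rule
        if (res$level != v && length(res$levels) > 1L) {
          below <- res$levels[length(res$levels) - 1L]
          sizes_below <- lengths(brute_pools(st$T, p, st$region[[below]]))
          expect_true(any(sizes_below < mp))
        }
      }
    }
  }
})

test_that("min_pool = 1 keeps representatives in the tightest region", {
  set.seed(41)
  T <- random_tree(30, lengths = FALSE)
  st <- build_search_tree(T)
  internals <- which(st$kind[seq_len(st$n_nodes)] == 1L)
  for (v in internals) {
    res <- quartetwalk:::st_pools(st, v, st$center[v], 1L)
    ## every internal node's own region already has >= 1 leaf per direction
    ## exactly when its ldir pools are all non-empty
    if (all(lengths(st$ldir[[v]]) >= 1L)) expect_equal(res$level, v)
  }
  ## representatives() samples from the right direction
  v <- internals[which.max(st$depth[internals])]
  for (slot in 1:3) {
    res <- quartetwalk:::st_pools(st, v, st$center[v], 20L)
    rep_taxon <- representatives(st, v, slot, min_pool = 20)
    expect_true(rep_taxon %in% st$T$label[res$pools[[slot]]])
  }
})

test_that("expand_leaf maintains the bijection and region bookkeeping", {
  set.seed(3)
  T <- random_tree(12, lengths = FALSE)
  st <- build_search_tree(T)
  for (i in 1:100) {
    alive <- quartetwalk:::phy_alive(st$T)
    e <- sample(alive, 1)
    leaf <- st$edge_leaf[e]
    old_depth <- st$depth[leaf]
    T2 <- attach_leaf(st$T, e, paste0("x", i))
    pl <- attr(T2, "placement")
    st$T <- T2
    n_before <- st_stats(st)$n_leaves
    expand_leaf(st, leaf, pl)
    expect_equal(st_stats(st)$n_leaves, n_before + 2L)
    expect_equal(st$depth[st$child[1, leaf]], old_depth + 1L)
  }
  expect_silent(quartetwalk:::st_audit(st))
  ## pools still match brute force after the insertions
  internals <- which(st$kind[seq_len(st$n_nodes)] == 1L)
  for (v in sample(internals, 15)) {
    res <- quartetwalk:::st_pools(st, v, st$center[v], 20L)
    expected <- brute_pools(st$T, st$center[v], st$region[[res$level]])
    for (slot in 1:3)
      expect_setequal(res$pools[[slot]], expected[[slot]])
  }
  ## a stale leaf id is rejected
  alive <- quartetwalk:::phy_alive(st$T)
  e <- sample(alive, 1)
  leaf <- st$edge_leaf[e]
  T3 <- attach_leaf(st$T, e, "stale_probe")
  pl <- attr(T3, "placement")
  st$T <- T3
  expand_leaf(st, leaf, pl)
  expect_error(expand_leaf(st, leaf, pl), "stale")
})
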