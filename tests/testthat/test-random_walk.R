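## walks on a guide tree with a taxon held out, driven by the noisy oracle
setup_holdout <- function(n, p_err = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  full <- yule_tree(n)
  labs <- taxa_labels(full)
  x <- labs[n]
  guide <- restrict_taxa(full, labs[-n])
  guide$edge_len[] <- NA_real_
  st <- build_search_tree(guide)
  list(full = full, st = st, x = x, oracle = noisy_oracle(full, p_err))
}

## the search leaf (edge) adjacent to x's true attachment: the edge of the
## guide tree whose split corresponds to inserting x correctly
true_edges <- function(hold) {
  ## edges e such that attaching x at e reproduces the full tree's topology
  alive <- quartetwalk:::phy_alive(hold$st$T)
  ok <- integer(0)
  for (e in alive) {
    T2 <- attach_leaf(hold$st$T, e, hold$x)
    if (rf_quality(T2, hold$full) == 100) ok <- c(ok, e)
  }
  ok
}

test_that("a perfect-oracle walk descends to the true edge and accepts", {
  hold <- setup_holdout(30, p_err = 0, seed = 71)
  cfg <- walk_config(k = 1, ell = 10)
  res <- random_walk(hold$x, hold$st, hold$oracle, cfg)
  expect_true(res$accepted)
  expect_s3_class(res, "walk_result")
  expect_lte(res$steps, st_stats(hold$st)$max_depth + 10 + 1)
  e_hit <- hold$st$region[[res$terminal]][1]
  expect_true(e_hit %in% true_edges(hold))
})

test_that("node_vote follows the true direction under a perfect oracle", {
  hold <- setup_holdout(25, p_err = 0, seed = 5)
  cfg <- walk_config(k = 1, ell = 5)
  v <- hold$st$root
  truth <- true_edges(hold)
  ## descending by node_vote from the root reaches a true edge
  while (hold$st$kind[v] == 1L) {
    nv <- node_vote(hold$x, hold$st, v, hold$oracle, cfg)
    expect_true(nv$direction %in% 1:3)
    expect_true(nv$child != 0L)
    v <- nv$child
  }
  expect_true(hold$st$region[[v]][1] %in% truth)
})

test_that("weighted-majority and winner-takes-all can disagree on one vote set", {
  ## dir1 holds two quartets of weight 0.3 (sum 0.6); dir2 holds one of 0.5:
  ## weighted majority picks dir1, winner-takes-all picks dir2
  votes <- list(dir = c(1L, 1L, 2L), w = c(0.3, 0.3, 0.5))
  wm_totals <- vapply(1:3, function(d) sum(votes$w[votes$dir == d]), 0)
  expect_equal(which.max(wm_totals), 1L)
  wta_pick <- votes$dir[which.max(votes$w)]
  expect_equal(wta_pick, 2L)
  ## and the engine exposes both schemes end to end with different outcomes
  ## on a noisy simulation under the same seed (smoke check of both paths)
  set.seed(123)
  sim <- simulate_cell(sim_config(40, f = 200, length = 250), seed = 17)
  r_wm <- build_tree(sim$alignment, cfg = walk_config(voting = "wm"),
                     guide = guide_config(size = 20), seed = 99)
  r_wta <- build_tree(sim$alignment, cfg = walk_config(voting = "wta"),
                      guide = guide_config(size = 20), seed = 99)
  expect_false(identical(format_newick(r_wm$tree), format_newick(r_wta$tree)))
})

test_that("majority voting amplifies a noisy oracle's accuracy", {
  set.seed(29)
  hold <- setup_holdout(40, p_err = 0.2)
  cfg1 <- walk_config(k = 1, ell = 5)
  cfg5 <- walk_config(k = 5, ell = 5)
  v <- hold$st$root
  ## correct direction at the root under k = 1 vs k = 5
  truth_dir <- node_vote(hold$x, hold$st, v, noisy_oracle(hold$full, 0), cfg1)$direction
  trials <- 400
  hit1 <- hit5 <- 0L
  for (i in seq_len(trials)) {
    hit1 <- hit1 + (node_vote(hold$x, hold$st, v, hold$oracle, cfg1)$direction == truth_dir)
    hit5 <- hit5 + (node_vote(hold$x, hold$st, v, hold$oracle, cfg5)$direction == truth_dir)
  }
  expect_gt(hit5, hit1)
})

test_that("boundary checks stay inside the region under a perfect oracle", {
  hold <- setup_holdout(30, p_err = 0, seed = 55)
  cfg <- walk_config(k = 1, ell = 5)
  expect_equal(boundary_check(hold$x, hold$st, hold$st$root, hold$oracle, cfg),
               "stay")
  ## descend along the true path: every boundary check on it says stay
  v <- hold$st$root
  while (hold$st$kind[v] == 1L) {
    expect_equal(boundary_check(hold$x, hold$st, v, hold$oracle, cfg), "stay")
    v <- node_vote(hold$x, hold$st, v, hold$oracle, cfg)$child
  }
  ## an off-path subtree triggers up: walk to a wrong child of the root and
  ## further down; the boundary of a deep wrong region points outside
  truth <- node_vote(hold$x, hold$st, hold$st$root, hold$oracle, cfg)$direction
  wrong <- setdiff(1:3, truth)[1]
  v <- hold$st$child[wrong, hold$st$root]
  while (hold$st$kind[v] == 1L && all(hold$st$child[, v] == 0L) == FALSE) {
    ups <- replicate(5, boundary_check(hold$x, hold$st, v, hold$oracle, cfg))
    if (any(ups == "up")) break
    kids <- hold$st$child[, v]
    v <- kids[kids != 0L][1]
  }
  expect_true(hold$st$kind[v] == 2L || any(ups == "up"))
})

test_that("walk acceptance is monotone in oracle quality", {
  set.seed(61)
  full <- yule_tree(60)
  labs <- taxa_labels(full)
  rates <- vapply(c(0, 0.15, 0.35), function(pe) {
    acc <- 0L
    for (r in 1:25) {
      x <- sample(labs, 1)
      guide <- restrict_taxa(full, setdiff(labs, x))
      guide$edge_len[] <- NA_real_
      st <- build_search_tree(guide)
      res <- random_walk(x, st, noisy_oracle(full, pe), walk_config(k = 3, ell = 10))
      acc <- acc + res$accepted
    }
    acc / 25
  }, 0)
  expect_equal(rates[1], 1)           # perfect oracle always accepts
  expect_gte(rates[1] + 0.10, rates[2])
  expect_gte(rates[2] + 0.15, rates[3])
})

test_that("repeated walks only accept agreeing leaves and lower the rate", {
  set.seed(83)
  hold <- setup_holdout(40, p_err = 0)
  cfg1 <- walk_config(k = 1, ell = 8, repeats = 1)
  cfg2 <- walk_config(k = 1, ell = 8, repeats = 2)
  r1 <- repeated_walk(hold$x, hold$st, hold$oracle, cfg1)
  r2 <- repeated_walk(hold$x, hold$st, hold$oracle, cfg2)
  expect_true(r1$accepted)
  expect_true(r2$accepted)  # perfect oracle: both walks hit the same leaf
  ## with noise, repeats = 2 cannot accept more often than repeats = 1
  noisy <- noisy_oracle(hold$full, 0.3)
  acc1 <- acc2 <- 0L
  for (i in 1:60) {
    acc1 <- acc1 + repeated_walk(hold$x, hold$st, noisy, cfg1)$accepted
    acc2 <- acc2 + repeated_walk(hold$x, hold$st, noisy, cfg2)$accepted
  }
  expect_lte(acc2, acc1 + 3)  # allow simulation slack
})

test_that("force_descent always ends at a leaf, the true one when noiseless", {
  hold <- setup_holdout(35, p_err = 0, seed = 9)
  cfg <- walk_config(k = 1, ell = 5)
  leaf <- force_descent(hold$x, hold$st, hold$oracle, cfg)
  expect_equal(hold$st$kind[leaf], 2L)
  expect_true(hold$st$region[[leaf]][1] %in% true_edges(hold))
  ## starting at a leaf returns it unchanged
  expect_equal(force_descent(hold$x, hold$st, hold$oracle, cfg, from = leaf), leaf)
  ## under heavy noise it still returns some leaf
  noisy <- noisy_oracle(hold$full, 0.5)
  leaf2 <- force_descent(hold$x, hold$st, noisy, walk_config(k = 1, ell = 5))
  expect_equal(hold$st$kind[leaf2], 2L)
})

test_that("identical seeds give identical walk traces", {
  hold <- setup_holdout(40, p_err = 0.2, seed = 303)
  cfg <- walk_config(k = 5, ell = 10)
  set.seed(404)
  r1 <- random_walk(hold$x, hold$st, hold$oracle, cfg)
  set.seed(404)
  r2 <- random_walk(hold$x, hold$st, hold$oracle, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$accepted, r2$accepted)
})

test_that("walk steps never leave the search tree and respect the budget", {
  set.seed(21)
  hold <- setup_holdout(30, p_err = 0.4)
  cfg <- walk_config(k = 1, ell = 30, step_budget = 50)
  res <- random_walk(hold$x, hold$st, hold$oracle, cfg)
  expect_lte(res$steps, 50)
  expect_true(all(res$trace >= 1 & res$trace <= hold$st$n_nodes))
  ## consecutive trace entries are identical (leaf counter) or neighbours
  for (i in seq_len(res$steps - 1)) {
    a <- res$trace[i]; b <- res$trace[i + 1]
    expect_true(a == b || quartetwalk:::st_is_ancestor(hold$st, a, b) &&
                  hold$st$depth[b] == hold$st$depth[a] + 1 ||
                  hold$st$parent[a] == b || hold$st$parent[b] == a)
  }
})
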