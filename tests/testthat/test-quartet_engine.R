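test_that("four_point picks the minimal within-pair sum with canonical ties", {
  ## additive quartet with unit edges: dWX+dYZ = 4 < 6 = the crossing sums
  expect_equal(as.integer(four_point(2, 3, 3, 3, 3, 2)), 1L)
  tied <- four_point(1, 1, 1, 1, 1, 1)
  expect_equal(as.integer(tied), 1L)
  expect_true(attr(tied, "tied"))
  ## 1000 random additive quartets recover the generating topology
  set.seed(31)
  for (i in 1:1000) {
    len <- runif(5, 0.05, 2)
    d <- additive_quartet_dists(len[1], len[2], len[3], len[4], len[5])
    perm_top <- sample(3, 1)
    ## permute taxa so the true topology is perm_top
    dd <- switch(perm_top, d, d[c(2, 1, 3, 4, 6, 5)], d[c(3, 2, 1, 6, 5, 4)])
    expect_equal(as.integer(four_point(dd[1], dd[2], dd[3], dd[4], dd[5], dd[6])),
                 perm_top)
  }
})

test_that("ols_quartet_lengths is exact on additive input and optimal on noise", {
  d <- additive_quartet_dists(1, 2, 3, 4, 5)
  fit <- ols_quartet_lengths(d[1], d[2], d[3], d[4], d[5], d[6], 1L)
  expect_equal(unname(fit), c(1, 2, 3, 4, 5), tolerance = 1e-12)
  ## equal distances: star quartet, middle edge 0
  fit0 <- ols_quartet_lengths(2, 2, 2, 2, 2, 2, 1L)
  expect_equal(unname(fit0), c(1, 1, 1, 1, 0), tolerance = 1e-12)
  ## residual matches a generic least-squares solve for every topology
  X <- rbind(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 1),
             c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1), c(0, 0, 1, 1, 0))
  set.seed(8)
  for (i in 1:100) {
    d <- runif(6, 0.1, 2)
    fit <- ols_quartet_lengths(d[1], d[2], d[3], d[4], d[5], d[6], 1L)
    ref <- qr.solve(X, d)
    expect_equal(unname(fit), unname(ref), tolerance = 1e-9)
  }
  ## permuted topologies agree with the canonical frame after relabelling
  for (i in 1:50) {
    d <- runif(6, 0.1, 2)
    f2 <- ols_quartet_lengths(d[1], d[2], d[3], d[4], d[5], d[6], 2L)
    ## topology 2 pairs W with Y: swap X and Y in the inputs and read frame 1
    f1 <- ols_quartet_lengths(d[2], d[1], d[3], d[4], d[6], d[5], 1L)
    expect_equal(unname(f2), unname(f1[c(1, 3, 2, 4, 5)]), tolerance = 1e-12)
  }
})

test_that("quartet_weight is the clamped middle-edge fraction", {
  expect_equal(quartet_weight(c(1, 1, 1, 1, 1)), 0.2)
  expect_equal(quartet_weight(c(1, 1, 1, 1, 0)), 0)
  expect_equal(quartet_weight(c(0, 0, 0, 0, 2)), 1)
  ## negative externals are clamped before summing
  expect_equal(quartet_weight(c(-1, 1, 1, 1, 1)), 1 / 4)
  expect_equal(quartet_weight(c(1, 1, 1, 1, -0.1)), 0)
  ## scale invariance through the full distance pipeline
  set.seed(4)
  for (i in 1:50) {
    d <- runif(6, 0.2, 3)
    top <- as.integer(four_point(d[1], d[2], d[3], d[4], d[5], d[6]))
    w1 <- quartet_weight(ols_quartet_lengths(d[1], d[2], d[3], d[4], d[5], d[6], top))
    lam <- runif(1, 0.1, 10)
    d2 <- lam * d
    w2 <- quartet_weight(ols_quartet_lengths(d2[1], d2[2], d2[3], d2[4], d2[5], d2[6], top))
    expect_equal(w1, w2, tolerance = 1e-9)
  }
})

test_that("batched weights agree with the scalar path", {
  set.seed(12)
  k <- 200
  D <- matrix(runif(6 * k, 0.05, 3), k, 6)
  top <- integer(k); w_scalar <- numeric(k)
  for (i in seq_len(k)) {
    top[i] <- as.integer(four_point(D[i, 1], D[i, 2], D[i, 3], D[i, 4], D[i, 5], D[i, 6]))
    w_scalar[i] <- quartet_weight(
      ols_quartet_lengths(D[i, 1], D[i, 2], D[i, 3], D[i, 4], D[i, 5], D[i, 6], top[i]))
  }
  w_batch <- quartetwalk:::quartet_weight_batch(D[, 1], D[, 2], D[, 3],
                                               D[, 4], D[, 5], D[, 6], top)
  expect_equal(w_batch, w_scalar, tolerance = 1e-12)
})

test_that("the distance oracle answers quartets through the four-point pipeline", {
  aln <- alignment(c(A = "ACGTACGTACGTACGTACGT", B = "ACGTACGTACGTACGTACGT",
                     C = "TGCATGCATGCATGCAACGT", D = "TGCATGCATGCATGCAACGT"),
                   "dna")
  o <- distance_oracle(aln, "jc")
  q <- query_quartet(o, "A", "B", "C", "D")
  expect_equal(q$topology, "A,B|C,D")
  expect_gt(q$weight, 0)
  ## a fully tied quartet gets weight 0
  aln2 <- alignment(c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA"), "dna")
  o2 <- distance_oracle(aln2, "jc")
  q2 <- query_quartet(o2, "A", "B", "C", "D")
  expect_equal(q2$weight, 0)
  expect_true(q2$tied)
})

test_that("distance-oracle quartets from a known tree are mostly correct", {
  ## quartet tree with internal edge 0.1 and externals 0.05, JC sequences of
  ## length 2000: at least 95% of replicate queries recover the topology
  set.seed(77)
  ## internal edge 0.1, external edges 0.05
  qt <- parse_newick("((A:0.05,B:0.05):0.1,C:0.05,D:0.05);")
  hits <- 0L
  for (r in 1:200) {
    aln <- evolve_jc(qt, 2000, rates = "constant")
    o <- distance_oracle(aln, "jc")
    q <- query_quartet(o, "A", "B", "C", "D")
    hits <- hits + (q$topology == "A,B|C,D")
  }
  expect_gte(hits / 200, 0.95)
})

test_that("four_point on tree path distances equals the induced quartet", {
  set.seed(19)
  for (i in 1:10) {
    T <- random_tree(10)
    D <- quartetwalk:::leaf_dist_matrix(T)
    labs <- taxa_labels(T)
    for (q in utils::combn(labs, 4, simplify = FALSE)) {
      top <- as.integer(four_point(D[q[1], q[2]], D[q[1], q[3]], D[q[1], q[4]],
                                   D[q[2], q[3]], D[q[2], q[4]], D[q[3], q[4]]))
      expect_equal(quartetwalk:::quartet_key(q, top), induced_quartet(T, q))
    }
  }
})

test_that("tree_oracle returns the sqrt-proportion weighted majority", {
  base <- parse_newick("((a,b),(c,d),e);")
  alt <- parse_newick("((a,c),(b,d),e);")
  o5 <- tree_oracle(list(base, base, base, base, base))
  q <- query_quartet(o5, "a", "b", "c", "d")
  expect_equal(q$topology, "a,b|c,d")
  expect_equal(q$weight, 1)
  o32 <- tree_oracle(list(base, base, base, alt, alt))
  q2 <- query_quartet(o32, "a", "b", "c", "d")
  expect_equal(q2$topology, "a,b|c,d")
  expect_equal(q2$weight, sqrt(3 / 5), tolerance = 1e-12)
  ## ABSENT when no single tree holds all four taxa (but the union does)
  p1 <- parse_newick("((a,b),(c,e),f);")
  p2 <- parse_newick("((a,b),(d,e),f);")
  o_abs <- tree_oracle(list(p1, p2))
  expect_null(query_quartet(o_abs, "c", "d", "e", "f"))
})

test_that("tree_oracle ABSENT frequency tracks the coverage model", {
  ## trees containing each taxon independently with probability cov:
  ## a random quartet is absent from all N trees with prob (1 - cov^4)^N
  set.seed(55)
  cov <- 0.7; N <- 3L
  big <- random_tree(40)
  labs <- taxa_labels(big)
  trees <- replicate(N, {
    keep <- labs[runif(40) < cov]
    while (length(keep) < 4) keep <- labs[runif(40) < cov]
    restrict_taxa(big, keep)
  }, simplify = FALSE)
  o <- tree_oracle(trees)
  draws <- 400
  absent <- 0L
  for (i in seq_len(draws)) {
    q <- sample(labs, 4)
    absent <- absent + is.null(query_quartet(o, q[1], q[2], q[3], q[4]))
  }
  p_hat <- absent / draws
  ## expected absence probability, given the realized per-tree taxon sets
  p_exp <- mean(replicate(2000, {
    q <- sample(labs, 4)
    all(vapply(trees, function(tr) !all(q %in% taxa_labels(tr)), TRUE))
  }))
  se <- sqrt(p_exp * (1 - p_exp) / draws)
  expect_lt(abs(p_hat - p_exp), 4 * se + 0.02)
})

test_that("noisy oracle errs at the configured rate and is seed-deterministic", {
  set.seed(23)
  T <- random_tree(12)
  labs <- taxa_labels(T)
  o0 <- noisy_oracle(T, 0)
  for (i in 1:20) {
    q <- sample(labs, 4)
    expect_equal(query_quartet(o0, q[1], q[2], q[3], q[4])$topology,
                 induced_quartet(T, q))
  }
  o3 <- noisy_oracle(T, 0.3)
  set.seed(99)
  correct <- 0L
  n_draws <- 10000L
  q <- labs[1:4]
  truth <- induced_quartet(T, q)
  for (i in seq_len(n_draws)) {
    correct <- correct + (query_quartet(o3, q[1], q[2], q[3], q[4])$topology == truth)
  }
  expect_lt(abs(correct / n_draws - 0.7), 0.015)
  ## identical seed, identical query stream
  set.seed(1234)
  s1 <- replicate(50, query_quartet(o3, q[1], q[2], q[3], q[4])$topology)
  set.seed(1234)
  s2 <- replicate(50, query_quartet(o3, q[1], q[2], q[3], q[4])$topology)
  expect_identical(s1, s2)
})
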