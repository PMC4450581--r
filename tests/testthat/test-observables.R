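test_that("ANPU/ANCD match hand evaluation and handle zero-degree nodes", {
  ap <- assortativity_profile(toy_graph())
  anpu <- ap$nodes$value[ap$nodes$layer == "rows"]
  ancd <- ap$nodes$value[ap$nodes$layer == "cols"]
  expect_equal(anpu, c(1.5, 2))
  expect_equal(ancd, c(1.5, 2, NA))
  expect_equal(ap$summary$mean_anpu, 1.75)
  expect_equal(ap$summary$mean_ancd, 1.75) # zero-degree column excluded
  expect_equal(ap$summary$globalization_index, 1.75 / 2)

  # complete graph: every neighbour has full degree, indices saturate
  full <- bipartite_graph(matrix(1, 3, 4))
  apf <- assortativity_profile(full)
  expect_true(all(apf$nodes$value[apf$nodes$layer == "rows"] == 3))
  expect_true(all(apf$nodes$value[apf$nodes$layer == "cols"] == 4))
  expect_equal(apf$summary$globalization_index, 1)
  expect_equal(apf$summary$homogeneity_index, 1)

  expect_error(assortativity_profile(bipartite_graph(matrix(0, 2, 2))), "degree zero")
})

test_that("ANPU/ANCD values stay inside their layer-size bounds", {
  # a row's neighbours have ubiquity in [1, C], so ANPU lies in [1, C];
  # symmetrically ANCD lies in [1, P]
  for (seed in 1:10) {
    g <- random_graph(sample(2:8, 1), sample(2:8, 1), p = 0.5, seed = seed)
    if (all(rowSums(biadjacency(g)) == 0)) next
    C <- nrow(biadjacency(g))
    P <- ncol(biadjacency(g))
    ap <- assortativity_profile(g)
    anpu <- ap$nodes$value[ap$nodes$layer == "rows"]
    ancd <- ap$nodes$value[ap$nodes$layer == "cols"]
    expect_true(all(is.na(anpu) | (anpu >= 1 & anpu <= C)))
    expect_true(all(is.na(ancd) | (ancd >= 1 & ancd <= P)))
  }
})

test_that("motif counts match definitions, subsets and a brute-force oracle", {
  toy <- toy_graph()
  expect_equal(count_motifs(toy, motif_spec("V", 2)), 1)
  expect_equal(count_motifs(toy, motif_spec("Lambda", 2)), 1)
  expect_equal(count_motifs(toy, motif_spec("V", 3)), 0)
  # order 1 degenerates to the link count on both families
  expect_equal(count_motifs(toy, motif_spec("V", 1)), 3)
  expect_equal(count_motifs(toy, motif_spec("Lambda", 1)), 3)

  disjoint <- bipartite_graph(matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, byrow = TRUE))
  expect_equal(count_motifs(disjoint, motif_spec("V", 2)), 0)

  # subset restriction counts tuples drawn entirely from the subset
  g <- random_graph(6, 8, seed = 4)
  sub <- rownames(biadjacency(g))[c(1, 3, 5)]
  expect_equal(
    count_motifs(g, motif_spec("V", 2, subset = sub)),
    brute_vn(biadjacency(g)[sub, ], 2)
  )
  expect_error(count_motifs(g, motif_spec("V", 2, subset = "nope")), "not in graph")

  for (seed in 1:6) {
    gg <- random_graph(sample(3:8, 1), sample(3:8, 1), seed = seed)
    for (n in 2:4) {
      expect_equal(count_motifs(gg, motif_spec("V", n)), brute_vn(biadjacency(gg), n))
      expect_equal(
        count_motifs(gg, motif_spec("Lambda", n)),
        brute_vn(t(biadjacency(gg)), n)
      )
    }
    # V1 = Lambda1 = L on every graph
    L <- sum(biadjacency(gg))
    expect_equal(count_motifs(gg, motif_spec("V", 1)), L)
    expect_equal(count_motifs(gg, motif_spec("Lambda", 1)), L)
    # V2 equals the off-diagonal weighted-projection mass over row pairs
    w <- project(gg, "rows")$weights
    expect_equal(count_motifs(gg, motif_spec("V", 2)), sum(w[upper.tri(w)]))
  }
})

test_that("motif counts vanish beyond the maximum degree and decay in its tail", {
  g <- random_graph(7, 9, p = 0.6, seed = 11)
  u_max <- max(colSums(biadjacency(g)))
  expect_equal(count_motifs(g, motif_spec("V", u_max + 1)), 0)
  # choose(k, n) is non-increasing in n once n >= k/2, hence so is the total
  start <- ceiling(u_max / 2) + 1
  counts <- vapply(
    start:(u_max + 1),
    function(n) count_motifs(g, motif_spec("V", n)), numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("assortativity coefficient matches hand Pearson values", {
  # nested star: edge endpoint degree pairs (2,2), (2,1), (1,2)
  star <- bipartite_graph(matrix(c(1, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(assortativity_coefficient(star), -0.5)

  block <- bipartite_graph(matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, byrow = TRUE))
  expect_gt(assortativity_coefficient(block), 0)

  expect_warning(
    r <- assortativity_coefficient(bipartite_graph(matrix(1, 2, 3))),
    "undefined"
  )
  expect_true(is.na(r))
  expect_error(
    assortativity_coefficient(bipartite_graph(matrix(c(1, 0, 0, 0), 2))),
    "two links"
  )
})

test_that("NODF matches limiting cases and the vegan implementation", {
  expect_equal(nodf(nested3())$nodf_total, 100)
  expect_equal(nodf(bipartite_graph(diag(2)))$nodf_total, 0)
  # equal marginal totals contribute zero under the decreasing-fill rule
  expect_equal(nodf(bipartite_graph(matrix(1, 2, 2)))$nodf_total, 0)

  skip_if_not_installed("vegan")
  for (seed in 1:8) {
    g <- random_graph(sample(3:9, 1), sample(3:9, 1), p = 0.5, seed = seed)
    m <- biadjacency(g)
    ours <- nodf(g)
    # order = TRUE sorts by marginal totals first, which is exactly the
    # order-invariant reading implemented here
    ref <- vegan::nestednodf(m, order = TRUE, weighted = FALSE)$statistic
    expect_equal(ours$nodf_total, unname(ref["NODF"]), tolerance = 1e-10)
    expect_equal(ours$nodf_rows, unname(ref["N.rows"]), tolerance = 1e-10)
    expect_equal(ours$nodf_cols, unname(ref["N.columns"]), tolerance = 1e-10)
  }
})

test_that("NODF is invariant under row and column permutations", {
  g <- random_graph(6, 9, seed = 5)
  base <- nodf(g)$nodf_total
  m <- biadjacency(g)
  for (k in 1:6) {
    perm <- withr::with_seed(100 + k, {
      list(r = sample(nrow(m)), c = sample(ncol(m)))
    })
    expect_equal(nodf(bipartite_graph(m[perm$r, perm$c]))$nodf_total, base)
  }
})

test_that("fitness-complexity reproduces fixed points, orderings and equivariance", {
  # complete matrix: the all-ones vector is a fixed point from iteration one
  full <- bipartite_graph(matrix(1, 3, 4))
  fc <- fitness_complexity(full)
  expect_true(fc$converged)
  expect_true(all(fc$fitness$fitness == 1))
  expect_true(all(fc$complexity$complexity == 1))
  expect_equal(mean(fc$fitness$fitness), 1)

  # nested matrix: fitness follows diversification, the rarest column is the
  # most complex
  fcn <- fitness_complexity(nested3(), max_iter = 2000)
  expect_equal(order(-fcn$fitness$fitness), 1:3)
  expect_equal(order(fcn$complexity$complexity), 1:3)
  expect_true(all(fcn$fitness$fitness >= 0))
  expect_equal(mean(fcn$fitness$fitness), 1)
  expect_equal(mean(fcn$complexity$complexity), 1)

  # permuting rows permutes fitness identically
  g <- random_graph(5, 8, p = 0.6, seed = 9)
  m <- biadjacency(g)
  perm <- c(3, 1, 5, 2, 4)
  a <- suppressWarnings(fitness_complexity(g, max_iter = 500))
  b <- suppressWarnings(fitness_complexity(bipartite_graph(m[perm, ]), max_iter = 500))
  merged <- merge(a$fitness, b$fitness, by = "label")
  expect_equal(merged$fitness.x, merged$fitness.y, tolerance = 1e-10)

  expect_warning(
    fitness_complexity(bipartite_graph(matrix(c(1, 0, 1, 0), 2))),
    "zero-degree"
  )
})

test_that("ranking by fitness restores nested ordering and preserves NODF", {
  n3 <- nested3()
  fc <- fitness_complexity(n3, max_iter = 2000)
  expect_identical(biadjacency(rank_by_fitness(n3, fc)), biadjacency(n3))

  flipped <- bipartite_graph(biadjacency(n3)[3:1, ])
  restored <- rank_by_fitness(flipped)
  expect_equal(unname(biadjacency(restored)), unname(biadjacency(n3)))

  g <- random_graph(6, 7, seed = 12)
  expect_equal(
    nodf(suppressWarnings(rank_by_fitness(g)))$nodf_total,
    nodf(g)$nodf_total
  )
})
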