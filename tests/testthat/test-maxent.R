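test_that("BiCM on symmetric and degenerate graphs yields the exact solutions", {
  # biregular graph: symmetry forces a uniform probability k/P = q/C
  bireg <- generate_bipartite("biregular", 4, 8, seed = 1, row_degree = 4)
  mb <- fit_bicm(bireg)
  expect_true(all(abs(link_probability(mb) - 0.5) < 1e-8))

  # the toy graph's degree sequence admits a single matrix: the ensemble
  # collapses onto the observation itself
  toy <- toy_graph()
  mt <- fit_bicm(toy)
  expect_equal(unname(link_probability(mt)), unname(biadjacency(toy)) + 0)
  expect_equal(mt$loglik, 0) # probability one
  expect_equal(mt$max_degree_residual, 0)

  # empty and complete graphs
  me <- fit_bicm(bipartite_graph(matrix(0, 2, 3)))
  expect_true(all(link_probability(me) == 0))
  mf <- fit_bicm(bipartite_graph(matrix(1, 2, 3)))
  expect_true(all(link_probability(mf) == 1))
})

test_that("fitted BiCM reproduces observed degrees and is order-independent", {
  g <- bipartite_graph(matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 0), 3, byrow = TRUE))
  m <- fit_bicm(g, tol = 1e-10)
  expect_lt(m$max_degree_residual, 1e-8)
  ed <- expected_degrees(m)
  expect_equal(
    ed$expected_degree,
    c(rowSums(biadjacency(g)), colSums(biadjacency(g))),
    tolerance = 1e-7, ignore_attr = TRUE
  )

  # nodes with identical degree share a hidden variable
  d <- rowSums(biadjacency(g))
  expect_equal(m$x[d == 2][[1]], m$x[d == 2][[2]], tolerance = 1e-12)

  # node ordering does not change the solution
  mat <- biadjacency(g)
  perm <- bipartite_graph(mat[c(2, 3, 1), c(3, 1, 2)])
  mp <- fit_bicm(perm, tol = 1e-10)
  expect_equal(
    link_probability(mp)[rownames(mat), colnames(mat)],
    link_probability(m),
    tolerance = 1e-9
  )
})

test_that("BiRG constrains only the connectance", {
  expect_equal(fit_birg(toy_graph())$p, 0.5)
  expect_equal(fit_birg(bipartite_graph(matrix(0, 2, 2)))$p, 0)
  expect_equal(fit_birg(bipartite_graph(matrix(1, 2, 2)))$p, 1)
  b <- fit_birg(toy_graph())
  ed <- expected_degrees(b)
  expect_equal(ed$expected_degree, c(1.5, 1.5, 1, 1, 1), ignore_attr = TRUE)
})

test_that("matrix probabilities factorize and normalize over the full ensemble", {
  # uniform ensemble: every 2x3 matrix has probability 0.5^6
  g23 <- bipartite_graph(matrix(c(1, 1, 0, 1, 0, 0), 2, byrow = TRUE))
  b <- fit_birg(g23)
  expect_equal(matrix_probability(b, g23), 6 * log(0.5))

  # collapsed BiCM puts probability one on the observation
  toy <- toy_graph()
  mt <- fit_bicm(toy)
  expect_equal(matrix_probability(mt, toy), 0)
  other <- bipartite_graph(
    matrix(c(1, 0, 1, 1, 0, 0), 2, byrow = TRUE),
    row_labels = c("c1", "c2"), col_labels = c("p1", "p2", "p3")
  )
  expect_equal(matrix_probability(mt, other), -Inf)

  # sum of P(M) over all 16 matrices of a 2x2 model is 1
  m22 <- fit_bicm_degrees(c(1.2, 0.7), c(1.0, 0.9))
  expect_equal(enum_total_probability(m22), 1, tolerance = 1e-12)
  b22 <- fit_birg(bipartite_graph(matrix(c(1, 0, 0, 1), 2)))
  expect_equal(enum_total_probability(b22), 1, tolerance = 1e-12)
})

test_that("analytic motif moments agree with hand values and full enumeration", {
  g24 <- bipartite_graph(matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, byrow = TRUE))
  b <- fit_birg(g24)
  v2 <- motif_spec("V", 2)
  expect_equal(expected_motif_mean(b, v2), 1.0)
  expect_equal(expected_motif_std(b, v2), sqrt(0.75))
  # order 1: the expected link count
  expect_equal(expected_motif_mean(b, motif_spec("V", 1)), 4)
  expect_equal(expected_motif_mean(b, motif_spec("Lambda", 1)), 4)

  # degenerate ensemble has zero spread
  mt <- fit_bicm(toy_graph())
  expect_equal(expected_motif_std(mt, v2), 0)

  # enumeration oracle on a fitted 3x3 model (512 matrices)
  g33 <- bipartite_graph(matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 0), 3, byrow = TRUE))
  m33 <- fit_bicm(g33, tol = 1e-12)
  for (spec in list(
    motif_spec("V", 2), motif_spec("Lambda", 2),
    motif_spec("V", 3), motif_spec("V", 2, subset = c("r1", "r3"))
  )) {
    mu_enum <- enum_expect(m33, function(mm) brute_vn(
      if (spec$family == "V") mm else t(mm),
      spec$order
    ))
    if (!is.null(spec$subset)) {
      mu_enum <- enum_expect(m33, function(mm) brute_vn(mm[c(1, 3), , drop = FALSE], spec$order))
    }
    expect_equal(expected_motif_mean(m33, spec), mu_enum, tolerance = 1e-10)
  }
  # second moment for order 2
  mu <- expected_motif_mean(m33, motif_spec("V", 2))
  m2_enum <- enum_expect(m33, function(mm) brute_vn(mm, 2)^2)
  expect_equal(
    expected_motif_std(m33, motif_spec("V", 2)),
    sqrt(m2_enum - mu^2),
    tolerance = 1e-10
  )
})

test_that("the fitted multipliers maximize the likelihood", {
  g <- bipartite_graph(matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 0), 3, byrow = TRUE))
  m <- fit_bicm(g, tol = 1e-12)
  base <- loglik_xy(m$x, m$y, biadjacency(g))
  expect_equal(base, m$loglik, tolerance = 1e-9)
  for (i in seq_along(m$x)) {
    for (fac in c(0.99, 1.01)) {
      x2 <- m$x
      x2[i] <- x2[i] * fac
      expect_lte(loglik_xy(x2, m$y, biadjacency(g)), base + 1e-12)
    }
  }
  for (j in seq_along(m$y)) {
    for (fac in c(0.99, 1.01)) {
      y2 <- m$y
      y2[j] <- y2[j] * fac
      expect_lte(loglik_xy(m$x, y2, biadjacency(g)), base + 1e-12)
    }
  }
})

test_that("ensemble entropy attains its known limits and orderings", {
  # uniform ensemble maximizes entropy at ln 2
  u <- fit_birg(bipartite_graph(matrix(c(1, 1, 0, 0), 2)))
  expect_equal(u$p, 0.5)
  expect_equal(ensemble_entropy(u), log(2))
  # deterministic ensemble carries no uncertainty
  expect_equal(ensemble_entropy(fit_bicm(toy_graph())), 0)
  # extra constraints cannot raise entropy
  for (seed in 1:5) {
    g <- random_graph(5, 9, p = 0.4, seed = seed)
    if (sum(biadjacency(g)) < 2) next
    expect_lte(
      ensemble_entropy(fit_bicm(g)),
      ensemble_entropy(fit_birg(g)) + 1e-12
    )
  }
})

test_that("degree-sequence fitting validates its inputs", {
  expect_error(fit_bicm_degrees(c(3, 1), c(1, 1)), "\\[0, P\\]")
  expect_error(fit_bicm_degrees(c(1, 1), c(1, 2)), "equal sums")
})
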