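# shared fixtures and independent oracles

toy_graph <- function() {
  bipartite_graph(
    matrix(c(1, 1, 0, 1, 0, 0), nrow = 2, byrow = TRUE),
    row_labels = c("c1", "c2"), col_labels = c("p1", "p2", "p3")
  )
}

nested3 <- function() {
  bipartite_graph(matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), nrow = 3, byrow = TRUE))
}

random_graph <- function(C, P, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(C * P, 1, p), C, P)
    bipartite_graph(m)
  })
}

# every binary matrix of shape C x P (for brute-force enumeration oracles)
enum_mats <- function(C, P) {
  grid <- expand.grid(rep(list(0:1), C * P))
  lapply(seq_len(nrow(grid)), function(i) {
    matrix(as.integer(grid[i, ]), C, P)
  })
}

# expectation of f(M) over the full grandcanonical ensemble of `model`,
# weighting each matrix by its factorized probability
enum_expect <- function(model, f) {
  p <- link_probability(model)
  mats <- enum_mats(nrow(p), ncol(p))
  vals <- vapply(mats, function(m) {
    prob <- prod(ifelse(m == 1, p, 1 - p))
    prob * f(m)
  }, numeric(1))
  sum(vals)
}

enum_total_probability <- function(model) enum_expect(model, function(m) 1)

# brute-force V-motif count (independent of the package's binomial formula)
brute_vn <- function(m, n) {
  rows <- seq_len(nrow(m))
  if (nrow(m) < n) {
    return(0)
  }
  combs <- utils::combn(rows, n, simplify = FALSE)
  sum(vapply(combs, function(cc) {
    sum(apply(m[cc, , drop = FALSE], 2, function(col) all(col == 1)))
  }, numeric(1)))
}

# brute-force weighted projection by explicit double loop
brute_projection <- function(m) {
  C <- nrow(m)
  w <- matrix(0, C, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      w[i, j] <- sum(m[i, ] * m[j, ])
    }
  }
  w
}

# log-likelihood of a matrix given explicit hidden variables (for the
# maximality perturbation check); limits handled as in the model
loglik_xy <- function(x, y, m) {
  xy <- outer(x, y)
  p <- xy / (1 + xy)
  p[is.nan(p)] <- 1 # Inf * 0 conventions do not occur in the perturbation test
  p1 <- p[m == 1]
  p0 <- p[m == 0]
  if (any(p1 == 0) || any(p0 == 1)) {
    return(-Inf)
  }
  sum(log(p1)) + sum(log1p(-p0))
}
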