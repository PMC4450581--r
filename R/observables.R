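#' Average nearest-neighbour degrees of a bipartite network
#'
#' For every row node `c`, the average nearest-neighbour ubiquity (ANPU)
#' `u_nn(c) = sum_p m_cp * u_p / d_c` is the mean degree of the column nodes it
#' touches; for every column node `p`, the average nearest-neighbour
#' diversification (ANCD) `d_nn(p) = sum_c m_cp * d_c / u_p` is the mean degree
#' of its row neighbours. Scattering these against the degree sequences
#' exposes (dis)assortative mixing. Zero-degree nodes have no neighbours: they
#' get `NA` and are excluded from the layer means and their normal-
#' approximation 95% confidence intervals. ANPU values live in `[1, C]`, so
#' the mean ANPU divided by `C` is a globalization (integration) index in
#' `[0, 1]` insensitive to the row-layer size; symmetrically the mean ANCD
#' divided by `P` is a homogeneity index for the column layer.
#'
#' @param g a [bipartite_graph()].
#' @return object of class `assortativity_profile`: `tidy()` gives the
#'   per-node values, `glance()` the layer means, confidence intervals and
#'   normalized indices.
#' @export
assortativity_profile <- function(g) {
  m <- biadjacency(g)
  d <- rowSums(m)
  u <- colSums(m)
  if (all(d == 0)) abort("all row nodes have degree zero: ANPU undefined")
  anpu <- ifelse(d > 0, as.numeric(m %*% u) / d, NA_real_)
  ancd <- ifelse(u > 0, as.numeric(crossprod(m, d)) / u, NA_real_)
  nodes <- tibble(
    label = c(rownames(m), colnames(m)),
    layer = rep(c("rows", "cols"), c(nrow(m), ncol(m))),
    degree = c(d, u),
    value = unname(c(anpu, ancd)),
    measure = rep(c("anpu", "ancd"), c(nrow(m), ncol(m)))
  )
  ci <- function(v) {
    v <- v[!is.na(v)]
    mu <- mean(v)
    half <- 1.96 * sd(v) / sqrt(length(v))
    c(mu, mu - half, mu + half)
  }
  a <- ci(anpu)
  b <- ci(ancd)
  summary <- tibble(
    mean_anpu = a[1], ci95_anpu_lower = a[2], ci95_anpu_upper = a[3],
    mean_ancd = b[1], ci95_ancd_lower = b[2], ci95_ancd_upper = b[3],
    globalization_index = a[1] / nrow(m),
    homogeneity_index = b[1] / ncol(m)
  )
  structure(list(nodes = nodes, summary = summary), class = "assortativity_profile")
}

#' @export
print.assortativity_profile <- function(x, ...) {
  cat("# assortativity_profile\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.assortativity_profile <- function(x, ...) x$nodes

#' @export
glance.assortativity_profile <- function(x, ...) x$summary

#' Describe a motif family to count or randomize
#'
#' A `Vn` motif is an n-tuple of row nodes all linked to one common column
#' node; a `Lambda-n` motif is the mirror image (n column nodes sharing a row
#' node). `V2`/`Lambda2` are the classic V and Lambda co-occurrence motifs;
#' order 1 degenerates to the link count. A subset of labels (row labels for
#' V, column labels for Lambda) restricts the n-tuples to nodes drawn entirely
#' from that subset.
#'
#' @param family `"V"` or `"Lambda"`.
#' @param order integer `n >= 1`.
#' @param subset optional character vector of node labels.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(family = c("V", "Lambda"), order = 2L, subset = NULL) {
  family <- match.arg(family)
  order <- as.integer(order)
  if (is.na(order) || order < 1L) abort("motif order must be an integer >= 1")
  structure(list(family = family, order = order, subset = subset), class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf(
    "# motif_spec: %s%d%s\n", x$family, x$order,
    if (is.null(x$subset)) "" else sprintf(" on %d-node subset", length(x$subset))
  ))
  invisible(x)
}

# restricted matrix whose column sums are the degrees the motif family counts
# over: rows restricted to the subset for V, the transpose for Lambda
motif_matrix <- function(m, spec) {
  if (spec$family == "Lambda") m <- t(m)
  if (!is.null(spec$subset)) {
    missing <- setdiff(spec$subset, rownames(m))
    if (length(missing) > 0L) {
      abort(sprintf("subset labels not in graph: %s", paste(missing, collapse = ", ")))
    }
    m <- m[spec$subset, , drop = FALSE]
  }
  m
}

#' Count Vn / Lambda-n motifs
#'
#' The number of `Vn` motifs is `sum_p choose(u_p, n)` with `u_p` the ubiquity
#' restricted to the chosen row subset (`choose(k, n) = 0` for `k < n`);
#' `Lambda-n` counts `sum_c choose(d_c, n)` symmetrically. Order 1 returns the
#' number of links incident to the subset; with no subset, `V1 = Lambda1 = L`.
#'
#' @param g a [bipartite_graph()].
#' @param spec a [motif_spec()], or a family string (then `order`/`subset`
#'   apply).
#' @inheritParams motif_spec
#' @return nonnegative count (numeric, as counts can exceed integer range).
#' @export
count_motifs <- function(g, spec = NULL, family = c("V", "Lambda"), order = 2L,
                         subset = NULL) {
  if (is.null(spec)) spec <- motif_spec(family, order, subset)
  if (is.character(spec)) spec <- motif_spec(spec, order, subset)
  stopifnot(inherits(spec, "motif_spec"))
  mm <- motif_matrix(biadjacency(g), spec)
  sum(choose(colSums(mm), spec$order))
}

#' Newman's assortativity coefficient for bipartite edges
#'
#' The Pearson correlation, across links, between the degrees of the two
#' endpoints `(d_c, u_p)`. It ranges in [-1, 1]; positive values mean links
#' preferentially join similar-degree nodes. In a bipartite graph each edge
#' has exactly one endpoint per layer, and the "remaining degree" convention
#' (degree minus one) differs from raw degrees by an affine shift that leaves
#' the correlation unchanged. When either endpoint degree sequence is constant
#' across edges (e.g. a complete or biregular graph) the coefficient is
#' undefined and `NA` is returned with a warning.
#'
#' @param g a [bipartite_graph()] with at least two links.
#' @return a number in [-1, 1], or `NA` for degenerate degree variance.
#' @export
assortativity_coefficient <- function(g) {
  m <- biadjacency(g)
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) < 2L) abort("assortativity needs at least two links")
  x <- rowSums(m)[idx[, 1L]]
  y <- colSums(m)[idx[, 2L]]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("degenerate endpoint-degree variance: assortativity coefficient undefined")
    return(NA_real_)
  }
  unname(cor(x, y))
}

#' NODF nestedness
#'
#' NODF (nestedness metric based on overlap and decreasing fill). For every
#' unordered pair of rows with strictly different, positive degrees, the
#' paired overlap is `100 * |shared columns| / d_min`; pairs with equal or
#' zero degrees contribute 0 (the decreasing-fill condition). `nodf_rows` is
#' the mean over all `C(C-1)/2` row pairs, `nodf_cols` the column analogue,
#' and `nodf_total` pools both sums over the total pair count. The measure is
#' invariant under row/column permutations.
#'
#' @param g a [bipartite_graph()] with at least two nodes in some layer.
#' @return one-row tibble with `nodf_total`, `nodf_rows`, `nodf_cols`
#'   (percentages in [0, 100]; a layer with fewer than two nodes gives `NA`
#'   for its component).
#' @export
nodf <- function(g) {
  m <- biadjacency(g)
  if (nrow(m) < 2L && ncol(m) < 2L) abort("NODF needs at least two nodes in one layer")
  part <- function(mm) {
    n <- nrow(mm)
    if (n < 2L) {
      return(c(sum = 0, pairs = 0, mean = NA_real_))
    }
    deg <- rowSums(mm)
    ov <- tcrossprod(mm)
    up <- upper.tri(ov)
    dmin <- outer(deg, deg, pmin)[up]
    decr <- (outer(deg, deg, "!=")[up]) & dmin > 0
    contrib <- ifelse(decr, 100 * ov[up] / dmin, 0)
    c(sum = sum(contrib), pairs = n * (n - 1) / 2, mean = mean(contrib))
  }
  r <- part(m)
  cpart <- part(t(m))
  tibble(
    nodf_total = (r[["sum"]] + cpart[["sum"]]) / (r[["pairs"]] + cpart[["pairs"]]),
    nodf_rows = r[["mean"]],
    nodf_cols = cpart[["mean"]]
  )
}

#' Fitness-complexity ranking
#'
#' The coupled nonlinear iteration of the economic-complexity literature:
#' starting from all-ones vectors, `F_c <- sum_p m_cp * Q_p` and
#' `Q_p <- 1 / sum_c (m_cp / F_c)` (both right-hand sides evaluated at the
#' previous iterates), each vector renormalized to unit mean after every step.
#' Fitness rewards diversified rows; complexity penalizes columns reachable by
#' weak (low-fitness) rows, so the rarest column held only by the fittest rows
#' scores highest. Zero-degree nodes are excluded (with a warning) since they
#' force divisions by zero. The iteration is known not to converge for every
#' matrix; the result is flagged rather than raising an error.
#'
#' @param g a [bipartite_graph()].
#' @param tol relative tolerance on the max elementwise change per iteration.
#' @param max_iter iteration cap.
#' @return object of class `fitness_complexity` with per-node scores
#'   (`tidy()`), convergence diagnostics (`glance()`), and the iteration
#'   trace.
#' @export
fitness_complexity <- function(g, tol = 1e-8, max_iter = 1000L) {
  m <- biadjacency(g)
  d <- rowSums(m)
  u <- colSums(m)
  if (any(d == 0) || any(u == 0)) {
    warn(sprintf(
      "excluding %d zero-degree row(s) and %d zero-degree column(s) from fitness-complexity",
      sum(d == 0), sum(u == 0)
    ))
  }
  keep_r <- d > 0
  keep_c <- u > 0
  mm <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(mm) == 0L || ncol(mm) == 0L) abort("no nonzero-degree nodes left")
  f <- rep(1, nrow(mm))
  q <- rep(1, ncol(mm))
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f_new <- as.numeric(mm %*% q)
    q_new <- 1 / as.numeric(crossprod(mm, 1 / f))
    f_new <- f_new / mean(f_new)
    q_new <- q_new / mean(q_new)
    delta <- max(abs(c(f_new - f, q_new - q)) / c(f, q))
    f <- f_new
    q <- q_new
    trace[it] <- delta
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      fitness = tibble(label = rownames(mm), fitness = f),
      complexity = tibble(label = colnames(mm), complexity = q),
      excluded_rows = rownames(m)[!keep_r],
      excluded_cols = colnames(m)[!keep_c],
      n_iterations = it,
      converged = converged,
      trace = trace
    ),
    class = "fitness_complexity"
  )
}

#' @export
print.fitness_complexity <- function(x, ...) {
  cat(sprintf(
    "# fitness_complexity: %d rows, %d cols; %d iterations, %s\n",
    nrow(x$fitness), nrow(x$complexity), x$n_iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @export
tidy.fitness_complexity <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$fitness, label = .data$label, layer = "rows", score = .data$fitness),
    dplyr::transmute(x$complexity, label = .data$label, layer = "cols", score = .data$complexity)
  )
}

#' @export
glance.fitness_complexity <- function(x, ...) {
  tibble(
    n_iterations = x$n_iterations,
    converged = x$converged,
    last_delta = if (length(x$trace)) x$trace[length(x$trace)] else NA_real_,
    n_excluded = length(x$excluded_rows) + length(x$excluded_cols)
  )
}

#' Reorder a graph by decreasing fitness and increasing complexity
#'
#' Sorts rows top-to-bottom by decreasing fitness and columns left-to-right by
#' increasing complexity, the ordering that renders a nested matrix in its
#' characteristic triangular form. Zero-degree nodes (excluded from the
#' ranking) are placed last on both layers. NODF is invariant under this
#' reordering.
#'
#' @param g a [bipartite_graph()].
#' @param fc a [fitness_complexity()] result computed on `g`; computed afresh
#'   when `NULL`.
#' @return a reordered [bipartite_graph()].
#' @export
rank_by_fitness <- function(g, fc = NULL) {
  if (is.null(fc)) fc <- suppressWarnings(fitness_complexity(g))
  m <- biadjacency(g)
  ro <- c(
    fc$fitness$label[order(-fc$fitness$fitness)],
    intersect(rownames(m), fc$excluded_rows)
  )
  co <- c(
    fc$complexity$label[order(fc$complexity$complexity)],
    intersect(colnames(m), fc$excluded_cols)
  )
  permute_graph(g, match(ro, rownames(m)), match(co, colnames(m)))
}
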