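#' Fit the Bipartite Configuration Model
#'
#' The BiCM is the maximum-entropy distribution over all binary bipartite
#' matrices of the observed shape whose expected row and column degree
#' sequences equal the observed ones. Entropy maximization under those soft
#' constraints yields an exponential family in which every link is an
#' independent Bernoulli variable with probability
#' `p_cp = x_c * y_p / (1 + x_c * y_p)`, where the positive hidden variables
#' `x_c = exp(-theta_c)` and `y_p = exp(-theta_p)` are the exponentiated
#' Lagrange multipliers. The multipliers are estimated by maximizing the
#' log-likelihood of the observed matrix, equivalent to solving the `C + P`
#' moment equations `sum_p p_cp = d_c`, `sum_c p_cp = u_p`.
#'
#' The solver first peels degenerate nodes exactly: zero-degree nodes get
#' `p = 0` on their line (`x -> 0` limit), nodes connected to everything still
#' active get `p = 1` (`x -> Inf` limit), repeating until stable. The
#' remaining core is reduced over degree equivalence classes (nodes with equal
#' degree provably share a hidden variable) and solved by a multiplicative
#' fixed-point iteration `x_i <- d_i / sum_j n_j y_j / (1 + x_i y_j)`, with a
#' BFGS polish on the concave reduced log-likelihood if the fixed point stalls.
#' The fit is deterministic and independent of node ordering.
#'
#' @param g a [bipartite_graph()].
#' @param tol convergence tolerance on the maximum absolute difference between
#'   expected and observed degrees.
#' @param max_iter fixed-point iteration cap.
#' @return object of class `bicm` with elements `x`, `y` (named hidden
#'   variables; `0` and `Inf` mark the degenerate limits), `link_prob`
#'   (the `C x P` probability matrix), `loglik`, `max_degree_residual`,
#'   `iterations`, `method`.
#' @export
fit_bicm <- function(g, tol = 1e-8, max_iter = 5000L) {
  m <- biadjacency(g)
  fit <- bicm_engine(rowSums(m), colSums(m),
    tol = tol, max_iter = max_iter,
    row_labels = rownames(m), col_labels = colnames(m)
  )
  fit$loglik <- matrix_probability(fit, g)
  fit
}

#' Fit a BiCM directly to a (possibly non-integer) degree sequence
#'
#' Solves the same moment equations as [fit_bicm()] but takes target expected
#' degrees instead of a matrix, which is what parameter-recovery exercises and
#' marginals-only datasets need. Targets must satisfy `0 <= d_c <= P`,
#' `0 <= u_p <= C` and `sum(d) == sum(u)`.
#'
#' @param row_degrees,col_degrees numeric target degree sequences (names, if
#'   present, become node labels).
#' @inheritParams fit_bicm
#' @return object of class `bicm`; its `loglik` is the reduced log-likelihood
#'   evaluated at the solution.
#' @export
fit_bicm_degrees <- function(row_degrees, col_degrees, tol = 1e-8, max_iter = 5000L) {
  bicm_engine(row_degrees, col_degrees,
    tol = tol, max_iter = max_iter,
    row_labels = names(row_degrees) %||% paste0("r", seq_along(row_degrees)),
    col_labels = names(col_degrees) %||% paste0("c", seq_along(col_degrees))
  )
}

bicm_engine <- function(d, u, tol, max_iter, row_labels, col_labels) {
  C <- length(d)
  P <- length(u)
  if (any(d < 0) || any(d > P + 1e-9)) abort("row degrees must lie in [0, P]")
  if (any(u < 0) || any(u > C + 1e-9)) abort("column degrees must lie in [0, C]")
  L <- sum(d)
  if (abs(L - sum(u)) > 1e-8 * max(1, L)) {
    abort("row and column degree sequences must have equal sums")
  }
  eps <- 1e-9
  p <- matrix(NA_real_, C, P, dimnames = list(row_labels, col_labels))
  x <- rep(NA_real_, C)
  y <- rep(NA_real_, P)
  ar <- rep(TRUE, C)
  ac <- rep(TRUE, P)
  dr <- d
  du <- u

  # exact peeling of degenerate nodes: empty lines get p = 0, saturated lines
  # (degree equal to the number of still-active partners) get p = 1
  repeat {
    changed <- FALSE
    zr <- ar & dr <= eps
    if (any(zr)) {
      p[zr, ac] <- 0
      x[zr] <- 0
      ar[zr] <- FALSE
      changed <- TRUE
    }
    zc <- ac & du <= eps
    if (any(zc)) {
      p[ar, zc] <- 0
      y[zc] <- 0
      ac[zc] <- FALSE
      changed <- TRUE
    }
    sr <- ar & dr >= sum(ac) - eps
    if (any(sr)) {
      p[sr, ac] <- 1
      x[sr] <- Inf
      du[ac] <- du[ac] - sum(sr)
      ar[sr] <- FALSE
      changed <- TRUE
    }
    sc <- ac & du >= sum(ar) - eps
    if (any(sc)) {
      p[ar, sc] <- 1
      y[sc] <- Inf
      dr[ar] <- dr[ar] - sum(sc)
      ac[sc] <- FALSE
      changed <- TRUE
    }
    if (any(dr[ar] < -eps) || any(du[ac] < -eps)) {
      abort("inconsistent degree sequence: peeling produced negative residual degrees")
    }
    if (!changed) break
  }

  iterations <- 0L
  method <- "exact-peeling"
  loglik_core <- 0

  if (any(ar) && any(ac)) {
    dc <- dr[ar]
    uc <- du[ac]
    # reduce over degree equivalence classes
    dk <- sort(unique(dc))
    uk <- sort(unique(uc))
    ridx <- match(dc, dk)
    cidx <- match(uc, uk)
    nk <- tabulate(ridx, length(dk))
    mk <- tabulate(cidx, length(uk))
    Lc <- sum(dc)
    xk <- dk / sqrt(Lc)
    yk <- uk / sqrt(Lc)

    expected <- function(xk, yk) {
      XY <- outer(xk, yk)
      Pm <- XY / (1 + XY)
      list(
        Pm = Pm,
        er = as.numeric(Pm %*% mk),
        ec = as.numeric(crossprod(Pm, nk))
      )
    }
    resid <- Inf
    while (iterations < max_iter) {
      iterations <- iterations + 1L
      e <- expected(xk, yk)
      xk <- xk * dk / pmax(e$er, .Machine$double.xmin)
      e <- expected(xk, yk)
      yk <- yk * uk / pmax(e$ec, .Machine$double.xmin)
      e <- expected(xk, yk)
      resid <- max(abs(e$er - dk), abs(e$ec - uk))
      if (resid <= tol) break
    }
    method <- "fixed-point"
    if (resid > tol) {
      # concave reduced log-likelihood in theta = log(x), log(y)
      Kr <- length(dk)
      negll <- function(th) {
        xk2 <- exp(th[seq_len(Kr)])
        yk2 <- exp(th[-seq_len(Kr)])
        -(sum(nk * dk * log(xk2)) + sum(mk * uk * log(yk2)) -
          sum(outer(nk, mk) * log1p(outer(xk2, yk2))))
      }
      grad <- function(th) {
        e <- expected(exp(th[seq_len(Kr)]), exp(th[-seq_len(Kr)]))
        -c(nk * (dk - e$er), mk * (uk - e$ec))
      }
      opt <- optim(log(c(xk, yk)), negll, grad,
        method = "BFGS",
        control = list(maxit = 1000L, reltol = 1e-15)
      )
      xk <- exp(opt$par[seq_len(Kr)])
      yk <- exp(opt$par[-seq_len(Kr)])
      e <- expected(xk, yk)
      resid <- max(abs(e$er - dk), abs(e$ec - uk))
      method <- "fixed-point+bfgs"
      if (resid > tol) {
        abort(sprintf(
          "BiCM solver failed to reach tol = %g (residual %.3g after %d iterations + BFGS)",
          tol, resid, iterations
        ))
      }
    }
    x[ar] <- xk[ridx]
    y[ac] <- yk[cidx]
    p[ar, ac] <- outer(x[ar], y[ac]) / (1 + outer(x[ar], y[ac]))
    loglik_core <- sum(nk * dk * log(xk)) + sum(mk * uk * log(yk)) -
      sum(outer(nk, mk) * log1p(outer(xk, yk)))
  }

  resid_full <- max(abs(rowSums(p) - d), abs(colSums(p) - u))
  structure(
    list(
      x = setNames(x, row_labels),
      y = setNames(y, col_labels),
      link_prob = p,
      loglik = loglik_core,
      max_degree_residual = resid_full,
      iterations = iterations,
      method = method,
      dim = c(C, P)
    ),
    class = "bicm"
  )
}

#' Fit the Bipartite Random Graph
#'
#' The BiRG constrains only the expected number of links: every pair carries
#' the same probability `p = L / (C * P)`, the observed connectance.
#'
#' @param g a [bipartite_graph()].
#' @return object of class `birg` with elements `p`, `dim`, `row_labels`,
#'   `col_labels`.
#' @export
fit_birg <- function(g) {
  m <- biadjacency(g)
  structure(
    list(
      p = sum(m) / length(m),
      dim = dim(m),
      row_labels = rownames(m),
      col_labels = colnames(m)
    ),
    class = "birg"
  )
}

#' Link-probability matrix of a fitted null model
#'
#' @param model a `bicm` or `birg` object.
#' @return `C x P` matrix of Bernoulli link probabilities.
#' @export
link_probability <- function(model) UseMethod("link_probability")

#' @export
link_probability.bicm <- function(model) model$link_prob

#' @export
link_probability.birg <- function(model) {
  matrix(model$p, model$dim[1], model$dim[2],
    dimnames = list(model$row_labels, model$col_labels)
  )
}

#' @export
print.bicm <- function(x, ...) {
  cat(sprintf(
    "# bicm: %d x %d, loglik %.4f, max degree residual %.3g (%s, %d iterations)\n",
    x$dim[1], x$dim[2], x$loglik, x$max_degree_residual, x$method, x$iterations
  ))
  invisible(x)
}

#' @export
print.birg <- function(x, ...) {
  cat(sprintf("# birg: %d x %d, p = %.6f\n", x$dim[1], x$dim[2], x$p))
  invisible(x)
}

#' @export
tidy.bicm <- function(x, ...) {
  p <- x$link_prob
  tibble(
    label = c(names(x$x), names(x$y)),
    layer = rep(c("rows", "cols"), x$dim),
    hidden_variable = c(unname(x$x), unname(x$y)),
    expected_degree = c(rowSums(p), colSums(p))
  )
}

#' @export
glance.bicm <- function(x, ...) {
  tibble(
    n_rows = x$dim[1], n_cols = x$dim[2],
    loglik = x$loglik,
    max_degree_residual = x$max_degree_residual,
    iterations = x$iterations,
    method = x$method,
    entropy = ensemble_entropy(x)
  )
}

#' @export
glance.birg <- function(x, ...) {
  tibble(
    n_rows = x$dim[1], n_cols = x$dim[2], p = x$p,
    entropy = ensemble_entropy(x)
  )
}

#' Log-probability of a matrix under a fitted model
#'
#' In the grandcanonical ensemble the probability of a matrix factorizes over
#' independent links: `log P(M) = sum_cp [m_cp log p_cp +
#' (1 - m_cp) log(1 - p_cp)]`, with `0 * log 0 = 0`. A matrix carrying a link
#' that the model forbids (`p = 0`), or missing a forced one (`p = 1`),
#' returns `-Inf`.
#'
#' @param model a `bicm` or `birg`.
#' @param g a [bipartite_graph()] of matching dimensions.
#' @return log-probability (possibly `-Inf`).
#' @export
matrix_probability <- function(model, g) {
  p <- link_probability(model)
  m <- biadjacency(g)
  if (!all(dim(p) == dim(m))) abort("model and matrix dimensions differ")
  p1 <- p[m == 1L]
  p0 <- p[m == 0L]
  if (any(p1 == 0) || any(p0 == 1)) {
    return(-Inf)
  }
  sum(log(p1)) + sum(log1p(-p0))
}

# elementary symmetric polynomials e_0..e_n of each column of a probability
# matrix, via the stable recurrence e_k(j) = e_k(j-1) + p_j * e_{k-1}(j-1)
esp_columns <- function(pm, n) {
  E <- matrix(0, n + 1L, ncol(pm))
  E[1L, ] <- 1
  for (r in seq_len(nrow(pm))) {
    pr <- pm[r, ]
    for (k in seq(min(n, r), 1L)) {
      E[k + 1L, ] <- E[k + 1L, ] + pr * E[k, ]
    }
  }
  E
}

#' Analytic expected motif abundance under a null model
#'
#' Under independent links the number of `Vn` motifs on a column is a binomial
#' count over a Poisson-binomial variable, whose expectation is the n-th
#' elementary symmetric polynomial of that column's link probabilities
#' (restricted to the subset rows); the total expectation sums over columns.
#' `Lambda-n` works on the transpose.
#'
#' @param model a `bicm` or `birg`.
#' @param spec a [motif_spec()].
#' @return nonnegative expected abundance.
#' @export
expected_motif_mean <- function(model, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  pm <- motif_matrix(link_probability(model), spec)
  sum(esp_columns(pm, spec$order)[spec$order + 1L, ])
}

#' Analytic motif standard deviation (orders 1 and 2)
#'
#' Columns (for `Vn`) are independent, so variances add. For order 1 the count
#' is a sum of Bernoullis: `Var = sum p(1-p)`. For order 2 the per-column pair
#' count is `T = S(S-1)/2` with `S` Poisson-binomial; factorial moments give
#' `Var(T) = 6 e4 + 6 e3 + e2 - e2^2` in the column's elementary symmetric
#' polynomials. For `n >= 3` no closed form is exposed and `NA` is returned:
#' [motif_report()] then falls back to sampled moments and flags the source.
#'
#' @inheritParams expected_motif_mean
#' @return standard deviation, or `NA_real_` for orders above 2.
#' @export
expected_motif_std <- function(model, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  if (spec$order > 2L) {
    return(NA_real_)
  }
  pm <- motif_matrix(link_probability(model), spec)
  if (spec$order == 1L) {
    return(sqrt(sum(pm * (1 - pm))))
  }
  E <- esp_columns(pm, 4L)
  v <- 6 * E[5L, ] + 6 * E[4L, ] + E[3L, ] - E[3L, ]^2
  sqrt(sum(pmax(v, 0)))
}

#' Expected degree sequences of a null model
#'
#' Row and column sums of the link-probability matrix. For a converged BiCM
#' these reproduce the observed degree sequence within solver tolerance; for a
#' BiRG every row expects `p * P` and every column `p * C`.
#'
#' @param model a `bicm` or `birg`.
#' @return tibble with columns `label`, `layer`, `expected_degree`.
#' @export
expected_degrees <- function(model) {
  p <- link_probability(model)
  tibble(
    label = c(rownames(p), colnames(p)),
    layer = rep(c("rows", "cols"), dim(p)),
    expected_degree = c(rowSums(p), colSums(p))
  )
}

#' Normalized Shannon entropy of the ensemble
#'
#' The Shannon entropy of the grandcanonical distribution, normalized by the
#' network volume `C * P`:
#' `S = -(1/(C P)) sum_cp [p ln p + (1-p) ln(1-p)]`, with `0 ln 0 = 0`. It is
#' bounded by `ln 2` (attained by the uniform ensemble, a BiRG at p = 1/2) and
#' is zero for a deterministic ensemble. Adding constraints can only lower it,
#' so `S(BiCM) <= S(BiRG)` on the same graph.
#'
#' @param model a `bicm` or `birg`.
#' @return entropy in nats per node pair, in `[0, ln 2]`.
#' @export
ensemble_entropy <- function(model) {
  p <- as.numeric(link_probability(model))
  h <- ifelse(p > 0 & p < 1, -(p * log(p) + (1 - p) * log1p(-p)), 0)
  mean(h)
}
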