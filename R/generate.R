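#' Generate synthetic bipartite networks
#'
#' Seed-deterministic generators for the matrix shapes this package is meant
#' to score. Defaults mirror a trade-network-like shape: 151 rows by 538
#' columns with connectance around 0.15 and broad degree distributions.
#'
#' Kinds:
#' * `hidden_variable` — draws each pair with probability
#'   `x_c y_p / (1 + x_c y_p)`, realizing the factorized grandcanonical
#'   measure with known hidden variables. `x` and `y` are log-normal
#'   (`sdlog`, default 1.5, heavy-tailed enough to mimic empirical degree
#'   heterogeneity), rescaled by a common factor so the expected connectance
#'   hits `target_connectance`. The generating `x`, `y` and probability matrix
#'   are attached as attributes `"x"`, `"y"`, `"link_prob"` for
#'   parameter-recovery work.
#' * `nested` — fills the triangular region `(i - 1/2)/C + (j - 1/2)/P <= t`
#'   with `t` chosen so the fill fraction equals `fill`, then flips every cell
#'   independently with probability `noise`; high but imperfect nestedness,
#'   the canonical disassortative fixture.
#' * `biregular` — circulant construction with every row of degree
#'   `row_degree`; columns are balanced (exactly biregular whenever
#'   `C * row_degree` is a multiple of `P`).
#' * `random_uniform` — independent Bernoulli(`p`) links.
#'
#' @param kind generator name.
#' @param n_rows,n_cols layer sizes.
#' @param seed integer seed (same config + seed = same matrix).
#' @param sdlog,target_connectance hidden-variable parameters.
#' @param fill,noise nested parameters (fraction of ones before noise; flip
#'   probability).
#' @param row_degree biregular row degree.
#' @param p uniform link probability.
#' @return a [bipartite_graph()].
#' @export
generate_bipartite <- function(kind = c("hidden_variable", "nested", "biregular", "random_uniform"),
                               n_rows = 151L, n_cols = 538L, seed,
                               sdlog = 1.5, target_connectance = 0.15,
                               fill = 0.35, noise = 0.02,
                               row_degree = 2L, p = 0.15) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) abort("an integer seed is required")
  C <- as.integer(n_rows)
  P <- as.integer(n_cols)
  if (C < 1L || P < 1L) abort("both layers need at least one node")
  rn <- paste0("r", seq_len(C))
  cn <- paste0("c", seq_len(P))
  withr::with_seed(as.integer(seed), {
    switch(kind,
      hidden_variable = {
        if (target_connectance <= 0 || target_connectance >= 1) {
          abort("target_connectance must lie in (0, 1)")
        }
        a <- rlnorm(C, 0, sdlog)
        b <- rlnorm(P, 0, sdlog)
        ab <- outer(a, b)
        dens <- function(ls) mean(exp(ls) * ab / (1 + exp(ls) * ab)) - target_connectance
        ls <- uniroot(dens, c(-40, 40), tol = 1e-12)$root
        pm <- exp(ls) * ab / (1 + exp(ls) * ab)
        m <- matrix(as.integer(runif(C * P) < pm), C, P, dimnames = list(rn, cn))
        g <- new_bipartite_graph(m)
        attr(g, "x") <- setNames(sqrt(exp(ls)) * a, rn)
        attr(g, "y") <- setNames(sqrt(exp(ls)) * b, cn)
        dimnames(pm) <- list(rn, cn)
        attr(g, "link_prob") <- pm
        g
      },
      nested = {
        if (fill <= 0 || fill >= 1) abort("fill must lie in (0, 1)")
        if (noise < 0 || noise >= 1) abort("noise must lie in [0, 1)")
        # threshold t for the anti-diagonal cut (i-1/2)/C + (j-1/2)/P <= t so
        # that the triangular area fraction equals `fill`
        t <- if (fill <= 0.5) sqrt(2 * fill) else 2 - sqrt(2 * (1 - fill))
        base <- outer(
          (seq_len(C) - 0.5) / C, (seq_len(P) - 0.5) / P,
          function(a, b) (a + b) <= t
        )
        flip <- matrix(runif(C * P) < noise, C, P)
        m <- matrix(as.integer(xor(base, flip)), C, P, dimnames = list(rn, cn))
        new_bipartite_graph(m)
      },
      biregular = {
        k <- as.integer(row_degree)
        if (k < 1L || k > P) abort("row_degree must lie in [1, n_cols]")
        m <- matrix(0L, C, P, dimnames = list(rn, cn))
        for (i in seq_len(C)) {
          m[i, ((i - 1L) * k + seq_len(k) - 1L) %% P + 1L] <- 1L
        }
        new_bipartite_graph(m)
      },
      random_uniform = {
        if (p < 0 || p > 1) abort("p must lie in [0, 1]")
        m <- matrix(as.integer(runif(C * P) < p), C, P, dimnames = list(rn, cn))
        new_bipartite_graph(m)
      }
    )
  })
}

#' Draw one matrix from a fitted model
#'
#' Convenience wrapper: a single grandcanonical draw as a
#' [bipartite_graph()] (the single-draw display workflow).
#'
#' @param model a `bicm` or `birg`.
#' @param seed integer seed.
#' @return a [bipartite_graph()].
#' @export
draw_matrix <- function(model, seed) {
  s <- sample_ensemble(model, 1L, seed, list("n_links"), keep_matrices = TRUE)
  new_bipartite_graph(s$matrices[[1L]])
}
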