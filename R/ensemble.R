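# ---- observable registry -----------------------------------------------
# Each parsed observable is a list(name, type, fn) where fn maps a plain 0/1
# matrix to a scalar or a vector. Scalars go into the draws tibble; vectors
# (per-node or per-rank curves) are accumulated into n_draws x length matrices.

scalar_observables <- function() {
  list(
    n_links = function(m) sum(m),
    connectance = function(m) sum(m) / length(m),
    assortativity = function(m) {
      idx <- which(m == 1L, arr.ind = TRUE)
      if (nrow(idx) < 2L) {
        return(NA_real_)
      }
      x <- rowSums(m)[idx[, 1L]]
      y <- colSums(m)[idx[, 2L]]
      if (sd(x) == 0 || sd(y) == 0) {
        return(NA_real_)
      }
      unname(cor(x, y))
    },
    nodf_total = function(m) nodf_fast(m)[1L],
    nodf_rows = function(m) nodf_fast(m)[2L],
    nodf_cols = function(m) nodf_fast(m)[3L],
    mean_anpu = function(m) {
      d <- rowSums(m)
      mean((as.numeric(m %*% colSums(m)) / d)[d > 0])
    },
    mean_ancd = function(m) {
      u <- colSums(m)
      mean((as.numeric(crossprod(m, rowSums(m))) / u)[u > 0])
    }
  )
}

nodf_fast <- function(m) {
  part <- function(mm) {
    n <- nrow(mm)
    if (n < 2L) {
      return(c(0, 0, NA_real_))
    }
    deg <- rowSums(mm)
    ov <- tcrossprod(mm)
    up <- upper.tri(ov)
    dmin <- outer(deg, deg, pmin)[up]
    decr <- (outer(deg, deg, "!=")[up]) & dmin > 0
    contrib <- ifelse(decr, 100 * ov[up] / dmin, 0)
    c(sum(contrib), n * (n - 1) / 2, mean(contrib))
  }
  r <- part(m)
  cc <- part(t(m))
  c((r[1] + cc[1]) / (r[2] + cc[2]), r[3], cc[3])
}

# per-node / per-rank vector observables
vector_observables <- function(C, P) {
  rank_curve <- function(v, len) {
    out <- rep(NA_real_, len)
    v <- sort(v, decreasing = TRUE)
    out[seq_along(v)] <- v
    out
  }
  list(
    anpu = list(len = quote(C), fn = function(m) {
      d <- rowSums(m)
      ifelse(d > 0, as.numeric(m %*% colSums(m)) / d, NA_real_)
    }),
    ancd = list(len = quote(P), fn = function(m) {
      u <- colSums(m)
      ifelse(u > 0, as.numeric(crossprod(m, rowSums(m))) / u, NA_real_)
    }),
    degree_rows = list(len = quote(C), fn = function(m) rowSums(m)),
    degree_cols = list(len = quote(P), fn = function(m) colSums(m)),
    fitness = list(len = quote(C), fn = function(m) {
      fc <- fc_fast(m)
      rank_curve(fc$f, C)
    }),
    complexity = list(len = quote(P), fn = function(m) {
      fc <- fc_fast(m)
      rank_curve(fc$q, P)
    })
  )
}

# lightweight fitness-complexity for per-draw evaluation
fc_fast <- function(m, tol = 1e-7, max_iter = 200L) {
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  mm <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(mm) == 0L || ncol(mm) == 0L) {
    return(list(f = numeric(0), q = numeric(0)))
  }
  f <- rep(1, nrow(mm))
  q <- rep(1, ncol(mm))
  for (it in seq_len(max_iter)) {
    f_new <- as.numeric(mm %*% q)
    q_new <- 1 / as.numeric(crossprod(mm, 1 / f))
    f_new <- f_new / mean(f_new)
    q_new <- q_new / mean(q_new)
    delta <- max(abs(c(f_new - f, q_new - q)) / c(f, q))
    f <- f_new
    q <- q_new
    if (delta < tol) break
  }
  list(f = f, q = q)
}

parse_observables <- function(observables, C, P) {
  if (!is.list(observables)) observables <- as.list(observables)
  sc <- scalar_observables()
  vec <- vector_observables(C, P)
  out <- purrr::map(observables, function(ob) {
    if (inherits(ob, "motif_spec")) {
      nm <- sprintf(
        "%s%d%s", ob$family, ob$order,
        if (is.null(ob$subset)) "" else sprintf("[%d]", length(ob$subset))
      )
      return(list(name = nm, type = "scalar", fn = local({
        spec <- ob
        function(m) sum(choose(colSums(motif_matrix(m, spec)), spec$order))
      })))
    }
    if (!is.character(ob) || length(ob) != 1L) {
      abort("observables must be strings or motif_spec objects")
    }
    if (grepl("^(V|Lambda)[0-9]+$", ob)) {
      fam <- sub("[0-9]+$", "", ob)
      ord <- as.integer(sub("^(V|Lambda)", "", ob))
      spec <- motif_spec(fam, ord)
      return(list(name = ob, type = "scalar", fn = function(m) {
        sum(choose(colSums(motif_matrix(m, spec)), spec$order))
      }))
    }
    if (ob %in% names(sc)) {
      return(list(name = ob, type = "scalar", fn = sc[[ob]]))
    }
    if (ob %in% names(vec)) {
      v <- vec[[ob]]
      return(list(
        name = ob, type = "vector",
        len = eval(v$len), fn = v$fn
      ))
    }
    abort(sprintf("unknown observable: '%s'", ob))
  })
  nms <- purrr::map_chr(out, "name")
  if (anyDuplicated(nms)) abort("duplicate observable names requested")
  setNames(out, nms)
}

#' Sample the grandcanonical ensemble of a fitted null model
#'
#' Draws `n_draws` matrices by setting every pair independently to 1 with its
#' model probability `p_cp`, evaluating the requested observables on each
#' draw. Draws are streamed: matrices are kept only under `keep_matrices`.
#' The draw stream is a deterministic function of `(model, seed, n_draws)`;
#' because observables are evaluated deterministically from each drawn matrix,
#' extending the observable list never changes earlier draws.
#'
#' @param model a `bicm` or `birg`.
#' @param n_draws number of matrices to draw (default 5000, the sampling depth
#'   used for the reference ensemble-density panels).
#' @param seed integer seed; required for reproducibility.
#' @param observables list mixing observable names (`"n_links"`,
#'   `"connectance"`, `"assortativity"`, `"nodf_total"`, `"nodf_rows"`,
#'   `"nodf_cols"`, `"mean_anpu"`, `"mean_ancd"`, `"V2"`, `"Lambda3"`, ...,
#'   per-node `"anpu"`/`"ancd"`/`"degree_rows"`/`"degree_cols"`, per-rank
#'   `"fitness"`/`"complexity"`) and [motif_spec()] objects. Unknown names
#'   error before any sampling starts.
#' @param keep_matrices store the drawn matrices (memory-hungry; only for
#'   small cases or single-draw displays).
#' @return object of class `ensemble_sample`: `$draws` is a tibble with one
#'   row per draw and one column per scalar observable, `$vectors` a list of
#'   `n_draws x length` matrices for vector observables.
#' @export
sample_ensemble <- function(model, n_draws = 5000L, seed,
                            observables = list("n_links"),
                            keep_matrices = FALSE) {
  if (missing(seed) || is.null(seed)) abort("an integer seed is required")
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) abort("n_draws must be >= 1")
  p <- link_probability(model)
  C <- nrow(p)
  P <- ncol(p)
  pv <- as.numeric(p)
  specs <- parse_observables(observables, C, P)
  is_scalar <- purrr::map_chr(specs, "type") == "scalar"
  sc_names <- names(specs)[is_scalar]
  scal <- matrix(NA_real_, n_draws, length(sc_names), dimnames = list(NULL, sc_names))
  vecs <- purrr::map(specs[!is_scalar], function(s) matrix(NA_real_, n_draws, s$len))
  mats <- if (keep_matrices) vector("list", n_draws) else NULL
  dn <- dimnames(p)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_draws)) {
      m <- matrix(as.integer(runif(length(pv)) < pv), C, P, dimnames = dn)
      for (nm in sc_names) scal[k, nm] <- specs[[nm]]$fn(m)
      for (nm in names(vecs)) vecs[[nm]][k, ] <- specs[[nm]]$fn(m)
      if (keep_matrices) mats[[k]] <- m
    }
  })
  structure(
    list(
      draws = dplyr::bind_cols(tibble(draw = seq_len(n_draws)), as_tibble(scal)),
      vectors = vecs,
      matrices = mats,
      n_draws = n_draws,
      seed = as.integer(seed),
      model_class = class(model)[1L],
      dim = c(C, P)
    ),
    class = "ensemble_sample"
  )
}

#' @export
print.ensemble_sample <- function(x, ...) {
  cat(sprintf(
    "# ensemble_sample: %d draws of a %d x %d %s ensemble (seed %d)\n",
    x$n_draws, x$dim[1], x$dim[2], x$model_class, x$seed
  ))
  invisible(x)
}

#' @export
tidy.ensemble_sample <- function(x, ...) {
  tidyr::pivot_longer(x$draws, -"draw",
    names_to = "observable", values_to = "value"
  )
}

#' Sampling moments of an ensemble observable
#'
#' Arithmetic mean and population standard deviation (denominator `n`) over
#' draws, the sampling estimates of the ensemble mean and standard deviation.
#'
#' @param s an [sample_ensemble()] result.
#' @param observable name of a scalar observable requested at sampling time.
#' @return one-row tibble `observable`, `mean`, `sd`, `n_draws`, `n_na`.
#' @export
sampling_moments <- function(s, observable) {
  stopifnot(inherits(s, "ensemble_sample"))
  if (!observable %in% names(s$draws)) {
    abort(sprintf("observable '%s' was not requested at sampling time", observable))
  }
  v <- s$draws[[observable]]
  v <- v[!is.na(v)]
  if (length(v) < 2L) abort("need at least two non-missing draws for moments")
  mu <- mean(v)
  tibble(
    observable = observable,
    mean = mu,
    sd = sqrt(mean((v - mu)^2)),
    n_draws = s$n_draws,
    n_na = s$n_draws - length(v)
  )
}

#' Motif significance report
#'
#' Compares the observed abundance of a motif family with its null
#' expectation. The z-score `z = (observed - expected) / sd` measures
#' statistical significance; the similarity `s = (observed - expected) /
#' expected` measures relative agreement, and their ratio `s/z = sd/expected`
#' is the motif's ensemble coefficient of variation. Standard deviations are
#' analytic for orders 1-2 and sampled (flagged in `moment_source`) for
#' higher orders. Default thresholds: `|z| > 1.65` for whole-graph families,
#' `|z| > 2` for subset-restricted motifs.
#'
#' @param g the observed [bipartite_graph()].
#' @param model a `bicm` or `birg` fitted on `g`.
#' @param spec a [motif_spec()] or list of them (one report row each).
#' @param n_draws,seed sampling controls, used only when a sampled standard
#'   deviation is needed (order >= 3).
#' @param z0 significance threshold; `NULL` picks 1.65 (global) or 2 (subset).
#' @return tibble with one row per motif: observed, expected, sd, z-score,
#'   similarity, coefficient of variation, significance flag and moment
#'   source. `similarity`/`cv` are `NA` when the expectation vanishes; a zero
#'   sd with a nonzero deviation yields an infinite z-score.
#' @export
motif_report <- function(g, model, spec, n_draws = 5000L, seed = NULL, z0 = NULL) {
  if (inherits(spec, "motif_spec")) spec <- list(spec)
  purrr::map_dfr(spec, function(sp) {
    observed <- count_motifs(g, sp)
    expected <- expected_motif_mean(model, sp)
    sdv <- expected_motif_std(model, sp)
    source <- "analytic"
    if (is.na(sdv)) {
      if (is.null(seed)) abort("order >= 3 motifs need sampled moments: supply a seed")
      samp <- sample_ensemble(model, n_draws, seed, list(sp))
      sdv <- sampling_moments(samp, names(samp$draws)[2L])$sd
      source <- "sampled"
    }
    z <- if (sdv > 0) {
      (observed - expected) / sdv
    } else if (observed == expected) 0 else sign(observed - expected) * Inf
    thr <- z0 %||% if (is.null(sp$subset)) 1.65 else 2
    tibble(
      family = sp$family,
      order = sp$order,
      subset_size = if (is.null(sp$subset)) NA_integer_ else length(sp$subset),
      observed = observed,
      expected = expected,
      sd = sdv,
      z_score = z,
      similarity = if (expected > 0) (observed - expected) / expected else NA_real_,
      cv = if (expected > 0) sdv / expected else NA_real_,
      z0 = thr,
      significant = is.finite(z) && abs(z) > thr || is.infinite(z),
      moment_source = source
    )
  })
}

#' Gaussianity diagnostic for an ensemble distribution
#'
#' Sample skewness, excess kurtosis and a Jarque-Bera omnibus statistic with
#' its chi-square p-value, justifying (or not) the gaussian reading of a
#' z-score for this observable. Constant draws are flagged degenerate.
#'
#' @param s an [sample_ensemble()] result with at least 100 draws.
#' @param observable scalar observable name.
#' @return one-row tibble `observable`, `skewness`, `ex_kurtosis`,
#'   `statistic`, `p_value`, `normal` (at the 1% level), `degenerate`.
#' @export
distribution_summary <- function(s, observable) {
  stopifnot(inherits(s, "ensemble_sample"))
  if (!observable %in% names(s$draws)) {
    abort(sprintf("observable '%s' was not requested at sampling time", observable))
  }
  v <- s$draws[[observable]]
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 100L) abort("distribution diagnostics need at least 100 draws")
  m2 <- mean((v - mean(v))^2)
  if (m2 == 0) {
    return(tibble(
      observable = observable, skewness = NA_real_, ex_kurtosis = NA_real_,
      statistic = NA_real_, p_value = NA_real_, normal = NA, degenerate = TRUE
    ))
  }
  g1 <- mean((v - mean(v))^3) / m2^1.5
  g2 <- mean((v - mean(v))^4) / m2^2 - 3
  jb <- n * (g1^2 / 6 + g2^2 / 24)
  pv <- pchisq(jb, df = 2, lower.tail = FALSE)
  tibble(
    observable = observable, skewness = g1, ex_kurtosis = g2,
    statistic = jb, p_value = pv, normal = pv > 0.01, degenerate = FALSE
  )
}

#' Full observed-vs-expected report for a graph under a null model
#'
#' Computes, on one pass through a sampled ensemble: scalar comparisons
#' (assortativity coefficient, NODF total/rows/cols, mean ANPU/ANCD) with
#' ensemble mean, standard deviation and z-score; per-node ANPU/ANCD with
#' ensemble bands at 1 and 2 standard deviations; optionally rank-averaged
#' fitness and complexity curves. Fitness/complexity ensemble averages are
#' taken over *ranked* nodes (the k-th largest value per draw), not node
#' identities, since node identity is not preserved across the ensemble.
#'
#' @param g the observed [bipartite_graph()].
#' @param model a `bicm` or `birg` fitted on `g`.
#' @param n_draws,seed sampling controls.
#' @param include_fitness also compute per-draw fitness-complexity rank curves
#'   (costly for large matrices).
#' @return object of class `observable_report` with tibbles `scalars`,
#'   `nodes` and (optionally) `ranks`.
#' @export
observable_report <- function(g, model, n_draws = 1000L, seed,
                              include_fitness = FALSE) {
  m <- biadjacency(g)
  obs_sc <- c(
    "assortativity", "nodf_total", "nodf_rows", "nodf_cols",
    "mean_anpu", "mean_ancd"
  )
  obs_vec <- c("anpu", "ancd")
  if (include_fitness) obs_vec <- c(obs_vec, "fitness", "complexity")
  samp <- sample_ensemble(model, n_draws, seed, as.list(c(obs_sc, obs_vec)))

  observed_sc <- c(
    assortativity = suppressWarnings(assortativity_coefficient(g)),
    setNames(as.numeric(nodf(g)[1, ]), c("nodf_total", "nodf_rows", "nodf_cols")),
    mean_anpu = scalar_observables()$mean_anpu(m),
    mean_ancd = scalar_observables()$mean_ancd(m)
  )
  scalars <- purrr::map_dfr(obs_sc, function(nm) {
    v <- samp$draws[[nm]]
    v <- v[!is.na(v)]
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    ob <- observed_sc[[nm]]
    tibble(
      observable = nm, observed = ob, expected = mu, sd = sdv,
      z_score = dplyr::case_when(
        is.na(ob) ~ NA_real_,
        sdv > 0 ~ (ob - mu) / sdv,
        ob == mu ~ 0,
        TRUE ~ sign(ob - mu) * Inf
      ),
      n_used = length(v)
    )
  })

  prof <- assortativity_profile(g)
  vec_stats <- function(nm) {
    mat <- samp$vectors[[nm]]
    mu <- colMeans(mat, na.rm = TRUE)
    sdv <- sqrt(colMeans(sweep(mat, 2, mu)^2, na.rm = TRUE))
    list(mean = mu, sd = sdv)
  }
  a <- vec_stats("anpu")
  b <- vec_stats("ancd")
  nodes <- dplyr::mutate(
    prof$nodes,
    expected = c(a$mean, b$mean),
    sd = c(a$sd, b$sd)
  )

  ranks <- NULL
  if (include_fitness) {
    fc <- suppressWarnings(fitness_complexity(g))
    rank_obs <- function(v, len) {
      out <- rep(NA_real_, len)
      out[seq_along(v)] <- sort(v, decreasing = TRUE)
      out
    }
    fstats <- vec_stats("fitness")
    qstats <- vec_stats("complexity")
    ranks <- dplyr::bind_rows(
      tibble(
        layer = "rows", rank = seq_len(nrow(m)),
        observed = rank_obs(fc$fitness$fitness, nrow(m)),
        expected = fstats$mean, sd = fstats$sd
      ),
      tibble(
        layer = "cols", rank = seq_len(ncol(m)),
        observed = rank_obs(fc$complexity$complexity, ncol(m)),
        expected = qstats$mean, sd = qstats$sd
      )
    )
  }

  structure(
    list(
      scalars = scalars, nodes = nodes, ranks = ranks,
      n_draws = samp$n_draws, seed = samp$seed, model_class = class(model)[1L]
    ),
    class = "observable_report"
  )
}

#' @export
print.observable_report <- function(x, ...) {
  cat(sprintf(
    "# observable_report (%s ensemble, %d draws, seed %d)\n",
    x$model_class, x$n_draws, x$seed
  ))
  print(x$scalars)
  invisible(x)
}

#' @export
tidy.observable_report <- function(x, ...) x$scalars
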