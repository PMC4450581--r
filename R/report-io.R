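# flatten a result object into (payload list, flat table) for serialization
report_parts <- function(obj) {
  if (inherits(obj, "assortativity_profile")) {
    list(
      type = "assortativity_profile",
      payload = list(nodes = obj$nodes, summary = obj$summary),
      table = obj$nodes
    )
  } else if (inherits(obj, "fitness_complexity")) {
    list(
      type = "fitness_complexity",
      payload = list(
        fitness = obj$fitness, complexity = obj$complexity,
        n_iterations = obj$n_iterations, converged = obj$converged
      ),
      table = tidy(obj)
    )
  } else if (inherits(obj, "bicm") || inherits(obj, "birg")) {
    list(
      type = class(obj)[1L],
      payload = c(
        list(nodes = tidy_model_safe(obj)),
        if (inherits(obj, "bicm")) {
          list(
            loglik = obj$loglik, max_degree_residual = obj$max_degree_residual,
            iterations = obj$iterations, method = obj$method
          )
        } else {
          list(p = obj$p)
        }
      ),
      table = tidy_model_safe(obj)
    )
  } else if (inherits(obj, "observable_report")) {
    list(
      type = "observable_report",
      payload = list(
        scalars = obj$scalars, nodes = obj$nodes, ranks = obj$ranks,
        n_draws = obj$n_draws, seed = obj$seed
      ),
      table = obj$scalars
    )
  } else if (inherits(obj, "ensemble_sample")) {
    list(
      type = "ensemble_sample",
      payload = list(draws = obj$draws, n_draws = obj$n_draws, seed = obj$seed),
      table = obj$draws
    )
  } else if (is.data.frame(obj)) {
    list(type = "table", payload = list(table = obj), table = obj)
  } else {
    abort(sprintf("cannot serialize object of class '%s'", class(obj)[1L]))
  }
}

tidy_model_safe <- function(obj) {
  if (inherits(obj, "bicm")) {
    df <- tidy(obj)
    # Inf hidden variables (saturated nodes) are not representable in JSON
    # numbers; keep them as strings in payloads
    df$hidden_variable <- ifelse(is.infinite(df$hidden_variable), "Inf",
      as.character(df$hidden_variable)
    )
    df$hidden_variable <- suppressWarnings(as.numeric(df$hidden_variable))
    df
  } else {
    tibble(
      label = c(obj$row_labels, obj$col_labels),
      layer = rep(c("rows", "cols"), obj$dim),
      link_probability = obj$p
    )
  }
}

#' Write a result object to disk
#'
#' JSON reports are nested and carry package version, a content checksum and
#' (where the object records one) the sampling seed; floating-point values are
#' written at full precision so a write/reload round trip is lossless. TSV
#' reports are the flat table form (the object's `tidy()` view).
#'
#' @param obj a package result: `assortativity_profile`,
#'   `fitness_complexity`, `bicm`, `birg`, `observable_report`,
#'   `ensemble_sample`, or any data frame (summaries, motif reports).
#' @param path output file.
#' @param fmt `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path, fmt = c("json", "tsv")) {
  fmt <- match.arg(fmt)
  parts <- report_parts(obj)
  if (fmt == "tsv") {
    tryCatch(suppressWarnings(readr::write_tsv(parts$table, path)),
      error = function(e) abort(sprintf("cannot write %s: %s", path, conditionMessage(e)))
    )
    return(invisible(path))
  }
  out <- c(
    list(
      type = parts$type,
      package = "bicm",
      version = as.character(packageVersion("bicm")),
      checksum = rlang::hash(parts$payload)
    ),
    if ("seed" %in% names(obj)) list(seed = obj[["seed"]]),
    parts$payload
  )
  tryCatch(
    suppressWarnings(
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    ),
    error = function(e) abort(sprintf("cannot write %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Reload a JSON report written by [write_report()]
#'
#' @param path JSON file.
#' @return named list; tabular components become data frames.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("report does not exist: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
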