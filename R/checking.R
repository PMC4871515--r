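# End-to-end model checking: evaluate every statement of a specification
# file against the same trace sequence with a chosen checker. Traces are
# loaded once and reused across statements (keeping several statements in
# one file avoids re-reading the trace set per statement, which dominates
# runtime for large traces).

#' Run statistical model checking for a specification
#'
#' @param spec Specification text or file path: one or more statements
#'   separated by \code{';'}, \code{'#'} comments allowed.
#' @param traces One of: a directory containing MSTML files (consumed in
#'   lexicographic order), a character vector of MSTML paths, or a list of
#'   \code{mst_trace} objects.
#' @param g \code{ma_graph} (object or path to its XML file).
#' @param checker One of \code{"blackbox"}, \code{"chernoff"},
#'   \code{"sprt"}, \code{"bayes-estimate"}, \code{"bayes-factor"}.
#' @param params Named list of checker parameters: \code{epsilon},
#'   \code{delta} (chernoff); \code{alpha}, \code{beta}, \code{half_width}
#'   (sprt); \code{prior_alpha}, \code{prior_beta} plus
#'   \code{variance_threshold} or \code{bf_threshold} (Bayesian checkers).
#' @param registry \code{spatial_registry} (object or config-file path).
#' @param generator Optional generator command for on-demand traces (used
#'   instead of \code{traces}); requires \code{generator_dir}.
#' @param generator_dir Directory watched for generated MSTML files.
#' @param locf Carry numeric variables forward over gaps.
#' @return A list of class \code{mstmc_report}: one element per statement,
#'   each \code{list(statement, verdict, error)} where exactly one of
#'   \code{verdict} / \code{error} is non-NULL.
#' @export
run_model_checking <- function(spec, traces = NULL, g,
                               checker = c("blackbox", "chernoff", "sprt",
                                           "bayes-estimate", "bayes-factor"),
                               params = list(),
                               registry = default_spatial_registry(),
                               generator = NULL, generator_dir = NULL,
                               locf = FALSE) {
  checker <- match.arg(checker)
  if (is.character(g)) g <- read_ma_graph(g)
  if (is.character(registry)) registry <- read_spatial_config(registry)

  trace_list <- NULL
  if (is.null(generator)) {
    if (is.null(traces))
      abort_usage("either traces or a generator command must be supplied")
    if (is.character(traces) && length(traces) == 1L && dir.exists(traces))
      traces <- sort(list.files(traces, pattern = "\\.(xml|mstml)$",
                                full.names = TRUE))
    if (is.character(traces)) {
      trace_list <- lapply(traces, read_mstml, registry = registry)
    } else {
      trace_list <- traces
    }
  }

  queries <- parse_specification(spec, g, registry)
  sources <- attr(queries, "sources")
  results <- vector("list", length(queries))
  for (k in seq_along(queries)) {
    q <- queries[[k]]
    res <- tryCatch({
      provider <- if (is.null(generator)) {
        trace_outcome_provider(trace_list, q, g, registry, locf)
      } else {
        if (is.null(generator_dir))
          abort_usage("generator_dir is required with a generator command")
        generator_outcome_provider(generator, generator_dir, q, g, registry,
                                   locf)
      }
      verdict <- switch(checker,
        blackbox = {
          if (is.null(trace_list))
            abort_usage("blackbox checking needs a fixed trace set")
          outcomes <- draw_n(provider, length(trace_list), "blackbox_check")
          blackbox_check(outcomes, q)
        },
        chernoff = chernoff_check(provider,
                                  need_param(params, "epsilon"),
                                  need_param(params, "delta"), q),
        sprt = sprt_check(provider,
                          need_param(params, "alpha"),
                          need_param(params, "beta"),
                          need_param(params, "half_width"), q),
        "bayes-estimate" = bayes_estimate_check(
          provider,
          need_param(params, "prior_alpha"),
          need_param(params, "prior_beta"),
          need_param(params, "variance_threshold"), q),
        "bayes-factor" = bayes_factor_check(
          provider,
          need_param(params, "prior_alpha"),
          need_param(params, "prior_beta"),
          need_param(params, "bf_threshold"), q))
      list(statement = sources[[k]], verdict = verdict, error = NULL)
    }, mstmc_error = function(e) {
      list(statement = sources[[k]], verdict = NULL,
           error = conditionMessage(e))
    })
    results[[k]] <- res
  }
  structure(results, class = "mstmc_report")
}

need_param <- function(params, name) {
  if (is.null(params[[name]]))
    abort_usage(sprintf("checker parameter '%s' is required", name))
  params[[name]]
}

#' Tabulate a model-checking report
#'
#' One row per statement with the verdict columns: statement text, holds,
#' estimate, total / true / false trace counts and the checker's confidence
#' quantities.
#'
#' @param report An \code{mstmc_report}.
#' @return A data frame.
#' @export
report_table <- function(report) {
  rows <- lapply(report, function(r) {
    if (is.null(r$verdict)) {
      data.frame(statement = r$statement, holds = NA, estimate = NA_real_,
                 n_total = NA_integer_, n_true = NA_integer_,
                 n_false = NA_integer_, confidence = NA_character_,
                 error = r$error, stringsAsFactors = FALSE)
    } else {
      v <- r$verdict
      data.frame(statement = r$statement, holds = v$holds,
                 estimate = v$estimate, n_total = v$n_total,
                 n_true = v$n_true, n_false = v$n_false,
                 confidence = paste(names(v$confidence), signif(v$confidence, 6),
                                    sep = "=", collapse = "; "),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write a report as CSV plus JSON sidecar
#'
#' @param report An \code{mstmc_report}.
#' @param path CSV output path; the JSON sidecar replaces the extension
#'   with \code{.json}.
#' @return Invisibly the report table.
#' @export
write_report <- function(report, path) {
  tab <- report_table(report)
  utils::write.csv(tab, path, row.names = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  payload <- lapply(report, function(r) {
    if (is.null(r$verdict)) {
      list(statement = r$statement, error = r$error)
    } else {
      v <- r$verdict
      list(statement = r$statement, holds = v$holds, estimate = v$estimate,
           n_total = v$n_total, n_true = v$n_true, n_false = v$n_false,
           confidence = as.list(v$confidence), method = v$method)
    }
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(tab)
}

#' @export
print.mstmc_report <- function(x, ...) {
  cat(sprintf("<mstmc_report> %d statement(s)\n", length(x)))
  for (r in x) {
    if (is.null(r$verdict)) {
      cat("  ERROR:", r$error, "\n")
    } else {
      cat(sprintf("  holds=%-5s est=%-8s n=%-4d  %s\n", r$verdict$holds,
                  format(r$verdict$estimate), r$verdict$n_total,
                  substr(r$statement, 1, 60)))
    }
  }
  invisible(x)
}
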