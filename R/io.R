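#' Read aligned event series from a delimited text file
#'
#' Expects a header row of channel labels and one row per sample, every cell
#' an integer 0 or 1. Tab- and comma-separated files are both supported (the
#' separator is inferred from the extension unless given). Missing values
#' and ragged rows are errors: event logic is undefined for gaps. A numeric
#' (non-binary) file can be thresholded on the fly with `binarize`.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated).
#' @param sep field separator; default inferred from the extension.
#' @param binarize optional numeric threshold: cells `>= binarize` become 1,
#'   others 0. Without it, any cell other than 0/1 is a parse error naming
#'   the offending row and column.
#' @return named list of [event_series()], one per column, all aligned.
#' @seealso [write_event_series()]
#' @export
read_event_series <- function(path, sep = NULL, binarize = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop("the series file is empty", call. = FALSE)
  out <- vector("list", ncol(df))
  names(out) <- names(df)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' is not numeric", names(df)[j]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing value at row %d, column '%s'",
                   which(is.na(v))[1L], names(df)[j]), call. = FALSE)
    if (!is.null(binarize)) {
      v <- as.integer(v >= binarize)
    } else {
      bad <- which(v != 0 & v != 1)
      if (length(bad))
        stop(sprintf("non-binary value %s at row %d, column '%s' (use 'binarize' to threshold numeric data)",
                     format(v[bad[1L]]), bad[1L], names(df)[j]),
             call. = FALSE)
    }
    out[[j]] <- event_series(v, label = names(df)[j])
  }
  out
}

#' Write aligned event series to a delimited text file
#'
#' @param series named list of [event_series()] (or 0/1 vectors), all of
#'   equal length; names (or labels) become the header row.
#' @param path output path; extension selects the separator as in
#'   [read_event_series()].
#' @param sep optional explicit separator.
#' @return `path`, invisibly.
#' @export
write_event_series <- function(series, path, sep = NULL) {
  if (inherits(series, "event_series")) series <- list(series)
  series <- lapply(series, as_event_series)
  lens <- vapply(series, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("all series must have equal length", call. = FALSE)
  labels <- names(series)
  if (is.null(labels))
    labels <- vapply(seq_along(series),
                     function(i) series_label(series[[i]], paste0("V", i)), "")
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(lapply(series, unclass), check.names = FALSE)
  names(df) <- labels
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The schema mirrors [sim_config()]:
#' ```yaml
#' n: 5000
#' seed: 7
#' nodes:
#'   - label: Y
#'     base_probability: 0.3          # or a random-walk spec:
#'   - label: X                        #   {initial: 0.3, step_sd: 0.005,
#'     base_probability: 0.3           #    bounds: [0.05, 0.6]}
#' interactions:
#'   - source: Y
#'     target: X
#'     p_interaction: 0.6
#'     delay: {kind: fixed, tau: 4}   # or {support: [...], probabilities: [...]}
#' ```
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path, handlers = yaml_keep_yn_strings())
  else jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$nodes)) stop("config has no 'nodes'", call. = FALSE)
  nodes <- lapply(raw$nodes, function(nd) {
    bp <- nd$base_probability
    if (is.list(bp))
      bp <- random_walk_spec(initial = bp$initial %||% 0.3,
                             step_sd = bp$step_sd %||% 0.005,
                             bounds = unlist(bp$bounds %||% c(0.05, 0.6)))
    node_spec(as.character(nd$label), bp)
  })
  interactions <- lapply(raw$interactions %||% list(), function(ia)
    interaction_spec(as.character(ia$source), as.character(ia$target),
                     ia$p_interaction, parse_delay(ia$delay)))
  sim_config(nodes, interactions,
             n = raw$n %||% 5000,
             seed = raw$seed)
}

# YAML 1.1 would read the bare scalars Y/N/yes/no as booleans, but they are
# the natural node labels here; keep anything that is not a spelled-out
# true/false as the original string
yaml_keep_yn_strings <- function() {
  keep <- function(truth) function(x) {
    if (toupper(x) %in% c("TRUE", "FALSE")) truth else x
  }
  list("bool#yes" = keep(TRUE), "bool#no" = keep(FALSE))
}

parse_delay <- function(d) {
  if (inherits(d, "delay_distribution")) return(d)
  if (is.null(d)) stop("interaction has no 'delay'", call. = FALSE)
  if (!is.null(d$kind)) {
    args <- lapply(d[setdiff(names(d), "kind")], unlist)
    return(do.call(make_delay, c(list(kind = as.character(d$kind)), args)))
  }
  delay_distribution(unlist(d$support), unlist(d$probabilities))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest
#'
#' A small provenance record written alongside every CLI output: package
#' version, the command and full parameter set, the seed, and a timestamp.
#'
#' @param command command or function name.
#' @param parameters named list of parameters.
#' @param seed seed used (or `NULL`).
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(command, parameters = list(), seed = NULL) {
  structure(list(
    tool = "cer",
    version = as.character(utils::packageVersion("cer")),
    command = command,
    parameters = parameters,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Serialize results to JSON
#'
#' Writes a [cer_test()], [bidirectional_scan()], [er_profile()] or
#' [run_experiment()] result (or any list) as JSON, echoing the parameters
#' that produced it. Numbers are written unrounded.
#'
#' @param x object to serialize.
#' @param path output path.
#' @param manifest optional [run_manifest()] embedded under `"manifest"`.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, manifest = NULL) {
  lst <- as_result_list(x)
  if (!is.null(manifest)) lst$manifest <- unclass(manifest)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

as_result_list <- function(x) {
  if (inherits(x, "cer_test")) {
    list(type = "cer_test",
         direction = as.list(x$direction),
         n = x$n, alpha = x$alpha, alpha_effective = x$alpha_effective,
         tail = x$tail, overlap_correction = x$overlap_correction,
         status = x$status, k0 = x$k0,
         upper_limit = x$upper_limit, lower_limit = x$lower_limit,
         lags = x$lags, counts = x$counts, n_eff = x$n_eff,
         pvalues = x$pvalues,
         significant_lags = x$significant$lag,
         significant_signs = x$significant$sign)
  } else if (inherits(x, "cer_scan")) {
    list(type = "cer_scan", pair = as.list(x$pair),
         alpha = x$alpha, tail = x$tail, k0 = x$k0,
         upper_limit = x$upper_limit,
         lags = x$lags, counts = x$counts,
         forward = as_result_list(x$forward),
         reverse = as_result_list(x$reverse))
  } else if (inherits(x, "er_profile")) {
    list(type = "er_profile", cause = x$cause, effect = x$effect,
         n = x$n, alpha = x$alpha, k0 = x$k0,
         upper_limit = x$upper_limit, lower_limit = x$lower_limit,
         lags = x$lags, counts = x$counts, n_eff = x$n_eff,
         frequencies = x$frequencies)
  } else if (inherits(x, "cer_evaluation")) {
    list(type = "cer_evaluation",
         n = attr(x, "n"), tau_max = attr(x, "tau_max"),
         tail = attr(x, "tail"), seed = attr(x, "seed"),
         rates = as.data.frame(x))
  } else if (is.list(x)) {
    x
  } else stop("cannot serialize objects of class ", class(x)[1L],
              call. = FALSE)
}

#' Write a Monte-Carlo evaluation report as tidy CSV
#'
#' One row per (alpha, interaction probability, outcome).
#'
#' @param report a `cer_evaluation` from [run_experiment()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(report, path) {
  if (!inherits(report, "cer_evaluation"))
    stop("'report' must come from run_experiment()", call. = FALSE)
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
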