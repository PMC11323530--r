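#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file describing a stepped-wedge design and an
#' analysis mode, validates every field (all violations are reported
#' together, not first-failure), and returns the validated design plus run
#' options.
#'
#' Recognised keys: `n_clusters`, `n_periods`, `cluster_size`,
#' `p_covariate`, `gammas`, `icc`, `cac`, `sig_level`, `test`, `t_df`,
#' `mode` (`power`, `size`, `nclusters`, `mde`, `simulate-oc`,
#' `reproduce-table`), `method` (`gee`, `kc`, `md`, `all`), `reps`, `seed`,
#' `table`, `target_power`, `effect_scale` (`odds_ratio`, default, or
#' `log_odds`); the baseline as either `baseline_prevalence` or `theta0`
#' (log-odds); effects as `ote`, `covariate_effect`, `hte` on the scale set
#' by `effect_scale`. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List of class `sw_config` with elements `design` ([sw_design()]),
#'   `mode`, `method`, `reps`, `seed`, `table`, `target_power` and the raw
#'   resolved values.
#' @export
load_sw_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("n_clusters", "n_periods", "cluster_size", "p_covariate",
             "gammas", "icc", "cac", "sig_level", "test", "t_df", "mode",
             "method", "reps", "seed", "table", "target_power",
             "effect_scale", "baseline_prevalence", "theta0", "ote",
             "covariate_effect", "hte")
  problems <- character()
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    problems <- c(problems, paste("unknown keys:", paste(unknown, collapse = ", ")))
  }
  need <- c("n_clusters", "n_periods", "cluster_size", "p_covariate",
            "icc", "ote", "covariate_effect", "hte")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    problems <- c(problems, paste("missing keys:", paste(missing, collapse = ", ")))
  }
  if (is.null(raw$theta0) && is.null(raw$baseline_prevalence)) {
    problems <- c(problems, "one of `theta0` (log-odds) or `baseline_prevalence` is required")
  }
  scale <- raw$effect_scale %||% "odds_ratio"
  if (!scale %in% c("odds_ratio", "log_odds")) {
    problems <- c(problems, "`effect_scale` must be 'odds_ratio' or 'log_odds'")
  }
  mode <- raw$mode %||% "power"
  modes <- c("power", "size", "nclusters", "mde", "simulate-oc", "reproduce-table")
  if (!mode %in% modes) {
    problems <- c(problems, paste0("`mode` must be one of: ", paste(modes, collapse = ", ")))
  }
  num_bad <- Filter(function(k) !is.null(raw[[k]]) && (!is.numeric(raw[[k]]) || anyNA(raw[[k]])),
                    intersect(names(raw), setdiff(known, c("mode", "method", "test", "effect_scale", "table"))))
  for (k in num_bad) problems <- c(problems, sprintf("`%s` must be numeric", k))
  for (k in c("n_clusters", "n_periods", "cluster_size", "reps")) {
    v <- raw[[k]]
    if (!is.null(v) && is.numeric(v) && (length(v) != 1 || v <= 0 || v != round(v))) {
      problems <- c(problems, sprintf("`%s` must be a positive integer", k))
    }
  }
  if (length(problems) > 0) {
    stop("invalid configuration (", path, "):\n",
         paste0("- ", problems, collapse = "\n"), call. = FALSE)
  }

  to_log <- function(v) if (scale == "odds_ratio") log(v) else v
  theta0 <- if (!is.null(raw$theta0)) raw$theta0 else stats::qlogis(raw$baseline_prevalence)
  design <- sw_design(
    n_clusters = raw$n_clusters, n_periods = raw$n_periods,
    cluster_size = raw$cluster_size, p_covariate = raw$p_covariate,
    theta0 = theta0,
    gammas = raw$gammas %||% rep(0, raw$n_periods),
    theta1 = to_log(raw$ote), theta2 = to_log(raw$covariate_effect),
    theta3 = to_log(raw$hte),
    icc = raw$icc, cac = raw$cac %||% 1,
    sig_level = raw$sig_level %||% 0.05,
    test = raw$test %||% "wald_z", t_df = raw$t_df
  )
  structure(list(design = design, mode = mode,
                 method = raw$method %||% "all",
                 reps = raw$reps %||% 1000, seed = raw$seed %||% 1,
                 table = raw$table, target_power = raw$target_power %||% 0.8,
                 effect_scale = scale, path = path),
            class = "sw_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table to CSV or JSON
#'
#' Floats are serialised at full precision (display rounding is the
#' caller's concern); reading the file back reproduces the values exactly
#' within double round-trip precision.
#'
#' @param result A data frame (any of the package's result tibbles).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_sw_results <- function(result, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  } else {
    jsonlite::write_json(result, path, digits = NA, auto_unbox = FALSE,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a result table written by [write_sw_results()]
#'
#' @param path File path (`.csv` or `.json`).
#' @return A tibble.
#' @export
read_sw_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
}
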