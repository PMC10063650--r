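# Serialization: scenario configs as JSON/YAML, datasets as CSV with a JSON
# sidecar carrying the generative truth, selection results as JSON.

#' Read or write a scenario configuration
#'
#' The format is chosen by file extension: `.json` via jsonlite, `.yaml` /
#' `.yml` via yaml.
#'
#' @param path File path.
#' @return `read_scenario_config()` returns a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  # YAML 1.1 coerces a bare `n:` key to a boolean; map it back
  names(lst)[names(lst) %in% c("FALSE", "no")] <- "n"
  do.call(scenario_config, lst[!vapply(lst, is.null, logical(1))])
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  lst <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Write a generated dataset to CSV with a JSON sidecar
#'
#' The CSV holds the `x1..xp` columns and the response `y`; the sidecar
#' (`<path>.json`) records `beta`, `signal_idx`, `intercept` and the
#' scenario, so evaluations against the generative truth stay possible.
#'
#' @param ds A [generate_dataset()] result.
#' @param path CSV path.
#' @param sidecar Write the sidecar (default `TRUE`).
#' @export
write_dataset_csv <- function(ds, path, sidecar = TRUE) {
  stopifnot(inherits(ds, "sim_dataset"))
  readr::write_csv(ds$data, path)
  if (sidecar) {
    jsonlite::write_json(
      list(beta = ds$beta, signal_idx = ds$signal_idx,
           intercept = ds$intercept, role = ds$role,
           config = unclass(ds$config)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a predictor/response CSV
#'
#' @param path CSV path with a header row; the response column is 0/1.
#' @param response Response column name (default `"y"`).
#' @return A tibble.
#' @export
read_dataset_csv <- function(path, response = "y") {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found in ", path, call. = FALSE)
  }
  data
}

#' Write a selection result to JSON
#'
#' Serializes the selected variables (1-based indices keyed to the input
#' column order, plus names), per-variable scores, method parameters, and —
#' for weighted stability selection — the per-iteration audit records.
#'
#' @param fit A `wss_fit` or `cpss_fit`.
#' @param path Output JSON path.
#' @export
write_selection_json <- function(fit, path) {
  out <- if (inherits(fit, "wss_fit")) {
    list(method = "wss",
         parameters = list(B = fit$B, alpha = fit$alpha,
                           lambda_rule = fit$lambda_rule, seed = fit$seed),
         scores = fit$score$A_w, p_w = fit$score$p_w,
         selected = fit$selected, selected_names = fit$variables[fit$selected],
         iterations = lapply(seq_along(fit$iterations), function(b) {
           r <- fit$iterations[[b]]
           list(b = b, support_half1 = r$support_half1,
                support_half2 = r$support_half2, intersection = r$intersection,
                refit_set = r$refit_set, auc = r$auc,
                weight = fit$weights[b], flags = r$flags)
         }))
  } else if (inherits(fit, "cpss_fit")) {
    list(method = "cpss",
         parameters = list(B = fit$B, pfer_bound = fit$pfer_bound,
                           pi_thr = fit$pi_thr, q = fit$q,
                           assumption = fit$assumption, seed = fit$seed),
         scores = fit$pi_tilde, error_bound = fit$error_bound,
         selected = fit$selected, selected_names = fit$variables[fit$selected])
  } else {
    stop("fit must be a wss_fit or cpss_fit", call. = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
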