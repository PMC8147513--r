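SESSION_LOG_VERSION <- "1.0"

#' Load a session configuration from JSON
#'
#' Missing fields take the protocol defaults (seeds 30/80/90/140 Hz, 8
#' iterations, 5 Hz grid from 10 to 185 Hz, exploration ratio 0.5,
#' preference querying on); an empty file yields the all-defaults config.
#' Validation failures name the offending fields.
#'
#' @param path path to a JSON config file.
#' @return a [session_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) invalid_parameter(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- if (nchar(trimws(txt)) == 0) list()
  else tryCatch(jsonlite::fromJSON(txt),
                error = function(e)
                  validation_error(sprintf("cannot parse config JSON: %s",
                                           conditionMessage(e))))
  known <- names(formals(session_config))
  unknown <- setdiff(names(obj), c(known, "format_version"))
  if (length(unknown))
    validation_error(sprintf("unknown config field(s): %s",
                             paste(unknown, collapse = ", ")),
                     fields = unknown)
  do.call(session_config, obj[intersect(names(obj), known)])
}

#' Save a session configuration to JSON
#'
#' @param config a [session_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  obj <- unclass(config)
  if (!is.finite(obj$ceiling)) obj$ceiling <- NULL  # Inf has no JSON literal
  jsonlite::write_json(c(list(format_version = SESSION_LOG_VERSION), obj),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a session log
#'
#' A lossless JSON round-trip of everything needed to re-fit every model
#' offline: the configuration (including the master seed), the measurement
#' history with acquisition metadata, the preference records, the final GP
#' hyperparameters and the frozen prior mean.
#'
#' @param state a `session_state` from [run_session()].
#' @param path JSON path.
#' @return [read_session_log()] returns a `session_state` (its `model` is
#'   rebuilt from the stored hyperparameters and history).
#' @export
write_session_log <- function(state, path) {
  stopifnot(inherits(state, "session_state"))
  cfg <- unclass(state$config)
  if (!is.finite(cfg$ceiling)) cfg$ceiling <- NULL
  obj <- list(format_version = SESSION_LOG_VERSION,
              config = cfg,
              history = state$history,
              preferences = state$preferences,
              model_params = unclass(state$model$params),
              mean_const = state$mean_const,
              ceiling = if (is.finite(state$ceiling)) state$ceiling else NULL,
              status = state$status)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) invalid_parameter(sprintf("no such file: %s", path))
  o <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  validation_error(sprintf("cannot parse session log: %s",
                                           conditionMessage(e))))
  if (is.null(o$format_version))
    validation_error("session log lacks a format_version field")
  if (!identical(o$format_version, SESSION_LOG_VERSION))
    dbs_error("dbstune_unsupported_version",
              sprintf("unsupported session log version '%s' (expected '%s')",
                      o$format_version, SESSION_LOG_VERSION))
  cfg <- do.call(session_config,
                 o$config[intersect(names(o$config),
                                    names(formals(session_config)))])
  h <- as.data.frame(o$history)
  # JSON row records do not preserve column order/types; rebuild canonically
  history <- data.frame(
    frequency_hz = as.numeric(h$frequency_hz),
    romar = as.numeric(h$romar),
    source = as.character(h$source),
    order_index = as.integer(h$order_index),
    utility_argmax = if (is.null(h$utility_argmax)) NA_real_
                     else as.numeric(h$utility_argmax),
    overexploit_flag = as.logical(h$overexploit_flag),
    ceiling = as.numeric(h$ceiling))
  prefs <- if (length(o$preferences)) {
    pf <- as.data.frame(o$preferences)
    data.frame(step_index = as.integer(pf$step_index),
               frequency_a_hz = as.numeric(pf$frequency_a_hz),
               frequency_b_hz = as.numeric(pf$frequency_b_hz),
               winner = as.character(pf$winner))
  } else empty_preferences()
  obs <- observation_set(history$frequency_hz, history$romar,
                         history$source, history$order_index)
  p <- o$model_params
  model <- gp_model(kernel_params(ell = p$ell, signal_var = p$signal_var,
                                  noise_var = p$noise_var, nu = p$nu),
                    obs, mean_const = o$mean_const)
  structure(list(config = cfg, history = history, preferences = prefs,
                 model = model, mean_const = o$mean_const,
                 ceiling = if (is.null(o$ceiling)) Inf else o$ceiling,
                 status = o$status),
            class = "session_state")
}
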