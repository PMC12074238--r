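# File round-trips. All tabular artifacts are UTF-8 CSV with a header;
# event logs additionally embed the producing config, agent label and seed
# as '#'-prefixed comment lines so every artifact is self-describing.
# Configs serialize to YAML or JSON (chosen by file extension).

config_to_list <- function(config) {
  out <- unclass(config)
  out$spawn_lane_distribution <- as.list(config$spawn_lane_distribution)
  out
}

config_from_list <- function(lst) {
  known <- names(formals(game_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(lst$spawn_lane_distribution)) {
    lst$spawn_lane_distribution <- unlist(lst$spawn_lane_distribution)
  }
  do.call(game_config, lst)
}

#' Read and write session configurations
#'
#' @param config A [game_config()].
#' @param path File path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @return `read_config()` returns a validated [game_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pam_game_config"))
  lst <- config_to_list(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lst <- tryCatch(
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    },
    error = function(e) {
      stop("malformed config file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  config_from_list(lst)
}

#' Read and write event logs
#'
#' One CSV row per trial. The producing config (JSON), agent label and
#' seed are embedded as comment lines and restored on read, so
#' `read_event_log(write_event_log(log, path))` reproduces the log,
#' including its attributes.
#'
#' @param log A `pam_event_log` from [run_session()].
#' @param path CSV file path.
#' @return `read_event_log()` returns the validated `pam_event_log`;
#'   `write_event_log()` returns `path` invisibly.
#' @export
write_event_log <- function(log, path) {
  validate_event_log(log)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  cfg <- attr(log, "config")
  if (!is.null(cfg)) {
    writeLines(paste0("# config: ", jsonlite::toJSON(
      config_to_list(cfg), auto_unbox = TRUE, digits = NA
    )), con)
  }
  if (!is.null(attr(log, "agent_label"))) {
    writeLines(paste0("# agent: ", attr(log, "agent_label")), con)
  }
  if (!is.null(attr(log, "seed"))) {
    writeLines(paste0("# seed: ", attr(log, "seed")), con)
  }
  utils::write.csv(as.data.frame(log)[event_log_columns], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 10L, encoding = "UTF-8")
  header <- header[startsWith(header, "#")]
  log <- tryCatch(
    utils::read.csv(path, comment.char = "#", encoding = "UTF-8"),
    error = function(e) {
      stop("malformed event-log CSV '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  validate_event_log(log)
  log <- log[event_log_columns]

  pull <- function(key) {
    line <- grep(paste0("^# ", key, ": "), header, value = TRUE)
    if (length(line)) sub(paste0("^# ", key, ": "), "", line[1]) else NULL
  }
  cfg_json <- pull("config")
  if (!is.null(cfg_json)) {
    attr(log, "config") <- config_from_list(
      jsonlite::fromJSON(cfg_json, simplifyVector = TRUE)
    )
  }
  agent <- pull("agent")
  if (!is.null(agent)) attr(log, "agent_label") <- agent
  seed <- pull("seed")
  if (!is.null(seed)) attr(log, "seed") <- as.integer(seed)
  class(log) <- c("pam_event_log", "data.frame")
  log
}

#' Read and write long-format rating datasets
#'
#' @param ratings A data frame with at least `participant` and `rating`
#'   columns (ratings in 1..7), e.g. from [generate_ratings()].
#' @param path CSV file path.
#' @return `read_ratings()` returns the validated `pam_rating_dataset`;
#'   `write_ratings()` returns `path` invisibly. Out-of-range or missing
#'   values are reported with row context.
#' @export
write_ratings <- function(ratings, path) {
  validate_rating_dataset(ratings)
  utils::write.csv(as.data.frame(ratings), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ratings <- tryCatch(
    utils::read.csv(path, encoding = "UTF-8"),
    error = function(e) {
      stop("malformed ratings CSV '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  missing_cols <- setdiff(c("participant", "rating"), names(ratings))
  if (length(missing_cols)) {
    stop("ratings CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!ratings$rating %in% 1:7)
  if (length(bad)) {
    stop("invalid rating at row ", bad[1], ": ", ratings$rating[bad[1]],
         " (must be an integer in 1..7)", call. = FALSE)
  }
  class(ratings) <- c("pam_rating_dataset", "data.frame")
  ratings
}
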