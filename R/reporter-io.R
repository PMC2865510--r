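#' Read a reporter fold-change table from CSV
#'
#' Expected columns: `enhancer`, `construct`, `intact_sites`
#' (semicolon-joined site names; empty for the enhancerless reference)
#' and `fold_enhancement`. Extra columns (e.g. `source`) are kept.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_reporter_csv <- function(path) {
  tb <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("enhancer", "construct", "intact_sites", "fold_enhancement")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    abort(paste0("Reporter CSV lacks column(s): ",
                 paste(miss, collapse = ", ")),
          class = "triadswitch_schema_error")
  }
  tb
}

#' Write a reporter table to CSV
#' @param data Reporter tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reporter_csv <- function(data, path) {
  if (is.list(data$intact_sites)) {
    data$intact_sites <- purrr::map_chr(data$intact_sites, paste,
                                        collapse = ";")
  }
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

model_to_list <- function(m) {
  cf <- m$configurations
  list(
    name = m$name,
    K = m$K,
    configurations = setNames(as.list(cf$weight), cf$id),
    omega = as.list(m$omega)
  )
}

list_to_model <- function(l) {
  m <- enhancer_model(l$name, unlist(l$configurations), l$K,
                      omega = unlist(l$omega))
  m
}

#' Write fitted enhancer models to a structured config file
#'
#' Serializes names, configuration weights, chromatin constants and
#' omega factors to JSON (`.json`) or YAML (`.yml`/`.yaml`).
#'
#' @param models Named list of [enhancer_model()] objects (or a single
#'   model).
#' @param path Output path; the extension picks the format.
#' @return `path`, invisibly.
#' @export
write_enhancer_config <- function(models, path) {
  if (inherits(models, "enhancer_model")) models <- list(models)
  payload <- purrr::map(models, model_to_list)
  names(payload) <- purrr::map_chr(models, ~ .x$key)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path, precision = 15)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read enhancer models from a structured config file
#' @param path JSON or YAML file written by [write_enhancer_config()].
#' @return Named list of [enhancer_model()] objects.
#' @export
read_enhancer_config <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map(payload, list_to_model)
}
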