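# Quota-aware, cached retrieval of OMIM-dialect entries.  The live API
# allows 250 requests per key per day, so fetches are cached on disk
# and a persisted daily-budget ledger (JSON sidecar keyed by UTC date)
# is decremented only on live fetches; cache hits never consume quota.

.quota_error <- function(budget) {
  stop(structure(
    class = c("gdamine_quota_error", "error", "condition"),
    list(message = sprintf(
      "daily API budget of %d requests exhausted; resume after the UTC day rolls over",
      budget), call = NULL)))
}

#' Load fetch configuration from YAML
#'
#' Reads \code{api_key}, \code{cache_dir} and \code{daily_budget}
#' (default 250) from a YAML file.
#'
#' @param path YAML file.
#' @return named list.
#' @export
load_fetch_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(api_key = cfg$api_key %||% "",
       cache_dir = cfg$cache_dir %||% ".",
       daily_budget = as.integer(cfg$daily_budget %||% 250L),
       base_url = cfg$base_url %||% "https://api.omim.org/api/entry")
}

quota_state <- function(cache_dir) {
  f <- file.path(cache_dir, "quota.json")
  today <- format(Sys.time(), "%Y-%m-%d", tz = "UTC")
  if (file.exists(f)) {
    st <- jsonlite::fromJSON(f)
    if (identical(st$date, today)) {
      return(list(file = f, date = today, used = as.integer(st$used)))
    }
  }
  list(file = f, date = today, used = 0L)
}

.quota_bump <- function(st) {
  st$used <- st$used + 1L
  jsonlite::write_json(list(date = st$date, used = st$used), st$file,
                       auto_unbox = TRUE)
  st
}

#' Fetch an OMIM-dialect entry, cache-first and quota-aware
#'
#' Returns the parsed entry for a MIM number.  A cached raw response is
#' served without consuming quota; a live fetch decrements the
#' persisted daily budget and fails with a quota-exhausted error once
#' the budget reaches zero (resume the next UTC day).
#'
#' @param mim_number 6-digit MIM identifier.
#' @param config list as returned by \code{\link{load_fetch_config}}:
#'   \code{api_key}, \code{cache_dir}, \code{daily_budget},
#'   \code{base_url}.
#' @return an \code{omim_entry}.
#' @export
fetch_entry <- function(mim_number, config) {
  mim <- suppressWarnings(as.integer(mim_number))
  if (is.na(mim) || mim < 100000L || mim > 999999L)
    stop("mim_number must be a 6-digit MIM identifier")
  cache_dir <- config$cache_dir
  if (!dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  cache_file <- file.path(cache_dir, paste0(mim, ".json"))
  if (file.exists(cache_file)) {
    return(parse_omim_entry(cache_file))
  }
  budget <- as.integer(config$daily_budget %||% 250L)
  st <- quota_state(cache_dir)
  if (st$used >= budget) .quota_error(budget)
  url <- sprintf("%s?mimNumber=%d&include=all&format=json&apiKey=%s",
                 config$base_url %||% "https://api.omim.org/api/entry",
                 mim, config$api_key %||% "")
  raw <- tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
                  error = function(e) {
                    stop(sprintf("entry %d could not be retrieved: %s",
                                 mim, conditionMessage(e)))
                  })
  st <- .quota_bump(st)
  entry <- parse_omim_entry(raw)   # malformed responses error here
  writeLines(raw, cache_file)
  entry
}
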