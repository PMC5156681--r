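trial_columns <- c("condition_id", "n_lines", "pitches", "length_deg",
                   "reported_pel_deg", "trial_idx")

# "20;30" -> c(20, 30); "" -> numeric(0). `row` labels errors for the user.
parse_pitches <- function(x, row = NULL) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(parts) == 0L || any(!nzchar(trimws(parts))) || any(is.na(vals)))
    stop(sprintf("malformed pitch list %s%s", dQuote(x, q = FALSE),
                 if (is.null(row)) "" else sprintf(" in row %d", row)),
         call. = FALSE)
  vals
}

validate_trials <- function(trials) {
  if (!is.data.frame(trials))
    stop("trial table must be a data frame")
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0L)
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  for (col in c("n_lines", "length_deg", "reported_pel_deg", "trial_idx")) {
    raw <- trials[[col]]
    if (is.character(raw)) raw[!is.na(raw) & !nzchar(trimws(raw))] <- NA
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column %s, row %d", col, bad[1L]))
    trials[[col]] <- v
  }
  bad <- which(!is.finite(trials$reported_pel_deg))
  if (length(bad) > 0L)
    stop(sprintf("non-finite reported_pel_deg in row %d", bad[1L]))
  trials$pitches[is.na(trials$pitches)] <- ""
  trials$condition_id <- as.character(trials$condition_id)
  trials$n_lines <- as.integer(trials$n_lines)
  trials$trial_idx <- as.integer(trials$trial_idx)
  for (i in seq_len(nrow(trials))) {
    p <- parse_pitches(trials$pitches[i], row = i)
    if (length(p) != trials$n_lines[i])
      stop(sprintf("row %d: n_lines = %d but %d pitches listed",
                   i, trials$n_lines[i], length(p)))
  }
  trials[, trial_columns]
}

#' Read a trial table from CSV
#'
#' Header-validated reader for the trial-table format written by
#' [write_trials()]: columns `condition_id`, `n_lines`, `pitches`
#' (semicolon-joined degrees; empty for dark trials), `length_deg` (empty for
#' dark), `reported_pel_deg`, `trial_idx`. Malformed angle lists and
#' non-numeric fields are reported with their row number.
#'
#' @param path Path to a CSV file.
#' @return A validated trial-table data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L)
    stop("trial table is empty: ", path)
  validate_trials(raw)
}

#' Write a trial table to CSV
#'
#' @param trials A trial-table data frame (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  out <- trials
  # 17 significant digits so doubles round-trip exactly
  for (col in c("length_deg", "reported_pel_deg")) {
    v <- formatC(out[[col]], digits = 17, format = "g")
    v[is.na(out[[col]])] <- ""
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' Configuration is a flat JSON object (e.g. `prior_mean`, `prior_sd`,
#' `sigma_vi` as a length-keyed map, `sigma_vl`, design fields, `seed`).
#' Command-line flags override config keys.
#'
#' @param path Path to a JSON file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config must be a flat JSON object")
  cfg
}

config_to_params <- function(cfg) {
  if (is.null(cfg$prior_mean) || is.null(cfg$prior_sd))
    stop("config needs `prior_mean` and `prior_sd`")
  sigma_vi <- if (!is.null(cfg$sigma_vi)) unlist(cfg$sigma_vi) else NULL
  model_params(gaussian_belief(cfg$prior_mean, sd = cfg$prior_sd),
               sigma_vi = sigma_vi, sigma_vl = cfg$sigma_vl)
}
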