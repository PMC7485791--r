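# CSV dialects shared by the generator and the pipeline: ISO-8601 dates,
# '.' decimal point, UTF-8. One schema per table kind.

SCHEMA_VERSION <- "1.0"

table_schemas <- function() {
  list(
    rri = readr::cols(
      driver_id = readr::col_character(), date = readr::col_date(),
      condition = readr::col_character(), beat_index = readr::col_integer(),
      rri_ms = readr::col_double()
    ),
    events = readr::cols(
      driver_id = readr::col_character(), date = readr::col_date(),
      event_id = readr::col_character(), start_time = readr::col_character(),
      sample_index = readr::col_integer(), speed_kmh = readr::col_double()
    ),
    drivers = readr::cols(
      driver_id = readr::col_character(), age = readr::col_double(),
      sex = readr::col_character()
    ),
    cohort = readr::cols(
      driver_id = readr::col_character(), date = readr::col_date(),
      wt_hours = readr::col_double(), vas_pre = readr::col_double(),
      vas_post = readr::col_double()
    ),
    hrv = readr::cols(
      driver_id = readr::col_character(), date = readr::col_date(),
      condition = readr::col_character(), n_beats = readr::col_integer(),
      accepted = readr::col_logical(), lf_power = readr::col_double(),
      hf_power = readr::col_double(), lf_hf = readr::col_double(),
      rri_average = readr::col_double(), lf_score = readr::col_double()
    ),
    daily = readr::cols(
      driver_id = readr::col_character(), date = readr::col_date(),
      R = readr::col_integer(), n_events = readr::col_integer(),
      wt_hours = readr::col_double(), r_1hr = readr::col_double(),
      included = readr::col_logical()
    ),
    features = readr::cols(
      driver_id = readr::col_character(), date = readr::col_date(),
      event_id = readr::col_character(), duration = readr::col_double(),
      max_speed = readr::col_double(), min_speed = readr::col_double(),
      avg_speed = readr::col_double(), speed_deviation = readr::col_double(),
      max_decel_per_s = readr::col_double(), label = readr::col_integer()
    )
  )
}

#' Read a typed pipeline table
#'
#' @param path CSV path.
#' @param schema one of `"rri"`, `"events"`, `"drivers"`, `"cohort"`,
#'   `"hrv"`, `"daily"`, `"features"`.
#' @return Typed tibble. Missing or extra required columns raise a
#'   schema error naming the column; an unparseable cell raises a
#'   row-level error with its line number. An empty file with a valid
#'   header yields zero rows.
#' @export
read_table <- function(path, schema) {
  spec <- table_schemas()[[schema]]
  if (is.null(spec)) stop_("unknown schema '%s'", schema)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  need <- names(spec$cols)
  miss <- setdiff(need, hdr)
  if (length(miss) > 0)
    stop_("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  # readr's parse warning is redundant here: problems are promoted to errors
  out <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                          show_col_types = FALSE))
  pr <- readr::problems(out)
  if (nrow(pr) > 0)
    stop_("%s: unparseable cell at line %d, column '%s' (expected %s)",
          path, pr$row[1], hdr[pr$col[1]] %||% pr$col[1], pr$expected[1])
  out[need]
}

#' Write a typed pipeline table
#'
#' @param x tibble holding at least the schema's columns.
#' @param path output CSV path.
#' @inheritParams read_table
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema) {
  spec <- table_schemas()[[schema]]
  if (is.null(spec)) stop_("unknown schema '%s'", schema)
  need <- names(spec$cols)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop_("cannot write %s table: missing column(s): %s", schema,
          paste(miss, collapse = ", "))
  readr::write_csv(x[need], path)
  invisible(path)
}
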