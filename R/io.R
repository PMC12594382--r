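# CSV + sidecar-schema reader/writer. The CSV carries a header row and
# empty fields (or the literal "NA") for missing cells; the JSON schema
# records each column's name, kind (continuous/categorical), declared
# level order and role (predictor/outcome), so factor levels survive the
# round trip.

#' Build the schema of a data frame
#'
#' @param data A data frame.
#' @param outcome Optional outcome column name (role `"outcome"`).
#' @return List of per-column schemas `{name, kind, levels, role}`.
#' @export
table_schema <- function(data, outcome = NULL) {
  data <- as_table(data)
  lapply(names(data), function(v) {
    list(name = v,
         kind = variable_kind(data[[v]]),
         levels = if (is.factor(data[[v]])) as.list(levels(data[[v]])) else list(),
         role = if (identical(v, outcome)) "outcome" else "predictor")
  })
}

#' Write a data frame as CSV plus a JSON schema sidecar
#'
#' @param data A data frame.
#' @param csv_path CSV output path; the schema is written to
#'   `schema_path`.
#' @param schema_path JSON schema path (default: `csv_path` with a
#'   `.schema.json` suffix).
#' @param outcome Optional outcome column name.
#' @return `csv_path`, invisibly.
#' @export
write_table <- function(data, csv_path,
                        schema_path = paste0(csv_path, ".schema.json"),
                        outcome = NULL) {
  data <- as_table(data)
  utils::write.csv(data, csv_path, row.names = FALSE, na = "")
  jsonlite::write_json(table_schema(data, outcome), schema_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(csv_path)
}

#' Read a CSV written with a JSON schema sidecar
#'
#' Empty fields and the literal `NA` are read as missing. Categorical
#' columns are restored as factors with the declared level order;
#' continuous columns as numeric.
#'
#' @param csv_path CSV input path.
#' @param schema_path JSON schema path.
#' @return List with `data` (tibble) and `outcome` (name or `NULL`).
#' @export
read_table <- function(csv_path, schema_path = paste0(csv_path, ".schema.json")) {
  schema <- jsonlite::read_json(schema_path)
  raw <- utils::read.csv(csv_path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  cols <- vapply(schema, function(s) s$name, character(1))
  if (!setequal(cols, names(raw))) abort("CSV columns do not match the schema")
  out <- tibble::as_tibble(raw)[cols]
  outcome <- NULL
  for (s in schema) {
    if (s$kind == "continuous") {
      out[[s$name]] <- as.numeric(out[[s$name]])
    } else {
      lv <- unlist(s$levels)
      bad <- !is.na(out[[s$name]]) & !(out[[s$name]] %in% lv)
      if (any(bad)) {
        abort(paste0("value(s) outside declared levels in column '", s$name, "'"))
      }
      out[[s$name]] <- factor(out[[s$name]], levels = lv)
    }
    if (identical(s$role, "outcome")) outcome <- s$name
  }
  list(data = out, outcome = outcome)
}

#' Write a run manifest next to command outputs
#'
#' @param path Manifest path.
#' @param command Command name.
#' @param args Named list of arguments/config (hashed into the manifest).
#' @param seed Integer seed used.
#' @param outputs Character vector of output paths.
#' @param elapsed Elapsed wall-clock seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, args, seed, outputs, elapsed) {
  manifest <- list(
    command = command,
    version = as.character(utils::packageVersion("forestfill")),
    seed = seed,
    config = args,
    config_hash = rlang::hash(args),
    outputs = outputs,
    elapsed_seconds = round(elapsed, 3),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
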