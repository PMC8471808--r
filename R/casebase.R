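#' Validate a case base against a schema
#'
#' A case base is a plain tibble: one row per case, an `id` column (character,
#' unique) and one column per schema feature. Validation checks that every
#' declared feature is present, that every value lies inside its declared
#' domain, and that no value is missing (the label column may be absent or
#' `NA` for unlabelled query cases).
#'
#' @param data A data frame of cases.
#' @param schema A `cbr_schema`.
#' @param strict If `TRUE` (default) any violation is an error naming the
#'   offending row and feature; if `FALSE`, offending rows are dropped with a
#'   message reporting how many were removed.
#' @param require_label Whether the label column must be present and complete.
#' @return The validated (possibly filtered) tibble, invisibly classed as-is.
#' @export
validate_casebase <- function(data, schema, strict = TRUE, require_label = FALSE) {
  validate_schema(schema)
  data <- tibble::as_tibble(data)
  id_col <- schema_features(schema, "id")
  if (length(id_col) == 0L) id_col <- "id"
  feats <- schema$name[!schema$channel %in% "id"]
  label <- schema_label(schema)
  needed <- c(id_col, setdiff(feats, label))
  missing_cols <- setdiff(needed, names(data))
  if (require_label && !label %in% names(data)) missing_cols <- c(missing_cols, label)
  if (length(missing_cols) > 0L) {
    abort(paste0("case base is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate case id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  data[[id_col]] <- ids

  check_cols <- intersect(feats, names(data))
  bad_rows <- rep(FALSE, nrow(data))
  first_bad <- NULL
  for (f in check_cols) {
    sp <- schema_spec(schema, f)
    x <- data[[f]]
    if (sp$kind == "categorical") {
      ok <- !is.na(x) & as.character(x) %in% sp$levels[[1]]
    } else {
      x <- as.numeric(x)
      data[[f]] <- x
      ok <- !is.na(x) & x >= sp$lower & x <= sp$upper
      if (sp$kind == "binary") ok <- ok & x %in% c(0, 1)
    }
    if (f == label) ok <- ok | is.na(data[[f]])  # unlabelled queries allowed
    if (f == label && require_label) ok <- !is.na(data[[f]]) & ok
    if (any(!ok) && is.null(first_bad)) {
      i <- which(!ok)[1]
      first_bad <- paste0("case '", ids[i], "': value ", format(data[[f]][i]),
                          " outside the declared domain of feature '", f, "'")
    }
    bad_rows <- bad_rows | !ok
  }
  if (any(bad_rows)) {
    if (strict) abort(first_bad)
    message(sum(bad_rows), " case(s) dropped during validation (", first_bad, ")")
    data <- data[!bad_rows, , drop = FALSE]
  }
  tibble::as_tibble(data)
}

#' Read and write case bases as CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with a header, `.` as the
#' decimal mark, and the id column first. Columns are parsed according to the
#' declared feature kinds and validated on load.
#'
#' @param path CSV file path.
#' @param schema A `cbr_schema`.
#' @param strict Passed to [validate_casebase()].
#' @return `read_casebase()` returns a validated tibble; `write_casebase()`
#'   returns `path` invisibly.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 10, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_casebase(base, f)
#' identical_base <- read_casebase(f, fna_schema())
read_casebase <- function(path, schema, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_schema(schema)
  id_col <- schema_features(schema, "id")
  if (length(id_col) == 0L) id_col <- "id"
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  expected <- c(id_col, setdiff(schema$name, c(id_col, schema_label(schema))))
  missing_cols <- setdiff(expected, header)
  if (length(missing_cols) > 0L) {
    abort(paste0("case-base file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  types <- purrr::map(setNames(schema$name, schema$name), function(f) {
    sp <- schema_spec(schema, f)
    if (sp$channel == "id" || sp$kind == "categorical") readr::col_character()
    else readr::col_double()
  })
  types[[id_col]] <- readr::col_character()
  types <- types[names(types) %in% header]
  data <- readr::read_csv(path, col_types = do.call(readr::cols, types),
                          progress = FALSE, show_col_types = FALSE)
  # keep declared order: id first, then schema order
  ord <- intersect(c(id_col, setdiff(schema$name, id_col)), names(data))
  data <- data[, c(ord, setdiff(names(data), ord)), drop = FALSE]
  validate_casebase(data, schema, strict = strict)
}

#' @rdname read_casebase
#' @param data A validated case-base tibble.
#' @export
write_casebase <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Partition a case base into benign and malignant sub-bases
#'
#' Splits the case base by a supplied id-to-class map. The map may carry the
#' recorded diagnoses or Phase-I classifier predictions — the caller chooses
#' the label source. The two sub-bases are disjoint and their union is the
#' input.
#'
#' @param data A case-base tibble with an `id` column.
#' @param labels Named vector (names = case ids, values in \{0, 1\}) or a data
#'   frame with columns `id` and `label`. Defaults to the case base's own
#'   `class` column.
#' @return A named list `list(benign = , malignant = )` of tibbles.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 30, seed = 1)
#' parts <- partition_by_class(base)
#' nrow(parts$benign) + nrow(parts$malignant) == nrow(base)
partition_by_class <- function(data, labels = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(labels)) {
    if (!"class" %in% names(data)) abort("no labels supplied and no 'class' column present")
    labels <- setNames(data$class, data$id)
  } else if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$id)
  }
  missing_ids <- setdiff(data$id, names(labels))
  if (length(missing_ids) > 0L) {
    abort(paste0("no label supplied for case id(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  y <- as.numeric(labels[data$id])
  if (any(is.na(y)) || !all(y %in% c(0, 1))) abort("labels must be 0 or 1")
  list(benign = data[y == 0, , drop = FALSE],
       malignant = data[y == 1, , drop = FALSE])
}
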