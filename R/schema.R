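#' Declare a single case-base feature
#'
#' A feature specification records everything the retrieval engine needs to
#' know about one column of a case base: its measurement kind, its admissible
#' domain, which channel it belongs to, and its retrieval weight.
#'
#' Channels separate the roles a column can play:
#' \describe{
#'   \item{`internal`}{clinical content of the case (age, tumour consistency,
#'     clump thickness, ...). Only internal features enter the similarity
#'     computation, weighted by `weight`.}
#'   \item{`ecc`}{external case characteristics — attributes of the case's
#'     provenance and appraisal (physician specialty, willingness to reveal
#'     the real name, case quality score) rather than of the patient.}
#'   \item{`label`}{the binary diagnosis, 1 = malignant, 0 = benign.}
#'   \item{`id`}{an opaque case identifier.}
#' }
#'
#' @param name Column name (a syntactic identifier).
#' @param kind One of `"numeric"`, `"ordinal"`, `"binary"`, `"categorical"`.
#' @param lower,upper Closed numeric domain for numeric/ordinal features.
#'   Binary features default to domain \{0, 1\}.
#' @param levels Character vector of admissible levels for categorical
#'   features.
#' @param channel One of `"internal"`, `"ecc"`, `"label"`, `"id"`.
#' @param weight Non-negative retrieval weight; used only for
#'   internal-channel features in the global similarity.
#'
#' @return A one-row tibble (a feature spec).
#' @export
#' @examples
#' feature_spec("age", "numeric", lower = 10, upper = 95)
feature_spec <- function(name, kind, lower = NA_real_, upper = NA_real_,
                         levels = NULL, channel = "internal", weight = 1) {
  kind <- match.arg(kind, c("numeric", "ordinal", "binary", "categorical"))
  channel <- match.arg(channel, c("internal", "ecc", "label", "id"))
  if (kind == "binary" && is.na(lower) && is.na(upper)) {
    lower <- 0; upper <- 1
  }
  if (!is.null(levels)) levels <- as.character(levels)
  tibble::tibble(
    name = as.character(name), kind = kind,
    lower = as.numeric(lower), upper = as.numeric(upper),
    levels = list(levels), channel = channel, weight = as.numeric(weight)
  )
}

#' Assemble and validate a feature schema
#'
#' A feature schema is an ordered collection of feature specs (see
#' [feature_spec()]) describing every column of a case base. It is validated
#' on construction: exactly one label feature (binary, domain \{0, 1\}), at
#' most one id feature, finite non-negative internal weights that are not all
#' zero, and a non-degenerate domain (`lower < upper`) for every numeric or
#' ordinal feature.
#'
#' @param ... Feature specs, or a single data frame of them.
#' @return A `cbr_schema` tibble.
#' @export
#' @examples
#' feature_schema(
#'   feature_spec("age", "numeric", 10, 95),
#'   feature_spec("class", "binary", channel = "label")
#' )
feature_schema <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1]])) {
    sch <- tibble::as_tibble(parts[[1]])
  } else {
    sch <- dplyr::bind_rows(parts)
  }
  sch <- tibble::new_tibble(sch, class = "cbr_schema")
  validate_schema(sch)
  sch
}

validate_schema <- function(schema) {
  req <- c("name", "kind", "lower", "upper", "levels", "channel", "weight")
  if (!all(req %in% names(schema))) {
    abort(paste0("schema is missing column(s): ",
                 paste(setdiff(req, names(schema)), collapse = ", ")))
  }
  if (anyDuplicated(schema$name)) abort("schema feature names must be unique")
  lab <- schema[schema$channel == "label", ]
  if (nrow(lab) != 1L) abort("schema must declare exactly one label feature")
  if (lab$kind != "binary") abort("the label feature must be binary with levels {0, 1}")
  if (sum(schema$channel == "id") > 1L) abort("at most one id feature is allowed")
  internal <- schema[schema$channel == "internal", ]
  if (nrow(internal) > 0L) {
    w <- internal$weight
    if (any(!is.finite(w)) || any(w < 0)) {
      abort("internal feature weights must be finite and non-negative")
    }
    if (all(w == 0)) abort("internal feature weights must not all be zero")
  }
  numish <- schema$kind %in% c("numeric", "ordinal")
  bad <- numish & !(is.finite(schema$lower) & is.finite(schema$upper) &
                      schema$lower < schema$upper)
  if (any(bad)) {
    abort(paste0("numeric/ordinal feature(s) need lower < upper: ",
                 paste(schema$name[bad], collapse = ", ")))
  }
  invisible(schema)
}

#' Names of schema features on a given channel
#'
#' @param schema A `cbr_schema`.
#' @param channel Channel to select (`"internal"`, `"ecc"`, `"label"`, `"id"`).
#' @return Character vector of feature names, in declared order.
#' @export
schema_features <- function(schema, channel = "internal") {
  schema$name[schema$channel == channel]
}

schema_spec <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) abort(paste0("feature '", name, "' is not declared in the schema"))
  schema[i, ]
}

schema_label <- function(schema) schema$name[schema$channel == "label"]

#' Bundled clinical case-base schema
#'
#' The default schema for a breast-cancer FNA case base: patient age (10–95
#' years), tumour consistency graded 1 (soft) to 5 (hard), clump thickness
#' (0–22 cm), FNA specimen type (1–5), number of swabs (1–10), the binary
#' diagnosis (`class`, 1 = malignant), and three ECC attributes — physician
#' specialty score (1–10), willingness to reveal the real name (\{0, 1\}) and
#' case quality score (1–10).
#'
#' @return A `cbr_schema`.
#' @export
#' @examples
#' fna_schema()
fna_schema <- function() {
  feature_schema(
    feature_spec("id", "categorical", channel = "id"),
    feature_spec("age", "numeric", 10, 95),
    feature_spec("consistency", "ordinal", 1, 5),
    feature_spec("clump_thickness", "numeric", 0, 22),
    feature_spec("fna", "ordinal", 1, 5),
    feature_spec("swabs", "ordinal", 1, 10),
    feature_spec("class", "binary", channel = "label"),
    feature_spec("specialty", "ordinal", 1, 10, channel = "ecc"),
    feature_spec("willingness", "binary", channel = "ecc"),
    feature_spec("quality", "ordinal", 1, 10, channel = "ecc")
  )
}

#' Extended retrieval schema variant
#'
#' A second bundled schema including the additional clinical attributes used
#' in worked retrieval examples: patient gender, clump mobility (`set`) and a
#' cell-description grade, alongside the core FNA attributes. It carries no
#' ECC block; use it for similarity/retrieval demonstrations.
#'
#' @return A `cbr_schema`.
#' @export
retrieval_schema <- function() {
  feature_schema(
    feature_spec("id", "categorical", channel = "id"),
    feature_spec("gender", "binary"),
    feature_spec("age", "numeric", 10, 95),
    feature_spec("consistency", "ordinal", 1, 5),
    feature_spec("clump_thickness", "numeric", 0, 22),
    feature_spec("fna", "ordinal", 1, 5),
    feature_spec("set", "binary"),
    feature_spec("swabs", "ordinal", 1, 10),
    feature_spec("cells", "ordinal", 1, 10),
    feature_spec("class", "binary", channel = "label")
  )
}

#' Read / write a schema as JSON
#'
#' Schemas serialize to a JSON array of feature records (name, kind, lower,
#' upper, levels, channel, weight) so that train-time and query-time runs
#' share one declaration.
#'
#' @param schema A `cbr_schema`.
#' @param path File path.
#' @return `read_schema()` returns a `cbr_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  recs <- purrr::pmap(schema, function(name, kind, lower, upper, levels, channel, weight) {
    list(name = name, kind = kind, lower = lower, upper = upper,
         levels = levels, channel = channel, weight = weight)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  recs <- jsonlite::read_json(path)
  specs <- purrr::map(recs, function(r) {
    feature_spec(r$name, r$kind,
                 lower = r$lower %||% NA_real_, upper = r$upper %||% NA_real_,
                 levels = if (is.null(r$levels)) NULL else unlist(r$levels),
                 channel = r$channel, weight = r$weight %||% 1)
  })
  do.call(feature_schema, specs)
}
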