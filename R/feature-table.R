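# data model: community feature tables with per-column metadata.
#
# A feature table holds one row per metropolitan community: a continuous
# response K (percentage of adults reporting poor mental health for more
# than 14 days of the past month, bounded to [0, 100]), a group key (US
# state or any grouping label), and numeric predictors each tagged with a
# category describing which aspect of the built environment or population
# health it measures.

PREDICTOR_CATEGORIES <- c("economic", "insurance_availability",
                          "insurance_type", "transport_cost",
                          "housing_vacancy", "behavioral", "preclinical",
                          "other")

#' Describe one column of a community feature table
#'
#' @param name column name as it appears in the CSV header.
#' @param role `"response"`, `"predictor"` or `"group_key"`.
#' @param category for predictors, one of `"economic"`,
#'   `"insurance_availability"`, `"insurance_type"`, `"transport_cost"`,
#'   `"housing_vacancy"`, `"behavioral"`, `"preclinical"`, `"other"`.
#' @param units free-text units, documentation only.
#' @param bounds optional numeric `c(lo, hi)` validity range; rows outside
#'   it are rejected at load time.
#' @return a `column_meta` object.
#' @seealso [feature_table()], [read_column_meta()]
#' @export
column_meta <- function(name, role = c("predictor", "response", "group_key"),
                        category = NULL, units = NULL, bounds = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (role == "predictor") {
    if (is.null(category)) {
      stop("predictor column '", name, "' needs a category", call. = FALSE)
    }
    category <- match.arg(category, PREDICTOR_CATEGORIES)
  } else {
    category <- NULL
  }
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2])
  }
  structure(list(name = name, role = role, category = category,
                 units = units, bounds = bounds),
            class = "column_meta")
}

validate_meta <- function(meta) {
  if (!length(meta) || !all(vapply(meta, inherits, logical(1), "column_meta")))
    stop("meta must be a list of column_meta objects", call. = FALSE)
  roles <- vapply(meta, `[[`, character(1), "role")
  if (sum(roles == "response") != 1L)
    stop("configuration error: exactly one column must have role 'response'",
         call. = FALSE)
  if (sum(roles == "group_key") != 1L)
    stop("configuration error: exactly one column must have role 'group_key'",
         call. = FALSE)
  nms <- vapply(meta, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate column names in metadata: ",
         paste(nms[duplicated(nms)], collapse = ", "), call. = FALSE)
  invisible(meta)
}

#' Read column metadata from a YAML or JSON config
#'
#' The config is a list of records with fields `name`, `role` and, for
#' predictors, `category`; optional `units` and `bounds`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list of [column_meta()] objects.
#' @export
read_column_meta <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  meta <- lapply(raw, function(r) {
    column_meta(name = r$name, role = r$role %||% "predictor",
                category = r$category, units = r$units,
                bounds = if (!is.null(r$bounds)) unlist(r$bounds))
  })
  validate_meta(meta)
  meta
}

#' Write column metadata to YAML
#'
#' @param meta a list of [column_meta()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_column_meta <- function(meta, path) {
  validate_meta(meta)
  recs <- lapply(meta, function(m) {
    r <- list(name = m$name, role = m$role)
    if (!is.null(m$category)) r$category <- m$category
    if (!is.null(m$units)) r$units <- m$units
    if (!is.null(m$bounds)) r$bounds <- as.numeric(m$bounds)
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Build a validated community feature table
#'
#' Validation enforces: all metadata columns present; predictors and the
#' response numeric with no missing values; every row carries a group
#' label; declared bounds respected. Rows violating bounds are *rejected
#' with a report naming them*, never silently dropped.
#'
#' @param data a data.frame whose columns match `meta`.
#' @param meta list of [column_meta()]; exactly one response and one
#'   group key.
#' @return a `feature_table` object.
#' @export
feature_table <- function(data, meta) {
  validate_meta(meta)
  nms <- vapply(meta, `[[`, character(1), "name")
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols)) {
    roles <- vapply(meta, `[[`, character(1), "role")
    key_missing <- intersect(missing_cols, nms[roles != "predictor"])
    if (length(key_missing))
      stop("configuration error: required column(s) missing from data: ",
           paste(key_missing, collapse = ", "), call. = FALSE)
    stop("configuration error: predictor column(s) missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, nms, drop = FALSE]

  for (m in meta) {
    col <- data[[m$name]]
    if (m$role == "group_key") {
      if (anyNA(col) || any(!nzchar(as.character(col))))
        stop("every row must have a group label ('", m$name, "')",
             call. = FALSE)
      data[[m$name]] <- as.character(col)
      next
    }
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))) &
                   !is.na(col))
      stop("parse error: non-numeric value in column '", m$name, "' at row",
           if (length(bad) > 1) "s" else "", " ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (anyNA(col)) {
      stop("missing values in column '", m$name, "' at row",
           if (sum(is.na(col)) > 1) "s" else "", " ",
           paste(utils::head(which(is.na(col)), 5), collapse = ", "),
           call. = FALSE)
    }
    bounds <- m$bounds
    if (m$role == "response" && is.null(bounds)) bounds <- c(0, 100)
    if (!is.null(bounds)) {
      bad <- which(col < bounds[1] | col > bounds[2])
      if (length(bad)) {
        stop("validation error: column '", m$name, "' outside [",
             bounds[1], ", ", bounds[2], "] at row",
             if (length(bad) > 1) "s" else "", " ",
             paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
      }
    }
  }

  structure(list(data = data, meta = meta), class = "feature_table")
}

#' Load a community feature table from CSV
#'
#' @param csv_path path to a plain CSV with a header row.
#' @param meta list of [column_meta()] or path to a YAML/JSON config
#'   readable by [read_column_meta()].
#' @return a validated `feature_table`.
#' @export
load_feature_table <- function(csv_path, meta) {
  if (is.character(meta)) meta <- read_column_meta(meta)
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  feature_table(df, meta)
}

#' Write a feature table back to CSV
#'
#' Numeric columns are written at full precision so that
#' `load_feature_table(write_feature_table(ft, f), meta)` round-trips
#' bit-exactly.
#'
#' @param ft a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  write_csv_precise(ft$data, path)
}

# ---- accessors -------------------------------------------------------------

meta_roles <- function(ft) vapply(ft$meta, `[[`, character(1), "role")
meta_names <- function(ft) vapply(ft$meta, `[[`, character(1), "name")

#' @export
#' @rdname feature_table_accessors
#' @title Feature-table accessors
#' @description Small accessors for the parts of a `feature_table`:
#'   response name/values, group key, predictor names (optionally by
#'   category), the numeric predictor matrix and per-column bounds.
#' @param ft a `feature_table`.
response_name <- function(ft) meta_names(ft)[meta_roles(ft) == "response"]

#' @export
#' @rdname feature_table_accessors
group_name <- function(ft) meta_names(ft)[meta_roles(ft) == "group_key"]

#' @export
#' @rdname feature_table_accessors
#' @param category optional category filter.
predictor_names <- function(ft, category = NULL) {
  keep <- meta_roles(ft) == "predictor"
  if (!is.null(category)) {
    cats <- vapply(ft$meta, function(m) m$category %||% NA_character_,
                   character(1))
    keep <- keep & cats %in% category
  }
  meta_names(ft)[keep]
}

#' @export
#' @rdname feature_table_accessors
response_values <- function(ft) ft$data[[response_name(ft)]]

#' @export
#' @rdname feature_table_accessors
group_labels <- function(ft) ft$data[[group_name(ft)]]

#' @export
#' @rdname feature_table_accessors
predictor_matrix <- function(ft) {
  as.matrix(ft$data[, predictor_names(ft), drop = FALSE])
}

#' @export
#' @rdname feature_table_accessors
#' @param name a predictor name.
column_bounds <- function(ft, name) {
  for (m in ft$meta) if (m$name == name) return(m$bounds)
  NULL
}

#' @export
print.feature_table <- function(x, ...) {
  cats <- table(vapply(x$meta, function(m) m$category %||% "(key)",
                       character(1)))
  cat(sprintf("feature_table: %d communities x %d predictors, %d groups\n",
              nrow(x$data), length(predictor_names(x)),
              length(unique(group_labels(x)))))
  cat("  response:", response_name(x), " group key:", group_name(x), "\n")
  cat("  predictor categories:",
      paste(sprintf("%s(%d)", names(cats), cats), collapse = " "), "\n")
  invisible(x)
}

#' Number of communities in a feature table
#' @param ft a `feature_table`.
#' @export
n_communities <- function(ft) nrow(ft$data)

# subset rows keeping class/meta
ft_subset <- function(ft, idx) {
  structure(list(data = ft$data[idx, , drop = FALSE], meta = ft$meta),
            class = "feature_table")
}
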