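#' Competing-risks cohorts
#'
#' A cohort is one row per subject: an identifier, a strictly positive
#' follow-up time measured from a common origin (e.g. disease diagnosis), an
#' integer event code `0..K` with 0 = censored and `1..K` the competing
#' causes, plus covariate columns. The covariate schema records, for each
#' covariate, whether it is numeric or categorical and, if categorical, its
#' ordered levels and the designated reference level.
#'
#' @param data data.frame with columns `id`, `time`, `event` and covariates.
#' @param n_causes number of competing causes `K` (>= maximum event code).
#' @param schema named list describing covariates; each entry is either
#'   `list(kind = "numeric")` or
#'   `list(kind = "categorical", levels = <chr>, ref = <chr>)`. Covariates
#'   present in `data` but absent from `schema` are auto-detected (factors
#'   and characters become categorical with the first observed level as
#'   reference).
#' @param label free-text cohort label.
#' @return An object of class `cr_cohort` (a data.frame with attributes
#'   `n_causes`, `schema`, `label`).
#' @export
cohort <- function(data, n_causes = NULL, schema = NULL, label = "") {
  req <- c("id", "time", "event")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("cohort schema error: missing column(s) ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$time <- as.numeric(data$time)
  ev <- suppressWarnings(as.integer(data$event))
  if (anyNA(data$time) || anyNA(ev) || anyNA(data$event))
    stop("cohort validation error: missing/unparseable time or event in row(s) ",
         paste(which(is.na(data$time) | is.na(ev)), collapse = ", "))
  data$event <- ev
  bad <- which(!is.finite(data$time) | data$time <= 0)
  if (length(bad))
    stop("cohort validation error: non-positive or non-finite time in row(s) ",
         paste(bad, collapse = ", "), " (id: ",
         paste(data$id[bad], collapse = ", "), ")")
  if (any(data$event < 0))
    stop("cohort validation error: negative event codes")
  kmax <- if (nrow(data)) max(data$event) else 0L
  if (is.null(n_causes)) n_causes <- max(kmax, 1L)
  n_causes <- as.integer(n_causes)
  if (n_causes < 1) stop("n_causes must be >= 1")
  if (kmax > n_causes) {
    bad <- which(data$event > n_causes)
    stop("cohort validation error: event code exceeds n_causes = ", n_causes,
         " in row(s) ", paste(bad, collapse = ", "))
  }
  covs <- setdiff(names(data), req)
  schema <- complete_schema(data, covs, schema)
  for (nm in names(schema)) {
    if (!nm %in% names(data))
      stop("cohort schema error: covariate '", nm, "' not present in data")
    sc <- schema[[nm]]
    if (sc$kind == "categorical") {
      vals <- as.character(data[[nm]])
      unknown <- setdiff(unique(vals), sc$levels)
      if (length(unknown))
        stop("cohort validation error: covariate '", nm,
             "' has value(s) outside declared levels: ",
             paste(unknown, collapse = ", "))
      if (!sc$ref %in% sc$levels)
        stop("cohort schema error: reference level '", sc$ref,
             "' of '", nm, "' is not a declared level")
      data[[nm]] <- vals
    } else {
      data[[nm]] <- as.numeric(data[[nm]])
      if (anyNA(data[[nm]]))
        stop("cohort validation error: covariate '", nm, "' has missing values")
    }
  }
  structure(data, n_causes = n_causes, schema = schema, label = label,
            class = c("cr_cohort", "data.frame"))
}

complete_schema <- function(data, covs, schema) {
  if (is.null(schema)) schema <- list()
  for (nm in covs) {
    if (!is.null(schema[[nm]])) next
    v <- data[[nm]]
    if (is.numeric(v)) {
      schema[[nm]] <- list(kind = "numeric")
    } else {
      lv <- if (is.factor(v)) levels(v) else unique(as.character(v))
      schema[[nm]] <- list(kind = "categorical", levels = lv, ref = lv[1])
    }
  }
  schema
}

#' @export
print.cr_cohort <- function(x, ...) {
  cat(sprintf("<cr_cohort> n = %d, K = %d%s\n", nrow(x), n_causes(x),
              if (nzchar(attr(x, "label"))) paste0(" (", attr(x, "label"), ")")
              else ""))
  ev <- table(factor(x$event, levels = 0:n_causes(x)))
  cat("  events:", paste(sprintf("cause %s: %d", names(ev), ev),
                         collapse = ", "), "\n")
  cat("  covariates:", paste(names(cohort_schema(x)), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cohort
#' @param x a `cr_cohort`.
#' @export
n_causes <- function(x) attr(x, "n_causes")

#' @rdname cohort
#' @export
cohort_schema <- function(x) attr(x, "schema")

#' Read a cohort from CSV
#'
#' Reads a comma-separated file (header row, UTF-8, "." decimal) into a
#' validated [cohort()]. Rows with missing or unparseable time/event are
#' rejected with an error naming the rows, never silently dropped.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the canonical names
#'   `id`, `time`, `event` to columns of the file, e.g.
#'   `c(time = "futime", event = "status")`. Unmapped canonical names are
#'   assumed to appear verbatim.
#' @param n_causes number of causes `K`.
#' @param schema optional covariate schema, as in [cohort()].
#' @return A `cr_cohort`.
#' @export
read_cohort <- function(path, column_map = NULL, n_causes = NULL,
                        schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop("cohort schema error: mapped column '", src, "' (for '", canon,
             "') not found in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  miss <- setdiff(c("id", "time", "event"), names(df))
  if (length(miss))
    stop("cohort schema error: missing column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  cohort(df, n_causes = n_causes, schema = schema,
         label = basename(path))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: values, column order and row order round-trip
#' exactly.
#'
#' @param x a `cr_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Reference-coded design matrix
#'
#' Encodes the named covariates of a cohort into a numeric design matrix.
#' Numeric covariates pass through as single columns; a categorical
#' covariate with L declared levels yields exactly L-1 dummy columns
#' (reference-level coding), in declaration order then level order, so the
#' encoding is deterministic.
#'
#' @param x a `cr_cohort`.
#' @param covariate_names covariates to encode, in the desired order.
#' @return A numeric matrix with attribute `encoding_map` (a data.frame
#'   mapping each column to its covariate and level).
#' @export
encode <- function(x, covariate_names) {
  encode_impl(x, cohort_schema(x), covariate_names)
}

# encoding core shared with the simulators (which encode covariate frames
# before event times exist)
encode_impl <- function(x, schema, covariate_names) {
  unknown <- setdiff(covariate_names, names(schema))
  if (length(unknown))
    stop("cohort schema error: unknown covariate(s) ",
         paste(unknown, collapse = ", "))
  cols <- list(); map <- list()
  for (nm in covariate_names) {
    sc <- schema[[nm]]
    if (sc$kind == "numeric") {
      cols[[nm]] <- as.numeric(x[[nm]])
      map[[length(map) + 1L]] <- data.frame(column = nm, covariate = nm,
                                            level = NA_character_)
    } else {
      non_ref <- setdiff(sc$levels, sc$ref)
      for (lv in non_ref) {
        cn <- paste0(nm, "_", gsub("[^A-Za-z0-9_.]", "_", lv))
        col <- as.numeric(x[[nm]] == lv)
        if (nrow(x) > 0 && length(unique(as.character(x[[nm]]))) < 2)
          warning("covariate '", nm, "' takes a single level in this cohort; ",
                  "column '", cn, "' is constant (non-identifiable)")
        cols[[cn]] <- col
        map[[length(map) + 1L]] <- data.frame(column = cn, covariate = nm,
                                              level = lv)
      }
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(x), 0)
  if (length(cols)) colnames(m) <- names(cols)
  attr(m, "encoding_map") <- do.call(rbind, map)
  m
}

#' Encode a single covariate profile
#'
#' Turns a named list such as `list(male = 1, agegrp = "lt40")` into the row
#' vector matching a design matrix previously built by [encode()].
#'
#' @param schema a cohort schema (see [cohort()]).
#' @param covariate_names covariates in the design, in order.
#' @param profile named list of raw covariate values.
#' @return Numeric vector aligned with the design columns.
#' @export
encode_profile <- function(schema, covariate_names, profile) {
  miss <- setdiff(covariate_names, names(profile))
  if (length(miss))
    stop("profile error: missing covariate(s) ", paste(miss, collapse = ", "))
  out <- numeric(0)
  for (nm in covariate_names) {
    sc <- schema[[nm]]
    v <- profile[[nm]]
    if (sc$kind == "numeric") {
      out <- c(out, stats::setNames(as.numeric(v), nm))
    } else {
      v <- as.character(v)
      if (!v %in% sc$levels)
        stop("profile error: '", v, "' is not a level of '", nm, "'")
      non_ref <- setdiff(sc$levels, sc$ref)
      vals <- as.numeric(non_ref == v)
      names(vals) <- paste0(nm, "_", gsub("[^A-Za-z0-9_.]", "_", non_ref))
      out <- c(out, vals)
    }
  }
  out
}

#' Cohort descriptives
#'
#' @param x a `cr_cohort`.
#' @return Tidy data.frame (`measure`, `value`): total n, per-cause event
#'   counts and percentages (count / n x 100), censoring count and
#'   percentage, and the median follow-up over all subjects.
#' @export
describe_cohort <- function(x) {
  if (nrow(x) == 0) stop("empty cohort")
  n <- nrow(x)
  K <- n_causes(x)
  counts <- tabulate(x$event + 1L, nbins = K + 1L)
  out <- data.frame(measure = "n", value = n)
  for (k in seq_len(K)) {
    out <- rbind(out,
      data.frame(measure = sprintf("events_cause%d", k), value = counts[k + 1]),
      data.frame(measure = sprintf("pct_cause%d", k),
                 value = counts[k + 1] / n * 100))
  }
  rbind(out,
        data.frame(measure = "censored", value = counts[1]),
        data.frame(measure = "pct_censored", value = counts[1] / n * 100),
        data.frame(measure = "median_followup",
                   value = stats::median(x$time)))
}
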