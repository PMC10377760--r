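#' Attribute specification for the heart-disease schema
#'
#' An attribute is one column of the 16-attribute clinical schema. Numeric
#' attributes are discretised into ordered bins with integer codes;
#' categorical and binary attributes map text labels to integer codes.
#'
#' @param name Machine-friendly attribute name (used as the CSV header).
#' @param label Human-readable label as printed on clinical forms.
#' @param kind One of `"binned-numeric"`, `"categorical"`, `"binary"`,
#'   `"passthrough"`.
#' @param bins For `binned-numeric`: a data frame with columns `lower`,
#'   `upper`, `lower_closed`, `upper_closed`, `code`, ordered by interval.
#' @param codes For `categorical`/`binary`: named integer vector mapping
#'   labels to codes.
#' @param units Free-text measurement units (`"mmHg"`, `"mg/dL"`, `"bpm"`,
#'   `"years"`, or `""`).
#' @param target Logical; is this attribute the prediction target?
#' @return An object of class `attribute_spec`.
#' @export
attribute_spec <- function(name, label = name, kind, bins = NULL, codes = NULL,
                           units = "", target = FALSE) {
  kind <- match.arg(kind, c("binned-numeric", "categorical", "binary",
                            "passthrough"))
  if (kind == "binned-numeric") {
    stopifnot(is.data.frame(bins),
              all(c("lower", "upper", "lower_closed", "upper_closed",
                    "code") %in% names(bins)))
    if (anyDuplicated(bins$code))
      stop("attribute '", name, "': duplicated bin codes", call. = FALSE)
    if (is.unsorted(bins$lower) || is.unsorted(bins$upper))
      stop("attribute '", name, "': bins must be ordered", call. = FALSE)
    if (any(bins$upper[-nrow(bins)] > bins$lower[-1]))
      stop("attribute '", name, "': bins overlap", call. = FALSE)
  }
  if (kind %in% c("categorical", "binary")) {
    stopifnot(!is.null(codes), !is.null(names(codes)))
    if (anyDuplicated(names(codes)) || anyDuplicated(codes))
      stop("attribute '", name, "': labels and codes must be unique",
           call. = FALSE)
    if (kind == "binary" &&
        !(length(codes) == 2L && setequal(codes, c(0L, 1L))))
      stop("attribute '", name, "': binary attributes map two labels to {0,1}",
           call. = FALSE)
  }
  structure(list(name = name, label = label, kind = kind, bins = bins,
                 codes = codes, units = units, target = target),
            class = "attribute_spec")
}

# interval helper used by both construction and encoding
.bin <- function(lower, upper, code, lower_closed = TRUE, upper_closed = TRUE) {
  data.frame(lower = lower, upper = upper, lower_closed = lower_closed,
             upper_closed = upper_closed, code = as.integer(code))
}

#' The default 16-attribute heart-disease encoding schema
#'
#' Builds the discretisation scheme used throughout the simulator: five
#' ordered age bands, three blood-pressure / cholesterol / heart-rate bands
#' centred on the clinically normal range, categorical ECG and thallium
#' status codes, and a binary disease target (`Yes = 1`, `No = 0`). Codes
#' are small integers centred near zero so encoded features need no further
#' scaling.
#'
#' Numeric bands deliberately leave small gaps between printed boundaries
#' (for instance heart rate bands `<69`, `70--90`, `>91`); values falling in
#' a gap are assigned to the band whose nearest boundary is closest, ties
#' going to the lower band (see [encode_record()]).
#'
#' @return A `heart_schema` object: an ordered list of 16
#'   [attribute_spec()]s with exactly one target attribute.
#' @examples
#' sch <- default_schema()
#' length(sch$attributes)
#' encode_record(list(
#'   age = 85, sex = "Male", chest_pain = 1.0, resting_bp = 125,
#'   serum_cholesterol = 250, fasting_blood_sugar = "False",
#'   resting_ecg = "Normal", diabetes = "No", exercise_angina = "No",
#'   st_depression = "Flat", st_slope = 0.2, smoke = "No",
#'   heart_status = "Normal", major_vessels = 0, max_heart_rate = 120), sch)
#' @export
default_schema <- function() {
  attrs <- list(
    attribute_spec("age", "Age in years", "binned-numeric", units = "years",
      bins = rbind(.bin(-Inf, 35, -2, upper_closed = FALSE),
                   .bin(35, 50, -1),
                   .bin(51, 60, 0),
                   .bin(61, 79, 1),
                   .bin(79, Inf, 2, lower_closed = FALSE))),
    attribute_spec("sex", "Sex", "binary",
      codes = c(Female = 0L, Male = 1L)),
    attribute_spec("chest_pain", "Chest Pain Type", "binned-numeric",
      bins = rbind(.bin(0, 0.3, -1),
                   .bin(0.9, 1.2, 0),
                   .bin(1.8, 2.1, 1),
                   .bin(2.7, 3.0, 2))),
    attribute_spec("resting_bp", "Resting BP", "binned-numeric",
      units = "mmHg",
      bins = rbind(.bin(-Inf, 120, -1, upper_closed = FALSE),
                   .bin(120, 139, 0),
                   .bin(139, Inf, 1, lower_closed = FALSE))),
    attribute_spec("serum_cholesterol", "Serum Cholesterol", "binned-numeric",
      units = "mg/dL",
      bins = rbind(.bin(-Inf, 200, -1, upper_closed = FALSE),
                   .bin(200, 239, 0),
                   .bin(240, Inf, 1, lower_closed = FALSE))),
    attribute_spec("fasting_blood_sugar", "Fasting blood sugar >120 mg/dL",
      "binary", codes = c(False = 0L, True = 1L)),
    attribute_spec("resting_ecg", "Resting electrocardiographic result",
      "categorical",
      codes = c(Normal = 0L, `ST T` = 1L, Hypertrophy = 2L)),
    attribute_spec("diabetes", "Diabetes", "binary",
      codes = c(No = 0L, Yes = 1L)),
    attribute_spec("exercise_angina", "Exercise-induced angina", "binary",
      codes = c(No = 0L, Yes = 1L)),
    attribute_spec("st_depression", "ST depression induced by exercise",
      "categorical", codes = c(Down = 0L, Flat = 1L, Up = 2L)),
    attribute_spec("st_slope", "Slope of peak exercise ST segment",
      "binned-numeric", units = "mm",
      bins = rbind(.bin(-Inf, 0.5, 0, upper_closed = FALSE),
                   .bin(0.5, Inf, 1, lower_closed = FALSE))),
    attribute_spec("smoke", "Smoke", "binary",
      codes = c(No = 0L, Yes = 1L)),
    attribute_spec("heart_status", "Status of heart", "categorical",
      # printed non-contiguous thallium codes kept verbatim
      codes = c(Normal = 3L, `Fixed defect` = 6L, `Reversible defect` = 7L)),
    attribute_spec("heart_disease", "Heart disease (target)", "binary",
      codes = c(No = 0L, Yes = 1L), target = TRUE),
    attribute_spec("major_vessels",
      "Number of major vessels colored by fluoroscopy", "categorical",
      codes = c(`0` = 0L, `1` = 1L, `2` = 2L, `3` = 3L)),
    attribute_spec("max_heart_rate", "Maximum heart rate", "binned-numeric",
      units = "bpm",
      bins = rbind(.bin(-Inf, 69, -1, upper_closed = FALSE),
                   .bin(70, 90, 0),
                   .bin(91, Inf, 1, lower_closed = FALSE)))
  )
  heart_schema(attrs)
}

#' Construct and validate a heart schema
#'
#' @param attributes Ordered list of [attribute_spec()]s; exactly 16 entries,
#'   exactly one flagged as target, and the target must be coded `{0, 1}`.
#' @return A `heart_schema` object.
#' @export
heart_schema <- function(attributes) {
  if (length(attributes) != 16L)
    stop("a heart schema has exactly 16 attributes, got ",
         length(attributes), call. = FALSE)
  is_target <- vapply(attributes, function(a) isTRUE(a$target), logical(1))
  if (sum(is_target) != 1L)
    stop("exactly one attribute must be the target", call. = FALSE)
  tgt <- attributes[[which(is_target)]]
  if (!setequal(tgt$codes, c(0L, 1L)))
    stop("target codes must be {0, 1}", call. = FALSE)
  names(attributes) <- vapply(attributes, `[[`, character(1), "name")
  structure(list(attributes = attributes, target_name = tgt$name),
            class = "heart_schema")
}

#' @export
print.heart_schema <- function(x, ...) {
  cat("Heart-disease schema:", length(x$attributes), "attributes, target '",
      x$target_name, "'\n", sep = "")
  for (a in x$attributes) {
    cs <- if (a$kind == "binned-numeric") {
      paste0(nrow(a$bins), " bins -> {",
             paste(a$bins$code, collapse = ","), "}")
    } else paste0("{", paste(names(a$codes), a$codes, sep = "=",
                             collapse = ", "), "}")
    cat(sprintf("  %-20s %-15s %s\n", a$name, a$kind, cs))
  }
  invisible(x)
}

#' Legal integer codes of an attribute
#' @param spec An [attribute_spec()].
#' @return Integer vector of the codes the attribute may take.
#' @export
legal_codes <- function(spec) {
  if (spec$kind == "binned-numeric") spec$bins$code
  else if (spec$kind == "passthrough") integer(0)
  else unname(spec$codes)
}

# encode one raw value under one attribute spec
.encode_value <- function(spec, value) {
  if (spec$kind == "passthrough") {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("attribute '", spec$name, "': non-numeric value '",
                       value, "'", call. = FALSE)
    return(v)
  }
  if (spec$kind == "binned-numeric") {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v))
      stop("attribute '", spec$name, "': non-numeric value '", value, "'",
           call. = FALSE)
    b <- spec$bins
    in_lo <- ifelse(b$lower_closed, v >= b$lower, v > b$lower)
    in_hi <- ifelse(b$upper_closed, v <= b$upper, v < b$upper)
    hit <- which(in_lo & in_hi)
    if (length(hit) >= 1L) return(b$code[hit[1L]])
    # gap between printed bins: nearest finite boundary wins, ties go to
    # the lower bin
    dist <- pmin(abs(v - ifelse(is.finite(b$lower), b$lower, Inf)),
                 abs(v - ifelse(is.finite(b$upper), b$upper, Inf)))
    return(b$code[which.min(dist)])  # which.min takes the first (lower) tie
  }
  # categorical / binary: strict label lookup; numeric codes passed raw are
  # rejected unless the label set itself is numeric (e.g. vessel counts)
  key <- as.character(value)
  idx <- match(key, names(spec$codes))
  if (is.na(idx))
    stop("attribute '", spec$name, "': unknown label '", key, "' (expected ",
         paste(sQuote(names(spec$codes)), collapse = ", "), ")",
         call. = FALSE)
  unname(spec$codes[idx])
}

#' Encode one raw clinical record into a numeric code vector
#'
#' Applies each attribute's discretisation or label map in schema order.
#' Numeric values falling in a gap between printed bin boundaries are
#' assigned to the bin whose nearest boundary is closest; exact ties go to
#' the lower bin. The target attribute is skipped (use [encode_dataset()]
#' to extract labels).
#'
#' @param record Named list or vector mapping attribute names to raw values
#'   (numbers for binned attributes, labels for categorical ones).
#' @param schema A [heart_schema()].
#' @return Named numeric vector of codes, one per non-target attribute, in
#'   schema order.
#' @examples
#' sch <- default_schema()
#' rec <- synthetic_raw_record(seed = 1)
#' encode_record(rec, sch)
#' @export
encode_record <- function(record, schema) {
  stopifnot(inherits(schema, "heart_schema"))
  record <- as.list(record)
  out <- numeric(0)
  for (a in schema$attributes) {
    if (a$target) next
    if (!a$name %in% names(record) || is.null(record[[a$name]]) ||
        (length(record[[a$name]]) == 1L && is.na(record[[a$name]])))
      stop("missing attribute '", a$name, "' in record", call. = FALSE)
    out[a$name] <- .encode_value(a, record[[a$name]])
  }
  out
}

#' Encode a collection of raw records into a dataset
#'
#' @param records A data frame (one row per record, columns named by
#'   attribute) or a list of named records. Must include the target column
#'   with its label values (e.g. `"Yes"`/`"No"`).
#' @param schema A [heart_schema()].
#' @return A `heart_dataset`: list with `features` (n x 15 numeric matrix of
#'   codes), `labels` (integer vector in `{0, 1}`) and `schema`.
#' @export
encode_dataset <- function(records, schema) {
  stopifnot(inherits(schema, "heart_schema"))
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  if (length(records) == 0L)
    stop("empty dataset: no records to encode", call. = FALSE)
  tgt <- schema$attributes[[schema$target_name]]
  feats <- vector("list", length(records))
  labels <- integer(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    feats[[i]] <- tryCatch(encode_record(rec, schema), error = function(e)
      stop("record ", i, ": ", conditionMessage(e), call. = FALSE))
    if (!tgt$name %in% names(rec))
      stop("record ", i, ": missing attribute '", tgt$name, "'", call. = FALSE)
    labels[i] <- tryCatch(.encode_value(tgt, rec[[tgt$name]]),
                          error = function(e)
      stop("record ", i, ": ", conditionMessage(e), call. = FALSE))
  }
  heart_dataset(do.call(rbind, feats), labels, schema)
}

#' Construct a heart dataset container
#'
#' @param features Numeric matrix of encoded codes (one row per record,
#'   columns named by non-target attributes in schema order).
#' @param labels Integer vector of binary targets.
#' @param schema The [heart_schema()] the codes follow.
#' @return A `heart_dataset` object.
#' @export
heart_dataset <- function(features, labels, schema) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            all(labels %in% c(0L, 1L)))
  structure(list(features = features, labels = as.integer(labels),
                 schema = schema), class = "heart_dataset")
}

#' @export
print.heart_dataset <- function(x, ...) {
  cat("heart_dataset:", nrow(x$features), "records x", ncol(x$features),
      "encoded features; prevalence",
      sprintf("%.3f", mean(x$labels)), "\n")
  invisible(x)
}

#' @export
dim.heart_dataset <- function(x) dim(x$features)

#' Subset a heart dataset by record index
#' @param dataset A `heart_dataset`.
#' @param idx Integer indices of records to keep.
#' @return A `heart_dataset` with the selected records, order preserved.
#' @export
subset_records <- function(dataset, idx) {
  heart_dataset(dataset$features[idx, , drop = FALSE], dataset$labels[idx],
                dataset$schema)
}

#' Read / write an encoded dataset as CSV
#'
#' The on-disk form is comma-separated UTF-8 text with a header row of
#' attribute names and integer codes as values (the target column included).
#' `write_dataset()` then `read_dataset()` is the identity on codes.
#'
#' @param path File path.
#' @param schema A [heart_schema()]; the file's columns must cover all of
#'   its attribute names.
#' @param dataset A `heart_dataset`.
#' @return `read_dataset()` returns a `heart_dataset`; `write_dataset()`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path, schema) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- vapply(schema$attributes, `[[`, character(1), "name")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file '", path, "' is missing schema column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("empty dataset: '", path, "' has a header but no records",
         call. = FALSE)
  for (a in schema$attributes) {
    col <- df[[a$name]]
    if (!is.numeric(col))
      stop("column '", a$name, "': non-numeric code at line ",
           which(is.na(suppressWarnings(as.numeric(col))))[1L] + 1L,
           call. = FALSE)
    legal <- legal_codes(a)
    if (length(legal) && !all(col %in% legal)) {
      bad <- which(!col %in% legal)[1L]
      stop("column '", a$name, "': illegal code ", col[bad], " at line ",
           bad + 1L, call. = FALSE)
    }
  }
  feats <- as.matrix(df[, setdiff(need, schema$target_name), drop = FALSE])
  storage.mode(feats) <- "double"
  heart_dataset(feats, df[[schema$target_name]], schema)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "heart_dataset"))
  df <- as.data.frame(dataset$features)
  df[[dataset$schema$target_name]] <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialise / parse a schema as YAML
#'
#' @param schema A [heart_schema()].
#' @param path File path of the YAML schema description.
#' @return `write_schema()` returns `path` invisibly; `read_schema()`
#'   returns the reconstructed `heart_schema`.
#' @export
write_schema <- function(schema, path) {
  ser <- lapply(schema$attributes, function(a) {
    out <- list(name = a$name, label = a$label, kind = a$kind,
                units = a$units, target = a$target)
    if (!is.null(a$bins))
      out$bins <- lapply(seq_len(nrow(a$bins)), function(i)
        as.list(a$bins[i, ]))
    if (!is.null(a$codes))
      out$codes <- as.list(a$codes)
    out
  })
  yaml::write_yaml(list(attributes = unname(ser)), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  attrs <- lapply(raw$attributes, function(a) {
    bins <- if (!is.null(a$bins))
      do.call(rbind, lapply(a$bins, function(b)
        .bin(as.numeric(b$lower), as.numeric(b$upper), b$code,
             b$lower_closed, b$upper_closed)))
    codes <- if (!is.null(a$codes)) {
      cc <- vapply(a$codes, as.integer, integer(1))
      stats::setNames(cc, names(a$codes))
    }
    attribute_spec(a$name, a$label, a$kind, bins = bins, codes = codes,
                   units = a$units, target = isTRUE(a$target))
  })
  heart_schema(attrs)
}
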