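#' Configuration for the synthetic heart-disease data generator
#'
#' The generator draws attribute codes from per-attribute probability tables
#' over each attribute's legal code set, then draws the disease target from
#' a logistic model on the encoded features — so every synthetic dataset has
#' a known ground-truth risk model against which learners can be validated.
#'
#' Three presets are provided:
#' \describe{
#'   \item{`"DS1-like"`}{intercept -0.2, moderate effects on the classical
#'     risk factors, 5% label noise; an easier cohort.}
#'   \item{`"DS2-like"`}{intercept +0.2, the same effects, 15% label noise;
#'     a harder, noisier cohort.}
#'   \item{`"separable"`}{a single overwhelming effect (exercise-induced
#'     angina) and no label noise; a nearly separable sanity cohort.}
#' }
#'
#' @param n Number of records to generate (`n >= 0`).
#' @param seed Integer seed; identical configs generate identical datasets.
#' @param coefficients Named numeric vector of per-attribute effects on the
#'   logit scale (names are non-target attribute names; unnamed attributes
#'   get 0). `NULL` means the preset's effects.
#' @param intercept Logit offset.
#' @param label_noise Probability in `[0, 0.5]` of flipping the drawn target.
#' @param profile Preset name: `"DS1-like"`, `"DS2-like"` or `"separable"`.
#' @param probs Optional named list of per-attribute probability vectors over
#'   that attribute's legal codes; default roughly uniform.
#' @param schema Schema to generate under; default [default_schema()].
#' @return A `generator_config` object.
#' @export
generator_config <- function(n = 303L, seed = 1L, coefficients = NULL,
                             intercept = NULL, label_noise = NULL,
                             profile = c("DS1-like", "DS2-like", "separable"),
                             probs = NULL, schema = default_schema()) {
  profile <- match.arg(profile)
  if (n < 0) stop("config error: n must be >= 0", call. = FALSE)
  base <- c(age = 1, sex = 0.6, chest_pain = 1.2, resting_bp = 0.8,
            serum_cholesterol = 0.8, fasting_blood_sugar = 0.4,
            resting_ecg = 0.6, diabetes = 0.8, exercise_angina = 1.2,
            st_depression = 0.6, st_slope = 1, smoke = 0.6,
            heart_status = 0.3, major_vessels = 1, max_heart_rate = -1)
  preset <- switch(profile,
    "DS1-like"  = list(coef = base, intercept = -0.2, noise = 0.05),
    "DS2-like"  = list(coef = base, intercept = 0.2, noise = 0.15),
    "separable" = list(coef = c(exercise_angina = 20), intercept = 0,
                       noise = 0))
  feat_names <- setdiff(names(schema$attributes), schema$target_name)
  cf <- stats::setNames(numeric(length(feat_names)), feat_names)
  src <- coefficients %||% preset$coef
  bad <- setdiff(names(src), feat_names)
  if (length(bad))
    stop("config error: unknown attribute(s) in coefficients: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cf[names(src)] <- src
  noise <- label_noise %||% preset$noise
  if (noise < 0 || noise > 0.5)
    stop("config error: label_noise must lie in [0, 0.5]", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 coefficients = cf, intercept = intercept %||% preset$intercept,
                 label_noise = noise, profile = profile, probs = probs,
                 schema = schema),
            class = "generator_config")
}

#' Generate a seeded synthetic heart-disease dataset
#'
#' Codes are sampled independently per attribute from the configured
#' probability tables; the binary target is drawn from
#' `p = plogis(intercept + sum(coef * code))` and then flipped with
#' probability `label_noise`. The same config always yields bit-identical
#' output, and the caller's RNG stream is left untouched.
#'
#' @param config A [generator_config()].
#' @return A `heart_dataset` with `config$n` records.
#' @examples
#' d <- generate_dataset(generator_config(n = 100, seed = 42))
#' d
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  schema <- config$schema
  feat_names <- setdiff(names(schema$attributes), schema$target_name)
  n <- config$n
  if (n == 0L)
    return(structure(list(
      features = matrix(numeric(0), 0, length(feat_names),
                        dimnames = list(NULL, feat_names)),
      labels = integer(0), schema = schema), class = "heart_dataset"))
  with_seed(config$seed, {
    feats <- sapply(feat_names, function(nm) {
      codes <- legal_codes(schema$attributes[[nm]])
      pr <- config$probs[[nm]] %||% rep(1 / length(codes), length(codes))
      sample(codes, n, replace = TRUE, prob = pr)
    })
    feats <- matrix(as.numeric(feats), nrow = n,
                    dimnames = list(NULL, feat_names))
    # effects act on codes centred at their expected value under the
    # sampling tables, so the intercept is the prevalence logit of the
    # average patient (thallium codes 3/6/7 would otherwise shift it)
    code_means <- vapply(feat_names, function(nm) {
      codes <- legal_codes(schema$attributes[[nm]])
      pr <- config$probs[[nm]] %||% rep(1 / length(codes), length(codes))
      sum(codes * pr / sum(pr))
    }, numeric(1))
    centred <- sweep(feats, 2L, code_means)
    eta <- config$intercept +
      as.vector(centred %*% config$coefficients[feat_names])
    y <- stats::rbinom(n, 1L, stats::plogis(eta))
    if (config$label_noise > 0) {
      flip <- stats::runif(n) < config$label_noise
      y[flip] <- 1L - y[flip]
    }
    heart_dataset(feats, y, schema)
  })
}

#' One synthetic raw (unencoded) clinical record
#'
#' Draws a coded record from the generator and maps every code back to a
#' representative raw value (a number inside the bin for binned attributes,
#' the label for categorical ones). Useful for exercising the encoding path
#' end to end.
#'
#' @param seed Integer seed.
#' @param schema Schema; default [default_schema()].
#' @return Named list of raw values including the target label.
#' @export
synthetic_raw_record <- function(seed = 1L, schema = default_schema()) {
  d <- generate_dataset(generator_config(n = 1L, seed = seed,
                                         schema = schema))
  rec <- list()
  for (a in schema$attributes) {
    if (a$target) {
      rec[[a$name]] <- names(a$codes)[match(d$labels[1L], a$codes)]
      next
    }
    code <- d$features[1L, a$name]
    rec[[a$name]] <- decode_code(a, code)
  }
  rec
}

#' Representative raw value for an attribute code
#'
#' Inverse of encoding up to bin resolution: binned attributes yield a
#' point inside the coded bin, categorical attributes yield the label.
#'
#' @param spec An [attribute_spec()].
#' @param code A legal code of that attribute.
#' @return A number or label such that encoding it reproduces `code`.
#' @export
decode_code <- function(spec, code) {
  if (spec$kind == "binned-numeric") {
    b <- spec$bins[match(code, spec$bins$code), ]
    if (is.na(b$lower))
      stop("attribute '", spec$name, "': illegal code ", code, call. = FALSE)
    if (is.finite(b$lower) && is.finite(b$upper))
      return((b$lower + b$upper) / 2)
    if (is.finite(b$lower)) return(b$lower + 1)
    return(b$upper - 1)
  }
  if (spec$kind == "passthrough") return(code)
  lbl <- names(spec$codes)[match(code, spec$codes)]
  if (is.na(lbl))
    stop("attribute '", spec$name, "': illegal code ", code, call. = FALSE)
  lbl
}

#' Split a dataset into training and held-out test sets
#'
#' Test size is `round_half_up(test_fraction * n)`; membership is a seeded
#' uniform shuffle, disjoint and exhaustive. With the cohort size of 303
#' records and a 33% held-out fraction this yields 203 training and 100
#' test records.
#'
#' @param dataset A `heart_dataset`.
#' @param test_fraction Proportion in `[0, 1)` held out for testing.
#' @param seed Integer seed for the shuffle.
#' @return List with elements `train` and `test`, both `heart_dataset`s.
#' @export
split_train_test <- function(dataset, test_fraction = 0.33, seed = 1L) {
  stopifnot(inherits(dataset, "heart_dataset"))
  if (test_fraction < 0 || test_fraction >= 1)
    stop("test_fraction must lie in [0, 1)", call. = FALSE)
  n <- nrow(dataset$features)
  k <- round_half_up(test_fraction * n)
  perm <- with_seed(seed, sample.int(n))
  test_idx <- sort(perm[seq_len(k)])
  train_idx <- sort(perm[setdiff(seq_len(n), seq_len(k))])
  list(train = subset_records(dataset, train_idx),
       test = subset_records(dataset, test_idx))
}

#' Partition a training set across client nodes
#'
#' Default is an IID equal split: a seeded shuffle dealt into `Z` nearly
#' equal shards (sizes differ by at most one; the remainder goes to the
#' lowest-index clients). With `non_iid = TRUE` records are instead sorted
#' by label before dealing contiguous shards, giving a label-skewed
#' federation for robustness exploration.
#'
#' @param train A `heart_dataset`.
#' @param Z Number of clients (`>= 1`).
#' @param seed Integer seed.
#' @param non_iid Logical; label-skewed shards instead of IID.
#' @return List of `Z` `heart_dataset`s forming a set partition of `train`.
#' @export
partition_clients <- function(train, Z, seed = 1L, non_iid = FALSE) {
  stopifnot(inherits(train, "heart_dataset"))
  n <- nrow(train$features)
  if (n < Z)
    stop("partition error: ", n, " training records cannot cover ", Z,
         " clients", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  if (non_iid) perm <- perm[order(train$labels[perm])]
  sizes <- rep(n %/% Z, Z)
  if (n %% Z > 0) sizes[seq_len(n %% Z)] <- sizes[seq_len(n %% Z)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(Z), function(z)
    subset_records(train, sort(perm[starts[z]:ends[z]])))
}
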