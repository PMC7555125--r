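# Feature construction: per-sensor cooling-segment ratios between two
# thermal periods, downsampled 165 -> 16, plus encoded age/sex/smoking.
# Input dimension: 14 x 16 + 3 = 227.

#' Elementwise period-ratio features
#'
#' For each of the 14 sensors, the elementwise ratio of the cooling segment
#' of thermal period `num_period` to that of period `den_period`
#' (default 4 over 1). Ratios cancel per-sensor gain and the shared cooling
#' template, isolating the injection response.
#'
#' @param seg a `segmented_record`.
#' @param num_period,den_period 1-based complete-cycle indices (defaults 4
#'   and 1).
#' @return numeric matrix, 14 sensors x 165 ratios.
#' @export
ratio_features <- function(seg, num_period = 4L, den_period = 1L) {
  n_cyc <- nrow(seg$cycles)
  if (num_period > n_cyc || den_period > n_cyc || num_period < 1L || den_period < 1L)
    abort_contract(sprintf(
      "record '%s' has %d complete cycles; periods %d/%d unavailable",
      seg$record_id, n_cyc, num_period, den_period))
  num <- seg$cooling_segments[, num_period, ]
  den <- seg$cooling_segments[, den_period, ]
  zero <- which(den == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    abort_enose(sprintf(
      "record '%s': zero ADC count in denominator period %d (sensor %s, sample %d); ADC floor hit, record unusable",
      seg$record_id, den_period,
      rownames(seg$cooling_segments)[zero[1, 1]], zero[1, 2] - 1L),
      "enose_degenerate_signal_error")
  }
  num / den
}

#' Downsample a 165-sample ratio trace to 16 values
#'
#' Keeps every 10th value: 0-based indices `offset, offset+10, ...,
#' offset+150` (16 values).
#'
#' @param ratios numeric vector of length 165.
#' @param stride sampling stride (default 10).
#' @param offset 0-based starting offset (default 0; must satisfy
#'   `offset + 15*stride < 165`).
#' @return numeric vector of length 16.
#' @export
downsample_ratios <- function(ratios, stride = 10L, offset = 0L) {
  if (length(ratios) != 165L)
    abort_contract(sprintf("expected 165 ratio values, got %d", length(ratios)))
  idx0 <- offset + stride * (0:15)
  if (max(idx0) >= 165L)
    abort_contract("downsampling indices exceed the 165-sample segment")
  ratios[idx0 + 1L]
}

#' Encode subject metadata as network inputs
#'
#' Age is scaled to `age/100` so it shares the O(1) magnitude of the ratio
#' features; sex and smoking are 0/1 indicators (male = 1, smoker = 1).
#'
#' @param age age in years (> 0).
#' @param sex `"F"` or `"M"`.
#' @param smoking `"no"` or `"yes"`.
#' @return named numeric vector `(age, sex, smoking)`.
#' @export
encode_metadata <- function(age, sex, smoking) {
  if (!is_scalar_num(age) || age <= 0)
    abort_validation("age must be a positive number")
  if (!sex %in% c("F", "M"))
    abort_validation(sprintf("unknown sex category '%s'", sex))
  if (!smoking %in% c("no", "yes"))
    abort_validation(sprintf("unknown smoking category '%s'", smoking))
  c(age = age / 100, sex = as.numeric(sex == "M"),
    smoking = as.numeric(smoking == "yes"))
}

feature_names <- function() {
  c(sprintf("s%02d_f%02d", rep(1:14, each = 16), rep(1:16, times = 14)),
    "age", "sex", "smoking")
}

#' Build the 227-dimensional feature vector of one record
#'
#' Concatenates, in fixed order, 16 downsampled ratio features per sensor
#' (sensor 1 first) and the three encoded metadata values.
#'
#' @inheritParams ratio_features
#' @inheritParams downsample_ratios
#' @return list with `values` (named numeric, length 227), `label`,
#'   `record_id`.
#' @export
build_feature_vector <- function(seg, num_period = 4L, den_period = 1L,
                                 stride = 10L, offset = 0L) {
  rat <- ratio_features(seg, num_period, den_period)
  # apply() returns 16 x 14 (one column per sensor); column-major unlisting
  # yields sensor-major order s01_f01..s01_f16, s02_f01, ...
  sens <- as.vector(apply(rat, 1L, downsample_ratios, stride = stride,
                          offset = offset))
  values <- c(sens, encode_metadata(seg$age, seg$sex, seg$smoking))
  names(values) <- feature_names()
  stopifnot(length(values) == 227L, all(is.finite(values)))
  list(values = values, label = seg$label, record_id = seg$record_id)
}

#' Build the feature matrix of a whole cohort
#'
#' Segments every record and assembles one feature vector per record.
#'
#' @param co an `enose_cohort`.
#' @inheritParams build_feature_vector
#' @return data.frame: `record_id`, `label`, then 227 feature columns
#'   (`s01_f01` .. `s14_f16`, `age`, `sex`, `smoking`).
#' @export
cohort_features <- function(co, num_period = 4L, den_period = 1L,
                            stride = 10L, offset = 0L) {
  rows <- lapply(co$records, function(rec) {
    fv <- build_feature_vector(segment_record(rec), num_period, den_period,
                               stride, offset)
    c(list(record_id = fv$record_id, label = fv$label), as.list(fv$values))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  if (is.null(df)) {
    df <- as.data.frame(matrix(numeric(), 0, 229,
      dimnames = list(NULL, c("record_id", "label", feature_names()))),
      check.names = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write / read a feature matrix as CSV
#'
#' Header: `record_id,label,s01_f01,...,s14_f16,age,sex,smoking`.
#'
#' @param features data.frame from [cohort_features()].
#' @param path CSV path.
#' @return `read_features` returns the data.frame.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as.data.frame(data.table::fread(path,
    colClasses = list(character = "record_id", integer = "label")))
  df
}
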