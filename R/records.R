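# Raw-record data model: one subject's 16-channel acquisition plus metadata.

#' Sensor channel names
#'
#' The 14 MOS gas sensors of the acquisition module, in fixed channel order,
#' followed by the two synchronization channels (`SYNC_A`, `SYNC_B`) that
#' carry the heater-phase square wave.
#'
#' @return character vector of length 16.
#' @export
enose_channel_names <- function() {
  c("MP503", "WSP2110", "MQ3", "MQ2", "MQ7", "MQ131", "MQ135", "MQ8",
    "MQ138", "TGS822", "TGS2602", "TGS2620", "TGS2600", "TGS2603",
    "SYNC_A", "SYNC_B")
}

#' Acquisition constants
#'
#' Records are sampled at 30 Hz for 90 s: 2700 samples on each of 16
#' channels, 43,200 values per subject. ADC counts live on a 12-bit scale,
#' 0 to 4095.
#'
#' @name acquisition-constants
#' @keywords internal
NULL

ENOSE_SAMPLE_RATE <- 30L
ENOSE_N_SAMPLES <- 2700L
ENOSE_N_CHANNELS <- 16L
ENOSE_N_SENSORS <- 14L
ENOSE_ADC_MAX <- 4095
SYNC_CHANNELS <- c(15L, 16L)

#' Construct a sensor record
#'
#' A `sensor_record` is one subject's raw acquisition: a 16 x 2700 matrix of
#' ADC counts (14 gas sensors + 2 sync channels, 30 Hz x 90 s), together
#' with the subject metadata used downstream as covariates.
#'
#' @param record_id unique identifier string.
#' @param channels numeric matrix, 16 rows (channels) x 2700 columns
#'   (samples), ADC counts in `[0, 4095]`.
#' @param age age in years (> 0).
#' @param sex `"F"` or `"M"`.
#' @param smoking `"no"` or `"yes"`.
#' @param label class label: `0` control, `1` cancer.
#' @param validate validate invariants on construction (default `TRUE`).
#' @return an object of class `sensor_record`.
#' @export
sensor_record <- function(record_id, channels, age, sex, smoking, label,
                          validate = TRUE) {
  rec <- structure(
    list(
      record_id = as.character(record_id),
      channels = channels,
      sample_rate = ENOSE_SAMPLE_RATE,
      age = as.numeric(age),
      sex = as.character(sex),
      smoking = as.character(smoking),
      label = as.integer(label),
      channel_names = enose_channel_names()
    ),
    class = "sensor_record"
  )
  if (validate) {
    problems <- validate_record(rec)
    if (length(problems)) {
      abort_validation(paste0(
        "invalid sensor record '", rec$record_id, "':\n",
        paste0("- ", problems, collapse = "\n")
      ))
    }
  }
  rec
}

#' Validate a sensor record, reporting every violated invariant
#'
#' @param rec a `sensor_record`.
#' @return character vector of problem descriptions; empty if valid.
#' @export
validate_record <- function(rec) {
  p <- character()
  ch <- rec$channels
  if (!is.matrix(ch) || !is.numeric(ch)) {
    return("channels is not a numeric matrix")
  }
  if (nrow(ch) != ENOSE_N_CHANNELS || ncol(ch) != ENOSE_N_SAMPLES) {
    p <- c(p, sprintf("channels has shape %d x %d, expected 16 x 2700",
                      nrow(ch), ncol(ch)))
    return(p) # shape wrong: remaining checks would misfire
  }
  if (anyNA(ch) || !all(is.finite(ch))) {
    p <- c(p, "channels contains non-finite values")
  } else {
    if (min(ch) < 0 || max(ch) > ENOSE_ADC_MAX)
      p <- c(p, sprintf("ADC counts outside [0, %d] (range %g..%g)",
                        ENOSE_ADC_MAX, min(ch), max(ch)))
    for (s in SYNC_CHANNELS) {
      vals <- unique(ch[s, ])
      ok <- length(vals) == 2L && 0 %in% vals && max(vals) > 0
      if (!ok)
        p <- c(p, sprintf(
          "sync channel %d must take exactly the two values {0, high > 0}; saw %d distinct value(s)",
          s, length(vals)))
    }
  }
  if (!is_scalar_num(rec$age) || rec$age <= 0)
    p <- c(p, "age must be a positive number")
  if (!rec$sex %in% c("F", "M"))
    p <- c(p, sprintf("sex must be 'F' or 'M', got '%s'", rec$sex))
  if (!rec$smoking %in% c("no", "yes"))
    p <- c(p, sprintf("smoking must be 'no' or 'yes', got '%s'", rec$smoking))
  if (!rec$label %in% c(0L, 1L))
    p <- c(p, "label must be 0 (control) or 1 (cancer)")
  p
}

#' @export
print.sensor_record <- function(x, ...) {
  cat(sprintf(
    "<sensor_record '%s'> 16 x 2700 ADC matrix | age %g, sex %s, smoking %s, label %d\n",
    x$record_id, x$age, x$sex, x$smoking, x$label))
  invisible(x)
}

#' Construct a cohort of sensor records
#'
#' @param records list of `sensor_record` objects with unique ids.
#' @param provenance `"synthetic"` or `"imported"`.
#' @param generator_config_hash hash string of the generating configuration
#'   (empty for imported cohorts).
#' @param validate validate all records and id uniqueness (default `TRUE`).
#' @return an object of class `enose_cohort`.
#' @export
cohort <- function(records, provenance = c("synthetic", "imported"),
                   generator_config_hash = "", validate = TRUE) {
  provenance <- match.arg(provenance)
  co <- structure(
    list(records = records, provenance = provenance,
         generator_config_hash = generator_config_hash),
    class = "enose_cohort"
  )
  if (validate) {
    problems <- validate_cohort(co)
    if (length(problems)) {
      abort_validation(paste0(
        "invalid cohort:\n", paste0("- ", problems, collapse = "\n")
      ))
    }
  }
  co
}

#' Validate a cohort, reporting all violations across all records
#'
#' @param co an `enose_cohort`.
#' @return character vector of problem descriptions; empty if valid.
#' @export
validate_cohort <- function(co) {
  p <- character()
  ids <- vapply(co$records, function(r) r$record_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    p <- c(p, sprintf("duplicate record_id(s): %s", paste(dup, collapse = ", ")))
  for (r in co$records) {
    pr <- validate_record(r)
    if (length(pr))
      p <- c(p, sprintf("record '%s': %s", r$record_id, pr))
  }
  p
}

#' @export
print.enose_cohort <- function(x, ...) {
  labs <- record_labels(x)
  cat(sprintf("<enose_cohort> %d records (%d cancer / %d control), %s\n",
              length(x$records), sum(labs == 1L), sum(labs == 0L),
              x$provenance))
  invisible(x)
}

#' @export
length.enose_cohort <- function(x) length(x$records)

#' Record ids of a cohort
#' @param co an `enose_cohort`.
#' @return character vector.
#' @export
record_ids <- function(co) {
  vapply(co$records, function(r) r$record_id, character(1))
}

#' Class labels of a cohort
#' @param co an `enose_cohort`.
#' @return integer vector of 0/1 labels in record order.
#' @export
record_labels <- function(co) {
  vapply(co$records, function(r) r$label, integer(1))
}
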