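# Cohort container I/O.
#
# On-disk layout (normative, inspectable): a ZIP archive holding
#   metadata.csv            record_id, age, sex, smoking, label
#   records/<record_id>.csv 2700 rows x 16 named columns, one column per
#                           channel in fixed order (MP503 .. TGS2603,
#                           SYNC_A, SYNC_B), header row, UTF-8, comma
#                           separated, decimal point.
# ADC counts are written with 17 significant digits so that write -> read
# round-trips doubles bit-exactly.

fmt_num <- function(x) {
  # shortest-ish decimal text that round-trips IEEE doubles
  sub("^\\s+", "", formatC(x, digits = 17, format = "g"))
}

#' Write a cohort to a ZIP container
#'
#' @param co an `enose_cohort`.
#' @param path output file path (conventionally `.zip`).
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(co, path) {
  stopifnot(inherits(co, "enose_cohort"))
  dir <- file.path(tempfile("cohort"), "stage")
  dir.create(file.path(dir, "records"), recursive = TRUE)
  on.exit(unlink(dirname(dir), recursive = TRUE), add = TRUE)

  meta <- data.table::data.table(
    record_id = record_ids(co),
    age = vapply(co$records, function(r) r$age, numeric(1)),
    sex = vapply(co$records, function(r) r$sex, character(1)),
    smoking = vapply(co$records, function(r) r$smoking, character(1)),
    label = record_labels(co)
  )
  if (nrow(meta) == 0L) {
    meta <- data.table::data.table(record_id = character(), age = numeric(),
                                   sex = character(), smoking = character(),
                                   label = integer())
  }
  data.table::fwrite(meta, file.path(dir, "metadata.csv"))

  for (r in co$records) {
    tab <- as.data.table_channels(r$channels)
    data.table::fwrite(tab, file.path(dir, "records",
                                      paste0(r$record_id, ".csv")))
  }

  ok <- tryCatch({
    # zip() runs from `root`, so the archive path must be absolute
    abs_path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                          basename(path))
    zip::zip(abs_path, files = c("metadata.csv", "records"),
             root = dir, mode = "mirror")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_enose(sprintf("cannot write cohort container '%s': %s",
                        path, conditionMessage(ok)), "enose_io_error")
  }
  invisible(path)
}

# channel matrix (16 x 2700) -> data.table of 16 character columns with
# round-trippable numeric text
as.data.table_channels <- function(channels) {
  cols <- lapply(seq_len(nrow(channels)), function(s) fmt_num(channels[s, ]))
  names(cols) <- enose_channel_names()
  data.table::as.data.table(cols)
}

#' Read a cohort from a ZIP container
#'
#' Validates every record against the raw-record invariants and reports all
#' violations (not only the first) in a single validation error.
#'
#' @param path path to a container written by [write_cohort()].
#' @param provenance provenance tag to attach (default `"imported"`).
#' @return an `enose_cohort`.
#' @export
read_cohort <- function(path, provenance = "imported") {
  if (!file.exists(path)) {
    abort_enose(sprintf("cohort container '%s' does not exist", path),
                "enose_io_error")
  }
  dir <- tempfile("cohort_read")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  zip::unzip(path, exdir = dir)

  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    abort_validation(sprintf("container '%s' has no metadata.csv", path))
  }
  meta <- data.table::fread(meta_path, colClasses = list(
    character = c("record_id", "sex", "smoking")))

  problems <- character()
  need <- c("record_id", "age", "sex", "smoking", "label")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort_validation(sprintf("metadata.csv lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(meta$age)) {
    bad <- meta$record_id[is.na(meta$age)]
    problems <- c(problems, sprintf("record '%s': metadata age is missing", bad))
  }

  records <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    rid <- meta$record_id[i]
    rec_path <- file.path(dir, "records", paste0(rid, ".csv"))
    if (!file.exists(rec_path)) {
      problems <- c(problems, sprintf("record '%s': no data file in container", rid))
      next
    }
    tab <- data.table::fread(rec_path, colClasses = "numeric")
    ch <- t(as.matrix(tab))
    dimnames(ch) <- NULL
    if (nrow(ch) != ENOSE_N_CHANNELS || ncol(ch) != ENOSE_N_SAMPLES) {
      problems <- c(problems, sprintf(
        "record '%s': shape %d channels x %d samples, expected 16 x 2700",
        rid, nrow(ch), ncol(ch)))
      next
    }
    rec <- sensor_record(rid, ch, age = meta$age[i], sex = meta$sex[i],
                         smoking = meta$smoking[i], label = meta$label[i],
                         validate = FALSE)
    pr <- validate_record(rec)
    if (length(pr)) {
      problems <- c(problems, sprintf("record '%s': %s", rid, pr))
      next
    }
    records[[i]] <- rec
  }

  if (length(problems)) {
    abort_validation(paste0(
      sprintf("container '%s' failed validation:\n", path),
      paste0("- ", problems, collapse = "\n")
    ))
  }
  cohort(records, provenance = provenance, validate = TRUE)
}
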