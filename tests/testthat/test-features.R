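# 227-dimensional feature construction: period ratios, downsampling,
# metadata encoding.

test_that("period ratios follow elementwise division contracts", {
  seg <- fake_segmented(const_segments(3))
  expect_true(all(ratio_features(seg) == 1))

  segs <- const_segments(5)
  segs[, 4, ] <- 10
  expect_true(all(ratio_features(fake_segmented(segs)) == 2))

  degenerate <- const_segments(5)
  degenerate[7, 1, 23] <- 0 # ADC floor in the denominator period
  err <- tryCatch(ratio_features(fake_segmented(degenerate)),
                  condition = function(e) e)
  expect_s3_class(err, "enose_degenerate_signal_error")
  expect_match(conditionMessage(err), "MQ135")
  expect_match(conditionMessage(err), "22") # 0-based sample index

  expect_error(ratio_features(fake_segmented(const_segments(1, n_cyc = 3L))),
               class = "enose_contract_error")
})

test_that("noise-free cancer record ratios equal the response factor", {
  cfg <- clean_config(effect_size = 0.8)
  rat <- ratio_features(segment_record(generate_record(cfg, label = 1L)))
  expected <- exp(cfg$sensor_params$beta * 0.8 + cfg$sensor_params$gamma)
  expect_equal(rat, matrix(expected, 14, 165), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("downsampling keeps every 10th of 165 values, yielding 16", {
  expect_identical(downsample_ratios(as.numeric(0:164)), seq(0, 150, 10))
  expect_identical(downsample_ratios(rep(7, 165)), rep(7, 16))
  expect_length(downsample_ratios(rnorm(165)), 16L)
  expect_identical(downsample_ratios(as.numeric(0:164), offset = 3L),
                   seq(3, 153, 10))
  expect_error(downsample_ratios(1:164), class = "enose_contract_error")
  expect_error(downsample_ratios(rnorm(165), offset = 20L),
               class = "enose_contract_error")
})

test_that("metadata encode as age/100 and 0/1 indicators", {
  expect_identical(unname(encode_metadata(50, "F", "no")), c(0.50, 0, 0))
  expect_identical(unname(encode_metadata(100, "M", "yes")), c(1.00, 1, 1))
  expect_identical(unname(encode_metadata(22, "M", "no")), c(0.22, 1, 0))
  expect_error(encode_metadata(50, "X", "no"), class = "enose_validation_error")
  expect_error(encode_metadata(50, "F", "sometimes"),
               class = "enose_validation_error")
  expect_error(encode_metadata(-3, "F", "no"), class = "enose_validation_error")
})

test_that("feature vectors have 227 ordered entries and are local per sensor", {
  seg <- fake_segmented(const_segments(2), label = 1L, age = 64, sex = "M",
                        smoking = "yes")
  fv <- build_feature_vector(seg)
  expect_length(fv$values, 227L)
  expect_identical(fv$label, 1L)
  expect_identical(unname(tail(fv$values, 3)), c(0.64, 1, 1))
  expect_identical(names(fv$values)[1:2], c("s01_f01", "s01_f02"))
  expect_identical(names(fv$values)[17], "s02_f01")

  other <- const_segments(2)
  other[3, 4, ] <- 11 # perturb only sensor 3, period 4
  fv2 <- build_feature_vector(fake_segmented(other, label = 1L, age = 64,
                                             sex = "M", smoking = "yes"))
  changed <- which(fv$values != fv2$values)
  expect_true(all(changed %in% (2 * 16 + 1):(3 * 16)))
  expect_length(changed, 16L)
})

test_that("ratio features are invariant to per-sensor gain", {
  rec <- generate_record(clean_config(), label = 1L)
  scaled <- rec
  scaled$channels[4, ] <- 0.5 * scaled$channels[4, ]
  f1 <- build_feature_vector(segment_record(rec))$values
  f2 <- build_feature_vector(segment_record(scaled))$values
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("feature extraction is label-blind", {
  co <- small_cohort(2L, 2L, seed = 13L)
  feats <- cohort_features(co)
  flipped <- co
  for (k in seq_along(flipped$records))
    flipped$records[[k]]$label <- 1L - flipped$records[[k]]$label
  feats_flip <- cohort_features(flipped)
  expect_identical(feats_flip$label, 1L - feats$label)
  expect_identical(feats[, setdiff(names(feats), "label")],
                   feats_flip[, setdiff(names(feats_flip), "label")])
})

test_that("cohort feature matrices have one row per record and round-trip CSV", {
  co <- small_cohort(3L, 2L, seed = 21L)
  feats <- cohort_features(co)
  expect_identical(dim(feats), c(5L, 229L)) # id + label + 227 features
  expect_identical(names(feats)[1:2], c("record_id", "label"))
  expect_identical(names(feats)[229], "smoking")
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, path)
  expect_equal(read_features(path), feats, tolerance = 1e-12)
  header <- readLines(path, n = 1L)
  expect_match(header, "^record_id,label,s01_f01,")
})
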