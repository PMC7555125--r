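# Synthetic cohort generator.
#
# Emulates the gas-analytical acquisition: 14 MOS sensors driven in a
# 3.5 s heat / 5.5 s cool thermal cycle, sampled at 30 Hz for 90 s, with two
# meander synchronization channels (high during heating, zero during
# cooling) and a breath-sample injection at the 5000 ms heat->cool
# transition. The sensor waveform is a periodic template (saturating rise
# while heating, exponential decay toward a per-sensor floor while cooling)
# multiplied, after the injection has dispersed, by a per-sensor response
# factor
#
#   r_s = exp(beta_s * effect_size * label + gamma_s + eta_s)
#
# where beta_s carries the class effect on a subset of sensors, gamma_s the
# class-independent breath response, and eta_s ~ N(0, subject_sd^2) a
# per-record biological/sampling variability. The factor ramps linearly
# from the end of the injection-period cooling to full effect one thermal
# period later, so the first cooling segment is a clean pre-response
# baseline. Gaussian sensor noise and a slow multiplicative per-cycle drift
# are added on top.

#' Per-sensor waveform and response parameters
#'
#' Fixed parameter table of the 14 gas sensors used by the generator:
#' cooling-floor and peak amplitude (ADC counts), cooling decay constant
#' (1/s), class-effect coefficient `beta` and common breath-response
#' coefficient `gamma`. Half of the sensors carry a substantial `beta`
#' (disease-linked VOC sensitivity), the other half near zero, so the class
#' signal is distributed but not universal. The magnitudes are synthetic
#' placeholders: real per-sensor response sizes for breath VOCs are not
#' published.
#'
#' @return data.frame with one row per sensor.
#' @export
enose_sensor_params <- function() {
  data.frame(
    sensor = enose_channel_names()[1:14],
    floor = c(260, 220, 300, 240, 210, 280, 230, 250, 270, 220, 240, 260, 230, 250),
    amplitude = c(700, 950, 680, 1000, 720, 1100, 760, 980, 700, 1050, 740, 990, 710, 730),
    decay = c(0.45, 0.60, 0.35, 0.55, 0.50, 0.40, 0.65, 0.30, 0.55, 0.45, 0.70, 0.38, 0.52, 0.48),
    beta = c(0.55, 0.00, 0.45, 0.05, 0.60, 0.00, 0.50, 0.00, 0.40, 0.05, 0.35, 0.00, 0.50, 0.05),
    gamma = c(0.20, 0.30, 0.15, 0.25, 0.10, 0.18, 0.22, 0.28, 0.12, 0.20, 0.16, 0.26, 0.14, 0.24),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the study conditions: 36 cancer and 23 control
#' subjects, a 3.5 s / 5.5 s thermal cycle at 30 Hz, sample injection at the
#' 5000 ms heat-to-cool transition, and cohort demographics matching the
#' published composition.
#'
#' @param n_cancer number of cancer-labelled records (default 36).
#' @param n_control number of control records (default 23).
#' @param effect_size dimensionless class effect (log-ratio shift of the
#'   post-injection response between classes); default 0.5.
#' @param noise_sd additive Gaussian sensor noise, ADC counts (default 8).
#' @param drift_per_cycle relative multiplicative drift per thermal cycle
#'   (default 0.005).
#' @param subject_sd standard deviation of the per-record per-sensor
#'   log-response jitter (between-subject variability; default 0.15).
#' @param heat_ms,cool_ms heating / cooling phase lengths in ms; must sum to
#'   the 9000 ms thermal period.
#' @param injection_time_ms time of the sample injection, at a heat->cool
#'   transition (default 5000).
#' @param sync_high high level of the meander sync channels, ADC counts.
#' @param demographics `"study"` (class-dependent sex/age composition as in
#'   the study cohort) or `"balanced"` (label-independent demographics, for
#'   leakage/null experiments).
#' @param smoking_prev smoking prevalence, label-independent (default 0.4).
#' @param sensor_params per-sensor parameter table, see
#'   [enose_sensor_params()].
#' @param seed integer RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cancer = 36L, n_control = 23L,
                         effect_size = 0.5, noise_sd = 8,
                         drift_per_cycle = 0.005, subject_sd = 0.15,
                         heat_ms = 3500L, cool_ms = 5500L,
                         injection_time_ms = 5000L, sync_high = 1000,
                         demographics = c("study", "balanced"),
                         smoking_prev = 0.4,
                         sensor_params = enose_sensor_params(),
                         seed = 1L) {
  demographics <- match.arg(demographics)
  cfg <- structure(
    list(n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
         effect_size = effect_size, noise_sd = noise_sd,
         drift_per_cycle = drift_per_cycle, subject_sd = subject_sd,
         heat_ms = as.integer(heat_ms), cool_ms = as.integer(cool_ms),
         injection_time_ms = as.integer(injection_time_ms),
         sync_high = sync_high, demographics = demographics,
         smoking_prev = smoking_prev, sensor_params = sensor_params,
         seed = as.integer(seed)),
    class = "synth_config"
  )
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$heat_ms + cfg$cool_ms != 9000L)
    abort_contract("heat_ms + cool_ms must equal the 9000 ms thermal period")
  if (cfg$n_cancer + cfg$n_control < 2L)
    abort_contract("cohort must contain at least 2 records")
  if (cfg$effect_size < 0) abort_contract("effect_size must be >= 0")
  if (cfg$noise_sd < 0) abort_contract("noise_sd must be >= 0")
  if (cfg$subject_sd < 0) abort_contract("subject_sd must be >= 0")
  if (cfg$sync_high <= 0 || cfg$sync_high > ENOSE_ADC_MAX)
    abort_contract("sync_high must be in (0, 4095]")
  if (nrow(cfg$sensor_params) != ENOSE_N_SENSORS)
    abort_contract("sensor_params must have 14 rows")
  invisible(cfg)
}

# Timing grid (sample indices, 0-based, half-open intervals) --------------

#' Thermal-cycle timing grid implied by a configuration
#'
#' @param cfg a `synth_config`.
#' @return list with `heat_samples` (105), `cool_samples` (165), `period`
#'   (270), `injection_sample` (150), `first_heat_start` (45; the record
#'   opens on the tail of a cooling phase), `ramp_start`, `ramp_end`, and
#'   `cool_starts`: the 0-based start indices of all complete cooling
#'   segments.
#' @export
synth_timing <- function(cfg) {
  sr <- ENOSE_SAMPLE_RATE
  heat <- (cfg$heat_ms * sr) %/% 1000L
  cool <- (cfg$cool_ms * sr) %/% 1000L
  period <- heat + cool
  inj <- (cfg$injection_time_ms * sr) %/% 1000L
  first_heat <- inj - heat
  cool_starts <- seq.int(inj, ENOSE_N_SAMPLES - cool, by = period)
  list(heat_samples = heat, cool_samples = cool, period = period,
       injection_sample = inj, first_heat_start = first_heat,
       ramp_start = inj + cool, ramp_end = inj + cool + period,
       cool_starts = cool_starts)
}

# Periodic baseline template for one sensor at 0-based sample indices i.
# Phase 0 = start of heating. Continuous and exactly 270-sample periodic.
baseline_template <- function(i, floor, amplitude, decay, timing,
                              rise = 1.3) {
  sr <- ENOSE_SAMPLE_RATE
  heat_s <- timing$heat_samples / sr
  cool_s <- timing$cool_samples / sr
  phase <- ((i - timing$first_heat_start) %% timing$period) / sr
  peak <- floor + amplitude
  v_end <- floor + amplitude * exp(-decay * cool_s)
  out <- numeric(length(i))
  heating <- phase < heat_s
  out[heating] <- v_end + (peak - v_end) *
    (1 - exp(-rise * phase[heating])) / (1 - exp(-rise * heat_s))
  out[!heating] <- floor + amplitude * exp(-decay * (phase[!heating] - heat_s))
  out
}

# Injection-response multiplier profile: 1 before ramp_start, linear ramp to
# r over one period, r afterwards.
response_profile <- function(i, r, timing) {
  frac <- clamp((i - timing$ramp_start) / (timing$ramp_end - timing$ramp_start),
                0, 1)
  1 + (r - 1) * frac
}

#' Evaluate the noise-free generative sensor signal
#'
#' Closed form of the generator for one sensor: periodic baseline template
#' times injection-response ramp times per-cycle drift, without noise. Used
#' by the generator itself and available to verify segment values
#' independently.
#'
#' @param cfg a `synth_config`.
#' @param sensor sensor index 1..14.
#' @param i 0-based sample indices.
#' @param label class label 0/1.
#' @param eta per-record log-response jitter for this sensor (default 0).
#' @return numeric vector of noise-free ADC values (unclipped).
#' @export
synth_signal <- function(cfg, sensor, i = seq_len(ENOSE_N_SAMPLES) - 1L,
                         label = 0L, eta = 0) {
  timing <- synth_timing(cfg)
  sp <- cfg$sensor_params[sensor, ]
  base <- baseline_template(i, sp$floor, sp$amplitude, sp$decay, timing)
  r <- exp(sp$beta * cfg$effect_size * label + sp$gamma + eta)
  resp <- response_profile(i, r, timing)
  cycle <- pmax(0, (i - timing$first_heat_start) %/% timing$period)
  base * resp * (1 + cfg$drift_per_cycle)^cycle
}

# Sync meander over the record: high during heating, 0 during cooling.
sync_wave <- function(cfg) {
  timing <- synth_timing(cfg)
  i <- seq_len(ENOSE_N_SAMPLES) - 1L
  phase <- (i - timing$first_heat_start) %% timing$period
  ifelse(phase < timing$heat_samples, cfg$sync_high, 0)
}

#' Generate one synthetic sensor record
#'
#' Draws from the generative model under the current RNG state (wrap in
#' [withr::with_seed()] or pass records through [generate_cohort()] for
#' reproducibility).
#'
#' @param cfg a `synth_config`.
#' @param label class label 0/1.
#' @param record_id identifier string.
#' @param age,sex,smoking subject metadata.
#' @return a validated `sensor_record`.
#' @export
generate_record <- function(cfg, label, record_id = "rec001",
                            age = 50, sex = "M", smoking = "no") {
  validate_synth_config(cfg)
  i <- seq_len(ENOSE_N_SAMPLES) - 1L
  ch <- matrix(0, ENOSE_N_CHANNELS, ENOSE_N_SAMPLES)
  eta <- if (cfg$subject_sd > 0) rnorm(ENOSE_N_SENSORS, 0, cfg$subject_sd)
         else numeric(ENOSE_N_SENSORS)
  for (s in seq_len(ENOSE_N_SENSORS)) {
    sig <- synth_signal(cfg, s, i, label = label, eta = eta[s])
    if (cfg$noise_sd > 0) sig <- sig + rnorm(ENOSE_N_SAMPLES, 0, cfg$noise_sd)
    ch[s, ] <- clamp(sig, 0, ENOSE_ADC_MAX)
  }
  wave <- sync_wave(cfg)
  ch[15, ] <- wave
  ch[16, ] <- wave
  sensor_record(record_id, ch, age = age, sex = sex, smoking = smoking,
                label = label)
}

# Demographics ----------------------------------------------------------

# Study composition: cancer 6 F / 30 M, ages 2 in 20-40 and 34 in 40-75;
# control 16 F / 7 M, ages 14 in 20-40 and 9 in 40-50. Ages uniform within
# bands. "balanced" mode draws label-independent demographics.
draw_demographics <- function(cfg, labels) {
  n <- length(labels)
  age <- numeric(n); sex <- character(n)
  if (cfg$demographics == "balanced") {
    age <- round(runif(n, 20, 75))
    sex <- ifelse(runif(n) < 0.5, "F", "M")
  } else {
    for (lab in c(1L, 0L)) {
      idx <- which(labels == lab)
      m <- length(idx)
      if (m == 0L) next
      if (lab == 1L) {
        n_f <- round(m * 6 / 36)
        n_young <- round(m * 2 / 36)
        ages <- c(runif(n_young, 20, 40), runif(m - n_young, 40, 75))
      } else {
        n_f <- round(m * 16 / 23)
        n_young <- round(m * 14 / 23)
        ages <- c(runif(n_young, 20, 40), runif(m - n_young, 40, 50))
      }
      sexes <- c(rep("F", n_f), rep("M", m - n_f))
      age[idx] <- round(ages[sample.int(m)])
      sex[idx] <- sexes[sample.int(m)]
    }
  }
  smoking <- ifelse(runif(n) < cfg$smoking_prev, "yes", "no")
  data.frame(age = age, sex = sex, smoking = smoking,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `cfg$seed`: the same configuration always yields a
#' bit-identical cohort. Records are ordered cancer first, then controls.
#'
#' @param cfg a `synth_config`.
#' @return an `enose_cohort` with `n_cancer + n_control` records.
#' @export
generate_cohort <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  labels <- c(rep(1L, cfg$n_cancer), rep(0L, cfg$n_control))
  n <- length(labels)
  ids <- sprintf("rec%03d", seq_len(n))
  with_seed(cfg$seed, {
    demo <- draw_demographics(cfg, labels)
    records <- vector("list", n)
    for (k in seq_len(n)) {
      records[[k]] <- generate_record(
        cfg, label = labels[k], record_id = ids[k],
        age = demo$age[k], sex = demo$sex[k], smoking = demo$smoking[k])
    }
    cohort(records, provenance = "synthetic",
           generator_config_hash = config_hash(cfg), validate = FALSE)
  })
}

#' Write / read a synthetic configuration as YAML
#'
#' The sensor-parameter table is embedded as a list of per-sensor rows.
#'
#' @param cfg a `synth_config`.
#' @param path YAML file path.
#' @return `read_synth_config` returns a `synth_config`.
#' @export
write_synth_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$sensor_params <- lapply(seq_len(nrow(cfg$sensor_params)),
                            function(i) as.list(cfg$sensor_params[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  sp <- do.call(rbind, lapply(x$sensor_params, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  # YAML renders whole-number doubles as integers; rebuild the table with
  # canonical types and attribute layout so config hashes are stable
  x$sensor_params <- data.frame(
    sensor = as.character(sp$sensor), floor = as.numeric(sp$floor),
    amplitude = as.numeric(sp$amplitude), decay = as.numeric(sp$decay),
    beta = as.numeric(sp$beta), gamma = as.numeric(sp$gamma),
    stringsAsFactors = FALSE)
  for (f in c("effect_size", "noise_sd", "drift_per_cycle", "subject_sd",
              "sync_high", "smoking_prev"))
    x[[f]] <- as.numeric(x[[f]])
  do.call(synth_config, x)
}
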