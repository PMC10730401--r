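# Seeded generators that emulate every pipeline input with known ground
# truth: differential-expression tables with planted enriched gene sets,
# phase-structured oxygen-consumption traces, pulsed calcium-uptake traces
# and linear-kinetic hydrogen-peroxide traces. All randomness flows from one
# seeded stream per call and the caller's RNG state is left untouched, so a
# fixed config always reproduces byte-identical output.

#' Configuration for a synthetic differential-expression table
#'
#' Null genes draw log2 fold changes from `Normal(0, null_sd)`; members of a
#' planted set are additionally shifted by `+delta` (direction `"up"`) or
#' `-delta` (`"down"`). Gene-level p-values come from the two-sided normal
#' test of `log2fc / se_per_gene` — the pipeline only consumes
#' `(log2fc, padj)`, so a closed-form gene-level model suffices and no count
#' simulation is attempted. Adjusted p-values are BH over all genes.
#'
#' @param n_genes Number of genes (> 0).
#' @param null_sd Null log2FC standard deviation (default 0.5).
#' @param planted_sets List of planted sets, each a list with `name`, `size`,
#'   `delta` (>= 0) and `direction` (`"up"`/`"down"`); an optional `members`
#'   field gives explicit gene indices (default: consecutive blocks starting
#'   at gene 1, so default sets are disjoint).
#' @param se_per_gene Standard error used for the gene-level z-test
#'   (default 0.25).
#' @param seed Integer seed.
#' @return A `de_sim_config` list.
#' @export
de_sim_config <- function(n_genes, null_sd = 0.5, planted_sets = list(),
                          se_per_gene = 0.25, seed = 1) {
  stop_unless_scalar_number(n_genes, "n_genes", positive = TRUE)
  stop_unless_scalar_number(null_sd, "null_sd", nonnegative = TRUE)
  stop_unless_scalar_number(se_per_gene, "se_per_gene", positive = TRUE)
  stop_unless_scalar_number(seed, "seed")
  offset <- 0L
  planted <- lapply(planted_sets, function(s) {
    stopifnot(is.list(s), !is.null(s$name), !is.null(s$size),
              !is.null(s$delta), !is.null(s$direction))
    stop_unless_scalar_number(s$size, "planted set size", positive = TRUE)
    stop_unless_scalar_number(s$delta, "delta", nonnegative = TRUE)
    if (!s$direction %in% c("up", "down")) {
      stop("planted set direction must be 'up' or 'down'", call. = FALSE)
    }
    if (s$size >= n_genes) {
      stop("planted set size must be < n_genes", call. = FALSE)
    }
    if (is.null(s$members)) {
      s$members <- offset + seq_len(s$size)
      offset <<- offset + as.integer(s$size)
      if (offset > n_genes) {
        stop("planted sets exceed n_genes; give explicit `members`",
             call. = FALSE)
      }
    } else {
      s$members <- as.integer(s$members)
      stopifnot(all(s$members >= 1L), all(s$members <= n_genes),
                length(s$members) == s$size)
    }
    s
  })
  # overlapping sets may not pull the same gene in opposite directions
  if (length(planted) > 1L) {
    for (i in seq_along(planted)) {
      for (j in seq_len(i - 1L)) {
        shared <- intersect(planted[[i]]$members, planted[[j]]$members)
        if (length(shared) > 0L &&
            planted[[i]]$direction != planted[[j]]$direction &&
            planted[[i]]$delta > 0 && planted[[j]]$delta > 0) {
          stop("planted sets '", planted[[j]]$name, "' and '",
               planted[[i]]$name,
               "' overlap with conflicting directions", call. = FALSE)
        }
      }
    }
  }
  structure(list(n_genes = as.integer(n_genes), null_sd = null_sd,
                 planted_sets = planted, se_per_gene = se_per_gene,
                 seed = seed),
            class = "de_sim_config")
}

#' Simulate a differential-expression table with planted gene sets
#'
#' @param cfg A [de_sim_config()].
#' @return List of class `de_sim`: `table` (data.frame `gene`, `log2fc`,
#'   `pvalue`, `padj`) and `truth` (planted membership, direction and delta
#'   per set, plus the config).
#' @export
#' @examples
#' cfg <- de_sim_config(500, planted_sets = list(
#'   list(name = "oxphos", size = 20, delta = 1, direction = "up")))
#' sim <- simulate_de_table(cfg)
#' head(sim$table)
simulate_de_table <- function(cfg) {
  stopifnot(inherits(cfg, "de_sim_config"))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  lfc <- with_seed(cfg$seed, stats::rnorm(cfg$n_genes, 0, cfg$null_sd))
  for (s in cfg$planted_sets) {
    shift <- if (s$direction == "up") s$delta else -s$delta
    lfc[s$members] <- lfc[s$members] + shift
  }
  p <- 2 * stats::pnorm(abs(lfc) / cfg$se_per_gene, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1] for BH
  tab <- data.frame(gene = genes, log2fc = lfc, pvalue = p,
                    padj = bh_fdr(p), stringsAsFactors = FALSE)
  truth <- list(
    sets = stats::setNames(lapply(cfg$planted_sets, function(s) {
      list(members = genes[s$members], direction = s$direction,
           delta = s$delta)
    }), vapply(cfg$planted_sets, `[[`, "", "name")),
    config = cfg
  )
  structure(list(table = tab, truth = truth), class = "de_sim")
}

#' Configuration for a phase-structured (OCR-style) trace
#'
#' The generator emulates a Seahorse-style run: the signal is
#' piecewise-constant at `phase_means` (one level per injection phase, e.g.
#' substrate-only baseline, then ADP, oligomycin, FCCP and antimycin A), with
#' `cycles_per_phase` measurement cycles per phase at `sample_interval`
#' seconds and additive Gaussian noise.
#'
#' @param phase_means Named numeric vector of true phase levels, in injection
#'   order; defaults to a coupling-assay profile
#'   (baseline 50, ADP 120, oligomycin 40, FCCP 130, antimycin 10).
#' @param cycles_per_phase Measurement cycles per phase (default 6).
#' @param noise_sd Gaussian noise SD in signal units (default 0).
#' @param sample_interval Seconds between cycles (default 360, a typical
#'   mix/wait/measure cycle length).
#' @param seed Integer seed.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(phase_means = c(baseline = 50, ADP = 120,
                                             oligomycin = 40, FCCP = 130,
                                             antimycin = 10),
                             cycles_per_phase = 6, noise_sd = 0,
                             sample_interval = 360, seed = 1) {
  if (length(phase_means) == 0L || is.null(names(phase_means)) ||
      any(!nzchar(names(phase_means)))) {
    stop("`phase_means` must be a non-empty named vector", call. = FALSE)
  }
  stop_unless_scalar_number(cycles_per_phase, "cycles_per_phase",
                            positive = TRUE)
  stop_unless_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  stop_unless_scalar_number(sample_interval, "sample_interval",
                            positive = TRUE)
  stop_unless_scalar_number(seed, "seed")
  structure(list(phase_means = phase_means,
                 cycles_per_phase = as.integer(cycles_per_phase),
                 noise_sd = noise_sd, sample_interval = sample_interval,
                 seed = seed),
            class = "trace_sim_config")
}

#' Simulate a phase-structured OCR trace with its injection schedule
#'
#' @param cfg A [trace_sim_config()].
#' @param well Well id for the long-format trace (default "A1").
#' @return List of class `ocr_sim`: `trace` (`well`, `time_s`, `signal`),
#'   `schedule` (`label`, `time_s`) and `truth` (the phase means).
#' @export
simulate_ocr_trace <- function(cfg, well = "A1") {
  stopifnot(inherits(cfg, "trace_sim_config"))
  n_phase <- length(cfg$phase_means)
  cpp <- cfg$cycles_per_phase
  n <- n_phase * cpp
  time_s <- (seq_len(n) - 1L) * cfg$sample_interval
  level <- rep(unname(cfg$phase_means), each = cpp)
  noise <- with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
  trace <- data.frame(well = well, time_s = time_s, signal = level + noise,
                      stringsAsFactors = FALSE)
  schedule <- data.frame(
    label = names(cfg$phase_means),
    time_s = (seq_len(n_phase) - 1L) * cpp * cfg$sample_interval,
    stringsAsFactors = FALSE
  )
  structure(list(trace = trace, schedule = schedule,
                 truth = list(phase_means = cfg$phase_means)),
            class = "ocr_sim")
}

#' Configuration for a pulsed calcium-retention trace
#'
#' Emulates a Calcium Green-5N style run on isolated mitochondria: after a
#' baseline period, CaCl2 pulses are added at fixed intervals. Each pulse
#' raises the extramitochondrial signal by `amplitude`; between pulses the
#' signal decays exponentially toward baseline at `rate` per second
#' (mitochondrial uptake) while the cumulative cleared signal stays below
#' `capacity`; once the capacity is exhausted uptake stops and added Ca2+
#' simply accumulates — the "loses its buffering capacity" phenotype.
#'
#' @param baseline Baseline fluorescence level (default 10).
#' @param amplitude Signal jump per pulse A (default 10, one 10 uM CaCl2
#'   pulse).
#' @param rate Uptake (decay) rate k per second (default 0.05, near-complete
#'   clearance within a 3-minute inter-pulse interval).
#' @param capacity Total signal the mitochondria can clear, in signal units
#'   (default `Inf` = never saturates).
#' @param n_pulses Number of pulses (default 5, the usual protocol).
#' @param pulse_interval Seconds between pulses (default 180 = 3 min).
#' @param baseline_duration Seconds of baseline before the first pulse
#'   (default 180).
#' @param sample_interval Sampling interval in seconds (default 5).
#' @param noise_sd Observation noise SD (default 0).
#' @param seed Integer seed.
#' @return A `crc_sim_config` list.
#' @export
crc_sim_config <- function(baseline = 10, amplitude = 10, rate = 0.05,
                           capacity = Inf, n_pulses = 5,
                           pulse_interval = 180, baseline_duration = 180,
                           sample_interval = 5, noise_sd = 0, seed = 1) {
  stop_unless_scalar_number(baseline, "baseline")
  stop_unless_scalar_number(amplitude, "amplitude", nonnegative = TRUE)
  stop_unless_scalar_number(rate, "rate", nonnegative = TRUE)
  if (!(is.numeric(capacity) && length(capacity) == 1L &&
        (is.infinite(capacity) || capacity >= 0))) {
    stop("`capacity` must be a non-negative number or Inf", call. = FALSE)
  }
  stop_unless_scalar_number(n_pulses, "n_pulses", positive = TRUE)
  stop_unless_scalar_number(pulse_interval, "pulse_interval", positive = TRUE)
  stop_unless_scalar_number(baseline_duration, "baseline_duration",
                            nonnegative = TRUE)
  stop_unless_scalar_number(sample_interval, "sample_interval",
                            positive = TRUE)
  stop_unless_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  stop_unless_scalar_number(seed, "seed")
  structure(list(baseline = baseline, amplitude = amplitude, rate = rate,
                 capacity = capacity, n_pulses = as.integer(n_pulses),
                 pulse_interval = pulse_interval,
                 baseline_duration = baseline_duration,
                 sample_interval = sample_interval, noise_sd = noise_sd,
                 seed = seed),
            class = "crc_sim_config")
}

#' Simulate a pulsed calcium-retention trace
#'
#' The latent state is advanced sample by sample; noise is added only to the
#' observed signal, so a zero-noise config reproduces the dynamics exactly.
#'
#' @param cfg A [crc_sim_config()].
#' @param well Well id (default "A1").
#' @return List of class `crc_sim`: `trace`, `pulse_times` and `truth`
#'   (amplitude, rate, capacity, pulse times, cumulative uptake actually
#'   delivered).
#' @export
simulate_crc_trace <- function(cfg, well = "A1") {
  stopifnot(inherits(cfg, "crc_sim_config"))
  dt <- cfg$sample_interval
  total <- cfg$baseline_duration + cfg$n_pulses * cfg$pulse_interval
  time_s <- seq(0, total, by = dt)
  pulse_times <- cfg$baseline_duration +
    (seq_len(cfg$n_pulses) - 1L) * cfg$pulse_interval
  s <- cfg$baseline
  cum <- 0
  latent <- numeric(length(time_s))
  for (i in seq_along(time_s)) {
    if (any(abs(pulse_times - time_s[i]) < dt / 2)) {
      s <- s + cfg$amplitude * sum(abs(pulse_times - time_s[i]) < dt / 2)
    }
    latent[i] <- s
    # uptake between this sample and the next
    removable <- (s - cfg$baseline) * (1 - exp(-cfg$rate * dt))
    allowed <- min(max(removable, 0), max(cfg$capacity - cum, 0))
    s <- s - allowed
    cum <- cum + allowed
  }
  noise <- with_seed(cfg$seed, stats::rnorm(length(time_s), 0, cfg$noise_sd))
  trace <- data.frame(well = well, time_s = time_s, signal = latent + noise,
                      stringsAsFactors = FALSE)
  structure(list(trace = trace, pulse_times = pulse_times,
                 truth = list(amplitude = cfg$amplitude, rate = cfg$rate,
                              capacity = cfg$capacity, baseline = cfg$baseline,
                              pulse_times = pulse_times,
                              cumulative_uptake = cum)),
            class = "crc_sim")
}

#' Simulate a linear-kinetic H2O2 fluorescence trace
#'
#' Emulates an Amplex Red style kinetic read: fluorescence rising linearly
#' with time (default 20 minutes at 30-second intervals) plus Gaussian noise.
#'
#' @param slope True slope in signal units per minute.
#' @param intercept Signal at time zero (default 0).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param duration Total duration in seconds (default 1200 = 20 min).
#' @param interval Sampling interval in seconds (default 30).
#' @param seed Integer seed.
#' @param well Well id (default "A1").
#' @return List of class `h2o2_sim`: `trace` and `truth` (slope, intercept).
#' @export
simulate_h2o2_trace <- function(slope, intercept = 0, noise_sd = 0,
                                duration = 1200, interval = 30, seed = 1,
                                well = "A1") {
  stop_unless_scalar_number(slope, "slope")
  stop_unless_scalar_number(intercept, "intercept")
  stop_unless_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  stop_unless_scalar_number(duration, "duration", positive = TRUE)
  stop_unless_scalar_number(interval, "interval", positive = TRUE)
  time_s <- seq(0, duration, by = interval)
  noise <- with_seed(seed, stats::rnorm(length(time_s), 0, noise_sd))
  trace <- data.frame(well = well, time_s = time_s,
                      signal = intercept + slope * time_s / 60 + noise,
                      stringsAsFactors = FALSE)
  structure(list(trace = trace,
                 truth = list(slope = slope, intercept = intercept)),
            class = "h2o2_sim")
}
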