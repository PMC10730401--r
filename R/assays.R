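# Derivation procedures for plate-based mitochondrial assays: phase
# segmentation of injection-structured traces, respiratory states and the
# respiratory control ratio, electron-flow complex activities, calcium
# retention capacity, hydrogen peroxide production slopes, ATP standard-curve
# quantification, plus the small morphometric and statistical helpers used
# alongside them (ER aspect ratio, exact Mann-Whitney, effect size +/- SEM).

# Canonical phase grammars per assay kind.
OCR_COUPLING_PHASES <- c("baseline", "ADP", "oligomycin", "FCCP", "antimycin")
OCR_EFLOW_PHASES <- c("baseline", "rotenone", "succinate", "antimycinA",
                      "ascTMPD")

#' Segment a plate trace into injection phases
#'
#' Samples are assigned to the phase of the most recent injection at or
#' before their timestamp. The first `discard_first` measurement cycles after
#' each injection (not of the initial phase, which has no injection) are
#' dropped as mixing artifacts.
#'
#' @param trace Data.frame with columns `time_s`, `signal` (strictly
#'   increasing times, at least two samples).
#' @param schedule Data.frame with columns `label`, `time_s`; the first event
#'   labels the initial phase and must not postdate the first sample.
#' @param discard_first Cycles dropped after each injection (default 1).
#' @return Data.frame with one row per phase in schedule order: `phase`,
#'   `mean`, `sd`, `n`.
#' @export
segment_phases <- function(trace, schedule, discard_first = 1) {
  if (!all(c("time_s", "signal") %in% names(trace)) || nrow(trace) < 2L) {
    stop("`trace` needs columns time_s, signal and >= 2 samples",
         call. = FALSE)
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  if (!all(c("label", "time_s") %in% names(schedule)) ||
      nrow(schedule) == 0L) {
    stop("`schedule` needs columns label, time_s", call. = FALSE)
  }
  sc <- schedule[order(schedule$time_s), ]
  if (sc$time_s[1L] > trace$time_s[1L]) {
    stop("first schedule event must not postdate the first sample",
         call. = FALSE)
  }
  if (max(sc$time_s) > max(trace$time_s)) {
    stop("schedule event beyond the end of the trace", call. = FALSE)
  }
  stop_unless_scalar_number(discard_first, "discard_first", nonnegative = TRUE)
  phase_idx <- findInterval(trace$time_s, sc$time_s)
  rows <- lapply(seq_len(nrow(sc)), function(k) {
    sel <- which(phase_idx == k)
    if (k > 1L && discard_first > 0) {
      sel <- sel[-seq_len(min(discard_first, length(sel)))]
    }
    if (length(sel) == 0L) {
      stop("phase '", sc$label[k], "' has no retained samples", call. = FALSE)
    }
    x <- trace$signal[sel]
    data.frame(phase = sc$label[k], mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

phase_mean <- function(phase_summary, label) {
  i <- match(label, phase_summary$phase)
  if (is.na(i)) {
    stop("required phase '", label, "' missing from phase summary",
         call. = FALSE)
  }
  phase_summary$mean[i]
}

#' Respiratory states from a coupling-assay phase summary
#'
#' The coupling assay runs substrate-only respiration (state II), ADP-driven
#' phosphorylating respiration (state III), oligomycin-inhibited leak
#' respiration (state IVo) and FCCP-uncoupled maximal respiration (state
#' IIIu), ending with antimycin A which leaves only non-mitochondrial oxygen
#' consumption. Every state is the phase mean minus that residual, floored at
#' zero (negative rates after subtraction are measurement noise and raise a
#' warning). The respiratory control ratio RCR = state III / state IVo is
#' reported when state IVo is positive.
#'
#' @param phase_summary Output of [segment_phases()] with phases `baseline`,
#'   `ADP`, `oligomycin`, `FCCP`, `antimycin`.
#' @return List of class `resp_states`: `state_II`, `state_III`, `state_IVo`,
#'   `state_IIIu`, `residual`, `rcr` (NA when undefined).
#' @export
#' @examples
#' ps <- data.frame(phase = c("baseline", "ADP", "oligomycin", "FCCP",
#'                            "antimycin"),
#'                  mean = c(50, 120, 40, 130, 10), sd = 0, n = 6)
#' derive_resp_states(ps) # II=40, III=110, IVo=30, IIIu=120, RCR=3.667
derive_resp_states <- function(phase_summary) {
  residual <- phase_mean(phase_summary, "antimycin")
  raw <- c(state_II = phase_mean(phase_summary, "baseline") - residual,
           state_III = phase_mean(phase_summary, "ADP") - residual,
           state_IVo = phase_mean(phase_summary, "oligomycin") - residual,
           state_IIIu = phase_mean(phase_summary, "FCCP") - residual)
  if (any(raw < 0)) {
    warning("state(s) below the non-mitochondrial residual floored at 0: ",
            paste(names(raw)[raw < 0], collapse = ", "), call. = FALSE)
    raw <- pmax(raw, 0)
  }
  rcr <- if (raw[["state_IVo"]] > 0) {
    raw[["state_III"]] / raw[["state_IVo"]]
  } else {
    NA_real_
  }
  structure(c(as.list(raw), list(residual = residual, rcr = rcr)),
            class = "resp_states")
}

#' @export
print.resp_states <- function(x, ...) {
  cat(sprintf(
    "respiratory states (residual-subtracted): II=%.3g III=%.3g IVo=%.3g IIIu=%.3g RCR=%.3g\n",
    x$state_II, x$state_III, x$state_IVo, x$state_IIIu, x$rcr))
  invisible(x)
}

#' Complex I-IV activities from an electron-flow phase summary
#'
#' The electron-flow assay starts with pyruvate/malate plus FCCP (complex
#' I-driven respiration, P1), then sequential injections of rotenone (P2),
#' succinate (P3), antimycin A (P4) and ascorbate/TMPD (P5). Activities are
#' the phase-mean differences: CxI = P1 - P2, CxII = P3 - P2,
#' CxIII = P3 - P4, CxIV = P5 - P4. Negative differences are reported as-is
#' but flagged, since inhibitor failures do occur.
#'
#' @param phase_summary Output of [segment_phases()] with phases `baseline`,
#'   `rotenone`, `succinate`, `antimycinA`, `ascTMPD`.
#' @return List of class `complex_activities`: `CxI`..`CxIV` plus a logical
#'   `flagged` vector marking negative activities.
#' @export
derive_complex_activities <- function(phase_summary) {
  p1 <- phase_mean(phase_summary, "baseline")
  p2 <- phase_mean(phase_summary, "rotenone")
  p3 <- phase_mean(phase_summary, "succinate")
  p4 <- phase_mean(phase_summary, "antimycinA")
  p5 <- phase_mean(phase_summary, "ascTMPD")
  act <- c(CxI = p1 - p2, CxII = p3 - p2, CxIII = p3 - p4, CxIV = p5 - p4)
  flagged <- act < 0
  if (any(flagged)) {
    warning("negative complex activity flagged: ",
            paste(names(act)[flagged], collapse = ", "), call. = FALSE)
  }
  structure(c(as.list(act), list(flagged = flagged)),
            class = "complex_activities")
}

#' @export
print.complex_activities <- function(x, ...) {
  cat(sprintf("complex activities: CxI=%.3g CxII=%.3g CxIII=%.3g CxIV=%.3g\n",
              x$CxI, x$CxII, x$CxIII, x$CxIV))
  invisible(x)
}

#' Calcium retention capacity from a pulsed fluorescence trace
#'
#' After each CaCl2 pulse the extramitochondrial indicator signal jumps and
#' then declines as mitochondria take the Ca2+ up. Two area readings are
#' offered:
#'
#' * `mode = "uptake"` (default): for each pulse, the peak within
#'   `peak_window` seconds of the pulse is located and the trapezoidal area
#'   of `peak - signal(t)` (negative contributions clipped at zero) is
#'   integrated from the peak to the next pulse (or trace end). This is the
#'   amount of added Ca2+ cleared from the medium: zero when nothing is
#'   taken up, larger for healthier mitochondria.
#' * `mode = "trace_auc"`: the area of the above-baseline transient
#'   `signal(t) - baseline` over the same windows, where the baseline is the
#'   pre-first-pulse mean. For an exponential transient of amplitude A and
#'   rate k that decays fully this converges to `A/k` per pulse.
#'
#' Retention is the sum over pulses; it is invariant to adding a constant to
#' the whole trace and additive over pulses.
#'
#' @param trace Data.frame with columns `time_s`, `signal`.
#' @param pulse_times Numeric vector of pulse injection times (>= 1, all
#'   within the trace span).
#' @param mode `"uptake"` or `"trace_auc"`.
#' @param peak_window Seconds after a pulse within which the peak is sought
#'   (default 15).
#' @return List of class `crc_result`: `retention` (signal-units x seconds),
#'   `per_pulse` data.frame (`pulse_time`, `peak`, `area`), `mode`.
#' @export
crc_retention <- function(trace, pulse_times,
                          mode = c("uptake", "trace_auc"), peak_window = 15) {
  mode <- match.arg(mode)
  if (!all(c("time_s", "signal") %in% names(trace))) {
    stop("`trace` needs columns time_s, signal", call. = FALSE)
  }
  pulse_times <- sort(as.numeric(pulse_times))
  if (length(pulse_times) == 0L) {
    stop("need at least one pulse", call. = FALSE)
  }
  t <- trace$time_s
  y <- trace$signal
  if (any(pulse_times > max(t)) || any(pulse_times < min(t))) {
    stop("pulse outside the trace span", call. = FALSE)
  }
  baseline <- if (any(t < pulse_times[1L])) {
    mean(y[t < pulse_times[1L]])
  } else {
    y[1L]
  }
  ends <- c(pulse_times[-1L], max(t))
  last <- length(pulse_times)
  per_pulse <- lapply(seq_along(pulse_times), function(i) {
    t0 <- pulse_times[i]
    t1 <- ends[i]
    # the sample at the next pulse time already carries that pulse's jump,
    # so non-final windows are right-open
    in_win <- if (i < last) {
      t >= t0 & t < min(t0 + peak_window, t1)
    } else {
      t >= t0 & t <= min(t0 + peak_window, t1)
    }
    win <- which(in_win)
    if (length(win) == 0L) {
      stop("no samples within the peak window after pulse at t = ", t0,
           call. = FALSE)
    }
    peak_at <- win[which.max(y[win])]
    seg <- if (i < last) {
      which(t >= t[peak_at] & t < t1)
    } else {
      which(t >= t[peak_at] & t <= t1)
    }
    area <- if (mode == "uptake") {
      trapz(t[seg], pmax(y[peak_at] - y[seg], 0))
    } else {
      trapz(t[seg], pmax(y[seg] - baseline, 0))
    }
    data.frame(pulse_time = t0, peak = y[peak_at], area = area)
  })
  per_pulse <- do.call(rbind, per_pulse)
  structure(list(retention = sum(per_pulse$area), per_pulse = per_pulse,
                 mode = mode, baseline = baseline),
            class = "crc_result")
}

#' @export
print.crc_result <- function(x, ...) {
  cat(sprintf("CRC retention (%s mode): %.4g over %d pulse(s)\n",
              x$mode, x$retention, nrow(x$per_pulse)))
  invisible(x)
}

#' Kinetic slope of an H2O2 (Amplex Red style) fluorescence trace
#'
#' Ordinary least-squares line over the requested time window; the slope is
#' reported per minute regardless of the sampling interval.
#'
#' @param trace Data.frame with columns `time_s`, `signal`.
#' @param window Optional `c(start_s, end_s)`; default is the whole trace.
#' @return List: `slope` (signal/min), `se` (standard error, signal/min),
#'   `intercept`, `r_squared`, `n`.
#' @export
h2o2_slope <- function(trace, window = NULL) {
  if (!all(c("time_s", "signal") %in% names(trace))) {
    stop("`trace` needs columns time_s, signal", call. = FALSE)
  }
  t <- trace$time_s
  y <- trace$signal
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- t >= window[1L] & t <= window[2L]
    t <- t[keep]
    y <- y[keep]
  }
  if (length(t) < 2L) {
    stop("need at least 2 samples in the window", call. = FALSE)
  }
  fit <- stats::lm(y ~ I(t / 60))
  sm <- suppressWarnings(summary(fit)) # noiseless fits warn harmlessly
  list(slope = unname(stats::coef(fit)[2L]),
       se = unname(sm$coefficients[2L, "Std. Error"]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       n = length(t))
}

#' ATP concentration from a luminescence standard curve
#'
#' Fits `log10(luminescence) ~ log10(concentration)` by least squares over
#' the standards (a serial dilution) and inverts the line for the sample.
#' Inversions further than 0.5 log10 units outside the standards' range are
#' refused as extrapolation.
#'
#' @param standards Data.frame with columns `conc` and `luminescence`, both
#'   strictly positive, at least two rows.
#' @param luminescence Sample luminescence value(s), strictly positive.
#' @return Estimated concentration(s), in the standards' concentration units.
#' @export
#' @examples
#' std <- data.frame(conc = c(1, 0.1, 0.01),
#'                   luminescence = c(1000, 100, 10))
#' atp_from_standard_curve(std, 100) # 0.1
atp_from_standard_curve <- function(standards, luminescence) {
  if (!all(c("conc", "luminescence") %in% names(standards))) {
    stop("`standards` needs columns conc and luminescence", call. = FALSE)
  }
  if (nrow(standards) < 2L) {
    stop("need at least 2 standards", call. = FALSE)
  }
  if (any(standards$conc <= 0) || any(standards$luminescence <= 0) ||
      any(luminescence <= 0)) {
    stop("concentrations and luminescence must be positive", call. = FALSE)
  }
  lc <- log10(standards$conc)
  ll <- log10(standards$luminescence)
  fit <- stats::lm(ll ~ lc)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  if (!is.finite(b) || b == 0) {
    stop("degenerate standard curve (zero slope)", call. = FALSE)
  }
  log_conc <- (log10(luminescence) - a) / b
  lo <- min(lc) - 0.5
  hi <- max(lc) + 0.5
  if (any(log_conc < lo | log_conc > hi)) {
    stop("sample outside the standard-curve range by > 0.5 log10 units",
         call. = FALSE)
  }
  10^log_conc
}

#' Endoplasmic-reticulum aspect ratio
#'
#' Elongation measure of an ER profile: major axis divided by minor axis.
#'
#' @param major_axis,minor_axis Numeric vectors; `minor_axis` must be
#'   positive and no larger than `major_axis`.
#' @return `major_axis / minor_axis`.
#' @export
er_aspect_ratio <- function(major_axis, minor_axis) {
  if (any(minor_axis <= 0)) {
    stop("minor axis must be > 0", call. = FALSE)
  }
  if (any(major_axis < minor_axis)) {
    stop("major axis must be >= minor axis", call. = FALSE)
  }
  major_axis / minor_axis
}

#' Exact two-sided Mann-Whitney U test
#'
#' Computes `U` for `group_a` (the number of (a, b) pairs with a > b, plus
#' half the ties) and a two-sided p-value from the permutation distribution
#' of U over all `choose(n_a + n_b, n_a)` group labelings. The exact
#' distribution is enumerated whenever that count is at most `max_enumerate`
#' (which covers the small per-group sample sizes typical of animal-model
#' assays); beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param max_enumerate Enumeration bound on the labeling count
#'   (default 2e5).
#' @return List of class `mwu_test`: `u`, `p`, `exact`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
mann_whitney_exact <- function(group_a, group_b, max_enumerate = 2e5) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L || any(!is.finite(c(a, b)))) {
    stop("both groups must be non-empty and finite", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled) # midranks under ties
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  n_label <- choose(na + nb, na)
  if (n_label <= max_enumerate) {
    labelings <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[labelings], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    exact <- TRUE
  } else {
    n <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    zn <- abs(u_obs - mu)
    zn <- max(zn - 0.5, 0) # continuity correction
    p <- min(1, 2 * stats::pnorm(zn / sigma, lower.tail = FALSE))
    exact <- FALSE
  }
  structure(list(u = u_obs, p = p, exact = exact, n_a = na, n_b = nb),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, two-sided p = %.4g (%s; n = %d vs %d)\n",
              x$u, x$p, if (x$exact) "exact" else "normal approx.",
              x$n_a, x$n_b))
  invisible(x)
}

#' Effect size as a difference of group means with its SEM
#'
#' Returns `mean(group_b) - mean(group_a)` (reference group first, treatment
#' second, so an increased treatment value gives a positive effect) with the
#' unpooled quadrature SEM `sqrt(sd_a^2/n_a + sd_b^2/n_b)`.
#'
#' @param group_a Reference group (e.g. wild type).
#' @param group_b Treatment group.
#' @return List: `effect` and `sem`.
#' @export
#' @examples
#' effect_size(c(1, 2, 3), c(4, 5, 6)) # effect 3, sem ~0.816
effect_size <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need >= 2 observations for an SEM", call. = FALSE)
  }
  sem <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  list(effect = mean(b) - mean(a), sem = sem)
}
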