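#' Rate of change of force
#'
#' Finite-difference dF/dt computed directly from the sampled force with no
#' smoothing: central differences at interior samples, one-sided at the two
#' edges.
#'
#' @param stim A stimulus or response trace with `time_s` and `force_mN`.
#' @return A tibble with columns `time_s` and `rate_mN_s`.
#' @export
force_rate <- function(stim) {
  stim <- validate_stimulus(stim)
  u <- stim$force_mN
  tt <- stim$time_s
  n <- length(u)
  if (n < 3L) {
    abort("need at least 3 samples to differentiate",
          class = "campaniform_input_error")
  }
  r <- numeric(n)
  r[1] <- (u[2] - u[1]) / (tt[2] - tt[1])
  r[n] <- (u[n] - u[n - 1]) / (tt[n] - tt[n - 1])
  idx <- 2:(n - 1)
  r[idx] <- (u[idx + 1] - u[idx - 1]) / (tt[idx + 1] - tt[idx - 1])
  tibble(time_s = tt, rate_mN_s = r)
}

#' Segment a trace into rise, hold and fall epochs
#'
#' Rise epochs are maximal runs of samples with dF/dt above `rate_eps`,
#' fall epochs runs below `-rate_eps`; everything else is a hold. The
#' default `rate_eps` is 5% of the protocol's nominal ramp rate when the
#' trace carries one, otherwise 5% of the largest measured |dF/dt|.
#'
#' @param stim A stimulus or response trace.
#' @param rate_eps Rate threshold, mN/s (> 0), or `NULL` for the default.
#' @return A tibble with one row per epoch: `epoch` (rise/hold/fall),
#'   sample indices `start`/`end` (inclusive), `t_start`, `t_end`,
#'   `duration_s`.
#' @export
segment_epochs <- function(stim, rate_eps = NULL) {
  fr <- force_rate(stim)$rate_mN_s
  if (is.null(rate_eps)) {
    p <- attr(stim, "protocol")
    nominal <- max(c(p$rise_rate, p$fall_rate, p$rate), 0)
    if (nominal <= 0) nominal <- max(abs(fr))
    rate_eps <- 0.05 * nominal
  }
  if (!is.numeric(rate_eps) || rate_eps <= 0) {
    abort("`rate_eps` must be > 0", class = "campaniform_input_error")
  }
  lab <- ifelse(fr > rate_eps, "rise", ifelse(fr < -rate_eps, "fall", "hold"))
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tibble(epoch = runs$values,
         start = starts, end = ends,
         t_start = stim$time_s[starts], t_end = stim$time_s[ends],
         duration_s = stim$time_s[ends] - stim$time_s[starts])
}

# Rows of the epoch table matching a label; errors when absent.
epoch_rows <- function(epochs, label) {
  rows <- epochs[epochs$epoch == label, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort(paste0("no ", label, " epoch found"),
          class = "campaniform_metric_error")
  }
  rows
}

# The plateau: first hold epoch that directly follows a rise.
plateau_hold <- function(epochs) {
  idx <- which(epochs$epoch == "hold" &
                 dplyr::lag(epochs$epoch, default = "") == "rise")
  if (length(idx) == 0L) {
    abort("no hold epoch following a rise was found",
          class = "campaniform_metric_error")
  }
  epochs[idx[1L], , drop = FALSE]
}

#' Off-response discharge over the fall epoch
#'
#' Mean and peak discharge frequency over a fall (force-decrement) epoch,
#' optionally extended by a post-fall window to capture firing that
#' outlasts the ramp.
#'
#' @param resp A `cs_response`.
#' @param epochs Epoch table from [segment_epochs()] (computed on the same
#'   grid); if `NULL` it is derived from `resp`.
#' @param fall Which fall epoch to use (1 = first).
#' @param extend_s Post-fall extension window, s (default 0).
#' @return A one-row tibble with `mean_hz`, `peak_hz`, `duration_s`.
#' @export
off_response <- function(resp, epochs = NULL, fall = 1L, extend_s = 0) {
  if (is.null(epochs)) epochs <- segment_epochs(resp)
  falls <- epoch_rows(epochs, "fall")
  if (fall > nrow(falls)) {
    abort("requested fall epoch does not exist",
          class = "campaniform_metric_error")
  }
  row <- falls[fall, ]
  dt <- stim_dt(resp)
  end <- min(nrow(resp), row$end + round(extend_s / dt))
  y <- resp$rate_hz[row$start:end]
  if (length(y) == 0L) {
    abort("empty fall epoch", class = "campaniform_metric_error")
  }
  tibble(mean_hz = mean(y), peak_hz = max(y),
         duration_s = resp$time_s[end] - row$t_start)
}

#' Relative gain of discharge across offset levels
#'
#' Each firing frequency divided by the frequency at the minimal offset, so
#' the gain at the minimal offset is 1 and the result is invariant to
#' rescaling all frequencies.
#'
#' @param frequencies Firing frequencies, Hz.
#' @param offsets Offset loads, mN (aligned with `frequencies`).
#' @return A tibble with columns `offset_mN`, `frequency_hz`, `gain`.
#' @export
relative_gain <- function(frequencies, offsets) {
  if (length(frequencies) != length(offsets) || length(offsets) < 1L) {
    abort("`frequencies` and `offsets` must be non-empty and aligned",
          class = "campaniform_input_error")
  }
  ref <- frequencies[which.min(offsets)]
  if (ref == 0) {
    abort("frequency at the minimal offset is zero; gain undefined",
          class = "campaniform_metric_error")
  }
  tibble(offset_mN = as.numeric(offsets),
         frequency_hz = as.numeric(frequencies),
         gain = frequencies / ref)
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors (>= 3 points, `x` not constant).
#' @return A one-row tibble with `slope`, `intercept` and `r_squared`
#'   (squared Pearson correlation of observed vs fitted).
#' @export
slope_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("need at least 3 aligned points", class = "campaniform_input_error")
  }
  if (sd(x) == 0) {
    abort("`x` has no variance; slope undefined",
          class = "campaniform_metric_error")
  }
  fit <- lm(y ~ x)
  cc <- coef(fit)
  r2 <- if (sd(y) == 0) 0 else stats::cor(y, stats::fitted(fit))^2
  tibble(slope = unname(cc[2]), intercept = unname(cc[1]), r_squared = r2)
}

#' Threshold creep during the hold phase
#'
#' Change of the dynamic threshold across the plateau,
#' `x(end of hold) - x(start of hold)`: the model analog of mechanical
#' creep in the cuticle. Positive for loading holds in the signed input
#' frame (negative for the antagonist subgroup, whose input is negated).
#'
#' @param resp A `cs_response`.
#' @param epochs Epoch table from [segment_epochs()]; derived from `resp`
#'   when `NULL`.
#' @return The threshold change in mN (scalar).
#' @export
threshold_creep <- function(resp, epochs = NULL) {
  if (is.null(epochs)) epochs <- segment_epochs(resp)
  row <- plateau_hold(epochs)
  resp$threshold_mN[row$end] - resp$threshold_mN[row$start]
}

#' Per-trial epoch metrics
#'
#' Segments a trial and summarizes the discharge per epoch class, the
#' off-response, the measured ramp rates, and the threshold creep, as one
#' tidy row suitable for binding across trials.
#'
#' @param resp A `cs_response`.
#' @param rate_eps Passed to [segment_epochs()].
#' @param extend_s Passed to [off_response()].
#' @return A one-row tibble.
#' @export
epoch_metrics <- function(resp, rate_eps = NULL, extend_s = 0) {
  epochs <- segment_epochs(resp, rate_eps = rate_eps)
  fr <- force_rate(resp)$rate_mN_s
  p <- attr(resp, "protocol") %||% list()
  pars <- attr(resp, "params")

  epoch_stat <- function(label, f) {
    rows <- epochs[epochs$epoch == label, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_real_)
    idx <- unlist(purrr::map2(rows$start, rows$end, seq))
    f(resp$rate_hz[idx])
  }
  rise_rate_meas <- {
    rows <- epochs[epochs$epoch == "rise", , drop = FALSE]
    if (nrow(rows) == 0L) NA_real_ else {
      idx <- unlist(purrr::map2(rows$start, rows$end, seq))
      median(fr[idx])
    }
  }
  fall_rate_meas <- {
    rows <- epochs[epochs$epoch == "fall", , drop = FALSE]
    if (nrow(rows) == 0L) NA_real_ else {
      idx <- unlist(purrr::map2(rows$start, rows$end, seq))
      median(fr[idx])
    }
  }
  off <- tryCatch(off_response(resp, epochs, extend_s = extend_s),
                  campaniform_metric_error = function(e) {
                    tibble(mean_hz = NA_real_, peak_hz = NA_real_,
                           duration_s = NA_real_)
                  })
  dx <- tryCatch(threshold_creep(resp, epochs),
                 campaniform_metric_error = function(e) NA_real_)
  tibble(
    subgroup = if (is.null(pars)) NA_character_ else pars$subgroup,
    offset_mN = p$baseline %||% NA_real_,
    hold_s = p$hold_s %||% NA_real_,
    rise_mean_hz = epoch_stat("rise", mean),
    rise_peak_hz = epoch_stat("rise", max),
    hold_mean_hz = epoch_stat("hold", mean),
    off_mean_hz = off$mean_hz,
    off_peak_hz = off$peak_hz,
    dx_creep_mN = dx,
    rise_rate_mN_s = rise_rate_meas,
    fall_rate_mN_s = fall_rate_meas
  )
}

#' Rate-sensitivity curve from a rate-series battery
#'
#' For each response, pairs the measured ramp rate with the peak discharge
#' during the encoding epoch of its subgroup: rise for agonist receptors,
#' fall (absolute rate) for antagonist receptors. The emergent power law of
#' the model makes log(peak) vs log(rate) approximately linear.
#'
#' @param responses A list of `cs_response` objects from a rate series.
#' @return A tibble with columns `rate_mN_s` and `peak_hz`, one row per
#'   response.
#' @export
rate_sensitivity_curve <- function(responses) {
  if (inherits(responses, "cs_response")) responses <- list(responses)
  purrr::map_dfr(responses, function(resp) {
    pars <- attr(resp, "params")
    label <- if (!is.null(pars) && pars$subgroup == "antagonist") {
      "fall"
    } else {
      "rise"
    }
    epochs <- segment_epochs(resp)
    rows <- epoch_rows(epochs, label)
    idx <- unlist(purrr::map2(rows$start, rows$end, seq))
    fr <- force_rate(resp)$rate_mN_s
    tibble(rate_mN_s = abs(median(fr[idx])),
           peak_hz = max(resp$rate_hz[idx]))
  })
}
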