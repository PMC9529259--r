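#' Draw a spike train from a simulated rate profile
#'
#' Inhomogeneous Poisson realization of the response's rate profile by
#' thinning against the peak rate: homogeneous candidate events at the
#' peak rate are accepted with probability `rate(t)/peak`. A single seeded
#' RNG stream per train makes trains reproducible; an optional absolute
#' dead time can be imposed (default none).
#'
#' @param resp A `cs_response` (rates must be non-negative).
#' @param seed Integer seed for the train's RNG stream.
#' @param dead_time Minimum inter-spike interval, s (default 0).
#' @param unit_label Label for the unit; defaults to `"6B"` for agonist and
#'   `"6A"` for antagonist parameter sets.
#' @param amplitude_class Extracellular amplitude class (arbitrary units).
#' @return A tibble of class `cs_spikes` with columns `time_s`,
#'   `unit_label`, `amplitude_class`, sorted by time, carrying the seed
#'   and the stimulus span as attributes.
#' @export
poisson_spikes <- function(resp, seed, dead_time = 0, unit_label = NULL,
                           amplitude_class = 1) {
  if (any(resp$rate_hz < 0)) {
    abort("rates must be non-negative", class = "campaniform_input_error")
  }
  pars <- attr(resp, "params")
  if (is.null(unit_label)) {
    unit_label <- if (!is.null(pars) && pars$subgroup == "antagonist") {
      "6A"
    } else {
      "6B"
    }
  }
  span <- range(resp$time_s)
  ymax <- max(resp$rate_hz)
  times <- numeric(0)
  if (ymax > 0) {
    withr::local_seed(seed)
    t_cur <- span[1]
    cand <- numeric(0)
    # draw candidate arrivals in blocks until past the end of the span
    repeat {
      n_draw <- max(64L, ceiling(1.5 * ymax * (span[2] - t_cur)))
      gaps <- rexp(n_draw, rate = ymax)
      cand <- c(cand, t_cur + cumsum(gaps))
      t_cur <- cand[length(cand)]
      if (t_cur > span[2]) break
    }
    cand <- cand[cand <= span[2]]
    keep <- runif(length(cand)) <
      approx(resp$time_s, resp$rate_hz, xout = cand)$y / ymax
    times <- cand[keep]
    if (dead_time > 0 && length(times) > 1L) {
      kept <- times[1L]
      last <- times[1L]
      for (s in times[-1L]) {
        if (s - last >= dead_time) {
          kept <- c(kept, s)
          last <- s
        }
      }
      times <- kept
    }
  }
  out <- tibble(time_s = times,
                unit_label = rep(unit_label, length(times)),
                amplitude_class = rep(amplitude_class, length(times)))
  structure(out, seed = seed, span = span, dead_time = dead_time,
            class = c("cs_spikes", class(out)))
}

#' Reconstruct a rate series from spike times
#'
#' `"isi_reciprocal"` assigns the instantaneous frequency 1/ISI at each
#' spike after the first (the convention of extracellular analysis);
#' `"binned"` returns counts per bin divided by the bin width on a uniform
#' grid over the train's span.
#'
#' @param train A `cs_spikes` tibble (or any tibble with `time_s`).
#' @param method `"isi_reciprocal"` or `"binned"`.
#' @param bin Bin width in seconds (binned method).
#' @param span Time span `c(start, end)`; defaults to the train's recorded
#'   span, falling back to the range of spike times.
#' @return A tibble with columns `time_s` and `rate_hz`. With fewer than
#'   two spikes, `isi_reciprocal` returns an empty series with a warning.
#' @export
rate_from_spikes <- function(train, method = c("isi_reciprocal", "binned"),
                             bin = 0.05, span = NULL) {
  method <- match.arg(method)
  st <- sort(train$time_s)
  span <- span %||% attr(train, "span") %||%
    (if (length(st)) range(st) else c(0, 0))
  if (method == "isi_reciprocal") {
    if (length(st) < 2L) {
      warn("fewer than 2 spikes; returning empty rate series",
           class = "campaniform_spikes_warning")
      return(tibble(time_s = numeric(0), rate_hz = numeric(0)))
    }
    return(tibble(time_s = st[-1L], rate_hz = 1 / diff(st)))
  }
  if (!is.numeric(bin) || bin <= 0) {
    abort("`bin` must be > 0", class = "campaniform_input_error")
  }
  nb <- max(1L, ceiling((span[2] - span[1]) / bin - 1e-9))
  breaks <- span[1] + (0:nb) * bin
  counts <- tabulate(findInterval(st, breaks,
                                  rightmost.closed = TRUE), nbins = nb)
  tibble(time_s = head(breaks, -1L) + bin / 2, rate_hz = counts / bin)
}

#' Merge spike trains from several units
#'
#' Time-sorted merge that preserves per-spike unit labels and amplitude
#' classes, so the merge is losslessly reversible with [split_units()].
#'
#' @param trains A list of `cs_spikes` tibbles.
#' @return A single `cs_spikes` tibble sorted by `time_s`.
#' @export
merge_units <- function(trains) {
  if (inherits(trains, "cs_spikes")) trains <- list(trains)
  out <- dplyr::arrange(dplyr::bind_rows(trains), .data$time_s)
  spans <- purrr::map(trains, ~ attr(.x, "span"))
  spans <- spans[!purrr::map_lgl(spans, is.null)]
  span <- if (length(spans)) {
    c(min(purrr::map_dbl(spans, 1)), max(purrr::map_dbl(spans, 2)))
  } else if (nrow(out)) {
    range(out$time_s)
  } else {
    c(0, 0)
  }
  structure(out, span = span, class = c("cs_spikes", class(tibble())))
}

#' @rdname merge_units
#' @param train A merged `cs_spikes` tibble.
#' @return `split_units()` returns a named list of `cs_spikes`, one per
#'   unit label.
#' @export
split_units <- function(train) {
  span <- attr(train, "span")
  parts <- split(as_tibble(train), train$unit_label)
  purrr::map(parts, function(p) {
    structure(as_tibble(p), span = span,
              class = c("cs_spikes", class(tibble())))
  })
}
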