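# Trace and spike-train analysis: the quantities the simulations are
# ultimately reported in.

#' Uniformly sampled probe trace
#'
#' @param t Time samples (ms), strictly increasing and uniformly spaced.
#' @param value Values (mV).
#' @param probe Probe identifier.
#' @return A `trace`.
#' @export
trace <- function(t, value, probe = "") {
  stopifnot(length(t) == length(value), length(t) >= 1L)
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("trace time must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * max(dt)) stop("trace time must be uniformly spaced")
  }
  structure(list(t = as.numeric(t), value = as.numeric(value), probe = probe),
            class = "trace")
}

as_trace <- function(x, column = NULL, probe = column) {
  if (inherits(x, "trace")) return(x)
  if (inherits(x, "simulation_result")) x <- x$traces
  if (is.data.frame(x)) {
    stopifnot(!is.null(column))
    return(trace(x$t_ms, x[[column]], probe = probe %||% column))
  }
  stop("cannot interpret object as a trace")
}

#' Spike train of one cell
#'
#' @param times Spike times (ms), strictly increasing.
#' @param cell Cell id.
#' @return A `spike_train`.
#' @export
spike_train <- function(times, cell = 1L) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  structure(list(cell = as.integer(cell), times = times), class = "spike_train")
}

#' Detect spikes by upward threshold crossing
#'
#' A spike is recorded at the first sample at or above `threshold` of each
#' upward crossing, provided at least `refractory` ms have elapsed since
#' the previous spike. A plateau above threshold yields a single spike (no
#' re-trigger without re-crossing).
#'
#' @param x A [trace()] (or a `simulation_result` plus `column`).
#' @param threshold Threshold (mV), default -20.
#' @param refractory Minimum inter-spike interval (ms), default 2.
#' @param column Trace column when `x` is a simulation result.
#' @param cell Cell id recorded in the returned train.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(x, threshold = -20, refractory = 2, column = NULL,
                          cell = 1L) {
  tr <- as_trace(x, column)
  if (length(tr$t) == 0L) stop("empty trace")
  above <- tr$value >= threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  times <- numeric(0)
  last <- -Inf
  for (k in cross) {
    if (tr$t[k] - last >= refractory) {
      times <- c(times, tr$t[k])
      last <- tr$t[k]
    }
  }
  spike_train(times, cell = cell)
}

#' Count spikes in a half-open window
#'
#' @param train A [spike_train()].
#' @param window `c(t0, t1)`: spikes with `t0 <= t < t1` are counted.
#' @return Integer count.
#' @export
count_spikes <- function(train, window = c(0, Inf)) {
  stopifnot(inherits(train, "spike_train"), length(window) == 2L,
            window[1] <= window[2])
  sum(train$times >= window[1] & train$times < window[2])
}

#' Spike-timing offsets between two cells
#'
#' For each spike of train A, the signed offset (B - A, ms) to the nearest
#' spike of train B. Spikes of A whose nearest partner is further than half
#' the median inter-spike interval of A are considered unmatched and
#' dropped (their count is reported in the `dropped` attribute).
#'
#' @param trainA,trainB [spike_train()] objects (A non-empty).
#' @return `data.frame(t, offset_ms)` ordered by t, with attribute
#'   `dropped`.
#' @export
spike_offset_series <- function(trainA, trainB) {
  stopifnot(inherits(trainA, "spike_train"), inherits(trainB, "spike_train"))
  if (length(trainA$times) == 0L) stop("train A is empty")
  if (length(trainB$times) == 0L) {
    out <- data.frame(t = numeric(0), offset_ms = numeric(0))
    attr(out, "dropped") <- length(trainA$times)
    warning("train B has no spikes; all offsets dropped")
    return(out)
  }
  cutoff <- if (length(trainA$times) >= 2L) {
    stats::median(diff(trainA$times)) / 2
  } else {
    Inf
  }
  off <- vapply(trainA$times, function(ta) {
    d <- trainB$times - ta
    d[which.min(abs(d))]
  }, 0)
  keep <- abs(off) <= cutoff
  out <- data.frame(t = trainA$times[keep], offset_ms = off[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Time at which two spike trains are synchronized
#'
#' The earliest time from which the absolute spike-timing offset stays at
#' or below `tol` for at least `hold` consecutive spikes and never exceeds
#' it afterwards. A hold count is required because single-spike
#' coincidences occur transiently during slow phase drift.
#'
#' @param series Offset series from [spike_offset_series()].
#' @param tol Offset tolerance (ms).
#' @param hold Minimum number of consecutive within-tolerance spikes.
#' @return `list(reached, t_ms)`; `t_ms` is `NA` when not reached.
#' @export
synchronization_time <- function(series, tol, hold = 3L) {
  stopifnot(is.data.frame(series), tol > 0, hold >= 1L)
  n <- nrow(series)
  if (n == 0L) return(list(reached = FALSE, t_ms = NA_real_))
  ok <- abs(series$offset_ms) <= tol
  # last index from which everything stays within tolerance
  run_start <- NA_integer_
  for (i in n:1) {
    if (ok[i]) run_start <- i else break
  }
  if (is.na(run_start) || n - run_start + 1L < hold) {
    return(list(reached = FALSE, t_ms = NA_real_))
  }
  list(reached = TRUE, t_ms = series$t[run_start])
}

#' Peak-to-trough half-amplitude of an oscillating trace
#'
#' Linearly detrends the trace inside the analysis window and returns half
#' of max - min. The window should exclude the initial transient
#' (conventionally: drop the first full stimulus period).
#'
#' @param x A [trace()] (or simulation result plus `column`).
#' @param window `c(t0, t1)` analysis window (ms); default: everything
#'   after the first `period_ms`.
#' @param period_ms Stimulus period, used for the default window and to
#'   reject windows shorter than one period.
#' @param column Trace column when `x` is a simulation result.
#' @return Amplitude (mV).
#' @export
oscillation_amplitude <- function(x, window = NULL, period_ms = NULL,
                                  column = NULL) {
  tr <- as_trace(x, column)
  if (is.null(window)) {
    if (is.null(period_ms)) stop("give either a window or period_ms")
    window <- c(tr$t[1] + period_ms, tr$t[length(tr$t)])
  }
  if (!is.null(period_ms) && diff(window) < period_ms - 1e-9) {
    stop("analysis window is shorter than one stimulus period")
  }
  sel <- tr$t >= window[1] & tr$t <= window[2]
  if (sum(sel) < 3L) stop("analysis window contains too few samples")
  tt <- tr$t[sel]; vv <- tr$value[sel]
  if (!is.null(period_ms)) {
    # slope from period-averaged endpoints: averaging over one full period
    # cancels the oscillation, so a pure sinusoid is left untouched while a
    # linear drift is removed exactly
    first <- tt <= tt[1] + period_ms
    last <- tt >= tt[length(tt)] - period_ms
    sep <- mean(tt[last]) - mean(tt[first])
    # windows shorter than two periods cannot distinguish drift from the
    # oscillation itself; leave them undetrended
    slope <- if (sep > period_ms / 2) {
      (mean(vv[last]) - mean(vv[first])) / sep
    } else 0
    r <- vv - slope * tt
  } else {
    r <- stats::lm.fit(cbind(1, tt), vv)$residuals
  }
  (max(r) - min(r)) / 2
}

#' Open-loop extracellular potential from membrane currents
#'
#' The classical point-source reconstruction: each membrane facet acts as a
#' monopole in an infinite homogeneous medium,
#' \eqn{u_e(p, t) = \sum_f I_{m,f}(t) A_f / (4\pi\sigma_e |p - x_f|)},
#' with outward membrane current producing a positive nearby potential.
#'
#' @param Im Facet current densities (uA/cm^2): a matrix with one row per
#'   time sample and one column per facet (a vector is treated as one
#'   sample).
#' @param centroids_cm Facet centroids, one row per facet (cm).
#' @param areas_cm2 Facet areas (cm^2).
#' @param sigma_e Extracellular conductivity (mS/cm).
#' @param points_cm Probe points, one row each (cm).
#' @param t Time samples (ms) for the returned traces.
#' @return A list of [trace()] objects, one per probe point.
#' @export
mie_extracellular_potential <- function(Im, centroids_cm, areas_cm2, sigma_e,
                                        points_cm, t = NULL) {
  if (is.null(dim(Im))) Im <- matrix(Im, nrow = 1)
  if (is.null(dim(points_cm))) points_cm <- matrix(points_cm, nrow = 1)
  stopifnot(ncol(Im) == nrow(centroids_cm), ncol(Im) == length(areas_cm2))
  if (is.null(t)) t <- seq_len(nrow(Im)) - 1
  lapply(seq_len(nrow(points_cm)), function(k) {
    p <- points_cm[k, ]
    r <- sqrt(rowSums((centroids_cm - matrix(p, nrow(centroids_cm), 3,
                                             byrow = TRUE))^2))
    if (any(r == 0)) stop("probe point coincides with a facet centroid")
    w <- areas_cm2 / (4 * pi * sigma_e * r)
    trace(t, as.numeric(Im %*% w), probe = sprintf("p%d", k))
  })
}

#' Compare first-spike times: fully coupled EMI vs the open-loop workflow
#'
#' Runs the same electrode-driven problem twice per conductivity value:
#' fully coupled (`mode = "emi"`) and open loop (`mode = "mie"`, membrane
#' ODEs driven by the analytic electrode field only, no feedback), and
#' reports the first spike time of each together with their difference
#' (positive delay = the open-loop workflow fires later).
#'
#' @param problem An [emi_problem()] with an excitable model, an electrode
#'   stimulus and at least one `v` probe (the first `v` probe is used).
#' @param sigma_e_values Extracellular conductivities to test (mS/cm).
#' @param threshold,refractory Spike detection settings.
#' @param normalize_drive If `TRUE`, the electrode current is rescaled by
#'   `sigma_e / sigma_e_ref` (the problem's own conductivity) for each run,
#'   keeping the open-loop analytic drive identical across conductivities;
#'   the remaining variation of the delay then isolates the feedback term,
#'   whose magnitude scales as 1/sigma_e.
#' @return `data.frame(sigma_e, t_emi_ms, t_mie_ms, delay_ms, fired_emi,
#'   fired_mie)`.
#' @export
emi_mie_firing_delay <- function(problem, sigma_e_values, threshold = -20,
                                 refractory = 2, normalize_drive = FALSE) {
  stopifnot(inherits(problem, "emi_problem"))
  vprobe <- NULL
  for (pr in problem$probes) if (pr$kind == "v") { vprobe <- pr$name; break }
  if (is.null(vprobe)) stop("problem needs a membrane-potential probe")
  rows <- lapply(sigma_e_values, function(se) {
    pb <- problem
    pb$sigma <- conductivities(problem$sigma$sigma_i, se)
    if (normalize_drive) {
      pb$stimuli <- lapply(pb$stimuli, function(s) {
        if (inherits(s, "electrode_stimulus")) {
          s$Ie <- s$Ie * se / problem$sigma$sigma_e
        }
        s
      })
    }
    first <- function(mode) {
      res <- run_simulation(pb, mode = mode)
      st <- detect_spikes(res, column = vprobe, threshold = threshold,
                          refractory = refractory)
      if (length(st$times)) st$times[1] else NA_real_
    }
    t_emi <- first("emi"); t_mie <- first("mie")
    data.frame(sigma_e = se, t_emi_ms = t_emi, t_mie_ms = t_mie,
               delay_ms = t_mie - t_emi,
               fired_emi = !is.na(t_emi), fired_mie = !is.na(t_mie))
  })
  do.call(rbind, rows)
}
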