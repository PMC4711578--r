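#' Parameters of a single bursting olfactory receptor neuron (bORN)
#'
#' A bORN bursts spontaneously with a characteristic rhythm and, when an
#' odor arrives, bursts in response with a probability that grows with the
#' time `tau` since its last burst.  Two ingredients define each neuron:
#'
#' * the spontaneous inter-burst interval (IBI) distribution, parameterized
#'   by its mean and coefficient of variation (`family` `"gamma"` by
#'   default, `"lnorm"` as an alternative);
#' * the evoked-response sigmoid
#'   `evoked_max / (1 + exp(-evoked_slope * (tau - evoked_mid)))`.
#'
#' Their product — response probability times the probability of having gone
#' `tau` seconds without a spontaneous burst — is the neuron's time
#' entrainment tuning curve ([tuning_curve()]), peaked at the odor-arrival
#' period the neuron encodes best.
#'
#' @param ibi_mean Mean spontaneous inter-burst interval (s), > 0.
#' @param ibi_cv Coefficient of variation of the spontaneous IBI, > 0.
#' @param evoked_max Plateau of the evoked-response sigmoid, in (0, 1].
#' @param evoked_mid `tau` at half plateau (s).
#' @param evoked_slope Sigmoid steepness (1/s), > 0.
#' @param family IBI distribution family, `"gamma"` or `"lnorm"`.
#' @return An object of class `"born_params"`.
#' @export
born_params <- function(ibi_mean, ibi_cv = 0.3, evoked_max = 0.95,
                        evoked_mid = 0.4 * ibi_mean,
                        evoked_slope = 5 / evoked_mid,
                        family = c("gamma", "lnorm")) {
  family <- match.arg(family)
  stopifnot(ibi_mean > 0, ibi_cv > 0, evoked_max > 0, evoked_max <= 1,
            evoked_slope > 0)
  structure(list(ibi_mean = ibi_mean, ibi_cv = ibi_cv,
                 evoked_max = evoked_max, evoked_mid = evoked_mid,
                 evoked_slope = evoked_slope, family = family),
            class = "born_params")
}

#' @export
print.born_params <- function(x, ...) {
  cat(sprintf("born_params: IBI %s(mean %.3g s, cv %.3g); evoked sigmoid max %.3g, mid %.3g s, slope %.3g /s\n",
              x$family, x$ibi_mean, x$ibi_cv, x$evoked_max, x$evoked_mid,
              x$evoked_slope))
  invisible(x)
}

.ibi_shape_rate <- function(p) {
  shape <- 1 / p$ibi_cv^2
  list(shape = shape, rate = shape / p$ibi_mean)
}

.ibi_lnorm_pars <- function(p) {
  sdlog <- sqrt(log(1 + p$ibi_cv^2))
  list(meanlog = log(p$ibi_mean) - sdlog^2 / 2, sdlog = sdlog)
}

.draw_ibi <- function(n, p) {
  if (p$family == "gamma") {
    sr <- .ibi_shape_rate(p)
    stats::rgamma(n, shape = sr$shape, rate = sr$rate)
  } else {
    lp <- .ibi_lnorm_pars(p)
    stats::rlnorm(n, lp$meanlog, lp$sdlog)
  }
}

#' Evoked-response probability of a bORN
#'
#' Probability of bursting in response to an odor arriving `tau` seconds
#' after the neuron's last burst: a sigmoid rising from near 0 (refractory
#' immediately after a burst) to its plateau `evoked_max`.
#'
#' @param tau Time since last burst (s), >= 0; vectorized.
#' @param p A [born_params()].
#' @return Response probabilities in `[0, evoked_max]`.
#' @export
evoked_prob <- function(tau, p) {
  stopifnot(all(tau >= 0))
  p$evoked_max / (1 + exp(-p$evoked_slope * (tau - p$evoked_mid)))
}

#' Spontaneous survival probability of a bORN
#'
#' Probability that the neuron goes `tau` seconds without bursting
#' spontaneously: one minus the CDF of the spontaneous inter-burst interval.
#'
#' @inheritParams evoked_prob
#' @return Survival probabilities, non-increasing in `tau`,
#'   `survival_prob(0, p) = 1`.
#' @export
survival_prob <- function(tau, p) {
  stopifnot(all(tau >= 0))
  if (p$family == "gamma") {
    sr <- .ibi_shape_rate(p)
    stats::pgamma(tau, shape = sr$shape, rate = sr$rate, lower.tail = FALSE)
  } else {
    lp <- .ibi_lnorm_pars(p)
    stats::plnorm(tau, lp$meanlog, lp$sdlog, lower.tail = FALSE)
  }
}

#' Time entrainment tuning curve of a bORN
#'
#' Product of [evoked_prob()] and [survival_prob()]: the probability that
#' the neuron is both still waiting (no spontaneous burst yet) and willing
#' to respond when an odor arrives at phase `tau`.  Near zero at both
#' extremes, with an interior maximum at the odor period the neuron is tuned
#' to.
#'
#' @inheritParams evoked_prob
#' @return Tuning-curve values.
#' @export
tuning_curve <- function(tau, p) evoked_prob(tau, p) * survival_prob(tau, p)

#' Build a heterogeneous bORN population
#'
#' Draws `n` neurons whose intrinsic IBI means are log-uniform over
#' `period_range`, spanning sensitivity from sub-second to tens-of-seconds
#' odor arrival periods.  The evoked sigmoid of each neuron is drawn so that
#' its tuning-curve peak sits near its own IBI mean: midpoint
#' `0.4 * ibi_mean` up to a log-normal-ish jitter, slope `5 / mid`, plateau
#' uniform on `[0.85, 1]`; the IBI coefficient of variation is uniform on
#' `cv_range`.  Priors are deliberately broad — the encoding scheme requires
#' heterogeneity, not fine tuning.
#'
#' @param n Number of neurons, >= 1.
#' @param period_range IBI mean range (s), default `c(0.2, 20)`.
#' @param cv_range Range of the IBI coefficient of variation.
#' @param family IBI distribution family for every neuron.
#' @return A list of [born_params()] of length `n` (class
#'   `"born_population"`).
#' @export
make_population <- function(n = 210, period_range = c(0.2, 20),
                            cv_range = c(0.2, 0.45),
                            family = c("gamma", "lnorm")) {
  family <- match.arg(family)
  stopifnot(n >= 1, period_range[1] > 0, period_range[1] < period_range[2])
  means <- exp(stats::runif(n, log(period_range[1]), log(period_range[2])))
  cvs <- stats::runif(n, cv_range[1], cv_range[2])
  mids <- 0.4 * means * exp(stats::runif(n, -0.2, 0.2))
  maxs <- stats::runif(n, 0.85, 1)
  pop <- lapply(seq_len(n), function(i)
    born_params(ibi_mean = means[i], ibi_cv = cvs[i], evoked_max = maxs[i],
                evoked_mid = mids[i], evoked_slope = 5 / mids[i],
                family = family))
  class(pop) <- c("born_population", "list")
  pop
}

#' @export
print.born_population <- function(x, ...) {
  mm <- range(vapply(x, `[[`, numeric(1), "ibi_mean"))
  cat(sprintf("born_population: %d neurons, IBI means %.3g-%.3g s\n",
              length(x), mm[1], mm[2]))
  invisible(x)
}

#' Simulate a single bORN driven by odor arrivals
#'
#' Renewal process: spontaneous bursts follow IBIs drawn from the neuron's
#' IBI distribution; when an odor arrives at phase `tau` (time since last
#' burst), the neuron bursts immediately and resets its cycle with
#' probability [evoked_prob()]`(tau)`, otherwise it continues unperturbed.
#' The process is warmed up for `burn_in` seconds before time 0 so that the
#' phase at the start of the record is approximately stationary.
#'
#' @param p A [born_params()].
#' @param odor_times Sorted odor arrival times within `[0, duration]` (s).
#' @param duration Simulated span (s), > 0.
#' @param burn_in Warm-up time before 0 (s); default `10 * ibi_mean`.
#' @return Increasing burst times in `[0, duration]`, with attribute
#'   `"responded"`: logical, one entry per odor time.
#' @export
simulate_born <- function(p, odor_times = numeric(0), duration,
                          burn_in = 10 * p$ibi_mean) {
  stopifnot(duration > 0)
  if (is.unsorted(odor_times)) stop("odor_times must be sorted")
  if (length(odor_times) > 0 &&
      (odor_times[1] < 0 || odor_times[length(odor_times)] > duration))
    stop("odor_times must lie within [0, duration]")
  bursts <- numeric(0)
  responded <- logical(length(odor_times))
  last <- -burn_in
  next_spont <- last + .draw_ibi(1L, p)
  oi <- 1L
  record <- function(tb) if (tb >= 0) bursts[length(bursts) + 1L] <<- tb
  while (TRUE) {
    t_odor <- if (oi <= length(odor_times)) odor_times[oi] else Inf
    if (next_spont <= t_odor) {
      if (next_spont > duration) break
      last <- next_spont
      record(last)
      next_spont <- last + .draw_ibi(1L, p)
    } else {
      tau <- t_odor - last
      if (tau > 0 && stats::runif(1) < evoked_prob(tau, p)) {
        responded[oi] <- TRUE
        last <- t_odor
        record(last)
        next_spont <- last + .draw_ibi(1L, p)
      }
      oi <- oi + 1L
    }
  }
  attr(bursts, "responded") <- responded
  bursts
}

#' Simulate a bORN population sharing one odor-arrival sequence
#'
#' Independent per-neuron simulation with [simulate_born()].
#'
#' @param pop A [make_population()] result (list of [born_params()]).
#' @param odor_times Shared sorted odor times (s).
#' @param duration Simulated span (s).
#' @return A `"burst_raster"`: list with `bursts` (list of per-neuron burst
#'   time vectors), `odor_times`, `duration`, and the population `pop`.
#' @export
simulate_population <- function(pop, odor_times = numeric(0), duration) {
  bursts <- lapply(pop, simulate_born, odor_times = odor_times,
                   duration = duration)
  structure(list(bursts = bursts, odor_times = odor_times,
                 duration = duration, pop = pop), class = "burst_raster")
}

#' @export
print.burst_raster <- function(x, ...) {
  cat(sprintf("burst_raster: %d neurons over %.3g s, %d odor stimuli, %d bursts\n",
              length(x$bursts), x$duration, length(x$odor_times),
              sum(lengths(x$bursts))))
  invisible(x)
}

#' Population state (per-neuron time since last burst) at an instant
#'
#' For each neuron, `tau = t - (last burst at or before t)`.  Neurons that
#' have not burst by `t` are flagged invalid and excluded from likelihood
#' computations downstream.
#'
#' @param raster A [simulate_population()] result.
#' @param t Query time within the simulated span (s).
#' @return A `"population_state"`: list with `neurons` (the population),
#'   `tau` (per-neuron seconds, `NA` when invalid), `valid` (logical),
#'   `t_now`.
#' @export
state_at <- function(raster, t) {
  stopifnot(inherits(raster, "burst_raster"))
  if (t < 0 || t > raster$duration)
    stop("query time ", t, " outside the simulated span [0, ",
         raster$duration, "]")
  tau <- vapply(raster$bursts, function(b) {
    b <- b[b <= t]
    if (length(b) == 0) NA_real_ else t - b[length(b)]
  }, numeric(1))
  structure(list(neurons = raster$pop, tau = tau, valid = !is.na(tau),
                 t_now = t), class = "population_state")
}

#' Subset a population state
#'
#' Keeps neurons `idx` (used e.g. to compare decoders across nested
#' population sizes on a common simulation).
#'
#' @param state A [state_at()] result.
#' @param idx Integer indices of the neurons to keep.
#' @return A `"population_state"`.
#' @export
subset_state <- function(state, idx) {
  structure(list(neurons = state$neurons[idx], tau = state$tau[idx],
                 valid = state$valid[idx], t_now = state$t_now),
            class = "population_state")
}

# stationary expectation of the evoked probability over the phase
# distribution (backward recurrence density survival(tau)/ibi_mean)
.mean_evoked <- function(p, upper = NULL) {
  if (is.null(upper)) upper <- p$ibi_mean * (1 + 6 * p$ibi_cv)
  tt <- seq(0, upper, length.out = 200L)
  w <- survival_prob(tt, p) / p$ibi_mean
  sum(evoked_prob(tt, p) * w) * (tt[2] - tt[1])
}

#' Maximum-likelihood decode of time since the last odor encounter
#'
#' Reads the elapsed time since the last odor arrival out of a population
#' state.  Under the hypothesis that the odor arrived `t` seconds ago, each
#' valid neuron's observed phase `tau_i` follows a two-component mixture:
#'
#' * with weight `w_i(t) = E[evoked] * survival_i(t)` the neuron responded
#'   to that odor and has not burst since, so `tau_i` is concentrated near
#'   `t` (Gaussian kernel of bandwidth `kernel_bw`);
#' * with weight `1 - w_i(t)` the neuron is in its free-running regime and
#'   `tau_i` follows the stationary backward-recurrence-time density
#'   `survival_i(tau) / ibi_mean_i`.
#'
#' `E[evoked]` is the neuron's evoked probability averaged over its
#' stationary phase distribution (the decoder does not know the phase the
#' neuron had when the odor arrived).  The decoded time is the grid argmax
#' of the summed log likelihood; ties break toward the smaller `t`.
#'
#' @param state A [state_at()] result with at least one valid neuron.
#' @param t_grid Sorted candidate elapsed times (s), default 0-30 s at 0.1 s.
#' @param kernel_bw Response-kernel bandwidth (s), default 0.25.
#' @return An `"interval_decode"`: list with `t_hat` (s), `t_grid`,
#'   `loglik`, and `n_valid`.
#' @export
decode_elapsed_time <- function(state, t_grid = seq(0, 30, by = 0.1),
                                kernel_bw = 0.25) {
  stopifnot(inherits(state, "population_state"), length(t_grid) > 0,
            !is.unsorted(t_grid))
  keep <- which(state$valid)
  if (length(keep) == 0) stop("no valid neurons: nothing to decode from")
  neurons <- state$neurons[keep]
  tau <- state$tau[keep]
  ll <- numeric(length(t_grid))
  for (i in seq_along(neurons)) {
    p <- neurons[[i]]
    w <- .mean_evoked(p) * survival_prob(t_grid, p)
    g <- survival_prob(tau[i], p) / p$ibi_mean
    f <- w * stats::dnorm(tau[i] - t_grid, sd = kernel_bw) + (1 - w) * g
    ll <- ll + log(pmax(f, 1e-300))
  }
  t_hat <- t_grid[which.max(ll)]  # which.max returns the first (smallest t) tie
  structure(list(t_hat = t_hat, t_grid = t_grid, loglik = ll,
                 n_valid = length(keep)), class = "interval_decode")
}

#' @export
print.interval_decode <- function(x, ...) {
  cat(sprintf("interval_decode: t_hat = %.3g s (%d neurons, grid %.3g-%.3g s)\n",
              x$t_hat, x$n_valid, min(x$t_grid), max(x$t_grid)))
  invisible(x)
}

#' Winner-take-all decode of time since the last odor encounter
#'
#' Cheap decoder variant: the modal phase among valid neurons, estimated as
#' the midpoint of the tallest histogram bin (ties toward the smaller
#' phase).
#'
#' @param state A [state_at()] result.
#' @param bin_width Histogram bin width (s), default 0.5.
#' @return Modal elapsed time (s).
#' @export
winner_take_all <- function(state, bin_width = 0.5) {
  stopifnot(inherits(state, "population_state"))
  tau <- state$tau[state$valid]
  if (length(tau) == 0) stop("no valid neurons: nothing to decode from")
  if (diff(range(tau)) < .Machine$double.eps) return(tau[1])
  br <- seq(0, max(tau) + bin_width, by = bin_width)
  h <- graphics::hist(tau, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Export a burst raster and its decoder readout as CSV
#'
#' `write_raster_csv()` writes `neuron_id, burst_time_s` rows plus a
#' companion `<path>.odor.csv` with the stimulus times;
#' `write_decode_csv()` writes `t_grid_s, loglik, is_argmax`.
#'
#' @param raster A [simulate_population()] result.
#' @param decode An [decode_elapsed_time()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "burst_raster"))
  df <- data.frame(
    neuron_id = rep(seq_along(raster$bursts), lengths(raster$bursts)),
    burst_time_s = unlist(raster$bursts, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(odor_time_s = raster$odor_times),
                   paste0(path, ".odor.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
write_decode_csv <- function(decode, path) {
  stopifnot(inherits(decode, "interval_decode"))
  df <- data.frame(t_grid_s = decode$t_grid, loglik = decode$loglik,
                   is_argmax = decode$t_grid == decode$t_hat)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
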