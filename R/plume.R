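#' Parameters of the statistical plume model
#'
#' Container for the constants of the parametric intermittency model of a
#' turbulent odor plume.  The source sits at the origin, `+x` points
#' downstream (direction of flow) and `y` is the cross-stream coordinate;
#' all lengths are in cm, times in seconds, concentrations in percent of
#' source concentration.
#'
#' The model has two halves:
#'
#' * **Whiff timing.**  Times between threshold up-crossings at a fixed point
#'   are exponential with mean \eqn{\bar\Delta(x,0)=\Delta_0 e^{\lambda x}} on
#'   the centerline and \eqn{\bar\Delta(x,y)=a(x)e^{\eta(x)|y|}} off it, with
#'   \eqn{a(x) = g e^{hx} + n} and \eqn{\eta(x) = p x^q + n}.
#' * **Instantaneous concentration.**  Concentration at a point is Gamma
#'   distributed with mean \eqn{\bar C(x,0)=C_0 e^{-\beta x}} on the
#'   centerline and \eqn{\bar C(x,y)=c(x) e^{-y^2/\sigma(x)^2}} off it, with
#'   \eqn{c(x) = k e^{bx} + n} and \eqn{\sigma(x) = m x^d + n}.  The Gamma
#'   scale parameter follows the same functional form as the mean (fields
#'   `scale_k`, `scale_b`, `scale_m`, `scale_d`) and the shape parameter is
#'   mean divided by scale.
#'
#' `n` is optional zero-mean Gaussian evaluation noise with standard
#' deviation `noise_sd` (default 0, i.e. fully deterministic evaluations);
#' when enabled it perturbs \eqn{a(x)}, \eqn{\eta(x)}, \eqn{c(x)} and
#' \eqn{\sigma(x)} independently at every evaluation, mimicking fitting
#' error.  Perturbed quantities are clamped to stay positive.
#'
#' The numeric defaults are calibration choices (the model constants are fit
#' to flume data in the original study but not tabulated): over
#' x in 50--250 cm, y in 0--10 cm they give centerline mean intervals of
#' roughly 0.3--3 s growing to ~8 s at y = 10 cm, and mean concentrations of
#' roughly 2--10% of source.  Holders of site-wise summary statistics can
#' re-estimate every constant with [fit_plume_params()].
#'
#' @param delta0 Centerline mean inter-arrival interval at `x = 0` (s).
#' @param lam Downstream exponential growth rate of the mean interval (1/cm).
#' @param g,h Constants of `a(x) = g*exp(h*x)`; default to `delta0`, `lam` so
#'   the cross-stream law is continuous with the centerline law at `y = 0`.
#' @param p,q Constants of the cross-stream growth rate `eta(x) = p*x^q`
#'   (per cm); the default negative `q` makes the plume effectively wider
#'   (weaker cross-stream decay of whiff rate) far downstream.
#' @param c0 Centerline mean concentration at `x = 0` (% of source).
#' @param beta Downstream exponential decay rate of mean concentration (1/cm).
#' @param k,b Constants of `c(x) = k*exp(b*x)`; default to `c0`, `-beta`.
#' @param m,d Constants of the Gaussian cross-stream width
#'   `sigma(x) = m*x^d` (cm).
#' @param scale_k,scale_b,scale_m,scale_d Constants of the Gamma scale
#'   parameter, same functional form as the mean concentration.  Defaults
#'   give a constant Gamma shape of 0.8 everywhere (coefficient of variation
#'   ~1.1, i.e. strong intermittency).
#' @param noise_sd Standard deviation of the additive evaluation noise `n`
#'   (same units as the perturbed quantity); default 0.
#' @param detect_threshold Odor detection threshold (% of source).
#' @param flow_speed Mean advection speed (cm/s); informational.
#' @param source_xy Source position, cm pair.
#'
#' @return An object of class `"plume_params"` (a validated list).
#' @seealso [mean_interval()], [mean_concentration()], [sample_concentration()],
#'   [generate_site_series()], [fit_plume_params()]
#' @examples
#' pp <- plume_params()
#' mean_interval(150, 0, pp)
#' mean_concentration(c(50, 150, 250), 0, pp)
#' @export
plume_params <- function(delta0 = 0.15, lam = 0.012,
                         g = delta0, h = lam, p = 2.6, q = -0.5,
                         c0 = 15, beta = 0.008,
                         k = c0, b = -beta, m = 0.5, d = 0.6,
                         scale_k = k / 0.8, scale_b = b,
                         scale_m = m, scale_d = d,
                         noise_sd = 0,
                         detect_threshold = 2.55,
                         flow_speed = 4.6,
                         source_xy = c(0, 0)) {
  pp <- list(delta0 = delta0, lam = lam, g = g, h = h, p = p, q = q,
             c0 = c0, beta = beta, k = k, b = b, m = m, d = d,
             scale_k = scale_k, scale_b = scale_b,
             scale_m = scale_m, scale_d = scale_d,
             noise_sd = noise_sd, detect_threshold = detect_threshold,
             flow_speed = flow_speed, source_xy = as.numeric(source_xy))
  validate_plume_params(pp)
  class(pp) <- "plume_params"
  pp
}

validate_plume_params <- function(pp) {
  num1 <- function(f) is.numeric(pp[[f]]) && length(pp[[f]]) == 1L && is.finite(pp[[f]])
  for (f in setdiff(names(pp), "source_xy"))
    if (!num1(f)) stop("plume_params field '", f, "' must be a finite numeric scalar")
  if (pp$delta0 <= 0) stop("delta0 must be > 0")
  if (pp$lam < 0) stop("lam must be >= 0")
  if (pp$c0 <= 0) stop("c0 must be > 0")
  if (pp$beta < 0) stop("beta must be >= 0")
  if (pp$g <= 0) stop("g must be > 0 (a(x) > 0 over the domain)")
  if (pp$m <= 0) stop("m must be > 0 (sigma(x) > 0 over the domain)")
  if (pp$scale_k <= 0) stop("scale_k must be > 0")
  if (pp$detect_threshold <= 0) stop("detect_threshold must be > 0")
  if (pp$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(pp$source_xy) != 2L) stop("source_xy must be a length-2 cm pair")
  invisible(pp)
}

#' @export
print.plume_params <- function(x, ...) {
  cat("Statistical plume model parameters\n")
  cat(sprintf("  intervals : delta0 = %.4g s, lam = %.4g /cm; a(x) = %.4g*exp(%.4g x), eta(x) = %.4g*x^%.4g\n",
              x$delta0, x$lam, x$g, x$h, x$p, x$q))
  cat(sprintf("  conc      : C0 = %.4g%%, beta = %.4g /cm; c(x) = %.4g*exp(%.4g x), sigma(x) = %.4g*x^%.4g\n",
              x$c0, x$beta, x$k, x$b, x$m, x$d))
  cat(sprintf("  gamma scl : %.4g*exp(%.4g x), width %.4g*x^%.4g\n",
              x$scale_k, x$scale_b, x$scale_m, x$scale_d))
  cat(sprintf("  threshold = %.4g%%, flow = %.4g cm/s, noise_sd = %.4g\n",
              x$detect_threshold, x$flow_speed, x$noise_sd))
  invisible(x)
}

# additive evaluation noise, clamped positive
.jitter_pos <- function(v, sd) {
  if (sd > 0) v <- v + stats::rnorm(length(v), 0, sd)
  pmax(v, 1e-8)
}

.check_x_domain <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("the plume model is defined for downstream positions x > 0 only")
}

#' Mean interval between odor encounters at a point
#'
#' Mean of the exponential distribution of times between odor threshold
#' up-crossings at position `(x, y)`:
#' \eqn{\bar\Delta(x,0)=\Delta_0 e^{\lambda x}} on the centerline,
#' \eqn{\bar\Delta(x,y)=a(x)e^{\eta(x)|y|}} off it.  Symmetric in `±y`.
#' Deterministic when `noise_sd = 0`.
#'
#' @param x,y Position in cm (vectors recycled to common length); `x` must be
#'   strictly downstream of the source (`x > 0`).
#' @param params A [plume_params()] object.
#' @return Mean interval(s) in seconds.
#' @export
mean_interval <- function(x, y, params = plume_params()) {
  stopifnot(inherits(params, "plume_params"))
  .check_x_domain(x)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  a   <- .jitter_pos(params$g * exp(params$h * x), params$noise_sd)
  eta <- .jitter_pos(params$p * x ^ params$q, params$noise_sd)
  ifelse(y == 0, params$delta0 * exp(params$lam * x), a * exp(eta * abs(y)))
}

#' Mean instantaneous concentration at a point
#'
#' \eqn{\bar C(x,0)=C_0 e^{-\beta x}} on the centerline,
#' \eqn{\bar C(x,y)=c(x)e^{-y^2/\sigma(x)^2}} off it; monotone non-increasing
#' in `|y|`.  Deterministic when `noise_sd = 0`.
#'
#' @inheritParams mean_interval
#' @return Mean concentration(s), % of source.
#' @export
mean_concentration <- function(x, y, params = plume_params()) {
  stopifnot(inherits(params, "plume_params"))
  .check_x_domain(x)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  cx  <- .jitter_pos(params$k * exp(params$b * x), params$noise_sd)
  sig <- .jitter_pos(params$m * x ^ params$d, params$noise_sd)
  ifelse(y == 0, params$c0 * exp(-params$beta * x), cx * exp(-y^2 / sig^2))
}

#' Gamma scale parameter of instantaneous concentration at a point
#'
#' The scale parameter of the concentration Gamma distribution follows the
#' same functional form as the mean concentration; the shape parameter is
#' mean divided by scale.
#'
#' @inheritParams mean_interval
#' @return Gamma scale parameter(s), % of source.
#' @export
concentration_scale <- function(x, y, params = plume_params()) {
  stopifnot(inherits(params, "plume_params"))
  .check_x_domain(x)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  cx  <- .jitter_pos(params$scale_k * exp(params$scale_b * x), params$noise_sd)
  sig <- .jitter_pos(params$scale_m * x ^ params$scale_d, params$noise_sd)
  ifelse(y == 0, params$scale_k * exp(params$scale_b * x), cx * exp(-y^2 / sig^2))
}

#' Draw instantaneous concentrations at a point
#'
#' Samples from the site Gamma distribution: scale from
#' [concentration_scale()], shape = [mean_concentration()] / scale, so the
#' draws have the site mean by construction.  Uses the current R random
#' number stream (seed with [set.seed()] for reproducibility).
#'
#' @inheritParams mean_interval
#' @param x,y Position in cm (scalars).
#' @param n Number of draws.
#' @return `n` concentration draws, % of source.
#' @export
sample_concentration <- function(x, y, params = plume_params(), n = 1) {
  mu <- mean_concentration(x, y, params)
  sc <- concentration_scale(x, y, params)
  shape <- mu / sc
  if (any(shape <= 0) || any(sc <= 0))
    stop("non-positive Gamma shape or scale; check plume parameterization")
  stats::rgamma(n, shape = shape, scale = sc)
}

# peak amplitude of a rendered whiff: site Gamma conditioned on exceeding the
# detection threshold (encounters are threshold up-crossings by definition)
.sample_whiff_peak <- function(n, x, y, params) {
  mu <- mean_concentration(x, y, params)
  sc <- concentration_scale(x, y, params)
  shape <- mu / sc
  lo <- stats::pgamma(params$detect_threshold, shape = shape, scale = sc)
  lo <- pmin(lo, 1 - 1e-12)
  stats::qgamma(stats::runif(n, lo, 1), shape = shape, scale = sc)
}

#' Draw odor encounter (threshold up-crossing) times at a point
#'
#' Homogeneous renewal process with exponential gaps of mean
#' [mean_interval()]`(x, y)`, truncated to `[0, duration]`.  May be empty.
#'
#' @inheritParams sample_concentration
#' @param duration Observation window (s), > 0.
#' @return Increasing vector of encounter times in seconds (possibly empty).
#' @export
sample_encounter_times <- function(x, y, duration, params = plume_params()) {
  stopifnot(duration > 0)
  mu <- mean_interval(x, y, params)
  times <- numeric(0)
  t_last <- 0
  repeat {
    n_chunk <- max(16L, ceiling((duration - t_last) / mu * 1.5))
    gaps <- stats::rexp(n_chunk, rate = 1 / mu)
    new <- t_last + cumsum(gaps)
    times <- c(times, new)
    t_last <- times[length(times)]
    if (t_last > duration) break
  }
  times[times <= duration]
}

#' Synthesize a concentration time series at a fixed point
#'
#' Renders the renewal encounter process of [sample_encounter_times()] as a
#' whiff/blank concentration series: each encounter becomes a whiff of
#' configurable width whose peak amplitude is drawn from the site Gamma
#' distribution conditioned on exceeding the detection threshold (an
#' encounter is a threshold up-crossing), on a sub-threshold baseline.
#' Overlapping whiffs merge by taking the pointwise maximum.
#'
#' The default triangular whiff (linear rise to the peak at the whiff
#' midpoint, then linear fall) makes the series pass continuously through
#' near-threshold values on every whiff edge, which is what the
#' recurrence-time statistics of [recurrence_times()] probe;
#' `shape = "rect"` gives instantaneous edges instead.
#'
#' @inheritParams sample_encounter_times
#' @param duration Series duration (s); default matches a 1025-frame video
#'   at 60 frames/s.
#' @param dt Sampling interval (s), default 1/60.
#' @param whiff_width Whiff duration (s), default 0.2.
#' @param whiff_shape `"triangle"` (default) or `"rect"`.
#' @param baseline Baseline concentration between whiffs (% of source); must
#'   be below the detection threshold.
#' @return A `"site_series"` object: list with fields `x`, `y`, `values`
#'   (% of source), `dt`, and the underlying `encounter_times`.
#' @export
generate_site_series <- function(x, y, duration = 1025 / 60, dt = 1 / 60,
                                 params = plume_params(),
                                 whiff_width = 0.2,
                                 whiff_shape = c("triangle", "rect"),
                                 baseline = 0.5) {
  whiff_shape <- match.arg(whiff_shape)
  stopifnot(duration >= dt, dt > 0, whiff_width > 0)
  if (baseline >= params$detect_threshold)
    stop("baseline must lie below the detection threshold")
  nt <- floor(duration / dt) + 1L
  tt <- (seq_len(nt) - 1L) * dt
  values <- rep(baseline, nt)
  enc <- sample_encounter_times(x, y, duration, params)
  if (length(enc) > 0) {
    peaks <- .sample_whiff_peak(length(enc), x, y, params)
    half <- whiff_width / 2
    for (i in seq_along(enc)) {
      i0 <- max(1L, ceiling(enc[i] / dt) + 1L)
      i1 <- min(nt, floor((enc[i] + whiff_width) / dt) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      env <- if (whiff_shape == "rect") rep(peaks[i], length(idx))
             else peaks[i] * (1 - abs(tt[idx] - (enc[i] + half)) / half)
      values[idx] <- pmax(values[idx], env)
    }
  }
  site_series(x = x, y = y, values = values, dt = dt, encounter_times = enc)
}

#' Concentration time series at a fixed plume location
#'
#' @param x,y Site position in cm (may be `NA` for series of unknown
#'   provenance, e.g. read from a file).
#' @param values Concentration samples, % of source; finite and non-negative.
#' @param dt Sampling interval (s), default 1/60.
#' @param encounter_times Optional vector of known encounter times (s).
#' @param label Optional site label.
#' @return An object of class `"site_series"`.
#' @export
site_series <- function(x = NA_real_, y = NA_real_, values, dt = 1 / 60,
                        encounter_times = NULL, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a site series needs at least 2 samples")
  if (any(!is.finite(values)) || any(values < 0))
    stop("site series values must be finite and >= 0")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  structure(list(x = x, y = y, values = values, dt = dt,
                 encounter_times = encounter_times, label = label),
            class = "site_series")
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("site_series at (x = %s, y = %s) cm: %d samples, dt = %.5g s (%.3g s)\n",
              format(x$x), format(x$y), length(x$values), x$dt,
              (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' Write a site series to CSV
#'
#' Columns `t_seconds`, `concentration_pct`.
#'
#' @param series A [site_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_series_csv <- function(series, path) {
  stopifnot(inherits(series, "site_series"))
  df <- data.frame(t_seconds = (seq_along(series$values) - 1L) * series$dt,
                   concentration_pct = series$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit plume-model constants from site-wise summary statistics
#'
#' Least squares on log-transformed means, mirroring how the model constants
#' are estimated from a measurement grid: the centerline laws by linear
#' regression of log-mean on `x`; the cross-stream laws by per-`x` regression
#' of log mean interval on `|y|` (giving `a(x)`, `eta(x)`) or of log mean
#' concentration on `y^2` (giving `c(x)`, `sigma(x)`), followed by
#' log-linear / log-log fits of those profiles in `x`.
#'
#' @param stats A data frame with columns `x`, `y` (cm) and at least one of
#'   `interval_mean` (s) and `conc_mean` (% source).  A grid with several
#'   `x` values, each with `y = 0` plus at least two `|y| > 0` levels, is
#'   required for the cross-stream fits (e.g. the 45-point grid of 15 sites
#'   by 3 downstream offsets).
#' @param params Baseline [plume_params()] supplying every constant not
#'   estimable from `stats`.
#' @return A [plume_params()] object with the fitted constants substituted.
#' @export
fit_plume_params <- function(stats, params = plume_params()) {
  stopifnot(is.data.frame(stats), all(c("x", "y") %in% names(stats)))
  pp <- unclass(params)

  fit_cross <- function(value, ylaw) {
    # per-x cross-stream regressions, then profile fits in x
    xs <- sort(unique(stats$x))
    prof <- lapply(xs, function(xi) {
      di <- stats[stats$x == xi & !is.na(stats[[value]]), ]
      if (sum(abs(di$y) > 0) < 2L) return(NULL)
      if (ylaw == "exp_absy") {
        f <- stats::lm(log(di[[value]]) ~ I(abs(di$y)))
        c(level = exp(stats::coef(f)[[1]]), rate = stats::coef(f)[[2]])
      } else { # gaussian in y
        f <- stats::lm(log(di[[value]]) ~ I(di$y^2))
        sl <- stats::coef(f)[[2]]
        if (sl >= 0) return(NULL)
        c(level = exp(stats::coef(f)[[1]]), rate = sqrt(-1 / sl))
      }
    })
    keep <- !vapply(prof, is.null, logical(1))
    if (sum(keep) < 2L) return(NULL)
    prof <- do.call(rbind, prof[keep])
    list(x = xs[keep], level = prof[, "level"], rate = prof[, "rate"])
  }

  if ("interval_mean" %in% names(stats)) {
    ctr <- stats[stats$y == 0 & !is.na(stats$interval_mean), ]
    if (nrow(ctr) >= 2L) {
      f <- stats::lm(log(interval_mean) ~ x, data = ctr)
      pp$delta0 <- exp(stats::coef(f)[[1]]); pp$lam <- stats::coef(f)[[2]]
    }
    cr <- fit_cross("interval_mean", "exp_absy")
    if (!is.null(cr)) {
      fa <- stats::lm(log(cr$level) ~ cr$x)
      pp$g <- exp(stats::coef(fa)[[1]]); pp$h <- stats::coef(fa)[[2]]
      fe <- stats::lm(log(cr$rate) ~ log(cr$x))
      pp$p <- exp(stats::coef(fe)[[1]]); pp$q <- stats::coef(fe)[[2]]
    }
  }
  if ("conc_mean" %in% names(stats)) {
    ctr <- stats[stats$y == 0 & !is.na(stats$conc_mean), ]
    if (nrow(ctr) >= 2L) {
      f <- stats::lm(log(conc_mean) ~ x, data = ctr)
      pp$c0 <- exp(stats::coef(f)[[1]]); pp$beta <- -stats::coef(f)[[2]]
    }
    cr <- fit_cross("conc_mean", "gaussian")
    if (!is.null(cr)) {
      fc <- stats::lm(log(cr$level) ~ cr$x)
      pp$k <- exp(stats::coef(fc)[[1]]); pp$b <- stats::coef(fc)[[2]]
      fs <- stats::lm(log(cr$rate) ~ log(cr$x))
      pp$m <- exp(stats::coef(fs)[[1]]); pp$d <- stats::coef(fs)[[2]]
    }
    pp$scale_k <- pp$k / 0.8; pp$scale_b <- pp$b
    pp$scale_m <- pp$m; pp$scale_d <- pp$d
  }
  do.call(plume_params, pp[setdiff(names(pp), character(0))])
}

#' Read / write plume parameters as a flat key-value config file
#'
#' YAML with keys named exactly as the [plume_params()] fields; unknown keys
#' raise an error naming the key, absent keys take their defaults.
#'
#' @param path Config file path.
#' @param params A [plume_params()] object (for writing).
#' @return `read_plume_config()` returns a [plume_params()];
#'   `write_plume_config()` returns `path` invisibly.
#' @export
read_plume_config <- function(path) {
  if (!file.exists(path)) stop("cannot read plume config: ", path)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(plume_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown plume config key(s): ", paste(bad, collapse = ", "))
  do.call(plume_params, cfg)
}

#' @rdname read_plume_config
#' @export
write_plume_config <- function(params, path) {
  stopifnot(inherits(params, "plume_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
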