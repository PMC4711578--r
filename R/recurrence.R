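#' Embedding / recurrence configuration
#'
#' Settings for delay embedding and recurrence-neighborhood analysis of
#' concentration time series.
#'
#' @param dim Embedding dimension (>= 1), default 10.
#' @param delay Embedding delay in samples (>= 1), or `NULL` to choose it per
#'   series with [choose_delay()].
#' @param r Neighborhood radius, same units as the series (default 0.33,
#'   i.e. % of source concentration).
#' @param reference Reference concentration used to pick the neighborhood
#'   center: the trajectory point whose first coordinate is closest to this
#'   value (default 2.55, the detection threshold).  May also be a full
#'   state vector of length `dim`.
#' @param strict Use the strict inequality `distance < r` (Heaviside with
#'   `H(0) = 0`); set `FALSE` for `<=`.
#' @param min_separation Sojourn clustering window (s) for the second-type
#'   recurrence time: neighborhood visits closer than this are treated as
#'   one return.  `0` (default) reduces to the consecutive-sample rule; a
#'   value on the order of a neural refractory period (~0.3 s) treats a
#'   whole whiff as one odor encounter.
#' @return An object of class `"embed_config"`.
#' @export
embed_config <- function(dim = 10, delay = 1, r = 0.33,
                         reference = 2.55, strict = TRUE,
                         min_separation = 0) {
  stopifnot(dim >= 1, is.null(delay) || delay >= 1, r > 0, min_separation >= 0)
  structure(list(dim = as.integer(dim),
                 delay = if (is.null(delay)) NULL else as.integer(delay),
                 r = r, reference = reference, strict = isTRUE(strict),
                 min_separation = min_separation),
            class = "embed_config")
}

#' Choose an embedding delay for a series
#'
#' First local minimum of the (binned) auto mutual information over lags
#' `1..max_lag`; falls back to the first zero crossing of the
#' autocorrelation, then to 1.
#'
#' @param series A [site_series()] or numeric vector.
#' @param max_lag Largest lag considered (samples).
#' @param bins Number of amplitude bins for the mutual-information estimate.
#' @return A delay in samples (integer >= 1).
#' @export
choose_delay <- function(series, max_lag = 60, bins = 16) {
  s <- if (inherits(series, "site_series")) series$values else as.numeric(series)
  max_lag <- min(max_lag, length(s) - 2L)
  if (max_lag < 1L) return(1L)
  br <- seq(min(s), max(s), length.out = bins + 1L)
  br[1] <- br[1] - 1e-9; br[bins + 1L] <- br[bins + 1L] + 1e-9
  disc <- cut(s, br, labels = FALSE)
  ami <- vapply(seq_len(max_lag), function(lag) {
    a <- disc[seq_len(length(disc) - lag)]
    b <- disc[(lag + 1L):length(disc)]
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  }, numeric(1))
  for (lag in seq_len(max_lag - 1L))
    if (ami[lag + 1L] > ami[lag]) return(lag)
  ac <- stats::acf(s, lag.max = max_lag, plot = FALSE)$acf[-1]
  zc <- which(ac <= 0)
  if (length(zc) > 0) return(as.integer(zc[1]))
  1L
}

#' Takens delay embedding of a scalar series
#'
#' Builds the trajectory matrix whose row `i` is
#' `(s_i, s_{i+delay}, ..., s_{i+(dim-1)*delay})`, reconstructing the state
#' space of the underlying dynamics from the scalar record.
#'
#' @param series A [site_series()] or numeric vector.
#' @param cfg An [embed_config()]; `cfg$delay = NULL` selects the delay with
#'   [choose_delay()].
#' @return An `"embedded_trajectory"`: list with `points`
#'   (`N x dim` matrix, `N = length(series) - (dim - 1) * delay`), `dt`,
#'   `dim`, `delay`.
#' @export
delay_embed <- function(series, cfg = embed_config()) {
  s <- if (inherits(series, "site_series")) series$values else as.numeric(series)
  dt <- if (inherits(series, "site_series")) series$dt else 1
  delay <- if (is.null(cfg$delay)) choose_delay(s) else cfg$delay
  n_pts <- length(s) - (cfg$dim - 1L) * delay
  if (n_pts < 1L)
    stop("series too short to embed: need length > (dim - 1) * delay = ",
         (cfg$dim - 1L) * delay)
  pts <- vapply(seq_len(cfg$dim) - 1L,
                function(j) s[(1L + j * delay):(n_pts + j * delay)],
                numeric(n_pts))
  if (n_pts == 1L) pts <- matrix(pts, nrow = 1L)
  structure(list(points = pts, dt = dt, dim = cfg$dim, delay = delay),
            class = "embedded_trajectory")
}

#' @export
print.embedded_trajectory <- function(x, ...) {
  cat(sprintf("embedded_trajectory: %d points in %d-D (delay %d, dt %.5g s)\n",
              nrow(x$points), x$dim, x$delay, x$dt))
  invisible(x)
}

#' Recurrence matrix of an embedded trajectory
#'
#' `R(i, j) = H(r - ||x_i - x_j||)` with `H` the Heaviside step function:
#' `TRUE` where the Euclidean distance between states `i` and `j` is below
#' the neighborhood radius `r`.  Symmetric with a `TRUE` main diagonal.
#'
#' @param traj An [delay_embed()] result (or a numeric matrix of states).
#' @param r Neighborhood radius, > 0.
#' @param strict Strict inequality (`H(0) = 0`), default `TRUE`.
#' @return An `N x N` logical matrix.
#' @export
recurrence_matrix <- function(traj, r, strict = TRUE) {
  stopifnot(r > 0)
  pts <- if (inherits(traj, "embedded_trajectory")) traj$points else as.matrix(traj)
  dmat <- unname(as.matrix(stats::dist(pts)))
  if (strict) dmat < r else dmat <= r
}

# squared distances from every trajectory point to a single state x0
.dist_to_ref <- function(pts, x0) {
  if (length(x0) == 1L && ncol(pts) > 1L)
    stop("reference state must have length equal to the embedding dimension")
  sqrt(colSums((t(pts) - x0)^2))
}

# resolve an embed_config reference into a concrete observed state; a scalar
# reference (a concentration) picks the observed state closest to it in the
# first coordinate, but only if that state actually comes within r of the
# reference level -- a series that never approaches the reference
# concentration has no recurrences at it (NULL, to be flagged by the caller)
.resolve_reference <- function(pts, reference, r = Inf) {
  if (length(reference) == ncol(pts)) return(as.numeric(reference))
  if (length(reference) != 1L)
    stop("reference must be a scalar concentration or a full state vector")
  i <- which.min(abs(pts[, 1] - reference))
  if (abs(pts[i, 1] - reference) >= r) return(NULL)
  pts[i, ]
}

#' Indices of trajectory points inside a reference neighborhood
#'
#' The ordered index set of points within distance `r` of the
#' reference state `x0` (strict inequality by default, matching the
#' Heaviside convention of [recurrence_matrix()]).
#'
#' @inheritParams recurrence_matrix
#' @param x0 Reference state: numeric vector of length `dim`.
#' @return Strictly increasing integer indices (1-based; possibly empty).
#' @export
neighbor_times <- function(traj, x0, r, strict = TRUE) {
  stopifnot(r > 0)
  pts <- if (inherits(traj, "embedded_trajectory")) traj$points else as.matrix(traj)
  d <- .dist_to_ref(pts, x0)
  which(if (strict) d < r else d <= r)
}

#' Recurrence times of the first and second type
#'
#' Visits of the trajectory to the `r`-neighborhood of a reference state
#' `x0` define the index set `S1`.  Recurrence times of the first type
#' (`T1`) are the differences between successive visit times.  Removing
#' sojourn points — points whose immediate predecessor is also in the
#' neighborhood, i.e. keeping only the first index of each maximal run of
#' consecutive indices — leaves the returning points `S2`; differences of
#' their times are the recurrence times of the second type (`T2`).  `T1`
#' counts every revisit, however brief; `T2` counts only genuine returns
#' after the trajectory has left the neighborhood, the analogue of a
#' sensor with a refractory period.
#'
#' @inheritParams neighbor_times
#' @param dt Seconds per trajectory step (default: taken from `traj`).
#' @param min_separation Cluster window in seconds for the returning-point
#'   set: a neighbor within `min_separation` of the previous neighbor is a
#'   sojourn point.  `0` (default) means the consecutive-sample rule (only
#'   immediately adjacent samples are sojourns); a positive value emulates a
#'   sensor whose refractory period merges visits in short succession.
#' @return A `"recurrence_times"` object: lists `t1_intervals`,
#'   `t2_intervals` (seconds), means `t1_mean`, `t2_mean` (`NA` when fewer
#'   than two neighbors / returning points exist), counts `n_neighbors`,
#'   `n_returning`, and the index sets `s1`, `s2`.
#' @examples
#' tr <- delay_embed(site_series(values = c(0, 1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 1),
#'                               dt = 1),
#'                   embed_config(dim = 1, delay = 1))
#' recurrence_times(tr, x0 = 1, r = 0.5)
#' @export
recurrence_times <- function(traj, x0, r, dt = NULL, strict = TRUE,
                             min_separation = 0) {
  if (is.null(dt))
    dt <- if (inherits(traj, "embedded_trajectory")) traj$dt else 1
  s1 <- neighbor_times(traj, x0, r, strict = strict)
  t1 <- if (length(s1) >= 2L) diff(s1) * dt else numeric(0)
  gap <- max(1L, ceiling(min_separation / dt))
  s2 <- if (length(s1) > 0L) s1[c(TRUE, diff(s1) > gap)] else integer(0)
  t2 <- if (length(s2) >= 2L) diff(s2) * dt else numeric(0)
  structure(list(
    t1_intervals = t1, t2_intervals = t2,
    t1_mean = if (length(t1) > 0) mean(t1) else NA_real_,
    t2_mean = if (length(t2) > 0) mean(t2) else NA_real_,
    n_neighbors = length(s1), n_returning = length(s2),
    s1 = s1, s2 = s2, dt = dt), class = "recurrence_times")
}

#' @export
print.recurrence_times <- function(x, ...) {
  cat(sprintf("recurrence_times: %d neighbors (%d returning); T1_mean = %s s, T2_mean = %s s\n",
              x$n_neighbors, x$n_returning,
              format(x$t1_mean, digits = 4), format(x$t2_mean, digits = 4)))
  invisible(x)
}

#' Detect threshold up-crossings in a concentration series
#'
#' Times `t_i` at which the series transitions from below the threshold to
#' at-or-above it (`s(t_i - dt) < threshold <= s(t_i)`).  A series that
#' starts above threshold does not count its first sample as a crossing.
#'
#' @param series A [site_series()] or numeric vector.
#' @param threshold Detection threshold, > 0.
#' @param dt Seconds per sample (taken from `series` when available).
#' @return Vector of up-crossing times in seconds (time of the first sample
#'   at or above threshold, with the first sample at time 0).
#' @export
detect_upcrossings <- function(series, threshold = 2.55, dt = NULL) {
  stopifnot(threshold > 0)
  s <- if (inherits(series, "site_series")) series$values else as.numeric(series)
  if (is.null(dt)) dt <- if (inherits(series, "site_series")) series$dt else 1
  if (length(s) < 2L) return(numeric(0))
  up <- which(s[-1] >= threshold & s[-length(s)] < threshold)
  up * dt
}

#' Per-site recurrence-time profile across replicate series
#'
#' For each site (unique `(x, y)`), embeds every replicate series, centers
#' the neighborhood on the observed state closest to the reference
#' concentration, computes [recurrence_times()], and aggregates the
#' replicate means.  With `pool = "replicates"` the mean and standard
#' deviation are taken across per-replicate means (one recording = one
#' estimate); `pool = "intervals"` pools all intervals of a site before
#' averaging.
#'
#' @param series_list A list of [site_series()] (replicates of the same site
#'   share their `(x, y)`).
#' @param cfg An [embed_config()].
#' @param pool `"replicates"` (default) or `"intervals"`.
#' @return A data frame with one row per site: `site_x_cm`, `site_y_cm`,
#'   `t1_mean_s`, `t1_sd_s`, `t2_mean_s`, `t2_sd_s`, `n_neighbors`,
#'   `n_returning`, `n_rep`, `n_valid_t1`, `n_valid_t2`.  Sites where no
#'   replicate yields a defined statistic keep `NA` means (flagged by the
#'   `n_valid_*` counts), they are never dropped silently.
#' @export
site_profile <- function(series_list, cfg = embed_config(),
                         pool = c("replicates", "intervals")) {
  pool <- match.arg(pool)
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, logical(1), "site_series")))
  key <- vapply(series_list, function(s) paste(s$x, s$y), character(1))
  out <- lapply(unique(key), function(k) {
    reps <- series_list[key == k]
    rt <- lapply(reps, function(s) {
      tr <- delay_embed(s, cfg)
      x0 <- .resolve_reference(tr$points, cfg$reference, cfg$r)
      if (is.null(x0))  # series never approaches the reference concentration
        return(recurrence_times(matrix(Inf, 1, tr$dim), rep(0, tr$dim),
                                cfg$r, dt = tr$dt))
      recurrence_times(tr, x0, cfg$r, strict = cfg$strict,
                       min_separation = cfg$min_separation)
    })
    t1m <- vapply(rt, `[[`, numeric(1), "t1_mean")
    t2m <- vapply(rt, `[[`, numeric(1), "t2_mean")
    if (pool == "intervals") {
      allt1 <- unlist(lapply(rt, `[[`, "t1_intervals"))
      allt2 <- unlist(lapply(rt, `[[`, "t2_intervals"))
      t1_mean <- if (length(allt1)) mean(allt1) else NA_real_
      t2_mean <- if (length(allt2)) mean(allt2) else NA_real_
      t1_sd <- if (length(allt1) > 1) stats::sd(allt1) else 0
      t2_sd <- if (length(allt2) > 1) stats::sd(allt2) else 0
    } else {
      t1_mean <- if (any(!is.na(t1m))) mean(t1m, na.rm = TRUE) else NA_real_
      t2_mean <- if (any(!is.na(t2m))) mean(t2m, na.rm = TRUE) else NA_real_
      t1_sd <- if (sum(!is.na(t1m)) > 1) stats::sd(t1m, na.rm = TRUE) else 0
      t2_sd <- if (sum(!is.na(t2m)) > 1) stats::sd(t2m, na.rm = TRUE) else 0
    }
    data.frame(site_x_cm = reps[[1]]$x, site_y_cm = reps[[1]]$y,
               t1_mean_s = t1_mean, t1_sd_s = t1_sd,
               t2_mean_s = t2_mean, t2_sd_s = t2_sd,
               n_neighbors = sum(vapply(rt, `[[`, integer(1), "n_neighbors")),
               n_returning = sum(vapply(rt, `[[`, integer(1), "n_returning")),
               n_rep = length(reps),
               n_valid_t1 = sum(!is.na(t1m)), n_valid_t2 = sum(!is.na(t2m)))
  })
  do.call(rbind, out)
}

#' Render a recurrence plot
#'
#' Black points mark recurrent index pairs; both axes are in seconds.
#'
#' @param rmat Logical recurrence matrix from [recurrence_matrix()].
#' @param dt Seconds per step.
#' @param ... Passed to [graphics::image()].
#' @return `NULL`, invisibly.
#' @export
plot_recurrence <- function(rmat, dt = 1, ...) {
  tv <- (seq_len(nrow(rmat)) - 1L) * dt
  graphics::image(tv, tv, t(rmat[nrow(rmat):1, , drop = FALSE])[, nrow(rmat):1],
                  col = c("white", "black"), xlab = "time (s)",
                  ylab = "time (s)", useRaster = TRUE, ...)
  invisible(NULL)
}
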