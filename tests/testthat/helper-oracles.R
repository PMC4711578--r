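# Independent brute-force oracles for recurrence quantities.  These stay
# deliberately naive (explicit double loops, no shared code with the
# package internals).

naive_recurrence_matrix <- function(pts, r, strict = TRUE) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      out[i, j] <- if (strict) d < r else d <= r
    }
  out
}

naive_recurrence_times <- function(pts, x0, r, dt) {
  pts <- as.matrix(pts)
  s1 <- integer(0)
  for (i in seq_len(nrow(pts)))
    if (sqrt(sum((pts[i, ] - x0)^2)) < r) s1 <- c(s1, i)
  t1 <- numeric(0)
  if (length(s1) >= 2)
    for (i in 2:length(s1)) t1 <- c(t1, (s1[i] - s1[i - 1]) * dt)
  s2 <- integer(0)
  for (i in seq_along(s1))
    if (i == 1 || s1[i] - s1[i - 1] > 1) s2 <- c(s2, s1[i])
  t2 <- numeric(0)
  if (length(s2) >= 2)
    for (i in 2:length(s2)) t2 <- c(t2, (s2[i] - s2[i - 1]) * dt)
  list(s1 = s1, s2 = s2, t1 = t1, t2 = t2,
       t1_mean = if (length(t1)) mean(t1) else NA_real_,
       t2_mean = if (length(t2)) mean(t2) else NA_real_)
}

# small plume with fast dynamics for quick search tests
test_plume <- function(...) plume_params(...)
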