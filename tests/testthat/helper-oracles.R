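# Independent oracles used across the suite.

# ---- dip statistic oracle --------------------------------------------------
# Pure-R band-feasibility bisection from the definition: the smallest b such
# that a unimodal CDF (convex left of a data-point mode, concave right of it,
# atom allowed at the mode) fits inside the sup-norm band [F-b, F+b].
# Independent of the shipped C++ implementation.

oracle_lower_hull <- function(px, py) {
  k <- length(px); idx <- integer(k); top <- 0L
  for (i in seq_len(k)) {
    while (top >= 2L) {
      a <- idx[top - 1L]; b <- idx[top]
      if ((py[b] - py[a]) * (px[i] - px[b]) >= (py[i] - py[b]) * (px[b] - px[a]))
        top <- top - 1L else break
    }
    top <- top + 1L; idx[top] <- i
  }
  if (top == 1L) return(rep(py[idx[1]], k))
  approx(px[idx[1:top]], py[idx[1:top]], xout = px)$y
}

oracle_vmin_convex <- function(v, caps, lo, v_end) {
  k <- length(v)
  if (k == 0L) return(0)
  H <- oracle_lower_hull(v, caps)
  if (any(lo - H > 1e-12)) return(Inf)
  vm <- max(0, lo[k])
  for (s in seq_len(k)) {
    sig <- 0
    if (s > 1L) {
      r <- 1:(s - 1L)
      sig <- max(0, (lo[s] - H[r]) / (v[s] - v[r]))
    }
    vm <- max(vm, lo[s] + sig * (v_end - v[s]))
  }
  vm
}

oracle_dip <- function(x) {
  x <- sort(x); n <- length(x)
  v <- unique(x); m <- length(v)
  if (m == 1L) return(0)
  c_ <- cumsum(tabulate(match(x, v), m))
  F_ <- c_ / n
  Fm <- c(0, F_[-m])
  feas <- function(tau, b) {
    vl <- 0
    if (tau > 1L) {
      vl <- oracle_vmin_convex(v[1:tau], Fm[1:tau] + b,
                               c(F_[seq_len(tau - 1L)], Fm[tau]) - b, v[tau])
      if (!is.finite(vl)) return(FALSE)
    }
    vr <- 1
    if (tau < m) {
      rng <- (tau + 1L):m
      vm <- oracle_vmin_convex(rev(-v[rng]), rev(1 - F_[rng] + b),
                               rev(1 - Fm[rng] - b), -v[tau])
      if (!is.finite(vm)) return(FALSE)
      vr <- min(1 - vm, F_[tau] + b)
      if (vr < F_[tau] - b - 1e-15) return(FALSE)
    }
    vl <= vr + 1e-15
  }
  per_mode <- function(tau) {
    lo <- 0; hi <- 0.5
    if (feas(tau, lo)) return(0)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (feas(tau, mid)) hi <- mid else lo <- mid
    }
    hi
  }
  min(vapply(seq_len(m), per_mode, 0))
}

# ---- exact hybrid-index grid oracle ---------------------------------------
oracle_hybrid_index <- function(pN, pS, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(h) sum(log(h * pN + (1 - h) * pS + 1e-300)), 0)
  grid[which.max(ll)]
}
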