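#' Weir-Cockerham F_ST (theta) between two population samples
#'
#' Multiallelic, multilocus theta computed from the standard variance
#' components (a: among populations, b: among individuals within
#' populations, c: within individuals), summed over alleles and loci:
#' \eqn{\hat\theta = \sum a / \sum (a + b + c)}.  Small negative estimates
#' are possible and retained.  Significance is assessed by permuting
#' individuals between the two pools and recomputing theta; the p-value
#' uses the add-one correction \eqn{(1 + \#\{\theta^* \ge \hat\theta\}) /
#' (n_{perm} + 1)}.
#'
#' @param x a [genotype_table()].
#' @param pool_a,pool_b disjoint site-id vectors defining the two samples.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed RNG seed for the permutations.
#' @param loci loci to use (default: all codominant loci).
#' @return list of class `fst_result`: `theta`, `p`, `n_perm`, `seed`,
#'   `per_locus` (per-locus theta), `components` (summed a, b, c).
#' @export
fst_theta <- function(x, pool_a, pool_b, n_perm = 999L, seed = NULL,
                      loci = gt_loci(x)) {
  pool_a <- as.integer(pool_a); pool_b <- as.integer(pool_b)
  if (length(intersect(pool_a, pool_b))) stop_hz("pools must be disjoint")
  ia <- which(x$site_id %in% pool_a)
  ib <- which(x$site_id %in% pool_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop_hz("each pool needs at least two individuals")
  calls <- lapply(loci, function(loc) gt_calls(x, loc))
  names(calls) <- loci
  comp <- theta_components(calls, ia, ib)
  if (comp$denom <= 0) stop_hz("theta undefined: no allelic variation in the pools")
  theta <- comp$num / comp$denom

  p <- NA_real_
  if (n_perm > 0L) {
    idx <- c(ia, ib); na <- length(ia)
    perm_theta <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      sh <- sample(idx)
      cc <- theta_components(calls, sh[seq_len(na)], sh[-seq_len(na)])
      if (cc$denom <= 0) return(0)
      cc$num / cc$denom
    }, 0))
    p <- (1 + sum(perm_theta >= theta)) / (n_perm + 1)
  }
  structure(list(theta = theta, p = p, n_perm = n_perm, seed = seed,
                 per_locus = comp$per_locus,
                 components = c(a = comp$num, bc = comp$denom - comp$num)),
            class = "fst_result")
}

# Weir & Cockerham (1984) per-allele components for r = 2 samples
theta_components <- function(calls, ia, ib) {
  num <- 0; denom <- 0
  per_locus <- setNames(rep(NA_real_, length(calls)), names(calls))
  r <- 2
  for (loc in names(calls)) {
    cl <- calls[[loc]]
    ca <- cl[ia, , drop = FALSE]; ca <- ca[!is.na(ca[, 1L]), , drop = FALSE]
    cb <- cl[ib, , drop = FALSE]; cb <- cb[!is.na(cb[, 1L]), , drop = FALSE]
    n1 <- nrow(ca); n2 <- nrow(cb)
    if (n1 < 1L || n2 < 1L || n1 + n2 < 3L) next   # nbar must exceed 1
    alleles <- sort(unique(c(ca, cb)))
    if (length(alleles) < 2L) next
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    l_num <- 0; l_den <- 0
    for (al in alleles) {
      p1 <- (sum(ca == al)) / (2 * n1)
      p2 <- (sum(cb == al)) / (2 * n2)
      h1 <- sum((ca[, 1L] == al) != (ca[, 2L] == al)) / n1
      h2 <- sum((cb[, 1L] == al) != (cb[, 2L] == al)) / n2
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      l_num <- l_num + a
      l_den <- l_den + a + b + cc
    }
    if (l_den > 0) per_locus[loc] <- l_num / l_den
    num <- num + l_num
    denom <- denom + l_den
  }
  list(num = num, denom = denom, per_locus = per_locus)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %.5f", x$theta))
  if (!is.na(x$p)) cat(sprintf(", p = %.5f (%d permutations)", x$p, x$n_perm))
  cat("\n")
  invisible(x)
}
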