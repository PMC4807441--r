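#' Composite linkage disequilibrium test for a locus pair within one site
#'
#' Burrows/Weir composite genotypic disequilibrium, which requires no
#' phase information: for alleles u (locus 1) and v (locus 2) with
#' per-individual dosages \eqn{x_{iu}, y_{iv} \in \{0,1,2\}},
#' \deqn{\hat\Delta_{uv} = \tfrac{1}{2n}\sum_i x_{iu} y_{iv} - 2\hat p_u \hat q_v.}
#' The aggregated statistic is
#' \eqn{X^2 = n \sum_{u,v} \hat\Delta_{uv}^2 / (\tau_u \tau_v)} with
#' \eqn{\tau_u = \hat p_u(1-\hat p_u) + \hat D_{uu}} the one-locus
#' Hardy-Weinberg-adjusted variance term, referred to a chi-square with
#' \eqn{(k_1-1)(k_2-1)} degrees of freedom.  The headline p-value is the
#' permutation one (genotypes at the second locus shuffled across
#' individuals), robust for microsatellites; the asymptotic p is also
#' reported.
#'
#' @param x a [genotype_table()].
#' @param site_id site to test within.
#' @param locus1,locus2 locus names.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param min_n minimum number of individuals typed at both loci.
#' @return list of class `ld_result`: `statistic`, `df`, `p_perm`,
#'   `p_asym`, `delta` (composite-disequilibrium matrix), `n`, `degenerate`.
#' @export
composite_ld_test <- function(x, site_id, locus1, locus2, n_perm = 999L,
                              seed = NULL, min_n = 5L) {
  sub <- x[x$site_id == as.integer(site_id), , drop = FALSE]
  c1 <- gt_calls(sub, locus1); c2 <- gt_calls(sub, locus2)
  keep <- !is.na(c1[, 1L]) & !is.na(c2[, 1L])
  c1 <- c1[keep, , drop = FALSE]; c2 <- c2[keep, , drop = FALSE]
  n <- nrow(c1)
  if (n < min_n)
    stop_hz("need at least ", min_n, " individuals typed at both loci (have ", n, ")")
  X <- dosage_matrix(c1); Y <- dosage_matrix(c2)
  res <- composite_ld_stat(X, Y, n)
  if (res$degenerate) {
    out <- list(statistic = 0, df = 0L, p_perm = 1, p_asym = 1,
                delta = res$delta, n = n, n_perm = n_perm, degenerate = TRUE)
    class(out) <- "ld_result"
    return(out)
  }
  p_asym <- pchisq(res$stat, res$df, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0L) {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      composite_ld_stat(X, Y[sample.int(n), , drop = FALSE], n)$stat
    }, 0))
    p_perm <- (1 + sum(perm >= res$stat - 1e-12)) / (n_perm + 1)
  }
  structure(list(statistic = res$stat, df = res$df, p_perm = p_perm,
                 p_asym = p_asym, delta = res$delta, n = n, n_perm = n_perm,
                 degenerate = FALSE),
            class = "ld_result")
}

# per-individual allele dosage matrix (n x k)
dosage_matrix <- function(calls) {
  alleles <- sort(unique(c(calls)))
  X <- matrix(0L, nrow(calls), length(alleles),
              dimnames = list(NULL, alleles))
  for (j in seq_along(alleles))
    X[, j] <- (calls[, 1L] == alleles[j]) + (calls[, 2L] == alleles[j])
  X
}

composite_ld_stat <- function(X, Y, n) {
  if (ncol(X) < 2L || ncol(Y) < 2L)
    return(list(stat = 0, df = 0L, delta = NULL, degenerate = TRUE))
  p <- colMeans(X) / 2
  q <- colMeans(Y) / 2
  delta <- crossprod(X, Y) / (2 * n) - 2 * outer(p, q)
  # HW-adjusted variance terms; zero-variance alleles carry no information
  tau_x <- p * (1 - p) + colMeans(X == 2L) - p^2
  tau_y <- q * (1 - q) + colMeans(Y == 2L) - q^2
  use_x <- tau_x > 1e-12; use_y <- tau_y > 1e-12
  if (!any(use_x) || !any(use_y))
    return(list(stat = 0, df = 0L, delta = delta, degenerate = TRUE))
  stat <- n * sum((delta[use_x, use_y, drop = FALSE]^2) /
                    outer(tau_x[use_x], tau_y[use_y]))
  df <- (ncol(X) - 1L) * (ncol(Y) - 1L)
  list(stat = stat, df = df, delta = delta, degenerate = FALSE)
}

#' @export
print.ld_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Composite LD test: degenerate (monomorphic locus), p = 1\n")
  } else {
    cat(sprintf("Composite LD X^2 = %.4f, df = %d, perm p = %.4g, asym p = %.4g (n = %d)\n",
                x$statistic, x$df, x$p_perm, x$p_asym, x$n))
  }
  invisible(x)
}

#' Scan all locus pairs for linkage disequilibrium, site by site
#'
#' @param x a [genotype_table()].
#' @param n_perm,seed,min_n see [composite_ld_test()].
#' @param q false discovery rate for flagging significant pairs.
#' @return data.frame with one row per (site, locus pair): statistic, df,
#'   p-values, and FDR flags computed over the whole scan (classical
#'   one-stage step-up at rate `q`).
#' @export
ld_scan <- function(x, n_perm = 999L, seed = NULL, min_n = 5L, q = 0.05) {
  sites <- sort(unique(x$site_id))
  loci <- gt_loci(x)
  pairs <- utils::combn(loci, 2L)
  seeds <- derive_seeds(seed, length(sites) * ncol(pairs))
  rows <- list(); si <- 0L
  for (sid in sites) {
    for (pp in seq_len(ncol(pairs))) {
      si <- si + 1L
      r <- tryCatch(
        composite_ld_test(x, sid, pairs[1L, pp], pairs[2L, pp],
                          n_perm = n_perm, seed = seeds[[si]], min_n = min_n),
        error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sid, locus1 = pairs[1L, pp], locus2 = pairs[2L, pp],
        statistic = r$statistic, df = r$df, p_perm = r$p_perm,
        p_asym = r$p_asym, n = r$n, degenerate = r$degenerate)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  fl <- fdr_adjust(out$p_perm, q = q)
  out$significant <- out$p_perm <= 0.05
  out$significant_fdr <- fl$flags
  out
}
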