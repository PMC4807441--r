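#' Cytonuclear disequilibrium between the mitochondrial type and one
#' nuclear locus within a site
#'
#' The nuclear locus is first reduced to a diallelic composite (pool-A vs
#' pool-B allele classes from [frequency_differential()]; individuals
#' carrying an uninformative allele, \eqn{\delta = 0}, are excluded).  With
#' mitotype M (the northern type, frequency \eqn{m}):
#' \deqn{D = P(A \wedge M) - p_A m} (allelic, over allele copies), and the
#' genotypic disequilibria
#' \eqn{D_1 = P(AA \wedge M) - P_{AA} m},
#' \eqn{D_2 = P(Aa \wedge M) - P_{Aa} m},
#' \eqn{D_3 = P(aa \wedge M) - P_{aa} m}, which sum to zero by construction.
#' Significance is by permutation of the mitotype labels (two-sided on each
#' statistic), with the add-one correction.
#'
#' @param x a [genotype_table()].
#' @param site_id site to test within.
#' @param locus nuclear locus name.
#' @param diff a [frequency_differential()] table defining allele classes.
#' @param n_perm,seed permutation settings.
#' @param min_n minimum number of individuals typed at both markers.
#' @return list of class `cnd_result`: `d_allelic`, `d_genotypic` (D1, D2,
#'   D3), `p_allelic`, `p_genotypic`, `n`, `m_freq`, `degenerate` (mito
#'   monomorphic or locus uninformative).
#' @export
cytonuclear_disequilibrium <- function(x, site_id, locus, diff,
                                       n_perm = 999L, seed = NULL, min_n = 5L) {
  sub <- x[x$site_id == as.integer(site_id), , drop = FALSE]
  calls <- gt_calls(sub, locus)
  keep <- !is.na(calls[, 1L]) & !is.na(sub$mito)
  calls <- calls[keep, , drop = FALSE]
  mito <- sub$mito[keep]
  cls1 <- composite_class(diff, locus, calls[, 1L])
  cls2 <- composite_class(diff, locus, calls[, 2L])
  ok <- !is.na(cls1) & !is.na(cls2)
  calls <- calls[ok, , drop = FALSE]; mito <- mito[ok]
  cls1 <- cls1[ok]; cls2 <- cls2[ok]
  n <- length(mito)
  if (n < min_n)
    stop_hz("need at least ", min_n,
            " individuals typed at both markers (have ", n, ")")
  dose_a <- (cls1 > 0) + (cls2 > 0)          # 0, 1, 2 copies of composite A
  is_m <- mito == "N"
  m <- mean(is_m)
  degenerate <- m == 0 || m == 1 || all(dose_a == dose_a[1L])
  stat <- cnd_stats(dose_a, is_m, n)
  if (degenerate) {
    out <- list(d_allelic = 0, d_genotypic = c(D1 = 0, D2 = 0, D3 = 0),
                p_allelic = 1, p_genotypic = c(D1 = 1, D2 = 1, D3 = 1),
                n = n, m_freq = m, n_perm = n_perm, degenerate = TRUE)
    class(out) <- "cnd_result"
    return(out)
  }
  p_all <- NA_real_; p_gen <- rep(NA_real_, 3L)
  if (n_perm > 0L) {
    perms <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      unlist(cnd_stats(dose_a, sample(is_m), n))
    }, numeric(4L)))
    obs <- abs(unlist(stat))
    p <- (1 + rowSums(abs(perms) >= obs - 1e-12)) / (n_perm + 1)
    p_all <- unname(p[1L]); p_gen <- unname(p[2:4])
  }
  structure(list(d_allelic = stat$d, d_genotypic = c(D1 = stat$d1, D2 = stat$d2,
                                                     D3 = stat$d3),
                 p_allelic = p_all,
                 p_genotypic = setNames(p_gen, c("D1", "D2", "D3")),
                 n = n, m_freq = m, n_perm = n_perm, degenerate = FALSE),
            class = "cnd_result")
}

cnd_stats <- function(dose_a, is_m, n) {
  m <- mean(is_m)
  p_a <- mean(dose_a) / 2
  d <- mean(dose_a * is_m) / 2 - p_a * m
  d1 <- mean((dose_a == 2L) & is_m) - mean(dose_a == 2L) * m
  d2 <- mean((dose_a == 1L) & is_m) - mean(dose_a == 1L) * m
  d3 <- mean((dose_a == 0L) & is_m) - mean(dose_a == 0L) * m
  list(d = d, d1 = d1, d2 = d2, d3 = d3)
}

#' @export
print.cnd_result <- function(x, ...) {
  cat(sprintf("Cytonuclear disequilibrium (n = %d, mito freq %.3f)%s\n", x$n,
              x$m_freq, if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  allelic D = %.5f (p = %.4g)\n", x$d_allelic, x$p_allelic))
  cat(sprintf("  D1 = %.5f, D2 = %.5f, D3 = %.5f\n",
              x$d_genotypic[1L], x$d_genotypic[2L], x$d_genotypic[3L]))
  invisible(x)
}

#' Scan cytonuclear disequilibrium for every locus at a set of sites
#'
#' @param x a [genotype_table()].
#' @param site_ids sites to test (default: all with both markers typed).
#' @param diff a [frequency_differential()] table.
#' @param n_perm,seed,min_n see [cytonuclear_disequilibrium()].
#' @return data.frame with one row per (site, locus).
#' @export
cnd_scan <- function(x, diff, site_ids = sort(unique(x$site_id)),
                     n_perm = 999L, seed = NULL, min_n = 5L) {
  loci <- gt_loci(x)
  grid <- expand.grid(site_id = site_ids, locus = loci, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- tryCatch(cytonuclear_disequilibrium(
      x, grid$site_id[i], grid$locus[i], diff,
      n_perm = n_perm, seed = seeds[[i]], min_n = min_n),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(site_id = grid$site_id[i], locus = grid$locus[i],
               d_allelic = r$d_allelic, p_allelic = r$p_allelic,
               d1 = r$d_genotypic[1L], d2 = r$d_genotypic[2L],
               d3 = r$d_genotypic[3L], n = r$n, degenerate = r$degenerate)
  })
  do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)], make.row.names = FALSE))
}
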