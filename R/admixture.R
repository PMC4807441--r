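#' Admixture proportions by expectation-maximization
#'
#' Fits the no-linkage admixture model: each of an individual's allele
#' copies is drawn from cluster \eqn{z} with probability \eqn{q_{iz}} and
#' then from that cluster's allele frequencies.  Point estimation is by EM
#' (E-step over the cluster origin of every allele copy; M-step updates
#' \eqn{q} and the cluster frequencies), which converges monotonically in
#' the log-likelihood.  Only nuclear codominant loci are used; the haploid
#' mitochondrial marker is excluded.  Clusters are anchored geographically
#' when a site table is available: cluster 1 is the one with the largest
#' mean membership at the southernmost (closest) site, so for `k = 2`
#' column 2 is the "northern" membership.
#'
#' @param x a [genotype_table()].
#' @param k number of clusters (>= 1).
#' @param seed RNG seed for the initialization.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   gain drops below `tol` or after `max_iter` iterations (the result is
#'   then flagged unconverged but still returned).
#' @return object of class `admixture_fit`: `q` (individuals x clusters,
#'   rows sum to 1), `freqs` (per-locus cluster allele frequencies),
#'   `logLik`, `k`, `iterations`, `converged`, `seed`.
#' @export
admixture_em <- function(x, k, seed = NULL, max_iter = 2000L, tol = 1e-6) {
  stopifnot(inherits(x, "genotype_table"), k >= 1L)
  loci <- gt_loci(x)
  n <- nrow(x)
  if (n < 5L * k) stop_hz("need at least 5*k individuals (have ", n, ")")
  if (k > length(unique(x$site_id)))
    stop_hz("k must not exceed the number of sampled sites")
  # per-locus allele index matrices (n x 2)
  amaps <- list(); idx <- list()
  for (loc in loci) {
    calls <- gt_calls(x, loc)
    alleles <- sort(unique(c(calls[!is.na(calls)])))
    amaps[[loc]] <- alleles
    idx[[loc]] <- matrix(match(calls, alleles), ncol = 2L)
  }
  with_seed(seed, {
    q <- matrix(rgamma(n * k, 1), n, k)
    q <- q / rowSums(q)
    freqs <- lapply(loci, function(loc) {
      na <- length(amaps[[loc]])
      f <- matrix(rgamma(k * na, 1), k, na)
      f / rowSums(f)
    })
    names(freqs) <- loci
    ll_old <- -Inf; ll <- -Inf; it <- 0L; converged <- FALSE
    ll_trace <- numeric(0)
    while (it < max_iter) {
      it <- it + 1L
      q_new <- matrix(0, n, k)
      copies <- numeric(n)
      f_new <- lapply(freqs, function(f) matrix(0, nrow(f), ncol(f)))
      ll <- 0
      for (loc in loci) {
        f <- freqs[[loc]]
        for (copy in 1:2) {
          a <- idx[[loc]][, copy]
          ok <- !is.na(a)
          if (!any(ok)) next
          lik <- q[ok, , drop = FALSE] * t(f)[a[ok], , drop = FALSE]
          tot <- rowSums(lik)
          tot[tot < 1e-300] <- 1e-300
          ll <- ll + sum(log(tot))
          r <- lik / tot
          q_new[ok, ] <- q_new[ok, ] + r
          copies[ok] <- copies[ok] + 1
          # accumulate responsibilities into cluster x allele counts
          for (z in seq_len(k)) {
            tab <- rowsum(r[, z], a[ok])
            f_new[[loc]][z, as.integer(rownames(tab))] <-
              f_new[[loc]][z, as.integer(rownames(tab))] + tab[, 1L]
          }
        }
      }
      typed <- copies > 0
      q[typed, ] <- q_new[typed, , drop = FALSE] / copies[typed]
      freqs <- lapply(f_new, function(f) {
        s <- rowSums(f)
        s[s < 1e-300] <- 1e-300
        f / s
      })
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
  })
  rownames(q) <- x$individual_id
  colnames(q) <- paste0("cluster", seq_len(k))
  for (loc in loci) colnames(freqs[[loc]]) <- as.character(amaps[[loc]])
  fit <- list(q = q, freqs = freqs, logLik = ll, k = k, iterations = it,
              converged = converged, seed = seed, site_id = x$site_id,
              ll_trace = ll_trace)
  class(fit) <- "admixture_fit"
  anchor_clusters(fit, gt_sites(x))
}

# order clusters south -> north by membership-weighted mean distance
anchor_clusters <- function(fit, sites) {
  if (is.null(sites) || fit$k == 1L) return(fit)
  d <- sites$distance_km[match(fit$site_id, sites$site_id)]
  if (any(is.na(d))) return(fit)
  score <- colSums(fit$q * d) / colSums(fit$q)
  ord <- order(score)
  fit$q <- fit$q[, ord, drop = FALSE]
  colnames(fit$q) <- paste0("cluster", seq_len(fit$k))
  fit$freqs <- lapply(fit$freqs, function(f) f[ord, , drop = FALSE])
  fit
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture EM fit: k = %d, %d individuals, logLik %.2f (%d iterations%s)\n",
              x$k, nrow(x$q), x$logLik, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik")
}

#' Replicated admixture runs over a range of cluster numbers
#'
#' Runs [admixture_em()] `n_rep` times per `k` with derived seeds,
#' mirroring the usual replicated-MCMC protocol of model-based clustering
#' programs.
#'
#' @param x a [genotype_table()].
#' @param k_range integer vector of cluster numbers.
#' @param n_rep replicates per k.
#' @param seed master seed; replicate seeds are derived from it.
#' @param ... passed to [admixture_em()].
#' @return list with `logl` (named list: per-k numeric vector of replicate
#'   log-likelihoods) and `best_fit` (per k, the highest-likelihood fit).
#' @export
admixture_replicates <- function(x, k_range = 1:4, n_rep = 5L, seed = NULL, ...) {
  seeds <- derive_seeds(seed, length(k_range) * n_rep)
  logl <- list(); best <- list(); si <- 0L
  for (k in k_range) {
    lls <- numeric(n_rep); bf <- NULL
    for (r in seq_len(n_rep)) {
      si <- si + 1L
      f <- admixture_em(x, k, seed = seeds[[si]], ...)
      lls[r] <- f$logLik
      if (is.null(bf) || f$logLik > bf$logLik) bf <- f
    }
    logl[[as.character(k)]] <- lls
    best[[as.character(k)]] <- bf
  }
  list(logl = logl, best_fit = best)
}

#' Evanno delta-K statistic for choosing the number of clusters
#'
#' The second-difference statistic
#' \eqn{\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / sd(L(K))}
#' over replicate log-likelihoods; the K with maximal \eqn{\Delta K} is
#' the suggested number of clusters.  \eqn{\Delta K} is defined only for
#' interior K with a positive replicate standard deviation.
#'
#' @param logl named list: for each K (consecutive integers), a numeric
#'   vector of at least 3 replicate log-likelihoods.
#' @return data.frame of class `evanno_result` with columns `k`,
#'   `mean_logl`, `sd_logl`, `delta_k`; the suggested K is in attribute
#'   `suggested_k`.
#' @export
evanno_delta_k <- function(logl) {
  ks <- as.integer(names(logl))
  if (any(is.na(ks)) || length(ks) < 3L)
    stop_hz("need replicate log-likelihoods for at least 3 consecutive k values")
  if (any(diff(sort(ks)) != 1L)) stop_hz("k values must be consecutive")
  o <- order(ks); ks <- ks[o]; logl <- logl[o]
  if (any(lengths(logl) < 3L)) stop_hz("need >= 3 replicates per k")
  m <- vapply(logl, mean, 0)
  s <- vapply(logl, sd, 0)
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1L, length(ks))]) {
    if (s[i] > 0) dk[i] <- abs(m[i + 1L] - 2 * m[i] + m[i - 1L]) / s[i]
  }
  out <- data.frame(k = ks, mean_logl = m, sd_logl = s, delta_k = dk)
  sug <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  structure(out, suggested_k = sug,
            class = c("evanno_result", "data.frame"))
}

#' Parental-site selection from admixture proportions
#'
#' Walking inward from each end of the transect, sites whose individuals
#' predominantly (> 50\%) show parental memberships (northern ancestry
#' `q > 0.9` on the northern flank, `q < 0.1` on the southern flank) are
#' parental; the zone edge is the innermost parental site before the
#' first site with a majority of admixed individuals
#' (\eqn{0.1 < q < 0.9}).
#'
#' @param q per-individual northern-ancestry proportions.
#' @param site_id site id per individual.
#' @param sites site table (for distances/ordering).
#' @return list: `southern` and `northern` site ids, plus the per-site
#'   classification table in `classification`.
#' @export
select_parental_sites <- function(q, site_id, sites) {
  sites <- validate_site_table(sites)
  ids <- sites$site_id[sites$site_id %in% unique(site_id)]
  cls <- vapply(ids, function(s) {
    qs <- q[site_id == s]
    props <- c(S = mean(qs < 0.1), adm = mean(qs >= 0.1 & qs <= 0.9),
               N = mean(qs > 0.9))
    mx <- which.max(props)
    if (props[mx] > 0.5) names(props)[mx] else "none"
  }, "")
  tab <- data.frame(site_id = ids,
                    distance_km = sites$distance_km[match(ids, sites$site_id)],
                    class = cls)
  run_s <- 0L
  for (cl in cls) { if (cl == "S") run_s <- run_s + 1L else break }
  run_n <- 0L
  for (cl in rev(cls)) { if (cl == "N") run_n <- run_n + 1L else break }
  if (run_s == 0L)
    stop_hz("no southern parental site: the southernmost site is not ",
            "predominantly q < 0.1; choose parental sites manually")
  if (run_n == 0L)
    stop_hz("no northern parental site: the northernmost site is not ",
            "predominantly q > 0.9; choose parental sites manually")
  list(southern = ids[run_s], northern = ids[length(ids) - run_n + 1L],
       classification = tab)
}
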