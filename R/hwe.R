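#' Genotype counts at one site and locus
#'
#' @param x a [genotype_table()].
#' @param site_id integer site id.
#' @param locus locus name.
#' @return symmetric matrix of genotype counts (alleles as dimnames); entry
#'   `[i, j]` with `i <= j` counts unordered genotype i/j.
#' @export
genotype_counts <- function(x, site_id, locus) {
  sub <- x[x$site_id == as.integer(site_id), , drop = FALSE]
  calls <- gt_calls(sub, locus)
  calls <- calls[!is.na(calls[, 1L]), , drop = FALSE]
  alleles <- sort(unique(c(calls)))
  k <- length(alleles)
  # counts stored in the upper triangle (pairs are sorted ascending)
  cnt <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (i in seq_len(nrow(calls))) {
    a <- match(calls[i, 1L], alleles); b <- match(calls[i, 2L], alleles)
    cnt[a, b] <- cnt[a, b] + 1L
  }
  cnt
}

hwe_check_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (any(counts < 0)) stop_hz("genotype counts must be nonnegative")
  if (any(counts[lower.tri(counts)] != 0)) {
    # accept symmetric-stored heterozygotes
    lo <- t(counts)[upper.tri(counts)]
    counts[upper.tri(counts)] <- counts[upper.tri(counts)] + lo
    counts[lower.tri(counts)] <- 0
  }
  if (sum(counts) < 1) stop_hz("need at least one typed individual")
  counts
}

het_count <- function(counts) sum(counts[upper.tri(counts)])

allele_margin <- function(counts) {
  k <- nrow(counts)
  up <- counts + t(counts); diag(up) <- diag(up) / 2  # not needed; direct:
  m <- integer(k)
  for (i in seq_len(k)) m[i] <- 2L * counts[i, i] + sum(counts[i, -i]) + sum(counts[-i, i])
  m
}

# log "configuration weight" of a table under the HWE conditional law:
# P(table | margins) proportional to 2^het / prod(n_ij!)
log_table_weight <- function(counts) {
  het_count(counts) * log(2) - sum(lgamma(counts[upper.tri(counts, diag = TRUE)] + 1))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test given allele counts, for codominant (possibly
#' multiallelic) genotype counts at one site and locus.  The global
#' alternative orders tables by their conditional probability (two-sided
#' probability test); one-sided heterozygote-deficit and heterozygote-excess
#' p-values order tables by the total heterozygote count.
#'
#' `method = "chain"` runs a Guo-Thompson-style Markov chain over individual
#' allele pairings (proposal: re-pair the alleles of two random individuals;
#' acceptance \eqn{\min(1, 2^{\Delta het})}), with dememorization, batching,
#' and a Monte Carlo standard error from between-batch variance.
#' `method = "enumerate"` sums the exact conditional probabilities over all
#' genotype tables with the observed allele margin (feasible for small
#' samples; used as the independent oracle in the test-suite).
#'
#' @param counts genotype count matrix as from [genotype_counts()].
#' @param method `"chain"` or `"enumerate"`.
#' @param dememorization,batches,iter_per_batch Markov-chain settings
#'   (defaults: 1000 dememorization steps, 100 batches of 1000 iterations).
#' @param seed RNG seed for the chain.
#' @return list of class `hwe_result`: `p_global`, `p_deficit`, `p_excess`,
#'   `se` (Monte Carlo standard errors, zero for enumeration), `het_obs`,
#'   `n`, `method`, `degenerate` (monomorphic locus), `chain` settings.
#' @export
hwe_exact_test <- function(counts, method = c("chain", "enumerate"),
                           dememorization = 1000L, batches = 100L,
                           iter_per_batch = 1000L, seed = NULL) {
  method <- match.arg(method)
  counts <- hwe_check_counts(counts)
  k <- nrow(counts)
  res <- list(het_obs = het_count(counts), n = sum(counts), method = method,
              degenerate = FALSE,
              chain = list(dememorization = dememorization, batches = batches,
                           iter_per_batch = iter_per_batch, seed = seed))
  if (k == 1L) {
    res <- c(res, list(p_global = 1, p_deficit = 1, p_excess = 1,
                       se = c(global = 0, deficit = 0, excess = 0)))
    res$degenerate <- TRUE
    class(res) <- "hwe_result"
    return(res)
  }
  out <- if (method == "enumerate") hwe_enumerate(counts)
         else hwe_chain(counts, dememorization, batches, iter_per_batch, seed)
  res <- c(res, out)
  class(res) <- "hwe_result"
  res
}

hwe_enumerate <- function(counts) {
  margin <- allele_margin(counts)
  tabs <- enumerate_tables(margin)
  lw0 <- vapply(tabs, log_table_weight, 0)
  lw <- lw0 - max(lw0)
  pr <- exp(lw) / sum(exp(lw))
  hets <- vapply(tabs, het_count, 0L)
  lw_obs <- log_table_weight(counts) - max(lw0)
  tol <- 1e-9
  list(p_global = sum(pr[lw <= lw_obs + tol]),
       p_deficit = sum(pr[hets <= het_count(counts)]),
       p_excess = sum(pr[hets >= het_count(counts)]),
       se = c(global = 0, deficit = 0, excess = 0))
}

# all symmetric genotype count tables with a given allele-copy margin
enumerate_tables <- function(margin) {
  k <- length(margin)
  if (sum(margin) %% 2L != 0L) stop_hz("allele margin must sum to an even number")
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  out <- list()
  tab <- matrix(0L, k, k)
  recurse <- function(ci, rem) {
    if (ci > nrow(cells)) {
      if (all(rem == 0L)) out[[length(out) + 1L]] <<- tab
      return(invisible())
    }
    i <- cells[ci, 1L]; j <- cells[ci, 2L]
    take <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (v in 0:take) {
      rem2 <- rem
      rem2[i] <- rem2[i] - v * (if (i == j) 2L else 1L)
      if (i != j) rem2[j] <- rem2[j] - v
      # prune: allele i can only appear in later cells if a later cell involves i
      if (rem2[i] > 0L && !any(cells[-seq_len(ci), 1L] == i | cells[-seq_len(ci), 2L] == i)) next
      tab[i, j] <<- v
      recurse(ci + 1L, rem2)
    }
    tab[i, j] <<- 0L
    invisible()
  }
  recurse(1L, as.integer(margin))
  out
}

hwe_chain <- function(counts, dememorization, batches, iter_per_batch, seed) {
  k <- nrow(counts)
  # individual-level state: two allele indices per individual
  pairs <- which(counts > 0, arr.ind = TRUE)
  g1 <- integer(0); g2 <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]; nn <- counts[i, j]
    g1 <- c(g1, rep.int(i, nn)); g2 <- c(g2, rep.int(j, nn))
  }
  n <- length(g1)
  if (n < 2L) {
    return(list(p_global = 1, p_deficit = 1, p_excess = 1,
                se = c(global = 0, deficit = 0, excess = 0)))
  }
  het_obs <- het_count(counts)
  lw_obs <- log_table_weight(counts)
  with_seed(seed, {
    tab <- counts
    het <- het_obs
    lw <- lw_obs
    run <- function(steps, record) {
      ps <- if (record) matrix(0, steps, 3L) else NULL
      ia <- sample.int(n, steps, replace = TRUE)
      ib <- sample.int(n - 1L, steps, replace = TRUE)
      ib <- ib + (ib >= ia)  # distinct pair
      sw <- sample.int(2L, steps, replace = TRUE)
      u <- runif(steps)
      pu <- sample.int(2L, steps, replace = TRUE)
      for (s in seq_len(steps)) {
        a <- ia[s]; b <- ib[s]
        i1 <- g1[a]; j1 <- g2[a]; i2 <- g1[b]; j2 <- g2[b]
        # swap one allele copy of a with one of b (classic switch proposal)
        x <- if (sw[s] == 1L) i1 else j1
        y <- if (pu[s] == 1L) i2 else j2
        n1 <- sort(c(if (sw[s] == 1L) j1 else i1, y))
        n2 <- sort(c(if (pu[s] == 1L) j2 else i2, x))
        # Hastings correction from allele-copy multiplicities
        q_fwd <- ((i1 == x) + (j1 == x)) * ((i2 == y) + (j2 == y))
        q_back <- ((n1[1L] == y) + (n1[2L] == y)) * ((n2[1L] == x) + (n2[2L] == x))
        d_het <- (n1[1L] != n1[2L]) + (n2[1L] != n2[2L]) -
                 (i1 != j1) - (i2 != j2)
        ratio <- 2^d_het * q_back / q_fwd
        if (ratio >= 1 || u[s] < ratio) {
          # update running table and weight cell by cell
          dl <- 0
          rm_cell <- function(i, j) {
            v <- tab[i, j]; tab[i, j] <<- v - 1L; dl <<- dl + log(v)
          }
          add_cell <- function(i, j) {
            v <- tab[i, j]; tab[i, j] <<- v + 1L; dl <<- dl - log(v + 1)
          }
          rm_cell(min(i1, j1), max(i1, j1)); rm_cell(min(i2, j2), max(i2, j2))
          add_cell(n1[1L], n1[2L]); add_cell(n2[1L], n2[2L])
          lw <<- lw + dl + d_het * log(2)
          het <<- het + d_het
          g1[a] <<- n1[1L]; g2[a] <<- n1[2L]
          g1[b] <<- n2[1L]; g2[b] <<- n2[2L]
        }
        if (record) {
          ps[s, 1L] <- lw <= lw_obs + 1e-9
          ps[s, 2L] <- het <= het_obs
          ps[s, 3L] <- het >= het_obs
        }
      }
      ps
    }
    run(dememorization, record = FALSE)
    batch_means <- matrix(0, batches, 3L)
    for (bb in seq_len(batches)) {
      ps <- run(iter_per_batch, record = TRUE)
      batch_means[bb, ] <- colMeans(ps)
    }
    p <- colMeans(batch_means)
    se <- apply(batch_means, 2L, sd) / sqrt(batches)
    list(p_global = p[1L], p_deficit = p[2L], p_excess = p[3L],
         se = c(global = se[1L], deficit = se[2L], excess = se[3L]))
  })
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("Exact HWE test (", x$method, "), n = ", x$n,
      if (x$degenerate) " [monomorphic]" else "", "\n", sep = "")
  cat(sprintf("  p (global)  = %.5g\n  p (deficit) = %.5g\n  p (excess)  = %.5g\n",
              x$p_global, x$p_deficit, x$p_excess))
  if (x$method == "chain")
    cat(sprintf("  MC SE: %.2g / %.2g / %.2g\n", x$se[1], x$se[2], x$se[3]))
  invisible(x)
}

#' Inbreeding coefficient F_IS from genotype counts
#'
#' \eqn{F_{IS} = 1 - H_{obs}/H_{exp}} with \eqn{H_{exp}} the unbiased
#' (small-sample corrected) expected heterozygosity
#' \eqn{\frac{2n}{2n-1}(1 - \sum_i p_i^2)}.  Positive values indicate a
#' heterozygote deficit, negative a heterozygote excess.
#'
#' @param counts genotype count matrix as from [genotype_counts()].
#' @return list of class `fis_result`: `fis` (NA when \eqn{H_{exp}=0}),
#'   `h_obs`, `h_exp`, `n`, `degenerate`.
#' @export
inbreeding_coefficient <- function(counts) {
  counts <- hwe_check_counts(counts)
  n <- sum(counts)
  h_obs <- het_count(counts) / n
  p <- allele_margin(counts) / (2 * n)
  h_exp <- (2 * n) / (2 * n - 1) * (1 - sum(p^2))
  if (2 * n - 1 == 0 || h_exp <= 0) {
    out <- list(fis = NA_real_, h_obs = h_obs, h_exp = max(h_exp, 0), n = n,
                degenerate = TRUE)
  } else {
    out <- list(fis = 1 - h_obs / h_exp, h_obs = h_obs, h_exp = h_exp, n = n,
                degenerate = FALSE)
  }
  class(out) <- "fis_result"
  out
}

#' @export
print.fis_result <- function(x, ...) {
  if (x$degenerate) cat("F_IS undefined (H_exp = 0), n =", x$n, "\n")
  else cat(sprintf("F_IS = %.4f (H_obs %.4f, H_exp %.4f, n %d)\n",
                   x$fis, x$h_obs, x$h_exp, x$n))
  invisible(x)
}

#' Site-by-locus F_IS and HWE scan
#'
#' Applies [inbreeding_coefficient()] and optionally [hwe_exact_test()] to
#' every site-locus cell, mirroring the usual per-marsh summary grid.
#'
#' @param x a [genotype_table()].
#' @param hwe run the exact HWE chain test per cell (slower).
#' @param ... chain settings passed to [hwe_exact_test()].
#' @param seed integer; per-cell chain seeds are derived from it.
#' @return data.frame with one row per (site, locus): `fis`, `h_obs`,
#'   `h_exp`, `n`, and when `hwe = TRUE` the three p-values.
#' @export
hwe_fis_scan <- function(x, hwe = FALSE, seed = NULL, ...) {
  sites <- sort(unique(x$site_id))
  grid <- expand.grid(site_id = sites, locus = gt_loci(x),
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cnt <- tryCatch(genotype_counts(x, grid$site_id[i], grid$locus[i]),
                    error = function(e) NULL)
    if (is.null(cnt) || sum(cnt) == 0L)
      return(data.frame(grid[i, ], fis = NA, h_obs = NA, h_exp = NA, n = 0L,
                        p_global = NA, p_deficit = NA, p_excess = NA))
    f <- inbreeding_coefficient(cnt)
    p <- if (hwe) hwe_exact_test(cnt, seed = seeds[[i]], ...) else
      list(p_global = NA, p_deficit = NA, p_excess = NA)
    data.frame(grid[i, ], fis = f$fis, h_obs = f$h_obs, h_exp = f$h_exp,
               n = f$n, p_global = p$p_global, p_deficit = p$p_deficit,
               p_excess = p$p_excess)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
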