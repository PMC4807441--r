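#' Cline concordance and coincidence test
#'
#' Tests whether clines at several loci share a common centre
#' (coincidence) and width (concordance).  Clines are fitted in the
#' scaled-logit shape
#' \deqn{p(x) = p_{min} + (p_{max}-p_{min}) / (1 + e^{-4(x-c)/w}),}
#' whose maximal slope is \eqn{(p_{max}-p_{min})/w} as in the tanh form.
#' Two nested models are compared by a likelihood ratio test: a *free*
#' model with per-locus centre, width and end frequencies, and a
#' *constrained* model sharing one centre and width across loci (end
#' frequencies stay per-locus).  \eqn{\chi^2 = 2(\log L_{free} -
#' \log L_{constrained})} with \eqn{2(L-1)} degrees of freedom for
#' \eqn{L} loci.
#'
#' @param data either a long data.frame with columns `locus`, `distance`,
#'   `successes`, `total`, or a named list of per-locus data.frames as for
#'   [fit_cline()].
#' @param n_starts optimizer starts per fit.
#' @param seed RNG seed.
#' @return object of class `cline_concordance`: `chisq`, `df`, `p`,
#'   `logLik_free`, `logLik_constrained`, `free` (per-locus parameter
#'   matrix), `constrained` (shared centre/width and per-locus ends),
#'   `degenerate` (TRUE when only one locus is supplied).
#' @export
concordance_test <- function(data, n_starts = 8L, seed = NULL) {
  if (is.data.frame(data)) {
    if (is.null(data$locus)) stop_hz("long-format data needs a 'locus' column")
    data <- split(data[setdiff(names(data), "locus")], data$locus)
  }
  data <- lapply(data, check_cline_data)
  L <- length(data)
  if (L < 1L) stop_hz("no loci supplied")
  seeds <- derive_seeds(seed, 2L * L + 1L)

  if (L == 1L) {
    f <- logit_fit(data[[1L]], n_starts, seeds[[1L]])
    return(structure(list(chisq = 0, df = 0L, p = NA_real_,
                          logLik_free = f$logLik, logLik_constrained = f$logLik,
                          free = rbind(f$par), constrained = NULL,
                          degenerate = TRUE),
                     class = "cline_concordance"))
  }

  free0 <- lapply(seq_len(L), function(i) logit_fit(data[[i]], n_starts, seeds[[i]]))

  # constrained: shared (centre, width), per-locus ends
  allx <- unlist(lapply(data, `[[`, "distance"))
  cb <- c(min(allx) - 200, max(allx) + 200)
  lower <- c(cb[1L], log(1), rep(c(0, 0), L))
  upper <- c(cb[2L], log(3000), rep(c(1, 1), L))
  nllc <- function(par) {
    tot <- 0
    for (i in seq_len(L)) {
      m <- par[2L + 2L * i - 1L]; s <- par[2L + 2L * i]
      tot <- tot - logit_loglik(data[[i]], par[1L], exp(par[2L]),
                                m, m + (1 - m) * s)
      if (!is.finite(tot)) return(1e10)
    }
    tot
  }
  ctr0 <- mean(vapply(free0, function(f) f$par[["centre"]], 0))
  w0 <- exp(mean(log(vapply(free0, function(f) f$par[["width"]], 0))))
  st0 <- c(min(max(ctr0, cb[1L]), cb[2L]), log(min(max(w0, 1), 3000)),
           unlist(lapply(free0, function(f) {
             m <- f$par[["p_min"]]
             c(m, (f$par[["p_max"]] - m) / max(1 - m, 1e-9))
           })))
  starts <- c(list(st0), with_seed(seeds[[2L * L + 1L]],
    lapply(seq_len(max(n_starts - 1L, 0L)), function(i) runif(length(lower), lower, upper))))
  bestc <- NULL
  for (st in starts) {
    fit <- try(optim(st, nllc, method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 1000)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(bestc) || fit$value < bestc$value) bestc <- fit
  }
  if (is.null(bestc)) stop_hz("constrained concordance fit failed to converge")
  ll_con <- -bestc$value
  con_par <- bestc$par

  # refit free including the constrained per-locus solution as a start, so
  # the free model always nests the constrained one numerically
  free <- lapply(seq_len(L), function(i) {
    m <- con_par[2L + 2L * i - 1L]; s <- con_par[2L + 2L * i]
    extra <- c(con_par[1L], con_par[2L], m, s)
    logit_fit(data[[i]], n_starts, seeds[[L + i]], extra_start = extra)
  })
  ll_free <- sum(vapply(free, function(f) f$logLik, 0))
  chisq <- max(0, 2 * (ll_free - ll_con))
  df <- 2L * (L - 1L)
  p <- pchisq(chisq, df, lower.tail = FALSE)
  free_par <- do.call(rbind, lapply(free, function(f) f$par))
  rownames(free_par) <- names(data)
  con_ends <- matrix(con_par[-(1:2)], ncol = 2L, byrow = TRUE)
  con_tab <- data.frame(locus = names(data),
                        p_min = con_ends[, 1L],
                        p_max = con_ends[, 1L] + (1 - con_ends[, 1L]) * con_ends[, 2L])
  structure(list(chisq = chisq, df = df, p = p, logLik_free = ll_free,
                 logLik_constrained = ll_con, free = free_par,
                 constrained = list(centre = con_par[1L], width = exp(con_par[2L]),
                                    ends = con_tab),
                 degenerate = FALSE),
            class = "cline_concordance")
}

logit_loglik <- function(d, centre, width, p_min, p_max) {
  p <- p_min + (p_max - p_min) / (1 + exp(-4 * (d$distance - centre) / width))
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(d$successes * log(p) + (d$total - d$successes) * log(1 - p))
}

# 4-parameter scaled-logit ML fit for one locus
logit_fit <- function(d, n_starts, seed, extra_start = NULL) {
  rng <- range(d$distance)
  lower <- c(rng[1L] - 200, log(1), 0, 0)
  upper <- c(rng[2L] + 200, log(3000), 1, 1)
  nll <- function(par) {
    m <- par[3L]
    v <- -logit_loglik(d, par[1L], exp(par[2L]), m, m + (1 - m) * par[4L])
    if (!is.finite(v)) 1e10 else v
  }
  f <- d$successes / d$total
  o <- order(d$distance)
  mid <- (max(f) + min(f)) / 2
  cross <- which(diff(sign(f[o] - mid)) != 0)
  c0 <- if (length(cross)) mean(d$distance[o][c(cross[1L], cross[1L] + 1L)]) else mean(rng)
  starts <- list(c(c0, log(max(diff(rng) / 5, 2)), max(min(f), 0.001), 0.9))
  if (!is.null(extra_start)) starts <- c(starts, list(pmin(pmax(extra_start, lower), upper)))
  starts <- c(starts, with_seed(seed, lapply(seq_len(max(n_starts - 1L, 0L)),
    function(i) runif(4L, lower, upper))))
  best <- NULL
  for (st in starts) {
    fit <- try(optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_hz("scaled-logit fit failed to converge")
  m <- best$par[3L]
  list(par = c(centre = best$par[1L], width = exp(best$par[2L]),
               p_min = m, p_max = m + (1 - m) * best$par[4L]),
       logLik = -best$value)
}

#' @export
print.cline_concordance <- function(x, ...) {
  if (x$degenerate) {
    cat("Cline concordance test: single locus (degenerate), chi^2 = 0\n")
    return(invisible(x))
  }
  cat(sprintf("Cline concordance/coincidence LRT (%d loci)\n", nrow(x$free)))
  cat(sprintf("  logLik free %.3f | constrained %.3f (shared centre %.2f km, width %.2f km)\n",
              x$logLik_free, x$logLik_constrained,
              x$constrained$centre, x$constrained$width))
  cat(sprintf("  chi^2 = %.4f, df = %d, p = %.4g\n", x$chisq, x$df, x$p))
  invisible(x)
}
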