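#' False discovery rate control (classical one-stage step-up)
#'
#' Sorts the p-values ascending, finds the largest \eqn{i} with
#' \eqn{p_{(i)} \le i\,q/m}, and flags the first \eqn{i} ordered tests.
#' This is the classical one-stage (Benjamini-Hochberg-type) step-up rule;
#' the flags always include everything a Bonferroni cut at the same rate
#' would flag.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q target false discovery rate.
#' @return list of class `fdr_result`: `flags` (logical, in input order),
#'   `threshold` (largest flagged p, 0 if none), `n_signif`, `adjusted`
#'   (step-up adjusted p-values), `q`, `m`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (length(p) == 0L)
    return(structure(list(flags = logical(0), threshold = 0, n_signif = 0L,
                          adjusted = numeric(0), q = q, m = 0L),
                     class = "fdr_result"))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_hz("p-values must be in [0, 1]")
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  pass <- which(ps <= seq_len(m) * q / m)
  flags <- logical(m)
  threshold <- 0
  if (length(pass)) {
    cut <- max(pass)
    flags[ord[seq_len(cut)]] <- TRUE
    threshold <- ps[cut]
  }
  structure(list(flags = flags, threshold = threshold,
                 n_signif = sum(flags), adjusted = p.adjust(p, method = "BH"),
                 q = q, m = m),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("FDR step-up at q = %g: %d of %d flagged (threshold p <= %.5g)\n",
              x$q, x$n_signif, x$m, x$threshold))
  invisible(x)
}
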