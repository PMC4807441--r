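#' Parental allele frequencies for hybrid-index estimation
#'
#' Computes per-locus allele frequencies in two designated parental site
#' samples.  Alleles absent from exactly one pool are floored at
#' \eqn{1/(2 n_{pool} + 1)} (so that observing them is rare but not
#' impossible under that ancestry); alleles absent from both pools carry
#' no information and cause the locus to be skipped for that individual.
#'
#' @param x a [genotype_table()].
#' @param south_sites,north_sites site ids of the designated southern and
#'   northern parental samples.
#' @return list of class `parental_freqs`: per locus, a matrix with rows
#'   `S`/`N` and one column per allele seen in either pool; attribute
#'   `pool_n` (allele copies per pool and locus).
#' @export
parental_frequencies <- function(x, south_sites, north_sites) {
  diff <- frequency_differential(x, pool_a = north_sites, pool_b = south_sites,
                                 include_mito = FALSE)
  pool_n <- attr(diff, "pool_n")
  loci <- unique(diff$locus)
  out <- lapply(loci, function(loc) {
    d <- diff[diff$locus == loc, ]
    f <- rbind(S = d$freq_b, N = d$freq_a)
    colnames(f) <- d$allele
    nn <- pool_n[[loc]]
    floorS <- 1 / (nn[["B"]] + 1)   # pool totals are allele copies (2n)
    floorN <- 1 / (nn[["A"]] + 1)
    zeroS <- f["S", ] == 0 & f["N", ] > 0
    zeroN <- f["N", ] == 0 & f["S", ] > 0
    f["S", zeroS] <- floorS
    f["N", zeroN] <- floorN
    f
  })
  names(out) <- loci
  structure(out, pool_n = pool_n, south_sites = south_sites,
            north_sites = north_sites, class = "parental_freqs")
}

#' Maximum-likelihood hybrid index per individual
#'
#' The hybrid index \eqn{\hat h \in [0,1]} is the estimated proportion of
#' an individual's ancestry from the northern parental pool.  Each of the
#' individual's allele copies is treated as an independent draw from the
#' mixture \eqn{h\,p_N(a) + (1-h)\,p_S(a)};
#' \eqn{\hat h} maximizes \eqn{\sum_{copies} \log(h\,p_N + (1-h)\,p_S)}
#' over a 0.001 grid refined by golden-section search, and the 2-unit
#' support interval is read from the same profile.  Loci with an allele
#' absent from both parental samples are skipped for that individual;
#' individuals with no usable locus get `NA` and are listed in the
#' `excluded` attribute.
#'
#' @param x a [genotype_table()].
#' @param parents a [parental_frequencies()] object, or a list
#'   `list(south = sites, north = sites)` from which one is built.
#' @return data.frame of class `hybrid_index_result`: `individual_id`,
#'   `site_id`, `h`, `lo`, `hi` (2-unit support), `n_loci` used.
#' @examples
#' sim <- simulate_hybrid_zone(hz_sim_config(seed = 1))
#' pf <- parental_frequencies(sim$table, south_sites = 1, north_sites = 13)
#' head(hybrid_index(sim$table, pf))
#' @export
hybrid_index <- function(x, parents) {
  if (!inherits(parents, "parental_freqs")) {
    if (!is.list(parents) || !all(c("south", "north") %in% names(parents)))
      stop_hz("parents must be parental_frequencies() or list(south=, north=)")
    parents <- parental_frequencies(x, parents$south, parents$north)
  }
  loci <- intersect(gt_loci(x), names(parents))
  grid <- seq(0, 1, by = 0.001)
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    pN <- numeric(0); pS <- numeric(0); used <- 0L
    for (loc in loci) {
      a <- c(x[[paste0(loc, ".a1")]][i], x[[paste0(loc, ".a2")]][i])
      if (is.na(a[1L])) next
      f <- parents[[loc]]
      known <- as.character(a) %in% colnames(f)
      if (!all(known)) next       # allele unseen in both pools: skip locus
      fN <- f["N", as.character(a)]; fS <- f["S", as.character(a)]
      if (all(fN == 0 & fS == 0)) next
      pN <- c(pN, fN); pS <- c(pS, fS)
      used <- used + 1L
    }
    if (used == 0L) {
      rows[[i]] <- data.frame(h = NA_real_, lo = NA_real_, hi = NA_real_,
                              n_loci = 0L)
      next
    }
    ll <- vapply(grid, function(h) sum(log(h * pN + (1 - h) * pS + 1e-300)), 0)
    gi <- which.max(ll)
    lo_br <- grid[max(gi - 1L, 1L)]; hi_br <- grid[min(gi + 1L, length(grid))]
    h_hat <- if (lo_br < hi_br) {
      opt <- optimize(function(h) sum(log(h * pN + (1 - h) * pS + 1e-300)),
                      c(lo_br, hi_br), maximum = TRUE, tol = 1e-9)
      if (opt$objective >= ll[gi]) opt$maximum else grid[gi]
    } else grid[gi]
    keep <- ll >= max(ll[gi]) - 2
    rows[[i]] <- data.frame(h = h_hat, lo = grid[min(which(keep))],
                            hi = grid[max(which(keep))], n_loci = used)
  }
  out <- cbind(data.frame(individual_id = x$individual_id,
                          site_id = x$site_id, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  structure(out, excluded = out$individual_id[out$n_loci == 0L],
            parents = parents,
            class = c("hybrid_index_result", "data.frame"))
}

#' @export
print.hybrid_index_result <- function(x, ...) {
  cat(sprintf("Hybrid indices for %d individuals (%d excluded, no usable loci)\n",
              nrow(x), length(attr(x, "excluded"))))
  print.data.frame(head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Histogram counts of hybrid indices in fixed-width bins
#'
#' Bins \eqn{[0,0.1), [0.1,0.2), \ldots, [0.9,1.0]} (the last bin is
#' closed).  `NA` values are dropped with a warning.
#'
#' @param h hybrid-index values in \[0, 1\] (or a
#'   [hybrid_index()] result).
#' @param bin_width bin width (default 0.10).
#' @return integer vector of class `hybrid_index_histogram` (named by bin),
#'   summing to the number of non-missing values.
#' @export
hybrid_index_distribution <- function(h, bin_width = 0.1) {
  if (inherits(h, "hybrid_index_result")) h <- h$h
  if (anyNA(h)) {
    warning("dropping ", sum(is.na(h)), " missing hybrid indices")
    h <- h[!is.na(h)]
  }
  if (length(h) == 0L)
    return(structure(integer(0), class = "hybrid_index_histogram"))
  if (any(h < 0 | h > 1)) stop_hz("hybrid indices must be in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-9) breaks <- c(breaks, 1)
  bin <- findInterval(h, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  names(counts) <- paste0("[", format(breaks[-length(breaks)]), ",",
                          format(breaks[-1L]),
                          c(rep(")", length(breaks) - 2L), "]"))
  structure(counts, class = "hybrid_index_histogram")
}

#' @export
print.hybrid_index_histogram <- function(x, ...) {
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' @export
plot.hybrid_index_result <- function(x, bin_width = 0.1, ...) {
  h <- x$h[!is.na(x$h)]
  hist(h, breaks = seq(0, 1, by = bin_width), right = FALSE,
       include.lowest = TRUE, xlab = "hybrid index",
       main = "Hybrid index distribution", ...)
  invisible(x)
}
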