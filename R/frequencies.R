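#' Allele frequencies by site or pooled groups
#'
#' Counts allele copies per locus, excluding missing calls; diploid loci
#' contribute two copies per typed individual and the haploid mitochondrial
#' marker one.  Groups with no typed individuals at a locus are omitted from
#' the table and reported in the `empty_groups` attribute rather than
#' propagating `NaN`.
#'
#' @param x a [genotype_table()].
#' @param groups `"site"` (default: one group per sampling site) or a named
#'   list of integer site-id vectors defining pooled groups.
#' @param include_mito include the haploid mitochondrial marker as locus
#'   `"mtDNA"` with alleles `N`/`S`.
#' @return a data.frame of class `allele_freqs` with columns `group`,
#'   `locus`, `allele`, `count`, `total`, `freq`.  Frequencies within each
#'   `(group, locus)` sum to one.
#' @export
allele_frequencies <- function(x, groups = "site", include_mito = TRUE) {
  stopifnot(inherits(x, "genotype_table"))
  if (identical(groups, "site")) {
    ids <- sort(unique(x$site_id))
    groups <- setNames(as.list(ids), ids)
  }
  if (!is.list(groups) || is.null(names(groups)))
    stop_hz("groups must be \"site\" or a named list of site-id vectors")
  loci <- gt_loci(x)
  rows <- list()
  empties <- list()
  for (g in names(groups)) {
    sub <- x[x$site_id %in% as.integer(groups[[g]]), , drop = FALSE]
    for (loc in loci) {
      calls <- gt_calls(sub, loc)
      copies <- c(calls[, 1L], calls[, 2L])
      copies <- copies[!is.na(copies)]
      if (!length(copies)) {
        empties[[length(empties) + 1L]] <- data.frame(group = g, locus = loc)
        next
      }
      tab <- table(copies)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus = loc, allele = names(tab),
        count = as.integer(tab), total = length(copies),
        stringsAsFactors = FALSE)
    }
    if (include_mito) {
      mt <- sub$mito[!is.na(sub$mito)]
      if (length(mt)) {
        tab <- table(mt)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, locus = "mtDNA", allele = names(tab),
          count = as.integer(tab), total = length(mt),
          stringsAsFactors = FALSE)
      } else if (any(!is.na(x$mito))) {
        empties[[length(empties) + 1L]] <- data.frame(group = g, locus = "mtDNA")
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), locus = character(),
                      allele = character(), count = integer(),
                      total = integer(), freq = numeric())
  else out$freq <- out$count / out$total
  structure(out, empty_groups = if (length(empties)) do.call(rbind, empties),
            class = c("allele_freqs", "data.frame"))
}

#' Allele-frequency differentials between two parental pools
#'
#' For each locus and allele, the differential is
#' \eqn{\delta = p_A - p_B}, the allele's frequency in pool A minus pool B.
#' The per-locus summary differential is \eqn{\frac{1}{2}\sum_a |\delta_a|},
#' which equals 1 for a fixed difference and 0 for identical pools; it
#' measures how informative the locus is about ancestry.
#'
#' @param x a [genotype_table()].
#' @param pool_a,pool_b disjoint integer vectors of site ids for the two
#'   parental pools (A conventionally the northern pool).
#' @param include_mito include the mitochondrial marker.
#' @return data.frame of class `diff_table` with columns `locus`, `allele`,
#'   `freq_a`, `freq_b`, `delta`, plus a `summary` attribute (per-locus
#'   \eqn{\frac{1}{2}\sum|\delta|}) and `pool_a`/`pool_b`/`pool_n`
#'   attributes (`pool_n`: allele copies counted per pool and locus).
#' @export
frequency_differential <- function(x, pool_a, pool_b, include_mito = TRUE) {
  pool_a <- as.integer(pool_a); pool_b <- as.integer(pool_b)
  if (length(intersect(pool_a, pool_b)))
    stop_hz("pools must be disjoint; shared site(s): ",
            paste(intersect(pool_a, pool_b), collapse = ", "))
  af <- allele_frequencies(x, groups = list(A = pool_a, B = pool_b),
                           include_mito = include_mito)
  loci <- unique(af$locus)
  rows <- list(); summ <- numeric(0); pool_n <- list()
  for (loc in loci) {
    a <- af[af$group == "A" & af$locus == loc, ]
    b <- af[af$group == "B" & af$locus == loc, ]
    if (!nrow(a) || !nrow(b)) next
    alleles <- sort(unique(c(a$allele, b$allele)))
    fa <- setNames(rep(0, length(alleles)), alleles); fa[a$allele] <- a$freq
    fb <- setNames(rep(0, length(alleles)), alleles); fb[b$allele] <- b$freq
    rows[[loc]] <- data.frame(locus = loc, allele = alleles,
                              freq_a = unname(fa), freq_b = unname(fb),
                              delta = unname(fa - fb), stringsAsFactors = FALSE)
    summ[loc] <- sum(abs(fa - fb)) / 2
    pool_n[[loc]] <- c(A = a$total[1L], B = b$total[1L])
  }
  if (!length(rows)) stop_hz("no locus typed in both pools")
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            summary = summ, pool_a = pool_a, pool_b = pool_b, pool_n = pool_n,
            class = c("diff_table", "data.frame"))
}

#' Reduce multiallelic loci to a diallelic composite
#'
#' Pools the alleles of each locus into a composite "pool-A" class (alleles
#' with \eqn{\delta > 0}, i.e. more frequent in pool A) versus the
#' complement (\eqn{\delta < 0}).  Alleles with \eqn{\delta = 0} carry no
#' ancestry information and are excluded from both the numerator and the
#' denominator.  Loci whose differentials are all zero are dropped and
#' flagged in the `noninformative` attribute.
#'
#' @param freqs an [allele_frequencies()] table (per site or per group).
#' @param diff a [frequency_differential()] table computed from the
#'   designated parental pools.
#' @return data.frame of class `diallelic_freqs` with columns `group`,
#'   `locus`, `count_a`, `total`, `freq_a` (composite-A allele frequency).
#' @export
diallelic_reduction <- function(freqs, diff) {
  stopifnot(inherits(freqs, "allele_freqs"), inherits(diff, "diff_table"))
  loci <- unique(diff$locus)
  noninf <- character(0)
  rows <- list()
  for (loc in loci) {
    d <- diff[diff$locus == loc, ]
    a_class <- d$allele[d$delta > 0]
    b_class <- d$allele[d$delta < 0]
    if (!length(a_class) && !length(b_class)) { noninf <- c(noninf, loc); next }
    f <- freqs[freqs$locus == loc, ]
    for (g in unique(f$group)) {
      fg <- f[f$group == g, ]
      ca <- sum(fg$count[fg$allele %in% a_class])
      cb <- sum(fg$count[fg$allele %in% b_class])
      if (ca + cb == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus = loc, count_a = ca, total = ca + cb,
        freq_a = ca / (ca + cb), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop_hz("all loci are non-informative (every delta is zero)")
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
    noninformative = noninf, class = c("diallelic_freqs", "data.frame"))
}

# composite class membership of each allele copy of one individual at `locus`:
# +1 pool-A allele, -1 pool-B, NA tie/unknown
composite_class <- function(diff, locus, alleles) {
  d <- diff[diff$locus == locus, ]
  cls <- setNames(sign(d$delta), d$allele)
  cls[cls == 0] <- NA
  unname(cls[as.character(alleles)])
}
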