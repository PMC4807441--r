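#' Run the full hybrid-zone analysis pipeline
#'
#' Binds the analysis stages end to end on one genotype dataset:
#' allele frequencies and parental differentials, the site-by-locus
#' F_IS/HWE grid, the linkage-disequilibrium scan with FDR control,
#' cytonuclear disequilibrium, per-locus cline fits with AIC model
#' selection and support limits, the cline concordance LRT, replicated
#' admixture runs with the Evanno delta-K table, parental-site selection,
#' hybrid indices with binned distributions, and per-site dip tests.
#' Every stage writes a TSV into `out_dir`, and a `manifest.json` records
#' the configuration, seeds, input hashes and package version, so the
#' same configuration and seed reproduce byte-identical outputs.
#'
#' @param x a [genotype_table()] (with site table), or a path to a
#'   genotype CSV.
#' @param out_dir output directory (created if needed).
#' @param sites site table (or CSV path) if `x` carries none.
#' @param parents `"auto"` (use [select_parental_sites()] on the k = 2
#'   admixture run) or `list(south = , north = )` site ids.
#' @param stages character vector of stages to run, any of
#'   `"stats"`, `"cline"`, `"concordance"`, `"admixture"`,
#'   `"hybrid_index"`, `"diptest"`.
#' @param seed master seed; stage seeds are derived from it.
#' @param n_perm permutations for the disequilibrium tests.
#' @param k_range,n_rep admixture cluster range and replicates per k.
#' @param chain HWE chain settings, a list
#'   `list(dememorization =, batches =, iter_per_batch =)`.
#' @param dip_n_null null replicates for the dip tests.
#' @param fdr_q false discovery rate.
#' @param min_site_n sites with fewer individuals are excluded from the
#'   per-site dip tests (small samples make the test uninformative).
#' @return (invisibly) a list with every stage's in-memory result plus
#'   `manifest`.
#' @export
hz_pipeline <- function(x, out_dir, sites = NULL, parents = "auto",
                        stages = c("stats", "cline", "concordance",
                                   "admixture", "hybrid_index", "diptest"),
                        seed = 1L, n_perm = 199L, k_range = 1:4, n_rep = 3L,
                        chain = list(dememorization = 200L, batches = 20L,
                                     iter_per_batch = 200L),
                        dip_n_null = 999L, fdr_q = 0.05, min_site_n = 20L) {
  input_path <- NULL
  if (is.character(x)) {
    input_path <- x
    if (is.character(sites)) sites <- read_site_table(sites)
    x <- read_genotype_table(x, format = "csv", sites = sites)
  } else if (!is.null(sites) && is.null(gt_sites(x))) {
    x <- genotype_table(as.data.frame(x), loci = gt_loci(x), sites = sites)
  }
  stopifnot(inherits(x, "genotype_table"))
  st <- gt_sites(x)
  if (is.null(st)) stop_hz("pipeline needs a site table")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 8L)
  res <- list()
  tsv <- function(d, f) {
    write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }
  outputs <- character(0)

  af <- allele_frequencies(x)
  outputs <- c(outputs, tsv(af, "allele_frequencies.tsv"))
  res$allele_freqs <- af

  present <- st[st$site_id %in% unique(x$site_id), , drop = FALSE]
  ends <- c(present$site_id[1L], present$site_id[nrow(present)])
  diff <- frequency_differential(x, pool_a = ends[2L], pool_b = ends[1L])
  outputs <- c(outputs, tsv(diff, "frequency_differentials.tsv"))
  res$diff <- diff

  if ("stats" %in% stages) {
    fis <- hwe_fis_scan(x, hwe = TRUE, seed = seeds[[1L]],
                        dememorization = chain$dememorization,
                        batches = chain$batches,
                        iter_per_batch = chain$iter_per_batch)
    fis$significant_deficit <- !is.na(fis$p_deficit) & fis$p_deficit <= 0.05
    fis$significant_excess <- !is.na(fis$p_excess) & fis$p_excess <= 0.05
    ok <- !is.na(fis$p_global)
    fis$significant_fdr <- FALSE
    fis$significant_fdr[ok] <- fdr_adjust(fis$p_global[ok], q = fdr_q)$flags
    outputs <- c(outputs, tsv(fis, "fis_hwe_grid.tsv"))
    res$fis <- fis

    ld <- ld_scan(x, n_perm = n_perm, seed = seeds[[2L]], q = fdr_q)
    outputs <- c(outputs, tsv(ld, "ld_scan.tsv"))
    res$ld <- ld

    cnd <- cnd_scan(x, diff, n_perm = n_perm, seed = seeds[[3L]])
    if (!is.null(cnd)) outputs <- c(outputs, tsv(cnd, "cytonuclear.tsv"))
    res$cnd <- cnd
  }

  if ("cline" %in% stages) {
    loci <- c(gt_loci(x), if (any(!is.na(x$mito))) "mtDNA")
    fit_rows <- list(); fits <- list()
    cseeds <- derive_seeds(seeds[[4L]], length(loci))
    for (i in seq_along(loci)) {
      loc <- loci[i]
      d <- try(cline_data(x, loc, diff), silent = TRUE)
      if (inherits(d, "try-error")) next
      vfits <- list()
      for (v in c("null", "I", "II", "III"))
        vfits[[v]] <- fit_cline(d, v, seed = cseeds[[i]])
      best <- select_cline_model(vfits)
      bf <- vfits[[best]]
      ci <- tryCatch(confint(bf, parm = intersect(
        c("centre", "width"),
        switch(bf$variant, null = character(0), I = c("centre", "width"),
               c("centre", "width")))),
        error = function(e) NULL)
      fit_rows[[loc]] <- data.frame(
        locus = loc, best_variant = best,
        centre = bf$model$centre, width = bf$model$width,
        p_min = bf$model$p_min, p_max = bf$model$p_max,
        centre_lo = if (!is.null(ci)) ci["centre", 1L] else NA,
        centre_hi = if (!is.null(ci)) ci["centre", 2L] else NA,
        width_lo = if (!is.null(ci)) ci["width", 1L] else NA,
        width_hi = if (!is.null(ci)) ci["width", 2L] else NA,
        aic_null = vfits$null$aic, aic_I = vfits$I$aic,
        aic_II = vfits$II$aic, aic_III = vfits$III$aic)
      fits[[loc]] <- bf
    }
    cline_tab <- do.call(rbind, c(fit_rows, make.row.names = FALSE))
    outputs <- c(outputs, tsv(cline_tab, "cline_fits.tsv"))
    res$cline <- list(table = cline_tab, fits = fits)
  }

  if ("concordance" %in% stages) {
    loci <- c(gt_loci(x), if (any(!is.na(x$mito))) "mtDNA")
    long <- list()
    for (loc in loci) {
      d <- try(cline_data(x, loc, diff), silent = TRUE)
      if (inherits(d, "try-error")) next
      long[[loc]] <- cbind(locus = loc, d)
    }
    conc <- concordance_test(do.call(rbind, long), seed = seeds[[5L]])
    outputs <- c(outputs, tsv(
      data.frame(chisq = conc$chisq, df = conc$df, p = conc$p,
                 logLik_free = conc$logLik_free,
                 logLik_constrained = conc$logLik_constrained),
      "concordance.tsv"))
    res$concordance <- conc
  }

  q2 <- NULL
  if ("admixture" %in% stages || identical(parents, "auto")) {
    reps <- admixture_replicates(x, k_range = k_range, n_rep = n_rep,
                                 seed = seeds[[6L]])
    if (length(k_range) >= 3L) {
      ev <- evanno_delta_k(reps$logl)
      outputs <- c(outputs, tsv(as.data.frame(ev), "evanno_delta_k.tsv"))
      res$evanno <- ev
    }
    q2 <- reps$best_fit[["2"]]
    if (!is.null(q2)) {
      qtab <- data.frame(individual_id = rownames(q2$q), site_id = q2$site_id,
                         q_north = q2$q[, 2L])
      outputs <- c(outputs, tsv(qtab, "admixture_q.tsv"))
      res$admixture <- reps
    }
  }

  if (identical(parents, "auto")) {
    if (is.null(q2)) stop_hz("parents = \"auto\" needs a k = 2 admixture run")
    ps <- select_parental_sites(q2$q[, 2L], q2$site_id, st)
    parents <- list(south = ps$southern, north = ps$northern)
    res$parental_sites <- ps
  }

  if (any(c("hybrid_index", "diptest") %in% stages)) {
    pf <- parental_frequencies(x, parents$south, parents$north)
    hi <- hybrid_index(x, pf)
    outputs <- c(outputs, tsv(as.data.frame(hi), "hybrid_index.tsv"))
    res$hybrid_index <- hi

    histos <- lapply(split(hi$h, hi$site_id), function(h)
      as.integer(hybrid_index_distribution(h[!is.na(h)])))
    htab <- data.frame(site_id = as.integer(names(histos)),
                       do.call(rbind, histos))
    names(htab)[-1L] <- paste0("bin_", seq_len(ncol(htab) - 1L))
    outputs <- c(outputs, tsv(htab, "hybrid_index_histograms.tsv"))

    if ("diptest" %in% stages) {
      dseeds <- derive_seeds(seeds[[7L]], length(histos))
      dip_rows <- list()
      for (i in seq_along(histos)) {
        sid <- as.integer(names(histos))[i]
        h <- hi$h[hi$site_id == sid & !is.na(hi$h)]
        if (length(h) < max(4L, min_site_n)) next
        dt <- dip_test(h, n_null = dip_n_null, seed = dseeds[[i]])
        dip_rows[[length(dip_rows) + 1L]] <- data.frame(
          site_id = sid, n = dt$n, D = dt$D, p = dt$p)
      }
      dip_tab <- do.call(rbind, c(dip_rows, make.row.names = FALSE))
      if (!is.null(dip_tab)) outputs <- c(outputs, tsv(dip_tab, "dip_tests.tsv"))
      res$dip <- dip_tab
    }
  }

  manifest <- list(
    package = "hybridzone",
    version = as.character(packageVersion("hybridzone")),
    seed = seed, stages = stages, n_perm = n_perm,
    k_range = k_range, n_rep = n_rep, chain = chain,
    dip_n_null = dip_n_null, fdr_q = fdr_q,
    parents = parents,
    n_individuals = nrow(x), loci = gt_loci(x),
    input_md5 = if (!is.null(input_path))
      unname(tools::md5sum(input_path)) else NULL,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
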