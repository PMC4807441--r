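# Small in-code fixtures.

# two-site, two-locus table (4 individuals) incl. mito and one missing call
tiny_table <- function() {
  genotype_table(data.frame(
    individual_id = c("a1", "a2", "b1", "b2"),
    site_id = c(1L, 1L, 2L, 2L),
    sex = c("F", "M", NA, "F"),
    year = c(2008L, 2008L, 2009L, 2009L),
    mito = c("S", "S", "N", NA),
    ms1.a1 = c(151L, 151L, 163L, 163L),
    ms1.a2 = c(155L, 151L, 163L, 167L),
    ms2.a1 = c(101L, 0L, 105L, 101L),
    ms2.a2 = c(103L, 0L, 105L, 105L),
    stringsAsFactors = FALSE),
    sites = data.frame(site_id = 1:2, name = c("south", "north"),
                       distance_km = c(0, 100), lat = NA, lon = NA, n = 2))
}

# genotype table from explicit per-individual allele pairs at one locus
one_locus_table <- function(pairs, site_id = 1L, mito = NULL) {
  n <- nrow(pairs)
  df <- data.frame(individual_id = sprintf("i%03d", seq_len(n)),
                   site_id = site_id,
                   ms1.a1 = pairs[, 1L], ms1.a2 = pairs[, 2L],
                   stringsAsFactors = FALSE)
  if (!is.null(mito)) df$mito <- mito
  genotype_table(df)
}

expect_gt_equal <- function(a, b) {
  expect_equal(gt_loci(a), gt_loci(b))
  da <- as.data.frame(a); db <- as.data.frame(b)
  da$site_id <- as.integer(da$site_id); db$site_id <- as.integer(db$site_id)
  ord_a <- order(da$individual_id); ord_b <- order(db$individual_id)
  rownames(da) <- rownames(db) <- NULL
  expect_equal(da[ord_a, names(db)], db[ord_b, ], ignore_attr = TRUE)
}
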