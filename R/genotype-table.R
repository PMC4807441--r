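#' Multilocus genotype tables
#'
#' A `genotype_table` holds codominant diploid genotypes (unordered allele
#' pairs, e.g. microsatellite fragment lengths) for a set of individuals
#' assigned to sampling sites, plus an optional haploid mitochondrial type
#' per individual (`"N"`/`"S"` for northern/southern mitotype).  It is a
#' `data.frame` with columns `individual_id`, `site_id`, `sex`, `year`,
#' `mito`, and two integer columns `<locus>.a1`/`<locus>.a2` per codominant
#' locus.  Allele pairs are stored sorted ascending; missing calls are `NA`
#' on both columns (the allele code `0` maps to missing on input).
#'
#' @param df a data.frame with the columns described above. `sex`, `year` and
#'   `mito` are optional and filled with `NA` when absent.
#' @param loci character vector of codominant locus names; by default
#'   detected from paired `<locus>.a1`/`<locus>.a2` columns.
#' @param sites optional site table: a data.frame with columns `site_id`,
#'   `name`, `distance_km` (along-coast distance from the southern reference,
#'   in km), `lat`, `lon`, and optionally `n`.  When supplied, every
#'   `site_id` in `df` must occur in it and distances must be unique.
#'
#' @return an object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(data.frame(
#'   individual_id = c("a", "b"), site_id = 1L, mito = c("N", "S"),
#'   ms1.a1 = c(151L, 151L), ms1.a2 = c(155L, 151L)))
#' gt_loci(gt)
#' @export
genotype_table <- function(df, loci = NULL, sites = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "site_id") %in% names(df)))
    stop_hz("genotype table needs 'individual_id' and 'site_id' columns")
  for (col in c("sex", "year", "mito")) if (is.null(df[[col]])) df[[col]] <- NA
  if (is.null(loci)) {
    a1 <- sub("\\.a1$", "", grep("\\.a1$", names(df), value = TRUE))
    a2 <- sub("\\.a2$", "", grep("\\.a2$", names(df), value = TRUE))
    loci <- intersect(a1, a2)
  }
  if (anyDuplicated(df$individual_id))
    stop_hz("duplicated individual ids: ",
            paste(unique(df$individual_id[duplicated(df$individual_id)]), collapse = ", "))
  meta <- c("individual_id", "site_id", "sex", "year", "mito")
  out <- df[, c(meta, as.vector(rbind(paste0(loci, ".a1"), paste0(loci, ".a2"))))]
  out$individual_id <- as.character(out$individual_id)
  out$site_id <- as.integer(out$site_id)
  out$mito <- as.character(out$mito)
  out$sex <- as.character(out$sex)
  out$year <- as.integer(out$year)
  out$mito[!is.na(out$mito) & out$mito == ""] <- NA_character_
  out$sex[!is.na(out$sex) & out$sex == ""] <- NA_character_
  for (loc in loci) {
    a1 <- as.integer(out[[paste0(loc, ".a1")]])
    a2 <- as.integer(out[[paste0(loc, ".a2")]])
    a1[!is.na(a1) & a1 == 0L] <- NA_integer_   # 0 = missing sentinel
    a2[!is.na(a2) & a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)              # half-missing calls dropped whole
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    if (any(!miss & (a1 < 0L | a2 < 0L)))
      stop_hz("negative allele code at locus ", loc)
    swap <- !miss & a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    out[[paste0(loc, ".a1")]] <- a1
    out[[paste0(loc, ".a2")]] <- a2
  }
  bad_mito <- !is.na(out$mito) & !out$mito %in% c("N", "S")
  if (any(bad_mito))
    stop_hz("mitochondrial type must be 'N' or 'S' (got ",
            paste(unique(out$mito[bad_mito]), collapse = ", "), ")")
  if (!is.null(sites)) {
    sites <- validate_site_table(sites)
    missing_sites <- setdiff(out$site_id, sites$site_id)
    if (length(missing_sites))
      stop_hz("site_id(s) not in site table: ", paste(missing_sites, collapse = ", "))
  }
  structure(out, loci = loci, sites = sites,
            class = c("genotype_table", "data.frame"))
}

validate_site_table <- function(sites) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("site_id", "name", "distance_km")
  if (!all(need %in% names(sites)))
    stop_hz("site table needs columns: ", paste(need, collapse = ", "))
  for (col in c("lat", "lon", "n")) if (is.null(sites[[col]])) sites[[col]] <- NA_real_
  sites$site_id <- as.integer(sites$site_id)
  if (anyDuplicated(sites$site_id)) stop_hz("duplicated site_id in site table")
  if (anyDuplicated(sites$distance_km)) stop_hz("site distances must be unique")
  if (any(sites$distance_km < 0)) stop_hz("distance_km must be non-negative")
  sites[order(sites$distance_km), c("site_id", "name", "distance_km", "lat", "lon", "n")]
}

#' @rdname genotype_table
#' @param x a `genotype_table`.
#' @export
gt_loci <- function(x) attr(x, "loci")

#' @rdname genotype_table
#' @export
gt_sites <- function(x) attr(x, "sites")

#' Subset a genotype table to a set of sites
#'
#' @param x a [genotype_table()].
#' @param site_ids integer site ids to keep.
#' @return a `genotype_table` with only the selected individuals.
#' @export
gt_subset_sites <- function(x, site_ids) {
  keep <- x$site_id %in% as.integer(site_ids)
  genotype_table(as.data.frame(x)[keep, , drop = FALSE],
                 loci = gt_loci(x), sites = gt_sites(x))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table: ", nrow(x), " individuals, ",
      length(gt_loci(x)), " codominant loci, ",
      length(unique(x$site_id)), " sites",
      if (any(!is.na(x$mito))) ", mito typed" else "", "\n", sep = "")
  cat("Loci:", paste(gt_loci(x), collapse = ", "), "\n")
  if (!is.null(gt_sites(x)))
    cat("Site distances (km):",
        paste(signif(gt_sites(x)$distance_km, 6), collapse = ", "), "\n")
  invisible(x)
}

# allele-pair matrix (n x 2) for one locus; NA rows = missing
gt_calls <- function(x, locus) {
  cbind(x[[paste0(locus, ".a1")]], x[[paste0(locus, ".a2")]])
}
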