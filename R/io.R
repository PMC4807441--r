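#' Read and write genotype tables
#'
#' Two plain-text dialects are supported.
#'
#' **CSV**: columns `individual_id`, `site_id`, `sex`, `year`, `mito`, then
#' two columns `<locus>.a1`/`<locus>.a2` per codominant locus; allele code
#' `0` means missing; `mito` is `N`, `S` or empty.
#'
#' **Genepop**: title line, one locus name per line (or one comma-separated
#' line), `POP` separators, and individual lines `id ,  aaabbb cccddd ...`
#' with 3-digit allele codes (`000` = missing).  Haploid mitochondrial
#' columns use a single 3-digit code per individual (`001` = N, `002` = S),
#' and are recognised on input by their 3-digit width.  Genepop carries no
#' site metadata: POP blocks are written in site order and mapped back to
#' site ids via `site_ids` (defaults to block order), and `sex`/`year` are
#' not representable in this dialect.
#'
#' @param path file path.
#' @param format `"csv"` or `"genepop"`.
#' @param sites optional site table attached to the result (see
#'   [genotype_table()]).
#' @param site_ids for Genepop input: integer site id for each POP block.
#' @return `read_genotype_table()` returns a [genotype_table()];
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path, format = c("csv", "genepop"),
                                sites = NULL, site_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_hz("file not found: ", path)
  if (format == "csv") read_gt_csv(path, sites) else read_gt_genepop(path, sites, site_ids)
}

#' @rdname read_genotype_table
#' @param x a [genotype_table()].
#' @export
write_genotype_table <- function(x, path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "genotype_table"))
  if (format == "csv") write_gt_csv(x, path) else write_gt_genepop(x, path)
  invisible(path)
}

read_gt_csv <- function(path, sites) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  genotype_table(df, sites = sites)
}

write_gt_csv <- function(x, path) {
  df <- as.data.frame(x)
  for (loc in gt_loci(x)) for (suf in c(".a1", ".a2")) {
    col <- paste0(loc, suf)
    df[[col]][is.na(df[[col]])] <- 0L
  }
  con <- file(path, "w"); on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
}

MITO_CODES <- c(N = "001", S = "002")

write_gt_genepop <- function(x, path) {
  loci <- gt_loci(x)
  has_mito <- any(!is.na(x$mito))
  locus_lines <- c(loci, if (has_mito) "mtDNA")
  site_order <- if (!is.null(gt_sites(x))) {
    intersect(gt_sites(x)$site_id, unique(x$site_id))
  } else sort(unique(x$site_id))
  lines <- c("hybridzone genotype export", locus_lines)
  fmt3 <- function(a) ifelse(is.na(a), "000", formatC(a, width = 3, flag = "0"))
  for (sid in site_order) {
    lines <- c(lines, "POP")
    sub <- x[x$site_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      codes <- vapply(loci, function(loc) {
        paste0(fmt3(sub[[paste0(loc, ".a1")]][i]), fmt3(sub[[paste0(loc, ".a2")]][i]))
      }, "")
      if (has_mito) {
        m <- sub$mito[i]
        codes <- c(codes, if (is.na(m)) "000" else unname(MITO_CODES[m]))
      }
      lines <- c(lines, paste0(sub$individual_id[i], " ,  ", paste(codes, collapse = " ")))
    }
  }
  writeLines(lines, path)
}

read_gt_genepop <- function(path, sites, site_ids) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_hz("genepop parse error: file too short")
  body <- lines[-1L]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop_hz("genepop parse error: no POP separator found")
  locus_lines <- body[seq_len(pop_idx[1L] - 1L)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  n_loc <- length(locus_names)
  if (!n_loc) stop_hz("genepop parse error: no locus names before first POP")

  blocks <- split_pop_blocks(body, pop_idx)
  if (is.null(site_ids)) site_ids <- seq_along(blocks)
  if (length(site_ids) != length(blocks))
    stop_hz("site_ids has length ", length(site_ids), " but file has ",
            length(blocks), " POP blocks")

  rows <- list()
  haploid <- rep(NA, n_loc)   # resolved from code widths
  for (b in seq_along(blocks)) {
    for (ln in blocks[[b]]) {
      line_no <- ln$line_no
      parts <- strsplit(ln$text, ",", fixed = TRUE)[[1L]]
      if (length(parts) < 2L)
        stop_hz("genepop parse error at line ", line_no, ": expected 'id , genotypes'")
      id <- trimws(parts[1L])
      codes <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
      if (length(codes) != n_loc)
        stop_hz("genepop parse error at line ", line_no, ": ", length(codes),
                " genotype fields for ", n_loc, " loci")
      for (j in seq_len(n_loc)) {
        wide <- nchar(codes[j])
        if (!wide %in% c(3L, 6L))
          stop_hz("genepop parse error at line ", line_no, ": allele code '",
                  codes[j], "' is not 3 (haploid) or 6 (diploid) digits")
        hap <- wide == 3L
        if (is.na(haploid[j])) haploid[j] <- hap
        else if (haploid[j] != hap)
          stop_hz("genepop parse error at line ", line_no,
                  ": inconsistent ploidy for locus ", locus_names[j])
      }
      rows[[length(rows) + 1L]] <- list(id = id, site = site_ids[b], codes = codes)
    }
  }
  dip <- which(!haploid)
  hap <- which(haploid)
  if (length(hap) > 1L)
    stop_hz("genepop parse error: more than one haploid (3-digit) locus")
  out <- data.frame(individual_id = vapply(rows, `[[`, "", "id"),
                    site_id = vapply(rows, function(r) as.integer(r$site), 1L),
                    stringsAsFactors = FALSE)
  out$sex <- NA_character_; out$year <- NA_integer_
  out$mito <- NA_character_
  if (length(hap)) {
    code <- vapply(rows, function(r) r$codes[hap], "")
    out$mito <- unname(c("001" = "N", "002" = "S")[code])
    if (any(!code %in% c("000", "001", "002")))
      stop_hz("genepop parse error: haploid mito codes must be 000/001/002")
  }
  for (j in dip) {
    code <- vapply(rows, function(r) r$codes[j], "")
    out[[paste0(locus_names[j], ".a1")]] <- as.integer(substr(code, 1L, 3L))
    out[[paste0(locus_names[j], ".a2")]] <- as.integer(substr(code, 4L, 6L))
  }
  genotype_table(out, loci = locus_names[dip], sites = sites)
}

split_pop_blocks <- function(body, pop_idx) {
  blocks <- list()
  bounds <- c(pop_idx, length(body) + 1L)
  for (b in seq_along(pop_idx)) {
    rng <- seq(bounds[b] + 1L, bounds[b + 1L] - 1L)
    rng <- rng[nzchar(trimws(body[rng]))]
    blocks[[b]] <- lapply(rng, function(i) list(line_no = i + 1L, text = body[i]))
  }
  blocks
}

#' Read or write a site table
#'
#' CSV with columns `site_id`, `name`, `distance_km`, `lat`, `lon` and
#' optionally `n` (sample size).
#'
#' @param path file path.
#' @return a validated site table data.frame ordered by distance.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop_hz("file not found: ", path)
  validate_site_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_site_table
#' @param sites a site table data.frame.
#' @export
write_site_table <- function(sites, path) {
  write.csv(validate_site_table(sites), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
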