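#' Locus specifications for the hybrid-zone simulator
#'
#' `locus_spec()` describes one codominant microsatellite locus by its
#' allele frequencies in the two parental gene pools.
#' `default_locus_panel()` returns a nine-locus panel whose per-locus
#' allele-frequency differentials (1.00, 0.95, 0.85, 0.70, 0.64, 0.57,
#' 0.24, 0.20, 0.15) mix near-diagnostic and weakly differentiated
#' markers, the typical make-up of a microsatellite panel spanning a
#' subspecies hybrid zone.  `fixed_difference_panel()` returns loci fixed
#' for alternative alleles in the two pools (differential 1 at every
#' locus), the maximally informative design used for estimator
#' calibration.
#'
#' @param name locus name.
#' @param s_freqs,n_freqs named numeric vectors: allele frequencies
#'   (summing to 1) in the southern and northern pool; names are integer
#'   allele labels (fragment lengths).
#' @return `locus_spec()`: a list of class `locus_spec`;
#'   the panel helpers: a named list of `locus_spec`s.
#' @export
locus_spec <- function(name, s_freqs, n_freqs) {
  for (f in list(s_freqs, n_freqs)) {
    if (abs(sum(f) - 1) > 1e-9) stop_hz("allele frequencies must sum to 1")
    if (any(f < 0)) stop_hz("allele frequencies must be nonnegative")
    if (is.null(names(f))) stop_hz("allele frequencies must be named by allele")
  }
  alleles <- sort(unique(c(names(s_freqs), names(n_freqs))))
  s <- setNames(rep(0, length(alleles)), alleles); s[names(s_freqs)] <- s_freqs
  n <- setNames(rep(0, length(alleles)), alleles); n[names(n_freqs)] <- n_freqs
  structure(list(name = name, alleles = alleles, s = s, n = n,
                 differential = sum(abs(s - n)) / 2),
            class = "locus_spec")
}

# one locus with target differential d: two southern-associated and two
# northern-associated alleles, class mass split 0.7/0.3
delta_locus <- function(name, d, base = 151L) {
  al <- as.character(base + c(0L, 4L, 8L, 12L))
  s <- c((0.5 + d / 2) * c(0.7, 0.3), (0.5 - d / 2) * c(0.7, 0.3))
  n <- c((0.5 - d / 2) * c(0.7, 0.3), (0.5 + d / 2) * c(0.7, 0.3))
  locus_spec(name, setNames(s, al), setNames(n, al))
}

#' @rdname locus_spec
#' @export
default_locus_panel <- function() {
  deltas <- c(1, 0.95, 0.85, 0.7, 0.64, 0.57, 0.24, 0.2, 0.15)
  panel <- lapply(seq_along(deltas), function(i) {
    if (deltas[i] >= 1) {
      locus_spec(sprintf("ms%02d", i),
                 s_freqs = setNames(c(0.7, 0.3), c("151", "155")),
                 n_freqs = setNames(c(0.7, 0.3), c("163", "167")))
    } else delta_locus(sprintf("ms%02d", i), deltas[i], base = 131L + 10L * i)
  })
  names(panel) <- vapply(panel, `[[`, "", "name")
  panel
}

#' @rdname locus_spec
#' @param n_loci number of loci.
#' @export
fixed_difference_panel <- function(n_loci = 9L) {
  panel <- lapply(seq_len(n_loci), function(i) {
    locus_spec(sprintf("fd%02d", i),
               s_freqs = setNames(1, "151"), n_freqs = setNames(1, "163"))
  })
  names(panel) <- vapply(panel, `[[`, "", "name")
  panel
}

#' Along-coast killifish sampling transect
#'
#' The 13-site Atlantic-coast transect spanning the killifish
#' (*Fundulus heteroclitus*) subspecies hybrid zone, from Brunswick,
#' Georgia (0 km) to Hampton, New Hampshire (1631 km), with sampling
#' concentrated on the New Jersey contact zone.  Distances are
#' along-coast km from the southern reference; `n` are the study sample
#' sizes.  This is the default transect of the simulator.
#'
#' @return a site table data.frame: `site_id`, `name`, `distance_km`,
#'   `lat`, `lon`, `n`.
#' @export
killifish_transect <- function() {
  validate_site_table(data.frame(
    site_id = 1:13,
    name = c("Brunswick GA", "RUMFS NJ", "Laurel Harbour NJ",
             "Metedeconk Creek NJ", "Navesink River NJ", "Sandy Hook Bay NJ",
             "Belford Creek NJ", "Cheesequake Creek NJ", "Wantagh NY",
             "Housatonic River CT", "Rogers Creek CT", "Hammonassett Creek CT",
             "Hampton NH"),
    distance_km = c(0, 1145.77, 1186.03, 1208.94, 1228.41, 1231.88, 1242.06,
                    1257.54, 1285.31, 1357.23, 1363.41, 1393.09, 1631.00),
    lat = c(31.116130, 39.512905, 39.750349, 40.065616, 40.376297, 40.412904,
            40.440968, 40.463420, 40.638689, 41.173856, 41.213379, 41.251971,
            42.937055),
    lon = c(-81.462250, -74.320450, -74.192734, -74.065320, -73.993993,
            -73.969487, -74.103963, -74.258888, -73.563080, -73.103081,
            -73.057564, -72.537634, -70.839844),
    n = c(19, 50, 50, 49, 13, 50, 49, 50, 39, 22, 12, 48, 20)))
}

GENOTYPE_CLASSES <- c("P_S", "P_N", "F1", "F2", "BC_S", "BC_N")
CLASS_DOSE <- c(P_S = 0, P_N = 1, F1 = 0.5, F2 = 0.5, BC_S = 0.25, BC_N = 0.75)

#' Configuration of a synthetic hybrid zone
#'
#' Describes a generative model for hybrid-zone genotypes with known
#' truth, in one of two ancestry regimes:
#'
#' * `"clinal"` (hybrid-swarm regime): at a site at distance x, every
#'   allele copy is independently of northern origin with probability
#'   p(x) from an ancestry [cline_model()]; so is the mitotype.  Hybrid
#'   indices at intermediate sites are then unimodal around p(x).
#' * `"classes"` (reproductive-isolation regime): each individual is one
#'   of the genotype classes P_S, P_N (parentals), F1, F2, BC_S, BC_N
#'   (backcrosses) drawn from per-site class weights; F1s receive one
#'   gamete from each pool, F2s two F1 gametes (pool origin Bernoulli(1/2)
#'   per copy), backcrosses one F1 gamete and one pure gamete.  Weights
#'   concentrated on the parental classes produce the bimodal regime.
#'
#' The mitotype follows the maternal side of the class definition via
#' `mito_maternal`, the probability that each class's mother is northern
#' (parentals and backcross recurrent parents are fixed by definition;
#' F1/F2 default to an even chance).
#'
#' @param loci a locus panel (list of [locus_spec()]).
#' @param sites a site table; its `n` column gives per-site sample sizes.
#' @param ancestry either a [cline_model()] (clinal regime) or a vector /
#'   matrix of class weights (classes regime; a matrix has one row per
#'   site, columns named by class).
#' @param mito_maternal named probabilities that each class's mother is
#'   northern (classes regime only).
#' @param seed RNG seed.
#' @return list of class `hz_sim_config`.
#' @export
hz_sim_config <- function(loci = default_locus_panel(),
                          sites = killifish_transect(),
                          ancestry = cline_model(centre = 1217, width = 58),
                          mito_maternal = c(P_S = 0, P_N = 1, F1 = 0.5,
                                            F2 = 0.5, BC_S = 0, BC_N = 1),
                          seed = NULL) {
  sites <- validate_site_table(sites)
  if (any(is.na(sites$n))) stop_hz("site table needs per-site sample sizes n")
  if (inherits(ancestry, "cline_model")) {
    regime <- "clinal"
  } else {
    regime <- "classes"
    if (is.null(dim(ancestry))) {
      ancestry <- matrix(ancestry, nrow(sites), length(ancestry), byrow = TRUE,
                         dimnames = list(NULL, names(ancestry)))
    }
    if (!all(colnames(ancestry) %in% GENOTYPE_CLASSES))
      stop_hz("class weights must be named among: ",
              paste(GENOTYPE_CLASSES, collapse = ", "))
    if (any(ancestry < 0)) stop_hz("class weights must be nonnegative")
    if (any(abs(rowSums(ancestry) - 1) > 1e-9))
      stop_hz("class weights must sum to 1 per site")
    stopifnot(nrow(ancestry) == nrow(sites))
  }
  structure(list(loci = loci, sites = sites, ancestry = ancestry,
                 regime = regime, mito_maternal = mito_maternal, seed = seed),
            class = "hz_sim_config")
}

draw_alleles <- function(spec, pool, n) {
  f <- if (pool == "S") spec$s else spec$n
  as.integer(sample(spec$alleles, n, replace = TRUE, prob = f))
}

#' Simulate a hybrid zone with known truth
#'
#' Generates a [genotype_table()] under a [hz_sim_config()], together
#' with a truth table: the per-individual generating class (or expected
#' northern ancestry) and the per-site expected composite northern-allele
#' frequency per locus.
#'
#' @param config a [hz_sim_config()].
#' @return list of class `hz_simulation`: `table` (genotype_table),
#'   `truth` (list `individuals`, `site_freqs`), `config`.
#' @examples
#' sim <- simulate_hybrid_zone(hz_sim_config(seed = 42))
#' sim$table
#' @export
simulate_hybrid_zone <- function(config) {
  stopifnot(inherits(config, "hz_sim_config"))
  sites <- config$sites; loci <- config$loci
  with_seed(config$seed, {
    rows <- list(); truth <- list()
    for (si in seq_len(nrow(sites))) {
      ns <- sites$n[si]
      if (ns < 1) next
      ids <- sprintf("s%02d_i%03d", sites$site_id[si], seq_len(ns))
      if (config$regime == "clinal") {
        h <- cline_eval(config$ancestry, sites$distance_km[si])
        pool1 <- matrix(ifelse(runif(ns * length(loci)) < h, "N", "S"), ns)
        pool2 <- matrix(ifelse(runif(ns * length(loci)) < h, "N", "S"), ns)
        mito <- ifelse(runif(ns) < h, "N", "S")
        cls <- rep(NA_character_, ns)
        h_true <- rep(h, ns)
      } else {
        w <- config$ancestry[si, ]
        cls <- sample(colnames(config$ancestry), ns, replace = TRUE, prob = w)
        gam <- function(side) {
          # pool label of one gamete per locus for each individual
          vapply(cls, function(cl) {
            switch(cl,
                   P_S = rep("S", length(loci)),
                   P_N = rep("N", length(loci)),
                   F1 = rep(side, length(loci)),   # one gamete from each pool
                   F2 = ifelse(runif(length(loci)) < 0.5, "N", "S"),
                   BC_S = if (side == "S") rep("S", length(loci)) else
                     ifelse(runif(length(loci)) < 0.5, "N", "S"),
                   BC_N = if (side == "S") ifelse(runif(length(loci)) < 0.5,
                                                  "N", "S") else
                     rep("N", length(loci)))
          }, character(length(loci)))
        }
        pool1 <- t(gam("S")); pool2 <- t(gam("N"))
        pm <- config$mito_maternal[cls]
        mito <- ifelse(runif(ns) < pm, "N", "S")
        h_true <- unname(CLASS_DOSE[cls])
      }
      df <- data.frame(individual_id = ids, site_id = sites$site_id[si],
                       sex = NA_character_, year = NA_integer_, mito = mito,
                       stringsAsFactors = FALSE)
      for (li in seq_along(loci)) {
        spec <- loci[[li]]
        a1 <- integer(ns); a2 <- integer(ns)
        for (p in c("S", "N")) {
          k1 <- pool1[, li] == p
          if (any(k1)) a1[k1] <- draw_alleles(spec, p, sum(k1))
          k2 <- pool2[, li] == p
          if (any(k2)) a2[k2] <- draw_alleles(spec, p, sum(k2))
        }
        df[[paste0(spec$name, ".a1")]] <- a1
        df[[paste0(spec$name, ".a2")]] <- a2
      }
      rows[[si]] <- df
      truth[[si]] <- data.frame(individual_id = ids,
                                site_id = sites$site_id[si],
                                class = cls, h_true = h_true,
                                stringsAsFactors = FALSE)
    }
    tab <- genotype_table(do.call(rbind, rows), sites = sites)
    structure(list(table = tab,
                   truth = list(individuals = do.call(rbind, truth),
                                site_freqs = expected_site_freqs(config)),
                   config = config),
              class = "hz_simulation")
  })
}

# expected composite northern-allele frequency per site x locus
expected_site_freqs <- function(config) {
  sites <- config$sites
  hbar <- if (config$regime == "clinal") {
    cline_eval(config$ancestry, sites$distance_km)
  } else {
    as.vector(config$ancestry %*% CLASS_DOSE[colnames(config$ancestry)])
  }
  out <- expand.grid(site_id = sites$site_id,
                     locus = names(config$loci), stringsAsFactors = FALSE)
  out$h_expected <- hbar[match(out$site_id, sites$site_id)]
  # expected composite northern-allele frequency: h * p_N(A) + (1-h) * p_S(A)
  # with A the allele class more frequent in the northern pool
  pa <- vapply(config$loci, function(spec) {
    a_class <- spec$n - spec$s > 0
    c(N = sum(spec$n[a_class]), S = sum(spec$s[a_class]))
  }, numeric(2L))
  out$freq_a_expected <- out$h_expected * pa["N", out$locus] +
    (1 - out$h_expected) * pa["S", out$locus]
  out
}

#' @export
print.hz_simulation <- function(x, ...) {
  cat("Synthetic hybrid zone (", x$config$regime, " regime, seed ",
      x$config$seed %||% "NULL", ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Simulate parental reference pools
#'
#' Hardy-Weinberg genotypes for two pure parental samples (mitotype fixed
#' S and N respectively), placed at the transect ends.
#'
#' @param loci a locus panel (list of [locus_spec()]).
#' @param n_per_pool individuals per pool, `c(S = , N = )` or one number.
#' @param seed RNG seed.
#' @param distances transect positions of the two pool sites, km.
#' @return list of class `hz_simulation` (sites 1 = S, 2 = N).
#' @export
simulate_parental_pools <- function(loci = default_locus_panel(),
                                    n_per_pool = c(S = 50, N = 50),
                                    seed = NULL,
                                    distances = c(0, 1631)) {
  if (length(n_per_pool) == 1L) n_per_pool <- c(S = n_per_pool, N = n_per_pool)
  sites <- data.frame(site_id = 1:2, name = c("pool_S", "pool_N"),
                      distance_km = distances, lat = NA, lon = NA,
                      n = as.numeric(n_per_pool[c("S", "N")]))
  cfg <- hz_sim_config(loci = loci, sites = sites,
                       ancestry = matrix(c(1, 0, 0, 0, 0, 0,
                                           0, 1, 0, 0, 0, 0),
                                         2, 6, byrow = TRUE,
                                         dimnames = list(NULL, GENOTYPE_CLASSES)),
                       seed = seed)
  simulate_hybrid_zone(cfg)
}

#' Simulate per-site binomial allele counts under a cline
#'
#' @param cline a [cline_model()].
#' @param sites data.frame with columns `distance` (km) and `total`
#'   (allele copies per site).
#' @param seed RNG seed.
#' @return data.frame `distance`, `successes`, `total` ready for
#'   [fit_cline()].
#' @export
simulate_clinal_counts <- function(cline, sites, seed = NULL) {
  stopifnot(inherits(cline, "cline_model"))
  x <- cline_distance_col(sites)
  if (any(sites$total <= 0)) stop_hz("totals must be positive")
  p <- cline_eval(cline, x)
  with_seed(seed, data.frame(distance = x,
                             successes = rbinom(length(x), sites$total, p),
                             total = sites$total))
}

#' Preset simulation configurations
#'
#' `preset_bimodal_config()`: one central marsh of `n` individuals with
#' class weights 0.4/0.4 on the two parentals, 0.1 on F1 and 0.1 split
#' between the backcrosses, at nine fixed-difference loci - the
#' reproductive-isolation (bimodal) regime at its study sample size.
#' `preset_clinal_config()`: the same marsh under a pure ancestry cline
#' centred there (every allele copy independently northern with
#' probability p(x)), the hybrid-swarm (unimodal) control.  The control
#' uses the mixed multiallelic panel: with purely diagnostic loci the
#' hybrid index is confined to a coarse lattice of values, and the dip
#' test against its continuous uniform null reads those atoms as modes
#' regardless of the ancestry regime; the mixed panel restores the
#' quasi-continuous hybrid indices that real microsatellite data give.
#'
#' @param n individuals at the central marsh.
#' @param seed RNG seed.
#' @return a [hz_sim_config()].
#' @export
preset_bimodal_config <- function(n = 89L, seed = NULL) {
  sites <- data.frame(site_id = 4L, name = "central marsh",
                      distance_km = 1208.94, lat = NA, lon = NA, n = n)
  hz_sim_config(loci = fixed_difference_panel(9L), sites = sites,
                ancestry = matrix(c(P_S = 0.4, P_N = 0.4, F1 = 0.1, F2 = 0,
                                    BC_S = 0.05, BC_N = 0.05),
                                  1L, 6L,
                                  dimnames = list(NULL, GENOTYPE_CLASSES)),
                seed = seed)
}

#' @rdname preset_bimodal_config
#' @export
preset_clinal_config <- function(n = 89L, seed = NULL) {
  sites <- data.frame(site_id = 4L, name = "central marsh",
                      distance_km = 1208.94, lat = NA, lon = NA, n = n)
  hz_sim_config(loci = default_locus_panel(), sites = sites,
                ancestry = cline_model(centre = 1208.94, width = 58),
                seed = seed)
}

#' Parental allele frequencies from a simulation panel's truth
#'
#' Builds the [parental_frequencies()] object directly from the
#' generating [locus_spec()]s, for estimating hybrid indices against the
#' simulator's true parental gene pools (no sampling noise).
#'
#' @param loci a locus panel (list of [locus_spec()]).
#' @return a `parental_freqs` object.
#' @export
parental_frequencies_from_panel <- function(loci) {
  out <- lapply(loci, function(spec) {
    m <- rbind(S = spec$s, N = spec$n)
    colnames(m) <- spec$alleles
    m
  })
  names(out) <- vapply(loci, `[[`, "", "name")
  structure(out, pool_n = NULL, south_sites = NULL, north_sites = NULL,
            class = "parental_freqs")
}
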