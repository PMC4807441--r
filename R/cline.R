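#' Geographic cline models
#'
#' A sigmoid cline in allele frequency along a one-dimensional transect,
#' parameterized by its centre \eqn{c} (km, the inflection point), width
#' \eqn{w} (km, the inverse of the maximal slope of the scaled sigmoid),
#' and end frequencies \eqn{p_{min} \le p_{max}}:
#' \deqn{p(x) = p_{min} + (p_{max}-p_{min})\,\frac{1+\tanh(2(x-c)/w)}{2}.}
#' Four variants are used for fitting: `"null"` (flat frequency, one
#' parameter), `"I"` (ends fixed to supplied constants, no tails), `"II"`
#' (ends estimated, no tails), `"III"` (ends estimated plus exponential
#' introgression tails).  A tail replaces the sigmoid beyond
#' \eqn{c \pm \delta} by an exponential decay, continuous at the splice,
#' whose slope there is \eqn{\tau} times the sigmoid's
#' (\eqn{0 \le \tau \le 1}).
#'
#' @param centre cline centre, km.
#' @param width cline width, km (> 0).
#' @param p_min,p_max end frequencies, with `p_min <= p_max`.
#' @param variant `"null"`, `"I"`, `"II"` or `"III"`.
#' @param delta_l,tau_l,delta_r,tau_r left/right tail descriptors (variant
#'   III): splice distance from the centre (km, >= 0) and slope ratio in
#'   \[0, 1\].
#' @return an object of class `cline_model`.
#' @examples
#' m <- cline_model(centre = 1217.47, width = 57.89, p_min = 0, p_max = 0.98)
#' cline_eval(m, c(1100, 1217.47, 1400))
#' @export
cline_model <- function(centre, width, p_min = 0, p_max = 1,
                        variant = c("II", "null", "I", "III"),
                        delta_l = 0, tau_l = 1, delta_r = 0, tau_r = 1) {
  variant <- match.arg(variant)
  if (width <= 0) stop_hz("cline width must be > 0")
  if (p_min > p_max) stop_hz("p_min must not exceed p_max")
  if (p_min < 0 || p_max > 1) stop_hz("end frequencies must be in [0, 1]")
  if (delta_l < 0 || delta_r < 0) stop_hz("tail distances must be >= 0")
  if (tau_l < 0 || tau_l > 1 || tau_r < 0 || tau_r > 1)
    stop_hz("tail slope ratios must be in [0, 1]")
  structure(list(centre = centre, width = width, p_min = p_min, p_max = p_max,
                 variant = variant, delta_l = delta_l, tau_l = tau_l,
                 delta_r = delta_r, tau_r = tau_r),
            class = "cline_model")
}

#' @export
print.cline_model <- function(x, ...) {
  cat(sprintf("Cline (variant %s): centre %.2f km, width %.2f km, p_min %.3f, p_max %.3f\n",
              x$variant, x$centre, x$width, x$p_min, x$p_max))
  if (x$variant == "III")
    cat(sprintf("  tails: left delta %.1f tau %.2f | right delta %.1f tau %.2f\n",
                x$delta_l, x$tau_l, x$delta_r, x$tau_r))
  invisible(x)
}

# scaled sigmoid phi(x) in [0,1], with optional exponential tails
cline_phi <- function(x, centre, width, variant,
                      delta_l = 0, tau_l = 1, delta_r = 0, tau_r = 1) {
  phi0 <- function(z) (1 + tanh(2 * (z - centre) / width)) / 2
  dphi0 <- function(z) (1 / cosh(2 * (z - centre) / width))^2 / width
  phi <- phi0(x)
  if (variant == "III") {
    sl <- centre - delta_l
    left <- x < sl
    if (any(left)) {
      pl <- phi0(sl); dl <- dphi0(sl)
      phi[left] <- if (pl < 1e-12) pl else pl * exp(tau_l * dl * (x[left] - sl) / pl)
    }
    sr <- centre + delta_r
    right <- x > sr
    if (any(right)) {
      pr <- 1 - phi0(sr); dr <- dphi0(sr)
      phi[right] <- if (pr < 1e-12) 1 - pr else
        1 - pr * exp(-tau_r * dr * (x[right] - sr) / pr)
    }
  }
  phi
}

#' Evaluate a cline model at transect positions
#'
#' @param model a [cline_model()].
#' @param x positions (km along the transect).
#' @return expected allele frequencies in \[0, 1\].
#' @export
cline_eval <- function(model, x) {
  stopifnot(inherits(model, "cline_model"))
  if (model$variant == "null")
    return(rep((model$p_min + model$p_max) / 2, length(x)))
  phi <- cline_phi(x, model$centre, model$width, model$variant,
                   model$delta_l, model$tau_l, model$delta_r, model$tau_r)
  pmin(pmax(model$p_min + (model$p_max - model$p_min) * phi, 0), 1)
}

#' @export
predict.cline_model <- function(object, newdata = NULL, ...) {
  x <- if (is.data.frame(newdata)) cline_distance_col(newdata) else newdata
  cline_eval(object, x)
}

cline_distance_col <- function(data) {
  for (cand in c("distance", "distance_km")) if (!is.null(data[[cand]])) return(data[[cand]])
  stop_hz("data needs a 'distance' (or 'distance_km') column")
}

check_cline_data <- function(data) {
  x <- cline_distance_col(data)
  if (any(!is.finite(x))) stop_hz("distances must be finite")
  k <- data$successes; n <- data$total
  if (is.null(k) || is.null(n)) stop_hz("data needs 'successes' and 'total' columns")
  if (any(n <= 0)) stop_hz("totals must be positive")
  if (any(k < 0 | k > n)) stop_hz("successes must lie in [0, total]")
  data.frame(distance = x, successes = k, total = n)
}

#' Binomial log-likelihood of a cline model
#'
#' \eqn{\sum_{sites} [k \log p(x) + (n-k)\log(1-p(x))]} with \eqn{p}
#' clamped to \eqn{[10^{-9}, 1-10^{-9}]}; the binomial coefficient is
#' omitted (it cancels from all model comparisons).
#'
#' @param model a [cline_model()].
#' @param data data.frame with columns `distance` (km), `successes`,
#'   `total` (allele copies counted per site).
#' @return the log-likelihood (scalar).
#' @export
cline_loglik <- function(model, data) {
  data <- check_cline_data(data)
  p <- pmin(pmax(cline_eval(model, data$distance), 1e-9), 1 - 1e-9)
  sum(data$successes * log(p) + (data$total - data$successes) * log(1 - p))
}

# ---- fitting ---------------------------------------------------------------

variant_k <- c(null = 1L, I = 2L, II = 4L, III = 8L)

# builds the free-parameter spec for one variant with optionally fixed
# natural parameters (used both for fitting and for profile likelihoods)
cline_par_spec <- function(variant, fixed, bounds) {
  nm <- character(); lo <- numeric(); hi <- numeric()
  add <- function(n, l, h) { nm <<- c(nm, n); lo <<- c(lo, l); hi <<- c(hi, h) }
  if (!"centre" %in% names(fixed)) add("centre", bounds$centre[1L], bounds$centre[2L])
  if (!"width" %in% names(fixed)) add("logw", log(bounds$width[1L]), log(bounds$width[2L]))
  if (variant %in% c("II", "III")) {
    fmin <- "p_min" %in% names(fixed); fmax <- "p_max" %in% names(fixed)
    if (!fmin && !fmax) { add("m", 0, 1); add("s", 0, 1) }
    else if (fmin && !fmax) add("s", 0, 1)
    else if (!fmin && fmax) add("m2", 0, 1)
  }
  if (variant == "III") {
    for (p in c("delta_l", "delta_r"))
      if (!p %in% names(fixed)) add(p, 0, bounds$tail_max)
    for (p in c("tau_l", "tau_r"))
      if (!p %in% names(fixed)) add(p, 0, 1)
  }
  list(names = nm, lower = lo, upper = hi)
}

cline_par_to_model <- function(par, spec, variant, fixed) {
  g <- function(n) if (n %in% spec$names) par[[match(n, spec$names)]] else NULL
  centre <- fixed$centre %||% g("centre")
  width <- fixed$width %||% exp(g("logw"))
  if (variant %in% c("I", "null")) {
    p_min <- fixed$p_min; p_max <- fixed$p_max
  } else if (!is.null(g("m"))) {
    p_min <- g("m"); p_max <- p_min + (1 - p_min) * g("s")
  } else if (!is.null(g("s"))) {
    p_min <- fixed$p_min; p_max <- p_min + (1 - p_min) * g("s")
  } else if (!is.null(g("m2"))) {
    p_max <- fixed$p_max; p_min <- p_max * g("m2")
  } else {
    p_min <- fixed$p_min; p_max <- fixed$p_max
  }
  cline_model(centre, width, p_min, p_max, variant,
              delta_l = fixed$delta_l %||% g("delta_l") %||% 0,
              tau_l = fixed$tau_l %||% g("tau_l") %||% 1,
              delta_r = fixed$delta_r %||% g("delta_r") %||% 0,
              tau_r = fixed$tau_r %||% g("tau_r") %||% 1)
}

cline_default_bounds <- function(data, bounds = NULL) {
  rng <- range(data$distance)
  b <- list(centre = c(rng[1L] - 200, rng[2L] + 200), width = c(1, 3000),
            tail_max = diff(rng) + 200)
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  b
}

cline_starts <- function(data, spec, n_starts, seed) {
  # heuristic start: centre where the empirical frequency crosses midrange
  f <- data$successes / data$total
  o <- order(data$distance)
  fo <- f[o]; xo <- data$distance[o]
  mid <- (max(fo) + min(fo)) / 2
  cross <- which(diff(sign(fo - mid)) != 0)
  c0 <- if (length(cross)) mean(xo[c(cross[1L], cross[1L] + 1L)]) else mean(xo)
  w0 <- max(diff(range(xo)) / 5, 2)
  base <- vapply(seq_along(spec$names), function(i) {
    switch(spec$names[i],
           centre = min(max(c0, spec$lower[i]), spec$upper[i]),
           logw = min(max(log(w0), spec$lower[i]), spec$upper[i]),
           m = max(min(fo), 0.001), s = 0.9,
           m2 = 0.1, delta_l = w0, delta_r = w0, tau_l = 0.5, tau_r = 0.5)
  }, 0)
  starts <- list(base)
  if (n_starts > 1L) {
    rand <- with_seed(seed, lapply(seq_len(n_starts - 1L), function(i) {
      runif(length(spec$names), spec$lower, spec$upper)
    }))
    starts <- c(starts, rand)
  }
  starts
}

# translate a fitted model into the free-parameter vector of a (possibly
# profiled) spec, for warm starts
model_to_free_par <- function(spec, model, fixed) {
  vapply(seq_along(spec$names), function(i) {
    v <- switch(spec$names[i],
      centre = model$centre,
      logw = log(model$width),
      m = model$p_min,
      s = {
        base <- fixed$p_min %||% model$p_min
        (model$p_max - base) / max(1 - base, 1e-9)
      },
      m2 = model$p_min / max(fixed$p_max %||% model$p_max, 1e-9),
      delta_l = model$delta_l, tau_l = model$tau_l,
      delta_r = model$delta_r, tau_r = model$tau_r)
    min(max(v, spec$lower[i]), spec$upper[i])
  }, 0)
}

cline_optim <- function(data, variant, fixed, bounds, n_starts, seed,
                        warm_model = NULL) {
  spec <- cline_par_spec(variant, fixed, bounds)
  nll <- function(par) {
    m <- try(cline_par_to_model(par, spec, variant, fixed), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    v <- -cline_loglik(m, data)
    if (!is.finite(v)) 1e10 else v
  }
  if (!length(spec$names)) {
    m <- cline_par_to_model(numeric(0), spec, variant, fixed)
    return(list(model = m, logLik = cline_loglik(m, data), converged = TRUE,
                value = -cline_loglik(m, data), n_ok = 1L))
  }
  starts <- if (n_starts > 0L) cline_starts(data, spec, n_starts, seed) else list()
  if (!is.null(warm_model))
    starts <- c(list(model_to_free_par(spec, warm_model, fixed)), starts)
  best <- NULL; n_ok <- 0L
  for (st in starts) {
    fit <- try(optim(st, nll, method = "L-BFGS-B", lower = spec$lower,
                     upper = spec$upper,
                     control = list(maxit = 500, factr = 1e9)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_hz("cline fit failed to converge from any of ", length(starts), " starts")
  model <- cline_par_to_model(best$par, spec, variant, fixed)
  list(model = model, logLik = -best$value, converged = best$convergence == 0,
       value = best$value, n_ok = n_ok)
}

#' Fit a geographic cline by maximum likelihood
#'
#' Bounded multi-start quasi-Newton maximization of the binomial
#' log-likelihood [cline_loglik()] for one of the four model variants (see
#' [cline_model()]).  The fit is deterministic given `seed`.  Two-unit
#' support limits (profile likelihood) are available through
#' [confint.cline_fit()] / [support_interval()].
#'
#' @param data data.frame with columns `distance` (km; `distance_km` also
#'   accepted), `successes` and `total` allele counts per site.
#' @param variant `"null"`, `"I"`, `"II"` (default) or `"III"`.
#' @param fixed_ends for variant I: `c(p_min, p_max)`.  Defaults to the
#'   observed frequencies at the two transect-end sites.
#' @param n_starts number of optimizer starts (first is a data-driven
#'   heuristic, the rest seeded random points in the box).
#' @param seed RNG seed controlling the random starts.
#' @param bounds optional list overriding the default box: `centre`
#'   (range, default data range widened by 200 km), `width` (default
#'   \[1, 3000\] km), `tail_max`.
#' @return object of class `cline_fit` with components `model` (the MLE as
#'   a [cline_model()]), `logLik`, `aic`, `k`, `data`, `variant`, `bounds`,
#'   `seed`, `converged`.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `simulate`, `residuals`, `logLik`, `confint`.
#' @examples
#' d <- data.frame(distance = seq(0, 600, by = 50), total = 40)
#' d$successes <- rbinom(nrow(d), d$total,
#'                       cline_eval(cline_model(300, 80), d$distance))
#' fit <- fit_cline(d, "II", seed = 1)
#' coef(fit)
#' @export
fit_cline <- function(data, variant = c("II", "null", "I", "III"),
                      fixed_ends = NULL, n_starts = 10L, seed = NULL,
                      bounds = NULL) {
  variant <- match.arg(variant)
  data <- check_cline_data(data)
  n_distinct <- length(unique(data$distance))
  if (variant == "null" && n_distinct < 2L)
    stop_hz("null-variant fit needs at least 2 sites")
  if (variant != "null" && n_distinct < 3L)
    stop_hz("cline fit needs at least 3 sites with distinct distances")
  bounds <- cline_default_bounds(data, bounds)

  if (variant == "null") {
    phat <- sum(data$successes) / sum(data$total)
    model <- cline_model(mean(range(data$distance)), diff(range(data$distance)) + 1,
                         p_min = phat, p_max = phat, variant = "null")
    ll <- cline_loglik(model, data)
    opt <- list(model = model, logLik = ll, converged = TRUE, n_ok = 1L)
    fixed <- list(p_min = phat, p_max = phat)
  } else {
    fixed <- list()
    if (variant == "I") {
      if (is.null(fixed_ends)) {
        o <- order(data$distance)
        fixed_ends <- c(data$successes[o[1L]] / data$total[o[1L]],
                        data$successes[o[length(o)]] / data$total[o[length(o)]])
      }
      fixed_ends <- sort(as.numeric(fixed_ends))
      fixed <- list(p_min = fixed_ends[1L], p_max = fixed_ends[2L])
    }
    opt <- cline_optim(data, variant, fixed, bounds, n_starts, seed)
  }
  k <- variant_k[[variant]]
  structure(list(model = opt$model, logLik = opt$logLik,
                 aic = 2 * k - 2 * opt$logLik, k = k, data = data,
                 variant = variant, fixed = fixed, bounds = bounds,
                 seed = seed, n_starts = n_starts, converged = opt$converged,
                 n_starts_ok = opt$n_ok),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("ML cline fit, variant %s (k = %d)\n", x$variant, x$k))
  print(x$model)
  cat(sprintf("  logLik %.3f, AIC %.3f, %d sites%s\n", x$logLik, x$aic,
              nrow(x$data), if (x$converged) "" else "  [optimizer warning]"))
  invisible(x)
}

#' @export
coef.cline_fit <- function(object, ...) {
  m <- object$model
  out <- c(centre = m$centre, width = m$width, p_min = m$p_min, p_max = m$p_max)
  if (object$variant == "III")
    out <- c(out, delta_l = m$delta_l, tau_l = m$tau_l,
             delta_r = m$delta_r, tau_r = m$tau_r)
  out
}

#' @export
logLik.cline_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = nrow(object$data),
            class = "logLik")
}

#' @export
predict.cline_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$distance
       else if (is.data.frame(newdata)) cline_distance_col(newdata)
       else newdata
  cline_eval(object$model, x)
}

#' @export
residuals.cline_fit <- function(object, type = c("pearson", "deviance", "response"), ...) {
  type <- match.arg(type)
  d <- object$data
  p <- pmin(pmax(predict(object), 1e-9), 1 - 1e-9)
  obs <- d$successes / d$total
  switch(type,
    response = obs - p,
    pearson = (obs - p) / sqrt(p * (1 - p) / d$total),
    deviance = {
      ll_sat <- ifelse(d$successes == 0, 0, d$successes * log(obs)) +
        ifelse(d$successes == d$total, 0, (d$total - d$successes) * log(1 - obs))
      ll_mod <- d$successes * log(p) + (d$total - d$successes) * log(1 - p)
      sign(obs - p) * sqrt(pmax(2 * (ll_sat - ll_mod), 0))
    })
}

#' @export
simulate.cline_fit <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$data
  p <- predict(object)
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, rbinom(nrow(d), d$total, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    cbind(d[c("distance", "total")], out)
  })
}

#' @export
plot.cline_fit <- function(x, ..., npoints = 200L) {
  d <- x$data
  xs <- seq(min(d$distance), max(d$distance), length.out = npoints)
  plot(d$distance, d$successes / d$total, xlab = "distance (km)",
       ylab = "allele frequency", ylim = c(0, 1),
       cex = 0.5 + sqrt(d$total) / 10, ...)
  lines(xs, cline_eval(x$model, xs), lwd = 2)
  abline(v = x$model$centre, lty = 3)
  invisible(x)
}

#' @export
summary.cline_fit <- function(object, support = TRUE, ...) {
  ci <- if (support) try(confint(object), silent = TRUE) else NULL
  if (inherits(ci, "try-error")) ci <- NULL
  structure(list(fit = object, support = ci), class = "summary.cline_fit")
}

#' @export
print.summary.cline_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$support)) {
    cat("2-unit support limits:\n")
    print(round(x$support, 3))
  }
  invisible(x)
}

# ---- profile likelihood support limits ------------------------------------

# generic walk+root machinery: f is a profile log-likelihood with maximum
# f(mle); returns the widest contiguous interval with f >= f(mle) - drop
support_limits_fn <- function(f, mle, lower, upper, drop = 2, f_max = NULL,
                              rel_tol = 1e-4) {
  if (is.null(f_max)) f_max <- f(mle)
  target <- f_max - drop
  one_side <- function(dir) {
    bound <- if (dir > 0) upper else lower
    if (abs(bound - mle) < .Machine$double.eps) return(c(bound, TRUE))
    step <- abs(bound - mle) / 64
    prev <- mle; v <- mle
    repeat {
      v <- v + dir * step
      hit_bound <- (dir > 0 && v >= bound) || (dir < 0 && v <= bound)
      if (hit_bound) v <- bound
      fv <- f(v)
      if (fv < target) {
        root <- uniroot(function(z) f(z) - target, c(min(prev, v), max(prev, v)),
                        tol = max(abs(upper - lower) * rel_tol / 20, 1e-10))$root
        return(c(root, FALSE))
      }
      if (hit_bound) return(c(bound, TRUE))
      prev <- v
      step <- step * 1.6
    }
  }
  lo <- one_side(-1); hi <- one_side(1)
  structure(c(lo[1L], hi[1L]),
            clipped = c(lower = as.logical(lo[2L]), upper = as.logical(hi[2L])))
}

#' Two-unit support interval
#'
#' The widest contiguous interval around the maximum-likelihood estimate
#' within which the profile log-likelihood stays within `drop` (default 2)
#' units of its maximum.  For a `cline_fit`, the profile re-maximizes the
#' likelihood over the remaining free parameters at each value of the
#' target parameter.  Intervals clipped at a parameter bound carry a
#' `clipped` attribute.
#'
#' @param object a `cline_fit`, or a function (the profile log-likelihood
#'   itself, e.g. a toy closed-form profile).
#' @param parm parameter name (`"centre"`, `"width"`, `"p_min"`,
#'   `"p_max"`) when `object` is a fit; ignored for functions.
#' @param mle,lower,upper for the function interface: the maximizer and the
#'   search bounds.
#' @param drop log-likelihood drop defining the interval (2 = 2-unit
#'   support, roughly a 95 percent confidence interval).
#' @return numeric `c(lower, upper)` with attribute `clipped`.
#' @export
support_interval <- function(object, parm = "centre", mle = NULL,
                             lower = NULL, upper = NULL, drop = 2) {
  if (is.function(object)) {
    if (is.null(mle) || is.null(lower) || is.null(upper))
      stop_hz("the function interface needs mle, lower and upper")
    return(support_limits_fn(object, mle, lower, upper, drop = drop,
                             rel_tol = 1e-6))
  }
  stopifnot(inherits(object, "cline_fit"))
  ci <- confint(object, parm = parm, drop = drop)
  structure(ci[1L, ], clipped = attr(ci, "clipped")[parm, ])
}

#' @rdname support_interval
#' @param level unused (the interval is defined by `drop`, not a coverage
#'   level).
#' @export
confint.cline_fit <- function(object, parm = NULL, level = NULL, drop = 2, ...) {
  free <- switch(object$variant,
                 null = character(0),
                 I = c("centre", "width"),
                 II = c("centre", "width", "p_min", "p_max"),
                 III = c("centre", "width", "p_min", "p_max"))
  parm <- parm %||% free
  parm <- intersect(parm, free)
  if (!length(parm)) stop_hz("no free parameters to profile for this variant")
  b <- object$bounds
  box <- list(centre = b$centre, width = b$width, p_min = c(0, 1), p_max = c(0, 1))
  out <- matrix(NA_real_, length(parm), 2L,
                dimnames = list(parm, c("lower", "upper")))
  clip <- matrix(FALSE, length(parm), 2L,
                 dimnames = list(parm, c("lower", "upper")))
  for (pm in parm) {
    prof <- function(v) {
      fixed <- object$fixed
      fixed[[pm]] <- v
      opt <- try(cline_optim(object$data, object$variant, fixed, object$bounds,
                             n_starts = 0L, seed = object$seed,
                             warm_model = object$model), silent = TRUE)
      if (inherits(opt, "try-error")) -Inf else opt$logLik
    }
    mle <- coef(object)[[pm]]
    lim <- support_limits_fn(prof, mle, box[[pm]][1L], box[[pm]][2L],
                             drop = drop, f_max = object$logLik)
    out[pm, ] <- lim
    clip[pm, ] <- attr(lim, "clipped")
  }
  structure(out, clipped = clip)
}

# ---- model selection and neutral width ------------------------------------

#' Select the best cline variant by AIC
#'
#' Picks the variant with the lowest AIC; exact ties are broken toward the
#' variant with fewer free parameters (null < I < II < III).
#'
#' @param fits either a named list of [fit_cline()] results or a named
#'   numeric vector of AIC values, with names among `null`, `I`, `II`,
#'   `III`.
#' @return the winning variant name, with the AIC table as attribute
#'   `aic`.
#' @examples
#' select_cline_model(c(null = 26.395, I = 21.223, II = 15.922, III = 24.875))
#' @export
select_cline_model <- function(fits) {
  if (length(fits) == 0L) stop_hz("no fitted variants supplied")
  aic <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$aic, 0)
  if (is.null(names(aic)) || !all(names(aic) %in% names(variant_k)))
    stop_hz("variants must be named among: ", paste(names(variant_k), collapse = ", "))
  if (length(aic) < 2L) stop_hz("need at least two fitted variants")
  k <- variant_k[names(aic)]
  ord <- order(aic, k)
  structure(names(aic)[ord[1L]], aic = aic)
}

#' Width of a neutral cline
#'
#' Under neutral diffusion after secondary contact, a cline relaxes to
#' width \eqn{w = \sigma\sqrt{2\pi T}} after \eqn{T} generations with
#' per-generation dispersal \eqn{\sigma}; equivalently
#' \eqn{T = (w / (\sqrt{2\pi}\,\sigma))^2}.  Observed widths significantly
#' below the neutral expectation indicate that selection maintains the
#' cline.
#'
#' @param T generations since secondary contact (> 0).
#' @param sigma dispersal distance per generation, km (> 0).
#' @return expected neutral cline width, km.
#' @examples
#' neutral_cline_width(T = 15000, sigma = 2)  # ~614 km
#' @export
neutral_cline_width <- function(T, sigma) {
  if (any(T <= 0) || any(sigma <= 0)) stop_hz("T and sigma must be positive")
  sigma * sqrt(2 * pi * T)
}

#' @rdname neutral_cline_width
#' @param w observed cline width, km (> 0).
#' @return `time_since_contact()`: the number of generations a neutral
#'   cline would need to reach width `w`.
#' @export
time_since_contact <- function(w, sigma) {
  if (any(w <= 0) || any(sigma <= 0)) stop_hz("w and sigma must be positive")
  (w / (sqrt(2 * pi) * sigma))^2
}

# ---- genotype-table bridge -------------------------------------------------

#' Per-site cline input counts for one locus
#'
#' Builds the `(distance, successes, total)` table that [fit_cline()]
#' consumes: for the mitochondrial marker, counts of the northern type;
#' for a nuclear locus, counts of the composite pool-A allele class after
#' [diallelic_reduction()].  The fitted frequency therefore rises with
#' distance when pool A is the northern pool.
#'
#' @param x a [genotype_table()] with a site table attached.
#' @param locus locus name (or `"mtDNA"`).
#' @param diff a [frequency_differential()] table (needed for nuclear
#'   loci).
#' @param sex optionally restrict to one sex label.
#' @return data.frame: `site_id`, `distance`, `successes`, `total`.
#' @export
cline_data <- function(x, locus, diff = NULL, sex = NULL) {
  sites <- gt_sites(x)
  if (is.null(sites)) stop_hz("genotype table has no site table attached")
  if (!is.null(sex)) {
    x <- genotype_table(as.data.frame(x)[!is.na(x$sex) & x$sex == sex, ,
                                         drop = FALSE],
                        loci = gt_loci(x), sites = sites)
  }
  af <- allele_frequencies(x)
  if (locus == "mtDNA") {
    sub <- af[af$locus == "mtDNA", ]
    succ <- sub[sub$allele == "N", c("group", "count")]
    tot <- unique(sub[c("group", "total")])
    d <- merge(tot, succ, by = "group", all.x = TRUE)
    d$count[is.na(d$count)] <- 0L
    out <- data.frame(site_id = as.integer(d$group), successes = d$count,
                      total = d$total)
  } else {
    if (is.null(diff)) stop_hz("nuclear loci need a frequency_differential table")
    red <- diallelic_reduction(af, diff)
    red <- red[red$locus == locus, ]
    if (!nrow(red)) stop_hz("locus ", locus, " is non-informative or untyped")
    out <- data.frame(site_id = as.integer(red$group), successes = red$count_a,
                      total = red$total)
  }
  out$distance <- sites$distance_km[match(out$site_id, sites$site_id)]
  out[order(out$distance), c("site_id", "distance", "successes", "total")]
}
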