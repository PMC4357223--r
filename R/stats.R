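#' Length-normalized mutation scores
#'
#' s_d = m_d / L_d, mutations per genomic base pair, where L_d is the
#' cumulative footprint length of domain d over all its occurrences.
#' Larger domain families accumulate more mutations by footprint alone;
#' this normalization removes that.
#'
#' @param counts A `domain_mutation_counts` object (or a data.frame with
#'   `domain_acc`, `m`).
#' @param footprints A `domain_footprints` object supplying L_d.
#' @return data.frame `domain_acc`, `m`, `L`, `s`. Domains with L = 0
#'   are excluded (message); m > 0 with L = 0 is a consistency error.
#' @export
normalize_counts <- function(counts, footprints) {
  cdf <- if (inherits(counts, "domain_mutation_counts")) counts$counts else counts
  L <- footprints$cumulative_length[cdf$domain_acc]
  L[is.na(L)] <- 0L
  if (any(cdf$m > 0L & L == 0L))
    stop2("normalize_counts: domain with mutations but zero footprint: ",
          cdf$domain_acc[cdf$m > 0L & L == 0L][1L])
  if (any(L == 0L)) {
    message("normalize_counts: excluding ", sum(L == 0L),
            " domain(s) with zero footprint")
  }
  keep <- L > 0L
  data.frame(domain_acc = cdf$domain_acc[keep], m = cdf$m[keep],
             L = as.integer(L[keep]), s = cdf$m[keep] / L[keep])
}

#' Bernoulli signal-to-noise z statistic
#'
#' Normalized scores are turned into relative frequencies
#' p_d = s_d / sum(s) (a probability over domains), and each p is
#' converted to the signal-to-noise ratio of a Bernoulli(p) variable,
#' z = p / sqrt(p (1 - p)) = sqrt(p / (1 - p)), a strictly increasing
#' transform of the normalized mutation rate.
#'
#' @param s_table Output of [normalize_counts()].
#' @return The table with columns `p` and `z` appended.
#' @export
z_scores <- function(s_table) {
  tot <- sum(s_table$s)
  if (tot <= 0) stop2("z_scores: all normalized scores are zero")
  p <- s_table$s / tot
  if (any(p >= 1))
    stop2("z_scores: degenerate case p = 1 (single mutated domain)")
  s_table$p <- p
  s_table$z <- ifelse(p == 0, 0, p / sqrt(p * (1 - p)))  # z = 0 iff m = 0
  s_table
}

#' Empirical-null local false discovery rate
#'
#' Fits the marginal density f(z) by Poisson regression of histogram bin
#' counts on a polynomial basis of the bin midpoints, estimates an
#' empirical null f0 = Normal(delta0, sigma0) with null proportion pi0
#' by central matching (a quadratic fit of log f over the central bins
#' around its mode), and returns lfdr(z) = min(1, pi0 f0(z) / f(z)),
#' interpolated between bin midpoints. With `null_method =
#' "theoretical"` the null is fixed at Normal(0, 1) and only pi0 is
#' estimated from the central bins.
#'
#' @param z Finite numeric vector of statistics (>= 200 values).
#' @param bins Histogram bin count (default 120).
#' @param poly_degree Degree of the polynomial Poisson regression
#'   (default 7).
#' @param null_method "central-matching" (empirical null) or
#'   "theoretical" (standard normal null).
#' @param transform "identity" fits on z as given; "log" fits on log(z)
#'   for z > 0 (non-positive z get lfdr 1) — useful when z is a strictly
#'   positive rate-like statistic.
#' @return Object of class `lfdr_fit` with elements `pi0`, `delta0`,
#'   `sigma0`, `bins`, `poly_degree`, `transform`, `breaks`, `mids`,
#'   `f` (fitted marginal density at mids), `f0` (null density at
#'   mids), `lfdr_fun` (function z -> lfdr).
#' @export
fit_lfdr <- function(z, bins = 120, poly_degree = 7,
                     null_method = c("central-matching", "theoretical"),
                     transform = c("identity", "log")) {
  null_method <- match.arg(null_method)
  transform <- match.arg(transform)
  if (any(!is.finite(z))) stop2("fit_lfdr: non-finite z values")
  x <- z
  pos <- rep(TRUE, length(z))
  if (transform == "log") {
    pos <- z > 0
    x <- log(z[pos])
  }
  if (length(x) < 200L)
    stop2("fit_lfdr: need >= 200 finite statistics (have ", length(x),
          "); with so few cases use an exact test instead")
  if (stats::sd(x) < 1e-12) stop2("fit_lfdr: degenerate z spread (sd ~ 0)")
  breaks <- seq(min(x), max(x), length.out = bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  bw <- diff(breaks)[1L]
  basis <- stats::poly(mids, degree = poly_degree)
  fit <- suppressWarnings(
    stats::glm(counts ~ basis, family = stats::poisson()))
  f <- as.numeric(stats::fitted(fit)) / (length(x) * bw)  # density scale
  logf <- log(pmax(f, 1e-300))
  # central bins: between the 25% and 75% quantiles of the data
  qs <- stats::quantile(x, c(0.25, 0.75))
  central <- mids >= qs[1L] & mids <= qs[2L]
  if (sum(central) < 5L) {
    central <- rank(abs(mids - mids[which.max(f)])) <= max(5L, bins %/% 4L)
  }
  if (null_method == "central-matching") {
    cf <- stats::lm(logf[central] ~ mids[central] + I(mids[central]^2))
    b <- stats::coef(cf)
    if (!is.finite(b[3L]) || b[3L] >= 0)
      stop2("fit_lfdr: central matching failed (no concave peak); ",
            "try transform = 'log' or the theoretical null")
    sigma0 <- sqrt(-1 / (2 * b[3L]))
    delta0 <- b[2L] * sigma0^2
    pi0 <- min(1, exp(b[1L] + delta0^2 / (2 * sigma0^2)) *
                 sigma0 * sqrt(2 * pi))
  } else {
    delta0 <- 0; sigma0 <- 1
    lf0 <- stats::dnorm(mids[central], log = TRUE)
    pi0 <- min(1, exp(stats::median(logf[central] - lf0)))
  }
  f0 <- stats::dnorm(mids, delta0, sigma0)
  lfdr_mid <- pmin(1, pmax(0, pi0 * f0 / pmax(f, 1e-300)))
  interp <- stats::approxfun(mids, lfdr_mid, rule = 2)
  lfdr_fun <- if (transform == "log") {
    function(zv) ifelse(zv > 0, interp(log(zv)), 1)
  } else {
    interp
  }
  structure(list(pi0 = unname(pi0), delta0 = unname(delta0),
                 sigma0 = unname(sigma0), bins = bins,
                 poly_degree = poly_degree, transform = transform,
                 null_method = null_method, breaks = breaks, mids = mids,
                 f = f, f0 = f0, lfdr_fun = lfdr_fun),
            class = "lfdr_fit")
}

#' @export
print.lfdr_fit <- function(x, ...) {
  cat(sprintf(
    "Empirical-null lfdr fit (%s, %s scale): pi0 = %.3f, null = N(%.4g, %.4g)\n",
    x$null_method, x$transform, x$pi0, x$delta0, x$sigma0))
  invisible(x)
}

#' Per-domain mutation statistics with lfdr
#'
#' Chains [normalize_counts()], [z_scores()] and [fit_lfdr()] into the
#' per-domain stats table and flags significance at `lfdr <
#' lfdr_threshold` (strict).
#'
#' @inheritParams normalize_counts
#' @inheritParams fit_lfdr
#' @param lfdr_threshold Significance cutoff on the local fdr
#'   (default 0.1).
#' @return list of class `domain_stats`: `table` (domain_acc, m, L, s,
#'   p, z, lfdr, significant — sorted by accession), `fit` (the
#'   `lfdr_fit`), `threshold`.
#' @export
domain_stats <- function(counts, footprints, lfdr_threshold = 0.1,
                         bins = 120, poly_degree = 7,
                         null_method = "central-matching",
                         transform = "identity") {
  tab <- z_scores(normalize_counts(counts, footprints))
  fit <- fit_lfdr(tab$z, bins = bins, poly_degree = poly_degree,
                  null_method = null_method, transform = transform)
  tab$lfdr <- fit$lfdr_fun(tab$z)
  tab$significant <- tab$lfdr < lfdr_threshold
  tab <- tab[order(tab$domain_acc), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, threshold = lfdr_threshold),
            class = "domain_stats")
}

#' @export
print.domain_stats <- function(x, ...) {
  cat("Domain mutation statistics:", nrow(x$table), "domains,",
      sum(x$table$significant), "significant at lfdr <", x$threshold, "\n")
  print(x$fit)
  invisible(x)
}

#' Significantly mutated domains
#'
#' Domains with lfdr strictly below the threshold, sorted by lfdr
#' ascending, ties by z descending, then accession.
#'
#' @param stats A `domain_stats` object (or its `table`).
#' @param lfdr_threshold Cutoff (default 0.1; strict `<`).
#' @return Character vector of domain accessions.
#' @export
call_significant <- function(stats, lfdr_threshold = 0.1) {
  tab <- if (inherits(stats, "domain_stats")) stats$table else stats
  hit <- tab[tab$lfdr < lfdr_threshold, , drop = FALSE]
  hit <- hit[order(hit$lfdr, -hit$z, hit$domain_acc), ]
  hit$domain_acc
}

#' Overlap structure of per-condition significant sets
#'
#' For c conditions, counts every one of the 2^c - 1 exclusive overlap
#' regions (as in a Venn diagram) and returns the full intersection.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return list with `regions` (data.frame `region` — condition names
#'   joined by "&" — and `size`), `intersection` (sorted members common
#'   to all), `union_size`.
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2L) stop2("overlap_sets: need >= 2 conditions")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  univ <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1L,
                                         dimnames = list(NULL, names(sets)))
  cn <- names(sets)
  combos <- unlist(lapply(seq_along(cn), function(k)
    utils::combn(cn, k, simplify = FALSE)), recursive = FALSE)
  regions <- data.frame(
    region = vapply(combos, paste, "", collapse = "&"),
    size = vapply(combos, function(co) {
      inside <- rowSums(memb[, co, drop = FALSE]) == length(co)
      outside <- rowSums(memb[, setdiff(cn, co), drop = FALSE]) == 0
      sum(inside & outside)
    }, 0L))
  inter <- univ[rowSums(memb) == length(sets)]
  list(regions = regions, intersection = inter, union_size = length(univ))
}
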