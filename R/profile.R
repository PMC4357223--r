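#' Per-core profiles of mutation burden, conservation and significance
#'
#' For each nested core order k, computes the mean normalized mutation
#' score, the percentage of conserved domains and the percentage of
#' significantly mutated domains over the core members, each compared
#' with its size-matched randomized ensemble (mean, sd, z, add-one
#' empirical p).
#'
#' @param decomposition A `core_decomposition` of the analyzed graph.
#' @param ensembles Matching `core_ensembles`.
#' @param stats A `domain_stats` object (or its table); domains absent
#'   from it get s = 0.
#' @param conservation Optional conservation label table (`domain_acc`,
#'   `conserved`); missing domains count as not conserved.
#' @param significant Optional character vector of significant domains
#'   (defaults to the flags in `stats`).
#' @param alternative Extremity rule for empirical p-values (see
#'   [core_attribute_profile()]).
#' @return Object of class `core_profile`: `table` (one row per k with
#'   columns `<quantity>`, `<quantity>_ens_mean`, `_ens_sd`, `_z`,
#'   `_p` for mean_s / pct_conserved / pct_significant) and
#'   `replicate_stats` (per quantity, a k_max x n_replicates matrix of
#'   the statistic on each random replicate, used by [trend_test()]).
#' @export
profile_cores <- function(decomposition, ensembles, stats,
                          conservation = NULL, significant = NULL,
                          alternative = "two.sided") {
  tab <- if (inherits(stats, "domain_stats")) stats$table else stats
  nodes <- decomposition$nodes
  if (!any(nodes %in% tab$domain_acc))
    stop2("profile_cores: stats table and decomposition share no domains")
  s_attr <- stats::setNames(tab$s, tab$domain_acc)
  attrs <- list(mean_s = s_attr)
  if (!is.null(conservation)) {
    attrs$pct_conserved <- stats::setNames(as.logical(conservation$conserved),
                                           conservation$domain_acc)
  }
  if (is.null(significant) && !is.null(tab$significant))
    significant <- tab$domain_acc[tab$significant]
  if (!is.null(significant)) {
    attrs$pct_significant <- stats::setNames(nodes %in% significant, nodes)
  }
  out <- NULL
  reps <- list()
  for (qn in names(attrs)) {
    prof <- core_attribute_profile(decomposition, ensembles, attrs[[qn]],
                                   alternative = alternative)
    reps[[qn]] <- replicate_stat_matrix(decomposition, ensembles,
                                        attrs[[qn]])
    colnames(prof) <- c("k", "N_k", qn, paste0(qn, c("_ens_mean",
                                                     "_ens_sd", "_z",
                                                     "_p")))
    out <- if (is.null(out)) prof else merge(out, prof,
                                             by = c("k", "N_k"),
                                             sort = TRUE)
  }
  structure(list(table = out[order(out$k), ], replicate_stats = reps,
                 attributes = attrs, n_replicates = ensembles$n_replicates),
            class = "core_profile")
}

# k_max x n_replicates matrix of the per-core statistic on each replicate
replicate_stat_matrix <- function(decomposition, ensembles, attribute) {
  miss <- setdiff(decomposition$nodes, names(attribute))
  if (length(miss)) {
    add <- rep(if (is.logical(attribute)) FALSE else 0, length(miss))
    names(add) <- miss
    attribute <- c(attribute, add)
  }
  ks <- seq_len(decomposition$k_max)
  t(vapply(ks, function(k) {
    vapply(ensembles$ensembles[[as.character(k)]],
           function(mbr) core_stat(attribute, mbr),
           0)
  }, numeric(ensembles$n_replicates)))
}

#' Randomization trend test across core orders
#'
#' Spearman rank correlation between core order k and a per-core
#' quantity, with the null distribution obtained by recomputing the
#' same correlation on each randomized replicate ensemble (replicate r
#' supplies one statistic per core). Add-one empirical p.
#'
#' @param profile A `core_profile`.
#' @param quantity Column to test: "mean_s", "pct_conserved" or
#'   "pct_significant".
#' @param alternative "two.sided" (default), "less" (decreasing trend)
#'   or "greater".
#' @return list of class `trend_test_result`: `statistic` (Spearman
#'   rho), `p_empirical`, `direction` ("decreasing", "increasing" or
#'   "none"), `null_statistics`.
#' @export
trend_test <- function(profile, quantity = "mean_s",
                       alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  tab <- profile$table
  if (nrow(tab) < 3L) stop2("trend_test: need >= 3 core orders")
  if (!quantity %in% names(tab)) stop2("trend_test: unknown quantity")
  y <- tab[[quantity]]
  k <- tab$k
  if (stats::sd(y) == 0) {
    return(structure(list(statistic = NA_real_, p_empirical = NA_real_,
                          direction = "none", null_statistics = numeric()),
                     class = "trend_test_result"))
  }
  rho <- stats::cor(k, y, method = "spearman")
  repmat <- profile$replicate_stats[[quantity]]
  null_rho <- apply(repmat, 2L, function(col) {
    if (stats::sd(col) == 0) 0 else stats::cor(k, col, method = "spearman")
  })
  extreme <- switch(alternative,
    two.sided = abs(null_rho) >= abs(rho),
    less = null_rho <= rho,
    greater = null_rho >= rho)
  p <- (1 + sum(extreme)) / (1 + length(null_rho))
  direction <- if (rho < 0) "decreasing" else if (rho > 0) "increasing" else "none"
  structure(list(statistic = rho, p_empirical = p, direction = direction,
                 null_statistics = null_rho),
            class = "trend_test_result")
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf("Core-order trend: Spearman rho = %.3f (%s), empirical p = %.4g\n",
              x$statistic, x$direction, x$p_empirical))
  invisible(x)
}

#' Chi-square goodness of fit of mutations across core shells
#'
#' Compares observed per-shell mutation assignments with counts
#' expected under footprint-length proportionality. Shells (coreness
#' exactly k) are used rather than nested cores so the categories
#' partition the domains. Expected_k = M * (footprint bp of shell-k
#' domains / total footprint bp), where M is the total assignments to
#' the analyzed domains. Shells with expected < `min_expected` are
#' pooled with the next-lower shell.
#'
#' @param decomposition A `core_decomposition`.
#' @param footprints A `domain_footprints` (supplies per-domain bp).
#' @param counts A `domain_mutation_counts` (supplies per-domain
#'   assignments m_d).
#' @param min_expected Pooling threshold (default 5).
#' @return list of class `core_gof`: `table` (shell_k labels, observed,
#'   expected after pooling), `statistic`, `df`, `p_value`.
#' @export
chi_square_cores <- function(decomposition, footprints, counts,
                             min_expected = 5) {
  cn <- decomposition$coreness
  doms <- names(cn)
  L <- footprints$cumulative_length[doms]
  L[is.na(L)] <- 0
  mm <- stats::setNames(counts$counts$m, counts$counts$domain_acc)[doms]
  mm[is.na(mm)] <- 0L
  ks <- sort(unique(cn))
  obs <- vapply(ks, function(k) sum(mm[cn == k]), 0)
  bp <- vapply(ks, function(k) sum(as.numeric(L[cn == k])), 0)
  if (sum(bp) <= 0) stop2("chi_square_cores: zero total footprint")
  M <- sum(obs)
  exp_k <- M * bp / sum(bp)
  # pool small-expectation shells downward (highest k into next lower)
  lab <- as.character(ks)
  i <- length(exp_k)
  while (i >= 2L) {
    if (exp_k[i] < min_expected) {
      exp_k[i - 1L] <- exp_k[i - 1L] + exp_k[i]
      obs[i - 1L] <- obs[i - 1L] + obs[i]
      lab[i - 1L] <- paste0(lab[i - 1L], "+", lab[i])
      exp_k <- exp_k[-i]; obs <- obs[-i]; lab <- lab[-i]
    }
    i <- i - 1L
  }
  if (length(exp_k) >= 2L && exp_k[1L] < min_expected) {
    exp_k[2L] <- exp_k[2L] + exp_k[1L]
    obs[2L] <- obs[2L] + obs[1L]
    lab[2L] <- paste0(lab[1L], "+", lab[2L])
    exp_k <- exp_k[-1L]; obs <- obs[-1L]; lab <- lab[-1L]
  }
  if (length(exp_k) < 2L)
    stop2("chi_square_cores: fewer than 2 shells after pooling")
  if (any(exp_k == 0))
    stop2("chi_square_cores: zero expected count after pooling")
  statistic <- sum((obs - exp_k)^2 / exp_k)
  df <- length(exp_k) - 1L
  structure(list(table = data.frame(shell_k = lab, observed = obs,
                                    expected = exp_k),
                 statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df,
                                         lower.tail = FALSE)),
            class = "core_gof")
}

#' @export
print.core_gof <- function(x, ...) {
  cat(sprintf(
    "Shell-wise goodness of fit: X-squared = %.3f, df = %d, p = %.4g\n",
    x$statistic, x$df, x$p_value))
  invisible(x)
}
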