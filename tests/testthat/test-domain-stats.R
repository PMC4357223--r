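fp_of <- function(L) {
  structure(list(intervals = NULL,
                 cumulative_length = L),
            class = "domain_footprints")
}

cnt_of <- function(m) {
  structure(list(counts = data.frame(domain_acc = names(m),
                                     m = as.integer(m)),
                 M = sum(m), mapped = sum(m),
                 mapped_percentage = 100),
            class = "domain_mutation_counts")
}

test_that("normalized score is count over cumulative length", {
  tab <- normalize_counts(cnt_of(c(A = 10L, B = 0L)),
                          fp_of(c(A = 500L, B = 100L)))
  expect_equal(tab$s, c(10 / 500, 0))
  # doubling the footprint at fixed m halves s
  tab2 <- normalize_counts(cnt_of(c(A = 10L)), fp_of(c(A = 1000L)))
  expect_equal(tab2$s, tab$s[1] / 2)
  # zero-footprint domains are excluded; mutated ones are an error
  expect_message(
    t3 <- normalize_counts(cnt_of(c(A = 1L, C = 0L)),
                           fp_of(c(A = 10L))),
    "zero footprint")
  expect_equal(t3$domain_acc, "A")
  expect_error(normalize_counts(cnt_of(c(C = 2L)), fp_of(c(A = 10L))),
               "zero footprint")
})

test_that("z statistic follows the Bernoulli signal-to-noise form", {
  # two domains with s 0.5/0.5 -> p = 0.5 -> z = 1 exactly
  tab <- data.frame(domain_acc = c("A", "B"), m = c(1L, 1L),
                    L = c(2L, 2L), s = c(0.5, 0.5))
  z <- z_scores(tab)
  expect_equal(z$p, c(0.5, 0.5))
  expect_equal(z$z, c(1, 1))
  # p = 0.2 -> z = 0.5
  tab2 <- data.frame(domain_acc = c("A", "B"), m = 0L, L = 1L,
                     s = c(0.2, 0.8))
  expect_equal(z_scores(tab2)$z[1], 0.5)
  # closed form sqrt(p/(1-p)) and strict monotonicity at random p
  set.seed(42)
  p <- sort(runif(10000, 1e-6, 1 - 1e-6))
  s <- data.frame(domain_acc = as.character(seq_along(p)),
                  m = 1L, L = 1L, s = p)
  zz <- z_scores(s)   # p recomputed on the simplex keeps ordering
  expect_equal(zz$z, zz$p / sqrt(zz$p * (1 - zz$p)))
  expect_equal(zz$z, sqrt(zz$p / (1 - zz$p)))
  expect_true(all(diff(zz$z) > 0))
  # degenerate cases
  expect_error(z_scores(data.frame(domain_acc = "A", m = 0L, L = 1L,
                                   s = 0)), "all normalized scores")
  expect_error(z_scores(data.frame(domain_acc = c("A", "B"),
                                   m = c(1L, 0L), L = 1L,
                                   s = c(0.3, 0))), "degenerate")
})

test_that("pure-null z keeps pi0 near 1 and calls almost nothing", {
  set.seed(1)
  z <- rnorm(5000)
  fit <- fit_lfdr(z)
  expect_gt(fit$pi0, 0.9)
  expect_lte(fit$pi0, 1.05)
  expect_lt(abs(fit$delta0), 0.15)
  expect_lt(abs(fit$sigma0 - 1), 0.15)
  expect_lt(mean(fit$lfdr_fun(z) < 0.1), 0.01)
  # fitted marginal density integrates to ~1 over the binned range
  expect_lt(abs(sum(fit$f * diff(fit$breaks)) - 1), 0.02)
})

test_that("a shifted component is found with high precision", {
  set.seed(2)
  lab <- runif(5000) < 0.05
  z <- ifelse(lab, rnorm(5000, 4, 1), rnorm(5000))
  fit <- fit_lfdr(z)
  called <- fit$lfdr_fun(z) < 0.1
  expect_gt(sum(called), 50)
  expect_gt(mean(lab[called]), 0.9)
})

test_that("shifting z shifts the null location, not the ranking", {
  set.seed(3)
  z <- c(rnorm(4800), rnorm(200, 4, 1))
  f1 <- fit_lfdr(z)
  f2 <- fit_lfdr(z + 2)
  expect_lt(abs((f2$delta0 - f1$delta0) - 2), 0.2)
  expect_equal(order(f1$lfdr_fun(z)[1:500]),
               order(f2$lfdr_fun(z + 2)[1:500]))
})

test_that("fit_lfdr rejects unusable input", {
  expect_error(fit_lfdr(rnorm(50)), ">= 200")
  expect_error(fit_lfdr(c(rnorm(300), NA)), "non-finite")
  expect_error(fit_lfdr(rep(1, 300)), "degenerate")
})

test_that("log-transform dialect handles positive rate-like statistics", {
  set.seed(4)
  z <- exp(rnorm(3000, -3, 0.4))
  z[1:30] <- z[1:30] * 12
  fit <- fit_lfdr(z, transform = "log")
  lf <- fit$lfdr_fun(z)
  expect_true(all(lf >= 0 & lf <= 1))
  expect_equal(fit$lfdr_fun(0), 1)
  expect_lt(mean(lf[1:30]), mean(lf[-(1:30)]))
})

test_that("call_significant is strict and deterministically ordered", {
  tab <- data.frame(domain_acc = c("C", "A", "B", "D"),
                    m = 1L, L = 1L, s = 1,
                    p = 0.25, z = c(2, 5, 5, 1),
                    lfdr = c(0.05, 0.02, 0.02, 0.1))
  out <- call_significant(tab, 0.1)
  expect_equal(out, c("A", "B", "C"))  # D at exactly 0.1 excluded
  tab$lfdr <- 1
  expect_equal(call_significant(tab), character())
})

test_that("overlap regions partition the union", {
  sets <- list(ov = c("A", "B"), br = c("B", "C"), pr = c("B"))
  ov <- overlap_sets(sets)
  expect_equal(ov$intersection, "B")
  expect_equal(sum(ov$regions$size), ov$union_size)
  expect_equal(ov$regions$size[ov$regions$region == "ov&br&pr"], 1L)
  # identical sets: intersection is the set
  ov2 <- overlap_sets(list(x = c("A", "B"), y = c("A", "B")))
  expect_setequal(ov2$intersection, c("A", "B"))
  # random sets: region sizes always sum to the union
  set.seed(9)
  for (i in 1:5) {
    ss <- lapply(1:3, function(j) sample(LETTERS, sample(3:10, 1)))
    names(ss) <- c("s1", "s2", "s3")
    o <- overlap_sets(ss)
    expect_equal(sum(o$regions$size), length(unique(unlist(ss))))
  }
  expect_error(overlap_sets(list(a = "X")), ">= 2")
})

test_that("stats pipeline is deterministic and ranking-consistent", {
  set.seed(10)
  m <- stats::setNames(rpois(400, 20), sprintf("PF%03d", 1:400))
  m[1:5] <- m[1:5] + 150L
  L <- stats::setNames(rep(600L, 400), names(m))
  st1 <- suppressMessages(domain_stats(cnt_of(m), fp_of(L)))
  st2 <- suppressMessages(domain_stats(cnt_of(m), fp_of(L)))
  expect_identical(st1$table, st2$table)
  # significance ranking before lfdr is the normalized-rate ranking
  tab <- st1$table
  expect_equal(order(tab$z, decreasing = TRUE),
               order(tab$s, decreasing = TRUE))
})
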