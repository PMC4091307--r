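# Correlation, binning, enrichment and group-comparison statistics.

test_that("spearman_rho matches a hand-coded ranking oracle, ties included", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4)),
               oracle_spearman(c(1, 2, 2, 3), c(1, 2, 3, 4)))
  # exhaustive small vectors with ties, n <= 6
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_lt(abs(spearman_rho(x, y) - oracle_spearman(x, y)), 1e-12)
    # and against the stock implementation as a second reference
    expect_lt(abs(spearman_rho(x, y) - cor(x, y, method = "spearman")), 1e-12)
  }
  # NA positions are dropped pairwise
  expect_equal(spearman_rho(c(1, 2, NA, 3, 4), c(2, 4, 5, NA, 8)),
               spearman_rho(c(1, 2, 4), c(2, 4, 8)))
})

test_that("degenerate correlations are signalled, not silently zero", {
  expect_error(spearman_rho(1:2, 2:1),
               class = "crequant_undefined_correlation_error")
  expect_error(spearman_rho(c(2, 2, 2), 1:3),
               class = "crequant_undefined_correlation_error")
  expect_error(spearman_rho(1:4, 1:3),
               class = "crequant_undefined_correlation_error")
})

test_that("line correlation enumerates plane-matched replicate pairs", {
  a1 <- manual_energy(1:6, c(1, 5, 3, 2, 6, 4), plane = "coronal")
  # identical replicate on both sides: rho = 1
  r <- line_correlation(list(a1), list(a1))
  expect_equal(r$mean_rho, 1)
  expect_equal(r$n_pairs, 1)

  # 2 x 3 replicates, all coronal: 6 pairs, mean equals explicit enumeration
  set.seed(13)
  as <- lapply(1:2, function(i) manual_energy(1:8, runif(8)))
  bs <- lapply(1:3, function(i) manual_energy(1:8, runif(8)))
  r2 <- line_correlation(as, bs)
  expect_equal(r2$n_pairs, 6)
  rhos <- c()
  for (a in as) for (b in bs) rhos <- c(rhos, oracle_spearman(a$energy, b$energy))
  expect_equal(r2$mean_rho, mean(rhos))
  expect_equal(r2$mean_rho_sq, mean(rhos^2))
  # mean_rho_sq is the mean of squares, not the square of the mean
  expect_false(isTRUE(all.equal(r2$mean_rho_sq, mean(rhos)^2)))

  # plane matching: coronal-only vs sagittal-only is incomparable
  sag <- manual_energy(1:8, runif(8), plane = "sagittal")
  expect_error(line_correlation(as, list(sag)),
               class = "crequant_incomparable_datasets_error")
  # mixed planes: only matched pairs count
  r3 <- line_correlation(as, c(bs, list(sag)))
  expect_equal(r3$n_pairs, 6)
})

test_that("line correlation is symmetric and missing-structure invariant", {
  set.seed(17)
  as <- lapply(1:2, function(i) manual_energy(1:10, runif(10)))
  bs <- lapply(1:2, function(i) manual_energy(1:10, runif(10)))
  expect_equal(line_correlation(as, bs)$mean_rho,
               line_correlation(bs, as)$mean_rho)
  # adding a structure missing on the other side never changes rho
  a_ext <- manual_energy(1:11, c(as[[1]]$energy, 0.9))
  b_na <- manual_energy(1:11, c(bs[[1]]$energy, NA))
  expect_equal(line_correlation(list(a_ext), list(b_na))$mean_rho,
               line_correlation(as[1], bs[1])$mean_rho)
})

test_that("replicate baseline averages within lines, then across lines", {
  e <- function(v) manual_energy(seq_along(v), v)
  # one line, two identical replicates -> 1
  expect_equal(replicate_baseline(list(L = list(e(1:5), e(1:5)))), 1)
  # each line contributes once regardless of replicate count
  set.seed(19)
  l1 <- lapply(1:2, function(i) e(runif(9)))
  l2 <- lapply(1:4, function(i) e(runif(9)))
  got <- replicate_baseline(list(A = l1, B = l2))
  line_mean <- function(evs) {
    rhos <- c()
    for (i in seq_along(evs)) for (j in seq_along(evs))
      if (j > i) rhos <- c(rhos, oracle_spearman(evs[[i]]$energy, evs[[j]]$energy))
    mean(rhos)
  }
  expect_equal(got, mean(c(line_mean(l1), line_mean(l2))))
  # single-replicate lines are ineligible
  expect_error(replicate_baseline(list(A = list(e(1:5)))),
               class = "crequant_incomparable_datasets_error")
})

test_that("independent ground truths give a near-zero replicate baseline", {
  set.seed(23)
  lines <- lapply(1:8, function(i)
    lapply(1:2, function(j) manual_energy(1:20, runif(20))))
  names(lines) <- paste0("L", 1:8)
  expect_lt(abs(replicate_baseline(lines)), 0.2)
})

test_that("percentile bins split quartiles with upward tie assignment", {
  b <- percentile_bins(1:8)
  expect_equal(unname(table(b)[c("high", "mid", "low", "very_low")]),
               rep(2L, 4), ignore_attr = TRUE)
  expect_setequal(unique(b), c("high", "mid", "low", "very_low"))
  expect_equal(percentile_bins(c(1, 2, 3)), rep("unbinned", 3))

  # independent oracle: hand-coded type-7 quantile + upward rule, over many
  # small vectors with ties, in every order
  q7 <- function(x, p) {
    s <- sort(x); h <- (length(x) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[min(floor(h) + 1, length(x))] - s[floor(h)])
  }
  set.seed(29)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    v <- sample(1:4, n, replace = TRUE)
    want <- vapply(v, function(x) {
      if (x >= q7(v, 0.75)) "high"
      else if (x >= q7(v, 0.5)) "mid"
      else if (x >= q7(v, 0.25)) "low"
      else "very_low"
    }, character(1))
    expect_equal(percentile_bins(v), want)
    # permutation equivariance
    p <- sample(n)
    expect_equal(percentile_bins(v[p]), want[p])
  }
  # values exactly at a threshold go upward
  v <- c(1, 2, 3, 4, 5)  # Q1 = 2, median = 3, Q3 = 4 under type 7
  expect_equal(percentile_bins(v), c("very_low", "low", "mid", "high", "high"))
})

test_that("fold changes divide energy by whole-brain energy, no floor", {
  e1 <- manual_energy(1:4, c(0.2, 0.1, 0.05, 0.05), line_id = "A",
                      whole_brain = 0.1)
  e2 <- manual_energy(1:4, c(0.3, NA, 0.1, 0.2), line_id = "B",
                      whole_brain = 0.2)
  tab <- fold_change_table(list(e1, e2))
  expect_equal(tab$fold_change[tab$line_id == "A"], c(2, 1, 0.5, 0.5))
  expect_equal(tab$fold_change[tab$line_id == "B"], c(1.5, NA, 0.5, 1))
  # energy equal to whole-brain -> fold change exactly 1
  expect_equal(tab$fold_change[tab$line_id == "A" & tab$structure_id == 2], 1)
  # zero whole-brain energy -> missing, not Inf
  e3 <- manual_energy(1:4, c(0, 0, 0, 0), line_id = "C", whole_brain = 0)
  tab3 <- fold_change_table(list(e3))
  expect_true(all(is.na(tab3$fold_change)))
  # tiny energies are still ratioed (no expression floor)
  e4 <- manual_energy(1:4, c(2e-6, 1e-6, 1e-6, 0), line_id = "D",
                      whole_brain = 1e-6)
  expect_equal(fold_change_table(list(e4))$fold_change[1], 2)
})

test_that("line ranking is by descending fold change, missing last, ties lexical", {
  mk <- function(lid, e, w) manual_energy(1:2, c(e, 0.1), line_id = lid,
                                          whole_brain = w)
  tab <- fold_change_table(list(mk("zeta", 0.4, 0.1), mk("alpha", 0.2, 0.1),
                                mk("beta", 0.2, 0.1), mk("gamma", NA, 0.1)))
  r <- rank_lines_for_structure(tab, 1)
  expect_equal(r$line_id, c("zeta", "alpha", "beta", "gamma"))
  expect_true(is.na(r$fold_change[4]))
  expect_error(rank_lines_for_structure(tab, 99),
               class = "crequant_unknown_structure_error")
  single <- fold_change_table(list(mk("only", 0.5, 0.1)))
  expect_equal(rank_lines_for_structure(single, 1)$line_id, "only")
})

test_that("group comparisons match closed-form t-test oracles", {
  # identical groups: t = 0, p = 1 (degenerate variance guard)
  g <- group_compare(c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(g$t, 0); expect_equal(g$p, 1)
  # paired with constant zero differences
  gp <- group_compare(c(3, 5, 3, 5), c("a", "a", "b", "b"), paired = TRUE)
  expect_equal(gp$t, 0); expect_equal(gp$p, 1)
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b"), paired = TRUE),
               class = "crequant_invalid_spec_error")

  # Welch formulas evaluated independently
  x <- c(2.1, 3.4, 2.8, 4.0, 3.1)
  y <- c(1.2, 1.9, 2.2)
  got <- group_compare(c(x, y), rep(c("x", "y"), c(5, 3)))
  sx2 <- sum((x - mean(x))^2) / 4; sy2 <- sum((y - mean(y))^2) / 2
  se2 <- sx2 / 5 + sy2 / 3
  t_oracle <- (mean(x) - mean(y)) / sqrt(se2)
  df_oracle <- se2^2 / ((sx2 / 5)^2 / 4 + (sy2 / 3)^2 / 2)
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  expect_lt(abs(got$t - t_oracle), 1e-9)
  expect_lt(abs(got$df - df_oracle), 1e-9)
  expect_lt(abs(got$p - p_oracle), 1e-12)

  # paired one-sample-on-differences oracle
  a <- c(0.5, 0.8, 0.3, 0.9); b <- c(0.4, 0.9, 0.1, 0.6)
  gotp <- group_compare(c(a, b), rep(c("a", "b"), each = 4), paired = TRUE)
  d <- a - b
  t_or <- mean(d) / (sd(d) / 2)
  expect_lt(abs(gotp$t - t_or), 1e-9)
  expect_equal(gotp$df, 3)
  expect_lt(abs(gotp$p - 2 * pt(-abs(t_or), 3)), 1e-12)
})
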