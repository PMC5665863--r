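test_that("identical two-group data give p = 1", {
  r <- compare_two_groups(1:10, 1:10)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_false(r$gate$different_variance)
})

test_that("unequal variances route to Mann-Whitney through the F gate", {
  set.seed(3)
  a <- rnorm(100, 0, 1)
  b <- rnorm(100, 0, 3)
  r <- compare_two_groups(a, b)
  expect_equal(r$test_name, "mann_whitney")
  expect_lt(r$gate$p, 0.05)
  expect_true(r$gate$different_variance)
})

test_that("a clear shift with equal variances routes to the t-test", {
  set.seed(4)
  a <- rnorm(30, 0, 0.5)
  b <- a + 10
  r <- compare_two_groups(a, b)
  expect_equal(r$test_name, "unpaired_t")
  expect_lt(r$p_value, 1e-6)
})

test_that("degenerate zero-variance groups use the documented convention", {
  r <- compare_two_groups(rep(2, 5), rep(2, 5))
  expect_equal(r$p_value, 1)
  r2 <- compare_two_groups(rep(2, 5), rep(3, 5))
  expect_equal(r2$p_value, 0)
  expect_error(compare_two_groups(1:2, 1:5), "n >= 3")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(5)
  a <- rlnorm(40); b <- rlnorm(40, 0.5)
  p1 <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  p2 <- stats::wilcox.test(exp(a), exp(b), exact = FALSE)$p.value
  expect_equal(p1, p2)
  g <- list(a = a, b = b, c = rlnorm(40, 1))
  k1 <- stats::kruskal.test(g)$p.value
  k2 <- stats::kruskal.test(lapply(g, exp))$p.value
  expect_equal(k1, k2)
  d1 <- dunn_test(g)
  d2 <- dunn_test(lapply(g, exp))
  expect_equal(d1$z, d2$z)
})

test_that("three identical groups share one letter at p = 1", {
  g <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  r <- compare_multi_groups(g)
  expect_equal(r$p_value, 1)
  expect_true(all(r$pairwise$p_adj == 1))
  expect_equal(unname(r$letters), rep("a", 3))
})

test_that("Dunn z for complete rank separation matches the brute-force formula", {
  g <- list(lo = 1:8, mid = 9:16, hi = 17:24)
  d <- dunn_test(g)
  # independent computation from mean ranks (no ties)
  N <- 24; n <- 8
  mean_ranks <- c(lo = mean(1:8), mid = mean(9:16), hi = mean(17:24))
  z_oracle <- (mean_ranks["lo"] - mean_ranks["hi"]) /
    sqrt((N * (N + 1) / 12) * (2 / n))
  row <- d[d$group1 == "lo" & d$group2 == "hi", ]
  expect_equal(row$z, unname(z_oracle))
  expect_equal(row$p_adj, min(2 * pnorm(-abs(z_oracle)) * 3, 1),
               ignore_attr = TRUE)
})

test_that("tied data are tie-corrected in the Dunn variance", {
  g <- list(a = c(1, 1, 2, 2), b = c(2, 2, 3, 3), c = c(3, 3, 4, 4))
  d <- dunn_test(g)
  x <- unlist(g); N <- length(x)
  ties <- table(x)
  corr <- sum(ties^3 - ties) / (12 * (N - 1))
  r <- rank(x)
  mr <- tapply(r, rep(names(g), each = 4), mean)
  z_oracle <- (mr[["a"]] - mr[["c"]]) /
    sqrt((N * (N + 1) / 12 - corr) * (1 / 4 + 1 / 4))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], z_oracle)
})

test_that("well-separated equal-variance groups produce ordered p-values", {
  set.seed(11)
  g <- list(g1 = rnorm(50, 0), g2 = rnorm(50, 1), g3 = rnorm(50, 2))
  r <- compare_multi_groups(g)
  expect_lt(r$omnibus_p, 1e-6)
  x <- unlist(g); mr <- tapply(rank(x), rep(names(g), each = 50), mean)
  expect_true(all(diff(mr[c("g1", "g2", "g3")]) > 0))
  p13 <- r$pairwise$p_adj[(r$pairwise$group1 == "g1" & r$pairwise$group2 == "g3") |
                            (r$pairwise$group1 == "g3" & r$pairwise$group2 == "g1")]
  p12 <- r$pairwise$p_adj[(r$pairwise$group1 == "g1" & r$pairwise$group2 == "g2") |
                            (r$pairwise$group1 == "g2" & r$pairwise$group2 == "g1")]
  expect_lte(p13, p12)
  # letters separate all three groups
  expect_equal(length(unique(r$letters)), 3)
})

test_that("heteroscedastic groups route to Kruskal-Wallis with Dunn", {
  set.seed(12)
  g <- list(a = rnorm(40, 0, 0.2), b = rnorm(40, 0.05, 0.2), c = rnorm(40, 3, 4))
  r <- compare_multi_groups(g)
  expect_equal(r$test_name, "kruskal_wallis_dunn")
  expect_true(r$gate$different_variance)
  expect_true(all(c("statistic", "p_adj") %in% names(r$pairwise)))
  # a and b are indistinguishable: they share a letter; c stands apart
  expect_equal(r$letters[["a"]], r$letters[["b"]])
})

test_that("Fisher's exact test reproduces the printed composition p-value", {
  # 0/75 fully-mutant polar/stalk units vs 6/82 in controls
  p <- fisher_exact_2x2(matrix(c(0, 6, 75, 76), 2, 2, byrow = FALSE))
  expect_equal(round(p, 2), 0.03)
  expect_equal(p, stats::fisher.test(matrix(c(0, 6, 75, 76), 2))$p.value,
               tolerance = 1e-9)
})

test_that("Fisher conventions: symmetry, extreme tables, zero margins", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2)), 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(1, 3, 3)), "2x2")
})

test_that("Fisher agrees with full enumeration on small tables", {
  # factorial-formula oracle, independent of the dhyper implementation
  oracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    n <- r1 + r2
    if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
    support <- max(0, c1 - r2):min(r1, c1)
    lp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
    p <- exp(lp)
    sum(p[p <= exp(lp[support == tab[1, 1]]) * (1 + 1e-7)])
  }
  for (n in 0:25) for (r1 in 0:n) for (c1 in 0:n) {
    r2 <- n - r1
    for (a in max(0, c1 - r2):min(r1, c1)) {
      tab <- matrix(c(a, c1 - a, r1 - a, r2 - (c1 - a)), 2, 2)
      if (any(tab < 0)) next
      expect_equal(fisher_exact_2x2(tab), oracle(tab), tolerance = 1e-9)
    }
  }
})

test_that("clone composition builds the published-style 2x2 table", {
  # group A: 75 units, none fully mutant; group B: 82 units, 6 fully mutant
  mk <- function(group, n_units, n_fully) {
    unit <- paste0(group, rep(seq_len(n_units), each = 2))
    clone <- rep("control", 2 * n_units)
    if (n_fully > 0) clone[seq_len(2 * n_fully)] <- "mutant"
    data.frame(unit_id = unit, group = group, clone = clone)
  }
  a <- mk("dsh", 75, 0)
  b <- mk("ctrl", 82, 6)
  tab <- clone_composition(c(a$unit_id, b$unit_id), c(a$group, b$group),
                           c(a$clone, b$clone))
  expect_equal(tab["dsh", "fully_mutant"], 0L)
  expect_equal(tab["dsh", "mixed_or_other"], 75L)
  expect_equal(tab["ctrl", "fully_mutant"], 6L)
  expect_equal(tab["ctrl", "mixed_or_other"], 76L)
  expect_equal(round(fisher_exact_2x2(tab), 2), 0.03)
})

test_that("clone composition handles edge labellings", {
  # all units fully mutant
  tab <- clone_composition(c("u1", "u1", "u2", "b1", "b2"),
                           c("A", "A", "A", "B", "B"),
                           c("mutant", "mutant", "mutant", "mutant", "mutant"))
  expect_equal(unname(tab[, "mixed_or_other"]), c(0L, 0L))
  # a single-cell mutant unit is fully mutant
  expect_equal(tab["A", "fully_mutant"], 2L)
  # unlabeled cells force mixed, with a warning
  expect_warning(
    tab2 <- clone_composition(c("u1", "u1", "b1"), c("A", "A", "B"),
                              c("mutant", NA, "control")),
    "unlabeled")
  expect_equal(tab2["A", "fully_mutant"], 0L)
  expect_error(clone_composition(c("u1", "u1"), c("A", "B"), c("mutant", "mutant")),
               "spans multiple groups")
})

test_that("proportion summaries average per-replicate fractions", {
  flag <- c(rep(c(TRUE, FALSE), c(1, 9)),   # rep1: 0.1
            rep(c(TRUE, FALSE), c(2, 8)),   # rep2: 0.2
            rep(c(TRUE, FALSE), c(3, 7)))   # rep3: 0.3
  out <- proportion_summary(flag, rep("g", 30), rep(c("r1", "r2", "r3"), each = 10))
  expect_equal(out$mean, 0.2)
  expect_equal(out$sd, 0.1)
  out0 <- proportion_summary(rep(FALSE, 20), rep("g", 20),
                             rep(c("r1", "r2"), each = 10))
  expect_equal(out0$mean, 0)
  expect_equal(out0$sd, 0)
  expect_error(proportion_summary(rep(TRUE, 5), rep("g", 5), rep("r1", 5)),
               "at least 2")
})

test_that("Tukey box statistics use type-7 quartiles and 1.5 IQR fences", {
  s <- tukey_box_stats(1:100)
  expect_equal(unname(s$quartiles), c(25.75, 50.5, 75.25))
  expect_equal(length(s$outliers), 0)
  expect_equal(unname(s$whiskers), c(1, 100))
  sc <- tukey_box_stats(rep(4, 10))
  expect_equal(unname(sc$quartiles), c(4, 4, 4))
  expect_equal(length(sc$outliers), 0)
  so <- tukey_box_stats(c(1:20, 1000))
  expect_equal(so$outliers, 1000)
  expect_lte(so$whiskers[["upper"]], 20)
})

test_that("fold-change CI covers a known deterministic ratio", {
  set.seed(13)
  ctrl <- rlnorm(200, 0, 0.2)
  mut <- rlnorm(200, log(1.83), 0.2)
  fc <- fold_change_ci(mut, ctrl)
  expect_equal(fc$fold_change, 1.83, tolerance = 0.1)
  expect_lt(fc$ci[["lower"]], 1.83)
  expect_gt(fc$ci[["upper"]], 1.83)
})
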