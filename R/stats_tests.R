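#' Variance-gated statistical decision tree
#'
#' Two-group comparisons use a two-tailed unpaired t-test when an F-test
#' finds similar variances, otherwise the two-tailed Mann-Whitney test.
#' Multi-group comparisons use ordinary one-way ANOVA with Tukey's HSD
#' when a Brown-Forsythe test finds similar variances, otherwise
#' Kruskal-Wallis with Dunn's multiple-comparisons test
#' (Bonferroni-adjusted, tie-corrected). The gate diagnostic is always
#' recorded in the result.
#'
#' @name fate_stats
NULL

new_test_result <- function(...) structure(list(...), class = "test_result")

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s", x$test_name))
  if (!is.null(x$statistic)) cat(sprintf("  statistic = %.4g", x$statistic))
  if (!is.null(x$p_value) && length(x$p_value) == 1)
    cat(sprintf("  p = %.4g", x$p_value))
  cat("\n")
  if (!is.null(x$gate))
    cat(sprintf("  gate: %s p = %.4g -> %s\n", x$gate$test, x$gate$p,
                if (x$gate$different_variance) "different variance" else "similar variance"))
  if (!is.null(x$pairwise)) {
    cat("  pairwise adjusted p:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Gated two-group comparison (F-test, then t or Mann-Whitney)
#'
#' @param a,b numeric samples, each n >= 3
#' @param alpha significance level for the comparison (and default for the
#'   gate)
#' @param gate_alpha significance level of the variance gate
#' @return a `test_result`: `test_name`, `statistic`, `p_value`, `gate`
#'   (F-test p and decision), `n`, `alpha`
#' @export
compare_two_groups <- function(a, b, alpha = 0.05, gate_alpha = alpha) {
  if (length(a) < 3 || length(b) < 3) stopf("each group needs n >= 3")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: no within-group variability at all
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(new_test_result(test_name = "degenerate_zero_variance",
                           statistic = mean(a) - mean(b), p_value = p,
                           gate = list(test = "F", p = NA_real_,
                                       different_variance = FALSE),
                           n = c(length(a), length(b)), alpha = alpha))
  }
  gate_p <- if (va == 0 || vb == 0) 0 else stats::var.test(a, b)$p.value
  different <- gate_p < gate_alpha
  if (different) {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    res <- new_test_result(test_name = "mann_whitney",
                           statistic = unname(wt$statistic),
                           p_value = wt$p.value,
                           gate = list(test = "F", p = gate_p,
                                       different_variance = TRUE),
                           n = c(length(a), length(b)), alpha = alpha)
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- new_test_result(test_name = "unpaired_t",
                           statistic = unname(tt$statistic),
                           p_value = tt$p.value,
                           gate = list(test = "F", p = gate_p,
                                       different_variance = FALSE),
                           n = c(length(a), length(b)), alpha = alpha)
  }
  res
}

#' Dunn's multiple-comparisons test after Kruskal-Wallis
#'
#' Pairwise z statistics on tie-corrected pooled mean ranks,
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`; two-sided p-values are
#' Bonferroni-adjusted over all pairs.
#'
#' @param groups named list of numeric vectors
#' @return data.frame: `group1`, `group2`, `z`, `p_adj`
#' @export
dunn_test <- function(groups) {
  g <- rep(names(groups), lengths(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  k <- ncol(pairs)
  z <- p <- numeric(k)
  for (i in seq_len(k)) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se2 <- (N * (N + 1) / 12 - tie_term) * (1 / ns[[g1]] + 1 / ns[[g2]])
    if (se2 <= 0) { z[i] <- 0; p[i] <- 1; next }
    z[i] <- (mr[[g1]] - mr[[g2]]) / sqrt(se2)
    p[i] <- min(2 * stats::pnorm(-abs(z[i])) * k, 1)
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_adj = p)
}

#' Compact letter display from pairwise significance
#'
#' Groups sharing a letter are not significantly different (insert-and-
#' absorb over the non-significance graph, groups ordered by mean).
#' @keywords internal
letter_display <- function(group_names, pairwise, alpha, means) {
  k <- length(group_names)
  ns <- diag(TRUE, k)
  rownames(ns) <- colnames(ns) <- group_names
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$group1[i]; b <- pairwise$group2[i]
    ok <- is.na(pairwise$p_adj[i]) || pairwise$p_adj[i] >= alpha
    ns[a, b] <- ns[b, a] <- ok
  }
  ord <- order(means)
  sets <- list()
  for (gi in ord) {
    placed <- FALSE
    for (si in seq_along(sets)) {
      if (all(ns[gi, sets[[si]]])) {
        sets[[si]] <- c(sets[[si]], gi)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- gi
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]))
      keep[i] <- FALSE
  sets <- sets[keep]
  letters_out <- rep("", k)
  for (si in seq_along(sets))
    for (gi in sets[[si]])
      letters_out[gi] <- paste0(letters_out[gi], letters[si])
  stats::setNames(letters_out, group_names)
}

#' Gated multi-group comparison (Brown-Forsythe, then ANOVA+Tukey or
#' Kruskal-Wallis+Dunn)
#'
#' @param groups named list of >= 3 numeric vectors, each n >= 3
#' @param alpha significance level
#' @return a `test_result` with `omnibus_p`, `pairwise` (adjusted
#'   p-values), `letters` (groups sharing a letter are not significantly
#'   different), and the Brown-Forsythe `gate`
#' @export
compare_multi_groups <- function(groups, alpha = 0.05) {
  if (length(groups) < 3) stopf("need at least 3 groups")
  if (any(lengths(groups) < 3)) stopf("each group needs n >= 3")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stopf("groups must be uniquely named")
  nm <- names(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  means <- sapply(groups, mean)
  if (stats::var(x) == 0) {
    pw <- data.frame(group1 = utils::combn(nm, 2)[1, ],
                     group2 = utils::combn(nm, 2)[2, ],
                     statistic = 0, p_adj = 1)
    return(new_test_result(
      test_name = "degenerate_all_identical", statistic = 0, omnibus_p = 1,
      p_value = 1, pairwise = pw,
      letters = stats::setNames(rep("a", length(nm)), nm),
      gate = list(test = "brown_forsythe", p = NA_real_,
                  different_variance = FALSE),
      n = lengths(groups), alpha = alpha))
  }
  bf <- tryCatch(car::leveneTest(x ~ g, center = stats::median),
                 error = function(e) NULL)
  gate_p <- if (is.null(bf)) NA_real_ else bf[1, "Pr(>F)"]
  different <- !is.na(gate_p) && gate_p < alpha
  if (different) {
    kw <- stats::kruskal.test(x ~ g)
    pw <- dunn_test(groups)
    names(pw)[names(pw) == "z"] <- "statistic"
    res <- new_test_result(
      test_name = "kruskal_wallis_dunn",
      statistic = unname(kw$statistic), omnibus_p = kw$p.value,
      p_value = kw$p.value, pairwise = pw,
      gate = list(test = "brown_forsythe", p = gate_p,
                  different_variance = TRUE),
      n = lengths(groups), alpha = alpha)
  } else {
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(group1 = vapply(pair_names, `[`, "", 2),
                     group2 = vapply(pair_names, `[`, "", 1),
                     statistic = tk[, "diff"], p_adj = tk[, "p adj"],
                     row.names = NULL)
    res <- new_test_result(
      test_name = "anova_tukey",
      statistic = an[["F value"]][1], omnibus_p = an[["Pr(>F)"]][1],
      p_value = an[["Pr(>F)"]][1], pairwise = pw,
      gate = list(test = "brown_forsythe", p = gate_p,
                  different_variance = FALSE),
      n = lengths(groups), alpha = alpha)
  }
  res$letters <- letter_display(nm, res$pairwise, alpha, means)
  res
}

#' Two-sided Fisher's exact test on a 2x2 table (probability-mass method)
#'
#' Exact hypergeometric p: with margins fixed, the two-sided p-value is
#' the sum of the probabilities of all tables whose probability does not
#' exceed that of the observed table (up to a 1e-7 relative tolerance for
#' floating-point ties). A zero margin gives p = 1 by convention (the
#' table is then fully determined by its margins).
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows are groups,
#'   columns outcome classes
#' @return two-sided p-value
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stopf("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  a <- tab[1, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' Clone-composition table of polar/stalk units
#'
#' Counts, per genotype group, how many multicellular units are composed
#' entirely of mutant (clone) cells versus mixed/other. A unit containing
#' any unlabeled cell counts as mixed, with a warning.
#'
#' @param unit_id unit identifier per cell
#' @param group genotype group per cell (must be constant within a unit;
#'   exactly 2 groups)
#' @param clone per-cell label: `"mutant"`, `"control"`, or `NA`/"" for
#'   unlabeled
#' @return 2x2 integer matrix, rows = groups, columns =
#'   `c("fully_mutant", "mixed_or_other")`
#' @export
clone_composition <- function(unit_id, group, clone) {
  if (any(!nzchar(unit_id)) || any(is.na(unit_id)))
    stopf("every cell needs a unit id")
  df <- data.frame(unit_id = as.character(unit_id),
                   group = as.character(group),
                   clone = as.character(clone), stringsAsFactors = FALSE)
  ug <- unique(df[, c("unit_id", "group")])
  if (anyDuplicated(ug$unit_id)) stopf("a unit spans multiple groups")
  groups <- unique(ug$group)
  if (length(groups) != 2) stopf("need exactly 2 genotype groups")
  unlabeled <- is.na(df$clone) | !(df$clone %in% c("mutant", "control"))
  if (any(unlabeled))
    warnf("units containing unlabeled cells are counted as mixed")
  fully <- tapply(df$clone, df$unit_id,
                  function(cl) all(!is.na(cl) & cl == "mutant"))
  out <- matrix(0L, 2, 2, dimnames = list(groups,
                                          c("fully_mutant", "mixed_or_other")))
  for (gi in groups) {
    units <- ug$unit_id[ug$group == gi]
    out[gi, 1] <- sum(fully[units])
    out[gi, 2] <- length(units) - out[gi, 1]
  }
  out
}

#' Per-group fraction of flagged cells across replicate samples
#'
#' The per-replicate fraction of `TRUE` flags, then the across-replicate
#' mean and sd per group (the "mean +/- s.d. from N experiments"
#' summary). Empty replicates are excluded with a warning.
#'
#' @param flag logical per cell
#' @param group group label per cell
#' @param replicate replicate sample id per cell (>= 2 non-empty
#'   replicates per group)
#' @return data.frame: `group`, `mean`, `sd`, `n_replicates`
#' @export
proportion_summary <- function(flag, group, replicate) {
  df <- data.frame(flag = as.logical(flag), group = as.character(group),
                   replicate = as.character(replicate))
  out <- list()
  for (gi in unique(df$group)) {
    sub <- df[df$group == gi, ]
    fr <- tapply(sub$flag, sub$replicate, function(f) {
      if (length(f) == 0) NA_real_ else mean(f)
    })
    if (any(is.na(fr))) {
      warnf("group %s: empty replicate(s) excluded", gi)
      fr <- fr[!is.na(fr)]
    }
    if (length(fr) < 2)
      stopf("group %s needs at least 2 non-empty replicate samples", gi)
    out[[gi]] <- data.frame(group = gi, mean = mean(fr), sd = stats::sd(fr),
                            n_replicates = length(fr))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Tukey box-plot statistics
#'
#' Quartiles by linear interpolation (R's default type-7 quantiles);
#' whiskers extend to the most extreme data inside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; points beyond are outliers.
#'
#' @param values numeric, n >= 1
#' @return list: `quartiles` (Q1, median, Q3), `whiskers` (lower, upper),
#'   `outliers`
#' @export
tukey_box_stats <- function(values) {
  if (length(values) < 1) stopf("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(quartiles = stats::setNames(q, c("q1", "median", "q3")),
       whiskers = c(lower = min(values[inside]), upper = max(values[inside])),
       outliers = sort(values[!inside]))
}

#' Fold-change estimate with confidence interval (ratio of means)
#'
#' Clone-vs-internal-control fold change `mean(mutant) / mean(control)`
#' with a delta-method CI on the log scale, the estimate reported for
#' mosaic-clone effects (e.g. "1.83-fold compared to control cells").
#'
#' @param mutant,control numeric samples (bg-subtracted or normalized)
#' @param conf confidence level
#' @return list: `fold_change`, `ci` (lower, upper), `conf`
#' @export
fold_change_ci <- function(mutant, control, conf = 0.95) {
  mm <- mean(mutant); mc <- mean(control)
  if (mc <= 0 || mm <= 0) stopf("means must be positive for a fold change")
  se2 <- stats::var(mutant) / (length(mutant) * mm^2) +
    stats::var(control) / (length(control) * mc^2)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  lfc <- log(mm / mc)
  list(fold_change = mm / mc,
       ci = c(lower = exp(lfc - zq * sqrt(se2)),
              upper = exp(lfc + zq * sqrt(se2))),
       conf = conf)
}
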