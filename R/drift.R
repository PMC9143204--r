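#' One-way analysis of variance over processing groups
#'
#' Classical one-way ANOVA of one feature's values across groups, testing
#' the null hypothesis that all group means are equal. Delegates to
#' [stats::oneway.test()] with equal variances assumed (the classical F
#' test); when the between-group sum of squares is exactly zero (all group
#' means identical) the statistic is 0 and the p-value 1, and when the
#' within-group sum of squares is zero while means differ the p-value
#' underflows to 0.
#'
#' @param samples named list of numeric vectors, one per group; at least 2
#'   groups with at least 2 values each.
#' @return List with `statistic` (F), `p.value` and `means` (named group
#'   means).
#' @export
anova_oneway <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (any(lengths(samples) < 2L)) stop("each group needs at least 2 values")
  means <- vapply(samples, mean, numeric(1))
  grand <- mean(unlist(samples))
  ssb <- sum(lengths(samples) * (means - grand)^2)
  if (ssb == 0) {
    return(list(statistic = 0, p.value = 1, means = means))
  }
  values <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), lengths(samples)))
  ft <- stats::oneway.test(values ~ group, var.equal = TRUE)
  f <- unname(ft$statistic)
  p <- unname(ft$p.value)
  if (!is.finite(f)) { # zero within-group variance, separated means
    f <- Inf
    p <- 0
  }
  list(statistic = f, p.value = p, means = means)
}

#' Tukey HSD pairwise comparisons
#'
#' Post-hoc pairwise comparison of balanced group means with the
#' studentized-range statistic
#' `Q = |x_bar_i - x_bar_j| / sqrt(s2_within / n)`,
#' where `s2_within` is the pooled within-group mean square and `n` the
#' common group size. P-values come from the studentized range
#' distribution with `k` means and `N - k` error degrees of freedom
#' ([stats::ptukey()]); pairs with `p < alpha` are flagged. Q is invariant
#' under adding a constant to all data and under rescaling (numerator and
#' denominator scale together).
#'
#' @param samples named list of numeric vectors; groups must be balanced
#'   (the Q formula assumes a common `n`).
#' @param alpha significance level for flagging (default 0.05).
#' @return Data frame with one row per unordered pair: `group_i`,
#'   `group_j`, `diff`, `Q`, `p.value`, `significant`.
#' @export
tukey_hsd <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  n <- unique(lengths(samples))
  if (length(n) != 1L) stop("groups must be balanced for the Q statistic")
  if (n < 2L) stop("each group needs at least 2 values")
  k <- length(samples)
  means <- vapply(samples, mean, numeric(1))
  ssw <- sum(vapply(samples, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- k * (n - 1L)
  msw <- ssw / df
  pairs <- utils::combn(names(samples), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    gi <- pairs[1, i]
    gj <- pairs[2, i]
    d <- means[[gi]] - means[[gj]]
    if (msw > 0) {
      q <- abs(d) / sqrt(msw / n)
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    } else {
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else 0
    }
    data.frame(group_i = gi, group_j = gj, diff = d, Q = q, p.value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Radiomics feature-drift report
#'
#' Quantifies how strongly each processing method shifts quantitative
#' image features away from the originals: per feature, a one-way ANOVA
#' across all groups, followed by Tukey HSD comparisons of every method
#' against the `original` group. A feature counts as drifted for a method
#' when the ANOVA is significant and the Tukey comparison of that
#' (original, method) pair is too. Percentages of drifted features are
#' summarized per method, split into first-order and texture panels.
#'
#' @param table a `feature_table` from [build_feature_table()] whose groups
#'   include `"original"`.
#' @param alpha significance level (default 0.05).
#' @return List of class `drift_report` with `per_feature` (data frame:
#'   feature, class, anova p, per-method Tukey p and drift flag) and
#'   `summary` (data frame: method, feature class, percent drifted).
#' @export
feature_drift_report <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (!"original" %in% table$groups) {
    stop("feature table must contain an 'original' group")
  }
  methods <- setdiff(table$groups, "original")
  rows <- lapply(names(table$features), function(f) {
    samples <- table$features[[f]]
    an <- anova_oneway(samples)
    tk <- tukey_hsd(samples, alpha = alpha)
    row <- data.frame(feature = f,
                      class = unname(table$feature_class[f]),
                      anova_p = an$p.value, stringsAsFactors = FALSE)
    for (m in methods) {
      hit <- (tk$group_i == "original" & tk$group_j == m) |
             (tk$group_j == "original" & tk$group_i == m)
      p <- tk$p.value[hit][1]
      row[[paste0("tukey_p_", m)]] <- p
      row[[paste0("drift_", m)]] <- an$p.value < alpha && p < alpha
    }
    row
  })
  per_feature <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(unique(per_feature$class), function(cl) {
      sel <- per_feature$class == cl
      data.frame(method = m, class = cl,
                 percent_drifted = 100 * mean(per_feature[[paste0("drift_", m)]][sel]),
                 n_features = sum(sel), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(per_feature = per_feature, summary = summ),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat("<drift_report> ", nrow(x$per_feature), " features\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
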