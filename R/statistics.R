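#' Prevalence of deformity locations by varus severity
#'
#' Cross-tabulates the malalignment-test location against the varus
#' severity grade and attaches within-severity percentages (columns sum to
#' 100 within each severity group, matching the study-style tables).
#'
#' @param cohort data frame with `mFTA`, `mMPTA`, `mLDFA`; `location` and
#'   `severity` columns are computed if absent.
#' @return List of class `prevalence_table` with `counts` (table,
#'   severity x location) and `percent` (same shape, row percentages
#'   within severity).
#' @export
prevalence_by_severity <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) {
    counts <- table(severity = factor(character(0),
                                      levels = SEVERITY_LEVELS),
                    location = factor(character(0),
                                      levels = LOCATION_LEVELS))
    return(structure(list(counts = counts, percent = counts),
                     class = "prevalence_table"))
  }
  if (!("location" %in% names(cohort)) || !("severity" %in% names(cohort)))
    cohort <- classify_cohort(cohort)
  counts <- table(severity = factor(cohort$severity,
                                    levels = SEVERITY_LEVELS),
                  location = factor(cohort$location,
                                    levels = LOCATION_LEVELS))
  percent <- counts
  rs <- rowSums(counts)
  for (i in seq_along(rs))
    percent[i, ] <- if (rs[i] > 0) 100 * counts[i, ] / rs[i] else 0
  structure(list(counts = counts, percent = percent),
            class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat("Counts (severity x location):\n")
  print(x$counts)
  cat("\nPercent within severity:\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Direct computation of the Pearson statistic
#' \eqn{\sum (O - E)^2 / E} with expected counts from the margins and an
#' upper-tail p-value on \eqn{(r-1)(c-1)} degrees of freedom. No
#' continuity correction is applied by default (`correct = TRUE` enables
#' the Yates correction for 2x2 tables).
#'
#' @param tab matrix or table of non-negative counts.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("counts must be finite and non-negative", call. = FALSE)
  n <- sum(tab)
  if (n <= 0) stop("table has no observations", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected <= 0)) {
    bad <- which(expected <= 0, arr.ind = TRUE)[1, ]
    rn <- rownames(tab); cn <- colnames(tab)
    stop(sprintf("expected count is zero in cell (%s, %s)",
                 if (is.null(rn)) bad[1] else rn[bad[1]],
                 if (is.null(cn)) bad[2] else cn[bad[2]]), call. = FALSE)
  }
  dev <- abs(tab - expected)
  if (correct && all(dim(tab) == c(2L, 2L)))
    dev <- pmax(0, dev - 0.5)
  statistic <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected)
}

#' Pairwise post hoc chi-square tests with Bonferroni correction
#'
#' Tests every pair of rows (or columns) of an omnibus contingency table
#' with a 2 x k chi-square and multiplies each raw p-value by the number
#' of comparisons, capping at 1.
#'
#' @param tab matrix or table of counts with at least 3 rows (or columns).
#' @param margin `"rows"` or `"columns"`: which margin to compare pairwise.
#' @param correct passed to [chi_square_independence()].
#' @return Data frame with `group1`, `group2`, `statistic`, `p_raw`,
#'   `p_adj`.
#' @export
pairwise_posthoc <- function(tab, margin = c("rows", "columns"),
                             correct = FALSE) {
  tab <- as.matrix(tab)
  margin <- match.arg(margin)
  if (margin == "columns") tab <- t(tab)
  k <- nrow(tab)
  if (k < 3L)
    stop("post hoc comparisons need at least 3 groups", call. = FALSE)
  labels <- rownames(tab)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    sub <- tab[c(i1, i2), , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    ct <- chi_square_independence(sub, correct = correct)
    data.frame(group1 = labels[i1], group2 = labels[i2],
               statistic = ct$statistic, p_raw = ct$p_value,
               p_adj = min(1, m * ct$p_value))
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Rank-based omnibus H statistic with tie correction, followed by
#' Dunn-type pairwise z-tests on mean ranks with Bonferroni adjustment.
#'
#' @param values numeric vector of observations (e.g. JLCA per knee).
#' @param groups factor/character vector of group labels, same length.
#' @return List with `H`, `df`, `p_value`, and `posthoc` (data frame
#'   `group1`, `group2`, `z`, `p_raw`, `p_adj`). Groups with fewer than 2
#'   observations are flagged in `small_groups` and excluded from the post
#'   hoc comparisons.
#' @export
kruskal_wallis_posthoc <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) > 0)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups)
  groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  nb <- tabulate(groups)
  rbar <- tapply(r, groups, mean)
  h <- 12 / (n * (n + 1)) * sum(nb * rbar^2) - 3 * (n + 1)
  ties <- table(values)
  tie_c <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_c > 0) h <- h / tie_c
  df <- k - 1L
  p <- stats::pchisq(h, df, lower.tail = FALSE)

  small <- levels(groups)[nb < 2L]
  use <- which(nb >= 2L)
  posthoc <- NULL
  if (length(use) >= 2L) {
    pairs <- utils::combn(use, 2)
    m <- ncol(pairs)
    tie_sum <- sum(ties^3 - ties)
    sig2 <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
    posthoc <- do.call(rbind, lapply(seq_len(m), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      z <- (rbar[i1] - rbar[i2]) / sqrt(sig2 * (1 / nb[i1] + 1 / nb[i2]))
      praw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
      data.frame(group1 = levels(groups)[i1], group2 = levels(groups)[i2],
                 z = as.numeric(z), p_raw = praw,
                 p_adj = min(1, m * praw))
    }))
    rownames(posthoc) <- NULL
  }
  list(H = h, df = df, p_value = p, posthoc = posthoc,
       small_groups = small)
}

#' Intraclass correlation coefficient (two-way model, single measure)
#'
#' Computes the ICC from the two-way ANOVA mean-squares decomposition of a
#' subjects x raters matrix. The default form is absolute agreement,
#' ICC(A,1) in the McGraw-Wong nomenclature:
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square. `type = "consistency"` drops the
#' rater-variance term (ICC(C,1)).
#'
#' @param ratings numeric matrix, subjects in rows, raters/sessions in
#'   columns; at least 2 of each, no missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return List with `icc`, `type`, and the mean squares `MSR`, `MSC`,
#'   `MSE`. `icc` is `NA` (with a message field) when the total variance
#'   is zero.
#' @export
icc <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings) || anyNA(ratings))
    stop("`ratings` must be a complete numeric matrix", call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= .Machine$double.eps * max(1, abs(grand))^2)
    return(list(icc = NA_real_, type = type, MSR = msr, MSC = msc,
                MSE = mse,
                message = "total variance is zero; ICC undefined"))
  val <- if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
  list(icc = val, type = type, MSR = msr, MSC = msc, MSE = mse)
}
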