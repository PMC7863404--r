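#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation between two columns, with the two-tailed
#' p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees
#' of freedom (delegated to [stats::cor.test()]).
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the two numeric variables.
#' @return A one-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p.value`, and `n`.
#' @examples
#' pearson_cor(data.frame(u = 1:4, v = c(2, 1, 4, 3)), u, v)
#' @export
pearson_cor <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L) abort("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("correlation undefined: a variable has zero variance")
  }
  ct <- cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value,
    n = length(xv)
  )
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak adjustment: sort the m p-values ascending, set
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforce monotone
#' non-decreasing adjusted values down the sorted list, cap at 1, and
#' return in the original input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_holm_sidak(c(0.04, 0.01, 0.03))
#' @export
adjust_holm_sidak <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("all p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Balanced two-way ANOVA
#'
#' Classical fixed-effects two-way analysis of variance with interaction,
#' for balanced designs (every A x B cell has the same number of
#' replicates, at least 2). The sums-of-squares decomposition and F tests
#' come from [stats::aov()]; unbalanced designs are rejected because the
#' classical decomposition is not unique there.
#'
#' @param data A data frame in long format.
#' @param value Unquoted numeric response column.
#' @param a,b Unquoted factor columns.
#' @return An object of class `oto_anova2`. Use [tidy()] for the ANOVA
#'   table (term, df, sumsq, meansq, statistic, p.value) and [glance()]
#'   for a one-row summary.
#' @examples
#' d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:2)
#' d$y <- c(1, 5, 2, 6, 3, 7, 4, 8)
#' tidy(anova_two_way(d, y, a, b))
#' @export
anova_two_way <- function(data, value, a, b) {
  yv <- eval_tidy(enquo(value), data)
  av <- factor(eval_tidy(enquo(a), data))
  bv <- factor(eval_tidy(enquo(b), data))
  if (anyNA(yv) || anyNA(av) || anyNA(bv)) abort("missing values not allowed")
  counts <- table(av, bv)
  if (any(counts < 2)) abort("every A x B cell needs at least 2 replicates")
  if (length(unique(as.vector(counts))) != 1L) {
    abort("unbalanced design: cell sizes differ (only balanced designs are supported)")
  }
  d <- data.frame(y = yv, a = av, b = bv)
  fit <- aov(y ~ a * b, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  terms[terms == "a"] <- "A"
  terms[terms == "b"] <- "B"
  terms[terms == "a:b"] <- "A:B"
  terms[terms == "Residuals"] <- "Residuals"
  tidy_tab <- tibble(
    term = terms,
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
  degenerate <- sum(tidy_tab$sumsq) < .Machine$double.eps * length(yv)
  if (degenerate) {
    tidy_tab$statistic[!is.na(tidy_tab$statistic)] <- 0
    tidy_tab$p.value[!is.na(tidy_tab$p.value)] <- NA_real_
  }
  structure(
    list(table = tidy_tab, fit = fit, degenerate = degenerate,
         n = length(yv), cell_size = unique(as.vector(counts))),
    class = "oto_anova2"
  )
}

#' @rdname anova_two_way
#' @param x,... An `oto_anova2` object; further arguments ignored.
#' @export
tidy.oto_anova2 <- function(x, ...) x$table

#' @rdname anova_two_way
#' @export
glance.oto_anova2 <- function(x, ...) {
  tab <- x$table
  tibble(
    n = x$n,
    cell_size = x$cell_size,
    statistic_A = tab$statistic[tab$term == "A"],
    statistic_B = tab$statistic[tab$term == "B"],
    statistic_AB = tab$statistic[tab$term == "A:B"],
    degenerate = x$degenerate
  )
}

#' @export
print.oto_anova2 <- function(x, ...) {
  cat("Balanced two-way ANOVA", if (x$degenerate) "(degenerate: SS_total = 0)",
      "\n")
  print(x$table)
  invisible(x)
}

#' Paired before/after contrast
#'
#' Paired t-test on within-subject differences (after - before), two-tailed,
#' delegated to [stats::t.test()]. Used for comparing each animal's score
#' before and after a stimulus (e.g. tone onset in cued fear conditioning).
#'
#' @param data A data frame with one row per subject.
#' @param before,after Unquoted numeric columns, paired by row.
#' @return A one-row tibble: `estimate` (mean difference after - before),
#'   `statistic` (t), `df`, `p.value`, `n`, and `degenerate` (TRUE when the
#'   differences have zero variance, in which case the test is undefined
#'   and `statistic`/`p.value` are `NA`).
#' @export
paired_contrast <- function(data, before, after) {
  bv <- eval_tidy(enquo(before), data)
  av <- eval_tidy(enquo(after), data)
  if (length(bv) != length(av)) abort("`before` and `after` must be paired")
  keep <- stats::complete.cases(bv, av)
  bv <- bv[keep]; av <- av[keep]
  n <- length(bv)
  if (n < 2L) abort("need at least 2 pairs")
  diffs <- av - bv
  if (sd(diffs) == 0) {
    if (all(diffs == 0)) {
      # identical before/after: t = 0, p = 1 by convention
      return(tibble(estimate = 0, statistic = 0, df = n - 1, p.value = 1,
                    n = n, degenerate = TRUE))
    }
    return(tibble(estimate = mean(diffs), statistic = NA_real_, df = n - 1,
                  p.value = NA_real_, n = n, degenerate = TRUE))
  }
  tt <- t.test(av, bv, paired = TRUE, alternative = "two.sided")
  tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    n = n,
    degenerate = FALSE
  )
}
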