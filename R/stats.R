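# Statistical comparison design: Welch's unequal-variance t-test for the
# cell-line and stroma factors, Mann-Whitney U for the day factor,
# significance at alpha = 0.05 per comparison (no multiplicity correction;
# the report carries the number of comparisons so users can apply their
# own). All tests are two-sided. Both tests are implemented from the closed
# form / exact null enumeration; base R's implementations serve only as
# independent oracles in the test-suite.

ALPHA <- 0.05

#' Welch's two-sample t-test (closed form)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate input (both groups zero-variance with
#' equal means) returns the conventional p = 1 with a message.
#'
#' @param x,y numeric vectors, each of length >= 2, finite.
#' @return list: `statistic`, `df`, `p_value`, `n` (group sizes).
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_("each group needs n >= 2 (got %d and %d)", length(x), length(y))
  if (any(!is.finite(c(x, y)))) stop_("non-finite values in test input")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(x) == mean(y)) {
      message("welch_test: both groups constant and equal; p = 1 by convention")
      return(list(statistic = 0, df = NA_real_, p_value = 1, n = c(nx, ny)))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p_value = 0, n = c(nx, ny)))
  }
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df), n = c(nx, ny))
}

#' Mann-Whitney U test (exact for small samples)
#'
#' U statistic with midrank tie handling. For group sizes <= `exact_max_n`
#' the two-sided p-value is computed from the exact permutation null
#' (enumeration of all group assignments of the pooled values, valid under
#' ties); otherwise the normal approximation with tie correction and
#' continuity correction is used. Two-sided p is `min(1, 2 * min(tails))`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_max_n enumeration threshold per group (default 8).
#' @return list: `statistic` (U of `x`), `p_value`, `exact`, `n`.
#' @export
mann_whitney_test <- function(x, y, exact_max_n = 8L) {
  if (length(x) < 2L || length(y) < 2L)
    stop_("each group needs n >= 2 (got %d and %d)", length(x), length(y))
  if (any(!is.finite(c(x, y)))) stop_("non-finite values in test input")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u_stat <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_max_n && ny <= exact_max_n) {
    eps <- 1e-9
    combos <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p_lo <- mean(u_all <= u_stat + eps)
    p_hi <- mean(u_all >= u_stat - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = u_stat, p_value = p, exact = TRUE, n = c(nx, ny)))
  }
  n <- nx + ny
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sd_u <- sqrt(nx * ny / 12 * (n + 1 - tie_term))
  if (sd_u == 0) {
    message("mann_whitney_test: all values tied; p = 1")
    return(list(statistic = u_stat, p_value = 1, exact = FALSE, n = c(nx, ny)))
  }
  mu_u <- nx * ny / 2
  z <- (u_stat - mu_u - sign(u_stat - mu_u) * 0.5) / sd_u
  list(statistic = u_stat, p_value = min(1, 2 * pnorm(-abs(z))),
       exact = FALSE, n = c(nx, ny))
}

check_metric_column <- function(table, metric) {
  if (!metric %in% names(table))
    stop_("metric '%s' not found in the table", metric)
  if (any(!is.finite(table[[metric]])))
    stop_("metric '%s' contains non-finite values", metric)
}

comparison_row <- function(metric, comparison, test, statistic, p_value,
                           n1, n2) {
  data.frame(metric = metric, comparison = comparison, test = test,
             statistic = statistic, p_value = p_value,
             significant = p_value < ALPHA, n1 = n1, n2 = n2,
             stringsAsFactors = FALSE)
}

#' Compare a two-level factor with Welch's t-test
#'
#' For every combination of the remaining design factors, Welch's t-test
#' between the two levels of `factor` on `metric` (the cell-line and stroma
#' comparisons of the study design).
#'
#' @param table metrics data.frame with columns `cell_line`, `stroma`,
#'   `day` and the metric.
#' @param factor `"cell_line"` or `"stroma"`.
#' @param metric metric column name.
#' @return data.frame of comparisons: `metric`, `comparison`, `test`,
#'   `statistic`, `p_value`, `significant`, `n1`, `n2`.
#' @export
compare_factor <- function(table, factor = c("cell_line", "stroma"), metric) {
  factor <- match.arg(factor)
  check_metric_column(table, metric)
  lv <- sort(unique(table[[factor]]))
  if (length(lv) != 2L)
    stop_("factor '%s' must have exactly 2 levels (found %d)", factor, length(lv))
  others <- setdiff(c("cell_line", "stroma", "day"), factor)
  strata <- unique(table[others])
  out <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- rep(TRUE, nrow(table))
    for (o in others) sel <- sel & table[[o]] == strata[[o]][i]
    g1 <- table[[metric]][sel & table[[factor]] == lv[1]]
    g2 <- table[[metric]][sel & table[[factor]] == lv[2]]
    res <- welch_test(g1, g2)
    comparison_row(metric,
                   sprintf("%s: %s vs %s | %s", factor, lv[1], lv[2],
                           paste(sprintf("%s=%s", others,
                                         vapply(strata[i, , drop = FALSE],
                                                as.character, "")),
                                 collapse = ", ")),
                   "welch_t", res$statistic, res$p_value, res$n[1], res$n[2])
  })
  do.call(rbind, out)
}

#' Compare culture days with the Mann-Whitney U test
#'
#' For every (cell_line, stroma) condition, the Mann-Whitney U test between
#' the two day levels on `metric`. Pairing across days (the same physical
#' models re-imaged) is deliberately ignored, matching the design this
#' module reproduces; the comparison label notes the two groups.
#'
#' @inheritParams compare_factor
#' @return data.frame of comparisons (same columns as [compare_factor()]).
#' @export
compare_days <- function(table, metric) {
  check_metric_column(table, metric)
  days <- sort(unique(table$day))
  if (length(days) != 2L)
    stop_("day factor must have exactly 2 levels (found %d)", length(days))
  strata <- unique(table[c("cell_line", "stroma")])
  out <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- table$cell_line == strata$cell_line[i] &
      table$stroma == strata$stroma[i]
    g1 <- table[[metric]][sel & table$day == days[1]]
    g2 <- table[[metric]][sel & table$day == days[2]]
    res <- mann_whitney_test(g1, g2)
    comparison_row(metric,
                   sprintf("day: %s vs %s | cell_line=%s, stroma=%s",
                           days[1], days[2], strata$cell_line[i],
                           strata$stroma[i]),
                   if (res$exact) "mann_whitney_exact" else "mann_whitney_normal",
                   res$statistic, res$p_value, res$n[1], res$n[2])
  })
  do.call(rbind, out)
}
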