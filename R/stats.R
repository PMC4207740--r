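#' Two-way fixed-effects ANOVA with interaction
#'
#' Full-factorial table for `value ~ A * B` with Type II sums of squares, the
#' partition commonly reported for these designs (it reduces to the classical
#' decomposition when the design is balanced). Time-course comparisons treat
#' time as a between factor; no repeated-measures correction is applied and
#' the output notes this.
#'
#' @param data Data frame.
#' @param value,factor_a,factor_b Column names (strings) of the response and
#'   the two factors.
#' @return A tibble of class `sleep_anova` with columns `term`, `sumsq`,
#'   `df`, `statistic` (F), `p_value`; the fitted `lm` is kept in the `fit`
#'   attribute.
#' @examples
#' d <- expand.grid(g = c("a", "b"), t = c("x", "y"), r = 1:3)
#' d$y <- rnorm(nrow(d)) + (d$g == "a") * 2
#' two_way_anova(d, "y", "g", "t")
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  df <- data.frame(
    y = data[[value]],
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  if (anyNA(df)) abort("Missing values in response or factors.")
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    abort("Both factors need at least 2 levels.")
  }
  cells <- table(df$A, df$B)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(paste0(
      "Empty design cell: ", rownames(cells)[bad[1]], " x ",
      colnames(cells)[bad[2]], "."
    ))
  }
  fit <- lm(y ~ A * B, data = df)
  # car refuses a zero residual sum of squares (e.g. all-constant data); the
  # sequential partition is identical for balanced designs and still defined
  a2 <- tryCatch(
    car::Anova(fit, type = 2),
    error = function(e) {
      a1 <- suppressWarnings(stats::anova(fit))
      data.frame(
        `Sum Sq` = a1$`Sum Sq`, Df = a1$Df,
        `F value` = a1$`F value`, `Pr(>F)` = a1$`Pr(>F)`,
        row.names = rownames(a1), check.names = FALSE
      )
    }
  )
  terms_map <- c(
    "A" = factor_a, "B" = factor_b, "A:B" = paste0(factor_a, ":", factor_b),
    "Residuals" = "Residuals"
  )
  out <- tibble::tibble(
    term = unname(terms_map[rownames(a2)]),
    sumsq = a2$`Sum Sq`,
    df = a2$Df,
    statistic = a2$`F value`,
    p_value = a2$`Pr(>F)`
  )
  # all-equal data: 0/0 F ratios are reported as no effect
  degenerate <- !is.na(out$sumsq) & out$sumsq < 1e-12 & out$term != "Residuals"
  out$statistic[degenerate] <- 0
  out$p_value[degenerate] <- 1
  structure(out,
    fit = fit, type = "II",
    note = "fixed-effects ANOVA; no repeated-measures correction",
    class = c("sleep_anova", class(tibble::tibble()))
  )
}

#' Bonferroni-corrected post-hoc t-tests
#'
#' Within each level of `within`, a two-tailed two-sample t-test compares the
#' two groups of `compare`; each raw p-value is multiplied by the number of
#' levels (capped at 1). Welch's t (unequal variances) is the default; set
#' `var_equal = TRUE` for the pooled-variance test. Levels with fewer than 2
#' observations per group are flagged, not fatal.
#'
#' @param data Data frame.
#' @param value,compare,within Column names: response, two-group factor, and
#'   the factor whose levels index the comparisons (e.g. time bins).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return A tibble: `level`, `estimate` (group-1 minus group-2 mean),
#'   `statistic`, `df`, `p_value`, `p_bonferroni`, `note`.
#' @export
bonferroni_posthoc <- function(data, value, compare, within,
                               var_equal = FALSE) {
  g <- factor(data[[compare]])
  if (nlevels(g) != 2) abort("`compare` must have exactly two groups.")
  lv <- factor(data[[within]])
  n_levels <- nlevels(lv)
  y <- data[[value]]
  purrr::map_dfr(levels(lv), function(l) {
    sel <- lv == l
    y1 <- y[sel & g == levels(g)[1]]
    y2 <- y[sel & g == levels(g)[2]]
    if (length(y1) < 2 || length(y2) < 2) {
      return(tibble::tibble(
        level = l, estimate = NA_real_, statistic = NA_real_, df = NA_real_,
        p_value = NA_real_, p_bonferroni = NA_real_,
        note = "fewer than 2 observations per group"
      ))
    }
    if (sd(y1) == 0 && sd(y2) == 0 && mean(y1) == mean(y2)) {
      return(tibble::tibble(
        level = l, estimate = 0, statistic = 0, df = NA_real_,
        p_value = 1, p_bonferroni = 1, note = NA_character_
      ))
    }
    tt <- t.test(y1, y2, var.equal = var_equal)
    tibble::tibble(
      level = l, estimate = unname(diff(rev(tt$estimate))),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      p_bonferroni = min(1, tt$p.value * n_levels),
      note = NA_character_
    )
  })
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. For `n_x + n_y <= 16` the
#' two-sided p-value is exact, obtained by enumerating every assignment of
#' the observed values to the two groups (ties handled by mid-ranks); above
#' that, the normal approximation with tie correction and continuity
#' correction is used. The U statistic counts pairs in which the first group
#' exceeds the second (ties count one half).
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default picks
#'   by total sample size.
#' @return A one-row tibble: `statistic` (U for `x`), `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  nx <- length(x)
  ny <- length(y)
  exact <- exact %||% (nx + ny <= 16)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (exact) {
    # enumerate all assignments of the observed values to group x
    vals <- c(x, y)
    rv <- rank(vals)
    combos <- combn(nx + ny, nx)
    us <- apply(combos, 2, function(ix) sum(rv[ix]) - nx * (nx + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    tie_tab <- table(r)
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- u - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  tibble::tibble(statistic = u, p_value = p, method = method)
}
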