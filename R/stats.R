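#' Two-way repeated-measures ANOVA with partial eta squared
#'
#' Classical sum-of-squares decomposition for a fully crossed, balanced
#' within-subject design with one observation per subject x cell. Each
#' effect is tested against its own subject-by-effect error stratum, and
#' the effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error_effect)`. With a single factor the
#' decomposition reduces to the one-way repeated-measures ANOVA.
#'
#' No sphericity correction is applied: it is exact for 2-level factors and
#' omitted elsewhere (uncorrected degrees of freedom are reported).
#'
#' @param data data frame of cell means.
#' @param value,subject column names of the response and the subject id.
#' @param within character vector of one or two within-subject factor
#'   column names.
#' @return a data frame with one row per effect: `effect`, `df_num`,
#'   `df_den`, `F`, `p`, `eta_p_sq`.
#' @export
rm_anova2 <- function(data, value, subject, within) {
  stopifnot(is.data.frame(data), length(within) %in% c(1L, 2L),
            all(c(value, subject, within) %in% names(data)))
  y <- data[[value]]
  s <- factor(data[[subject]])
  a <- factor(data[[within[1]]])
  b <- if (length(within) == 2) factor(data[[within[2]]]) else factor(rep("1", nrow(data)))
  ns <- nlevels(s); na <- nlevels(a); nb <- nlevels(b)
  if (nrow(data) != ns * na * nb ||
      any(table(s, a, b) != 1)) {
    stop("design must be complete and balanced: one observation per subject x cell")
  }
  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)
  m_ab <- tapply(y, list(a, b), mean)

  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_s <- na * nb * sum((m_s - gm)^2)
  dev_as <- m_as - outer(m_a, rep(1, ns)) - outer(rep(1, na), m_s) + gm
  ss_as <- nb * sum(dev_as^2)
  dev_bs <- m_bs - outer(m_b, rep(1, ns)) - outer(rep(1, nb), m_s) + gm
  ss_bs <- na * sum(dev_bs^2)
  dev_ab <- m_ab - outer(m_a, rep(1, nb)) - outer(rep(1, na), m_b) + gm
  ss_ab <- ns * sum(dev_ab^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_as - ss_bs - ss_ab

  row <- function(name, ss_eff, df_num, ss_err, df_den) {
    f <- if (ss_err <= 0) {
      if (ss_eff <= 0) 0 else Inf
    } else (ss_eff / df_num) / (ss_err / df_den)
    data.frame(
      effect = name, df_num = df_num, df_den = df_den, F = f,
      p = stats::pf(f, df_num, df_den, lower.tail = FALSE),
      eta_p_sq = if (ss_eff + ss_err <= 0) 0 else ss_eff / (ss_eff + ss_err),
      stringsAsFactors = FALSE
    )
  }
  out <- row(within[1], ss_a, na - 1, ss_as, (na - 1) * (ns - 1))
  if (length(within) == 2) {
    out <- rbind(
      out,
      row(within[2], ss_b, nb - 1, ss_bs, (nb - 1) * (ns - 1)),
      row(paste(within, collapse = ":"), ss_ab, (na - 1) * (nb - 1),
          ss_abs, (na - 1) * (nb - 1) * (ns - 1))
    )
  }
  rownames(out) <- NULL
  out
}

#' One-way between-groups ANOVA
#'
#' Classical fixed-effects decomposition, used for comparisons of SSRT
#' estimates across task cells where the published analyses pooled the
#' cells as independent groups.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @return a one-row data frame: `df_num`, `df_den`, `F`, `p`, `eta_p_sq`.
#' @export
oneway_anova <- function(values, groups) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  gm <- mean(values)
  m_g <- tapply(values, g, mean)
  n_g <- tapply(values, g, length)
  ss_b <- sum(n_g * (m_g - gm)^2)
  ss_w <- sum((values - m_g[g])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  f <- if (ss_w <= 0) { if (ss_b <= 0) 0 else Inf } else (ss_b / df1) / (ss_w / df2)
  data.frame(
    df_num = df1, df_den = df2, F = f,
    p = stats::pf(f, df1, df2, lower.tail = FALSE),
    eta_p_sq = if (ss_b + ss_w <= 0) 0 else ss_b / (ss_b + ss_w)
  )
}

#' Paired t test
#'
#' Classical two-tailed paired t. Degenerate input (all differences zero)
#' reports `t = 0, p = 1` rather than an error, so that identical paired
#' samples compare as indistinguishable.
#'
#' @param a,b paired numeric samples of equal length (>= 2).
#' @return a list with `t`, `df`, `p`, and `mean_diff` (`mean(a - b)`).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_diff = md))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), mean_diff = md)
}

#' Bonferroni adjustment
#'
#' @param p_values numeric p values.
#' @param m number of comparisons (defaults to `length(p_values)`; must be
#'   at least that).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(m >= length(p_values), all(p_values >= 0 & p_values <= 1))
  pmin(1, p_values * m)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p value uses the
#' t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom. Constant input has no defined rank correlation and returns
#' `NA`.
#'
#' @param a,b paired numeric samples (n >= 5).
#' @return a list with `r` and `p` (both `NA` for constant input).
#' @export
spearman_cor <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ra <- rank(a); rb <- rank(b)
  r <- stats::cor(ra, rb)
  n <- length(a)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Two-proportion z test (pooled)
#'
#' Compares two binomial proportions with the pooled-variance z statistic
#' and a two-tailed normal p value.
#'
#' @param k1,n1 successes and trials in the first sample.
#' @param k2,n2 successes and trials in the second sample.
#' @return a list with `z`, `p`, `p1`, `p2`.
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0)
  if (k1 > n1 || k2 > n2) stop("successes cannot exceed trials")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Qualitative label for a partial eta squared effect size
#'
#' Conventional reference values: 0.01 small, 0.06 medium, 0.14 or higher
#' large; values below 0.01 are reported as negligible. Thresholds are
#' left-closed.
#'
#' @param eta_p_sq value in `[0, 1]`.
#' @return one of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_size_label <- function(eta_p_sq) {
  stopifnot(is.numeric(eta_p_sq))
  if (any(eta_p_sq < 0 | eta_p_sq > 1)) stop("eta_p_sq must lie in [0, 1]")
  labs <- c("negligible", "small", "medium", "large")
  labs[findInterval(eta_p_sq, c(0.01, 0.06, 0.14)) + 1L]
}
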