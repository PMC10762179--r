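# Statistics layer implemented from the defining formulas: one-way ANOVA,
# Tukey HSD (studentized-range CDF by numerical integration),
# repeated-measures one-way ANOVA, Pearson correlation with linear
# regression, and Shapiro-Wilk (Royston's coefficient algorithm). Every
# statistic is covered by a brute-force oracle in the test suite. All
# p-values are two-sided / upper-tail as appropriate.

new_stat_result <- function(statistic, df, p_value, method, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_lq("p-value outside [0,1]")
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, ...), class = "lq_stat")
}

#' @export
print.lq_stat <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, df = (%s), p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  invisible(x)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_lq("need at least 2 groups")
  for (g in groups) {
    if (!is.numeric(g) || length(g) < 2L || !all(is.finite(g)))
      stop_lq("each group needs >= 2 finite values")
  }
  groups
}

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` with df `(k - 1, N - k)`; p from the upper
#' tail of the F distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return `lq_stat` with fields `statistic`, `df`, `p_value`, plus
#'   `ms_within` and `group_means` for downstream Tukey pooling.
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ss_within <= 0) stop_lq("zero within-group variance: F undefined")
  df1 <- k - 1L; df2 <- N - k
  f <- (ss_between / df1) / (ss_within / df2)
  new_stat_result(f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE),
                  "one-way ANOVA", ms_within = ss_within / df2,
                  group_means = means, group_n = n)
}

#' Tukey's honestly-significant-difference comparisons
#'
#' Pairwise studentized-range statistics pooled on the ANOVA `MS_within`:
#' `q = |m_i - m_j| / sqrt((MSW/2) (1/n_i + 1/n_j))` (Tukey-Kramer, which
#' reduces to `|m_i - m_j| / sqrt(MSW/n)` under equal n). Adjusted p-values
#' from the studentized range distribution with parameters `(k, N - k)`.
#'
#' @param groups list of numeric samples, optionally named.
#' @return object of class `pairwise_comparisons`: data frame with columns
#'   `group1`, `group2`, `diff`, `q`, `p_adj`, and attribute `family`.
#' @export
tukey_hsd <- function(groups) {
  a <- one_way_anova(groups)
  k <- length(groups)
  labs <- names(groups) %||% as.character(seq_len(k))
  df_err <- a$df[2L]
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- a$group_means[i] - a$group_means[j]
    se <- sqrt(a$ms_within / 2 * (1 / a$group_n[i] + 1 / a$group_n[j]))
    q <- abs(d) / se
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = labs[i], group2 = labs[j], diff = unname(d), q = unname(q),
      p_adj = 1 - studentized_range_cdf(q, k, df_err),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "family") <- sprintf("Tukey HSD, k = %d, df = %d", k, df_err)
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' Studentized range distribution function
#'
#' `P(Q <= q)` for the range of `k` iid standard normals divided by an
#' independent chi estimate on `df` degrees of freedom, computed by direct
#' numerical integration (documented tolerance about 1e-6):
#' `integral over s of f_s(s) * k * integral phi(z) (Phi(z) - Phi(z - q s))^(k-1) dz`,
#' with `s ~ sqrt(chisq_df / df)`.
#'
#' @param q quantile (scalar).
#' @param k number of groups.
#' @param df error degrees of freedom (`Inf` allowed).
#' @return cumulative probability.
#' @export
studentized_range_cdf <- function(q, k, df) {
  if (!is.finite(q)) return(if (q > 0) 1 else 0)
  if (q <= 0) return(0)
  gl <- gauss_legendre(96L)
  # inner integral over z on [-8, 8]: the standard-normal factor kills the
  # tails far below the documented tolerance
  z <- 8 * gl$nodes
  wz <- 8 * gl$weights
  phi_z <- stats::dnorm(z)
  Phi_z <- stats::pnorm(z)
  prange <- function(u) {  # vectorised over u >= 0
    dz <- Phi_z - stats::pnorm(outer(z, u, `-`))
    pmin(k * colSums(wz * phi_z * dz^(k - 1)), 1)
  }
  if (is.infinite(df)) return(prange(q))
  # outer integral over the scale s ~ sqrt(chisq_df/df) on its effective
  # support
  s_lo <- sqrt(stats::qchisq(1e-14, df) / df)
  s_hi <- sqrt(stats::qchisq(1 - 1e-14, df) / df)
  s <- (s_hi - s_lo) / 2 * gl$nodes + (s_hi + s_lo) / 2
  ws <- (s_hi - s_lo) / 2 * gl$weights
  log_norm <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2)
  dens <- exp(log_norm + (df - 1) * log(s) - df * s^2 / 2)
  v <- sum(ws * dens * prange(q * s))
  min(1, max(0, v))
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; cached.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  hit <- .gl_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(nodes = rev(e$values),
              weights = rev(2 * e$vectors[1L, ]^2))
  .gl_cache[[key]] <- out
  out
}

#' Repeated-measures one-way ANOVA
#'
#' Complete subjects-by-conditions table; the subject effect is removed and
#' `F = MS_condition / MS_error` with df `(k - 1, (k - 1)(n - 1))`.
#'
#' @param table numeric matrix, rows = subjects, columns = conditions
#'   (complete; no imputation -- missing values error).
#' @return `lq_stat`, additionally carrying `ms_error` and
#'   `condition_means`.
#' @export
rm_one_way_anova <- function(table) {
  check_matrix(table, "table")
  if (anyNA(table) || !all(is.finite(table)))
    stop_lq("incomplete table: repeated-measures ANOVA requires complete data")
  n <- nrow(table); k <- ncol(table)
  if (n < 2L || k < 2L) stop_lq("need >= 2 subjects and >= 2 conditions")
  grand <- mean(table)
  subj_means <- rowMeans(table)
  cond_means <- colMeans(table)
  ss_total <- sum((table - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_err <- ss_err / df2
  if (ms_err <= 0) stop_lq("zero error variance: F undefined")
  f <- (ss_cond / df1) / ms_err
  new_stat_result(f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE),
                  "repeated-measures one-way ANOVA",
                  ms_error = ms_err, condition_means = cond_means)
}

#' Tukey comparisons after repeated-measures ANOVA
#'
#' Pairwise condition comparisons pooled on the repeated-measures error
#' term: `q = |m_i - m_j| / sqrt(MS_error / n)` with the studentized range
#' distribution on `(k, (k-1)(n-1))`.
#'
#' @param table subjects-by-conditions matrix as in [rm_one_way_anova()].
#' @return `pairwise_comparisons` data frame.
#' @export
tukey_hsd_rm <- function(table) {
  a <- rm_one_way_anova(table)
  k <- ncol(table); n <- nrow(table)
  labs <- colnames(table) %||% as.character(seq_len(k))
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- a$condition_means[i] - a$condition_means[j]
    q <- abs(d) / sqrt(a$ms_error / n)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = labs[i], group2 = labs[j], diff = unname(d), q = unname(q),
      p_adj = 1 - studentized_range_cdf(q, k, a$df[2L]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "family") <- sprintf("Tukey HSD (RM), k = %d, df = %d", k, a$df[2L])
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' Pearson correlation with linear regression
#'
#' Product-moment `r`; two-sided p from `t = r sqrt((n-2)/(1-r^2))`.
#' Because correlation and simple linear regression are routinely reported
#' together, the least-squares slope and intercept are attached.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return `lq_stat` with `statistic = r`, plus `slope` and `intercept`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_lq("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_lq("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_lq("non-finite input")
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx <= 0 || sy <= 0) stop_lq("zero variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sx * sy)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(t), n - 2L, lower.tail = FALSE)
  }
  new_stat_result(r, c(n - 2L), p, "Pearson correlation",
                  slope = sxy / sx, intercept = mean(y) - sxy / sx * mean(x),
                  n = n)
}

#' Shapiro-Wilk normality test
#'
#' W statistic from Royston's coefficient algorithm (normal order-statistic
#' scores with polynomial-corrected tail weights), p-value from Royston's
#' normal approximations. Valid for 3 <= n <= 5000.
#'
#' @param x numeric sample.
#' @return `lq_stat` with `statistic = W`.
#' @export
shapiro_wilk <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 3L || n > 5000L) stop_lq("Shapiro-Wilk requires 3 <= n <= 5000")
  if (!all(is.finite(x))) stop_lq("non-finite input")
  if (x[1L] == x[n]) stop_lq("zero variance: W undefined")
  m <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  ssq_m <- sum(m^2)
  rsn <- 1 / sqrt(n)
  a <- m / sqrt(ssq_m)
  if (n > 5L) {
    a_n <- a[n] + rsn * (-2.706056 * rsn^4 + 4.434685 * rsn^3 -
                           2.071190 * rsn^2 - 0.147981 * rsn + 0.221157)
    a_n1 <- a[n - 1L] + rsn * (-3.582633 * rsn^4 + 5.682633 * rsn^3 -
                                 1.752461 * rsn^2 - 0.293762 * rsn + 0.042981)
    phi <- (ssq_m - 2 * m[n]^2 - 2 * m[n - 1L]^2) /
      (1 - 2 * a_n^2 - 2 * a_n1^2)
    a <- m / sqrt(phi)
    a[n] <- a_n; a[1L] <- -a_n
    a[n - 1L] <- a_n1; a[2L] <- -a_n1
  } else if (n > 3L) {
    a_n <- a[n] + rsn * (-2.706056 * rsn^4 + 4.434685 * rsn^3 -
                           2.071190 * rsn^2 - 0.147981 * rsn + 0.221157)
    phi <- (ssq_m - 2 * m[n]^2) / (1 - 2 * a_n^2)
    a <- m / sqrt(phi)
    a[n] <- a_n; a[1L] <- -a_n
  }
  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  W <- min(W, 1)
  p <- if (n == 3L) {
    # exact for n = 3: small W gives small p directly
    6 / pi * (asin(sqrt(W)) - asin(sqrt(0.75)))
  } else if (n <= 11L) {
    gma <- -2.273 + 0.459 * n
    w1 <- -log(gma - log(1 - W))
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    stats::pnorm((w1 - mu) / sig, lower.tail = FALSE)
  } else {
    ln <- log(n)
    w1 <- log(1 - W)
    mu <- 0.0038915 * ln^3 - 0.083751 * ln^2 - 0.31082 * ln - 1.5861
    sig <- exp(0.0030302 * ln^2 - 0.082676 * ln - 0.4803)
    stats::pnorm((w1 - mu) / sig, lower.tail = FALSE)
  }
  new_stat_result(W, c(n), min(max(p, 0), 1), "Shapiro-Wilk", n = n)
}

#' Flatten statistics results to a summary data frame
#'
#' @param results named list of `lq_stat` and/or `pairwise_comparisons`.
#' @return data frame with columns `analysis`, `method`, `statistic`, `df`,
#'   `p_value`, `comparison`.
#' @export
stats_summary <- function(results) {
  rows <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "lq_stat")) {
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = nm, method = x$method, statistic = x$statistic,
        df = paste(x$df, collapse = ","), p_value = x$p_value,
        comparison = NA_character_, stringsAsFactors = FALSE)
    } else if (inherits(x, "pairwise_comparisons")) {
      for (i in seq_len(nrow(x))) {
        rows[[length(rows) + 1L]] <- data.frame(
          analysis = nm, method = attr(x, "family"), statistic = x$q[i],
          df = NA_character_, p_value = x$p_adj[i],
          comparison = paste(x$group1[i], "vs", x$group2[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
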