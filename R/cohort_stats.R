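#' Adaptive two-group comparison
#'
#' Chooses the test from the data type and normality: categorical data get a
#' chi-squared test on the contingency table (no continuity correction by
#' default); continuous data are checked per group with Shapiro-Wilk at
#' `normality_alpha` — both groups normal gives a two-tailed Student t test
#' (pooled variance), otherwise a Wilcoxon rank-sum test (exact p when both
#' groups have n < 25 and no ties, else the normal approximation with tie
#' correction). A group with fewer than 3 observations cannot be
#' normality-tested and falls back to Wilcoxon with a warning.
#'
#' @param values Outcome vector (numeric, or factor/character/logical for
#'   categorical data).
#' @param group Two-level grouping vector.
#' @param type `"continuous"` or `"categorical"`.
#' @param normality_alpha Shapiro-Wilk alpha (default .05).
#' @param chisq_correct Apply the Yates continuity correction
#'   (default `FALSE`).
#' @return A list of class `comparison_result`: `test_used` (`"t"`,
#'   `"wilcoxon"` or `"chi2"`), `statistic`, `p_value`, `group_summaries`.
#' @export
compare_groups <- function(values, group,
                           type = c("continuous", "categorical"),
                           normality_alpha = 0.05, chisq_correct = FALSE) {
  type <- match.arg(type)
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) != 2) stop("exactly two non-empty groups are required")
  if (type == "categorical") {
    tab <- table(group, values)
    ht <- stats::chisq.test(tab, correct = chisq_correct)
    summaries <- lapply(split(values, group), function(v) {
      tb <- table(v); list(n = as.integer(tb), pct = 100 * as.numeric(tb) / length(v))
    })
    res <- list(test_used = "chi2", statistic = unname(ht$statistic),
                p_value = ht$p.value, group_summaries = summaries,
                table = tab)
  } else {
    values <- as.numeric(values)
    vs <- split(values, group)
    small <- vapply(vs, length, integer(1)) < 3
    norm_p <- rep(NA_real_, 2)
    if (any(small)) {
      warning("a group has fewer than 3 observations; falling back to Wilcoxon")
      normal <- FALSE
    } else {
      norm_p <- vapply(vs, function(v) {
        if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
      }, numeric(1))
      normal <- all(norm_p > normality_alpha)
    }
    if (normal) {
      ht <- stats::t.test(vs[[1]], vs[[2]], var.equal = TRUE)
      test <- "t"
    } else {
      n1 <- length(vs[[1]]); n2 <- length(vs[[2]])
      ties <- anyDuplicated(values) > 0
      exact <- n1 < 25 && n2 < 25 && !ties
      ht <- stats::wilcox.test(vs[[1]], vs[[2]], exact = exact)
      test <- "wilcoxon"
    }
    summaries <- lapply(vs, function(v) list(n = length(v), mean = mean(v),
                                             sd = stats::sd(v),
                                             median = stats::median(v)))
    res <- list(test_used = test, statistic = unname(ht$statistic),
                p_value = ht$p.value, group_summaries = summaries,
                normality_p = norm_p)
  }
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  invisible(x)
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Tests each main effect adjusting for the other factor (e.g., phenotype
#' differences in Fitbit measures adjusting for employment status).
#'
#' @param values Numeric outcome.
#' @param factor_a,factor_b Factors (each needs at least two observed
#'   levels).
#' @return Data.frame `factor, F, p` with one row per main effect.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- droplevels(factor(factor_a)); b <- droplevels(factor(factor_b))
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("each factor needs at least two levels")
  }
  d <- data.frame(y = as.numeric(values), a = a, b = b)
  fit <- stats::lm(y ~ a + b, data = d)
  tab <- car::Anova(fit, type = 2)
  eff <- rownames(tab) %in% c("a", "b")
  data.frame(factor = c("factor_a", "factor_b"),
             F = tab$`F value`[eff], p = tab$`Pr(>F)`[eff],
             stringsAsFactors = FALSE)
}

# ---- missing-data machinery ------------------------------------------------

# EM estimates of a multivariate normal mean/covariance with missing entries
em_norm_missing <- function(X, max_iter = 300, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  vars <- apply(X, 2, stats::var, na.rm = TRUE)
  vars[!is.finite(vars) | vars <= 0] <- 1
  S <- diag(vars, p)
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p)
    for (i in seq_len(n)) {
      o <- !is.na(X[i, ]); m <- !o
      xi <- X[i, ]
      if (any(m)) {
        if (any(o)) {
          B <- S[m, o, drop = FALSE] %*% solve(S[o, o, drop = FALSE])
          xi[m] <- mu[m] + B %*% (xi[o] - mu[o])
          C <- S[m, m, drop = FALSE] - B %*% t(S[m, o, drop = FALSE])
        } else {
          xi[m] <- mu[m]; C <- S[m, m, drop = FALSE]
        }
        T2[m, m] <- T2[m, m] + C
      }
      T1 <- T1 + xi; T2 <- T2 + tcrossprod(xi)
    }
    mu_new <- T1 / n
    S_new <- T2 / n - tcrossprod(mu_new)
    if (max(abs(mu_new - mu), abs(S_new - S)) < tol) {
      mu <- mu_new; S <- S_new; break
    }
    mu <- mu_new; S <- S_new
  }
  list(mu = mu, sigma = S)
}

# single stochastic imputation from the conditional normal
impute_conditional_normal <- function(X, mu, S) {
  X <- as.matrix(X)
  for (i in seq_len(nrow(X))) {
    m <- is.na(X[i, ]); o <- !m
    if (!any(m)) next
    if (any(o)) {
      B <- S[m, o, drop = FALSE] %*% solve(S[o, o, drop = FALSE])
      cm <- mu[m] + drop(B %*% (X[i, o] - mu[o]))
      C <- S[m, m, drop = FALSE] - B %*% t(S[m, o, drop = FALSE])
    } else {
      cm <- mu; C <- S
    }
    C <- (C + t(C)) / 2
    X[i, m] <- cm + drop(stats::rnorm(sum(m)) %*% chol(C + 1e-10 * diag(sum(m))))
  }
  X
}

# Neyman smooth statistic (4 components, orthonormal shifted Legendre)
neyman_smooth4 <- function(u) {
  n <- length(u)
  p1 <- sqrt(3) * (2 * u - 1)
  p2 <- sqrt(5) * (6 * u^2 - 6 * u + 1)
  p3 <- sqrt(7) * (20 * u^3 - 30 * u^2 + 12 * u - 1)
  p4 <- 3 * (70 * u^4 - 140 * u^3 + 90 * u^2 - 20 * u + 1)
  sum(c(sum(p1), sum(p2), sum(p3), sum(p4))^2) / n
}

# Hawkins k-sample homoscedasticity/normality statistic on complete data.
# For case j of group i, d_ij = z' A^{-1} z with z the within-group
# deviation and A the pooled within-group SSCP; under multivariate
# normality with equal covariances B = n_i d_ij/(n_i-1) ~ Beta(p/2,(n-k-p)/2),
# mapped to F(p, n-k-p) tail areas that are uniform under the null.
hawkins_stat <- function(Xc, g) {
  Xc <- as.matrix(Xc)
  n <- nrow(Xc); p <- ncol(Xc)
  grps <- split(seq_len(n), g); k <- length(grps)
  if (n - k - p <= 0) stop("too few cases for the Hawkins statistic")
  A <- matrix(0, p, p); means <- vector("list", k)
  for (gi in seq_len(k)) {
    idx <- grps[[gi]]
    means[[gi]] <- colMeans(Xc[idx, , drop = FALSE])
    Z <- sweep(Xc[idx, , drop = FALSE], 2, means[[gi]])
    A <- A + crossprod(Z)
  }
  Ainv <- solve(A)
  stat <- 0
  for (gi in seq_len(k)) {
    idx <- grps[[gi]]; ni <- length(idx)
    Z <- sweep(Xc[idx, , drop = FALSE], 2, means[[gi]])
    d <- rowSums((Z %*% Ainv) * Z)
    B <- pmin(ni * d / (ni - 1), 1 - 1e-12)
    Fij <- ((n - k - p) * B) / (p * (1 - B))
    Aij <- stats::pf(Fij, p, n - k - p, lower.tail = FALSE)
    stat <- stat + neyman_smooth4(Aij)
  }
  list(statistic = stat, df = 4 * k,
       p = stats::pchisq(stat, 4 * k, lower.tail = FALSE))
}

# Little-type likelihood-ratio comparison of pattern-wise observed means
# against the EM estimates under a common normal model
little_mean_stat <- function(X, mu, S, pat) {
  X <- as.matrix(X)
  d2 <- 0; df <- 0
  for (pp in unique(pat)) {
    idx <- which(pat == pp)
    o <- !is.na(X[idx[1], ])
    ni <- length(idx)
    xb <- colMeans(X[idx, o, drop = FALSE])
    So <- S[o, o, drop = FALSE]
    d2 <- d2 + ni * drop(t(xb - mu[o]) %*% solve(So) %*% (xb - mu[o]))
    df <- df + sum(o)
  }
  df <- df - ncol(X)
  list(statistic = d2, df = df,
       p = stats::pchisq(d2, df, lower.tail = FALSE))
}

#' Hawkins-style test of the missing-completely-at-random mechanism
#'
#' Groups cases by missingness pattern and asks whether the patterns look
#' like random subsamples of one multivariate normal population — patterns
#' are compared for equal means and equal covariances. The mean component is
#' a Little-type likelihood-ratio statistic on the pattern-wise observed
#' means under EM-estimated normal parameters; the covariance/normality
#' component is the Hawkins k-sample statistic (Neyman smooth combination of
#' studentized-distance tail areas) computed after a single stochastic
#' conditional-normal imputation. The overall p-value Fisher-combines the
#' two components. A p-value above alpha is consistent with MCAR.
#'
#' The imputation draws from the current RNG stream; seed it for
#' reproducibility.
#'
#' @param X Numeric matrix or data.frame (cases x variables) containing
#'   `NA`s. Cases missing every variable are dropped.
#' @param min_pattern_cases Patterns with fewer cases are dropped (default
#'   6) — the Hawkins statistic needs within-pattern dispersion.
#' @return A list of class `mcar_test`: `p_value` (overall), `p_means`,
#'   `p_covariances`, `statistic` (Hawkins), `n_patterns`, `n_used`.
#' @export
hawkins_mcar_test <- function(X, min_pattern_cases = 6) {
  X <- as.matrix(X)
  if (!anyNA(X)) stop("test undefined: data are complete (a single missingness pattern)")
  X <- X[rowSums(!is.na(X)) > 0, , drop = FALSE]
  pat <- apply(is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  keep <- pat %in% names(which(table(pat) >= min_pattern_cases))
  if (sum(!keep) > 0) {
    message(sum(!keep), " case(s) in patterns with fewer than ",
            min_pattern_cases, " cases dropped")
  }
  X <- X[keep, , drop = FALSE]; pat <- pat[keep]
  if (length(unique(pat)) < 2) {
    stop("test undefined: need at least 2 distinct missingness patterns")
  }
  est <- em_norm_missing(X)
  mean_comp <- little_mean_stat(X, est$mu, est$sigma, pat)
  Xc <- impute_conditional_normal(X, est$mu, est$sigma)
  cov_comp <- hawkins_stat(Xc, pat)
  fisher <- -2 * (log(mean_comp$p) + log(cov_comp$p))
  out <- list(p_value = stats::pchisq(fisher, 4, lower.tail = FALSE),
              p_means = mean_comp$p, p_covariances = cov_comp$p,
              statistic = cov_comp$statistic,
              n_patterns = length(unique(pat)), n_used = nrow(X))
  class(out) <- "mcar_test"
  out
}

#' @export
print.mcar_test <- function(x, ...) {
  cat(sprintf(paste0("MCAR test on %d cases in %d missingness patterns\n",
                     "  means p = %.4g, covariances/normality p = %.4g\n",
                     "  overall p = %.4g (%s MCAR at alpha = .05)\n"),
              x$n_used, x$n_patterns, x$p_means, x$p_covariances, x$p_value,
              if (x$p_value > 0.05) "consistent with" else "inconsistent with"))
  invisible(x)
}
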