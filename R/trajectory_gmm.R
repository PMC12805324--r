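#' Growth-mixture model specification
#'
#' Latent-class linear growth for day-level series: each class has its own
#' fixed intercept and slope over days since individual device deployment;
#' a patient-level random intercept variance and the residual variance are
#' shared across classes. Fitted by EM, best of `n_restarts` by
#' log-likelihood, with deterministic seeding of restarts.
#'
#' @param n_classes Number of latent classes (>= 1).
#' @param n_restarts EM restarts (first restart uses a deterministic
#'   quantile split of patient means; later restarts randomise).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param seed Seed for restart initialisation (mandatory for
#'   reproducibility).
#' @return A list of class `gmm_spec`.
#' @export
gmm_spec <- function(n_classes = 2, n_restarts = 5, max_iter = 500,
                     tol = 1e-6, seed = 1) {
  stopifnot(n_classes >= 1, tol > 0, n_restarts >= 1, max_iter >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "gmm_spec")
}

#' Build a day-level series table from day summaries
#'
#' @param summaries Day-summary data.frame.
#' @param measure Feature column to model (e.g. `"mvpa_minutes"`).
#' @param valid_only Use valid wear days only (default `TRUE`).
#' @return Data.frame `patient_id, day, value` with `day` = days since each
#'   patient's first day (day 0 of deployment).
#' @export
gmm_series <- function(summaries, measure, valid_only = TRUE) {
  s <- summaries
  if (valid_only) s <- s[!is.na(s$is_valid_day) & s$is_valid_day, , drop = FALSE]
  if (!measure %in% names(s)) stop("unknown measure: ", measure)
  first <- tapply(as.numeric(s$date), s$patient_id, min)
  data.frame(patient_id = s$patient_id,
             day = as.numeric(s$date) - first[s$patient_id],
             value = s[[measure]], stringsAsFactors = FALSE, row.names = NULL)
}

# sufficient statistics per patient for the linear-growth likelihood
gmm_suffstats <- function(series) {
  sp <- split(series, series$patient_id)
  ids <- names(sp)
  stats_mat <- t(vapply(sp, function(d) {
    c(n = nrow(d), S1 = sum(d$value), S2 = sum(d$value^2),
      St = sum(d$day), Stt = sum(d$day^2), Sty = sum(d$day * d$value))
  }, numeric(6)))
  list(ids = ids, n = stats_mat[, "n"], S1 = stats_mat[, "S1"],
       S2 = stats_mat[, "S2"], St = stats_mat[, "St"],
       Stt = stats_mat[, "Stt"], Sty = stats_mat[, "Sty"])
}

# per-patient, per-class marginal log-density under y ~ N(a + b t + u, se2 I),
# u ~ N(0, su2): Sigma = se2 I + su2 J, handled via its closed-form inverse
gmm_class_loglik <- function(ss, a, b, su2, se2) {
  K <- length(a); P <- length(ss$n)
  ll <- rs <- matrix(0, P, K)
  for (k in seq_len(K)) {
    r_sum <- ss$S1 - a[k] * ss$n - b[k] * ss$St
    r_ss <- ss$S2 - 2 * a[k] * ss$S1 - 2 * b[k] * ss$Sty +
      a[k]^2 * ss$n + 2 * a[k] * b[k] * ss$St + b[k]^2 * ss$Stt
    denom <- se2 + ss$n * su2
    ll[, k] <- -0.5 * (ss$n * log(2 * pi) + (ss$n - 1) * log(se2) +
                         log(denom) + r_ss / se2 -
                         su2 * r_sum^2 / (se2 * denom))
    rs[, k] <- r_sum
  }
  list(ll = ll, r_sum = rs)
}

gmm_obs_loglik <- function(ss, pi_k, a, b, su2, se2) {
  cl <- gmm_class_loglik(ss, a, b, su2, se2)
  lw <- sweep(cl$ll, 2, log(pi_k), "+")
  mx <- apply(lw, 1, max)
  sum(mx + log(rowSums(exp(lw - mx))))
}

gmm_em_once <- function(ss, K, init, max_iter, tol) {
  pi_k <- init$pi; a <- init$a; b <- init$b
  su2 <- init$su2; se2 <- init$se2
  P <- length(ss$n); N <- sum(ss$n)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cl <- gmm_class_loglik(ss, a, b, su2, se2)
    lw <- sweep(cl$ll, 2, log(pi_k), "+")
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    # EM guarantee: the observed log-likelihood never decreases
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      stop("internal error: EM log-likelihood decreased")
    }
    ll_trace <- c(ll_trace, ll)
    w <- exp(lw - lse)                       # responsibilities, rows sum to 1
    pi_new <- colMeans(w)
    if (min(pi_new) < 1 / P) {
      return(list(failed = TRUE, reason = "empty_class"))
    }
    denom <- se2 + ss$n * su2
    Eu <- su2 * cl$r_sum / denom             # E[u_i | y, class k]
    Vu <- su2 * se2 / denom                  # Var[u_i | y, class k] (per patient)
    # class-specific weighted regression of (y - E[u]) on time
    a_new <- a; b_new <- b
    for (k in seq_len(K)) {
      wk <- w[, k]
      sw_n <- sum(wk * ss$n); sw_t <- sum(wk * ss$St); sw_tt <- sum(wk * ss$Stt)
      sw_y <- sum(wk * (ss$S1 - ss$n * Eu[, k]))
      sw_ty <- sum(wk * (ss$Sty - ss$St * Eu[, k]))
      M <- matrix(c(sw_n, sw_t, sw_t, sw_tt), 2, 2)
      sol <- tryCatch(solve(M, c(sw_y, sw_ty)), error = function(e) NULL)
      if (is.null(sol)) return(list(failed = TRUE, reason = "singular_design"))
      a_new[k] <- sol[1]; b_new[k] <- sol[2]
    }
    # variance components from residuals at the new class lines
    su2_new <- sum(w * (Eu^2 + Vu)) / P
    se2_acc <- 0
    for (k in seq_len(K)) {
      r_sum_k <- ss$S1 - a_new[k] * ss$n - b_new[k] * ss$St
      r_ss_k <- ss$S2 - 2 * a_new[k] * ss$S1 - 2 * b_new[k] * ss$Sty +
        a_new[k]^2 * ss$n + 2 * a_new[k] * b_new[k] * ss$St +
        b_new[k]^2 * ss$Stt
      se2_acc <- se2_acc +
        sum(w[, k] * (r_ss_k - 2 * Eu[, k] * r_sum_k + ss$n * (Eu[, k]^2 + Vu)))
    }
    se2_new <- se2_acc / N
    pi_k <- pi_new; a <- a_new; b <- b_new
    su2 <- max(su2_new, 1e-10); se2 <- max(se2_new, 1e-10)
    if (ll - ll_old < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(failed = FALSE, pi = pi_k, a = a, b = b, su2 = su2, se2 = se2,
       loglik = ll_old, converged = converged, n_iter = length(ll_trace),
       ll_trace = ll_trace)
}

gmm_init <- function(ss, K, random) {
  pmean <- ss$S1 / ss$n
  P <- length(pmean)
  grp <- if (K == 1) {
    rep(1L, P)
  } else if (random) {
    sample(rep_len(seq_len(K), P))
  } else {
    cut(rank(pmean, ties.method = "first"), K, labels = FALSE)
  }
  a <- as.numeric(tapply(pmean, grp, mean))
  a[is.na(a)] <- mean(pmean)
  if (random) a <- a + stats::rnorm(K, 0, stats::sd(pmean) / 4 + 1e-6)
  within_var <- mean(pmax((ss$S2 - ss$S1^2 / ss$n) / pmax(ss$n - 1, 1), 1e-6))
  su2 <- stats::var(pmean) / 2
  if (!is.finite(su2) || su2 <= 0) su2 <- within_var / 2
  list(pi = rep(1 / K, K), a = a, b = rep(0, K),
       su2 = max(su2, 1e-6), se2 = within_var)
}

# full-parameter negative log-likelihood for SE computation; mixing
# proportions enter through a multinomial-logit and variances through logs
gmm_negll_par <- function(par, ss, K) {
  a <- par[1:K]; b <- par[(K + 1):(2 * K)]
  if (K > 1) {
    eta <- c(par[(2 * K + 1):(3 * K - 1)], 0)
    pi_k <- exp(eta) / sum(exp(eta))
  } else pi_k <- 1
  su2 <- exp(par[3 * K]); se2 <- exp(par[3 * K + 1])
  -gmm_obs_loglik(ss, pi_k, a, b, su2, se2)
}

#' Fit a growth mixture model to day-level series
#'
#' @param series Data.frame `patient_id, day, value` (see [gmm_series()]);
#'   each patient needs at least 2 days.
#' @param spec A [gmm_spec()].
#' @return A list of class `gmm_fit`: `classes` (per-class proportion,
#'   intercept, slope, SEs and p-values, modal size), `sigma_u2`,
#'   `sigma_e2`, `loglik`, `BIC`, `posterior` (patients x classes),
#'   `n_patients`, `converged`, `ll_trace`. Classes are canonicalised in
#'   ascending intercept order.
#' @export
fit_gmm <- function(series, spec = gmm_spec()) {
  series <- series[!is.na(series$value), , drop = FALSE]
  ss <- gmm_suffstats(series)
  if (any(ss$n < 2)) stop("every patient needs at least 2 days of data")
  K <- spec$n_classes
  P <- length(ss$n)
  if (K > P) stop("more classes than patients")
  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  for (r in seq_len(spec$n_restarts)) {
    set.seed(spec$seed + r - 1)
    init <- gmm_init(ss, K, random = r > 1)
    res <- gmm_em_once(ss, K, init, spec$max_iter, spec$tol)
    if (res$failed) next
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) stop("all EM restarts failed (empty class or singular design)")
  if (!best$converged) {
    warning("EM did not converge in ", spec$max_iter,
            " iterations; returning best fit so far")
  }
  ord <- order(best$a)                      # canonical order: ascending intercept
  a <- best$a[ord]; b <- best$b[ord]; pi_k <- best$pi[ord]
  cl <- gmm_class_loglik(ss, a, b, best$su2, best$se2)
  lw <- sweep(cl$ll, 2, log(pi_k), "+")
  mx <- apply(lw, 1, max)
  post <- exp(lw - (mx + log(rowSums(exp(lw - mx)))))
  rownames(post) <- ss$ids
  modal <- apply(post, 1, which.max)
  # SEs from the numerical Hessian of the full-parameter log-likelihood
  par <- c(a, b, if (K > 1) log(pi_k[-K] / pi_k[K]), log(best$su2), log(best$se2))
  se_a <- se_b <- rep(NA_real_, K)
  H <- tryCatch(stats::optimHess(par, gmm_negll_par, ss = ss, K = K),
                error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      if (all(dv[1:(2 * K)] > 0)) {
        se_a <- sqrt(dv[1:K]); se_b <- sqrt(dv[(K + 1):(2 * K)])
      }
    }
  }
  classes <- data.frame(
    class = seq_len(K), proportion = pi_k, intercept = a, slope = b,
    se_intercept = se_a, se_slope = se_b,
    p_intercept = 2 * stats::pnorm(-abs(a / se_a)),
    p_slope = 2 * stats::pnorm(-abs(b / se_b)),
    modal_size = as.integer(tabulate(modal, nbins = K)))
  npar <- 2 * K + (K - 1) + 2
  out <- list(classes = classes, sigma_u2 = best$su2, sigma_e2 = best$se2,
              loglik = best$loglik,
              BIC = -2 * best$loglik + npar * log(P),
              posterior = post, n_patients = P,
              converged = best$converged, n_iter = best$n_iter,
              ll_trace = best$ll_trace, spec = spec)
  class(out) <- "gmm_fit"
  out
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Growth mixture fit: %d class(es), %d patients, logLik %.2f, BIC %.2f\n",
              nrow(x$classes), x$n_patients, x$loglik, x$BIC))
  print(x$classes, digits = 4)
  invisible(x)
}

#' Choose the number of latent classes by BIC
#'
#' Fits K = 1..`k_max` with common seeds and picks the lowest BIC (ties go
#' to the smaller K). A K whose restarts all fail is skipped with a warning.
#'
#' @param series Data.frame `patient_id, day, value`.
#' @param k_max Largest class count to try.
#' @param spec Base [gmm_spec()] (its `n_classes` is overridden).
#' @return List `table` (data.frame `K, BIC, loglik, converged`),
#'   `chosen_k`, `fits`.
#' @export
select_classes <- function(series, k_max, spec = gmm_spec()) {
  stopifnot(k_max >= 1)
  fits <- list(); rows <- list()
  for (K in seq_len(k_max)) {
    sp <- spec; sp$n_classes <- K
    fit <- tryCatch(fit_gmm(series, sp), error = function(e) {
      warning("K = ", K, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    fits[[as.character(K)]] <- fit
    rows[[length(rows) + 1]] <- data.frame(K = K, BIC = fit$BIC,
                                           loglik = fit$loglik,
                                           converged = fit$converged)
  }
  if (length(rows) == 0) stop("no class count could be fitted")
  tab <- do.call(rbind, rows)
  chosen <- tab$K[which.min(tab$BIC)]      # which.min takes the first (smallest K) on ties
  list(table = tab, chosen_k = chosen, fits = fits)
}

#' Modal class assignment and classification entropy
#'
#' @param fit A `gmm_fit`.
#' @return List `assignments` (data.frame `patient_id, class,
#'   max_posterior`) and `entropy`: relative entropy in \[0, 1\], 1 for
#'   perfect separation (and by convention for a single class), near 0 for
#'   completely overlapping classes.
#' @export
classify_posterior <- function(fit) {
  post <- fit$posterior
  K <- ncol(post)
  modal <- apply(post, 1, which.max)
  assignments <- data.frame(patient_id = rownames(post), class = modal,
                            max_posterior = post[cbind(seq_len(nrow(post)), modal)],
                            stringsAsFactors = FALSE, row.names = NULL)
  entropy <- if (K == 1) 1 else {
    h <- -sum(post * log(pmax(post, 1e-300)))
    1 - h / (nrow(post) * log(K))
  }
  list(assignments = assignments, entropy = entropy)
}
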