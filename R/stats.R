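#' One-sample and paired t-tests with effect size
#'
#' Standard two-sided one-sample t-test against `mu0`, reporting the
#' within-subject effect size `d_z = (mean - mu0) / sd`. `paired_t()` is the
#' identical test on the paired differences `x - y`.
#'
#' @param x Numeric vector (`n >= 2`, non-zero variance).
#' @param mu0 Null value (default 0).
#' @return A one-row tibble: `estimate`, `t`, `df`, `p_value`, `d_z`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) abort("need at least 2 observations")
  s <- sd(x)
  if (s == 0) abort("zero variance: t-test undefined")
  m <- mean(x)
  t_stat <- (m - mu0) / (s / sqrt(n))
  tibble(estimate = m, t = t_stat, df = n - 1,
         p_value = 2 * pt(-abs(t_stat), n - 1), d_z = (m - mu0) / s)
}

#' @rdname one_sample_t
#' @param y Second vector, paired with `x`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("paired samples must have equal length")
  d <- x - y
  if (all(d == 0)) {
    # identical samples: no difference at all, t = 0 by convention
    return(tibble(estimate = 0, t = 0, df = length(d) - 1, p_value = 1, d_z = 0))
  }
  one_sample_t(d)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusts a family of p-values by the Holm step-down procedure (uniformly
#' more powerful than Bonferroni at the same family-wise error rate).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with `p`, `p_adjusted`, `reject`, in the input order.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  tibble(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Greenhouse-Geisser epsilon from a cell covariance matrix
#'
#' Sphericity-violation correction factor for a within-subject effect with
#' `k` levels: orthonormal contrasts `C` are applied to the `k x k`
#' covariance `S` of the subject-level cell scores, and
#' `eps = tr(CSC')^2 / ((k - 1) * tr((CSC')^2))`, clamped to
#' `[1/(k - 1), 1]`. Equals 1 when sphericity holds (e.g. compound
#' symmetry) and always equals 1 for `k = 2`.
#'
#' @param s `k x k` covariance matrix of the cell scores (positive
#'   semi-definite, symmetric).
#' @param k Number of levels (`>= 2`).
#' @return The scalar epsilon.
#' @export
gg_epsilon <- function(s, k) {
  k <- as.integer(k)
  if (k < 2) abort("`k` must be >= 2")
  s <- check_matrix(s, "s")
  if (nrow(s) != k || ncol(s) != k) abort("`s` must be k x k")
  if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s)))) abort("`s` must be symmetric")
  ev <- eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) abort("`s` must be positive semi-definite")
  cc <- stats::contr.helmert(k)
  cc <- sweep(cc, 2, sqrt(colSums(cc^2)), "/")     # orthonormal contrasts, k x (k-1)
  sc <- t(cc) %*% s %*% cc
  num <- sum(diag(sc))^2
  den <- (k - 1) * sum(sc^2)
  if (den <= 0) return(1)
  min(max(num / den, 1 / (k - 1)), 1)
}

# orthonormal contrast matrix for one factor (k x (k-1)), or intercept (k x 1)
contrast_basis <- function(k, effect = TRUE) {
  if (!effect) return(matrix(1 / sqrt(k), k, 1))
  cc <- stats::contr.helmert(k)
  sweep(cc, 2, sqrt(colSums(cc^2)), "/")
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject factorial ANOVA on a balanced complete long table:
#' sums of squares are decomposed through orthonormal within-subject
#' contrasts (Kronecker products of per-factor contrast bases), giving each
#' effect its own subject-by-effect error stratum;
#' a Greenhouse-Geisser epsilon is computed for every effect (a no-op for
#' 2-level effects) from the covariance of the within-subject contrasts,
#' and effect sizes are reported as partial eta-squared
#' `SS_eff / (SS_eff + SS_err)` and generalized eta-squared
#' `SS_eff / (SS_eff + sum of all error SS)` (all factors treated as
#' manipulated).
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric outcome column.
#' @param within Character vector of 1-4 within-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @return An object of class `cnp_rm_anova`; `tidy()` returns the ANOVA
#'   table with columns `effect`, `df_num`, `df_den`, `ss`, `ss_error`, `F`,
#'   `p_value`, `eps_gg`, `df_num_gg`, `df_den_gg`, `p_gg`, `eta_p_sq`,
#'   `eta_g_sq`.
#' @export
rm_anova <- function(data, dv, within, subject) {
  if (length(within) < 1 || length(within) > 4) abort("1 to 4 within-subject factors supported")
  data <- as.data.frame(data)
  for (col in c(dv, within, subject)) {
    if (!col %in% names(data)) abort(sprintf("column '%s' not found", col))
  }
  data[within] <- lapply(data[within], factor)
  data[[subject]] <- factor(data[[subject]])
  counts <- table(data[c(subject, within)])
  if (any(counts != 1)) abort("design must be balanced and complete (exactly one observation per subject per cell)")

  # cell order: first factor varies slowest, matching the Kronecker products
  cells <- as.data.frame(do.call(tidyr::expand_grid, lapply(data[within], levels)))
  cells[] <- lapply(cells, factor)
  key <- function(df) do.call(paste, c(df[within], sep = "\r"))
  subj_levels <- levels(data[[subject]])
  wide <- matrix(NA_real_, length(subj_levels), nrow(cells),
                 dimnames = list(subj_levels, NULL))
  wide[cbind(match(data[[subject]], subj_levels),
             match(key(data), key(cells)))] <- data[[dv]]

  n_sub <- nrow(wide)
  k_cells <- ncol(wide)
  if (n_sub < 2) abort("need at least 2 subjects")

  effects <- unlist(lapply(seq_along(within), function(r) {
    utils::combn(within, r, simplify = FALSE)
  }), recursive = FALSE)
  lv <- lapply(data[within], levels)

  grand <- matrix(1 / sqrt(k_cells), k_cells, 1)
  table_rows <- vector("list", length(effects))
  ss_err_all <- numeric(0)

  # between-subject (intercept) stratum
  subj_means <- rowMeans(wide)
  ss_subject <- sum((subj_means - mean(subj_means))^2) * k_cells
  ss_err_all <- c(ss_err_all, ss_subject)

  for (idx in seq_along(effects)) {
    eff <- effects[[idx]]
    # Kronecker product of per-factor contrast bases, ordered like `cells`
    mats <- lapply(within, function(f) contrast_basis(length(lv[[f]]), f %in% eff))
    cmat <- Reduce(`%x%`, mats)                  # k_cells x df_num
    scores <- wide %*% cmat                      # subjects x df_num contrast scores
    df_num <- ncol(cmat)
    df_den <- (n_sub - 1) * df_num
    mean_scores <- colMeans(scores)
    ss_eff <- n_sub * sum(mean_scores^2)
    resid <- sweep(scores, 2, mean_scores)
    ss_err <- sum(resid^2)
    ss_err_all <- c(ss_err_all, ss_err)
    f_val <- if (ss_eff == 0) 0 else (ss_eff / df_num) / (ss_err / df_den)
    # GG epsilon from the covariance of the contrast scores
    eps <- if (df_num == 1) 1 else {
      sc <- stats::cov(scores)
      e <- sum(diag(sc))^2 / (df_num * sum(sc^2))
      min(max(e, 1 / df_num), 1)
    }
    p_unc <- if (ss_err == 0) NA_real_ else pf(f_val, df_num, df_den, lower.tail = FALSE)
    p_gg <- if (ss_err == 0) NA_real_ else pf(f_val, eps * df_num, eps * df_den, lower.tail = FALSE)
    table_rows[[idx]] <- tibble(
      effect = paste(eff, collapse = ":"),
      df_num = df_num, df_den = df_den,
      ss = ss_eff, ss_error = ss_err, F = f_val, p_value = p_unc,
      eps_gg = eps, df_num_gg = eps * df_num, df_den_gg = eps * df_den,
      p_gg = p_gg, eta_p_sq = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err))
  }
  tab <- bind_rows(table_rows) |>
    mutate(eta_g_sq = ifelse(.data$ss + sum(ss_err_all) == 0, 0,
                             .data$ss / (.data$ss + sum(ss_err_all))))
  structure(list(table = tab, n_subjects = n_sub, within = within,
                 ss_subject = ss_subject, cells = cells,
                 cell_means = colMeans(wide), wide = wide),
            class = "cnp_rm_anova")
}

#' @export
print.cnp_rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects, factors: %s)\n",
              x$n_subjects, paste(x$within, collapse = ", ")))
  print(x$table)
  invisible(x)
}

#' @export
tidy.cnp_rm_anova <- function(x, ...) x$table

#' @export
glance.cnp_rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_factors = length(x$within),
         n_cells = nrow(x$cells))
}

#' Tukey post-hoc contrasts
#'
#' All pairwise comparisons between cell means using the studentized-range
#' distribution, with the supplied (within-subject) error stratum. With two
#' cells, the Tukey p reduces to the unadjusted pairwise p.
#'
#' @param cell_means Named (or unnamed) numeric vector of cell means.
#' @param error_ms Error mean square of the effect's stratum.
#' @param df_err Error degrees of freedom (`>= 1`).
#' @param n Number of observations per cell (subjects).
#' @return A tibble of pairs: `cell_a`, `cell_b`, `difference`, `q`,
#'   `p_value`.
#' @export
tukey_contrasts <- function(cell_means, error_ms, df_err, n) {
  if (length(cell_means) < 2) abort("need at least 2 cells")
  if (df_err < 1) abort("`df_err` must be >= 1")
  assert_scalar_number(error_ms, "error_ms", lower = 0)
  k <- length(cell_means)
  nm <- names(cell_means) %||% as.character(seq_len(k))
  se <- sqrt(error_ms / n)
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff_ab <- cell_means[[a]] - cell_means[[b]]
    q <- if (se == 0) ifelse(diff_ab == 0, 0, Inf) else abs(diff_ab) / se
    tibble(cell_a = nm[a], cell_b = nm[b], difference = diff_ab, q = q,
           p_value = ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE))
  })
}

#' Convert partial eta-squared to Cohen's f
#'
#' `f = sqrt(eta / (1 - eta))`; the effect-size metric G*Power expects for
#' ANOVA power analyses.
#'
#' @param eta_p_sq Partial eta-squared in `[0, 1)`.
#' @return Cohen's f.
#' @export
cohens_f_from_partial_eta <- function(eta_p_sq) {
  assert_scalar_number(eta_p_sq, "eta_p_sq", lower = 0, upper = 1)
  if (eta_p_sq >= 1) abort("`eta_p_sq` must be < 1")
  sqrt(eta_p_sq / (1 - eta_p_sq))
}

#' Power of a one-sample t-test
#'
#' Exact power from the non-central t distribution:
#' `P(|T| > t_crit)` with `ncp = d * sqrt(n)`.
#'
#' @param d Effect size (Cohen's d_z).
#' @param n Sample size (`>= 2`).
#' @param alpha Significance criterion in `(0, 1)`.
#' @param two_sided Two-sided test (default `TRUE`).
#' @return Power in `[0, 1]`.
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05, two_sided = TRUE) {
  n <- as.integer(n)
  if (n < 2) abort("`n` must be >= 2")
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  ncp <- d * sqrt(n)
  df <- n - 1
  if (two_sided) {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Power of a one-way repeated-measures ANOVA (SPSS effect-size convention)
#'
#' Non-central F power with `df1 = m - 1`, `df2 = (n - 1)(m - 1)` and
#' noncentrality `lambda = f^2 * n`, where `f` is Cohen's f specified "as in
#' SPSS" (i.e. already incorporating the within-subject error structure).
#'
#' @param f Cohen's f (`>= 0`).
#' @param m_levels Number of repeated measurements / factor levels (`>= 2`).
#' @param n Sample size.
#' @param alpha Significance criterion.
#' @return Power in `[0, 1]`.
#' @export
power_rm_anova_spss <- function(f, m_levels, n, alpha = 0.05) {
  m_levels <- as.integer(m_levels)
  if (m_levels < 2) abort("`m_levels` must be >= 2")
  assert_scalar_number(f, "f", lower = 0)
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  df1 <- m_levels - 1
  df2 <- (n - 1) * df1
  lambda <- f^2 * n
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}
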