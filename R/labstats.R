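#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject decomposition of an n x k table (subjects x
#' conditions) into condition, subject and error sums of squares. The
#' Greenhouse-Geisser epsilon is computed from the sample covariance of the
#' conditions and applied unconditionally to the degrees of freedom (the
#' corrected df are reported alongside epsilon). Effect size is partial eta
#' squared, `SS_condition / (SS_condition + SS_error)`.
#'
#' @param data numeric matrix, subjects in rows, conditions in columns;
#'   complete cases required.
#' @return List: `F`, `df1`, `df2` (GG-corrected), `p`, `partial_eta2`,
#'   `epsilon_gg`, `ss` (named sums of squares).
#' @export
rm_anova_oneway <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing values: complete cases required", call. = FALSE)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  grand <- mean(data)
  col_m <- colMeans(data); row_m <- rowMeans(data)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_err <- sum((data - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  eps <- gg_epsilon(data)
  df1 <- (k - 1) * eps
  df2 <- (n - 1) * (k - 1) * eps
  ms_cond <- ss_cond / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  Fv <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond > 0) Inf else 0
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       partial_eta2 = if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0,
       epsilon_gg = eps,
       ss = c(condition = ss_cond, subject = ss_subj, error = ss_err))
}

#' Greenhouse-Geisser epsilon from a subjects x conditions table
#'
#' `eps = tr(C)^2 / ((k - 1) * tr(C %*% C))` where C is the double-centered
#' sample covariance matrix of the conditions; bounded in `[1/(k-1), 1]`,
#' equal to 1 under compound symmetry.
#'
#' @param data numeric matrix, subjects x conditions.
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(data) {
  data <- as.matrix(data)
  k <- ncol(data)
  S <- stats::cov(data)
  rm_ <- rowMeans(S); gm <- mean(S)
  C <- S - outer(rm_, rep(1, k)) - outer(rep(1, k), rm_) + gm
  tr <- sum(diag(C))
  denom <- (k - 1) * sum(C * C)
  if (denom <= 0) return(1)
  max(1 / (k - 1), min(1, tr^2 / denom))
}

#' Post-hoc paired t-tests with Bonferroni correction
#'
#' Paired t-test for each requested pair of conditions, Bonferroni-adjusted
#' over `m_comparisons` (default: the number of pairs), capped at 1. Paired
#' Cohen's d is `mean(diff) / sd(diff)`.
#'
#' @param data numeric matrix, subjects x conditions (named columns).
#' @param pairs list of length-2 character or index vectors; default all
#'   pairs.
#' @param m_comparisons number of comparisons for the Bonferroni adjustment.
#' @return data.frame: `pair, t, df, p_raw, p_adjusted, cohens_d`.
#' @export
posthoc_paired_t <- function(data, pairs = NULL, m_comparisons = NULL) {
  data <- as.matrix(data)
  if (is.null(pairs)) {
    idx <- utils::combn(ncol(data), 2, simplify = FALSE)
    pairs <- lapply(idx, function(i)
      if (!is.null(colnames(data))) colnames(data)[i] else i)
  }
  if (is.null(m_comparisons)) m_comparisons <- length(pairs)
  out <- lapply(pairs, function(pr) {
    d <- data[, pr[1]] - data[, pr[2]]
    sd_d <- stats::sd(d)
    if (sd_d == 0 && mean(d) == 0) {
      tv <- 0; p <- 1
    } else if (sd_d == 0) {
      return(data.frame(pair = paste(pr, collapse = " vs "), t = NA_real_,
                        df = length(d) - 1L, p_raw = NA_real_,
                        p_adjusted = NA_real_, cohens_d = NA_real_,
                        stringsAsFactors = FALSE))
    } else {
      tv <- mean(d) / (sd_d / sqrt(length(d)))
      p <- 2 * stats::pt(abs(tv), length(d) - 1, lower.tail = FALSE)
    }
    data.frame(pair = paste(pr, collapse = " vs "), t = tv,
               df = length(d) - 1L, p_raw = p,
               p_adjusted = min(1, m_comparisons * p),
               cohens_d = if (sd_d > 0) mean(d) / sd_d else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation matrix with p-values and pairwise deletion
#'
#' Correlates every pair of columns using the complete cases for that pair
#' (pairwise deletion). Pairs with a constant column or fewer than 3 complete
#' cases are reported as NA, mirroring the "-" entries a lab summary table
#' shows when a variable did not vary.
#'
#' @param table data.frame or matrix, subjects x variables.
#' @return List of two matrices, `r` and `p` (unit diagonal on `r`).
#' @export
pearson_matrix <- function(table) {
  x <- as.matrix(table)
  v <- ncol(x)
  r <- matrix(NA_real_, v, v, dimnames = list(colnames(x), colnames(x)))
  p <- r
  diag(r) <- 1
  for (i in seq_len(v - 1)) for (j in seq.int(i + 1, v)) {
    ok <- stats::complete.cases(x[, i], x[, j])
    if (sum(ok) < 3 || stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0)
      next
    ct <- stats::cor.test(x[ok, i], x[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}

#' A priori power for the one-way repeated-measures design
#'
#' Noncentral-F power under the "within factors" convention used by standard
#' power software for repeated-measures designs: with total sample size n,
#' `n_measures` repetitions (m), `n_conditions` groups (k), nonsphericity
#' correction epsilon and correlation rho among repeated measures,
#' `lambda = f2 * n * m * epsilon / (1 - rho)`, numerator df `(m - 1) *
#' epsilon`, denominator df `(n - k) * (m - 1) * epsilon`, and power
#' `P(F(df1, df2, lambda) > F_crit(alpha))`. The default effect-size
#' conversion is `f2 = eta2` (the direct f = sqrt(eta2) convention, which
#' reproduces the design's published minimum sample size); set
#' `f2_method = "partial"` for `f2 = eta2 / (1 - eta2)`.
#'
#' @param n total sample size.
#' @param eta2 effect size (eta squared).
#' @param alpha type-I error rate.
#' @param n_conditions number of conditions (groups), k.
#' @param n_measures number of repeated measures, m.
#' @param rho correlation among repeated measures.
#' @param epsilon nonsphericity correction in (0, 1].
#' @param f2_method `"direct"` (`f2 = eta2`) or `"partial"`
#'   (`f2 = eta2/(1-eta2)`).
#' @return Power (probability).
#' @export
rm_power <- function(n, eta2 = 0.06, alpha = 0.05, n_conditions = 3,
                     n_measures = 10, rho = 0.5, epsilon = 1,
                     f2_method = c("direct", "partial")) {
  f2_method <- match.arg(f2_method)
  stopifnot(eta2 > 0, eta2 < 1, rho > 0, rho < 1,
            epsilon > 0, epsilon <= 1)
  f2 <- if (f2_method == "direct") eta2 else eta2 / (1 - eta2)
  k <- n_conditions; m <- n_measures
  df1 <- (m - 1) * epsilon
  df2 <- (n - k) * (m - 1) * epsilon
  if (df2 < 1) return(0)
  lambda <- f2 * n * m * epsilon / (1 - rho)
  fc <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fc, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' Searches n upward from `n_conditions + 1` for the first [rm_power()]
#' at or above `target`.
#'
#' @param target target power.
#' @param n_max largest n to consider.
#' @inheritParams rm_power
#' @return Integer minimum n.
#' @export
min_n_power <- function(target = 0.80, eta2 = 0.06, alpha = 0.05,
                        n_conditions = 3, n_measures = 10, rho = 0.5,
                        epsilon = 1, f2_method = c("direct", "partial"),
                        n_max = 1000) {
  f2_method <- match.arg(f2_method)
  for (n in seq.int(n_conditions + 1, n_max)) {
    if (rm_power(n, eta2, alpha, n_conditions, n_measures, rho, epsilon,
                 f2_method) >= target)
      return(n)
  }
  stop("target power unreachable below n_max", call. = FALSE)
}

#' Monte-Carlo power for the repeated-measures design
#'
#' Simulates the design the analytic formula models: n subjects in
#' `n_conditions` groups (null group effect), `n_measures` repeated measures
#' with compound-symmetric covariance (total variance 1, correlation `rho`),
#' and level means with variance `f2` (matching the `"direct"` effect-size
#' convention). Each replicate is analyzed with the split-plot
#' repeated-measures F for the within factor; power is the rejection rate.
#'
#' @param n total sample size.
#' @param n_reps Monte-Carlo replicates.
#' @inheritParams rm_power
#' @return List: `power`, `se` (binomial Monte-Carlo SE).
#' @export
rm_power_mc <- function(n, eta2 = 0.06, alpha = 0.05, n_conditions = 3,
                        n_measures = 10, rho = 0.5, n_reps = 10000) {
  k <- n_conditions; m <- n_measures
  f2 <- eta2
  # level means scaled so their population variance (divisor m) is f2
  mu <- sin(2 * pi * seq_len(m) / m)
  mu <- (mu - mean(mu)) * sqrt(f2 / mean((mu - mean(mu))^2))
  grp <- rep(seq_len(k), length.out = n)
  ng <- tabulate(grp, k)
  df1 <- m - 1; df2 <- (n - k) * (m - 1)
  fc <- stats::qf(1 - alpha, df1, df2)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    subj <- stats::rnorm(n, 0, sqrt(rho))
    y <- outer(subj, rep(1, m)) +
      matrix(stats::rnorm(n * m, 0, sqrt(1 - rho)), n, m) +
      outer(rep(1, n), mu)
    grand <- mean(y)
    cm <- colMeans(y)
    ss_meas <- n * sum((cm - grand)^2)
    gmeans <- rowsum(y, grp) / ng
    gm <- rowMeans(gmeans)
    resid <- y - outer(rowMeans(y), rep(1, m)) - gmeans[grp, , drop = FALSE] +
      outer(gm[grp], rep(1, m))
    ss_err <- sum(resid^2)
    Fv <- (ss_meas / df1) / (ss_err / df2)
    if (Fv > fc) hits <- hits + 1L
  }
  pw <- hits / n_reps
  list(power = pw, se = sqrt(pw * (1 - pw) / n_reps))
}
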