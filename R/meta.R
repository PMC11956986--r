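#' Paired condition contrast for one lab
#'
#' Computes a lab's raw effect: the mean (or median) of within-subject
#' differences between two conditions at one frequency. For the mean
#' statistic the standard error is `sd(diff)/sqrt(n)` (correct for a
#' within-subject contrast); for the median it is the normal-theory quantile
#' estimator `1.2533 * (IQR/1.349) / sqrt(n)`, with a seeded bootstrap
#' alternative.
#'
#' @param a,b paired subject-level amplitude vectors (uV) for the two
#'   conditions (effect is `a - b`).
#' @param statistic `"mean"` or `"median"`.
#' @param se_method for the median: `"quantile"` (default) or `"bootstrap"`.
#' @param boot_reps bootstrap resamples when `se_method = "bootstrap"`.
#' @param lab_id,effect_name,moderators metadata carried along.
#' @return An `effect_estimate` data.frame row: `lab_id, effect_name, y, se,
#'   n` plus any moderators.
#' @export
lab_effect <- function(a, b, statistic = c("mean", "median"),
                       se_method = c("quantile", "bootstrap"),
                       boot_reps = 2000,
                       lab_id = NA_character_, effect_name = NA_character_,
                       moderators = NULL) {
  statistic <- match.arg(statistic)
  se_method <- match.arg(se_method)
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  d <- a - b
  n <- length(d)
  if (n < 2) stop("need at least 2 paired subjects", call. = FALSE)
  if (statistic == "mean") {
    y <- mean(d)
    se <- stats::sd(d) / sqrt(n)
  } else {
    y <- stats::median(d)
    if (se_method == "quantile") {
      iqr <- diff(stats::quantile(d, c(0.25, 0.75), names = FALSE))
      se <- 1.2533 * (iqr / 1.349) / sqrt(n)
    } else {
      meds <- vapply(seq_len(boot_reps), function(i)
        stats::median(sample(d, n, replace = TRUE)), numeric(1))
      se <- stats::sd(meds)
    }
  }
  out <- data.frame(lab_id = lab_id, effect_name = effect_name,
                    y = y, se = se, n = n, stringsAsFactors = FALSE)
  if (!is.null(moderators)) out <- cbind(out, as.data.frame(as.list(moderators)))
  class(out) <- c("effect_estimate", class(out))
  out
}

#' The four imagery effects, by name
#'
#' Each effect is a paired difference of condition means (or medians) at one
#' imagery frequency: binary_control = binary - control at 1.2 Hz,
#' binary_active = binary - ternary at 1.2 Hz, ternary_control = ternary -
#' control at 0.8 Hz, ternary_active = ternary - binary at 0.8 Hz.
#'
#' @return data.frame with `effect_name`, `cond_a`, `cond_b`, `frequency_hz`.
#' @export
effect_definitions <- function() {
  data.frame(
    effect_name = c("binary_control", "binary_active",
                    "ternary_control", "ternary_active"),
    cond_a = c("binary", "binary", "ternary", "ternary"),
    cond_b = c("control", "ternary", "control", "binary"),
    frequency_hz = c(1.2, 1.2, 0.8, 0.8),
    stringsAsFactors = FALSE)
}

#' Per-lab effects from a tidy SSEP estimate table
#'
#' @param ssep data.frame from [subject_ssep_table()] (columns `lab_id,
#'   subject_id, condition, frequency_hz, amplitude_uv`).
#' @param effect_name one of the names in [effect_definitions()].
#' @param statistic `"mean"` or `"median"`.
#' @param participants optional participants table supplying
#'   `music_years`/`dance_years`; lab means are attached as moderators.
#' @param ... passed to [lab_effect()].
#' @return data.frame of per-lab `effect_estimate` rows.
#' @export
lab_effects <- function(ssep, effect_name, statistic = "mean",
                        participants = NULL, ...) {
  def <- effect_definitions()
  def <- def[def$effect_name == effect_name, ]
  if (nrow(def) != 1) stop("unknown effect: ", effect_name, call. = FALSE)
  sub <- ssep[ssep$frequency_hz == def$frequency_hz, ]
  out <- lapply(split(sub, sub$lab_id), function(lab) {
    wide <- stats::reshape(
      lab[, c("subject_id", "condition", "amplitude_uv")],
      idvar = "subject_id", timevar = "condition", direction = "wide")
    a <- wide[[paste0("amplitude_uv.", def$cond_a)]]
    b <- wide[[paste0("amplitude_uv.", def$cond_b)]]
    ok <- stats::complete.cases(a, b)
    mods <- NULL
    if (!is.null(participants)) {
      pl <- participants[participants$lab_id == lab$lab_id[1], ]
      mods <- c(music_years_mean = mean(pl$music_years),
                dance_years_mean = mean(pl$dance_years))
    }
    lab_effect(a[ok], b[ok], statistic = statistic,
               lab_id = lab$lab_id[1], effect_name = effect_name,
               moderators = mods, ...)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Random-effects meta-analysis of raw differences
#'
#' Pools per-lab effects by inverse-variance weighting with between-study
#' variance tau2 estimated by REML (default) or DerSimonian-Laird. Cochran's
#' Q uses fixed-effect weights `1/se^2`; `I2 = max(0, (Q - df)/Q) * 100`,
#' `H2 = Q/df`. The pooled estimate gets a Wald z confidence interval and
#' p-value (no Knapp-Hartung adjustment).
#'
#' @param effects data.frame with columns `y` and `se` (one row per lab), or
#'   an `effect_estimate` collection from [lab_effects()].
#' @param method `"REML"` or `"DL"`.
#' @param level confidence level.
#' @return A `meta_result` list: `estimate, se, ci_low, ci_high, p, tau2,
#'   tau, Q, df_Q, I2, H2, method, k`.
#' @export
re_meta <- function(effects, method = c("REML", "DL"), level = 0.95) {
  method <- match.arg(method)
  y <- effects$y; v <- effects$se^2
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all standard errors must be positive", call. = FALSE)
  k <- length(y)
  w_fe <- 1 / v
  mu_fe <- sum(w_fe * y) / sum(w_fe)
  Q <- sum(w_fe * (y - mu_fe)^2)
  df_Q <- k - 1
  tau2 <- if (k < 2) 0 else switch(method,
    DL = max(0, (Q - df_Q) / (sum(w_fe) - sum(w_fe^2) / sum(w_fe))),
    REML = reml_tau2(y, v))
  w <- 1 / (v + tau2)
  est <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    estimate = est, se = se,
    ci_low = est - z * se, ci_high = est + z * se,
    p = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE),
    tau2 = tau2, tau = sqrt(tau2),
    Q = Q, df_Q = df_Q,
    I2 = if (df_Q > 0 && Q > 0) max(0, (Q - df_Q) / Q) * 100 else 0,
    H2 = if (df_Q > 0) Q / df_Q else NA_real_,
    method = method, k = k), class = "meta_result")
}

# REML estimate of tau2 by Fisher scoring, for a fixed-effects design X
# (intercept-only or with moderators). Truncated at zero; falls back to a
# grid-refined profile search if scoring fails to settle.
reml_tau2_fs <- function(y, v, X = matrix(1, length(y), 1)) {
  k <- length(y)
  p <- ncol(X)
  if (k <= p) return(0)
  score <- function(t2) {
    w <- 1 / (v + t2)
    W <- diag(w, k)
    XtWX <- crossprod(X, W %*% X)
    P <- W - W %*% X %*% solve(XtWX, t(X) %*% W)
    U <- -0.5 * sum(diag(P)) + 0.5 * drop(t(y) %*% P %*% P %*% y)
    I <- 0.5 * sum(P * P)
    c(U = U, I = I)
  }
  t2 <- max(0, stats::var(y) - mean(v))
  for (it in 1:100) {
    s <- score(t2)
    step <- s["U"] / s["I"]
    t2_new <- max(0, t2 + step)
    if (abs(t2_new - t2) < 1e-12 * (1 + t2)) {
      t2 <- t2_new
      break
    }
    t2 <- t2_new
  }
  # boundary: if the restricted score at 0 is negative, the MLE is 0
  if (t2 < 1e-12 && score(0)["U"] <= 0) return(0)
  t2
}

reml_tau2 <- function(y, v) reml_tau2_fs(y, v)

#' Mixed-effects (moderator) meta-analysis
#'
#' Weighted least squares of per-lab effects on one moderator with weights
#' `1/(se^2 + tau2)`, tau2 re-estimated by REML under the moderator model.
#' Reports intercept and slope with Wald z tests, residual heterogeneity,
#' and the model-predicted pooled effect at the moderator mean and mean +/-
#' 1 SD (the three-diamond forest convention).
#'
#' @param effects data.frame with `y`, `se` and the moderator column.
#' @param moderator name of the moderator column.
#' @param level confidence level.
#' @return A `meta_result` with `moderator_coefs` (data.frame) and
#'   `predicted` (effect at mean - 1 SD, mean, mean + 1 SD).
#' @export
meta_regression <- function(effects, moderator, level = 0.95) {
  y <- effects$y; v <- effects$se^2
  x <- effects[[moderator]]
  if (is.null(x)) stop("moderator '", moderator, "' not found", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant moderator: singular design", call. = FALSE)
  X <- cbind(1, x)
  tau2 <- reml_tau2_mods(y, v, X)
  w <- 1 / (v + tau2)
  W <- diag(w)
  XtWX <- crossprod(X, W %*% X)
  beta <- solve(XtWX, crossprod(X, w * y))
  vcov_b <- solve(XtWX)
  se_b <- sqrt(diag(vcov_b))
  zval <- beta / se_b
  resid <- y - X %*% beta
  Q <- sum((resid^2) / v)   # residual Q with fixed-effect weights
  df_Q <- length(y) - 2
  z <- stats::qnorm(1 - (1 - level) / 2)
  xm <- mean(x); xs <- stats::sd(x)
  pred_at <- function(x0) {
    x0v <- c(1, x0)
    est <- sum(x0v * beta)
    se <- sqrt(drop(t(x0v) %*% vcov_b %*% x0v))
    c(x = x0, estimate = est, ci_low = est - z * se, ci_high = est + z * se)
  }
  structure(list(
    estimate = sum(c(1, xm) * beta), tau2 = tau2, tau = sqrt(tau2),
    Q = Q, df_Q = df_Q,
    I2 = if (df_Q > 0 && Q > 0) max(0, (Q - df_Q) / Q) * 100 else 0,
    H2 = if (df_Q > 0) Q / df_Q else NA_real_,
    method = "REML", k = length(y),
    moderator = moderator,
    moderator_coefs = data.frame(
      term = c("intercept", moderator),
      estimate = as.numeric(beta), se = se_b, z = as.numeric(zval),
      p = 2 * stats::pnorm(abs(as.numeric(zval)), lower.tail = FALSE),
      stringsAsFactors = FALSE),
    predicted = t(vapply(c(xm - xs, xm, xm + xs), pred_at, numeric(4)))),
    class = "meta_result")
}

reml_tau2_mods <- function(y, v, X) reml_tau2_fs(y, v, X)

#' Meta-analysis of median differences
#'
#' Pools per-lab median differences (from [lab_effects()] with
#' `statistic = "median"`, whose SEs come from the quantile-based estimator)
#' by the same inverse-variance random-effects machinery as [re_meta()].
#'
#' @inheritParams re_meta
#' @return A `meta_result`.
#' @export
median_meta <- function(effects, method = c("REML", "DL"), level = 0.95) {
  re_meta(effects, method = method, level = level)
}

#' Forest-plot data export
#'
#' One row per lab (effect, Wald CI, normalized weight) plus a pooled row.
#'
#' @param meta a `meta_result` from [re_meta()].
#' @param effects the per-lab effects that produced it.
#' @param level confidence level for the per-lab CIs.
#' @return data.frame: `row, lab_id, y, ci_low, ci_high, weight`.
#' @export
forest_export <- function(meta, effects, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  w <- 1 / (effects$se^2 + meta$tau2)
  rows <- data.frame(
    row = "lab", lab_id = effects$lab_id, y = effects$y,
    ci_low = effects$y - z * effects$se,
    ci_high = effects$y + z * effects$se,
    weight = w / sum(w), stringsAsFactors = FALSE)
  pooled <- data.frame(row = "pooled", lab_id = "pooled", y = meta$estimate,
                       ci_low = meta$ci_low, ci_high = meta$ci_high,
                       weight = 1, stringsAsFactors = FALSE)
  rbind(rows, pooled)
}

#' Per-lab mean differences from a lab summary table
#'
#' Desk arithmetic on the packaged lab summary fixture: for each included
#' lab, the difference of printed condition means at the effect's frequency.
#' No standard error is computable from printed cell means/SDs alone (the
#' within-subject difference SD is not recoverable), so only the point
#' differences and their cross-lab range are returned.
#'
#' @param table1 data.frame from [read_table1_fixture()].
#' @param effect_name one of [effect_definitions()]'s names.
#' @param included_only drop labs below the minimum sample rule?
#' @return data.frame `lab, diff`, with attribute `range = c(min, max)`.
#' @export
summary_table_differences <- function(table1, effect_name,
                                      included_only = TRUE) {
  def <- effect_definitions()
  def <- def[def$effect_name == effect_name, ]
  t1 <- table1[table1$frequency_hz == def$frequency_hz, ]
  if (included_only) t1 <- t1[t1$total_included >= 8, ]
  wide <- stats::reshape(t1[, c("lab", "condition", "mean_uv")],
                         idvar = "lab", timevar = "condition",
                         direction = "wide")
  d <- wide[[paste0("mean_uv.", def$cond_a)]] -
    wide[[paste0("mean_uv.", def$cond_b)]]
  out <- data.frame(lab = wide$lab, diff = d)
  attr(out, "range") <- range(d)
  out
}
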