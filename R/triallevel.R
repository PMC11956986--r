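#' Build the design matrix for the trial-level accuracy regression
#'
#' Predictors follow the pre-registered list: lab, subject, music and dance
#' experience, imagery type, probe type (ON vs OFF the imagined beat), EEG
#' amplitude at the imagined-beat frequency, and EEG amplitude at the
#' stimulus frequency. Categorical predictors are dummy-coded against the
#' alphabetically first level. Because full subject dummies are collinear
#' with lab dummies, the default `subject_encoding = "cluster"` keeps
#' subjects out of the fixed design (they enter through cluster-robust SEs
#' in [fit_logistic()]); `"dummy"` adds them and raises an explicit aliasing
#' error naming the aliased columns; `"omit"` drops them silently.
#'
#' @param records data.frame of trial records with columns `lab_id,
#'   subject_id, music_years, dance_years, imagery_type, probe_type,
#'   amp_imagery, amp_stimulus, accuracy` (probe_type coded `"ON"`/`"OFF"`
#'   or by beat position matching `imagery_type`).
#' @param subject_encoding `"cluster"`, `"dummy"` or `"omit"`.
#' @param include_imagery keep the imagery-type column? (dropped in the
#'   per-imagery-condition variant).
#' @param standardize standardize continuous predictors?
#' @return List: `X` (design matrix), `y` (0/1 response), `cluster`
#'   (subject factor).
#' @export
build_design <- function(records,
                         subject_encoding = c("cluster", "dummy", "omit"),
                         include_imagery = TRUE, standardize = FALSE) {
  subject_encoding <- match.arg(subject_encoding)
  if (nrow(records) == 0) stop("no trial records", call. = FALSE)
  r <- records
  if (!all(r$probe_type %in% c("ON", "OFF")))
    r$probe_type <- ifelse(r$probe_type == r$imagery_type, "ON", "OFF")
  num <- function(v) if (standardize && stats::sd(v) > 0) as.numeric(scale(v)) else v
  fml_terms <- c("music_years", "dance_years", "probe_type",
                 "amp_imagery", "amp_stimulus")
  if (include_imagery) fml_terms <- c("imagery_type", fml_terms)
  if (length(unique(r$lab_id)) > 1) fml_terms <- c("lab_id", fml_terms)
  if (subject_encoding == "dummy") fml_terms <- c("subject_id", fml_terms)
  df <- data.frame(
    lab_id = factor(r$lab_id),
    subject_id = factor(paste(r$lab_id, r$subject_id, sep = ":")),
    imagery_type = factor(r$imagery_type),
    probe_type = factor(r$probe_type, levels = c("OFF", "ON")),
    music_years = num(r$music_years), dance_years = num(r$dance_years),
    amp_imagery = num(r$amp_imagery), amp_stimulus = num(r$amp_stimulus))
  X <- stats::model.matrix(
    stats::reformulate(fml_terms), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  list(X = X, y = as.numeric(r$accuracy), cluster = df$subject_id)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an explicit IRLS loop (the deviance
#' trace is returned so the likelihood ascent can be inspected), per-term
#' Wald chi-square tests (`(coef/SE)^2` on 1 df), and optional
#' cluster-robust (sandwich) standard errors grouped by subject. Perfect
#' separation surfaces as a non-convergence flag with diverging
#' coefficients, never as silent output.
#'
#' @param X design matrix (with intercept column).
#' @param y binary response.
#' @param cluster optional cluster factor for robust SEs.
#' @param max_iter,tol IRLS iteration cap and deviance-change tolerance.
#' @return A `logistic_result`: data.frame `terms` (coef, se, wald_chi2, p),
#'   plus `converged`, `deviance`, `deviance_trace`, `n_used`, `vcov`.
#' @export
fit_logistic <- function(X, y, cluster = NULL, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))[seq_len(p)]
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  beta <- rep(0, p)
  dev_old <- Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- tryCatch(qr.solve(crossprod(X, w * X), crossprod(X, w * z)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    # recompute deviance at the new beta for the trace
    mu_new <- stats::plogis(drop(X %*% beta))
    mu_new <- pmin(pmax(mu_new, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu_new) + (1 - y) * log(1 - mu_new))
    trace <- c(trace, dev)
    if (is.finite(dev_old) && abs(dev_old - dev) < tol * (abs(dev) + 1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  # separation diagnostic: a vanishing deviance or runaway coefficients mean
  # the MLE does not exist and the reported estimates are untrustworthy
  if (dev_old < 1e-6 || max(abs(beta)) > 1e3) converged <- FALSE
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  w <- mu * (1 - mu)
  bread <- solve(crossprod(X, w * X))
  if (is.null(cluster)) {
    vcov_b <- bread
  } else {
    sc <- X * (y - mu)                       # score contributions per row
    g <- rowsum(sc, cluster)
    meat <- crossprod(g)
    vcov_b <- bread %*% meat %*% bread
  }
  se <- sqrt(diag(vcov_b))
  chi2 <- (beta / se)^2
  structure(list(
    terms = data.frame(term = colnames(X), coef = beta, se = se,
                       wald_chi2 = chi2,
                       p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                       row.names = NULL, stringsAsFactors = FALSE),
    converged = converged, deviance = dev_old, deviance_trace = trace,
    n_used = n, vcov = vcov_b), class = "logistic_result")
}

#' Trial-level accuracy regression from records
#'
#' Convenience wrapper: [build_design()] then [fit_logistic()], with
#' cluster-robust SEs when `subject_encoding = "cluster"`.
#'
#' @inheritParams build_design
#' @param ... passed to [fit_logistic()].
#' @return A `logistic_result`.
#' @export
trial_regression <- function(records,
                             subject_encoding = c("cluster", "dummy", "omit"),
                             include_imagery = TRUE, standardize = FALSE,
                             ...) {
  subject_encoding <- match.arg(subject_encoding)
  d <- build_design(records, subject_encoding, include_imagery, standardize)
  cl <- if (subject_encoding == "cluster") d$cluster else NULL
  fit_logistic(d$X, d$y, cluster = cl, ...)
}

#' Per-imagery-condition accuracy regressions
#'
#' Runs the trial-level regression separately on the binary-imagery and
#' ternary-imagery subsets, dropping imagery type from the predictors.
#'
#' @inheritParams trial_regression
#' @return Named list of two `logistic_result`s (`binary`, `ternary`).
#' @export
fit_by_imagery <- function(records,
                           subject_encoding = c("cluster", "dummy", "omit"),
                           ...) {
  subject_encoding <- match.arg(subject_encoding)
  out <- lapply(c(binary = "binary", ternary = "ternary"), function(im) {
    sub <- records[records$imagery_type == im, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty imagery subset: ", im, call. = FALSE)
    trial_regression(sub, subject_encoding, include_imagery = FALSE, ...)
  })
  out
}
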