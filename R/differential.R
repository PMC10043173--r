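#' Design matrices and contrasts for the time-course models
#'
#' Builds the model matrix and the named contrast list for one of the study
#' designs. "time" enters as a categorical factor, and the condition effect is
#' parameterised per timepoint (a \code{time:condition} interaction without a
#' condition main effect), so each interaction coefficient is directly the
#' condition effect at that timepoint.
#'
#' Designs:
#' \describe{
#'   \item{timecourse_stim}{\code{~ 1 + time + stimulus:time}; contrasts =
#'     stimulus effect at each timepoint.}
#'   \item{washout}{\code{~ 1 + experiment + time + primary:time}; contrasts =
#'     lasting effect of the primary stimulus at each division.}
#'   \item{washout_with_pam}{\code{~ 1 + experiment + time + primary:time +
#'     (Pam:time):primary}; contrasts = primary effect and per-timepoint
#'     priming (difference of Pam responses between arms).}
#'   \item{priming}{\code{~ 1 + experiment + primary + Pam:primary} on a
#'     single timepoint; contrast = Pam response in the BG arm minus the Pam
#'     response in the control arm.}
#' }
#'
#' @param meta sample metadata (see [sample_meta()]).
#' @param design one of \code{"timecourse_stim"}, \code{"washout"},
#'   \code{"washout_with_pam"}, \code{"priming"}.
#' @return list with \code{X} (model matrix) and \code{contrasts} (named list
#'   of numeric contrast vectors over the columns of \code{X}).
#' @export
design_matrix <- function(meta,
                          design = c("washout", "timecourse_stim",
                                     "washout_with_pam", "priming")) {
  design <- match.arg(design)
  meta <- sample_meta(meta)
  df <- data.frame(
    time = factor(meta$division),
    primary = meta$condition,
    experiment = meta$experiment)
  if ("secondary" %in% names(meta)) df$secondary <- meta$secondary
  divs <- levels(df$time)

  unit <- function(X, col) {
    v <- stats::setNames(numeric(ncol(X)), colnames(X))
    if (!col %in% colnames(X)) stop("missing design column: ", col)
    v[col] <- 1
    v
  }
  if (design == "timecourse_stim") {
    X <- stats::model.matrix(~ time + time:primary, df)
    ctr <- lapply(divs, function(d)
      unit(X, sprintf("time%s:primaryBG", d)))
    names(ctr) <- paste0("d", divs)
  } else if (design == "washout") {
    X <- stats::model.matrix(~ experiment + time + time:primary, df)
    ctr <- lapply(divs, function(d)
      unit(X, sprintf("time%s:primaryBG", d)))
    names(ctr) <- paste0("d", divs)
  } else if (design == "washout_with_pam") {
    if (is.null(df$secondary)) stop("design needs a 'secondary' column")
    X <- stats::model.matrix(
      ~ experiment + time + time:primary + time:primary:secondary, df)
    ctr <- c(
      stats::setNames(lapply(divs, function(d)
        unit(X, sprintf("time%s:primaryBG", d))), paste0("d", divs)),
      stats::setNames(lapply(divs, function(d)
        unit(X, sprintf("time%s:primaryBG:secondaryPam", d)) -
          unit(X, sprintf("time%s:primarycontrol:secondaryPam", d))),
        paste0("priming_d", divs)))
  } else {  # priming: one timepoint at a time
    if (is.null(df$secondary)) stop("design needs a 'secondary' column")
    if (length(divs) != 1L)
      stop("'priming' design expects samples from a single timepoint; got: ",
           paste(divs, collapse = ", "))
    X <- stats::model.matrix(~ experiment + primary + primary:secondary, df)
    ctr <- list(priming = unit(X, "primaryBG:secondaryPam") -
                  unit(X, "primarycontrol:secondaryPam"))
  }
  rownames(X) <- meta$sample
  list(X = X, contrasts = ctr, design = design)
}

#' Moderate residual variances by moment matching
#'
#' Fits a scaled inverse-chi-square prior to the distribution of residual
#' variances by matching its first two moments, then shrinks every variance
#' toward the prior mean with weights \code{df / (df + prior_df)}: a simple
#' empirical-Bayes pooling across features that stabilises t-statistics at
#' small replicate numbers.
#'
#' @param residual_variances per-feature residual variances (length >= 10).
#' @param residual_df residual degrees of freedom (scalar).
#' @return list with \code{var} (moderated variances), \code{prior_df},
#'   \code{prior_var}, and \code{degenerate} (TRUE when the variances carry no
#'   spread; \code{prior_df} is then a large finite sentinel and the variances
#'   are returned unchanged).
#' @export
moderate_variances <- function(residual_variances, residual_df) {
  s2 <- residual_variances
  if (length(s2) < 10L) stop("need >= 10 features to moderate variances")
  if (any(!is.finite(s2)) || any(s2 < 0)) stop("invalid residual variances")
  m <- mean(s2)
  v <- stats::var(s2)
  if (!is.finite(v) || v <= m^2 * 1e-12) {
    return(list(var = s2, prior_df = 1e6, prior_var = m, degenerate = TRUE))
  }
  # scaled-inv-chi2(d0, s0^2): mean mu = d0 s0^2/(d0-2), var = 2 mu^2/(d0-4)
  d0 <- 4 + 2 * m^2 / v
  s2_mod <- (residual_df * s2 + d0 * m) / (residual_df + d0)
  list(var = s2_mod, prior_df = d0, prior_var = m, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH false discovery rate adjustment (via \code{stats::p.adjust})
#' with input validation.
#'
#' @param p numeric p-values in \[0, 1\]; NA/NaN are rejected.
#' @return adjusted p-values (FDR), same length.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p))) stop("NA/NaN p-values not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit per-feature linear models and extract per-timepoint contrasts
#'
#' Fits ordinary least squares per feature on log-CPM values for one of the
#' study designs, moderates the residual variances across features (see
#' [moderate_variances()]), and tests each contrast with a moderated
#' two-sided t-test on \code{df + prior_df} degrees of freedom. P-values are
#' BH-adjusted per contrast across features.
#'
#' @param logcpm matrix of log2 CPM values (features x samples).
#' @param meta sample metadata matching the columns of \code{logcpm}.
#' @param design design name passed to [design_matrix()], or a list as
#'   returned by it.
#' @param moderate logical; moderate variances across features (default TRUE).
#' @return object of class \code{epimem_fit}: a list with \code{tables} (one
#'   data.frame per contrast: feature, log2FC, SE, t, p, fdr), \code{design},
#'   \code{df}, \code{prior_df}, \code{sigma2} and \code{coefficients}.
#' @export
fit_model <- function(logcpm, meta, design = "washout", moderate = TRUE) {
  logcpm <- as.matrix(logcpm)
  meta <- sample_meta(meta, logcpm)
  ds <- if (is.list(design)) design else design_matrix(meta, design)
  X <- ds$X
  if (!all(rownames(X) == colnames(logcpm)))
    X <- X[match(colnames(logcpm), rownames(X)), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- n - p
  if (df < 1L) stop("no residual degrees of freedom")

  # one QR, all features at once
  B <- t(qr.coef(qrX, t(logcpm)))          # features x p
  fitted <- B %*% t(X)
  res <- logcpm - fitted
  s2 <- rowSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))

  if (moderate) {
    mod <- moderate_variances(s2, df)
    s2_use <- mod$var
    df_total <- df + min(mod$prior_df, 1e6)
    prior_df <- mod$prior_df
  } else {
    s2_use <- s2
    df_total <- df
    prior_df <- 0
  }

  tables <- lapply(ds$contrasts, function(cv) {
    eff <- as.numeric(B %*% cv)
    u <- as.numeric(t(cv) %*% XtXinv %*% cv)
    se <- sqrt(s2_use * u)
    tstat <- eff / se
    pval <- 2 * stats::pt(-abs(tstat), df = df_total)
    data.frame(feature = rownames(logcpm), log2FC = eff, SE = se, t = tstat,
               p = pval, fdr = bh_adjust(pval), stringsAsFactors = FALSE)
  })
  out <- list(tables = tables, design = ds$design, df = df,
              prior_df = prior_df, sigma2 = s2, coefficients = B)
  class(out) <- "epimem_fit"
  out
}

#' @export
print.epimem_fit <- function(x, ...) {
  cat(sprintf("epimem_fit: %d features, design '%s', %d contrasts, residual df %d (prior df %.1f)\n",
              nrow(x$coefficients), x$design, length(x$tables), x$df,
              x$prior_df))
  invisible(x)
}

#' @export
summary.epimem_fit <- function(object, alpha = 0.05, ...) {
  n_sig <- vapply(object$tables, function(tb) sum(tb$fdr < alpha), numeric(1))
  out <- data.frame(contrast = names(object$tables), n_significant = n_sig,
                    row.names = NULL)
  cat(sprintf("Significant features per contrast (FDR < %g):\n", alpha))
  print(out)
  invisible(out)
}

#' Significant feature sets per timepoint
#'
#' Extracts, per contrast of a fitted model, the set of features whose FDR
#' falls below a threshold.
#'
#' @param fit an \code{epimem_fit}.
#' @param alpha FDR threshold (default 0.1, the per-timepoint threshold used
#'   for significant-site counting).
#' @return named list of character vectors, one per contrast.
#' @export
significant_features <- function(fit, alpha = 0.1) {
  stopifnot(inherits(fit, "epimem_fit"), alpha > 0, alpha < 1)
  lapply(fit$tables, function(tb) tb$feature[tb$fdr < alpha])
}
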