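#' Forward-stepwise linear discriminant analysis
#'
#' Variable selection by the partial F on the reduction of Wilks' lambda: at
#' each step the candidate with the largest partial F enters if F >=
#' `f_enter`; after every entry, previously entered variables whose partial F
#' given the others falls below `f_remove` are removed. The discriminant
#' functions are then fit on the selected variables, reporting canonical
#' scores, resubstitution and leave-one-out confusion matrices, and the
#' overall Wilks' lambda with Rao's F approximation.
#'
#' @param features data.frame of numeric predictors (or a feature table; the
#'   columns in `columns` are used, complete cases only).
#' @param labels group labels (factor or character), one per row.
#' @param f_enter,f_remove F-to-enter and F-to-remove thresholds; classical
#'   defaults 4.0 / 3.9.
#' @param columns candidate predictor columns.
#' @param prior class priors for classification: "equal" (default) or
#'   "proportional".
#' @return a `stepwise_lda` object: `selected_vars`, `step_trace`, `model`
#'   (the [MASS::lda()] fit), `scores`, `confusion_resub`, `confusion_loo`,
#'   `accuracy_resub`, `accuracy_loo` (percent), `wilks_lambda`, `wilks_F`,
#'   `wilks_df`, `wilks_p`, `misclassified_resub` (row ids).
#' @export
stepwise_lda <- function(features, labels,
                         f_enter = 4.0, f_remove = 3.9,
                         columns = intersect(feature_columns(),
                                             names(features)),
                         prior = c("equal", "proportional")) {
  prior <- match.arg(prior)
  x <- as.matrix(features[, columns, drop = FALSE])
  g <- factor(labels)
  cc <- stats::complete.cases(x)
  if (!all(cc)) {
    message(sum(!cc), " incomplete row(s) dropped before discriminant analysis")
    x <- x[cc, , drop = FALSE]
    g <- droplevels(g[cc])
  }
  k <- nlevels(g)
  n <- nrow(x)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 specimens")

  W <- within_sscp(x, g)
  Tt <- total_sscp(x)
  lambda_of <- function(sel) {
    if (length(sel) == 0L) return(1)
    dw <- det(W[sel, sel, drop = FALSE])
    dt <- det(Tt[sel, sel, drop = FALSE])
    if (!is.finite(dw) || !is.finite(dt) || dt <= 0) return(NA_real_)
    dw / dt
  }

  sel <- character(0)
  trace <- list()
  repeat {
    changed <- FALSE
    pool <- setdiff(columns, sel)
    lam0 <- lambda_of(sel)
    if (length(pool) > 0L) {
      p <- length(sel)
      cand <- vapply(pool, function(v) {
        lam1 <- lambda_of(c(sel, v))
        if (!is.finite(lam1) || lam1 <= 0) return(NA_real_)
        (lam0 / lam1 - 1) * (n - k - p) / (k - 1)
      }, numeric(1))
      if (any(is.na(cand))) {
        bad <- pool[is.na(cand)]
        warning("singular covariance for candidate(s) ",
                paste(bad, collapse = ", "), ": skipped")
      }
      if (any(!is.na(cand)) && max(cand, na.rm = TRUE) >= f_enter) {
        v <- pool[which.max(cand)]
        lam1 <- lambda_of(c(sel, v))
        fval <- max(cand, na.rm = TRUE)
        sel <- c(sel, v)
        trace[[length(trace) + 1L]] <- data.frame(
          step = length(trace) + 1L, action = "enter", variable = v,
          wilks_lambda = lam1, F = fval,
          p = stats::pf(fval, k - 1, n - k - length(sel) + 1, lower.tail = FALSE),
          stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    # removal sweep
    repeat {
      if (length(sel) < 2L) break
      p <- length(sel)
      lam_full <- lambda_of(sel)
      frem <- vapply(sel, function(v) {
        lam_red <- lambda_of(setdiff(sel, v))
        (lam_red / lam_full - 1) * (n - k - p + 1) / (k - 1)
      }, numeric(1))
      if (min(frem) < f_remove) {
        v <- sel[which.min(frem)]
        sel <- setdiff(sel, v)
        trace[[length(trace) + 1L]] <- data.frame(
          step = length(trace) + 1L, action = "remove", variable = v,
          wilks_lambda = lambda_of(sel), F = min(frem),
          p = stats::pf(min(frem), k - 1, n - k - p + 1, lower.tail = FALSE),
          stringsAsFactors = FALSE)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(sel) == 0L) stop("no discriminative variables: no candidate reached F-to-enter")

  pr <- if (prior == "equal") rep(1 / k, k) else as.numeric(table(g)) / n
  fit <- MASS::lda(x[, sel, drop = FALSE], grouping = g, prior = pr)
  pred <- stats::predict(fit)
  conf_resub <- table(truth = g, predicted = pred$class)
  loo <- MASS::lda(x[, sel, drop = FALSE], grouping = g, prior = pr, CV = TRUE)
  conf_loo <- table(truth = g, predicted = loo$class)
  lam <- lambda_of(sel)
  rao <- rao_f(lam, p = length(sel), k = k, n = n)

  structure(list(
    selected_vars = sel,
    step_trace = do.call(rbind, trace),
    model = fit,
    scores = pred$x,
    group = g,
    confusion_resub = conf_resub,
    confusion_loo = conf_loo,
    accuracy_resub = 100 * sum(diag(conf_resub)) / n,
    accuracy_loo = 100 * sum(diag(conf_loo)) / n,
    wilks_lambda = lam,
    wilks_F = rao$F, wilks_df = c(rao$df1, rao$df2), wilks_p = rao$p,
    misclassified_resub = which(pred$class != g)
  ), class = "stepwise_lda")
}

#' @export
print.stepwise_lda <- function(x, ...) {
  cat("Forward-stepwise LDA\n")
  cat("  selected:", paste(x$selected_vars, collapse = ", "), "\n")
  cat(sprintf("  Wilks lambda = %.4f, F(%d, %.1f) = %.2f, p = %.3g\n",
              x$wilks_lambda, x$wilks_df[1], x$wilks_df[2], x$wilks_F, x$wilks_p))
  cat(sprintf("  accuracy: %.1f%% resubstitution, %.1f%% leave-one-out\n",
              x$accuracy_resub, x$accuracy_loo))
  invisible(x)
}

within_sscp <- function(x, g) {
  W <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    xc <- sweep(xi, 2, colMeans(xi))
    W <- W + crossprod(xc)
  }
  W
}

total_sscp <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc)
}

# Rao's F approximation for Wilks' lambda
rao_f <- function(lambda, p, k, n) {
  q <- k - 1
  df1 <- p * q
  denom <- p^2 + q^2 - 5
  s <- if (denom > 0) sqrt((p^2 * q^2 - 4) / denom) else 1
  m <- n - 1 - (p + k) / 2
  df2 <- m * s - df1 / 2 + 1
  lam_s <- lambda^(1 / s)
  Fv <- (1 - lam_s) / lam_s * df2 / df1
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}
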