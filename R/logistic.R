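#' Zero-intercept ridge-stabilized logistic fit
#'
#' Fits `logit P(y = 1) = X beta` with no intercept by iteratively
#' reweighted least squares. A small ridge penalty (default `1e-6`) keeps
#' the fit defined under complete separation, where the unpenalized
#' maximum-likelihood estimate diverges.
#'
#' @param x Numeric matrix of predictors (no intercept column).
#' @param y Binary response (0/1).
#' @param ridge Ridge penalty on the coefficients.
#' @param max_iter,tol IRLS iteration controls.
#' @return List with `coefficients`, `converged`, `iterations`.
#' @export
fit_logistic0 <- function(x, y, ridge = 1e-6, max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  p <- ncol(x)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- tryCatch(
      drop(solve(xtw %*% x + diag(ridge, p), xtw %*% z)),
      error = function(e) rep(NA_real_, p)
    )
    if (anyNA(beta_new)) break
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  list(coefficients = setNames(beta, colnames(x)),
       converged = converged, iterations = iter)
}

#' Evaluate a zero-intercept logistic model of pathogenicity
#'
#' The untrained-model evaluation protocol: a zero-intercept logistic
#' regression of the binary label on the supplied features, assessed either
#' by 500 random 70/30 train/test splits (AUC on each held-out set,
#' summarized by the mean) or by leave-one-out prediction (one AUC over all
#' held-out predictions). All randomness is controlled by `seed`, so a
#' rerun with the same seed reproduces the result bit for bit.
#' Non-convergent iterations are excluded from the summary and counted.
#'
#' @param features Numeric matrix or data frame of predictors.
#' @param labels Binary labels (see [roc_auc()] for accepted encodings).
#' @param mode `"split_500"` or `"loo"`.
#' @param seed Integer seed for the split sequence.
#' @param n_splits Number of random splits in `"split_500"` mode.
#' @param train_frac Training fraction per split.
#' @param ridge Ridge stabilizer passed to [fit_logistic0()].
#' @return Object of class `sbna_logit_eval`: full-data `coefficients`,
#'   per-iteration `iteration_auc`, `summary_auc`, `n_nonconverged`,
#'   `mode`, `seed`. [tidy()] returns the coefficients, [glance()] the
#'   summary.
#' @export
logistic_eval <- function(features, labels, mode = c("split_500", "loo"),
                          seed = 1L, n_splits = 500L, train_frac = 0.7,
                          ridge = 1e-6) {
  mode <- match.arg(mode)
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as_binary_label(labels)
  keep <- complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    abort("need at least 2 observations per class")
  }
  full <- fit_logistic0(x, y, ridge = ridge)
  n <- nrow(x)
  if (mode == "split_500") {
    rng <- withr_seed(seed)
    on.exit(rng(), add = TRUE)
    n_train <- round(train_frac * n)
    aucs <- rep(NA_real_, n_splits)
    for (i in seq_len(n_splits)) {
      idx <- sample.int(n, n_train)
      ytr <- y[idx]; yte <- y[-idx]
      if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L) next
      fit <- fit_logistic0(x[idx, , drop = FALSE], ytr, ridge = ridge)
      if (!fit$converged) next
      pred <- drop(x[-idx, , drop = FALSE] %*% fit$coefficients)
      aucs[i] <- roc_auc(pred, yte)$auc
    }
    summary_auc <- mean(aucs, na.rm = TRUE)
    n_bad <- sum(is.na(aucs))
  } else {
    pred <- vapply(seq_len(n), function(i) {
      fit <- fit_logistic0(x[-i, , drop = FALSE], y[-i], ridge = ridge)
      drop(x[i, , drop = FALSE] %*% fit$coefficients)
    }, numeric(1))
    aucs <- roc_auc(pred, y)$auc
    summary_auc <- aucs
    n_bad <- 0L
  }
  structure(list(coefficients = full$coefficients,
                 iteration_auc = aucs,
                 summary_auc = summary_auc,
                 n_nonconverged = n_bad,
                 mode = mode, seed = seed, n = n),
            class = "sbna_logit_eval")
}

# scoped RNG: set a seed now, return a restorer for the previous state
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' @export
print.sbna_logit_eval <- function(x, ...) {
  cat(sprintf("zero-intercept logistic evaluation (%s): summary AUC = %.4f\n",
              x$mode, x$summary_auc))
  cat("coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sbna_logit_eval <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.sbna_logit_eval <- function(x, ...) {
  tibble(summary_auc = x$summary_auc, mode = x$mode, n = x$n,
         n_nonconverged = x$n_nonconverged, seed = x$seed)
}
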