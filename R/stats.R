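#' ROC curve and AUC for a pathogenicity score
#'
#' Computes the ROC curve over all score thresholds and the area under it
#' via the rank (Mann-Whitney) formulation with average-rank tie handling,
#' so `auc == U / (n1 * n0)` exactly. An operating point
#' (sensitivity, specificity, PPV, NPV) can be extracted at any threshold
#' with [operating_point()].
#'
#' @param scores Numeric scores (higher = more pathogenic).
#' @param labels Binary labels: logical, 0/1, or a factor/character with
#'   positive class `"pathogenic"`.
#' @return Object of class `sbna_roc`: list with `curve` (tibble
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#'   [tidy()] returns the curve, [glance()] the AUC, [autoplot()] draws it.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]
  y <- y[keep]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           sensitivity = sum(pred & y == 1) / n1,
           specificity = sum(!pred & y == 0) / n0)
  })
  structure(list(curve = curve, auc = auc, n_pos = n1, n_neg = n0,
                 scores = scores, labels = y),
            class = "sbna_roc")
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  l <- tolower(as.character(labels))
  ifelse(is.na(l), NA_integer_, as.integer(l %in% c("pathogenic", "1", "true")))
}

#' @export
print.sbna_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d pathogenic vs %d benign)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sbna_roc <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.sbna_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Classifier operating point at a threshold
#'
#' @param roc An `sbna_roc` object.
#' @param threshold Score cut; `strict` selects `>` (as used for the
#'   modified-score call) instead of `>=`.
#' @param strict Use a strict inequality for the positive call.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
operating_point <- function(roc, threshold, strict = FALSE) {
  stopifnot(inherits(roc, "sbna_roc"))
  pred <- if (strict) roc$scores > threshold else roc$scores >= threshold
  y <- roc$labels
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
  tibble(threshold = threshold,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = ifelse(tp + fp == 0, NA_real_, tp / (tp + fp)),
         npv = ifelse(tn + fn == 0, NA_real_, tn / (tn + fn)))
}

#' Spearman rank correlation with t-approximation p value
#'
#' Rank correlation with average ranks for ties; the p value uses the
#' large-sample t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (pairs with `NA` dropped).
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  tibble(rho = rho, p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Encode pathogenicity labels as ordinal integers
#'
#' benign -> 0, vus -> 1, pathogenic -> 2; the ordinal coding used to
#' correlate scores with clinical labels. Unlabeled entries are an error
#' and must be filtered first.
#'
#' @param labels Factor/character vector of labels.
#' @return Integer vector.
#' @export
encode_labels <- function(labels) {
  l <- tolower(as.character(labels))
  if (any(!l %in% c("benign", "vus", "pathogenic"))) {
    abort("labels must be benign/vus/pathogenic (drop unlabeled first)")
  }
  c(benign = 0L, vus = 1L, pathogenic = 2L)[l] |> unname()
}

#' Two-sided Mann-Whitney U test
#'
#' Wraps the tie-corrected normal-approximation test; exact p values are
#' available for small samples without ties.
#'
#' @param a,b Numeric samples.
#' @param exact Use the exact distribution (only honoured when both groups
#'   have 10 or fewer observations and there are no ties).
#' @return Tibble with `U`, `p_value`, group sizes and medians.
#' @export
mann_whitney <- function(a, b, exact = FALSE) {
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty")
  use_exact <- exact && length(a) <= 10L && length(b) <= 10L &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = FALSE)
  )
  tibble(U = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(a), n_b = length(b),
         median_a = stats::median(a), median_b = stats::median(b))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H test across groups, followed (when three
#' or more groups are present) by Dunn's pairwise z tests on mean ranks
#' with Bonferroni-adjusted p values (`min(1, m * p)` over the `m` pairs).
#'
#' @param groups Named list of numeric vectors.
#' @return List of class `sbna_grouptest`: `statistic`, `p_value`,
#'   `group_medians`, and `pairwise` tibble (`pair`, `z`, `p_raw`,
#'   `p_adjusted`).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2L) abort("need at least 2 groups")
  if (any(lengths(groups) == 0L)) abort("all groups must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- kruskal.test(x, g)
  pairwise <- tibble(pair = character(0), z = numeric(0),
                     p_raw = numeric(0), p_adjusted = numeric(0))
  if (length(groups) >= 3L) {
    r <- rank(x)
    N <- length(x)
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    mean_rank <- tapply(r, g, mean)
    ns <- lengths(groups)
    combos <- utils::combn(names(groups), 2)
    m <- ncol(combos)
    pairwise <- purrr::map_dfr(seq_len(m), function(k) {
      i <- combos[1, k]; j <- combos[2, k]
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
      z <- (mean_rank[[i]] - mean_rank[[j]]) / se
      p <- 2 * pnorm(-abs(z))
      tibble(pair = paste(i, j, sep = " vs "), z = z,
             p_raw = p, p_adjusted = pmin(1, m * p))
    })
  }
  structure(list(statistic = unname(kw$statistic),
                 p_value = kw$p.value,
                 group_medians = purrr::map_dbl(groups, stats::median),
                 pairwise = pairwise),
            class = "sbna_grouptest")
}

#' @export
print.sbna_grouptest <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4f, p = %.3g\n", x$statistic, x$p_value))
  if (nrow(x$pairwise) > 0L) print(x$pairwise)
  invisible(x)
}

#' Position-wise mean of functional scores
#'
#' Deep-mutagenesis experiments can score several substitutions at one
#' position; the per-position value used downstream is their arithmetic
#' mean.
#'
#' @param functional Tibble with columns `position` and `functional_score`.
#' @return Tibble `position`, `functional_mean`, `n_variants`.
#' @export
position_functional_mean <- function(functional) {
  functional %>%
    filter(!is.na(.data$functional_score)) %>%
    group_by(.data$position) %>%
    summarise(functional_mean = mean(.data$functional_score),
              n_variants = n(), .groups = "drop")
}
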