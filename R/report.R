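#' Full statistical evaluation of a scored variant table
#'
#' Runs the complete evaluation protocol on a scored, labeled variant
#' table: ROC/AUC of the modified score (benign vs pathogenic), the
#' operating point at the configured call threshold, Kruskal-Wallis with
#' Dunn/Bonferroni post hoc across the three label groups, Mann-Whitney
#' benign-vs-pathogenic, Spearman correlation between score and the
#' 0/1/2 ordinal label encoding, and — when EVE scores are present — the
#' same ROC/operating-point block for the combined score.
#'
#' @param scored Tibble from [score_variants()] (needs `modified`, `label`;
#'   optionally `combined`).
#' @param config Thresholds; see [sbna_config()].
#' @return List of class `sbna_report` with components `n`, `roc_modified`,
#'   `operating_modified`, `group_test`, `mann_whitney`, `spearman`, and
#'   (optionally) `roc_combined`, `operating_combined`. Serialize with
#'   [write_report()].
#' @export
evaluate_variants <- function(scored, config = sbna_config()) {
  d <- filter(scored, !is.na(.data$modified), .data$label != "unlabeled")
  d$label <- droplevels(factor(d$label,
                               levels = c("benign", "vus", "pathogenic")))
  bp <- filter(d, .data$label %in% c("benign", "pathogenic"))
  if (length(unique(bp$label)) < 2L) {
    abort("need both benign and pathogenic variants to evaluate",
          class = "sbnar_config_error")
  }
  roc_mod <- roc_auc(bp$modified, bp$label == "pathogenic")
  groups <- split(d$modified, d$label)
  groups <- groups[lengths(groups) > 0L]
  out <- list(
    n = nrow(d),
    n_by_label = table(d$label),
    roc_modified = roc_mod,
    operating_modified = operating_point(roc_mod,
                                         config$threshold_modified,
                                         strict = TRUE),
    group_test = if (length(groups) >= 2L) kruskal_dunn(groups) else NULL,
    mann_whitney = mann_whitney(
      d$modified[d$label == "benign"],
      d$modified[d$label == "pathogenic"]),
    spearman = spearman_cor(d$modified, encode_labels(d$label))
  )
  if ("combined" %in% names(d) && any(!is.na(d$combined))) {
    cb <- filter(bp, !is.na(.data$combined))
    if (length(unique(cb$label)) == 2L) {
      roc_c <- roc_auc(cb$combined, cb$label == "pathogenic")
      out$roc_combined <- roc_c
      out$operating_combined <- operating_point(roc_c,
                                                config$threshold_combined)
    }
  }
  structure(out, class = "sbna_report")
}

#' @export
print.sbna_report <- function(x, ...) {
  cat(sprintf("evaluation over %d labeled variants\n", x$n))
  print(x$roc_modified)
  cat(sprintf("Spearman rho (0/1/2 encoding) = %.3f, p = %.3g\n",
              x$spearman$rho, x$spearman$p_value))
  if (!is.null(x$group_test)) print(x$group_test)
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' Writes every statistic of an `sbna_report` (plus the configuration,
#' seed and package version) as structured JSON.
#'
#' @param report An `sbna_report` from [evaluate_variants()].
#' @param file Output path; `NULL` returns the JSON string.
#' @param config,seed Recorded alongside the results for provenance.
#' @return The JSON string, invisibly.
#' @export
write_report <- function(report, file = NULL, config = sbna_config(),
                         seed = NULL) {
  payload <- list(
    software = paste0("sbnar ", as.character(utils::packageVersion("sbnar"))),
    seed = seed,
    config = config,
    n = report$n,
    n_by_label = as.list(report$n_by_label),
    auc_modified = report$roc_modified$auc,
    operating_modified = report$operating_modified,
    auc_combined = if (!is.null(report$roc_combined)) report$roc_combined$auc,
    operating_combined = report$operating_combined,
    kruskal_wallis = if (!is.null(report$group_test)) {
      list(H = report$group_test$statistic,
           p_value = report$group_test$p_value,
           group_medians = as.list(report$group_test$group_medians),
           pairwise = report$group_test$pairwise)
    },
    mann_whitney = report$mann_whitney,
    spearman = report$spearman
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(file)) writeLines(json, file)
  invisible(as.character(json))
}
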