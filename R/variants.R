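aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62_env <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62[aa1, aa1]
  }
  blosum62_env$m
}

#' BLOSUM62 substitution score
#'
#' Log-odds substitution score for a reference/alternate amino-acid pair
#' from the standard BLOSUM62 matrix. Conservative substitutions score
#' high, radical ones low; off-diagonal values for the 20 canonical amino
#' acids span -4 to 3. Vectorized over pairs.
#'
#' @param ref_aa,alt_aa One-letter amino-acid codes.
#' @return Integer vector of substitution scores.
#' @examples
#' blosum62_score("R", "S")  # -1
#' blosum62_score("C", "Y")  # -2
#' @export
blosum62_score <- function(ref_aa, alt_aa) {
  ref_aa <- toupper(ref_aa)
  alt_aa <- toupper(alt_aa)
  bad <- !(ref_aa %in% aa1) | !(alt_aa %in% aa1)
  if (any(bad)) {
    abort(paste0("non-canonical amino-acid code(s): ",
                 paste(unique(c(ref_aa[bad], alt_aa[bad])), collapse = ", ")))
  }
  m <- blosum62_matrix()
  as.integer(m[cbind(ref_aa, alt_aa)])
}

#' Modified network score for a substitution
#'
#' The per-residue network score minus the BLOSUM62 entry of the
#' substitution, so a topologically constrained position hit by a
#' non-conservative change scores highest. The two terms are on comparable
#' scales (network scores are standardized per protein; BLOSUM62
#' off-diagonals span -4 to 3), which makes the simple difference
#' meaningful.
#'
#' @param network_score Numeric network score(s) at the variant position.
#' @param ref_aa,alt_aa One-letter codes of the substitution.
#' @return Numeric modified score(s); `NA` network scores propagate.
#' @examples
#' modified_score(3.672, "R", "S")  # 4.672
#' @export
modified_score <- function(network_score, ref_aa, alt_aa) {
  network_score - blosum62_score(ref_aa, alt_aa)
}

#' Bin ClinVar classifications into benign / VUS / pathogenic
#'
#' Maps ClinVar clinical-significance strings to three bins — benign
#' ("Benign", "Benign/Likely benign", "Likely benign"), VUS ("Uncertain
#' significance", "not provided", "Conflicting interpretations of
#' pathogenicity") and pathogenic ("Pathogenic", "Pathogenic/Likely
#' pathogenic", "Likely pathogenic") — and applies the review-confidence
#' filter: entries with fewer than `min_stars` gold stars (default 2, i.e.
#' multiple concordant submitters with assertion criteria) are left
#' unlabeled. Unrecognized strings are unlabeled with a warning.
#'
#' @param clinvar_class Character vector of ClinVar significance strings
#'   (`NA`/empty allowed).
#' @param clinvar_stars Integer review-star counts (`NA` treated as 0).
#' @param min_stars Minimum stars for a label to be trusted.
#' @return Factor with levels `benign`, `vus`, `pathogenic`, `unlabeled`.
#' @export
bin_clinvar <- function(clinvar_class, clinvar_stars, min_stars = 2) {
  cls <- tolower(trimws(ifelse(is.na(clinvar_class), "", clinvar_class)))
  benign_set <- c("benign", "benign/likely benign", "likely benign")
  vus_set <- c("uncertain significance", "not provided",
               "conflicting interpretations of pathogenicity")
  path_set <- c("pathogenic", "pathogenic/likely pathogenic",
                "likely pathogenic")
  known <- cls %in% c(benign_set, vus_set, path_set, "")
  if (any(!known)) {
    warn(paste0("unrecognized ClinVar classification(s) left unlabeled: ",
                paste(unique(clinvar_class[!known]), collapse = "; ")))
  }
  stars <- ifelse(is.na(clinvar_stars), 0L, clinvar_stars)
  lab <- case_when(
    stars < min_stars ~ "unlabeled",
    cls %in% benign_set ~ "benign",
    cls %in% vus_set ~ "vus",
    cls %in% path_set ~ "pathogenic",
    TRUE ~ "unlabeled"
  )
  factor(lab, levels = c("benign", "vus", "pathogenic", "unlabeled"))
}

#' gnomAD frequency rule for benign variants
#'
#' A locus with at least `min_count` alternate-allele observations in
#' gnomAD is considered benign; this supplies additional relatively benign
#' variants to otherwise unlabeled positions.
#'
#' @param gnomad_alt_count Integer allele counts (`NA` -> `FALSE`).
#' @param min_count Threshold count (default 250).
#' @return Logical vector.
#' @export
gnomad_benign <- function(gnomad_alt_count, min_count = 250) {
  !is.na(gnomad_alt_count) & gnomad_alt_count >= min_count
}

#' Attach pathogenicity labels to a variant table
#'
#' Applies [bin_clinvar()] and, where that leaves a variant unlabeled,
#' the gnomAD frequency rule ([gnomad_benign()]). A trusted ClinVar label
#' always wins over the frequency rule.
#'
#' @param variants Tibble with columns `clinvar_class`, `clinvar_stars`,
#'   `gnomad_alt_count` (missing columns are treated as all-`NA`).
#' @param min_stars,gnomad_min_count Rule thresholds.
#' @return The input with an added `label` factor column.
#' @export
label_variants <- function(variants, min_stars = 2, gnomad_min_count = 250) {
  v <- variants
  for (col in c("clinvar_class", "clinvar_stars", "gnomad_alt_count")) {
    if (!col %in% names(v)) v[[col]] <- NA
  }
  lab <- bin_clinvar(v$clinvar_class, v$clinvar_stars, min_stars = min_stars)
  freq_benign <- gnomad_benign(v$gnomad_alt_count, min_count = gnomad_min_count)
  lab[lab == "unlabeled" & freq_benign] <- "benign"
  v$label <- lab
  v
}

#' Read a delimited variant table
#'
#' Reads a tab- or comma-delimited variant file with a header. Expected
#' columns: `gene`, `position` (1-based protein coordinate), `ref_aa`,
#' `alt_aa`; optional: `clinvar_class`, `clinvar_stars`,
#' `gnomad_alt_count`, `eve`, `functional_score`.
#'
#' @param file Path to the variant table.
#' @return Tibble of variant records.
#' @export
read_variants <- function(file) {
  v <- suppressMessages(readr::read_delim(file, show_col_types = FALSE))
  required <- c("gene", "position", "ref_aa", "alt_aa")
  miss <- setdiff(required, names(v))
  if (length(miss) > 0L) {
    abort(paste0("variant table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  v
}

#' Join variants to structure-derived network scores
#'
#' Maps 1-based protein positions onto scored structure residues, either by
#' a constant offset (`protein position = resno + offset`) or through an
#' explicit alignment table for structures with gaps or insertion codes.
#' Positions outside structural coverage keep an `NA` score and are flagged.
#' Optionally the structure residue type is checked against the variant's
#' reference amino acid.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param scores Score table from [sbna_scores()].
#' @param offset Integer offset mapping residue numbers to protein
#'   positions (ignored when `mapping` is given).
#' @param mapping Optional tibble `position`, `chain`, `resno`, `insert`
#'   giving an explicit position-to-residue alignment.
#' @param strict Reject (drop) variants whose reference amino acid does not
#'   match the structure residue; otherwise mismatches only warn.
#' @return The variant tibble with `network_score`, `struct_resid` and
#'   logical `covered` columns added.
#' @export
map_variants <- function(variants, scores, offset = 0, mapping = NULL,
                         strict = FALSE) {
  if (is.null(mapping)) {
    mapping <- scores %>%
      mutate(position = .data$resno + offset) %>%
      select("position", "chain", "resno", "insert")
  }
  key <- mapping %>%
    left_join(scores, by = c("chain", "resno", "insert")) %>%
    select("position", struct_resid = "resid", "network_score")
  out <- variants %>%
    left_join(key, by = "position") %>%
    mutate(covered = !is.na(.data$network_score))
  mism <- out$covered & !is.na(out$struct_resid) &
    aa3_to_1[out$struct_resid] != toupper(out$ref_aa)
  if (any(mism)) {
    msg <- paste0(sum(mism), " variant(s) whose reference amino acid does ",
                  "not match the structure residue")
    if (strict) {
      warn(paste0("dropping ", msg, " (strict mode)"))
      out <- out[!mism, ]
    } else {
      warn(msg)
    }
  }
  out
}

#' Compute per-variant scores and pathogenicity calls
#'
#' Given variants already joined to network scores, adds the BLOSUM62
#' substitution score, the modified score (network minus BLOSUM62), the
#' min-max scaled modified score, the EVE-combined score where an EVE score
#' is present, threshold calls, and the evidence-derived label. The
#' min-max scaling is computed over all modified scores in the table (which
#' may span several proteins), matching how the combined score's
#' `[0, 2]` range is constructed.
#'
#' @param variants Output of [map_variants()] (or any tibble with
#'   `ref_aa`, `alt_aa`, `network_score` and optional `eve`,
#'   `clinvar_class`, `clinvar_stars`, `gnomad_alt_count`).
#' @param config Threshold configuration; see [sbna_config()].
#' @param scale_range Optional numeric length-2 `(min, max)` to use for
#'   scaling instead of the table's own range (for scoring new variants on
#'   a previously fixed scale).
#' @return Tibble with added columns `blosum`, `modified`, `scaled`,
#'   `combined`, `call_modified`, `call_eve`, `call_combined`, `label`.
#' @export
score_variants <- function(variants, config = sbna_config(),
                           scale_range = NULL) {
  v <- variants
  if (!"eve" %in% names(v)) v$eve <- NA_real_
  v$blosum <- blosum62_score(v$ref_aa, v$alt_aa)
  v$modified <- v$network_score - v$blosum
  fin <- v$modified[is.finite(v$modified)]
  v$scaled <- NA_real_
  if (!is.null(scale_range) ||
      (length(fin) >= 2L && length(unique(fin)) >= 2L)) {
    v$scaled <- scale_modified(v$modified, range = scale_range)
  }
  v$combined <- combined_score(v$scaled, v$eve)
  v <- classify_variants(v, config = config)
  label_variants(v, min_stars = config$min_stars,
                 gnomad_min_count = config$gnomad_min_count)
}

#' Min-max scale modified scores to \[0, 1\]
#'
#' `(x - min) / (max - min)` with the minimum and maximum taken across the
#' full score set (all proteins analysed together), so the scaled score is
#' comparable across genes before being added to EVE.
#'
#' @param x Numeric modified scores (`NA` allowed, propagated).
#' @param range Optional `(min, max)` overriding the observed range.
#' @return Numeric vector in `[0, 1]` (values outside a supplied `range`
#'   are clipped).
#' @export
scale_modified <- function(x, range = NULL) {
  fin <- x[is.finite(x)]
  if (is.null(range)) {
    if (length(fin) < 2L) abort("need at least 2 finite scores to scale")
    range <- c(min(fin), max(fin))
  }
  if (range[2] <= range[1]) {
    abort("cannot min-max scale: all scores identical")
  }
  pmin(pmax((x - range[1]) / (range[2] - range[1]), 0), 1)
}

#' Combine scaled network score with EVE
#'
#' Sum of the min-max scaled modified score and the EVE evolutionary score,
#' each in `[0, 1]`, giving a combined pathogenicity score in `[0, 2]`.
#' Missing EVE scores yield `NA` (EVE does not cover every variant).
#'
#' @param scaled Scaled modified scores in `[0, 1]`.
#' @param eve EVE scores in `[0, 1]` or `NA`.
#' @return Numeric combined scores.
#' @export
combined_score <- function(scaled, eve) {
  ok <- !is.na(eve) & !is.na(scaled)
  if (any(eve[ok] < 0 | eve[ok] > 1)) abort("EVE scores must lie in [0, 1]")
  out <- rep(NA_real_, length(scaled))
  out[ok] <- scaled[ok] + eve[ok]
  out
}

#' Apply pathogenicity thresholds
#'
#' Calls a variant pathogenic when the modified score exceeds 1.5
#' (strictly), the EVE score is at least 0.65, or the combined score is at
#' least 1.0 — the 1.0 cut being the sum of the minimum pathogenic EVE
#' score and the scaled minimum pathogenic modified score. All thresholds
#' are configurable.
#'
#' @param variants Tibble with `modified` and optionally `eve`, `combined`.
#' @param config See [sbna_config()].
#' @return The input with logical `call_modified`, `call_eve`,
#'   `call_combined` columns (`NA` where the underlying score is missing).
#' @export
classify_variants <- function(variants, config = sbna_config()) {
  v <- variants
  v$call_modified <- v$modified > config$threshold_modified
  v$call_eve <- if ("eve" %in% names(v)) v$eve >= config$threshold_eve else NA
  v$call_combined <- if ("combined" %in% names(v)) {
    v$combined >= config$threshold_combined
  } else NA
  v
}

#' Analysis configuration with field defaults
#'
#' Collects every tunable threshold in one list: the heavy-atom contact
#' cutoff (4.5 Angstrom) and adjacency exclusion (1) for graph building,
#' unit sub-score weights, the solvent exclusion list, the pathogenicity
#' thresholds (modified > 1.5, EVE >= 0.65, combined >= 1.0), the ClinVar
#' star filter (2) and the gnomAD benign count (250).
#'
#' @param ... Named overrides of any default.
#' @return Named list of settings.
#' @export
sbna_config <- function(...) {
  cfg <- list(
    contact_cutoff = 4.5,
    exclude_adjacent = 1,
    subscore_weights = c(1, 1, 1, 1),
    solvent_list = default_solvent_list(),
    threshold_modified = 1.5,
    threshold_eve = 0.65,
    threshold_combined = 1.0,
    min_stars = 2,
    gnomad_min_count = 250
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config option(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}
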