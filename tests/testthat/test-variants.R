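test_that("BLOSUM62 lookups match the published matrix", {
  expect_equal(blosum62_score("R", "S"), -1L)
  expect_equal(blosum62_score("C", "Y"), -2L)
  expect_equal(blosum62_score("A", "A"), 4L)
  expect_equal(blosum62_score("A", "T"), 0L)
  expect_error(blosum62_score("A", "B"), "non-canonical")
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  grid <- expand.grid(r = aa, a = aa, stringsAsFactors = FALSE)
  s <- blosum62_score(grid$r, grid$a)
  expect_equal(s, blosum62_score(grid$a, grid$r))  # symmetry
  off <- s[grid$r != grid$a]
  expect_equal(range(off), c(-4L, 3L))
})

test_that("the modified score is network minus substitution score", {
  expect_equal(modified_score(3.672, "R", "S"), 4.672)
  expect_equal(modified_score(2.154, "C", "Y"), 4.154)
  expect_equal(modified_score(0, "A", "A"), -4)
  expect_true(is.na(modified_score(NA_real_, "A", "T")))
  # monotone: a more conservative substitution lowers the score
  expect_lt(modified_score(1, "L", "I"), modified_score(1, "L", "D"))
})

test_that("ClinVar strings bin into the three classes", {
  cls <- c("Benign", "Benign/Likely benign", "Likely benign",
           "Uncertain significance", "not provided",
           "Conflicting interpretations of pathogenicity",
           "Pathogenic", "Pathogenic/Likely pathogenic", "Likely pathogenic")
  got <- bin_clinvar(cls, rep(2L, 9))
  expect_equal(as.character(got),
               c(rep("benign", 3), rep("vus", 3), rep("pathogenic", 3)))
})

test_that("the review-star filter and unknown strings leave variants unlabeled", {
  expect_equal(as.character(bin_clinvar("Pathogenic", 1L)), "unlabeled")
  expect_equal(as.character(bin_clinvar("Pathogenic", NA)), "unlabeled")
  expect_equal(as.character(bin_clinvar("Benign", 3L)), "benign")
  expect_warning(got <- bin_clinvar("drug response", 2L), "unrecognized")
  expect_equal(as.character(got), "unlabeled")
  expect_equal(as.character(bin_clinvar(NA, 2L)), "unlabeled")
})

test_that("the gnomAD frequency rule uses an inclusive count threshold", {
  expect_equal(gnomad_benign(c(249L, 250L, 251L, NA)),
               c(FALSE, TRUE, TRUE, FALSE))
})

test_that("a trusted ClinVar label beats the frequency rule", {
  v <- tibble::tibble(
    clinvar_class = c("Pathogenic", NA, "Benign", "Pathogenic"),
    clinvar_stars = c(2L, NA, 1L, 1L),
    gnomad_alt_count = c(5000L, 300L, 300L, 100L))
  got <- label_variants(v)
  expect_equal(as.character(got$label),
               c("pathogenic", "benign", "benign", "unlabeled"))
})

test_that("variant tables require the core columns", {
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "G", position = 1L, ref_aa = "A",
                                  alt_aa = "T"), f)
  expect_equal(nrow(read_variants(f)), 1L)
  f2 <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "G", position = 1L), f2)
  expect_error(read_variants(f2), "ref_aa")
})

test_that("position mapping flags coverage and reference mismatches", {
  scores <- tibble::tibble(chain = "A", resno = 1:3, insert = "",
                           resid = c("ALA", "ARG", "CYS"),
                           network_score = c(0.5, 3.672, 2.154))
  v <- tibble::tibble(gene = "G", position = c(2L, 3L, 9L),
                      ref_aa = c("R", "C", "A"), alt_aa = c("S", "Y", "T"))
  m <- map_variants(v, scores)
  expect_equal(m$covered, c(TRUE, TRUE, FALSE))
  expect_equal(m$network_score, c(3.672, 2.154, NA))
  # constant offset shifts the coordinate frame
  m2 <- map_variants(tibble::tibble(gene = "G", position = 12L, ref_aa = "R",
                                    alt_aa = "S"), scores, offset = 10)
  expect_equal(m2$network_score, 3.672)
  # mismatching reference amino acid: warn, or drop under strict mode
  bad <- tibble::tibble(gene = "G", position = 2L, ref_aa = "K", alt_aa = "S")
  expect_warning(kept <- map_variants(bad, scores), "reference amino acid")
  expect_equal(nrow(kept), 1L)
  expect_warning(dropped <- map_variants(bad, scores, strict = TRUE),
                 "dropping")
  expect_equal(nrow(dropped), 0L)
})

test_that("min-max scaling is an affine map onto [0, 1]", {
  x <- c(-2, 0, 1, 6)
  s <- scale_modified(x)
  expect_equal(s, (x + 2) / 8)
  expect_equal(range(s), c(0, 1))
  # a supplied range clips values outside it
  expect_equal(scale_modified(c(-5, 5, 15), range = c(0, 10)),
               c(0, 0.5, 1))
  expect_error(scale_modified(c(1, 1, 1)), "identical")
  expect_true(is.na(scale_modified(c(0, NA, 1))[2]))
})

test_that("the combined score adds scaled and EVE components", {
  expect_equal(combined_score(1, 1), 2)
  expect_equal(combined_score(0.37, 0.65), 1.02)
  expect_true(is.na(combined_score(0.5, NA)))
  expect_error(combined_score(0.5, 1.2), "\\[0, 1\\]")
})

test_that("pathogenicity calls apply the documented inequalities", {
  v <- tibble::tibble(modified = c(1.5, 1.5001, NA),
                      eve = c(0.65, 0.6499, NA),
                      combined = c(1.0, 0.9999, NA))
  got <- classify_variants(v)
  expect_equal(got$call_modified, c(FALSE, TRUE, NA))  # strictly greater
  expect_equal(got$call_eve, c(TRUE, FALSE, NA))       # at least
  expect_equal(got$call_combined, c(TRUE, FALSE, NA))  # at least
})

test_that("score_variants composes scoring, calls and labels", {
  v <- tibble::tibble(
    gene = "G", position = 1:4, ref_aa = c("R", "C", "A", "L"),
    alt_aa = c("S", "Y", "T", "I"),
    network_score = c(3.672, 2.154, -0.5, 0.1),
    eve = c(0.9, 0.7, 0.1, NA),
    clinvar_class = c("Pathogenic", "Likely pathogenic", "Benign", NA),
    clinvar_stars = c(2L, 2L, 2L, NA),
    gnomad_alt_count = c(NA, NA, NA, 400L))
  got <- score_variants(v)
  expect_equal(got$modified, c(4.672, 4.154, -0.5, -1.9))
  expect_equal(got$scaled,
               (got$modified - min(got$modified)) / diff(range(got$modified)))
  expect_equal(got$combined[1], got$scaled[1] + 0.9)
  expect_true(is.na(got$combined[4]))
  expect_equal(as.character(got$label),
               c("pathogenic", "pathogenic", "benign", "benign"))
  expect_equal(got$call_modified, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the configuration rejects unknown options", {
  cfg <- sbna_config(threshold_modified = 2)
  expect_equal(cfg$threshold_modified, 2)
  expect_equal(cfg$contact_cutoff, 4.5)
  expect_equal(cfg$threshold_eve, 0.65)
  expect_equal(cfg$threshold_combined, 1.0)
  expect_equal(cfg$min_stars, 2)
  expect_equal(cfg$gnomad_min_count, 250)
  expect_error(sbna_config(cutoff = 5), "unknown config")
})
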