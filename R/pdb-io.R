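#' Read a PDB structure into an atom tibble
#'
#' Parses a PDB-format file (or literal text) into one row per heavy atom.
#' Multi-model files (NMR ensembles, alternative conformers) yield one block
#' of rows per `MODEL` record; single-model files get `model = 1`. Alternate
#' locations are resolved per residue to the highest-occupancy altloc (ties
#' broken alphabetically) and hydrogen/deuterium atoms are discarded, so the
#' result is directly usable for heavy-atom contact counting.
#'
#' @param file Path to a PDB file, or a character vector of PDB-format lines
#'   (anything containing a newline or more than one element is treated as
#'   literal text).
#' @param keep_hydrogens Keep H/D atoms instead of dropping them.
#'
#' @return A tibble with one row per atom and columns `model`, `record`
#'   (`"ATOM"` or `"HETATM"`), `chain`, `resno`, `insert`, `resid` (3-letter
#'   code), `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom),
#'   `occupancy` and `b`. The `role` column (used downstream) is absent until
#'   [prepare_structure()] assigns it.
#'
#' @examples
#' pdb <- generate_structure(n_residues = 8, geometry = "ideal_helix")
#' atoms <- read_pdb_structure(pdb)
#' dplyr::count(atoms, model, chain)
#' @export
read_pdb_structure <- function(file, keep_hydrogens = FALSE) {
  path <- file
  if (length(file) > 1L || any(grepl("\n", file, fixed = TRUE))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), path)
    on.exit(unlink(path), add = TRUE)
  }
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse error: ", conditionMessage(e)))
  )
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0L || !any(at$type == "ATOM")) {
    abort("no ATOM records found in PDB input")
  }
  n_models <- nrow(pdb$xyz)
  xyz <- matrix(as.numeric(pdb$xyz), nrow = n_models)
  per_model <- purrr::map(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    at %>%
      mutate(model = m, x = co[, 1], y = co[, 2], z = co[, 3])
  })
  atoms <- bind_rows(per_model) %>%
    mutate(
      insert = ifelse(is.na(.data$insert), "", .data$insert),
      alt = ifelse(is.na(.data$alt), "", .data$alt),
      element = toupper(trimws(ifelse(is.na(.data$elesy), "", .data$elesy))),
      occupancy = ifelse(is.na(.data$o), 1, .data$o)
    ) %>%
    select(model = "model", record = "type", chain = "chain",
           resno = "resno", insert = "insert", resid = "resid",
           elety = "elety", alt = "alt", element = "element",
           x = "x", y = "y", z = "z", occupancy = "occupancy", b = "b")
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " atom record(s) with non-finite coordinates"))
    atoms <- atoms[!bad, ]
  }
  atoms <- resolve_altloc(atoms)
  if (!keep_hydrogens) {
    atoms <- filter(atoms, !.data$element %in% c("H", "D"))
  }
  atoms %>% select(-"alt")
}

# Keep, per residue, atoms with blank altloc plus the single altloc letter
# with the highest occupancy (ties -> alphabetically first).
resolve_altloc <- function(atoms) {
  if (!any(atoms$alt != "")) return(atoms)
  pick <- atoms %>%
    filter(.data$alt != "") %>%
    group_by(.data$model, .data$chain, .data$resno, .data$insert, .data$alt) %>%
    summarise(occ = mean(.data$occupancy), .groups = "drop") %>%
    arrange(.data$model, .data$chain, .data$resno, .data$insert,
            desc(.data$occ), .data$alt) %>%
    group_by(.data$model, .data$chain, .data$resno, .data$insert) %>%
    slice(1L) %>%
    ungroup() %>%
    select("model", "chain", "resno", "insert", keep_alt = "alt")
  atoms %>%
    left_join(pick, by = c("model", "chain", "resno", "insert")) %>%
    filter(.data$alt == "" | is.na(.data$keep_alt) | .data$alt == .data$keep_alt) %>%
    select(-"keep_alt")
}

#' Write an atom tibble as PDB-format text
#'
#' Serializes the atom table back to fixed-width PDB records (one
#' `MODEL`/`ENDMDL` block per model when several are present). Coordinates
#' are written to 3 decimals, so a read/write round trip preserves them
#' exactly at that precision.
#'
#' @param atoms Atom tibble from [read_pdb_structure()] or
#'   [prepare_structure()].
#' @param file Output path; when `NULL` the lines are returned invisibly
#'   as a character vector.
#' @param b Optional numeric vector (one per atom row) written into the
#'   B-factor column, clamped to `[-9.99, 99.99]`.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(atoms, file = NULL, b = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  bvals <- if (is.null(b)) atoms$b else pmin(pmax(b, -9.99), 99.99)
  bvals[is.na(bvals)] <- 0
  models <- sort(unique(atoms$model))
  multi <- length(models) > 1L
  lines <- character(0)
  serial <- 0L
  for (m in models) {
    idx <- which(atoms$model == m)
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    blk <- atoms[idx, ]
    bb <- bvals[idx]
    rec <- vapply(seq_len(nrow(blk)), function(i) {
      serial <<- serial + 1L
      name <- blk$elety[i]
      # standard PDB rule: 1-3 char atom names start in column 14
      name_fmt <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
      sprintf("%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              blk$record[i], serial %% 100000L, name_fmt, blk$resid[i],
              blk$chain[i], blk$resno[i],
              ifelse(blk$insert[i] == "", " ", blk$insert[i]),
              blk$x[i], blk$y[i], blk$z[i], blk$occupancy[i], bb[i],
              blk$element[i])
    }, character(1))
    lines <- c(lines, rec)
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a score-annotated PDB for external visualization
#'
#' Writes the first model of a prepared structure with each scored residue's
#' network score in the B-factor column (clamped to `[-9.99, 99.99]`), so any
#' molecular viewer can color or size residues by topological constraint.
#' Unscored atoms (ligands, partner chains) get B = 0.
#'
#' @param atoms Prepared atom tibble ([prepare_structure()]).
#' @param scores Score table from [sbna_scores()].
#' @param file Output PDB path.
#' @return Invisibly, the PDB lines.
#' @export
write_score_pdb <- function(atoms, scores, file) {
  m1 <- filter(atoms, .data$model == min(.data$model))
  key <- paste(m1$chain, m1$resno, m1$insert)
  skey <- paste(scores$chain, scores$resno, scores$insert)
  b <- scores$network_score[match(key, skey)]
  b[is.na(b)] <- 0
  write_pdb(m1, file = file, b = b)
}

#' Read per-residue accessible surface area from a DSSP file
#'
#' Minimal reader for the classic DSSP text format: extracts chain, residue
#' number, insertion code, one-letter amino acid and the ACC column
#' (solvent-accessible surface area in square Angstrom). Useful as an
#' external alternative to [compute_rsa()]'s built-in surface calculation.
#'
#' @param file Path to a DSSP output file.
#' @return A tibble with columns `chain`, `resno`, `insert`, `aa`, `sasa`.
#' @export
read_dssp_acc <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) abort("not a DSSP file: no '  #  RESIDUE' header found")
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 38 & substr(body, 14, 14) != "!"]
  tibble(
    chain = trimws(substr(body, 12, 12)),
    resno = as.integer(trimws(substr(body, 6, 10))),
    insert = trimws(substr(body, 11, 11)),
    aa = substr(body, 14, 14),
    sasa = as.numeric(trimws(substr(body, 35, 38)))
  )
}
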