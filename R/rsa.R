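#' Theoretical maximum accessible surface areas
#'
#' Residue-type maxima (square Angstrom) from the theoretical Gly-X-Gly
#' tripeptide set of Tien et al. (2013), used to normalize absolute SASA
#' into relative solvent accessibility.
#'
#' @return Tibble with `resid` (3-letter code) and `max_sasa`.
#' @export
max_sasa_theoretical <- function() {
  tibble(
    resid = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL"),
    max_sasa = c(129.0, 274.0, 195.0, 193.0, 167.0, 225.0, 223.0, 104.0,
                 224.0, 197.0, 201.0, 236.0, 224.0, 240.0, 159.0, 155.0,
                 172.0, 285.0, 263.0, 174.0)
  )
}

# heavy-atom van der Waals radii (Angstrom); unknown elements fall back to C
vdw_radius <- function(element) {
  r <- c("C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80, "P" = 1.80,
         "SE" = 1.90, "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98,
         "FE" = 1.80, "ZN" = 1.39, "MG" = 1.73, "CA" = 2.31, "MN" = 1.80,
         "CU" = 1.40, "NA" = 2.27, "K" = 2.75)
  out <- r[element]
  out[is.na(out)] <- 1.70
  unname(out)
}

# deterministic near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Shrake-Rupley accessible surface per atom against a fixed neighbour set
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  rr <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 > 0 & d2 <= (rr[i] + rr)^2)
    surf <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        d2p <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        free <- free & d2p > rr[j]^2
        if (!any(free)) break
      }
      acc <- sum(free)
    }
    out[i] <- 4 * pi * rr[i]^2 * acc / n_points
  }
  out
}

#' Relative solvent accessibility per residue
#'
#' Computes per-residue solvent-accessible surface area with a rolling
#' probe (Shrake-Rupley sphere sampling, 1.4 Angstrom probe, deterministic
#' 960-point quadrature per atom) over all retained atoms of one conformer,
#' and divides by the residue-type theoretical maximum. Values above 1
#' (possible for exposed termini, since the maxima assume a tripeptide
#' context) are clipped to 1.
#'
#' @param atoms Prepared atom tibble ([prepare_structure()]).
#' @param model Conformer to use (default: first).
#' @param max_sasa Table of residue-type maxima; see
#'   [max_sasa_theoretical()].
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere sample points per atom.
#' @return Tibble per scored residue: identity columns, `sasa`, `max_sasa`,
#'   `rsa` in `[0, 1]`.
#' @export
compute_rsa <- function(atoms, model = NULL,
                        max_sasa = max_sasa_theoretical(),
                        probe = 1.4, n_points = 960L) {
  if (!"role" %in% names(atoms)) {
    abort("atoms must be prepared with prepare_structure() first")
  }
  m <- if (is.null(model)) min(atoms$model) else model
  at <- filter(atoms, .data$model == m)
  sc <- filter(at, .data$role == "scored")
  missing_type <- setdiff(unique(sc$resid), max_sasa$resid)
  if (length(missing_type) > 0L) {
    abort(paste0("no maximum SASA value for residue type(s): ",
                 paste(missing_type, collapse = ", ")))
  }
  sasa_atom <- shrake_rupley(as.matrix(at[, c("x", "y", "z")]),
                             vdw_radius(at$element),
                             probe = probe, n_points = n_points)
  at %>%
    mutate(.atom_sasa = sasa_atom) %>%
    filter(.data$role == "scored") %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$resid) %>%
    summarise(sasa = sum(.data$.atom_sasa), .groups = "drop") %>%
    left_join(max_sasa, by = "resid") %>%
    mutate(rsa = pmin(.data$sasa / .data$max_sasa, 1)) %>%
    arrange(.data$resno, .data$insert)
}
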