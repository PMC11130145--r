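#' Generate a deterministic synthetic protein structure
#'
#' Emits real PDB text (ATOM/HETATM/MODEL records) for a toy protein whose
#' contact topology is known by construction, so the whole scoring pipeline
#' can be exercised end to end without external structure files.
#'
#' Geometries:
#' \describe{
#'   \item{ideal_helix}{backbone + CB atoms on ideal alpha-helix geometry
#'     (1.5 Angstrom rise, 100 degree twist per residue).}
#'   \item{two_domain}{two dense circular clusters joined by a 4-residue
#'     extended linker; the linker residues are the only route between the
#'     domains, so they acquire the top bridging (betweenness) scores. The
#'     linker beads carry deliberately non-consecutive residue numbers so
#'     that peptide-neighbour exclusion cannot sever the inter-domain
#'     path.}
#'   \item{compact_cluster}{one dense circular cluster in which every
#'     residue pair is within contact range.}
#' }
#' With `ligand = TRUE` a 5-atom HET group (`LIG`) is placed adjacent to
#' exactly three designated residues (recorded in the `ligand_resno`
#' attribute). With `n_models > 1`, additional conformers with seeded
#' Gaussian coordinate jitter (sd 0.2 Angstrom) are appended as `MODEL`
#' blocks.
#'
#' @param n_residues Number of residues (at least 4; at least 12 for
#'   `two_domain`, 16 when it also carries a ligand).
#' @param geometry One of `"ideal_helix"`, `"two_domain"`,
#'   `"compact_cluster"`.
#' @param ligand Add the 5-atom ligand group.
#' @param n_models Number of conformers.
#' @param seed Seed fixing the residue sequence and the conformer jitter.
#' @return A single string of PDB text. Attributes: `linker_resno`
#'   (two_domain only), `ligand_resno` (when `ligand`), `sequence`
#'   (3-letter codes in residue-number order).
#'
#' @examples
#' pdb <- generate_structure(30, geometry = "two_domain", seed = 7)
#' attr(pdb, "linker_resno")
#' @export
generate_structure <- function(n_residues,
                               geometry = c("ideal_helix", "two_domain",
                                            "compact_cluster"),
                               ligand = FALSE, n_models = 1L, seed = 42L) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 4L, n_models >= 1L)
  if (geometry == "two_domain" && n_residues < 12L) {
    abort("two_domain geometry needs at least 12 residues")
  }
  if (geometry == "two_domain" && ligand && n_residues < 16L) {
    abort("two_domain with a ligand needs at least 16 residues (smaller domains cannot host a three-residue ligand site)")
  }
  restore <- withr_seed(seed)
  on.exit(restore(), add = TRUE)

  layout <- switch(geometry,
    ideal_helix = helix_layout(n_residues),
    two_domain = two_domain_layout(n_residues),
    compact_cluster = cluster_layout(n_residues)
  )
  # GLY is excluded: fixtures guarantee a CB atom per residue so ligand
  # placement and contact topology are independent of the sampled sequence
  seq3 <- sample(setdiff(canonical_aa3, "GLY"), n_residues, replace = TRUE)

  lig_xyz <- NULL
  lig_resno <- integer(0)
  if (ligand) {
    lp <- ligand_placement(layout, geometry)
    lig_xyz <- lp$xyz
    lig_resno <- lp$resno
  }

  n_atoms <- nrow(layout$atoms) + NROW(lig_xyz)
  lines <- character(0)
  for (m in seq_len(n_models)) {
    jit <- if (m == 1L) {
      matrix(0, n_atoms, 3)
    } else {
      matrix(rnorm(3L * n_atoms, sd = 0.2), n_atoms, 3)
    }
    lines <- c(lines, sprintf("MODEL     %4d", m),
               model_records(layout, seq3, lig_xyz, jit),
               "ENDMDL")
  }
  if (n_models == 1L) {
    lines <- lines[-c(1L, length(lines))]  # single model: no MODEL wrapper
  }
  out <- paste(c(lines, "END"), collapse = "\n")
  attr(out, "sequence") <- seq3
  if (geometry == "two_domain") attr(out, "linker_resno") <- layout$linker_resno
  if (ligand) attr(out, "ligand_resno") <- lig_resno
  out
}

# per-residue heavy-atom offsets from the residue centre (local frame u,t,a)
residue_offsets <- function() {
  rbind(N  = c(-0.30, -1.20, -0.60),
        CA = c( 0.00,  0.00,  0.00),
        C  = c(-0.30,  1.20,  0.60),
        O  = c(-1.00,  1.80,  1.20),
        CB = c( 1.50,  0.30, -0.50))
}

expand_atoms <- function(centers, frames_u, frames_t, frames_a, resno) {
  off <- residue_offsets()
  purrr::map_dfr(seq_len(nrow(centers)), function(i) {
    xyz <- t(vapply(seq_len(nrow(off)), function(k) {
      centers[i, ] + off[k, 1] * frames_u[i, ] + off[k, 2] * frames_t[i, ] +
        off[k, 3] * frames_a[i, ]
    }, numeric(3)))
    tibble(resno = resno[i], name = rownames(off),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

helix_layout <- function(n) {
  i <- seq_len(n)
  theta <- i * 100 * pi / 180
  centers <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  u <- cbind(cos(theta), sin(theta), 0)
  t <- cbind(-sin(theta), cos(theta), 0)
  a <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  list(atoms = expand_atoms(centers, u, t, a, i), linker_resno = integer(0))
}

# radius grows with k to hold the inter-residue spacing at ~1.55 A, dense
# enough that small circles are contact cliques but sparse enough that a
# ligand blob can single out three consecutive residues
circle_radius <- function(k) max(3.2, 1.55 * k / (2 * pi))

circle_centers <- function(k, radius = circle_radius(k), center = c(0, 0, 0),
                           phase = 0) {
  ang <- phase + 2 * pi * (seq_len(k) - 1) / k
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        center[3])
}

circle_frames <- function(centers, origin) {
  u <- sweep(centers, 2, origin)
  u <- u / sqrt(rowSums(u^2))
  t <- cbind(-u[, 2], u[, 1], 0)
  a <- matrix(rep(c(0, 0, 1), each = nrow(centers)), ncol = 3)
  list(u = u, t = t, a = a)
}

cluster_layout <- function(n) {
  centers <- circle_centers(n)
  f <- circle_frames(centers, c(0, 0, 0))
  list(atoms = expand_atoms(centers, f$u, f$t, f$a, seq_len(n)),
       linker_resno = integer(0))
}

two_domain_layout <- function(n) {
  k1 <- (n - 4L) %/% 2L
  k2 <- n - 4L - k1
  step <- 3.8
  gap <- 2.5  # terminal beads sit close enough to touch several domain
              # residues, so no single gateway residue out-bridges the linker
  c1 <- circle_centers(k1, center = c(0, 0, 0))                # exit at +x
  bead_x <- circle_radius(k1) + gap + step * (0:3)
  beads <- cbind(bead_x, 0, 0)
  cen2 <- c(max(bead_x) + gap + circle_radius(k2), 0, 0)
  c2 <- circle_centers(k2, center = cen2, phase = pi)          # entry at -x
  f1 <- circle_frames(c1, c(0, 0, 0))
  f2 <- circle_frames(c2, cen2)
  fb <- list(u = matrix(rep(c(0, 0, 1), each = 4), ncol = 3),
             t = matrix(rep(c(0, 1, 0), each = 4), ncol = 3),
             a = matrix(rep(c(1, 0, 0), each = 4), ncol = 3))
  # bead residue numbers permuted so geometric neighbours in the linker are
  # never sequence-adjacent (|delta resno| >= 2 along the physical chain)
  bead_resno <- n - 4L + c(3L, 1L, 4L, 2L)
  atoms <- bind_rows(
    expand_atoms(c1, f1$u, f1$t, f1$a, seq_len(k1)),
    expand_atoms(beads, fb$u, fb$t, fb$a, bead_resno),
    expand_atoms(c2, f2$u, f2$t, f2$a, k1 + seq_len(k2))
  )
  list(atoms = atoms, linker_resno = sort(bead_resno))
}

# place the 5-atom ligand so that exactly three designated residues have a
# heavy atom within the default 4.5 A cutoff of a ligand atom
ligand_placement <- function(layout, geometry) {
  resno_set <- sort(unique(layout$atoms$resno))
  cb_dir <- function(rn) {
    cb <- layout$atoms %>% filter(.data$resno == rn, .data$name == "CB")
    ca <- layout$atoms %>% filter(.data$resno == rn, .data$name == "CA")
    cb <- as.numeric(cb[1, c("x", "y", "z")])
    d <- cb - as.numeric(ca[1, c("x", "y", "z")])
    list(cb = cb, dir = d / sqrt(sum(d * d)))
  }
  if (geometry == "ideal_helix") {
    # one anchor atom 2 A beyond each designated side chain, plus two
    # stalk atoms further out along the middle residue's direction
    target <- resno_set[c(5, 6, 7)]
    anchors <- t(vapply(target, function(rn) {
      g <- cb_dir(rn)
      g$cb + 2.0 * g$dir
    }, numeric(3)))
    mid <- cb_dir(target[2])
    xyz <- rbind(anchors, mid$cb + 3.4 * mid$dir, mid$cb + 4.6 * mid$dir)
  } else {
    # a compact blob radially outside the middle of three circle residues,
    # on the side facing away from any linker; the blob radius is chosen
    # (deterministically) as the smallest one touching exactly the three
    if (geometry == "two_domain") {
      k1 <- (length(resno_set) - 4L) %/% 2L
      m <- max(2L, k1 %/% 2L + 1L)          # angle ~ pi, away from beads
      target <- m + c(-1L, 0L, 1L)
    } else {
      target <- resno_set[c(1, 2, 3)]
    }
    g <- cb_dir(target[2])
    offs <- rbind(c(0, 0, 0), c(0.8, 0, 0), c(-0.8, 0, 0),
                  c(0, 0.8, 0), c(0, -0.8, 0))
    prot <- as.matrix(layout$atoms[, c("x", "y", "z")])
    rn <- layout$atoms$resno
    xyz <- NULL
    for (r in seq(2, 6, by = 0.1)) {
      cand <- sweep(offs, 2, g$cb + r * g$dir, `+`)
      mind <- vapply(seq_len(nrow(prot)), function(i) {
        min(sqrt(colSums((t(cand) - prot[i, ])^2)))
      }, numeric(1))
      touched <- sort(unique(as.integer(rn[mind <= 4.5])))
      if (identical(touched, sort(as.integer(target)))) {
        xyz <- cand
        break
      }
    }
    if (is.null(xyz)) {
      abort("could not place ligand adjacent to exactly three residues")
    }
  }
  list(xyz = xyz, resno = target)
}

model_records <- function(layout, seq3, lig_xyz, jit) {
  # jit indexes the full unfiltered atom set so models stay aligned
  full <- layout$atoms
  keep <- !(full$name == "CB" &
              seq3[match(full$resno, sort(unique(full$resno)))] == "GLY")
  resno_sorted <- sort(unique(full$resno))
  lines <- character(0)
  serial <- 0L
  for (i in which(keep)) {
    serial <- serial + 1L
    rn <- full$resno[i]
    res3 <- seq3[match(rn, resno_sorted)]
    el <- substr(full$name[i], 1, 1)
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, full$name[i], res3, "A", rn,
      full$x[i] + jit[i, 1], full$y[i] + jit[i, 2], full$z[i] + jit[i, 3],
      1.0, 0.0, el))
  }
  if (!is.null(lig_xyz)) {
    lig_el <- c("P", "O", "O", "O", "O")
    lig_nm <- c("P1", "O1", "O2", "O3", "O4")
    for (k in seq_len(nrow(lig_xyz))) {
      serial <- serial + 1L
      j <- nrow(full) + k
      lines <- c(lines, sprintf(
        "HETATM%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, lig_nm[k], "LIG", "A", 900L,
        lig_xyz[k, 1] + jit[j, 1], lig_xyz[k, 2] + jit[j, 2],
        lig_xyz[k, 3] + jit[j, 3], 1.0, 0.0, lig_el[k]))
    }
  }
  lines
}

#' Generate a variant table with a planted structural signal
#'
#' Draws missense variants uniformly over the scored positions of a network
#' score table, assigns each a random alternate amino acid, and plants the
#' pathogenicity label as a logistic function of the variant's modified
#' score: `P(pathogenic) = plogis(qlogis(base_rate) + effect_slope *
#' modified)`. Labels are then flipped with probability `label_noise`.
#' EVE scores are emitted as a noisy monotone transform of the planted
#' pathogenicity probability. Labels are carried as two-star ClinVar
#' classifications so the standard labeling path applies.
#'
#' @param scores Score table from [sbna_scores()].
#' @param n_variants Number of variants to draw.
#' @param effect_slope Log-odds of pathogenicity per unit modified score
#'   (0 = no structural signal).
#' @param base_rate Baseline pathogenic fraction at modified score 0.
#' @param label_noise Probability of flipping each planted label.
#' @param seed Seed fixing all draws.
#' @param gene Gene symbol stamped on every record.
#' @return Variant tibble (`gene`, `position`, `ref_aa`, `alt_aa`,
#'   `clinvar_class`, `clinvar_stars`, `gnomad_alt_count`, `eve`,
#'   `functional_score`) plus the hidden truth columns `planted_prob` and
#'   `planted_label`. Positions equal residue numbers (offset 0 mapping).
#' @export
generate_variants <- function(scores, n_variants = 1000L, effect_slope = 1,
                              base_rate = 0.5, label_noise = 0, seed = 1L,
                              gene = "SYNTH1") {
  stopifnot(nrow(scores) > 0L, base_rate > 0, base_rate < 1,
            label_noise >= 0, label_noise <= 1)
  restore <- withr_seed(seed)
  on.exit(restore(), add = TRUE)
  idx <- sample.int(nrow(scores), n_variants, replace = TRUE)
  ref <- unname(aa3_to_1[scores$resid[idx]])
  alt <- vapply(ref, function(r) sample(setdiff(aa1, r), 1L), character(1))
  net <- scores$network_score[idx]
  modified <- modified_score(net, ref, alt)
  p <- plogis(qlogis(base_rate) + effect_slope * modified)
  lab <- rbinom(n_variants, 1L, p)
  if (label_noise > 0) {
    flip <- runif(n_variants) < label_noise
    lab[flip] <- 1L - lab[flip]
  }
  p_clamped <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  eve <- plogis(qlogis(p_clamped) + rnorm(n_variants, sd = 0.75))
  tibble(
    gene = gene,
    position = scores$resno[idx],
    ref_aa = ref,
    alt_aa = unname(alt),
    clinvar_class = ifelse(lab == 1L, "Pathogenic", "Benign"),
    clinvar_stars = 2L,
    gnomad_alt_count = NA_integer_,
    eve = eve,
    functional_score = NA_real_,
    planted_prob = p,
    planted_label = lab
  )
}

#' Generate synthetic deep-mutagenesis functional scores
#'
#' Emits a per-position functional (mutational-tolerance) score as a
#' negative linear transform of the network score plus seeded Gaussian
#' noise, emulating the inverse relationship between tolerance to mutation
#' and topological constraint.
#'
#' @param scores Score table from [sbna_scores()].
#' @param slope Linear coefficient on the network score (negative by
#'   default: constrained residues tolerate mutation poorly).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed.
#' @return Tibble `position`, `functional_score`.
#' @export
generate_functional_scores <- function(scores, slope = -1, noise_sd = 0.3,
                                       seed = 1L) {
  restore <- withr_seed(seed)
  on.exit(restore(), add = TRUE)
  tibble(position = scores$resno,
         functional_score = slope * scores$network_score +
           rnorm(nrow(scores), sd = noise_sd))
}

#' Generate a synthetic logistic-regression benchmark set
#'
#' Standard-normal predictors with a zero-intercept logistic response at
#' the planted coefficients, for evaluating the regression protocol
#' (coefficient-sign recovery, null behaviour under label shuffling).
#'
#' @param n Number of observations.
#' @param beta Planted coefficient vector (its length sets the number of
#'   predictors).
#' @param seed Seed.
#' @return List with `x` (matrix) and `y` (0/1 vector).
#' @export
generate_regression_data <- function(n = 300L, beta = c(2, -1), seed = 1L) {
  restore <- withr_seed(seed)
  on.exit(restore(), add = TRUE)
  x <- matrix(rnorm(n * length(beta)), nrow = n)
  colnames(x) <- paste0("x", seq_along(beta))
  y <- rbinom(n, 1L, plogis(drop(x %*% beta)))
  list(x = x, y = y)
}
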