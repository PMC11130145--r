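# Independent oracles and small fixture builders used across the suite.

# Betweenness centrality by Floyd-Warshall distances plus shortest-path
# counting - a different algorithm family from the Brandes-style routine
# used in the package, so it serves as an independent cross-check.
# edges: data frame with columns a, b, weight (edge length = 1/weight);
# n: number of nodes. Returns the normalized betweenness vector.
oracle_betweenness <- function(edges, n, tol = 1e-9) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  len <- 1 / edges$weight
  for (k in seq_len(nrow(edges))) {
    d[edges$a[k], edges$b[k]] <- min(d[edges$a[k], edges$b[k]], len[k])
    d[edges$b[k], edges$a[k]] <- d[edges$a[k], edges$b[k]]
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  # sigma[s, t]: number of shortest s-t paths, by dynamic programming over
  # nodes in order of distance from s
  adj <- matrix(Inf, n, n)
  for (k in seq_len(nrow(edges))) {
    adj[edges$a[k], edges$b[k]] <- min(adj[edges$a[k], edges$b[k]], len[k])
    adj[edges$b[k], edges$a[k]] <- adj[edges$a[k], edges$b[k]]
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(is.finite(adj[, v]) &
                      abs(d[s, ] + adj[, v] - d[s, v]) < tol)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
        if (abs(d[s, v] + d[v, t] - d[s, t]) < tol) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# AUC by exhaustive concordant-pair counting (+1/2 per tie)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Mann-Whitney U by exhaustive pair comparison
oracle_u <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot
}

# Monte-Carlo solvent-accessible surface area (random sphere points), an
# independent check on the deterministic quadrature in the package
oracle_sasa <- function(xyz, radii, probe = 1.4, n_points = 4000L,
                        seed = 99L) {
  set.seed(seed)
  rr <- radii + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(rnorm(3 * n_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    surf <- sweep(u * rr[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      free <- free & d2 > rr[j]^2
    }
    out[i] <- 4 * pi * rr[i]^2 * mean(free)
  }
  out
}

# build an sbna_graph directly from an edge list (unit ligand contacts 0)
make_graph_fixture <- function(n, edges, ligand_contacts = integer(n)) {
  structure(list(
    nodes = tibble::tibble(chain = "A", resno = seq_len(n), insert = "",
                           resid = rep("ALA", n)),
    edges = tibble::as_tibble(edges),
    ligand_contacts = ligand_contacts
  ), class = "sbna_graph")
}

# hand-rolled atom tibble for contact-geometry fixtures;
# pos: data frame with resno, elety, x, y, z (chain A, ALA, scored)
make_atoms <- function(pos, role = "scored", resid = "ALA", chain = "A",
                       model = 1L) {
  tibble::tibble(
    model = model, record = ifelse(role == "ligand", "HETATM", "ATOM"),
    chain = chain, resno = pos$resno, insert = "",
    resid = resid, elety = pos$elety,
    element = substr(pos$elety, 1, 1),
    x = pos$x, y = pos$y, z = pos$z, occupancy = 1, b = 0, role = role
  )
}

# random rigid-body transform applied to the coordinate columns
apply_rigid <- function(atoms, seed = 1L) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  rot <- rx %*% ry %*% rz
  shift <- runif(3, -20, 20)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# write text to a session temp file and return its path
withr_tempfile <- function(text, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}

# minimal hand-written PDB text fixtures
pdb_three_residues <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.804   6.900  -5.480  1.00 10.00           C",
    "ATOM      3  N   GLY A   2      11.804   8.340  -5.800  1.00 11.00           N",
    "ATOM      4  CA  GLY A   2      12.400   9.200  -4.900  1.00 11.00           C",
    "ATOM      5  N   SER A   3      13.000  10.600  -5.100  1.00 12.00           N",
    "ATOM      6  CA  SER A   3      13.600  11.500  -4.200  1.00 12.00           C",
    "END"), collapse = "\n")
}

pdb_altloc <- function(occ_a = 0.6, occ_b = 0.4) {
  paste(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    sprintf("ATOM      2  CA AALA A   1      11.804   6.900  -5.480%6.2f 10.00           C", occ_a),
    sprintf("ATOM      3  CA BALA A   1      11.904   6.800  -5.580%6.2f 10.00           C", occ_b),
    "END"), collapse = "\n")
}
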