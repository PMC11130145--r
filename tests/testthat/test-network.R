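one_atom_residues <- function(coords, resno = seq_len(nrow(coords))) {
  make_atoms(data.frame(resno = resno, elety = "CB",
                        x = coords[, 1], y = coords[, 2], z = coords[, 3]))
}

test_that("contacts obey the distance cutoff and adjacency exclusion", {
  at <- one_atom_residues(rbind(c(0, 0, 0), c(4.4, 0, 0)), resno = c(1L, 5L))
  g <- build_contact_graph(at, contact_cutoff = 4.5)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 1L)

  at2 <- one_atom_residues(rbind(c(0, 0, 0), c(4.6, 0, 0)), resno = c(1L, 5L))
  expect_equal(nrow(build_contact_graph(at2, contact_cutoff = 4.5)$edges), 0L)

  # peptide neighbours (|delta resno| <= 1) are never connected by default
  adj <- one_atom_residues(rbind(c(0, 0, 0), c(3.8, 0, 0)), resno = c(1L, 2L))
  expect_equal(nrow(build_contact_graph(adj)$edges), 0L)
  expect_equal(nrow(build_contact_graph(adj, exclude_adjacent = 0)$edges), 1L)
})

test_that("edge weight counts qualifying heavy-atom pairs", {
  at <- make_atoms(data.frame(
    resno = c(1L, 1L, 3L, 3L),
    elety = c("CA", "CB", "CA", "CB"),
    x = c(0, 0, 4, 4), y = c(0, 0, 0, 0), z = c(0, 1.5, 0, 3.0)))
  g <- build_contact_graph(at, contact_cutoff = 4.5)
  # pairs within 4.5 A: (0,0,0)-(4,0,0), (0,0,1.5)-(4,0,0), (0,0,1.5)-(4,0,3)
  expect_equal(g$edges$weight, 3L)
})

test_that("ligand proximity counts residue atoms near the ligand", {
  prot <- one_atom_residues(rbind(c(0, 0, 0), c(10, 0, 0)), resno = c(1L, 4L))
  lig <- make_atoms(data.frame(resno = 900L, elety = "P1",
                               x = 3, y = 0, z = 0),
                    role = "ligand", resid = "LIG")
  g <- build_contact_graph(dplyr::bind_rows(prot, lig))
  expect_equal(g$ligand_contacts, c(1L, 0L))
})

test_that("degree and second-order sums match hand computation", {
  # star: centre 1 connected to 2,3,4 with weights 2,3,5
  g <- make_graph_fixture(4, data.frame(a = 1L, b = 2:4, weight = c(2, 3, 5)))
  s <- compute_subscores(g)
  expect_equal(s$local_connectivity, c(10, 2, 3, 5))
  expect_equal(s$second_order, c(2 + 3 + 5, 10, 10, 10))
})

test_that("bridging is betweenness with 1/weight edge lengths", {
  # path 1-2-3: middle node carries the only 1-3 shortest path
  p3 <- make_graph_fixture(3, data.frame(a = c(1L, 2L), b = c(2L, 3L),
                                         weight = c(1, 1)))
  expect_equal(compute_subscores(p3)$bridging, c(0, 1, 0))

  # triangle: a strong (short) direct 1-3 edge removes node 2's bridging,
  # a weak (long) one restores it
  tri_weak <- make_graph_fixture(3, data.frame(
    a = c(1L, 2L, 1L), b = c(2L, 3L, 3L), weight = c(1, 1, 0.4)))
  expect_equal(compute_subscores(tri_weak)$bridging, c(0, 1, 0))
  tri_strong <- make_graph_fixture(3, data.frame(
    a = c(1L, 2L, 1L), b = c(2L, 3L, 3L), weight = c(1, 1, 1)))
  expect_equal(compute_subscores(tri_strong)$bridging, c(0, 0, 0))
})

test_that("bridging agrees with an independent all-pairs oracle", {
  set.seed(11)
  for (trial in 1:12) {
    n <- sample(5:8, 1)
    pairs <- t(combn(n, 2))
    pick <- runif(nrow(pairs)) < 0.5
    if (!any(pick)) pick[1] <- TRUE
    edges <- data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
                        weight = sample(c(1, 2, 4), sum(pick), replace = TRUE))
    got <- compute_subscores(make_graph_fixture(n, edges))$bridging
    want <- oracle_betweenness(edges, n)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("isolated residues receive zero sub-scores", {
  g <- make_graph_fixture(4, data.frame(a = 1L, b = 2L, weight = 1))
  s <- compute_subscores(g)
  expect_equal(s$local_connectivity[3:4], c(0, 0))
  expect_equal(s$bridging[3:4], c(0, 0))
})

test_that("normalization yields mean 0 and sd 1 per protein", {
  g <- make_graph_fixture(6, data.frame(
    a = c(1L, 2L, 3L, 4L, 1L), b = c(2L, 3L, 4L, 5L, 6L),
    weight = c(1, 2, 1, 3, 1)))
  norm <- normalize_scores(compute_subscores(g))
  expect_equal(mean(norm$network_score), 0, tolerance = 1e-9)
  expect_equal(sd(norm$network_score), 1, tolerance = 1e-9)
  for (col in c("z_local_connectivity", "z_second_order", "z_bridging")) {
    expect_equal(mean(norm[[col]]), 0, tolerance = 1e-9)
    expect_equal(sd(norm[[col]]), 1, tolerance = 1e-9)
  }
  # ligand_proximity is constant (0) here: zeroed, not dropped
  expect_equal(norm$z_ligand_proximity, rep(0, 6))
})

test_that("normalization rejects degenerate inputs", {
  g <- make_graph_fixture(1, data.frame(a = integer(0), b = integer(0),
                                        weight = numeric(0)))
  expect_error(normalize_scores(compute_subscores(g)), "at least 2")
})

test_that("sub-score weights steer the combination", {
  g <- make_graph_fixture(5, data.frame(
    a = c(1L, 2L, 3L, 1L), b = c(2L, 3L, 4L, 5L), weight = c(1, 1, 1, 2)))
  s <- compute_subscores(g)
  only_deg <- normalize_scores(s, weights = c(1, 0, 0, 0))
  expect_equal(only_deg$network_score,
               (only_deg$z_local_connectivity -
                  mean(only_deg$z_local_connectivity)) /
                 sd(only_deg$z_local_connectivity))
})

test_that("conformer averaging is idempotent and tracks coverage", {
  g <- make_graph_fixture(4, data.frame(a = c(1L, 2L), b = c(3L, 4L),
                                        weight = c(1, 2)))
  tab <- normalize_scores(compute_subscores(g))
  one <- average_conformers(list(tab))
  expect_equal(one$network_score, tab$network_score)
  expect_equal(one$n_models, rep(1L, 4))
  two <- average_conformers(list(tab, tab))
  expect_equal(two$network_score, tab$network_score)
  expect_equal(two$n_models, rep(2L, 4))
  # partial coverage: positions missing from one conformer average over fewer
  part <- average_conformers(list(tab, tab[1:2, ]))
  expect_equal(part$n_models, c(2L, 2L, 1L, 1L))
})

test_that("scores are invariant to rigid motion and atom order", {
  atoms <- generate_structure(15, geometry = "ideal_helix", seed = 3) |>
    read_pdb_structure() |>
    prepare_structure(target_chain = "A")
  base <- sbna_scores(atoms)
  moved <- sbna_scores(apply_rigid(atoms, seed = 8))
  expect_equal(moved$network_score, base$network_score, tolerance = 1e-9)
  shuffled <- sbna_scores(atoms[sample.int(nrow(atoms)), ])
  expect_equal(shuffled$network_score, base$network_score, tolerance = 1e-9)
})

test_that("adding a contact raises local connectivity at both ends", {
  coords <- rbind(c(0, 0, 0), c(4.0, 0, 0), c(20, 0, 0))
  at <- one_atom_residues(coords, resno = c(1L, 4L, 8L))
  s1 <- compute_subscores(build_contact_graph(at))
  coords2 <- rbind(coords, c(4.0, 4.0, 0))
  at2 <- one_atom_residues(coords2, resno = c(1L, 4L, 8L, 12L))
  s2 <- compute_subscores(build_contact_graph(at2))
  expect_gt(s2$local_connectivity[s2$resno == 4],
            s1$local_connectivity[s1$resno == 4])
})
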