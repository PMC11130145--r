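#' Build the weighted residue-interaction graph for one conformer
#'
#' Two scored residues are connected when any pair of their heavy atoms lies
#' within `contact_cutoff` and their sequence separation exceeds
#' `exclude_adjacent`; the edge weight is the number of qualifying atom
#' pairs, so tightly packed interfaces weigh more than grazing ones.
#' Ligand proximity is recorded per residue as the number of its heavy atoms
#' with at least one ligand or binding-partner atom within the same cutoff.
#'
#' @param atoms Prepared atom tibble ([prepare_structure()]).
#' @param model Which conformer to use (default: first).
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom.
#' @param exclude_adjacent Residue pairs with sequence separation less than
#'   or equal to this value are never connected (1 removes peptide-bonded
#'   neighbours, whose contact is obligatory and uninformative).
#'
#' @return A list of class `sbna_graph`: `nodes` (tibble of scored residues:
#'   `chain`, `resno`, `insert`, `resid`), `edges` (tibble `a`, `b`,
#'   `weight` with `a`/`b` indices into `nodes`), and `ligand_contacts`
#'   (integer vector, one per node).
#' @export
build_contact_graph <- function(atoms, model = NULL,
                                contact_cutoff = 4.5, exclude_adjacent = 1) {
  stopifnot(contact_cutoff > 0)
  if (!"role" %in% names(atoms)) {
    abort("atoms must be prepared with prepare_structure() first")
  }
  m <- if (is.null(model)) min(atoms$model) else model
  at <- filter(atoms, .data$model == m)
  sc <- filter(at, .data$role == "scored")
  if (nrow(sc) == 0L) abort("no scored residues in this model")

  nodes <- sc %>%
    distinct(.data$chain, .data$resno, .data$insert, .data$resid) %>%
    arrange(.data$resno, .data$insert)
  node_key <- paste(nodes$chain, nodes$resno, nodes$insert)
  ridx <- match(paste(sc$chain, sc$resno, sc$insert), node_key)

  xyz <- as.matrix(sc[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  within <- d <= contact_cutoff
  diag(within) <- FALSE
  ij <- which(within, arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  edges <- tibble(a = integer(0), b = integer(0), weight = integer(0))
  if (nrow(ij) > 0L) {
    ra <- ridx[ij[, 1]]
    rb <- ridx[ij[, 2]]
    keep <- ra != rb &
      abs(nodes$resno[ra] - nodes$resno[rb]) > exclude_adjacent
    if (any(keep)) {
      pa <- pmin(ra[keep], rb[keep])
      pb <- pmax(ra[keep], rb[keep])
      edges <- tibble(a = pa, b = pb) %>%
        group_by(.data$a, .data$b) %>%
        summarise(weight = n(), .groups = "drop")
    }
  }

  lig <- filter(at, .data$role %in% c("ligand", "partner"))
  ligand_contacts <- integer(nrow(nodes))
  if (nrow(lig) > 0L) {
    lxyz <- as.matrix(lig[, c("x", "y", "z")])
    # per scored atom: does any ligand atom sit within the cutoff?
    near <- vapply(seq_len(nrow(sc)), function(i) {
      dx <- lxyz[, 1] - xyz[i, 1]
      dy <- lxyz[, 2] - xyz[i, 2]
      dz <- lxyz[, 3] - xyz[i, 3]
      any(dx * dx + dy * dy + dz * dz <= contact_cutoff^2)
    }, logical(1))
    cnt <- tapply(near, ridx, sum)
    ligand_contacts[as.integer(names(cnt))] <- as.integer(cnt)
  }

  structure(list(nodes = nodes, edges = edges,
                 ligand_contacts = ligand_contacts),
            class = "sbna_graph")
}

#' Raw topology sub-scores per residue
#'
#' From the weighted contact graph computes, for every scored residue:
#' \describe{
#'   \item{local_connectivity}{sum of incident edge weights (weighted degree).}
#'   \item{second_order}{sum of the neighbours' weighted degrees, a
#'     second-shell extension of local connectivity.}
#'   \item{bridging}{betweenness centrality with edge length `1/weight`
#'     (stronger contacts are shorter), normalized by `(n-1)(n-2)/2`.}
#'   \item{ligand_proximity}{number of the residue's heavy atoms contacting
#'     a ligand or binding-partner atom.}
#' }
#' Isolated residues receive zeros throughout.
#'
#' @param graph An `sbna_graph` from [build_contact_graph()].
#' @return Tibble: node identity columns plus the four raw sub-scores.
#' @export
compute_subscores <- function(graph) {
  stopifnot(inherits(graph, "sbna_graph"))
  n <- nrow(graph$nodes)
  if (n == 0L) abort("empty graph")
  deg <- numeric(n)
  second <- numeric(n)
  btw <- numeric(n)
  if (nrow(graph$edges) > 0L) {
    e <- graph$edges
    for (k in seq_len(nrow(e))) {
      deg[e$a[k]] <- deg[e$a[k]] + e$weight[k]
      deg[e$b[k]] <- deg[e$b[k]] + e$weight[k]
    }
    for (k in seq_len(nrow(e))) {
      second[e$a[k]] <- second[e$a[k]] + deg[e$b[k]]
      second[e$b[k]] <- second[e$b[k]] + deg[e$a[k]]
    }
    g <- igraph::graph_from_edgelist(cbind(e$a, e$b), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    btw <- igraph::betweenness(g, weights = 1 / e$weight,
                               normalized = TRUE)
  }
  graph$nodes %>%
    mutate(local_connectivity = deg,
           second_order = second,
           bridging = btw,
           ligand_proximity = as.numeric(graph$ligand_contacts))
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

subscore_cols <- c("local_connectivity", "second_order",
                   "bridging", "ligand_proximity")

#' Standardize sub-scores into a per-protein network score
#'
#' Each sub-score is z-scored across the protein's scored residues (a
#' zero-variance component is zeroed, not dropped, so the combination keeps
#' a fixed length); the weighted sum of the standardized components is then
#' z-scored again, giving a single-conformer network score with mean 0 and
#' standard deviation 1 over the protein.
#'
#' @param subscores Tibble from [compute_subscores()].
#' @param weights Numeric length-4 weights for `local_connectivity`,
#'   `second_order`, `bridging`, `ligand_proximity` (default all 1).
#' @return The input tibble with added `z_*` columns and `network_score`.
#' @export
normalize_scores <- function(subscores, weights = c(1, 1, 1, 1)) {
  stopifnot(length(weights) == 4L, is.numeric(weights))
  if (nrow(subscores) < 2L) {
    abort("need at least 2 scored residues to standardize")
  }
  z <- purrr::map(subscore_cols, ~ zscore(subscores[[.x]]))
  names(z) <- paste0("z_", subscore_cols)
  combo <- Reduce(`+`, purrr::map2(z, weights, ~ .x * .y))
  out <- subscores
  for (nm in names(z)) out[[nm]] <- z[[nm]]
  out$network_score <- zscore(combo)
  out
}

#' Average network scores over conformers
#'
#' Per residue position, takes the arithmetic mean of the network score (and
#' of the raw sub-scores) over the conformer tables in which that position
#' appears.
#'
#' @param tables List of single-conformer score tables
#'   ([normalize_scores()]).
#' @return Tibble with per-position mean raw sub-scores, mean
#'   `network_score`, and `n_models` (conformers contributing).
#' @export
average_conformers <- function(tables) {
  if (length(tables) == 0L) abort("no conformer tables supplied")
  bind_rows(tables) %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$resid) %>%
    summarise(across(all_of(c(subscore_cols, "network_score")), mean),
              n_models = n(), .groups = "drop") %>%
    arrange(.data$resno, .data$insert)
}

#' Per-residue network scores for a prepared structure
#'
#' The full scoring pipeline for one structure: build the residue contact
#' graph of every conformer, compute and standardize the topology
#' sub-scores per conformer, and average over conformers. Higher scores
#' mark residues that are more topologically constrained (densely packed,
#' bridging between regions, or at ligand interfaces) and therefore more
#' likely to be intolerant to substitution.
#'
#' @inheritParams build_contact_graph
#' @inheritParams normalize_scores
#' @return Tibble with one row per scored residue position: identity
#'   columns, conformer-averaged raw sub-scores, `network_score`, and
#'   `n_models`.
#'
#' @examples
#' atoms <- generate_structure(20, geometry = "two_domain") |>
#'   read_pdb_structure() |>
#'   prepare_structure(target_chain = "A")
#' sbna_scores(atoms)
#' @export
sbna_scores <- function(atoms, contact_cutoff = 4.5, exclude_adjacent = 1,
                        weights = c(1, 1, 1, 1)) {
  models <- sort(unique(atoms$model))
  tabs <- purrr::map(models, function(m) {
    build_contact_graph(atoms, model = m, contact_cutoff = contact_cutoff,
                        exclude_adjacent = exclude_adjacent) %>%
      compute_subscores() %>%
      normalize_scores(weights = weights)
  })
  average_conformers(tabs)
}

#' Write a per-residue score table as TSV
#'
#' @param scores Tibble from [sbna_scores()].
#' @param file Output path.
#' @return The input, invisibly.
#' @export
write_score_tsv <- function(scores, file) {
  readr::write_tsv(scores, file)
  invisible(scores)
}
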