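#' Solvent and crystallization-additive residue codes
#'
#' The default exclusion list applied by [prepare_structure()]: water and
#' common crystallization additives that carry no biological signal for
#' residue-network analysis. Override via the `solvent_list` argument.
#'
#' @return Character vector of 3-letter HET codes.
#' @export
default_solvent_list <- function() {
  c("HOH", "DOD", "SO4", "PO4", "GOL", "EDO", "PEG", "ACT", "DMS", "NAG")
}

# canonical 20 plus common modified residues mapped to their parent
canonical_aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

noncanonical_parent <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                         CSO = "CYS", HYP = "PRO", MLY = "LYS", M3L = "LYS",
                         KCX = "LYS", PCA = "GLU")

aa3_to_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
aa1_to_3 <- setNames(names(aa3_to_1), unname(aa3_to_1))

#' Prepare a parsed structure for network scoring
#'
#' Applies the preprocessing used before residue-network analysis: waters
#' and solvent/crystallization additives are removed; standard amino acids
#' of the target chain become the scored residues; standard amino acids of
#' every other retained chain are kept as binding-partner groups; remaining
#' HET groups (cofactors, substrates, metals) are kept as ligands. Chains
#' present only through crystal packing can be dropped explicitly so one
#' copy of the molecule is scored. Modified residues with a known parent
#' (e.g. selenomethionine) are renamed to the parent and scored.
#'
#' @param atoms Atom tibble from [read_pdb_structure()].
#' @param target_chain Chain identifier of the protein whose residues get
#'   network scores.
#' @param drop_chains Character vector of chain ids to remove entirely
#'   (user-declared crystal-packing duplicates).
#' @param solvent_list 3-letter codes removed as solvent; see
#'   [default_solvent_list()].
#'
#' @return The atom tibble restricted to retained atoms, with an added
#'   `role` column: `"scored"`, `"partner"` or `"ligand"`.
#'
#' @examples
#' atoms <- read_pdb_structure(generate_structure(10, ligand = TRUE))
#' prep <- prepare_structure(atoms, target_chain = "A")
#' dplyr::count(prep, role)
#' @export
prepare_structure <- function(atoms, target_chain = "A", drop_chains = NULL,
                              solvent_list = default_solvent_list()) {
  stopifnot(is.data.frame(atoms))
  if (!target_chain %in% atoms$chain) {
    abort(paste0("target chain '", target_chain, "' not present in structure"),
          class = "sbnar_config_error")
  }
  out <- atoms %>%
    filter(!.data$resid %in% solvent_list,
           !.data$chain %in% drop_chains) %>%
    mutate(resid = ifelse(.data$resid %in% names(noncanonical_parent),
                          noncanonical_parent[.data$resid], .data$resid),
           role = case_when(
             .data$resid %in% canonical_aa3 & .data$chain == target_chain ~ "scored",
             .data$resid %in% canonical_aa3 ~ "partner",
             TRUE ~ "ligand"
           ))
  if (!any(out$role == "scored")) {
    abort(paste0("target chain '", target_chain,
                 "' has no standard amino-acid residues"),
          class = "sbnar_config_error")
  }
  keys_by_model <- out %>%
    filter(.data$role == "scored") %>%
    distinct(.data$model, .data$chain, .data$resno, .data$insert) %>%
    group_by(.data$model) %>%
    summarise(keys = list(paste(.data$chain, .data$resno, .data$insert)),
              .groups = "drop")
  if (nrow(keys_by_model) > 1L) {
    ref <- keys_by_model$keys[[1]]
    same <- vapply(keys_by_model$keys, identical, logical(1), y = ref)
    if (!all(same)) {
      warn("conformers do not share identical scored-residue keys; scores are averaged over the models covering each position")
    }
  }
  out
}

#' Residue-level view of a prepared structure
#'
#' Collapses a prepared atom tibble to one row per residue/model with the
#' residue role and atom count, handy for inspection and joins.
#'
#' @param atoms Prepared atom tibble.
#' @return Tibble with `model`, `chain`, `resno`, `insert`, `resid`, `role`,
#'   `n_atoms`.
#' @export
structure_residues <- function(atoms) {
  atoms %>%
    group_by(.data$model, .data$chain, .data$resno, .data$insert,
             .data$resid, .data$role) %>%
    summarise(n_atoms = n(), .groups = "drop")
}
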