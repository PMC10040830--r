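# Shared fixtures, built once per test run. The reference database is the
# deterministic synthetic stand-in shipped with the package.
REFDB <- synthetic_reference_db()
NET <- build_default_network()

# a small annotated strain: a 60%-identity ArAT + LDH homolog pair among
# a few decoys, reused by homology and pipeline tests
make_small_proteome <- function(enzymes = c("ArAT", "LDH"), identity = 60,
                                decoys = 3, seed = 101) {
  prot <- character(0)
  for (k in seq_along(enzymes)) {
    rid <- REFDB$index[[enzymes[k]]][1]
    ref <- REFDB$records$sequence[REFDB$records$seq_id == rid]
    prot[sprintf("plant_%s_%d", enzymes[k], k)] <-
      mutate_to_identity(ref, identity, seed = child_seed_t(seed, k))$sequence
  }
  for (d in seq_len(decoys))
    prot[paste0("decoy_", d)] <- random_protein(300, seed = child_seed_t(seed, 100 + d))
  prot
}

# deterministic child seed for fixtures (mirrors nothing in the package)
child_seed_t <- function(seed, k) (seed * 1009 + k * 31) %% 2000000011

# Emulation of the divergent within-species homolog clusters: three
# clusters for one species, each anchored near a different other-species
# background homolog so clusters stay separated in the tree. Members sit
# at ~80% identity to their cluster center, centers at ~55% to their
# anchor, background homologs at ~75% to the anchor.
make_fldh_fixture <- function() {
  seqs <- character(0)
  species <- character(0)
  for (cl in 1:3) {
    anchor <- random_protein(120, seed = 600 + cl)
    center <- mutate_to_identity(anchor, 55, seed = 650 + cl)$sequence
    seqs[sprintf("bg_%d", cl)] <-
      mutate_to_identity(anchor, 75, seed = 680 + cl)$sequence
    species[sprintf("bg_%d", cl)] <- sprintf("Other_%d", cl)
    for (m in 1:3) {
      id <- sprintf("sal_t%d_%d", cl, m)
      seqs[id] <- mutate_to_identity(center, 80,
                                     seed = 700 + 10 * cl + m)$sequence
      species[id] <- "L. salivarius"
    }
  }
  list(seqs = seqs, species = species)
}
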