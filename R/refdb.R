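#' Load a reference enzyme database
#'
#' A reference database is a protein FASTA plus a two-column tab-separated
#' mapping table \code{seq_id<TAB>enzyme_abbrev} assigning each reference
#' sequence to an enzyme family of the registry. FASTA records without a
#' mapping are skipped with a warning; mappings that point at ids absent
#' from the FASTA are an error.
#'
#' @param fasta_path Multi-FASTA of reference proteins.
#' @param mapping_path Tab-separated mapping table (no header required;
#'   a \code{seq_id} / \code{enzyme} header line is tolerated).
#' @param registry Enzyme registry data.frame (default
#'   \code{\link{enzyme_registry}()}).
#' @return An object of class \code{trp_refdb}: list with \code{records}
#'   (data.frame \code{seq_id}, \code{enzyme}, \code{sequence}) and
#'   \code{index} (enzyme abbrev -> character vector of seq ids).
#' @export
load_reference_db <- function(fasta_path, mapping_path,
                              registry = enzyme_registry()) {
  seqs <- read_fasta(fasta_path)
  map <- read.delim(mapping_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(map) < 2) stop("mapping table must have two columns")
  map <- map[, 1:2]
  names(map) <- c("seq_id", "enzyme")
  if (identical(tolower(map$seq_id[1]), "seq_id")) map <- map[-1, ]
  missing_ids <- setdiff(map$seq_id, names(seqs))
  if (length(missing_ids))
    stop("mapping references ids absent from FASTA: ",
         paste(missing_ids, collapse = ", "))
  unmapped <- setdiff(names(seqs), map$seq_id)
  if (length(unmapped))
    warning(length(unmapped), " unmapped FASTA record(s) skipped: ",
            paste(head(unmapped, 5), collapse = ", "))
  build_refdb(setNames(map$enzyme, map$seq_id), seqs[map$seq_id], registry)
}

build_refdb <- function(enzyme_of, seqs, registry = enzyme_registry()) {
  unknown <- setdiff(unique(enzyme_of), registry$abbrev)
  if (length(unknown))
    stop("mapping references enzyme absent from registry: ",
         paste(unknown, collapse = ", "))
  records <- data.frame(seq_id = names(enzyme_of),
                        enzyme = unname(enzyme_of),
                        sequence = unname(seqs[names(enzyme_of)]),
                        stringsAsFactors = FALSE)
  # registry order, independent of locale collation
  index <- split(records$seq_id,
                 factor(records$enzyme, levels = registry$abbrev))
  index <- index[vapply(index, length, 0L) > 0]
  structure(list(records = records, index = index, registry = registry),
            class = "trp_refdb")
}

#' @export
print.trp_refdb <- function(x, ...) {
  cat("Reference enzyme database:", nrow(x$records), "sequences,",
      length(x$index), "enzyme families\n")
  invisible(x)
}

#' Synthetic reference enzyme database
#'
#' No curated reference set ships with the package; this generator builds a
#' deterministic synthetic stand-in: one random full-length protein per
#' enzyme family (two for families given in \code{duplicated_families}),
#' drawn from the background amino-acid frequencies of
#' \code{\link{random_protein}}. Sequences are random, so they carry no
#' biochemical information; they serve as anchors that planted homologs are
#' mutated from and searched against.
#'
#' @param seed Integer seed; the default gives the database used throughout
#'   the package's examples and tests.
#' @param length_range Length range (uniform) of the reference proteins.
#' @param duplicated_families Families that get a second, independent
#'   reference sequence (mimicking multiple database entries per enzyme).
#' @param registry Enzyme registry.
#' @return A \code{trp_refdb}.
#' @export
synthetic_reference_db <- function(seed = 20260101L,
                                   length_range = c(300L, 420L),
                                   duplicated_families = c("ArAT", "LDH"),
                                   registry = enzyme_registry()) {
  fams <- registry$abbrev
  enzyme_of <- character(0)
  seqs <- character(0)
  for (k in seq_along(fams)) {
    n_copies <- if (fams[k] %in% duplicated_families) 2L else 1L
    for (cp in seq_len(n_copies)) {
      s <- child_seed(seed, k * 10L + cp)
      len <- with_seed(s, sample(length_range[1]:length_range[2], 1))
      id <- sprintf("REF_%s_%d", fams[k], cp)
      seqs[id] <- random_protein(len, seed = child_seed(s, 1L))
      enzyme_of[id] <- fams[k]
    }
  }
  build_refdb(enzyme_of, seqs, registry)
}

#' Write a reference database to FASTA + mapping table
#' @param refdb A \code{trp_refdb}.
#' @param fasta_path,mapping_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_reference_db <- function(refdb, fasta_path, mapping_path) {
  stopifnot(inherits(refdb, "trp_refdb"))
  write_fasta(setNames(refdb$records$sequence, refdb$records$seq_id),
              fasta_path)
  write_tsv(refdb$records[, c("seq_id", "enzyme")], mapping_path)
  invisible(list(fasta = fasta_path, mapping = mapping_path))
}
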