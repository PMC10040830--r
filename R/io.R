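AA_ALPHABET20X <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                    "F","P","S","T","W","Y","V","X")

#' Read a protein FASTA file
#'
#' Wraps \code{Biostrings::readAAStringSet} with the validation the pipeline
#' relies on: ids are the header token before the first whitespace, sequences
#' are uppercased, and empty files, empty records, duplicate ids or residues
#' outside the 20-letter amino-acid alphabet (X tolerated) are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0))
    stop("empty sequence for record '", ids[nchar(seqs) == 0][1], "' in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "' in ", path)
  validate_protein(seqs)
  seqs
}

validate_protein <- function(seqs) {
  ok <- paste(AA_ALPHABET20X, collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), seqs)
  if (any(bad)) {
    res <- regmatches(seqs[bad][1],
                      regexpr(sprintf("[^%s]", ok), seqs[bad][1]))
    stop("illegal residue '", res, "' in sequence '",
         names(seqs[bad])[1], "'")
  }
  invisible(seqs)
}

#' Write named protein sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format percentages in species-summary style
#'
#' Rounds half away from zero to one decimal and drops a trailing ".0", so
#' 8/9 of 100 prints as \code{"88.9"} and 1 as \code{"100"}.
#'
#' @param x Numeric vector of percentages.
#' @return Character vector.
#' @export
format_percent <- function(x) {
  r <- round_half_up(x, 1)
  out <- sprintf("%.1f", r)
  sub("\\.0$", "", out)
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
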