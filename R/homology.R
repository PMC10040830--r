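#' Homology-search thresholds
#'
#' The four filters a hit must pass to count as a pathway-enzyme homolog:
#' identity >= 30 percent, E-value <= 1e-3, query cover >= 70 percent and
#' subject cover >= 70 percent. All comparisons are inclusive.
#'
#' @param min_identity Minimum percent identity.
#' @param max_evalue Maximum E-value.
#' @param min_query_cover,min_subject_cover Minimum percent coverage of the
#'   query (strain protein) and subject (reference) by the aligned span.
#' @return An object of class \code{trp_thresholds}.
#' @export
thresholds <- function(min_identity = 30, max_evalue = 1e-3,
                       min_query_cover = 70, min_subject_cover = 70) {
  stopifnot(min_identity >= 0, min_identity <= 100, max_evalue > 0,
            min_query_cover >= 0, min_query_cover <= 100,
            min_subject_cover >= 0, min_subject_cover <= 100)
  structure(list(min_identity = min_identity, max_evalue = max_evalue,
                 min_query_cover = min_query_cover,
                 min_subject_cover = min_subject_cover),
            class = "trp_thresholds")
}

passes <- function(identity, evalue, qcov, scov, th) {
  identity >= th$min_identity & evalue <= th$max_evalue &
    qcov >= th$min_query_cover & scov >= th$min_subject_cover
}

empty_hits <- function() {
  data.frame(strain_id = character(0), enzyme = character(0),
             query_id = character(0), subject_id = character(0),
             raw_score = numeric(0), bitscore = numeric(0),
             identity_pct = numeric(0), query_cover_pct = numeric(0),
             subject_cover_pct = numeric(0), evalue = numeric(0),
             qstart = numeric(0), qend = numeric(0), sstart = numeric(0),
             send = numeric(0), aligned_cols = numeric(0),
             matches = numeric(0), stringsAsFactors = FALSE)
}

# Assemble a StrainAnnotation from a table of passing hits.
new_annotation <- function(strain_id, hits, registry = enzyme_registry()) {
  fams <- registry$abbrev
  count <- setNames(integer(length(fams)), fams)
  best_identity <- setNames(rep(NA_real_, length(fams)), fams)
  best_subject <- setNames(rep(NA_character_, length(fams)), fams)
  best_evalue <- setNames(rep(NA_real_, length(fams)), fams)
  if (nrow(hits)) {
    # deterministic best-hit order: bitscore desc, identity desc, then ids
    hits <- hits[order(hits$enzyme, -hits$bitscore, -hits$identity_pct,
                       hits$subject_id, hits$query_id), , drop = FALSE]
    rownames(hits) <- NULL
    for (e in unique(hits$enzyme)) {
      he <- hits[hits$enzyme == e, , drop = FALSE]
      count[e] <- length(unique(he$query_id))
      best_identity[e] <- he$identity_pct[1]
      best_subject[e] <- he$subject_id[1]
      best_evalue[e] <- he$evalue[1]
    }
  }
  structure(list(strain_id = strain_id, hits = hits, count = count,
                 best_identity = best_identity, best_subject = best_subject,
                 best_evalue = best_evalue),
            class = "trp_annotation")
}

#' @export
print.trp_annotation <- function(x, ...) {
  found <- x$count[x$count > 0]
  cat("Strain", x$strain_id, "-", nrow(x$hits), "passing hits;",
      length(found), "enzyme families:",
      paste(sprintf("%s(%d)", names(found), found), collapse = " "), "\n")
  invisible(x)
}

#' Search a strain proteome for pathway-enzyme homologs
#'
#' Aligns every strain protein against every reference sequence with the
#' affine-gap local aligner, estimates E-values from the Karlin-Altschul
#' formula, and keeps hits passing all four thresholds. Each strain protein
#' may count towards several enzyme families unless
#' \code{unique_best_family} restricts it to its single best family
#' (highest bitscore, ties by identity then subject id).
#'
#' @param proteome Named character vector of protein sequences (one strain).
#' @param refdb Reference database from \code{\link{load_reference_db}} or
#'   \code{\link{synthetic_reference_db}}.
#' @param th Thresholds from \code{\link{thresholds}}.
#' @param scoring Scoring scheme from \code{\link{default_scoring}}.
#' @param strain_id Strain identifier recorded in the annotation.
#' @param unique_best_family If TRUE, a strain protein counts only for the
#'   family of its best hit.
#' @return A \code{trp_annotation}: passing hits, per-family distinct-query
#'   counts and best-hit identities.
#' @export
search_homologs <- function(proteome, refdb, th = thresholds(),
                            scoring = default_scoring(),
                            strain_id = "strain",
                            unique_best_family = FALSE) {
  stopifnot(inherits(refdb, "trp_refdb"))
  if (length(proteome) == 0) stop("proteome must be non-empty")
  if (nrow(refdb$records) == 0) stop("reference database is empty")
  if (is.null(names(proteome))) stop("proteome sequences must be named")
  validate_protein(proteome)
  subj <- refdb$records
  rows <- vector("list", length(proteome))
  for (qi in seq_along(proteome)) {
    aln <- .cpp_align_many(proteome[[qi]], subj$sequence, scoring$matrix,
                           scoring$gap_open, scoring$gap_extend)
    ev <- estimate_evalue(aln[, "raw_score"], nchar(proteome[[qi]]),
                          nchar(subj$sequence), scoring)
    keep <- passes(aln[, "identity_pct"], ev, aln[, "query_cover_pct"],
                   aln[, "subject_cover_pct"], th)
    if (!any(keep)) next
    k <- which(keep)
    rows[[qi]] <- data.frame(
      strain_id = strain_id, enzyme = subj$enzyme[k],
      query_id = names(proteome)[qi], subject_id = subj$seq_id[k],
      raw_score = aln[k, "raw_score"],
      bitscore = bitscore(aln[k, "raw_score"], scoring),
      identity_pct = aln[k, "identity_pct"],
      query_cover_pct = aln[k, "query_cover_pct"],
      subject_cover_pct = aln[k, "subject_cover_pct"], evalue = ev[k],
      qstart = aln[k, "qstart"], qend = aln[k, "qend"],
      sstart = aln[k, "sstart"], send = aln[k, "send"],
      aligned_cols = aln[k, "aligned_cols"], matches = aln[k, "matches"],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(list(empty_hits()), rows))
  if (unique_best_family && nrow(hits))
    hits <- restrict_to_best_family(hits)
  new_annotation(strain_id, hits, refdb$registry)
}

restrict_to_best_family <- function(hits) {
  ord <- order(hits$query_id, -hits$bitscore, -hits$identity_pct,
               hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  best_fam <- tapply(h$enzyme, h$query_id, function(e) e[1])
  keep <- hits$enzyme == unname(best_fam[hits$query_id])
  hits[keep, , drop = FALSE]
}

#' Export passing hits in 12-column BLAST tabular format
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore; coordinates 1-based inclusive. \code{gapopen} is
#' reported as 0 (the traceback does not record it) and is not consumed by
#' \code{\link{import_external_hits}}.
#'
#' @param annotation A \code{trp_annotation}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
export_hits_tabular <- function(annotation, path) {
  h <- annotation$hits
  pairs <- (h$qend - h$qstart + 1) + (h$send - h$sstart + 1) - h$aligned_cols
  df <- data.frame(qseqid = h$query_id, sseqid = h$subject_id,
                   pident = h$identity_pct, length = h$aligned_cols,
                   mismatch = pairs - h$matches, gapopen = 0L,
                   qstart = h$qstart, qend = h$qend, sstart = h$sstart,
                   send = h$send, evalue = h$evalue, bitscore = h$bitscore,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, scientific = NA, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Import externally produced tabular homology hits
#'
#' Reads the standard 12-column tabular search output (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore), e.g.
#' from DIAMOND or BLAST+ \code{-outfmt 6}, recomputes query and subject
#' cover from the alignment coordinates and the supplied sequence lengths,
#' and re-applies the same four thresholds as \code{\link{search_homologs}}.
#' Rows whose subject id is absent from the reference database are skipped
#' with a warning.
#'
#' @param path Tabular file; an empty file yields an all-zero annotation.
#' @param refdb Reference database (supplies subject lengths and families).
#' @param th Thresholds.
#' @param query_lengths Named vector of strain-protein lengths.
#' @param strain_id Strain identifier.
#' @return A \code{trp_annotation}.
#' @export
import_external_hits <- function(path, refdb, th = thresholds(),
                                 query_lengths, strain_id = "strain") {
  stopifnot(inherits(refdb, "trp_refdb"))
  subject_lengths <- setNames(nchar(refdb$records$sequence),
                              refdb$records$seq_id)
  enzyme_of <- setNames(refdb$records$enzyme, refdb$records$seq_id)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(new_annotation(strain_id, empty_hits(), refdb$registry))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12)
      stop("malformed tabular row at line ", i, ": expected 12 columns, got ",
           length(f))
    num <- suppressWarnings(as.numeric(f[c(3:11, 12)]))
    if (anyNA(num))
      stop("malformed tabular row at line ", i, ": non-numeric field")
    if (!(f[2] %in% names(enzyme_of))) {
      warning("line ", i, ": unknown subject id '", f[2], "' skipped")
      next
    }
    if (!(f[1] %in% names(query_lengths)))
      stop("line ", i, ": query id '", f[1], "' missing from query_lengths")
    qs <- num[5]; qe <- num[6]; ss <- num[7]; se <- num[8]
    qcov <- 100 * (abs(qe - qs) + 1) / query_lengths[[f[1]]]
    scov <- 100 * (abs(se - ss) + 1) / subject_lengths[[f[2]]]
    rows[[i]] <- data.frame(
      strain_id = strain_id, enzyme = unname(enzyme_of[f[2]]),
      query_id = f[1], subject_id = f[2], raw_score = NA_real_,
      bitscore = num[10], identity_pct = num[1],
      query_cover_pct = qcov, subject_cover_pct = scov, evalue = num[9],
      qstart = qs, qend = qe, sstart = ss, send = se,
      aligned_cols = num[2], matches = NA_real_, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(list(empty_hits()), rows))
  if (nrow(hits)) {
    keep <- passes(hits$identity_pct, hits$evalue, hits$query_cover_pct,
                   hits$subject_cover_pct, th)
    hits <- hits[keep, , drop = FALSE]
  }
  new_annotation(strain_id, hits, refdb$registry)
}

#' Annotate a set of strain proteomes
#'
#' Runs \code{\link{search_homologs}} over a list of proteomes.
#'
#' @param proteomes Named list of proteomes (each a named character vector);
#'   names are strain ids.
#' @inheritParams search_homologs
#' @return Named list of \code{trp_annotation}.
#' @export
annotate_strains <- function(proteomes, refdb, th = thresholds(),
                             scoring = default_scoring(),
                             unique_best_family = FALSE) {
  stopifnot(!is.null(names(proteomes)))
  out <- lapply(names(proteomes), function(sid)
    search_homologs(proteomes[[sid]], refdb, th, scoring, strain_id = sid,
                    unique_best_family = unique_best_family))
  setNames(out, names(proteomes))
}

#' Per-strain enzyme summary table
#'
#' Long-format summary \code{strain, enzyme, count, best_identity,
#' best_subject, best_evalue} across annotations.
#'
#' @param annotations List of \code{trp_annotation}.
#' @return data.frame.
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) data.frame(
    strain = a$strain_id, enzyme = names(a$count), count = unname(a$count),
    best_identity = unname(a$best_identity),
    best_subject = unname(a$best_subject),
    best_evalue = unname(a$best_evalue), row.names = NULL,
    stringsAsFactors = FALSE)))
}

#' Strain-by-enzyme count matrix
#' @param annotations List of \code{trp_annotation}.
#' @return Integer matrix, rows = strains, columns = enzyme families.
#' @export
count_matrix <- function(annotations) {
  stopifnot(length(annotations) > 0)
  fams <- names(annotations[[1]]$count)
  m <- t(vapply(annotations, function(a) a$count[fams],
                integer(length(fams))))
  rownames(m) <- vapply(annotations, function(a) a$strain_id, "")
  m
}
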