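#' Run configuration
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults are the
#' study settings: identity >= 30 percent, E <= 1e-3, covers >= 70 percent,
#' BLOSUM62 11/1 scoring, detection threshold 0 ng/mL, FDR alpha 0.05 and
#' the |rho| > 0.3 reporting screen.
#'
#' @param th Homology thresholds (\code{\link{thresholds}}).
#' @param scoring Alignment scoring (\code{\link{default_scoring}}).
#' @param network A \code{trp_network} or path to a network JSON.
#' @param alpha FDR level for the association screen.
#' @param rho_screen Minimum |rho| to report an association.
#' @param detection_threshold Phenotype detection threshold, ng/mL.
#' @param hdhd_as_fldh Count HdhD homologs under fldH.
#' @param unique_best_family Restrict each strain protein to its best
#'   family.
#' @param include_ipya_in_accuracy Include the inferred IPYA phenotype in
#'   concordance accuracies.
#' @param seed Integer seed for any stochastic stage.
#' @return An object of class \code{trp_config}.
#' @export
run_config <- function(th = thresholds(), scoring = default_scoring(),
                       network = build_default_network(), alpha = 0.05,
                       rho_screen = 0.3, detection_threshold = 0,
                       hdhd_as_fldh = TRUE, unique_best_family = FALSE,
                       include_ipya_in_accuracy = TRUE, seed = 1L) {
  if (is.character(network)) network <- load_network(network)
  structure(list(th = th, scoring = scoring, network = network,
                 alpha = alpha, rho_screen = rho_screen,
                 detection_threshold = detection_threshold,
                 hdhd_as_fldh = hdhd_as_fldh,
                 unique_best_family = unique_best_family,
                 include_ipya_in_accuracy = include_ipya_in_accuracy,
                 seed = as.integer(seed)),
            class = "trp_config")
}

#' Run the full annotate - predict - summarize (- concord - stats) pipeline
#'
#' Executes homology annotation of every proteome, pathway-completeness
#' prediction, species-level summarization and, when a concentration table
#' is supplied, genotype-phenotype concordance and the gene-count /
#' concentration association screen. All stage outputs are written as TSV
#' under \code{out_dir} together with a run manifest recording the applied
#' thresholds.
#'
#' @param proteomes Named list of proteomes (named character vectors), or a
#'   directory of per-strain FASTA files (strain id = file stem).
#' @param refdb Reference database.
#' @param metadata data.frame \code{strain, species, source}.
#' @param concentrations Optional strains x metabolites matrix (or TSV path
#'   with a \code{strain} column).
#' @param config A \code{trp_config}.
#' @param out_dir Output directory; NULL to skip writing.
#' @return List with \code{annotations}, \code{profiles}, \code{summary},
#'   and (when concentrations are given) \code{phenotypes},
#'   \code{concordance}, \code{correlations}, \code{source_tests}.
#' @export
run_pipeline <- function(proteomes, refdb, metadata, concentrations = NULL,
                         config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "trp_config"))
  if (is.character(proteomes) && length(proteomes) == 1) {
    files <- list.files(proteomes, pattern = "\\.(fa|faa|fasta)$",
                        full.names = TRUE)
    if (length(files) == 0) stop("no FASTA files in ", proteomes)
    proteomes <- setNames(lapply(files, read_fasta),
                          sub("\\.[^.]+$", "", basename(files)))
  }
  if (is.character(concentrations) && length(concentrations) == 1) {
    df <- read_tsv(concentrations)
    concentrations <- as.matrix(df[, -1, drop = FALSE])
    rownames(concentrations) <- df[[1]]
  }
  species_map <- setNames(metadata$species, metadata$strain)
  annotations <- annotate_strains(proteomes, refdb, config$th,
                                  config$scoring,
                                  config$unique_best_family)
  profiles <- prediction_profiles(annotations, config$network,
                                  config$hdhd_as_fldh)
  summary <- summarize_by_species(profiles, species_map, config$network)
  out <- list(annotations = annotations, profiles = profiles,
              summary = summary)
  if (!is.null(concentrations)) {
    phen <- phenotype_from_concentrations(concentrations,
                                          config$detection_threshold)
    out$phenotypes <- phen
    out$concordance <- accuracy_report(profiles, phen, species_map,
                                       config$network,
                                       config$include_ipya_in_accuracy)
    counts <- count_matrix(annotations)
    shared <- intersect(rownames(counts), rownames(concentrations))
    if (length(shared) >= 3) {
      out$correlations <- gene_metabolite_correlations(
        counts, concentrations, config$alpha, config$rho_screen)
    } else {
      message("fewer than 3 strains with both counts and concentrations; ",
              "association screen skipped")
    }
    out$source_tests <- source_comparisons(concentrations, metadata)
  }
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(annotation_table(out$annotations),
            file.path(out_dir, "annotation.tsv"))
  write_tsv(prediction_table(out$profiles, config$network),
            file.path(out_dir, "predictions.tsv"))
  write_species_summary(out$summary,
                        file.path(out_dir, "species_summary.tsv"))
  if (!is.null(out$concordance)) {
    write_concordance(out$concordance,
                      file.path(out_dir, "concordance_cells.tsv"),
                      file.path(out_dir, "concordance_summary.tsv"))
    if (!is.null(out$correlations))
      write_tsv(out$correlations, file.path(out_dir, "correlations.tsv"))
    if (!is.null(out$source_tests))
      write_tsv(out$source_tests, file.path(out_dir, "source_tests.tsv"))
  }
  manifest <- list(
    thresholds = unclass(config$th),
    scoring = list(gap_open = config$scoring$gap_open,
                   gap_extend = config$scoring$gap_extend,
                   lambda = config$scoring$lambda, K = config$scoring$K),
    alpha = config$alpha, rho_screen = config$rho_screen,
    detection_threshold = config$detection_threshold,
    hdhd_as_fldh = config$hdhd_as_fldh,
    unique_best_family = config$unique_best_family,
    include_ipya_in_accuracy = config$include_ipya_in_accuracy,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("indolepath")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
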