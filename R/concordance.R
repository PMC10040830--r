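#' Derive phenotype presence from a concentration table
#'
#' A metabolite phenotype is present when its measured concentration exceeds
#' the detection threshold (default 0 ng/mL: any positive quantified value
#' counts as production). Metabolites not in the table are unmeasured.
#' Because indole-3-pyruvic acid is the only upstream product of
#' indole-3-lactic acid but too transient to quantify, observed ILA proves
#' IPYA occurred: the IPYA phenotype is set equal to the ILA phenotype
#' (measured-by-inference).
#'
#' @param conc Numeric matrix or data.frame, strains x metabolites, ng/mL;
#'   NA = unmeasured cell.
#' @param threshold Detection threshold in ng/mL (>= 0).
#' @param infer_ipya Apply the IPYA-from-ILA inference rule.
#' @return An object of class \code{trp_phenotypes}: list with
#'   \code{presence} (character matrix strains x metabolites in
#'   \{"present","absent","unmeasured"\}), \code{measured} (metabolites with
#'   direct measurements), \code{inferred} (metabolites whose phenotype is
#'   inferred), \code{threshold}.
#' @export
phenotype_from_concentrations <- function(conc, threshold = 0,
                                          infer_ipya = TRUE) {
  stopifnot(threshold >= 0)
  conc <- as.matrix(conc)
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentration")
  presence <- ifelse(is.na(conc), "unmeasured",
                     ifelse(conc > threshold, "present", "absent"))
  measured <- colnames(conc)
  inferred <- character(0)
  if (infer_ipya && "ILA" %in% colnames(presence)) {
    if (!("IPYA" %in% colnames(presence))) {
      presence <- cbind(presence, IPYA = presence[, "ILA"])
    } else {
      presence[, "IPYA"] <- presence[, "ILA"]
    }
    inferred <- "IPYA"
  }
  structure(list(presence = presence,
                 measured = setdiff(measured, inferred),
                 inferred = inferred, threshold = threshold),
            class = "trp_phenotypes")
}

phenotype_of <- function(phenotypes, strain, metabolite) {
  p <- phenotypes$presence
  if (!(strain %in% rownames(p)) || !(metabolite %in% colnames(p)))
    return("unmeasured")
  p[strain, metabolite]
}

#' Classify one strain-metabolite cell
#'
#' Crosses gene prediction (GE = metabolite predicted, GA = not) with
#' phenotype (PE = present, PA = absent). Unmeasured phenotypes are skipped
#' and excluded from accuracy denominators.
#'
#' @param profile A prediction profile (element of
#'   \code{\link{prediction_profiles}}).
#' @param phenotypes A \code{trp_phenotypes}.
#' @param metabolite Metabolite id (must be predictable).
#' @param network A \code{trp_network}.
#' @return One of "GE_PE", "GE_PA", "GA_PE", "GA_PA", or "skipped".
#' @export
classify_cell <- function(profile, phenotypes, metabolite,
                          network = build_default_network()) {
  if (!(metabolite %in% network$predictable))
    stop("metabolite not predictable: ", metabolite)
  ph <- phenotype_of(phenotypes, profile$strain_id, metabolite)
  if (ph == "unmeasured") return("skipped")
  gene <- if (metabolite %in% profile$predicted) "GE" else "GA"
  phen <- if (ph == "present") "PE" else "PA"
  paste(gene, phen, sep = "_")
}

#' Genotype-phenotype concordance report
#'
#' Classifies every strain x predictable-metabolite cell into GE/GA x PE/PA
#' and reports accuracy = 100 * (GE_PE + GA_PA) / evaluated cells, per
#' metabolite, per species x metabolite, and overall. Two overall figures
#' are reported: the unweighted mean of per-metabolite accuracies (the
#' headline figure) and the pooled accuracy over all evaluated cells.
#'
#' @param profiles List of prediction profiles.
#' @param phenotypes A \code{trp_phenotypes}.
#' @param species_map Named character vector strain -> species.
#' @param network A \code{trp_network}.
#' @param include_ipya Include the inferred IPYA phenotype in accuracies.
#' @return An object of class \code{trp_concordance}: list with
#'   \code{cells} (data.frame \code{strain, species, metabolite, gene,
#'   phenotype, cell}), \code{per_metabolite} (data.frame with evaluated
#'   counts and accuracy), \code{per_species} (data.frame species x
#'   metabolite accuracy), \code{overall_by_metabolite_mean},
#'   \code{overall_pooled}.
#' @export
accuracy_report <- function(profiles, phenotypes, species_map,
                            network = build_default_network(),
                            include_ipya = TRUE) {
  strains <- vapply(profiles, `[[`, "", "strain_id")
  missing <- setdiff(strains, names(species_map))
  if (length(missing))
    stop("strain(s) missing from species map: ",
         paste(missing, collapse = ", "))
  mets <- network$predictable
  if (!include_ipya) mets <- setdiff(mets, phenotypes$inferred)
  cells <- do.call(rbind, lapply(profiles, function(p) {
    cl <- vapply(mets, function(m)
      classify_cell(p, phenotypes, m, network), "")
    data.frame(strain = p$strain_id,
               species = unname(species_map[p$strain_id]),
               metabolite = mets,
               gene = ifelse(cl == "skipped", NA,
                             substr(cl, 1, 2)),
               phenotype = ifelse(cl == "skipped", NA, substr(cl, 4, 5)),
               cell = cl, row.names = NULL, stringsAsFactors = FALSE)
  }))
  acc <- function(cl) {
    ev <- cl[cl != "skipped"]
    if (length(ev) == 0) return(NA_real_)
    100 * sum(ev %in% c("GE_PE", "GA_PA")) / length(ev)
  }
  per_met <- data.frame(
    metabolite = mets,
    evaluated = vapply(mets, function(m)
      sum(cells$metabolite == m & cells$cell != "skipped"), 0L),
    accuracy = vapply(mets, function(m)
      acc(cells$cell[cells$metabolite == m]), 0), row.names = NULL,
    stringsAsFactors = FALSE)
  sp_levels <- unique(unname(species_map[strains]))
  per_sp <- do.call(rbind, lapply(sp_levels, function(sp)
    data.frame(species = sp, metabolite = mets,
               accuracy = vapply(mets, function(m)
                 acc(cells$cell[cells$species == sp &
                                  cells$metabolite == m]), 0),
               row.names = NULL, stringsAsFactors = FALSE)))
  evaluated <- cells$cell != "skipped"
  structure(list(
    cells = cells, per_metabolite = per_met, per_species = per_sp,
    overall_by_metabolite_mean = mean(per_met$accuracy, na.rm = TRUE),
    overall_pooled = acc(cells$cell),
    n_evaluated = sum(evaluated)), class = "trp_concordance")
}

#' @export
print.trp_concordance <- function(x, ...) {
  cat("Genotype-phenotype concordance over", x$n_evaluated,
      "evaluated cells\n")
  df <- x$per_metabolite
  df$accuracy <- ifelse(is.na(df$accuracy), "n/a",
                        format_percent(df$accuracy))
  print(df, row.names = FALSE)
  cat(sprintf("Overall: %.1f%% (per-metabolite mean), %.1f%% (pooled)\n",
              x$overall_by_metabolite_mean, x$overall_pooled))
  invisible(x)
}

#' Stacked cell counts per metabolite
#' @param report A \code{trp_concordance}.
#' @return data.frame metabolite x cell-type counts.
#' @export
concordance_counts <- function(report) {
  tab <- table(report$cells$metabolite, report$cells$cell)
  df <- as.data.frame.matrix(tab)
  for (lv in c("GE_PE", "GE_PA", "GA_PE", "GA_PA"))
    if (!(lv %in% names(df))) df[[lv]] <- 0L
  cbind(metabolite = rownames(df),
        df[, intersect(c("GE_PE", "GE_PA", "GA_PE", "GA_PA", "skipped"),
                       names(df)), drop = FALSE], row.names = NULL)
}

#' Write a concordance report (cells + accuracy summary)
#' @param report A \code{trp_concordance}.
#' @param cells_path,summary_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_concordance <- function(report, cells_path, summary_path) {
  write_tsv(report$cells, cells_path)
  summary <- rbind(
    data.frame(scope = "metabolite", name = report$per_metabolite$metabolite,
               accuracy = report$per_metabolite$accuracy),
    data.frame(scope = "overall", name = "per_metabolite_mean",
               accuracy = report$overall_by_metabolite_mean),
    data.frame(scope = "overall", name = "pooled",
               accuracy = report$overall_pooled))
  write_tsv(summary, summary_path)
  invisible(list(cells = cells_path, summary = summary_path))
}
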