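#' Enzyme families present in a strain annotation
#'
#' A family is present when at least one strain protein has a passing hit
#' against it. With \code{hdhd_as_fldh} (the default), HdhD hits count as
#' evidence for the fldH family: HdhD shares the partial EC number of fldH
#' and acts as an indole-3-lactate dehydrogenase, so its homologs complete
#' the IPYA -> ILA step.
#'
#' @param annotation A \code{trp_annotation} (or a named count vector).
#' @param hdhd_as_fldh Count HdhD homologs under fldH.
#' @return Character vector of enzyme abbreviations.
#' @export
enzymes_present <- function(annotation, hdhd_as_fldh = TRUE) {
  count <- if (inherits(annotation, "trp_annotation")) annotation$count
           else annotation
  present <- names(count)[count >= 1]
  if (hdhd_as_fldh && "HdhD" %in% present)
    present <- union(present, "fldH")
  present
}

#' Predict producible metabolites from an enzyme set
#'
#' Pathway completeness: a strain is predicted to produce a metabolite iff
#' some directed path from tryptophan to it has every reaction requirement
#' satisfied by the strain's enzyme set. Implemented as breadth-first
#' reachability from the root using only satisfied edges; the result is
#' intersected with the network's predictable set, so IAld (whose producing
#' enzyme is unknown) is never returned.
#'
#' @param present Character vector of enzyme family abbreviations.
#' @param network A \code{trp_network}.
#' @return Character vector of metabolite ids (subset of
#'   \code{network$predictable}, in network order).
#' @examples
#' net <- build_default_network()
#' predict_metabolites(c("ArAT", "LDH", "ALD", "amiE", "IPD"), net)
#' @export
predict_metabolites <- function(present, network = build_default_network()) {
  stopifnot(inherits(network, "trp_network"))
  unknown <- setdiff(present, network$registry$abbrev)
  if (length(unknown))
    stop("unknown enzyme abbreviation: ", paste(unknown, collapse = ", "))
  reached <- reachable(network$root, network$edges,
                       ignore_requirements = FALSE,
                       requirements = network$requirements,
                       present = present)
  intersect(network$predictable, reached)
}

#' Per-strain prediction profiles
#'
#' Combines \code{\link{enzymes_present}} and
#' \code{\link{predict_metabolites}} over a list of annotations.
#'
#' @param annotations Named list of \code{trp_annotation}.
#' @param network A \code{trp_network}.
#' @param hdhd_as_fldh Count HdhD homologs under fldH.
#' @return Named list of profiles, each a list \code{strain_id},
#'   \code{enzymes_present}, \code{predicted}.
#' @export
prediction_profiles <- function(annotations,
                                network = build_default_network(),
                                hdhd_as_fldh = TRUE) {
  out <- lapply(annotations, function(a) {
    pres <- enzymes_present(a, hdhd_as_fldh = hdhd_as_fldh)
    list(strain_id = a$strain_id,
         enzymes_present = pres,
         predicted = predict_metabolites(pres, network))
  })
  setNames(out, vapply(out, `[[`, "", "strain_id"))
}

# profiles from explicit enzyme sets (used by the synthetic generator and
# in tests where no alignment step is wanted)
profiles_from_enzymes <- function(enzyme_sets,
                                  network = build_default_network()) {
  out <- lapply(names(enzyme_sets), function(sid) list(
    strain_id = sid, enzymes_present = enzyme_sets[[sid]],
    predicted = predict_metabolites(enzyme_sets[[sid]], network)))
  setNames(out, names(enzyme_sets))
}

#' Per-strain prediction table (long format)
#' @param profiles List of prediction profiles.
#' @param network A \code{trp_network}.
#' @return data.frame \code{strain, metabolite, predicted} (0/1).
#' @export
prediction_table <- function(profiles, network = build_default_network()) {
  do.call(rbind, lapply(profiles, function(p) data.frame(
    strain = p$strain_id, metabolite = network$predictable,
    predicted = as.integer(network$predictable %in% p$predicted),
    row.names = NULL, stringsAsFactors = FALSE)))
}

#' Species-level summary of predicted metabolites
#'
#' For each species, the percentage of its strains predicted to produce
#' each predictable metabolite, rounded half away from zero to one decimal.
#'
#' @param profiles List of prediction profiles
#'   (\code{\link{prediction_profiles}}).
#' @param species_map Named character vector strain -> species.
#' @param network A \code{trp_network}.
#' @return An object of class \code{trp_species_summary}: list with
#'   \code{table} (numeric matrix species x metabolite, rounded percent),
#'   \code{n_strains} (named integer vector), and \code{formatted}
#'   (character matrix in the mixed "100"/"6.7" display style).
#' @export
summarize_by_species <- function(profiles, species_map,
                                 network = build_default_network()) {
  strains <- vapply(profiles, `[[`, "", "strain_id")
  missing <- setdiff(strains, names(species_map))
  if (length(missing))
    stop("strain(s) missing from species map: ",
         paste(missing, collapse = ", "))
  species <- unique(unname(species_map[strains]))
  mets <- network$predictable
  tab <- matrix(0, length(species), length(mets),
                dimnames = list(species, mets))
  n <- setNames(integer(length(species)), species)
  for (sp in species) {
    members <- profiles[species_map[strains] == sp]
    n[sp] <- length(members)
    if (n[sp] == 0) stop("species with zero strains: ", sp)
    for (m in mets) {
      k <- sum(vapply(members, function(p) m %in% p$predicted, logical(1)))
      tab[sp, m] <- round_half_up(100 * k / n[sp], 1)
    }
  }
  fmt <- matrix(format_percent(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  structure(list(table = tab, n_strains = n, formatted = fmt),
            class = "trp_species_summary")
}

#' @export
print.trp_species_summary <- function(x, ...) {
  df <- data.frame(Species = rownames(x$table),
                   `No. of Strains` = unname(x$n_strains),
                   x$formatted, check.names = FALSE,
                   stringsAsFactors = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a species summary as TSV
#' @param summary A \code{trp_species_summary}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_species_summary <- function(summary, path) {
  df <- data.frame(species = rownames(summary$table),
                   n_strains = unname(summary$n_strains),
                   summary$formatted, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
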