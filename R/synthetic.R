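# Background amino-acid frequencies (Robinson & Robinson counts, as used
# for protein database statistics), normalized to 1.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Random protein sequence
#'
#' Residues drawn i.i.d. from the Robinson-Robinson background amino-acid
#' frequencies. Fully reproducible per seed; the session RNG state is left
#' untouched.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @return A single protein sequence string.
#' @export
random_protein <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  with_seed(seed, paste(sample(names(AA_BACKGROUND), length, replace = TRUE,
                               prob = AA_BACKGROUND), collapse = ""))
}

#' Mutate a protein towards a target global identity
#'
#' Applies random substitutions (and, at \code{indel_rate}, single-residue
#' insertions or deletions) until the global alignment identity to the
#' input sequence lies within 2 percentage points of the target. Used to
#' plant diverged enzyme homologs in synthetic proteomes, emulating the
#' roughly 30-60 percent identity regime of real cross-species homologs.
#'
#' @param seq Input protein sequence.
#' @param target_identity_pct Target identity, in (15, 100].
#' @param indel_rate Probability that a mutation event is an indel rather
#'   than a substitution.
#' @param seed Integer seed.
#' @param scoring Scoring scheme for the identity measurements.
#' @param max_rounds Bail out with an error after this many rounds.
#' @return List \code{sequence}, \code{achieved_identity}.
#' @export
mutate_to_identity <- function(seq, target_identity_pct, indel_rate = 0.02,
                               seed = NULL, scoring = default_scoring(),
                               max_rounds = 400L) {
  stopifnot(target_identity_pct > 15, target_identity_pct <= 100)
  if (target_identity_pct == 100)
    return(list(sequence = seq, achieved_identity = 100))
  with_seed(seed, {
    cur <- seq
    for (round in seq_len(max_rounds)) {
      id <- global_identity(seq, cur, scoring)
      if (abs(id - target_identity_pct) <= 2)
        return(list(sequence = cur, achieved_identity = id))
      if (id < target_identity_pct - 2) {
        cur <- seq  # overshot: restart, smaller steps will follow
        id <- 100
      }
      k <- max(1L, floor(nchar(cur) * (id - target_identity_pct) / 300))
      cur <- mutate_once(cur, k, indel_rate)
    }
    stop("target identity ", target_identity_pct,
         " not reached in ", max_rounds, " rounds")
  })
}

# apply k mutation events to a sequence (uses the current RNG stream)
mutate_once <- function(s, k, indel_rate) {
  chars <- strsplit(s, "")[[1]]
  for (e in seq_len(k)) {
    if (runif(1) < indel_rate && length(chars) > 30) {
      if (runif(1) < 0.5) {  # deletion
        chars <- chars[-sample.int(length(chars), 1)]
      } else {               # insertion
        pos <- sample.int(length(chars) + 1, 1)
        chars <- append(chars, sample(names(AA_BACKGROUND), 1,
                                      prob = AA_BACKGROUND), after = pos - 1)
      }
    } else {
      pos <- sample.int(length(chars), 1)
      repl <- sample(names(AA_BACKGROUND), 1, prob = AA_BACKGROUND)
      while (repl == chars[pos])
        repl <- sample(names(AA_BACKGROUND), 1, prob = AA_BACKGROUND)
      chars[pos] <- repl
    }
  }
  paste(chars, collapse = "")
}

#' Cohort specification for the synthetic generator
#'
#' @param species A list of species entries, each a list with fields
#'   \code{name}, \code{n_strains}, \code{enzymes} (character vector planted
#'   in every strain, or a list of per-strain vectors), and optionally
#'   \code{target_identity} (default 60), \code{decoys_per_strain}
#'   (default 20), \code{decoy_length_range} (default c(250, 400)),
#'   \code{sources} (recycled across strains, default "synthetic").
#' @param seed Integer seed.
#' @return An object of class \code{trp_cohort_spec}.
#' @export
cohort_spec <- function(species, seed = 1L) {
  for (sp in species) {
    stopifnot(!is.null(sp$name), sp$n_strains >= 1)
    if (is.list(sp$enzymes)) stopifnot(length(sp$enzymes) == sp$n_strains)
  }
  structure(list(species = species, seed = as.integer(seed)),
            class = "trp_cohort_spec")
}

#' Build one species entry of a cohort specification
#'
#' Convenience constructor for \code{\link{cohort_spec}} species entries:
#' every strain of the species carries the \code{base} enzyme families, and
#' the first \code{n_extra} strains additionally carry \code{extra}.
#'
#' @param name Species name.
#' @param n Number of strains.
#' @param base Character vector of enzyme families planted in all strains.
#' @param extra Families additionally planted in the first \code{n_extra}
#'   strains.
#' @param n_extra How many strains receive \code{extra}.
#' @param target_identity Identity of planted homologs (percent).
#' @param sources Isolation sources, recycled across strains.
#' @return A species entry list.
#' @export
species_entry <- function(name, n, base, extra = NULL, n_extra = 0,
                          target_identity = 60, sources = "synthetic") {
  enzymes <- replicate(n, base, simplify = FALSE)
  if (n_extra > 0)
    for (k in seq_len(n_extra))
      enzymes[[k]] <- c(enzymes[[k]], extra)
  list(name = name, n_strains = n, enzymes = enzymes,
       target_identity = target_identity, sources = sources)
}

#' Default synthetic cohort emulating the study's 148-strain panel
#'
#' Thirteen lactic acid bacteria species with the published strain counts
#' and enzyme complements: every species except \emph{L. curvatus} carries
#' the aminotransferase first step plus an ILA dehydrogenase, amidase and
#' aldehyde dehydrogenase in all strains; species-specific subsets carry
#' the monooxygenase (TMO) and the indolepyruvate decarboxylase (IPD)
#' routes. No strain carries TDC or the fldA/fldBC/fldI cluster, matching
#' the genomic findings.
#'
#' @param seed Integer seed.
#' @param target_identity Identity of planted homologs (percent).
#' @return A \code{trp_cohort_spec} with 148 strains over 13 species.
#' @export
default_cohort_spec <- function(seed = 1L, target_identity = 60) {
  core <- c("ArAT", "LDH", "amiE", "ALD")
  corf <- c("ArAT", "fldH", "amiE", "ALD")  # fldH-carrying species
  sp <- list(
    species_entry("L. acidophilus",  8, core, "TMO", 1, target_identity),
    species_entry("L. crispatus",   14, c(core, "TMO"), NULL, 0, target_identity),
    species_entry("L. curvatus",     4, c("amiE", "ALD"), NULL, 0, target_identity),
    species_entry("L. fermentum",   11, c(core, "IPD"), NULL, 0, target_identity),
    species_entry("L. gasseri",      8, core, NULL, 0, target_identity),
    species_entry("L. helveticus",   9, core, "TMO", 8, target_identity,
                  sources = c("fermented yak milk", "dairy fan")),
    species_entry("L. mucosae",     15, c(core, "IPD"), "TMO", 2, target_identity),
    species_entry("L. paracasei",   10, c(core, "IPD"), "TMO", 4, target_identity),
    species_entry("L. plantarum",   10, c(core, "IPD"), "TMO", 8, target_identity),
    species_entry("L. reuteri",     30, c(core, "IPD"), "TMO", 2, target_identity,
                  sources = c("fermented rice milk", "human feces")),
    species_entry("L. rhamnosus",    9, c(core, "IPD"), NULL, 0, target_identity),
    species_entry("L. salivarius",  12, c(corf, "IPD"), "TMO", 8, target_identity),
    species_entry("L. pentosus",     8, c(core, "IPD", "TMO"), NULL, 0, target_identity))
  cohort_spec(sp, seed = seed)
}

#' Generate a synthetic strain cohort
#'
#' Each strain proteome consists of full-length mutated homologs of the
#' reference sequences for its specified enzyme families, hidden among
#' random decoy proteins. The returned manifest records the ground-truth
#' enzyme content of every strain.
#'
#' @param spec A \code{trp_cohort_spec}.
#' @param refdb Reference database supplying the sequences homologs are
#'   derived from.
#' @return List with \code{proteomes} (named list of named character
#'   vectors), \code{metadata} (data.frame \code{strain, species, source}),
#'   \code{truth} (named list of planted enzyme sets).
#' @export
generate_cohort <- function(spec, refdb = synthetic_reference_db()) {
  stopifnot(inherits(spec, "trp_cohort_spec"), inherits(refdb, "trp_refdb"))
  fams <- refdb$registry$abbrev
  proteomes <- list()
  meta <- list()
  truth <- list()
  strain_no <- 0L
  for (si in seq_along(spec$species)) {
    sp <- spec$species[[si]]
    target <- if (is.null(sp$target_identity)) 60 else sp$target_identity
    ndec <- if (is.null(sp$decoys_per_strain)) 20L else sp$decoys_per_strain
    dlr <- if (is.null(sp$decoy_length_range)) c(250L, 400L)
           else sp$decoy_length_range
    sources <- if (is.null(sp$sources)) "synthetic" else sp$sources
    sources <- rep(sources, length.out = sp$n_strains)
    for (k in seq_len(sp$n_strains)) {
      strain_no <- strain_no + 1L
      sid <- sprintf("S%03d_%s", strain_no,
                     gsub("[^A-Za-z0-9]", "", sp$name))
      enz <- if (is.list(sp$enzymes)) sp$enzymes[[k]] else sp$enzymes
      unknown <- setdiff(enz, fams)
      if (length(unknown))
        stop("spec references unknown enzyme: ",
             paste(unknown, collapse = ", "))
      sseed <- child_seed(spec$seed, strain_no)
      prot <- character(0)
      for (ei in seq_along(enz)) {
        ref_ids <- refdb$index[[enz[ei]]]
        ref_seq <- refdb$records$sequence[refdb$records$seq_id == ref_ids[1]]
        hom <- mutate_to_identity(ref_seq, target,
                                  seed = child_seed(sseed, ei))
        prot[sprintf("%s_plant_%s", sid, enz[ei])] <- hom$sequence
      }
      if (ndec > 0) {
        for (di in seq_len(ndec)) {
          dseed <- child_seed(sseed, 1000L + di)
          len <- with_seed(dseed, sample(dlr[1]:dlr[2], 1))
          prot[sprintf("%s_decoy_%02d", sid, di)] <-
            random_protein(len, seed = child_seed(dseed, 1L))
        }
      }
      proteomes[[sid]] <- prot
      truth[[sid]] <- sort(enz)
      meta[[sid]] <- data.frame(strain = sid, species = sp$name,
                                source = sources[k],
                                stringsAsFactors = FALSE)
    }
  }
  list(proteomes = proteomes, metadata = do.call(rbind, c(meta,
                                                          make.row.names = FALSE)),
       truth = truth)
}

#' Metabolomics specification for the synthetic generator
#'
#' @param means data.frame \code{species, metabolite, mean, cv} overriding
#'   the defaults for specific cells; NULL for none.
#' @param default_mean,default_cv Lognormal arithmetic mean (ng/mL) and
#'   coefficient of variation used where no override applies.
#' @param false_negative_rate Probability that a genotype-positive strain
#'   still yields 0 (emulates fermentation dropouts).
#' @param phenotype_injections data.frame \code{species, metabolite} (and
#'   optionally \code{mean}): cells forced to a positive concentration
#'   regardless of genotype, emulating observed metabolites without genetic
#'   evidence (the tryptamine / indoleacrylate anomalies).
#' @param detection_limit Values at or below this (ng/mL) are floored to 0.
#' @param measured Metabolites with direct measurements.
#' @param seed Integer seed.
#' @return An object of class \code{trp_metabolomics_spec}.
#' @export
metabolomics_spec <- function(means = NULL, default_mean = 100,
                              default_cv = 0.5, false_negative_rate = 0,
                              phenotype_injections = NULL,
                              detection_limit = 0,
                              measured = c("ILA", "IA", "IPA", "IAM",
                                           "TA", "IAA"),
                              seed = 1L) {
  stopifnot(false_negative_rate >= 0, false_negative_rate <= 1,
            default_mean >= 0, detection_limit >= 0)
  structure(list(means = means, default_mean = default_mean,
                 default_cv = default_cv,
                 false_negative_rate = false_negative_rate,
                 phenotype_injections = phenotype_injections,
                 detection_limit = detection_limit, measured = measured,
                 seed = as.integer(seed)),
            class = "trp_metabolomics_spec")
}

#' Default metabolomics spec emulating the study's concentration structure
#'
#' Species-level lognormal means with strain-level spread (CV 0.5); the
#' ILA mean of \emph{L. salivarius} is set an order of magnitude above the
#' other species (1907 vs about 103 ng/mL), and the two genotype-discordant
#' phenotypes of the study are injected: tryptamine in \emph{L. helveticus}
#' and indoleacrylate in \emph{L. mucosae}.
#'
#' @param seed Integer seed.
#' @return A \code{trp_metabolomics_spec}.
#' @export
default_metabolomics_spec <- function(seed = 1L) {
  metabolomics_spec(
    means = data.frame(
      species = c("L. salivarius", "L. pentosus"),
      metabolite = c("ILA", "IAA"),
      mean = c(1907, 22.5), cv = c(0.5, 0.5), stringsAsFactors = FALSE),
    default_mean = 100, default_cv = 0.5,
    phenotype_injections = data.frame(
      species = c("L. helveticus", "L. mucosae"),
      metabolite = c("TA", "IA"), mean = c(39, 20),
      stringsAsFactors = FALSE),
    seed = seed)
}

#' Generate a synthetic concentration table from prediction profiles
#'
#' Genotype-positive strain x metabolite cells draw lognormal
#' concentrations (zeroed with the false-negative probability);
#' genotype-negative cells are 0 except for the configured phenotype
#' injections. Values at or below the detection limit are floored to 0.
#'
#' @param profiles List of prediction profiles (ground truth or predicted).
#' @param species_map Named character vector strain -> species.
#' @param spec A \code{trp_metabolomics_spec}.
#' @return Numeric matrix strains x measured metabolites (ng/mL).
#' @export
generate_metabolomics <- function(profiles, species_map,
                                  spec = default_metabolomics_spec()) {
  stopifnot(inherits(spec, "trp_metabolomics_spec"))
  strains <- vapply(profiles, `[[`, "", "strain_id")
  mets <- spec$measured
  conc <- matrix(0, length(strains), length(mets),
                 dimnames = list(strains, mets))
  lookup_mean <- function(sp, m) {
    if (!is.null(spec$means)) {
      hit <- spec$means$species == sp & spec$means$metabolite == m
      if (any(hit))
        return(c(spec$means$mean[hit][1], spec$means$cv[hit][1]))
    }
    c(spec$default_mean, spec$default_cv)
  }
  inj <- spec$phenotype_injections
  for (i in seq_along(strains)) {
    sid <- strains[i]
    sp <- unname(species_map[sid])
    sseed <- child_seed(spec$seed, i)
    for (j in seq_along(mets)) {
      m <- mets[j]
      positive <- m %in% profiles[[i]]$predicted
      injected <- !is.null(inj) &&
        any(inj$species == sp & inj$metabolite == m)
      cseed <- child_seed(sseed, j)
      if (positive) {
        mc <- lookup_mean(sp, m)
        val <- with_seed(cseed, {
          if (runif(1) < spec$false_negative_rate) 0
          else rlnorm_mean_cv(1, mc[1], mc[2])
        })
      } else if (injected) {
        mu <- if ("mean" %in% names(inj))
          inj$mean[inj$species == sp & inj$metabolite == m][1]
        else spec$default_mean
        val <- with_seed(cseed, rlnorm_mean_cv(1, mu, spec$default_cv))
      } else {
        val <- 0
      }
      conc[i, j] <- if (val <= spec$detection_limit) 0 else val
    }
  }
  conc
}

# lognormal draws parameterized by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

#' Write a synthetic cohort to disk
#'
#' One proteome FASTA per strain plus \code{metadata.tsv} and
#' \code{truth.tsv}; optionally \code{concentrations.tsv}.
#'
#' @param cohort Result of \code{\link{generate_cohort}}.
#' @param dir Output directory (created if needed).
#' @param concentrations Optional strains x metabolites matrix.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, concentrations = NULL) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (sid in names(cohort$proteomes))
    write_fasta(cohort$proteomes[[sid]],
                file.path(dir, "proteomes", paste0(sid, ".faa")))
  write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- data.frame(
    strain = names(cohort$truth),
    enzymes = vapply(cohort$truth, paste, "", collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  write_tsv(truth, file.path(dir, "truth.tsv"))
  if (!is.null(concentrations)) {
    df <- data.frame(strain = rownames(concentrations), concentrations,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, "concentrations.tsv"))
  }
  invisible(dir)
}
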