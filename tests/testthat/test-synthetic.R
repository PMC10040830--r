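test_that("random proteins are reproducible and length-correct", {
  expect_identical(random_protein(300, seed = 8), random_protein(300, seed = 8))
  expect_false(identical(random_protein(300, seed = 8),
                         random_protein(300, seed = 9)))
  expect_equal(nchar(random_protein(300, seed = 1)), 300)
  # residue frequencies approach the declared background table
  s <- random_protein(10000, seed = 12)
  obs <- table(factor(strsplit(s, "")[[1]],
                      levels = names(indolepath:::AA_BACKGROUND)))
  gof <- stats::chisq.test(as.vector(obs),
                           p = indolepath:::AA_BACKGROUND /
                             sum(indolepath:::AA_BACKGROUND))
  expect_gt(gof$p.value, 0.001)
})

test_that("mutate_to_identity reaches its target within tolerance", {
  ref <- random_protein(300, seed = 21)
  expect_identical(mutate_to_identity(ref, 100)$sequence, ref)
  h40 <- mutate_to_identity(ref, 40, seed = 22)
  id40 <- global_identity(ref, h40$sequence)
  expect_gte(id40, 38); expect_lte(id40, 42)
  expect_equal(h40$achieved_identity, id40)
  # achieved identity decreases along a target sweep
  sweep <- vapply(c(90, 75, 60, 45, 30),
                  function(t) mutate_to_identity(ref, t,
                                                 seed = 23)$achieved_identity,
                  0)
  expect_true(all(diff(sweep) < 0))
  expect_error(mutate_to_identity(ref, 10), "target_identity_pct > 15")
})

test_that("generated cohorts recover their planted enzyme content", {
  spec <- cohort_spec(list(
    list(name = "A. plantus", n_strains = 5,
         enzymes = c("ArAT", "LDH"), target_identity = 60,
         decoys_per_strain = 5),
    list(name = "B. vacuus", n_strains = 2, enzymes = character(0),
         decoys_per_strain = 8)), seed = 33)
  coh <- generate_cohort(spec, REFDB)
  expect_equal(nrow(coh$metadata), 7)
  anns <- annotate_strains(coh$proteomes, REFDB)
  for (sid in names(coh$proteomes)) {
    found <- enzymes_present(anns[[sid]], hdhd_as_fldh = FALSE)
    expect_setequal(found, coh$truth[[sid]])
  }
  # determinism per seed
  coh2 <- generate_cohort(spec, REFDB)
  expect_identical(coh$proteomes, coh2$proteomes)
  bad <- cohort_spec(list(list(name = "X", n_strains = 1,
                               enzymes = "NOPE")), seed = 1)
  expect_error(generate_cohort(bad, REFDB), "NOPE")
})

test_that("metabolomics generator yields perfect concordance when noiseless", {
  sets <- list(s1 = c("ArAT", "LDH", "amiE", "ALD"),
               s2 = c("ArAT", "fldH", "TMO", "amiE"),
               s3 = character(0))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  species <- setNames(c("X", "X", "Y"), names(sets))
  spec <- metabolomics_spec(false_negative_rate = 0, seed = 5)
  conc <- generate_metabolomics(prof, species, spec)
  ph <- phenotype_from_concentrations(conc)
  rep <- accuracy_report(prof, ph, species, NET)
  expect_true(all(rep$per_metabolite$accuracy == 100, na.rm = TRUE))
  # reproducible per seed
  expect_identical(conc, generate_metabolomics(prof, species, spec))
})

test_that("a phenotype injection lowers exactly one metabolite's accuracy", {
  sets <- setNames(c(replicate(9, c("ArAT", "LDH"), simplify = FALSE),
                     replicate(11, c("ArAT", "LDH"), simplify = FALSE)),
                   sprintf("s%02d", 1:20))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  species <- setNames(rep(c("L. helv", "L. other"), c(9, 11)), names(sets))
  spec <- metabolomics_spec(
    phenotype_injections = data.frame(species = "L. helv",
                                      metabolite = "TA", mean = 39),
    seed = 6)
  conc <- generate_metabolomics(prof, species, spec)
  rep <- accuracy_report(prof, phenotype_from_concentrations(conc),
                         species, NET)
  pm <- rep$per_metabolite
  expect_equal(pm$accuracy[pm$metabolite == "TA"], 100 * 11 / 20)
  expect_true(all(pm$accuracy[pm$metabolite != "TA"] == 100, na.rm = TRUE))
})

test_that("false negatives lower concordance at the expected rate", {
  sets <- setNames(replicate(40, c("ArAT", "LDH"), simplify = FALSE),
                   sprintf("s%02d", 1:40))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  species <- setNames(rep("X", 40), names(sets))
  spec <- metabolomics_spec(false_negative_rate = 0.25, seed = 7)
  conc <- generate_metabolomics(prof, species, spec)
  rep <- accuracy_report(prof, phenotype_from_concentrations(conc),
                         species, NET)
  ila <- rep$per_metabolite
  acc <- ila$accuracy[ila$metabolite == "ILA"]
  expect_lt(acc, 100)
  expect_gt(acc, 100 * (1 - 0.25) - 25)  # binomial spread around 75
})

test_that("lognormal concentrations follow the requested mean and cv", {
  set.seed(9)
  x <- indolepath:::rlnorm_mean_cv(20000, mean = 100, cv = 0.5)
  expect_lt(abs(mean(x) - 100) / 100, 0.03)
  expect_lt(abs(stats::sd(x) / mean(x) - 0.5), 0.03)
})

test_that("cohort files round-trip through the writer", {
  spec <- cohort_spec(list(list(name = "A sp", n_strains = 2,
                                enzymes = "ArAT", target_identity = 70,
                                decoys_per_strain = 2)), seed = 12)
  coh <- generate_cohort(spec, REFDB)
  dir <- withr::local_tempdir()
  prof <- indolepath:::profiles_from_enzymes(coh$truth, NET)
  conc <- generate_metabolomics(prof, setNames(coh$metadata$species,
                                               coh$metadata$strain))
  write_cohort(coh, dir, conc)
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "concentrations.tsv")))
  fastas <- list.files(file.path(dir, "proteomes"), pattern = "\\.faa$")
  expect_length(fastas, 2)
  back <- read_fasta(file.path(dir, "proteomes", fastas[1]))
  expect_equal(sort(names(back)), sort(names(coh$proteomes[[1]])))
})
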