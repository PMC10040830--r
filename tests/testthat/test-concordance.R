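make_conc <- function(strains, mets, fill = 0) {
  matrix(fill, length(strains), length(mets),
         dimnames = list(strains, mets))
}

test_that("phenotypes derive from concentrations with the IPYA inference", {
  conc <- make_conc(c("a", "b"), c("ILA", "IA"))
  conc["a", "ILA"] <- 3864.553
  ph <- phenotype_from_concentrations(conc, threshold = 0)
  expect_equal(ph$presence["a", "ILA"], "present")
  expect_equal(ph$presence["a", "IPYA"], "present")  # inferred from ILA
  expect_equal(ph$presence["b", "ILA"], "absent")
  expect_equal(ph$presence["b", "IPYA"], "absent")
  expect_equal(ph$inferred, "IPYA")
  # metabolites not in the table are unmeasured
  expect_equal(indolepath:::phenotype_of(ph, "a", "IAAld"), "unmeasured")
  # NA cells are unmeasured
  conc["b", "IA"] <- NA
  ph2 <- phenotype_from_concentrations(conc)
  expect_equal(ph2$presence["b", "IA"], "unmeasured")
  conc["b", "IA"] <- -1
  expect_error(phenotype_from_concentrations(conc), "negative")
})

test_that("detection threshold separates presence from absence", {
  conc <- make_conc("a", "ILA", fill = 5)
  expect_equal(phenotype_from_concentrations(conc, 5)$presence[1, "ILA"],
               "absent")  # strictly greater than threshold required
  expect_equal(phenotype_from_concentrations(conc, 4.9)$presence[1, "ILA"],
               "present")
})

test_that("cells classify into the GE/GA x PE/PA grid", {
  sets <- list(s1 = c("ArAT", "LDH"))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)[[1]]
  conc <- make_conc("s1", c("ILA", "TA", "IA"))
  conc["s1", c("ILA", "TA")] <- c(100, 30)
  ph <- phenotype_from_concentrations(conc)
  expect_equal(classify_cell(prof, ph, "ILA", NET), "GE_PE")
  expect_equal(classify_cell(prof, ph, "TA", NET), "GA_PE")
  expect_equal(classify_cell(prof, ph, "IA", NET), "GA_PA")
  expect_equal(classify_cell(prof, ph, "IAAld", NET), "skipped")
  expect_error(classify_cell(prof, ph, "IAld", NET), "not predictable")
})

test_that("a phenotype table equal to predictions scores 100 everywhere", {
  sets <- list(s1 = c("ArAT", "LDH", "amiE", "ALD", "IPD"),
               s2 = c("amiE", "ALD"),
               s3 = c("ArAT", "fldH", "TMO", "amiE"))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  mets <- c("ILA", "IA", "IPA", "IAM", "TA", "IAA")
  conc <- make_conc(names(sets), mets)
  for (s in names(sets))
    for (m in intersect(mets, prof[[s]]$predicted))
      conc[s, m] <- 50
  ph <- phenotype_from_concentrations(conc)
  rep <- accuracy_report(prof, ph, setNames(rep("X", 3), names(sets)), NET)
  expect_true(all(rep$per_metabolite$accuracy == 100, na.rm = TRUE))
  expect_equal(rep$overall_by_metabolite_mean, 100)
  expect_equal(rep$overall_pooled, 100)
})

test_that("accuracy matches a hand count with one discordant strain", {
  sets <- setNames(replicate(10, c("ArAT", "LDH"), simplify = FALSE),
                   sprintf("s%02d", 1:10))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  conc <- make_conc(names(sets), c("ILA", "TA"))
  conc[, "ILA"] <- 80
  conc["s01", "TA"] <- 25  # phenotype without genotype in one strain
  ph <- phenotype_from_concentrations(conc)
  rep <- accuracy_report(prof, ph, setNames(rep("X", 10), names(sets)), NET)
  pm <- rep$per_metabolite
  expect_equal(pm$accuracy[pm$metabolite == "TA"], 90)
  expect_equal(pm$accuracy[pm$metabolite == "ILA"], 100)
  # cells partition: evaluated + skipped = strains x metabolites in scope
  expect_equal(nrow(rep$cells), 10 * length(NET$predictable))
  expect_equal(sum(rep$cells$cell == "skipped") + rep$n_evaluated,
               nrow(rep$cells))
})

test_that("pooled accuracy is the cell-weighted mean of per-metabolite accuracies", {
  set.seed(3)
  sets <- lapply(1:12, function(k)
    sample(NET$registry$abbrev, sample(2:6, 1)))
  names(sets) <- sprintf("s%02d", 1:12)
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  mets <- c("ILA", "IA", "IAM", "IAA")
  conc <- make_conc(names(sets), mets)
  conc[] <- sample(c(0, 60), length(conc), replace = TRUE)
  ph <- phenotype_from_concentrations(conc)
  species <- setNames(rep(c("X", "Y"), each = 6), names(sets))
  rep <- accuracy_report(prof, ph, species, NET)
  pm <- rep$per_metabolite[!is.na(rep$per_metabolite$accuracy), ]
  expect_equal(rep$overall_pooled,
               sum(pm$accuracy * pm$evaluated) / sum(pm$evaluated))
  # invariance under strain relabeling
  perm <- sample(names(sets))
  rep2 <- accuracy_report(prof[perm], ph, species, NET)
  expect_equal(sort(rep2$per_metabolite$accuracy),
               sort(rep$per_metabolite$accuracy))
  expect_equal(rep2$overall_pooled, rep$overall_pooled)
})

test_that("IPYA concordance cell mirrors ILA under the inference rule", {
  set.seed(5)
  sets <- lapply(1:10, function(k)
    sample(c("ArAT", "LDH", "fldH", "amiE", "ALD"), sample(1:5, 1)))
  names(sets) <- sprintf("s%02d", 1:10)
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  conc <- make_conc(names(sets), "ILA")
  conc[, "ILA"] <- sample(c(0, 45), 10, replace = TRUE)
  ph <- phenotype_from_concentrations(conc)
  rep <- accuracy_report(prof, ph, setNames(rep("X", 10), names(sets)), NET)
  for (s in names(sets)) {
    ila_pred <- "ILA" %in% prof[[s]]$predicted
    ipya_pred <- "IPYA" %in% prof[[s]]$predicted
    if (ila_pred == ipya_pred) {
      ci <- rep$cells
      expect_equal(ci$cell[ci$strain == s & ci$metabolite == "IPYA"],
                   ci$cell[ci$strain == s & ci$metabolite == "ILA"])
    }
  }
})

test_that("include_ipya flag removes the inferred metabolite from scope", {
  sets <- list(s1 = c("ArAT", "LDH"))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  conc <- make_conc("s1", "ILA", fill = 10)
  ph <- phenotype_from_concentrations(conc)
  rep_in <- accuracy_report(prof, ph, c(s1 = "X"), NET, include_ipya = TRUE)
  rep_out <- accuracy_report(prof, ph, c(s1 = "X"), NET,
                             include_ipya = FALSE)
  expect_true("IPYA" %in% rep_in$cells$metabolite)
  expect_false("IPYA" %in% rep_out$cells$metabolite)
})

test_that("concordance counts table partitions all cells", {
  sets <- list(s1 = c("ArAT", "LDH"), s2 = character(0))
  prof <- indolepath:::profiles_from_enzymes(sets, NET)
  conc <- make_conc(names(sets), c("ILA", "TA"))
  conc["s1", "ILA"] <- 90
  ph <- phenotype_from_concentrations(conc)
  rep <- accuracy_report(prof, ph, setNames(rep("X", 2), names(sets)), NET)
  counts <- concordance_counts(rep)
  expect_equal(sum(counts[, -1]), nrow(rep$cells))
})
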