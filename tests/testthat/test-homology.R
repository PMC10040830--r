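test_that("an exact planted reference copy is found at identity 100", {
  rid <- REFDB$index[["ArAT"]][1]
  ref <- REFDB$records$sequence[REFDB$records$seq_id == rid]
  prot <- c(copy = ref, decoy = random_protein(300, seed = 9))
  ann <- search_homologs(prot, REFDB, strain_id = "s1")
  expect_gte(ann$count[["ArAT"]], 1)
  expect_equal(ann$best_identity[["ArAT"]], 100)
  expect_equal(ann$best_subject[["ArAT"]], rid)
})

test_that("random decoy proteomes yield no hits at default thresholds", {
  prot <- setNames(
    vapply(1:25, function(k) random_protein(300, seed = 5000 + k), ""),
    paste0("decoy_", 1:25))
  ann <- search_homologs(prot, REFDB, strain_id = "d")
  expect_true(all(ann$count == 0))
  expect_true(all(is.na(ann$best_identity)))
})

test_that("a reference truncated to half length fails subject cover", {
  rid <- REFDB$index[["LDH"]][1]
  ref <- REFDB$records$sequence[REFDB$records$seq_id == rid]
  half <- substr(ref, 1, floor(nchar(ref) / 2))
  ann <- search_homologs(c(frag = half), REFDB, strain_id = "s")
  expect_equal(ann$count[["LDH"]], 0L)
})

test_that("relaxing thresholds never removes hits, tightening never adds", {
  prot <- make_small_proteome(c("ArAT", "LDH"), identity = 45, seed = 77)
  strict <- search_homologs(prot, REFDB, thresholds(40, 1e-6, 80, 80))
  default <- search_homologs(prot, REFDB, thresholds())
  loose <- search_homologs(prot, REFDB, thresholds(20, 1e-2, 50, 50))
  key <- function(a) paste(a$hits$enzyme, a$hits$query_id, a$hits$subject_id)
  expect_true(all(key(strict) %in% key(default)))
  expect_true(all(key(default) %in% key(loose)))
})

test_that("tabular import applies inclusive threshold boundaries", {
  qlen <- c(q1 = 100)
  rid <- REFDB$records$seq_id[1]
  slen <- nchar(REFDB$records$sequence[1])
  span_s <- ceiling(0.7 * slen)
  row <- function(pident, evalue) {
    sprintf("q1\t%s\t%s\t70\t10\t0\t1\t70\t1\t%d\t%s\t50.0",
            rid, pident, span_s, evalue)
  }
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(row("29.9", "1e-3"), path)
  ann <- import_external_hits(path, REFDB, thresholds(), qlen)
  expect_equal(sum(ann$count), 0L)

  writeLines(row("30.0", "1e-3"), path)
  ann <- import_external_hits(path, REFDB, thresholds(), qlen)
  expect_equal(sum(ann$count), 1L)

  writeLines(row("30.0", "2e-3"), path)
  ann <- import_external_hits(path, REFDB, thresholds(), qlen)
  expect_equal(sum(ann$count), 0L)
})

test_that("tabular import handles empty, malformed and unknown-subject rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  ann <- import_external_hits(path, REFDB, thresholds(), c(q1 = 100))
  expect_true(all(ann$count == 0))

  writeLines("q1\tonly\tthree", path)
  expect_error(import_external_hits(path, REFDB, thresholds(), c(q1 = 100)),
               "line 1")

  writeLines("q1\tNOSUCH\t50\t70\t10\t0\t1\t70\t1\t70\t1e-9\t80", path)
  expect_warning(
    ann <- import_external_hits(path, REFDB, thresholds(), c(q1 = 100)),
    "NOSUCH")
  expect_true(all(ann$count == 0))
})

test_that("import of the built-in aligner's own export reproduces the annotation", {
  prot <- make_small_proteome(c("ArAT", "amiE"), identity = 55, seed = 31)
  ann <- search_homologs(prot, REFDB, strain_id = "s1")
  expect_gt(nrow(ann$hits), 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_hits_tabular(ann, path)
  ann2 <- import_external_hits(path, REFDB, thresholds(),
                               setNames(nchar(prot), names(prot)),
                               strain_id = "s1")
  expect_equal(ann2$count, ann$count)
  expect_equal(ann2$best_identity, ann$best_identity)
  expect_equal(ann2$best_subject, ann$best_subject)
  key <- function(a) sort(paste(a$hits$enzyme, a$hits$query_id,
                                a$hits$subject_id))
  expect_equal(key(ann2), key(ann))
})

test_that("unique_best_family restricts each query to one family", {
  # a query similar to two families: mutate an ArAT reference lightly and
  # register it as both families' neighborhoods via the LDH duplicate
  prot <- make_small_proteome("fldH", identity = 80, decoys = 0, seed = 55)
  ann_all <- search_homologs(prot, REFDB, thresholds(20, 10, 30, 30))
  ann_uni <- search_homologs(prot, REFDB, thresholds(20, 10, 30, 30),
                             unique_best_family = TRUE)
  per_query <- table(unique(ann_uni$hits[c("query_id", "enzyme")])$query_id)
  expect_true(all(per_query <= 1) || nrow(ann_uni$hits) == 0)
  expect_lte(nrow(ann_uni$hits), nrow(ann_all$hits))
})

test_that("annotation count equals distinct passing queries per family", {
  prot <- make_small_proteome(c("ArAT", "ArAT", "LDH"), identity = 60,
                              seed = 91)
  ann <- search_homologs(prot, REFDB, strain_id = "s")
  for (e in names(ann$count)) {
    he <- ann$hits[ann$hits$enzyme == e, ]
    expect_equal(ann$count[[e]], length(unique(he$query_id)))
    if (ann$count[[e]] > 0) expect_false(is.na(ann$best_identity[[e]]))
  }
  expect_equal(ann$count[["ArAT"]], 2L)
})
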