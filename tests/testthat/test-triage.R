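fixture_result <- table2_triage()
fixture_tab <- read_table2()

test_that("fixture triage reproduces the published per-patient outcomes", {
  dx <- fixture_tab |> dplyr::distinct(patient_id, dx)
  got <- fixture_result$reports |>
    dplyr::inner_join(dx, by = "patient_id") |>
    dplyr::mutate(expect = ifelse(dx == "Yes", "positive", "inconclusive"))
  expect_equal(nrow(got), 45L)
  expect_equal(got$category, got$expect)
})

test_that("rule arms behave as specified on representative patients", {
  cat_of <- function(id) {
    fixture_result$reports$category[fixture_result$reports$patient_id == id]
  }
  expect_equal(cat_of("59"), "positive")      # het P, AD registered, fit
  expect_equal(cat_of("548"), "positive")     # hom LP, AR registered
  expect_equal(cat_of("206"), "positive")     # LP + VUS(2 moderate) comp het
  expect_equal(cat_of("62"), "positive")      # het P in digenic entry
  expect_equal(cat_of("411"), "inconclusive") # P in literature candidate
  expect_equal(cat_of("105"), "inconclusive") # two VUS, AR registered
  expect_equal(cat_of("860"), "inconclusive") # het VUS, X-linked registered

  reported_206 <- fixture_result$reports$reported[[
    which(fixture_result$reports$patient_id == "206")]]
  expect_setequal(reported_206$role, c("primary", "comp_het_partner"))
  expect_true("VUS" %in% reported_206$tier)
})

test_that("comp-het VUS with at most one moderate criterion is inconclusive", {
  snap <- one_entry_snapshot(gene = "PTPN23", disease_id = "618890",
                             inheritance = "AR")
  v <- tibble::tibble(
    patient_id = "x", gene = "PTPN23", transcript = "NM_015466.3",
    hgvs_c = c("c.345del", "c.4052A>G"),
    zygosity = "heterozygous", allele_origin = "unknown",
    tier = c("LP", "VUS"), moderate_count = c(0L, 1L)) |>
    annotate_variants()
  rep1 <- triage_case(v, snap)
  expect_equal(rep1$category, "inconclusive")
  v$moderate_count[2] <- 2L
  rep2 <- triage_case(v, snap)
  expect_equal(rep2$category, "positive")
})

test_that("below-threshold phenotype fit demotes P/LP to inconclusive", {
  snap <- one_entry_snapshot()
  v <- tibble::tibble(
    patient_id = "x", gene = "DLG4", transcript = "NM_001365.4",
    hgvs_c = "c.1608-2A>G", zygosity = "heterozygous",
    allele_origin = "unknown", tier = "LP", moderate_count = 0L) |>
    annotate_variants()
  fit <- triage_case(v, snap,
                     similarity = tibble::tibble(disease_id = "618793",
                                                 score = 8))
  unfit <- triage_case(v, snap,
                       similarity = tibble::tibble(disease_id = "618793",
                                                   score = 3))
  expect_equal(fit$category, "positive")
  expect_equal(unfit$category, "inconclusive")
  expect_match(unfit$rule_citations, "phenotyp")
})

test_that("patients with no variants or unknown genes triage negative", {
  snap <- one_entry_snapshot()
  none <- triage_case(tibble::tibble(
    patient_id = character(), gene = character(),
    variant_key = character(), zygosity = character(),
    allele_origin = character(), tier = character()), snap)
  expect_equal(none$category, "negative")

  v <- tibble::tibble(
    patient_id = "x", gene = "NOSUCH", transcript = "NM_1.1",
    hgvs_c = "c.1A>G", zygosity = "heterozygous",
    allele_origin = "unknown", tier = "P", moderate_count = 0L) |>
    annotate_variants()
  expect_warning(rep <- triage_case(v, snap), "absent from snapshot")
  expect_equal(rep$category, "negative")
})

test_that("categories partition the cohort and ignore input order", {
  counts <- fixture_result$summary$by_category
  expect_equal(sum(counts$patients), nrow(fixture_result$reports))

  tab <- fixture_tab
  variants <- tab |>
    dplyr::select(patient_id, gene, transcript, hgvs_c, zygosity,
                  allele_origin, tier, moderate_count) |>
    annotate_variants()
  kc <- table2_knowledge(tab)
  set.seed(5)
  shuffled <- variants[sample(nrow(variants)), ]
  res2 <- triage_cohort(shuffled, kc$snapshot, phenotypes = kc$phenotypes,
                        ontology = kc$ontology)
  merged <- dplyr::inner_join(
    fixture_result$reports |> dplyr::select(patient_id, a = category),
    res2$reports |> dplyr::select(patient_id, b = category),
    by = "patient_id")
  expect_equal(merged$a, merged$b)
})

test_that("secondary findings are flagged for P/LP only and never drive category", {
  snap <- one_entry_snapshot()
  v <- tibble::tibble(
    patient_id = "x", gene = c("DLG4", "BRCA2", "TP53"),
    transcript = "NM_1.1",
    hgvs_c = c("c.1608-2A>G", "c.100C>T", "c.200C>T"),
    zygosity = "heterozygous", allele_origin = "unknown",
    tier = c("LP", "P", "VUS"), moderate_count = 0L) |>
    annotate_variants()
  res <- suppressWarnings(triage_cohort(v, snap,
                                        sf_genes = c("BRCA2", "TP53")))
  rep <- res$reports$reported[[1]]
  sf <- rep[rep$role == "secondary_finding", ]
  expect_equal(sf$gene, "BRCA2")          # the VUS in TP53 is not flagged
  expect_equal(res$reports$category, "positive")

  res0 <- suppressWarnings(triage_cohort(v, snap, sf_genes = character(0)))
  expect_false("secondary_finding" %in%
                 res0$reports$reported[[1]]$role)
})

test_that("tidy and glance expose the reports in broom shape", {
  td <- tidy(fixture_result)
  expect_true(all(c("patient_id", "category", "variant_key", "role") %in%
                    names(td)))
  gl <- glance(fixture_result)
  expect_equal(gl$n_patients, 45L)
  expect_equal(gl$positive + gl$inconclusive + gl$negative, 45)
  p <- ggplot2::ggplot_build(autoplot(fixture_result))
  expect_s3_class(p, "ggplot_built")
})
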