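test_that("a new gene-disease entry flips a negative case to positive", {
  sc <- dlg4_scenario()
  state <- new_cohort_state(sc$variants, sc$phenotypes, sc$old_snap,
                            sc$ontology, date = sc$old_snap$date)
  expect_equal(state$reports$category, "negative")
  expect_equal(state$reports$report_date, as.Date("2019-11-26"))

  delta <- diff_snapshots(sc$old_snap, sc$new_snap)
  res <- daily_run(state, delta, sc$new_snap, run_date = "2020-02-26")
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$trigger, "new_gene_disease")
  expect_true(res$events$new_tier %in% c("P", "LP"))
  expect_equal(res$state$reports$category, "positive")

  m <- cohort_metrics(res$state$events, res$state$first_report,
                      res$state$diagnoses)
  expect_equal(m$mean_years, 92 / 365.25, tolerance = 1e-9)
})

test_that("the daily run is idempotent and rejects out-of-order deltas", {
  sc <- dlg4_scenario()
  state <- new_cohort_state(sc$variants, sc$phenotypes, sc$old_snap,
                            sc$ontology, date = sc$old_snap$date)
  delta <- diff_snapshots(sc$old_snap, sc$new_snap)
  first <- daily_run(state, delta, sc$new_snap, run_date = "2020-02-26")
  second <- daily_run(first$state, delta, sc$new_snap,
                      run_date = "2020-02-26")
  expect_equal(nrow(second$events), 0L)

  expect_error(
    daily_run(state, delta, sc$new_snap, run_date = "2020-02-25"),
    "ordering")
  empty_delta <- diff_snapshots(sc$old_snap, sc$old_snap)
  none <- daily_run(state, empty_delta, sc$old_snap,
                    run_date = sc$old_snap$date)
  expect_equal(nrow(none$events), 0L)
})

test_that("eligibility keeps undiagnosed cases and matches a brute-force filter", {
  reports <- tibble::tibble(
    patient_id = sprintf("p%d", 1:30),
    category = sample(c("positive", "inconclusive", "negative"), 30,
                      replace = TRUE))
  got <- eligible_cases(reports)
  brute <- reports$patient_id[vapply(
    seq_len(nrow(reports)),
    function(i) reports$category[i] %in% c("negative", "inconclusive"),
    logical(1))]
  expect_setequal(got, brute)
  expect_false(any(reports$patient_id[reports$category == "positive"]
                   %in% got))
})

test_that("exclusion suppresses re-emission until the evidence changes", {
  sc <- dlg4_scenario()
  state <- new_cohort_state(sc$variants, sc$phenotypes, sc$old_snap,
                            sc$ontology, date = sc$old_snap$date)
  delta <- diff_snapshots(sc$old_snap, sc$new_snap)
  res <- daily_run(state, delta, sc$new_snap, run_date = "2020-02-26",
                   auto_confirm = FALSE)
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$state$reports$category, "negative")  # awaiting review

  st <- record_review(res$state, "345", res$events$variant_key,
                      "excluded", date = "2020-02-27")
  # same evidence state on a forced rescan: suppressed
  rescan <- daily_run(st, delta, sc$new_snap, run_date = "2020-02-26",
                      full_scan = TRUE, auto_confirm = FALSE)
  expect_equal(nrow(rescan$events), 0L)

  # a new assertion for the variant changes the fingerprint: re-emitted
  snap3 <- sc$new_snap
  snap3$date <- as.Date("2020-03-05")
  snap3$assertions <- tibble::tibble(
    variant_key = res$events$variant_key, asserted_class = "LP",
    protein_residue = NA_character_, source = "new paper",
    assertion_date = as.Date("2020-03-05"))
  delta3 <- diff_snapshots(sc$new_snap, snap3)
  res3 <- daily_run(st, delta3, snap3, run_date = "2020-03-05",
                    auto_confirm = FALSE)
  expect_equal(nrow(res3$events), 1L)

  # confirmation finalises the report and removes the case from the loop
  st4 <- record_review(res3$state, "345", res$events$variant_key,
                       "confirmed", date = "2020-03-06")
  expect_equal(st4$reports$category, "positive")
  expect_false("345" %in% eligible_cases(st4$reports))
  expect_error(record_review(st4, "345", "nope|NM|c.1A>G", "excluded"),
               "no emitted event")
})

test_that("phenotype updates rescore similarity and emit VUS flags", {
  # VUS in a registered entry, phenotype initially too sparse to flag
  terms <- tibble::tibble(id = c("R", "A", "B", "A1", "A2", "B1"))
  edges <- tibble::tibble(child = c("A", "B", "A1", "A2", "B1"),
                          parent = c("R", "R", "A", "A", "B"))
  annotations <- tibble::tibble(
    disease_id = c("600100", "600100", "600100", "600101"),
    term = c("A", "A1", "A2", "B1"))
  ontology <- hpo_ontology(terms, edges, annotations)
  snap <- kb_snapshot("2020-01-01", tibble::tibble(
    gene = "GENEA", disease_id = "600100", disease_name = "disorder A",
    inheritance = "AD", registration = "omim_registered",
    hpo_profile = list(c("A", "A1", "A2")),
    entry_date = as.Date("2020-01-01"), lof_mechanism = FALSE,
    missense_constrained = FALSE, digenic = FALSE))
  variants <- tibble::tibble(
    patient_id = "p1", gene = "GENEA", transcript = "NM_1.1",
    hgvs_c = "c.100G>A", hgvs_p = "p.Gly34Arg",
    zygosity = "heterozygous", allele_origin = "unknown",
    insilico = "none", nmd_predicted = NA, segregation = FALSE)
  phenotypes <- tibble::tibble(patient_id = "p1", term = "B1")
  state <- new_cohort_state(variants, phenotypes, snap, ontology)
  expect_equal(state$variants$tier, "VUS")
  expect_equal(state$reports$category, "negative")  # no phenotype fit yet
  base_score <- similarity_score("B1", c("A", "A1", "A2"), ontology)$score
  expect_lt(base_score, 5)

  res <- phenotype_update(state, "p1", c("A2", "A"), date = "2020-02-01")
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$trigger, "phenotype_update")
  expect_gte(res$events$similarity_score, 5)
  expect_equal(res$state$reports$category, "inconclusive")

  # unknown terms only: warning, no change
  expect_warning(
    res2 <- phenotype_update(res$state, "p1", "ZZZ", date = "2020-02-02"),
    "unknown terms")
  expect_equal(nrow(res2$events), 0L)
})

test_that("cohort metrics compute intervals in years with validation", {
  events <- tibble::tibble(
    event_date = as.Date(c("2020-01-10", "2020-01-10", "2020-02-01")),
    patient_id = c("a", "b", "a"), variant_key = "k",
    old_tier = NA_character_, new_tier = "P",
    similarity_score = 10, trigger = "new_gene_disease",
    fingerprint = "f")
  first <- tibble::tibble(patient_id = c("a", "b"),
                          first_report_date = as.Date("2019-10-12"))
  dx <- tibble::tibble(patient_id = "a",
                       diagnosis_date = as.Date("2020-01-10"))
  m <- cohort_metrics(events, first, dx)
  expect_equal(nrow(m$per_day), 2L)
  expect_equal(m$per_day$variants, c(2L, 1L))
  expect_equal(m$per_day$patients, c(2L, 1L))
  expect_equal(m$mean_years, 90 / 365.25)
  expect_true(all(diff(m$cumulative$diagnosed) >= 0))

  bad_dx <- tibble::tibble(patient_id = "a",
                           diagnosis_date = as.Date("2019-01-01"))
  expect_error(cohort_metrics(events, first, bad_dx), "data error")
})

test_that("event logs and ledgers round-trip through disk", {
  events <- tibble::tibble(
    event_date = as.Date("2020-01-10"), patient_id = "a",
    variant_key = "G|NM_1.1|c.1A>G", old_tier = NA_character_,
    new_tier = "LP", similarity_score = 7.25,
    trigger = "assertion_update", fingerprint = "abc|def|1|t")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_event_log(events, ep)
  expect_equal(as.data.frame(read_event_log(ep)), as.data.frame(events))

  ledger <- tibble::tibble(
    patient_id = "a", variant_key = "G|NM_1.1|c.1A>G",
    decision = "excluded", decision_date = as.Date("2020-01-11"),
    fingerprint = "abc|def|1|t")
  lp <- withr::local_tempfile(fileext = ".json")
  write_ledger(ledger, lp)
  expect_equal(as.data.frame(read_ledger(lp)), as.data.frame(ledger))
})
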