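test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- small_replay_config(seed = 9)
  skeleton <- make_toy_ontology()
  corpus <- make_disease_corpus(skeleton, 50, seed = 3)
  a <- generate_cohort(cfg, corpus, skeleton)
  b <- generate_cohort(cfg, corpus, skeleton)
  expect_identical(a, b)
  expect_error(simulation_config(n_patients = 10), "seed")
})

test_that("noise-free plantable patients match their disease profile exactly", {
  cfg <- simulation_config(n_patients = 40, timeline_days = 90,
                           frac_plantable = 1, noise_add_terms = 0,
                           noise_drop_prob = 0, seed = 21)
  skeleton <- make_toy_ontology()
  corpus <- make_disease_corpus(skeleton, 50, seed = 3)
  ont <- hpo_ontology(skeleton$terms, skeleton$edges, corpus$annotations)
  cohort <- generate_cohort(cfg, corpus, skeleton)
  for (i in seq_len(10)) {
    gt <- cohort$ground_truth[i, ]
    profile <- corpus$diseases$hpo_profile[[
      which(corpus$diseases$disease_id == gt$disease_id)]]
    terms <- cohort$phenotypes$term[
      cohort$phenotypes$patient_id == gt$patient_id]
    expect_setequal(terms, profile)
    expect_equal(similarity_score(terms, profile, ont)$score, 10)
  }
})

test_that("background phenotype sizes track the configured distribution", {
  cfg <- simulation_config(n_patients = 150, timeline_days = 90,
                           frac_plantable = 0, seed = 33)
  skeleton <- make_toy_ontology()
  corpus <- make_disease_corpus(skeleton, 50, seed = 3)
  cohort <- generate_cohort(cfg, corpus, skeleton)
  sizes <- cohort$phenotypes |> dplyr::count(patient_id)
  expect_equal(mean(sizes$n), cfg$hpo_mean,
               tolerance = 3 * cfg$hpo_sd / sqrt(150) / cfg$hpo_mean)
})

test_that("discovery events follow the configured Poisson rate", {
  skeleton <- make_toy_ontology()
  corpus <- make_disease_corpus(skeleton, 50, seed = 3)
  for (seed in c(1, 2, 3)) {
    cfg <- simulation_config(n_patients = 10, timeline_days = 365,
                             frac_plantable = 0.5, frac_undiscovered = 0.5,
                             variant_assertion_rate = 0, seed = seed)
    cohort <- generate_cohort(cfg, corpus, skeleton)
    tl <- generate_kb_timeline(cfg, cohort$ground_truth, corpus, skeleton)
    final <- tl$snapshots[[length(tl$snapshots)]]
    baseline <- tl$snapshots[[1]]
    n_events <- nrow(final$entries) - nrow(baseline$entries)
    expect_lt(abs(n_events - 250), 3 * sqrt(250) + 1)
  }
})

test_that("zero rates and no planted discoveries freeze the knowledge base", {
  cfg <- simulation_config(n_patients = 10, timeline_days = 120,
                           gene_discovery_rate = 0,
                           variant_assertion_rate = 0,
                           frac_undiscovered = 0, seed = 4)
  skeleton <- make_toy_ontology()
  corpus <- make_disease_corpus(skeleton, 50, seed = 3)
  cohort <- generate_cohort(cfg, corpus, skeleton)
  tl <- generate_kb_timeline(cfg, cohort$ground_truth, corpus, skeleton)
  expect_equal(length(tl$snapshots), 1L)
})

test_that("a planted discovery enters the snapshot exactly on its day", {
  cfg <- simulation_config(n_patients = 20, timeline_days = 180,
                           frac_plantable = 1, frac_undiscovered = 1,
                           variant_assertion_rate = 0,
                           noise_add_terms = 0, seed = 12)
  skeleton <- make_toy_ontology()
  corpus <- make_disease_corpus(skeleton, 50, seed = 3)
  cohort <- generate_cohort(cfg, corpus, skeleton)
  tl <- generate_kb_timeline(cfg, cohort$ground_truth, corpus, skeleton)
  gt <- tl$ground_truth[tl$ground_truth$undiscovered, ][1, ]
  dates <- as.Date(purrr::map_dbl(tl$snapshots, "date"),
                   origin = "1970-01-01")
  k <- which(dates == gt$discovery_date)
  expect_length(k, 1L)
  d <- diff_snapshots(tl$snapshots[[k - 1]], tl$snapshots[[k]])
  expect_true(gt$disease_id %in% d$added_entries$disease_id)
  before <- tl$snapshots[[k - 1]]
  expect_false(gt$disease_id %in% before$entries$disease_id)
})

test_that("replay is deterministic and recovers planted diagnoses", {
  cfg <- small_replay_config(seed = 42)
  r1 <- replay(cfg)
  r2 <- replay(cfg)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$recovery$diagnosed, r2$recovery$diagnosed)
  expect_equal(r1$recall, 1.0)
  expect_equal(r1$false_early, 0L)
  gl <- glance(r1)
  expect_equal(gl$n_patients, 12L)
  p <- ggplot2::ggplot_build(autoplot(r1))
  expect_s3_class(p, "ggplot_built")
})

test_that("delta-scoped reanalysis loses nothing against a full scan", {
  cfg <- small_replay_config(seed = 8)
  scoped <- replay(cfg)
  full <- replay(cfg, full_scan = TRUE)
  expect_identical(
    scoped$events[, c("event_date", "patient_id", "variant_key",
                      "new_tier")],
    full$events[, c("event_date", "patient_id", "variant_key",
                    "new_tier")])
})
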