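test_that("criterion assignment follows the evidence rules", {
  entry <- one_entry_snapshot()$entries[1, ]

  # truncating, population-absent, de novo variant in a LoF gene
  a <- evaluate_criteria(
    "frameshift",
    evidence_facts(de_novo = TRUE),
    entry)
  expect_setequal(a$code, c("PVS1", "PS2", "PM2"))
  expect_equal(a$applied_strength[a$code == "PVS1"], "very_strong")
  expect_equal(a$applied_strength[a$code == "PM2"], "supporting")
  expect_equal(combine_criteria(a), "P")

  # decay-escaping transcript downgrades the null-variant criterion
  a2 <- evaluate_criteria(
    "stop_gain", evidence_facts(nmd_predicted = FALSE), entry)
  expect_equal(a2$applied_strength[a2$code == "PVS1"], "moderate")

  # common variant: stand-alone benign only
  a3 <- evaluate_criteria("missense",
                          evidence_facts(population_af = 0.12), entry)
  expect_equal(a3$code, "BA1")
  expect_equal(combine_criteria(a3), "B")

  # missense with no facts beyond a recorded frequency above PM2
  a4 <- evaluate_criteria("missense",
                          evidence_facts(population_af = 5e-4), entry)
  expect_equal(nrow(a4), 0L)
  expect_equal(combine_criteria(a4), "VUS")

  # recessive in-trans support requires recessive inheritance
  ar_entry <- one_entry_snapshot(inheritance = "AR")$entries[1, ]
  a5 <- evaluate_criteria("missense",
                          evidence_facts(in_trans_with_plp = TRUE),
                          ar_entry)
  expect_true("PM3" %in% a5$code)
  a6 <- evaluate_criteria("missense",
                          evidence_facts(in_trans_with_plp = TRUE), entry)
  expect_false("PM3" %in% a6$code)

  expect_error(
    evaluate_criteria("missense",
                      evidence_facts(de_novo = TRUE, inherited = TRUE),
                      entry),
    "conflict")
})

test_that("PM2 strength and thresholds are configurable", {
  entry <- one_entry_snapshot()$entries[1, ]
  cfg <- acmg_config(pm2_strength = "moderate")
  a <- evaluate_criteria("canonical_splice", evidence_facts(), entry, cfg)
  expect_equal(a$applied_strength[a$code == "PM2"], "moderate")
  expect_equal(combine_criteria(a), "LP")   # very strong + 1 moderate

  ar_entry <- one_entry_snapshot(inheritance = "AR")$entries[1, ]
  a_dom <- evaluate_criteria("missense",
                             evidence_facts(population_af = 5e-5), entry)
  a_rec <- evaluate_criteria("missense",
                             evidence_facts(population_af = 5e-5), ar_entry)
  expect_false("PM2" %in% a_dom$code)   # above dominant ceiling
  expect_true("PM2" %in% a_rec$code)    # below recessive ceiling
})

test_that("combining matches the spelled-out guideline examples", {
  expect_equal(combine_criteria(assignments_from_counts(0, 0, 0, 0, 0, 0, 0)),
               "VUS")
  expect_equal(combine_criteria(assignments_from_counts(1, 1, 0, 1, 0, 0, 0)),
               "P")
  expect_equal(combine_criteria(assignments_from_counts(1, 0, 1, 0, 0, 0, 0)),
               "LP")
  expect_equal(combine_criteria(assignments_from_counts(0, 0, 0, 0, 1, 0, 0)),
               "B")
  expect_equal(combine_criteria(assignments_from_counts(0, 1, 0, 0, 0, 1, 0)),
               "VUS")   # conflicting strong evidence
  expect_equal(combine_criteria(assignments_from_counts(0, 0, 0, 0, 0, 1, 1)),
               "LB")
})

test_that("moderate pathogenic criteria are counted exactly", {
  expect_equal(count_moderate_pathogenic(
    assignments_from_counts(0, 0, 2, 0, 0, 0, 0)), 2L)
  expect_equal(count_moderate_pathogenic(
    assignments_from_counts(0, 0, 0, 1, 0, 0, 0)), 0L)
  set.seed(11)
  for (i in 1:25) {
    cnt <- sample(0:3, 7, replace = TRUE)
    a <- assignments_from_counts(cnt[1], cnt[2], cnt[3], cnt[4],
                                 cnt[5], cnt[6], cnt[7])
    expect_equal(count_moderate_pathogenic(a),
                 if (is.null(a) || nrow(a) == 0) 0L else
                   sum(a$direction == "pathogenic" &
                         a$applied_strength == "moderate"))
  }
})

test_that("adding criteria moves tiers monotonically (conflict pinned at VUS)", {
  rank_of <- function(t) match(t, c("B", "LB", "VUS", "LP", "P"))
  set.seed(31)
  strengths_p <- c("very_strong", "strong", "moderate", "supporting")
  strengths_b <- c("strong", "supporting")
  for (i in 1:200) {
    cnt <- sample(0:2, 7, replace = TRUE)
    base <- assignments_from_counts(cnt[1], cnt[2], cnt[3], cnt[4],
                                    cnt[5], cnt[6], cnt[7])
    t0 <- combine_criteria(base)
    add_p <- dplyr::bind_rows(base, tibble::tibble(
      code = "PX", direction = "pathogenic",
      applied_strength = sample(strengths_p, 1), rationale = "test"))
    t_p <- combine_criteria(add_p)
    expect_true(rank_of(t_p) >= rank_of(t0) || t_p == "VUS",
                info = paste("pathogenic add:", t0, "->", t_p))
    add_b <- dplyr::bind_rows(base, tibble::tibble(
      code = "BX", direction = "benign",
      applied_strength = sample(strengths_b, 1), rationale = "test"))
    t_b <- combine_criteria(add_b)
    expect_true(rank_of(t_b) <= rank_of(t0) || t_b == "VUS",
                info = paste("benign add:", t0, "->", t_b))
  }
})

test_that("a classification's tier is recomputable from its assignments", {
  entry <- one_entry_snapshot()$entries[1, ]
  facts <- list(
    evidence_facts(de_novo = TRUE),
    evidence_facts(insilico_consensus = "pathogenic_support"),
    evidence_facts(population_af = 0.2),
    evidence_facts(population_af = 0.02),
    evidence_facts())
  for (f in facts) {
    for (cons in c("missense", "frameshift", "inframe_indel",
                   "canonical_splice")) {
      cls <- classify_variant(cons, f, entry)
      expect_equal(combine_criteria(cls$assignments), cls$tier)
    }
  }
})
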