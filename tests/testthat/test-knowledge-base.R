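test_that("snapshot files round-trip through JSON and TSV", {
  snap <- one_entry_snapshot(date = "2020-02-26",
                             entry_date = "2020-02-26")
  snap$assertions <- tibble::tibble(
    variant_key = "DLG4|NM_001365.4|c.1608-2A>G",
    asserted_class = "LP", protein_residue = NA_character_,
    source = "curation", assertion_date = as.Date("2020-02-26"))
  snap$frequencies <- tibble::tibble(
    variant_key = "DLG4|NM_001365.4|c.1608-2A>G", af = 1e-6)

  for (ext in c("json", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_snapshot(snap, path)
    back <- read_snapshot(path, expected_date = "2020-02-26")
    expect_equal(back$date, snap$date)
    expect_equal(back$entries$gene, "DLG4")
    expect_equal(back$entries$disease_id, "618793")
    expect_equal(back$entries$hpo_profile, snap$entries$hpo_profile)
    expect_equal(back$assertions$asserted_class, "LP")
    expect_equal(back$frequencies$af, 1e-6)
    expect_error(read_snapshot(path, expected_date = "2021-01-01"),
                 "date mismatch")
  }
})

test_that("empty snapshots load and invalid records are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  write_snapshot(kb_snapshot("2020-01-01"), path)
  empty <- read_snapshot(path)
  expect_equal(nrow(empty$entries), 0L)
  expect_equal(empty$date, as.Date("2020-01-01"))

  expect_error(
    kb_snapshot("2020-01-01", frequencies = tibble::tibble(
      variant_key = "G|T|c.1A>G", af = 1.2)),
    "\\[0, 1\\]")
  expect_error(
    one_entry_snapshot(registration = "omim_registered",
                       disease_id = "PMID31278393"),
    "registration")
  expect_error(
    one_entry_snapshot(profile = character(0)),
    "hpo_profile")
  expect_error(
    one_entry_snapshot(entry_date = "2021-01-01", date = "2020-01-01"),
    "entry_date")
})

test_that("diffing an identical snapshot yields an empty delta", {
  set.seed(7)
  for (i in 1:5) {
    s <- random_snapshot("2020-06-01")
    expect_true(delta_is_empty(diff_snapshots(s, s)))
  }
})

test_that("a newly registered entry appears in the delta with its gene", {
  old <- kb_snapshot("2020-02-25")
  new <- one_entry_snapshot(date = "2020-02-26",
                            entry_date = "2020-02-26")
  d <- diff_snapshots(old, new)
  expect_equal(nrow(d$added_entries), 1L)
  expect_equal(d$added_entries$disease_id, "618793")
  expect_true("DLG4" %in% d$affected_genes)
  expect_error(diff_snapshots(new, old), "ordering")
})

test_that("delta agrees with a brute-force field comparison", {
  set.seed(99)
  for (i in 1:20) {
    old <- random_snapshot("2020-01-01", n_entries = sample(0:8, 1),
                           n_assertions = sample(0:8, 1),
                           n_freqs = sample(0:8, 1))
    new <- random_snapshot("2020-01-02", n_entries = sample(0:8, 1),
                           n_assertions = sample(0:8, 1),
                           n_freqs = sample(0:8, 1))
    d <- diff_snapshots(old, new)
    bf <- brute_force_delta(old, new)
    col <- function(x, nm) {
      if (is.null(x) || nrow(x) == 0) character(0) else x[[nm]]
    }
    expect_equal(nrow(d$added_entries), nrow(bf$added_entries))
    expect_setequal(
      paste(col(d$added_entries, "gene"),
            col(d$added_entries, "disease_id")),
      paste(col(bf$added_entries, "gene"),
            col(bf$added_entries, "disease_id")))
    expect_setequal(col(d$changed_or_added_assertions, "variant_key"),
                    col(bf$changed_assertions, "variant_key"))
    expect_setequal(col(d$changed_frequencies, "variant_key"),
                    col(bf$changed_frequencies, "variant_key"))
  }
})

test_that("affected genes compose across nested snapshots", {
  base_entries <- one_entry_snapshot("2020-01-01", gene = "AAA",
                                     disease_id = "600001")$entries
  mid_entries <- dplyr::bind_rows(
    base_entries,
    one_entry_snapshot("2020-01-02", gene = "BBB",
                       disease_id = "600002",
                       entry_date = "2020-01-02")$entries)
  top_entries <- dplyr::bind_rows(
    mid_entries,
    one_entry_snapshot("2020-01-03", gene = "CCC",
                       disease_id = "600003",
                       entry_date = "2020-01-03")$entries)
  s0 <- kb_snapshot("2020-01-01", base_entries)
  s1 <- kb_snapshot("2020-01-02", mid_entries)
  s2 <- kb_snapshot("2020-01-03", top_entries)
  expect_setequal(
    diff_snapshots(s0, s2)$affected_genes,
    union(diff_snapshots(s0, s1)$affected_genes,
          diff_snapshots(s1, s2)$affected_genes))
})

test_that("frequency updates mark genes affected only across criterion bins", {
  cfg <- acmg_config()
  old <- kb_snapshot("2020-01-01", frequencies = tibble::tibble(
    variant_key = c("AAA|T|c.1A>G", "BBB|T|c.2A>G"),
    af = c(0.02, 2e-6)))
  new <- kb_snapshot("2020-01-02", frequencies = tibble::tibble(
    variant_key = c("AAA|T|c.1A>G", "BBB|T|c.2A>G"),
    af = c(0.03, 2e-4)))           # within-bin vs PM2->above-PM2 crossing
  d <- diff_snapshots(old, new, cfg)
  expect_equal(nrow(d$changed_frequencies), 2L)
  expect_setequal(d$affected_genes, "BBB")
})
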