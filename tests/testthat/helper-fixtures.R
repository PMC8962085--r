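# shared builders for tests; everything is constructed in code

toy_fixture_ontology <- function() {
  load_ontology(
    system.file("extdata", "toy.obo", package = "varitriage"),
    system.file("extdata", "toy_corpus.tsv", package = "varitriage"))
}

# a minimal snapshot with one registered entry
one_entry_snapshot <- function(date = "2020-03-01", gene = "DLG4",
                               disease_id = "618793", inheritance = "AD",
                               registration = "omim_registered",
                               profile = c("HP:0000002", "HP:0000004"),
                               entry_date = date, lof = TRUE,
                               digenic = FALSE) {
  kb_snapshot(date, tibble::tibble(
    gene = gene, disease_id = disease_id,
    disease_name = paste0(gene, "-related disorder"),
    inheritance = inheritance, registration = registration,
    hpo_profile = list(profile), entry_date = as.Date(entry_date),
    lof_mechanism = lof, missense_constrained = FALSE, digenic = digenic))
}

# random small snapshot for property tests
random_snapshot <- function(date, n_entries = 5, n_assertions = 5,
                            n_freqs = 5) {
  genes <- sprintf("G%02d", seq_len(max(n_entries, 1)))
  entries <- if (n_entries == 0) NULL else tibble::tibble(
    gene = genes[seq_len(n_entries)],
    disease_id = as.character(sample(600000:600050, n_entries)),
    disease_name = paste0("d", seq_len(n_entries)),
    inheritance = sample(c("AD", "AR", "XL", "AD_AR"), n_entries, TRUE),
    registration = "omim_registered",
    hpo_profile = purrr::map(seq_len(n_entries),
                             ~ sprintf("HP:%07d", sample(1:20, 3))),
    entry_date = as.Date(date) - sample(0:100, n_entries, TRUE),
    lof_mechanism = sample(c(TRUE, FALSE), n_entries, TRUE),
    missense_constrained = FALSE, digenic = FALSE)
  assertions <- if (n_assertions == 0) NULL else tibble::tibble(
    variant_key = sprintf("G%02d|NM_1.1|c.%dA>G",
                          sample(seq_along(genes), n_assertions, TRUE),
                          sample(100:999, n_assertions)),
    asserted_class = sample(c("P", "LP", "VUS", "LB", "B"),
                            n_assertions, TRUE),
    protein_residue = NA_character_, source = "test",
    assertion_date = as.Date(date) - sample(0:100, n_assertions, TRUE))
  freqs <- if (n_freqs == 0) NULL else tibble::tibble(
    variant_key = sprintf("G%02d|NM_1.1|c.%dC>T",
                          sample(seq_along(genes), n_freqs, TRUE),
                          sample(100:999, n_freqs)),
    af = round(stats::runif(n_freqs), 6))
  dedupe <- function(x) {
    if (is.null(x)) x else dplyr::distinct(x, variant_key, .keep_all = TRUE)
  }
  kb_snapshot(date, entries, dedupe(assertions), dedupe(freqs))
}

# independent brute-force comparator for snapshot diffs
brute_force_delta <- function(old, new) {
  added_entries <- list()
  for (i in seq_len(nrow(new$entries))) {
    e <- new$entries[i, ]
    j <- which(old$entries$gene == e$gene &
                 old$entries$disease_id == e$disease_id)
    same <- length(j) == 1 &&
      identical(old$entries$disease_name[j], e$disease_name) &&
      identical(old$entries$inheritance[j], e$inheritance) &&
      identical(old$entries$registration[j], e$registration) &&
      setequal(old$entries$hpo_profile[[j]], e$hpo_profile[[1]]) &&
      identical(old$entries$entry_date[j], e$entry_date) &&
      identical(old$entries$lof_mechanism[j], e$lof_mechanism) &&
      identical(old$entries$digenic[j], e$digenic)
    if (!same) added_entries[[length(added_entries) + 1L]] <- e
  }
  changed_assertions <- list()
  for (i in seq_len(nrow(new$assertions))) {
    a <- new$assertions[i, ]
    j <- which(old$assertions$variant_key == a$variant_key)
    same <- length(j) == 1 &&
      identical(old$assertions$asserted_class[j], a$asserted_class) &&
      identical(old$assertions$source[j], a$source) &&
      identical(old$assertions$assertion_date[j], a$assertion_date)
    if (!same) changed_assertions[[length(changed_assertions) + 1L]] <- a
  }
  changed_freqs <- list()
  for (i in seq_len(nrow(new$frequencies))) {
    f <- new$frequencies[i, ]
    j <- which(old$frequencies$variant_key == f$variant_key)
    if (length(j) == 0 || old$frequencies$af[j] != f$af) {
      changed_freqs[[length(changed_freqs) + 1L]] <- f
    }
  }
  list(added_entries = dplyr::bind_rows(added_entries),
       changed_assertions = dplyr::bind_rows(changed_assertions),
       changed_frequencies = dplyr::bind_rows(changed_freqs))
}

# independent rule-list evaluator of the combining table
oracle_combine <- function(vs, s, m, p, ba, bs, bp) {
  meets <- function(rules, have) {
    any(vapply(rules, function(r) all(have[names(r)] >= r), logical(1)))
  }
  have <- c(vs = vs, s = s, m = m, p = p)
  p_rules <- list(c(vs = 1, s = 1), c(vs = 1, m = 2),
                  c(vs = 1, m = 1, p = 1), c(vs = 1, p = 2),
                  c(s = 2), c(s = 1, m = 3), c(s = 1, m = 2, p = 2),
                  c(s = 1, m = 1, p = 4))
  lp_rules <- list(c(vs = 1, m = 1), c(s = 1, m = 1), c(s = 1, p = 2),
                   c(m = 3), c(m = 2, p = 2), c(m = 1, p = 4))
  path <- if (meets(p_rules, have)) "P"
          else if (meets(lp_rules, have)) "LP" else NA
  ben <- if (ba >= 1 || bs >= 2) "B"
         else if ((bs >= 1 && bp >= 1) || bp >= 2) "LB" else NA
  if (!is.na(path) && !is.na(ben)) return("VUS")
  if (!is.na(path)) return(path)
  if (!is.na(ben)) return(ben)
  "VUS"
}

# build an assignment tibble from strength counts
assignments_from_counts <- function(vs, s, m, p, ba, bs, bp) {
  mk <- function(n, dir, strength) {
    if (n == 0) return(NULL)
    tibble::tibble(code = paste0(substr(dir, 1, 1), strength, seq_len(n)),
                   direction = dir, applied_strength = strength,
                   rationale = "test")
  }
  dplyr::bind_rows(
    mk(vs, "pathogenic", "very_strong"), mk(s, "pathogenic", "strong"),
    mk(m, "pathogenic", "moderate"), mk(p, "pathogenic", "supporting"),
    mk(ba, "benign", "stand_alone"), mk(bs, "benign", "strong"),
    mk(bp, "benign", "supporting"))
}

# the patient-345 style scenario: negative initial report, a new
# gene-disease entry later enables the diagnosis
dlg4_scenario <- function() {
  terms <- tibble::tibble(id = c("R", "A", "B", "A1", "A2"))
  edges <- tibble::tibble(child = c("A", "B", "A1", "A2"),
                          parent = c("R", "R", "A", "A"))
  annotations <- tibble::tibble(
    disease_id = c("618793", "618793", "100001"),
    term = c("A", "A1", "B"))
  ontology <- hpo_ontology(terms, edges, annotations)
  old_snap <- kb_snapshot("2019-11-26")
  new_snap <- one_entry_snapshot(
    date = "2020-02-26", gene = "DLG4", disease_id = "618793",
    inheritance = "AD", profile = c("A", "A1"),
    entry_date = "2020-02-26")
  variants <- tibble::tibble(
    patient_id = "345", gene = "DLG4", transcript = "NM_001365.4",
    hgvs_c = "c.1608-2A > G", hgvs_p = NA_character_,
    zygosity = "heterozygous", allele_origin = "unknown",
    insilico = "pathogenic_support", nmd_predicted = NA,
    segregation = FALSE)
  phenotypes <- tibble::tibble(patient_id = "345", term = c("A", "A1"))
  list(ontology = ontology, old_snap = old_snap, new_snap = new_snap,
       variants = variants, phenotypes = phenotypes)
}

small_replay_config <- function(seed = 42, ...) {
  simulation_config(n_patients = 12, timeline_days = 120,
                    noise_add_terms = 0, seed = seed, ...)
}
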