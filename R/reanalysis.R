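#' Initialise cohort state for the prospective reanalysis loop
#'
#' Classifies every variant against the baseline snapshot, issues each
#' patient's initial report, and packages everything the daily loop needs:
#' current tiers, phenotype term sets, latest reports, the set of already
#' flagged variants, and the review ledger.
#'
#' @param variants cohort variant tibble: `patient_id`, `gene`,
#'   `transcript`, `hgvs_c`, `zygosity`, `allele_origin`, and optionally
#'   `hgvs_p`, `insilico` ("pathogenic_support"/"benign_support"/"none"),
#'   `nmd_predicted`, `segregation` columns feeding the evidence engine.
#' @param phenotypes tibble `patient_id`, `term`.
#' @param snapshot baseline [kb_snapshot()].
#' @param ontology an [hpo_ontology()].
#' @param config an [acmg_config()].
#' @param date initial report date.
#' @return an object of class `cohort_state`.
#' @export
new_cohort_state <- function(variants, phenotypes, snapshot, ontology,
                             config = acmg_config(), date = snapshot$date) {
  variants <- annotate_variants(tibble::as_tibble(variants)) |>
    dplyr::mutate(gene = normalize_gene(.data$gene))
  for (col in c("insilico", "nmd_predicted", "segregation")) {
    if (!col %in% names(variants)) {
      variants[[col]] <- switch(col, insilico = "none",
                                nmd_predicted = NA, segregation = FALSE)
    }
  }
  variants$tier <- NA_character_
  variants$moderate_count <- 0L
  state <- structure(
    list(variants = variants,
         phenotypes = tibble::as_tibble(phenotypes),
         snapshot = snapshot, ontology = ontology, config = config,
         reports = NULL, flagged = tibble::tibble(
           patient_id = character(), variant_key = character(),
           fingerprint = character()),
         ledger = empty_ledger(),
         events = empty_events(),
         diagnoses = tibble::tibble(patient_id = character(),
                                    diagnosis_date = as.Date(character()))),
    class = "cohort_state"
  )
  state <- reclassify_genes(state, snapshot, genes = NULL)
  state <- refresh_reports(state, snapshot,
                           patients = unique(variants$patient_id),
                           date = as.Date(date))
  state$first_report <- state$reports |>
    dplyr::select("patient_id", first_report_date = "report_date")
  state
}

empty_events <- function() {
  tibble::tibble(event_date = as.Date(character()),
                 patient_id = character(), variant_key = character(),
                 old_tier = character(), new_tier = character(),
                 similarity_score = numeric(), trigger = character(),
                 fingerprint = character())
}

empty_reports <- function() {
  tibble::tibble(patient_id = character(), category = character(),
                 report_date = as.Date(character()),
                 n_reported = integer(), reported = list())
}

empty_ledger <- function() {
  tibble::tibble(patient_id = character(), variant_key = character(),
                 decision = character(),
                 decision_date = as.Date(character()),
                 fingerprint = character())
}

tier_rank <- function(tier) {
  match(tier, c("B", "LB", "VUS", "LP", "P"))
}

# evidence facts for one variant row under a snapshot + entry
variant_facts <- function(v, entry, snapshot, siblings_plp = FALSE) {
  af <- snapshot$frequencies$af[
    match(v$variant_key, snapshot$frequencies$variant_key)]
  asrt <- snapshot$assertions[
    snapshot$assertions$variant_key == v$variant_key, ]
  matching <- if (nrow(asrt) > 0 && any(asrt$asserted_class == "P")) {
    list(asserted_class = "P")
  } else NULL
  evidence_facts(
    population_af = if (length(af) == 0) NA_real_ else af,
    nmd_predicted = v$nmd_predicted,
    matching_assertion = matching,
    de_novo = v$allele_origin == "assumed_de_novo",
    inherited = v$allele_origin %in%
      c("inherited_affected_parent", "inherited_unaffected_parent"),
    in_trans_with_plp = v$allele_origin == "trans_confirmed" && siblings_plp,
    insilico_consensus = v$insilico,
    segregation_observed = isTRUE(v$segregation)
  )
}

# classify one variant against every entry of its gene; keep the most
# pathogenic outcome (an entry can only add evidence for its own disease)
classify_against_entries <- function(v, entries, snapshot, config,
                                     siblings_plp = FALSE) {
  best <- list(tier = NA_character_, moderate_count = 0L)
  if (nrow(entries) == 0) return(best)
  for (i in seq_len(nrow(entries))) {
    entry <- entries[i, ]
    facts <- variant_facts(v, entry, snapshot, siblings_plp)
    cls <- classify_variant(v$consequence, facts, entry, config)
    if (is.na(best$tier) ||
        tier_rank(cls$tier) > tier_rank(best$tier)) {
      best <- list(tier = cls$tier, moderate_count = cls$moderate_count)
    }
  }
  best
}

# recompute tiers for variants whose gene is in `genes` (NULL = all)
reclassify_genes <- function(state, snapshot, genes = NULL) {
  v <- state$variants
  idx <- if (is.null(genes)) seq_len(nrow(v)) else which(v$gene %in% genes)
  for (i in idx) {
    entries <- snapshot$entries[snapshot$entries$gene == v$gene[i], ]
    sibs <- v$tier[v$patient_id == v$patient_id[i] &
                     v$gene == v$gene[i] &
                     v$variant_key != v$variant_key[i]]
    cls <- classify_against_entries(v[i, ], entries, snapshot,
                                    state$config,
                                    siblings_plp = any(sibs %in% c("P", "LP")))
    v$tier[i] <- cls$tier
    v$moderate_count[i] <- cls$moderate_count
  }
  state$variants <- v
  state
}

# rerun triage for the given patients; update latest reports
refresh_reports <- function(state, snapshot, patients, date) {
  if (length(patients) == 0) {
    if (is.null(state$reports)) state$reports <- empty_reports()
    return(state)
  }
  classified <- state$variants |>
    dplyr::filter(.data$patient_id %in% patients, !is.na(.data$tier))
  sim <- cohort_similarity(classified, state$phenotypes, snapshot,
                           state$ontology, state$config)
  newly <- purrr::map_dfr(patients, function(id) {
    s <- if (nrow(sim) == 0) NULL else
      sim[sim$patient_id == id, c("disease_id", "score")]
    rep <- suppressWarnings(
      triage_case(classified[classified$patient_id == id, ] |>
                    dplyr::mutate(patient_id = id),
                  snapshot, similarity = s, config = state$config,
                  report_date = date))
    tibble::tibble(patient_id = id, category = rep$category,
                   report_date = date, n_reported = nrow(rep$reported_variants),
                   reported = list(rep$reported_variants))
  })
  if (is.null(state$reports)) {
    state$reports <- newly
  } else {
    state$reports <- state$reports |>
      dplyr::filter(!.data$patient_id %in% patients) |>
      dplyr::bind_rows(newly)
  }
  new_dx <- newly |>
    dplyr::filter(.data$category == "positive",
                  !.data$patient_id %in% state$diagnoses$patient_id) |>
    dplyr::transmute(.data$patient_id, diagnosis_date = date)
  state$diagnoses <- dplyr::bind_rows(state$diagnoses, new_dx)
  state
}

#' Cases eligible for daily reanalysis
#'
#' Undiagnosed cases stay in the daily loop: every case whose latest
#' report is negative, and inconclusive cases (single or multiple VUS,
#' potential compound heterozygotes of a P/LP with a VUS, P/LP in
#' candidate genes or pending phenotype confirmation). Positive cases
#' leave the loop permanently.
#'
#' @param reports tibble of latest reports with `patient_id`, `category`.
#' @return character vector of eligible patient ids.
#' @export
eligible_cases <- function(reports) {
  reports$patient_id[reports$category != "positive"]
}

#' Evidence fingerprint of a variant under a snapshot
#'
#' Canonical string over the evidence state a reviewer saw: the variant's
#' assertions, its gene's entry fields, its allele-frequency threshold bin
#' and the patient's phenotype term set. An excluded variant stays
#' suppressed exactly while this fingerprint is unchanged; any change in a
#' component is "a new change" and lifts the suppression.
#'
#' @param variant_key the variant key.
#' @param gene gene symbol.
#' @param snapshot a [kb_snapshot()].
#' @param patient_terms character vector of the patient's HPO terms.
#' @param config an [acmg_config()].
#' @return a single string.
#' @export
evidence_fingerprint <- function(variant_key, gene, snapshot, patient_terms,
                                 config = acmg_config()) {
  a <- snapshot$assertions[snapshot$assertions$variant_key == variant_key, ]
  a_sig <- paste(sort(paste(a$asserted_class, a$protein_residue, a$source,
                            a$assertion_date, sep = ",")), collapse = ";")
  e <- snapshot$entries[snapshot$entries$gene == gene, ]
  e_sig <- paste(sort(paste(
    e$disease_id, e$inheritance, e$registration,
    purrr::map_chr(e$hpo_profile, ~ paste(sort(.x), collapse = ",")),
    e$lof_mechanism, e$digenic, sep = ",")), collapse = ";")
  af <- snapshot$frequencies$af[
    match(variant_key, snapshot$frequencies$variant_key)]
  bin <- af_bin(if (length(af) == 0) NA_real_ else af, config)
  paste(a_sig, e_sig, bin, paste(sort(unique(patient_terms)), collapse = ","),
        sep = "|")
}

detect_trigger <- function(gene, delta) {
  if (gene %in% delta$added_entries$gene) return("new_gene_disease")
  gene_of_key <- function(key) sub("\\|.*$", "", key)
  if (gene %in% gene_of_key(delta$changed_or_added_assertions$variant_key)) {
    return("assertion_update")
  }
  if (gene %in% gene_of_key(delta$changed_frequencies$variant_key)) {
    return("frequency_update")
  }
  "assertion_update"
}

#' One day of the prospective reanalysis loop
#'
#' Re-evaluates the variants of eligible (undiagnosed) cases in genes
#' touched by the day's knowledge-base delta, reclassifies them, rescores
#' phenotype fit, and emits reclassification events: a variant newly
#' reaching P or LP, or a VUS whose symptom-similarity score is at or
#' above the flagging threshold and which has not been flagged before
#' under the same evidence state. Variants excluded in the review ledger
#' stay suppressed while their evidence fingerprint is unchanged. In
#' simulation mode (`auto_confirm = TRUE`) every emitted event is treated
#' as reviewer-confirmed and the case report is refreshed immediately;
#' otherwise confirmations arrive through [record_review()].
#'
#' Rerunning the same day with the same delta and ledger emits nothing new
#' (idempotence).
#'
#' @param state a [new_cohort_state()].
#' @param delta the [diff_snapshots()] of the previous and current
#'   snapshot; its end date must equal `run_date`.
#' @param new_snapshot the current [kb_snapshot()].
#' @param run_date the calendar day being processed.
#' @param full_scan re-evaluate all genes, not only delta-touched ones.
#' @param auto_confirm apply report updates without manual review
#'   (simulation mode).
#' @return list with updated `state` and the day's `events` tibble.
#' @export
daily_run <- function(state, delta, new_snapshot, run_date,
                      full_scan = FALSE, auto_confirm = TRUE) {
  stopifnot(inherits(state, "cohort_state"),
            inherits(delta, "kb_delta"),
            inherits(new_snapshot, "kb_snapshot"))
  run_date <- as.Date(run_date)
  if (delta$to != new_snapshot$date || delta$to != run_date) {
    stop("ordering error: delta must end at the run date's snapshot (",
         delta$to, " vs ", run_date, ")", call. = FALSE)
  }

  eligible <- eligible_cases(state$reports)
  genes <- if (full_scan) unique(state$variants$gene) else
    delta$affected_genes
  cand <- state$variants |>
    dplyr::filter(.data$patient_id %in% eligible, .data$gene %in% genes)

  events <- empty_events()
  if (nrow(cand) > 0) {
    old_tiers <- stats::setNames(state$variants$tier,
                                 paste(state$variants$patient_id,
                                       state$variants$variant_key))
    state <- reclassify_genes(state, new_snapshot, genes = genes)
    events <- collect_events(state, cand, old_tiers, new_snapshot,
                             run_date, delta = delta)
    state$events <- dplyr::bind_rows(state$events, events)
    state$flagged <- dplyr::bind_rows(
      state$flagged,
      events |> dplyr::filter(.data$new_tier == "VUS") |>
        dplyr::select("patient_id", "variant_key", "fingerprint")) |>
      dplyr::distinct()
    if (auto_confirm && nrow(events) > 0) {
      state <- refresh_reports(state, new_snapshot,
                               patients = unique(events$patient_id),
                               date = run_date)
    }
  }
  state$snapshot <- new_snapshot
  list(state = state, events = events)
}

# shared event-emission logic for daily_run and phenotype_update
collect_events <- function(state, cand, old_tiers, snapshot, run_date,
                           delta = NULL, trigger = NULL) {
  v <- state$variants
  sim <- cohort_similarity(v |> dplyr::filter(!is.na(.data$tier),
                                              .data$patient_id %in%
                                                unique(cand$patient_id)),
                           state$phenotypes, snapshot, state$ontology,
                           state$config)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    pid <- cand$patient_id[i]
    key <- cand$variant_key[i]
    row <- v[v$patient_id == pid & v$variant_key == key, ]
    new_tier <- row$tier
    if (is.na(new_tier)) next
    old_tier <- old_tiers[[paste(pid, key)]]
    entries <- snapshot$entries[snapshot$entries$gene == row$gene, ]
    score <- if (nrow(sim) == 0) NA_real_ else {
      s <- sim$score[sim$patient_id == pid &
                       sim$disease_id %in% entries$disease_id]
      if (length(s) == 0) NA_real_ else max(s, na.rm = TRUE)
    }
    terms <- state$phenotypes$term[state$phenotypes$patient_id == pid]
    fp <- evidence_fingerprint(key, row$gene, snapshot, terms, state$config)

    excl <- state$ledger |>
      dplyr::filter(.data$patient_id == pid, .data$variant_key == key,
                    .data$decision == "excluded")
    # an excluded variant re-surfaces exactly when its evidence changed
    if (nrow(excl) > 0 && any(excl$fingerprint == fp)) next
    resurfaced <- nrow(excl) > 0 && !any(excl$fingerprint == fp)

    emit_plp <- new_tier %in% c("P", "LP") &&
      (is.na(old_tier) || new_tier != old_tier || resurfaced)
    emit_vus <- identical(new_tier, "VUS") &&
      !is.na(score) && score >= state$config$fit_threshold &&
      (resurfaced ||
         !any(state$flagged$patient_id == pid &
                state$flagged$variant_key == key &
                state$flagged$fingerprint == fp))
    if (!emit_plp && !emit_vus) next

    out[[length(out) + 1L]] <- tibble::tibble(
      event_date = run_date, patient_id = pid, variant_key = key,
      old_tier = old_tier %||% NA_character_, new_tier = new_tier,
      similarity_score = score,
      trigger = trigger %||% detect_trigger(row$gene, delta),
      fingerprint = fp
    )
  }
  if (length(out) == 0) empty_events() else dplyr::bind_rows(out)
}

#' Record a reviewer decision for an emitted event
#'
#' Confirmed decisions finalise the report update for the case; excluded
#' decisions suppress the variant until its evidence fingerprint changes.
#'
#' @param state a `cohort_state`.
#' @param patient_id,variant_key identify the event's variant.
#' @param decision "confirmed" or "excluded".
#' @param date decision date.
#' @return updated state.
#' @export
record_review <- function(state, patient_id, variant_key,
                          decision = c("confirmed", "excluded"),
                          date = Sys.Date()) {
  decision <- match.arg(decision)
  hit <- state$events |>
    dplyr::filter(.data$patient_id == !!patient_id,
                  .data$variant_key == !!variant_key)
  if (nrow(hit) == 0) {
    stop("no emitted event for patient ", patient_id, " variant ",
         variant_key, call. = FALSE)
  }
  fp <- hit$fingerprint[nrow(hit)]
  state$ledger <- dplyr::bind_rows(
    state$ledger,
    tibble::tibble(patient_id = patient_id, variant_key = variant_key,
                   decision = decision, decision_date = as.Date(date),
                   fingerprint = fp))
  if (decision == "confirmed") {
    state <- refresh_reports(state, state$snapshot, patients = patient_id,
                             date = as.Date(date))
  }
  state
}

#' Apply a phenotype update to one case
#'
#' Physicians may submit additional phenotype terms after the initial
#' analysis; the pipeline then rescores symptom similarity for the case's
#' candidate entries. VUS variants newly crossing the flagging threshold
#' emit events with trigger `phenotype_update`. Positive (diagnosed) cases
#' are not eligible and produce no events.
#'
#' @param state a `cohort_state`.
#' @param patient_id the case.
#' @param added_terms new HPO term ids (unknown terms are dropped with a
#'   warning).
#' @param date event date.
#' @return list with updated `state` and `events`.
#' @export
phenotype_update <- function(state, patient_id, added_terms, date) {
  stopifnot(length(added_terms) > 0)
  known <- added_terms[added_terms %in% names(state$ontology$ic)]
  if (length(known) < length(added_terms)) {
    warning("dropping unknown terms: ",
            paste(setdiff(added_terms, known), collapse = ", "),
            call. = FALSE)
  }
  if (length(known) == 0) {
    return(list(state = state, events = empty_events()))
  }
  existing <- state$phenotypes$term[state$phenotypes$patient_id == patient_id]
  add <- setdiff(known, existing)
  if (length(add) > 0) {
    state$phenotypes <- dplyr::bind_rows(
      state$phenotypes,
      tibble::tibble(patient_id = patient_id, term = add))
  }
  if (!patient_id %in% eligible_cases(state$reports)) {
    return(list(state = state, events = empty_events()))
  }
  cand <- state$variants |> dplyr::filter(.data$patient_id == !!patient_id)
  old_tiers <- stats::setNames(state$variants$tier,
                               paste(state$variants$patient_id,
                                     state$variants$variant_key))
  events <- collect_events(state, cand, old_tiers, state$snapshot,
                           as.Date(date), trigger = "phenotype_update")
  # only similarity changed; restrict to VUS flag crossings
  events <- events |> dplyr::filter(.data$new_tier == "VUS")
  state$events <- dplyr::bind_rows(state$events, events)
  state$flagged <- dplyr::bind_rows(
    state$flagged,
    events |> dplyr::select("patient_id", "variant_key", "fingerprint")) |>
    dplyr::distinct()
  if (nrow(events) > 0) {
    state <- refresh_reports(state, state$snapshot, patients = patient_id,
                             date = as.Date(date))
  }
  list(state = state, events = events)
}

#' Cohort-level reanalysis metrics
#'
#' Summarises a reanalysis run: newly reclassified variants and distinct
#' patients per day (over days with at least one event), the cumulative
#' diagnosed curve, and the time from each case's first report to its
#' confirming event, in years (365.25 days), with mean and standard
#' deviation.
#'
#' @param events event tibble (from `daily_run`/`cohort_state$events`).
#' @param first_reports tibble `patient_id`, `first_report_date`.
#' @param diagnoses tibble `patient_id`, `diagnosis_date`.
#' @return object of class `cohort_metrics`: `per_day`, `cumulative`,
#'   `time_to_diagnosis`, `mean_years`, `sd_years`,
#'   `mean_variants_per_day`, `mean_patients_per_day`.
#' @export
cohort_metrics <- function(events, first_reports, diagnoses) {
  per_day <- events |>
    dplyr::group_by(.data$event_date) |>
    dplyr::summarise(variants = dplyr::n(),
                     patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop")
  dx <- diagnoses |>
    dplyr::inner_join(first_reports, by = "patient_id")
  if (nrow(dx) > 0 && any(dx$diagnosis_date < dx$first_report_date)) {
    stop("data error: diagnosis event precedes first report", call. = FALSE)
  }
  ttd <- dx |>
    dplyr::mutate(years = as.numeric(.data$diagnosis_date -
                                       .data$first_report_date) / 365.25)
  cumulative <- dx |>
    dplyr::count(.data$diagnosis_date) |>
    dplyr::arrange(.data$diagnosis_date) |>
    dplyr::mutate(diagnosed = cumsum(.data$n)) |>
    dplyr::select("diagnosis_date", "diagnosed")
  structure(
    list(per_day = per_day, cumulative = cumulative,
         time_to_diagnosis = ttd,
         mean_years = if (nrow(ttd)) mean(ttd$years) else NA_real_,
         sd_years = if (nrow(ttd) > 1) stats::sd(ttd$years) else NA_real_,
         mean_variants_per_day = if (nrow(per_day)) mean(per_day$variants)
                                 else NA_real_,
         mean_patients_per_day = if (nrow(per_day)) mean(per_day$patients)
                                 else NA_real_),
    class = "cohort_metrics"
  )
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat(sprintf(
    "<cohort_metrics> %.1f variants / %.1f patients per event-day; %d diagnosed; time to diagnosis %.2f +/- %.2f years\n",
    x$mean_variants_per_day %||% NA, x$mean_patients_per_day %||% NA,
    nrow(x$time_to_diagnosis), x$mean_years, x$sd_years))
  invisible(x)
}

#' Write / read the append-only event log
#'
#' @param events event tibble.
#' @param path TSV file.
#' @return `path` / event tibble.
#' @export
write_event_log <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    event_date = readr::col_date(),
                    patient_id = readr::col_character(),
                    variant_key = readr::col_character(),
                    old_tier = readr::col_character(),
                    new_tier = readr::col_character(),
                    similarity_score = readr::col_double(),
                    trigger = readr::col_character(),
                    fingerprint = readr::col_character()))
}

#' Write / read the review ledger
#' @param ledger ledger tibble.
#' @param path JSON file.
#' @return `path` / ledger tibble.
#' @export
write_ledger <- function(ledger, path) {
  doc <- ledger |> dplyr::mutate(decision_date = format(.data$decision_date))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(doc) == 0) return(empty_ledger())
  tibble::as_tibble(doc) |>
    dplyr::mutate(decision_date = as.Date(.data$decision_date))
}

#' @export
print.cohort_state <- function(x, ...) {
  cat("<cohort_state>", dplyr::n_distinct(x$variants$patient_id),
      "patients,", nrow(x$variants), "variants;",
      nrow(x$diagnoses), "diagnosed;", nrow(x$events), "events\n")
  invisible(x)
}
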