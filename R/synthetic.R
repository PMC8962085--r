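#' Simulation configuration
#'
#' Conditions for the synthetic cohort and knowledge-base timeline. The
#' discovery-rate defaults reflect the reported pace of the field
#' (roughly 250 novel gene-disease and 9200 novel variant-disease
#' associations per year); the phenotype-size distribution matches a
#' clinical neurodevelopmental cohort (8.6 +/- 4.6 HPO terms per
#' patient).
#'
#' @param n_patients cohort size.
#' @param start_date first day of the study window.
#' @param timeline_days length of the simulated window in days.
#' @param enrollment_days patients enrol uniformly over the first this
#'   many days (default: the whole window).
#' @param gene_discovery_rate new gene-disease entries per year.
#' @param variant_assertion_rate new variant assertions per year.
#' @param frac_plantable fraction of patients carrying a plantable causal
#'   variant.
#' @param frac_undiscovered fraction of plantable patients whose causal
#'   gene-disease entry is not yet in the knowledge base at baseline and
#'   enters during the timeline.
#' @param noise_add_terms mean number of unrelated phenotype terms added
#'   per patient (Poisson); 0 = noise-free.
#' @param noise_drop_prob probability of dropping each profile term from a
#'   plantable patient's phenotype.
#' @param hpo_mean,hpo_sd target phenotype-size distribution for
#'   patients without a planted profile.
#' @param seed mandatory random seed (integer below 2^31).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 200,
                              start_date = as.Date("2019-04-01"),
                              timeline_days = 730,
                              enrollment_days = timeline_days,
                              gene_discovery_rate = 250,
                              variant_assertion_rate = 9200,
                              frac_plantable = 0.5,
                              frac_undiscovered = 0.5,
                              noise_add_terms = 2,
                              noise_drop_prob = 0,
                              hpo_mean = 8.6, hpo_sd = 4.6,
                              seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_patients >= 1, timeline_days >= 1,
            enrollment_days >= 1, enrollment_days <= timeline_days,
            gene_discovery_rate >= 0, variant_assertion_rate >= 0,
            frac_plantable >= 0, frac_plantable <= 1,
            frac_undiscovered >= 0, frac_undiscovered <= 1,
            noise_add_terms >= 0, noise_drop_prob >= 0, noise_drop_prob <= 1)
  structure(
    list(n_patients = n_patients, start_date = as.Date(start_date),
         timeline_days = timeline_days, enrollment_days = enrollment_days,
         gene_discovery_rate = gene_discovery_rate,
         variant_assertion_rate = variant_assertion_rate,
         frac_plantable = frac_plantable,
         frac_undiscovered = frac_undiscovered,
         noise_add_terms = noise_add_terms,
         noise_drop_prob = noise_drop_prob,
         hpo_mean = hpo_mean, hpo_sd = hpo_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# independent sub-seeds so changing one concern does not reshuffle others
stream_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                  c("cohort", "timeline", "noise"))
}

#' Generate a balanced toy phenotype ontology
#'
#' Four-level is-a tree (root, branches, sub-branches, leaves) of about
#' 200 terms, deterministic (no randomness), used as a stand-in for the
#' Human Phenotype Ontology in simulations. The term inventory is
#' synthetic and not a subset of the real ontology.
#'
#' @param n_branches,n_sub,n_leaves shape parameters (defaults give 199
#'   terms).
#' @return list with `terms` and `edges` tibbles.
#' @export
make_toy_ontology <- function(n_branches = 6, n_sub = 4, n_leaves = 7) {
  id_of <- function(i) sprintf("HP:%07d", i)
  terms <- character()
  edges_child <- character()
  edges_parent <- character()
  nxt <- 1L
  root <- id_of(nxt); nxt <- nxt + 1L
  terms <- root
  for (b in seq_len(n_branches)) {
    bid <- id_of(nxt); nxt <- nxt + 1L
    terms <- c(terms, bid)
    edges_child <- c(edges_child, bid); edges_parent <- c(edges_parent, root)
    for (s in seq_len(n_sub)) {
      sid <- id_of(nxt); nxt <- nxt + 1L
      terms <- c(terms, sid)
      edges_child <- c(edges_child, sid); edges_parent <- c(edges_parent, bid)
      for (l in seq_len(n_leaves)) {
        lid <- id_of(nxt); nxt <- nxt + 1L
        terms <- c(terms, lid)
        edges_child <- c(edges_child, lid)
        edges_parent <- c(edges_parent, sid)
      }
    }
  }
  list(terms = tibble::tibble(id = terms, name = terms),
       edges = tibble::tibble(child = edges_child, parent = edges_parent))
}

#' Generate a synthetic disease corpus over a toy ontology
#'
#' Draws coherent disease profiles (leaves sampled within one sub-branch
#' plus the sub-branch itself) and assigns gene symbols, OMIM-like ids and
#' inheritance modes in field-typical proportions.
#'
#' @param skeleton output of [make_toy_ontology()].
#' @param n_diseases corpus size.
#' @param seed random seed for this concern.
#' @return list with `diseases` tibble (`gene`, `disease_id`,
#'   `disease_name`, `inheritance`, `hpo_profile` list-column) and
#'   `annotations` tibble for [hpo_ontology()].
#' @export
make_disease_corpus <- function(skeleton, n_diseases = 50, seed = 1L) {
  set.seed(seed)
  edges <- skeleton$edges
  leaves <- setdiff(edges$child, edges$parent)
  leaf_parent <- stats::setNames(edges$parent[match(leaves, edges$child)],
                                 leaves)
  subs <- unique(leaf_parent)
  diseases <- purrr::map_dfr(seq_len(n_diseases), function(i) {
    sb <- sample(subs, 1)
    pool <- leaves[leaf_parent == sb]
    profile <- c(sb, sample(pool, min(length(pool), sample(4:6, 1))))
    tibble::tibble(
      gene = sprintf("GENE%03d", i),
      disease_id = as.character(600000 + i),
      disease_name = sprintf("synthetic disorder %d", i),
      inheritance = sample(c("AD", "AR", "XL", "AD_AR"), 1,
                           prob = c(0.70, 0.19, 0.09, 0.02)),
      hpo_profile = list(profile)
    )
  })
  annotations <- diseases |>
    dplyr::select("disease_id", term = "hpo_profile") |>
    tidyr::unnest_longer("term")
  list(diseases = diseases, annotations = annotations)
}

# HGVS templates covering the consequence categories; causal variants are
# restricted to categories the evidence engine can call P/LP
causal_variant_template <- function(i, inheritance, seed_offset = 0L) {
  kind <- (i + seed_offset) %% 3L
  if (inheritance == "AR") kind <- 0L  # frameshift keeps recessive calls P
  base <- 300L + 3L * i
  switch(as.character(kind),
    "0" = list(hgvs_c = sprintf("c.%ddel", base + 1L), hgvs_p = NA_character_,
               consequence = "frameshift"),
    "1" = list(hgvs_c = sprintf("c.%dC>T", base),
               hgvs_p = sprintf("p.Arg%dTer", ceiling(base / 3)),
               consequence = "stop_gain"),
    "2" = list(hgvs_c = sprintf("c.%d+1G>A", base), hgvs_p = NA_character_,
               consequence = "canonical_splice")
  )
}

#' Generate a synthetic cohort with planted diagnoses
#'
#' Each plantable patient receives one causal variant in a corpus disease
#' gene and a phenotype drawn from the disease profile (minus dropped
#' terms, plus Poisson-added unrelated terms); non-plantable patients
#' receive background variants in genes absent from the knowledge base
#' and background phenotypes sized to the configured distribution.
#' Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @param corpus a [make_disease_corpus()].
#' @param skeleton the [make_toy_ontology()] skeleton (for background
#'   terms).
#' @return list with `variants`, `phenotypes`, `ground_truth` tibbles.
#' @export
generate_cohort <- function(config, corpus, skeleton) {
  seeds <- stream_seeds(config$seed)
  set.seed(seeds[["cohort"]])
  n <- config$n_patients
  ids <- sprintf("SIM%04d", seq_len(n))
  plantable <- stats::runif(n) < config$frac_plantable
  undiscovered <- plantable & (stats::runif(n) < config$frac_undiscovered)
  disease_idx <- sample.int(nrow(corpus$diseases), n, replace = TRUE)
  enrollment <- config$start_date +
    sample.int(config$enrollment_days, n, replace = TRUE) - 1L

  all_terms <- skeleton$terms$id

  variants <- list(); phenos <- list(); truth <- list()
  set.seed(seeds[["noise"]])
  for (i in seq_len(n)) {
    d <- corpus$diseases[disease_idx[i], ]
    if (plantable[i]) {
      tpl <- causal_variant_template(i, d$inheritance)
      zyg <- switch(d$inheritance, AR = "homozygous", XL = "hemizygous",
                    "heterozygous")
      origin <- if (d$inheritance %in% c("AD", "XL", "AD_AR"))
        "assumed_de_novo" else "unknown"
      tx <- sprintf("NM_%06d.1", 100000 + i)
      variants[[i]] <- tibble::tibble(
        patient_id = ids[i], gene = d$gene, transcript = tx,
        hgvs_c = tpl$hgvs_c, hgvs_p = tpl$hgvs_p, zygosity = zyg,
        allele_origin = origin, insilico = "pathogenic_support",
        nmd_predicted = NA, segregation = FALSE)
      profile <- d$hpo_profile[[1]]
      kept <- profile[stats::runif(length(profile)) >= config$noise_drop_prob]
      if (length(kept) == 0) kept <- profile[1]
      extra_n <- stats::rpois(1, config$noise_add_terms)
      extra <- sample(setdiff(all_terms, kept), extra_n)
      phenos[[i]] <- tibble::tibble(patient_id = ids[i],
                                    term = unique(c(kept, extra)))
      truth[[i]] <- tibble::tibble(
        patient_id = ids[i], plantable = TRUE, gene = d$gene,
        disease_id = d$disease_id,
        variant_key = variant_key(d$gene, tx, tpl$hgvs_c),
        undiscovered = undiscovered[i],
        enrollment_date = enrollment[i],
        expected_category = "positive")
    } else {
      tx <- sprintf("NM_%06d.1", 200000 + i)
      variants[[i]] <- tibble::tibble(
        patient_id = ids[i], gene = sprintf("BGV%03d", i), transcript = tx,
        hgvs_c = sprintf("c.%dG>A", 100 + i), hgvs_p = NA_character_,
        zygosity = "heterozygous", allele_origin = "unknown",
        insilico = "none", nmd_predicted = NA, segregation = FALSE)
      n_terms <- max(1L, round(stats::rnorm(1, config$hpo_mean,
                                            config$hpo_sd)))
      phenos[[i]] <- tibble::tibble(
        patient_id = ids[i],
        term = sample(all_terms, min(n_terms, length(all_terms))))
      truth[[i]] <- tibble::tibble(
        patient_id = ids[i], plantable = FALSE, gene = NA_character_,
        disease_id = NA_character_, variant_key = NA_character_,
        undiscovered = FALSE, enrollment_date = enrollment[i],
        expected_category = "negative")
    }
  }
  list(variants = dplyr::bind_rows(variants),
       phenotypes = dplyr::bind_rows(phenos),
       ground_truth = dplyr::bind_rows(truth))
}

#' Generate the evolving knowledge-base timeline
#'
#' Draws gene-discovery and variant-assertion events as Poisson processes
#' at the configured yearly rates. The causal entries of
#' planted-but-undiscovered patients are assigned to discovery events, so
#' each such entry appears in the knowledge base exactly on its discovery
#' date; remaining discovery events create novel background entries, and
#' assertion events touch background variant keys. Snapshots are
#' cumulative, one per day with at least one event, plus the baseline.
#'
#' @param config a [simulation_config()].
#' @param ground_truth from [generate_cohort()].
#' @param corpus the disease corpus.
#' @param skeleton toy-ontology skeleton.
#' @return list with `snapshots` (date-ordered list of [kb_snapshot()]),
#'   and `ground_truth` with `discovery_date` filled (`NA` = in the
#'   baseline).
#' @export
generate_kb_timeline <- function(config, ground_truth, corpus, skeleton) {
  seeds <- stream_seeds(config$seed)
  set.seed(seeds[["timeline"]])
  days <- config$timeline_days
  start <- config$start_date
  years <- days / 365.25

  # discovery is a property of the disease entry: if any carrier patient
  # was sampled as undiscovered-at-enrolment, the whole entry is withheld
  # from the baseline and enters on its discovery date
  undisc_ids <- ground_truth |>
    dplyr::filter(.data$plantable, .data$undiscovered) |>
    dplyr::pull(.data$disease_id) |>
    unique()
  ground_truth$undiscovered <- ground_truth$plantable &
    ground_truth$disease_id %in% undisc_ids
  undisc <- ground_truth |>
    dplyr::filter(.data$undiscovered) |>
    dplyr::distinct(.data$gene, .data$disease_id, .keep_all = TRUE)

  n_gene_events <- stats::rpois(1, config$gene_discovery_rate * years)
  n_gene_events <- max(n_gene_events, nrow(undisc))
  gene_event_days <- sort(sample.int(days, n_gene_events, replace = TRUE))
  assigned <- sample(seq_len(n_gene_events), nrow(undisc))
  discovery_days <- stats::setNames(gene_event_days[assigned],
                                    undisc$disease_id)

  ground_truth$discovery_date <- as.Date(NA)
  is_un <- ground_truth$undiscovered & ground_truth$plantable
  ground_truth$discovery_date[is_un] <-
    start + discovery_days[ground_truth$disease_id[is_un]]

  # baseline: all corpus diseases except the planted-undiscovered ones
  baseline_entries <- corpus$diseases |>
    dplyr::filter(!.data$disease_id %in% undisc$disease_id) |>
    dplyr::mutate(registration = "omim_registered",
                  entry_date = start, lof_mechanism = TRUE,
                  missense_constrained = FALSE, digenic = FALSE)

  # discovered entries appear with their discovery date
  disc_entries <- corpus$diseases |>
    dplyr::filter(.data$disease_id %in% undisc$disease_id) |>
    dplyr::mutate(registration = "omim_registered",
                  entry_date = start + discovery_days[.data$disease_id],
                  lof_mechanism = TRUE, missense_constrained = FALSE,
                  digenic = FALSE,
                  day = discovery_days[.data$disease_id])

  # remaining discovery events: novel background entries in fresh genes
  bg_days <- gene_event_days[-assigned]
  all_terms <- skeleton$terms$id
  bg_entries <- if (length(bg_days) == 0) NULL else purrr::map_dfr(
    seq_along(bg_days), function(j) {
      tibble::tibble(
        gene = sprintf("NOVG%04d", j),
        disease_id = as.character(700000 + j),
        disease_name = sprintf("novel background disorder %d", j),
        inheritance = "AD", registration = "omim_registered",
        hpo_profile = list(sample(all_terms, 4)),
        entry_date = start + bg_days[j], lof_mechanism = TRUE,
        missense_constrained = FALSE, digenic = FALSE, day = bg_days[j])
    })

  n_asrt <- stats::rpois(1, config$variant_assertion_rate * years)
  asrt <- if (n_asrt == 0) NULL else tibble::tibble(
    variant_key = sprintf("ASRT%05d|NM_900000.1|c.%dA>G",
                          seq_len(n_asrt), 100 + seq_len(n_asrt)),
    asserted_class = sample(c("P", "LP", "VUS", "LB", "B"), n_asrt,
                            replace = TRUE),
    protein_residue = NA_character_, source = "synthetic literature",
    day = sort(sample.int(days, n_asrt, replace = TRUE))
  ) |> dplyr::mutate(assertion_date = start + .data$day)

  event_days <- sort(unique(c(
    0L,
    if (!is.null(disc_entries)) disc_entries$day,
    if (!is.null(bg_entries)) bg_entries$day,
    if (!is.null(asrt)) asrt$day
  )))

  pending_entries <- dplyr::bind_rows(disc_entries, bg_entries)
  snapshots <- vector("list", length(event_days))
  for (k in seq_along(event_days)) {
    d <- event_days[k]
    ent <- dplyr::bind_rows(
      baseline_entries,
      if (!is.null(pending_entries) && nrow(pending_entries) > 0)
        pending_entries |> dplyr::filter(.data$day <= d) |>
          dplyr::select(-"day")
    )
    asr <- if (is.null(asrt)) NULL else
      asrt |> dplyr::filter(.data$day <= d) |> dplyr::select(-"day")
    snapshots[[k]] <- kb_snapshot(start + d, ent, asr, NULL)
  }
  list(snapshots = snapshots, ground_truth = ground_truth)
}

#' Enrol additional cases into an existing cohort state
#'
#' Classifies the new patients against the current snapshot and issues
#' their initial reports dated `date`.
#'
#' @param state a `cohort_state`.
#' @param variants,phenotypes tibbles for the new patients.
#' @param date enrolment date.
#' @return updated state.
#' @export
enroll_cases <- function(state, variants, phenotypes, date) {
  variants <- annotate_variants(tibble::as_tibble(variants)) |>
    dplyr::mutate(gene = normalize_gene(.data$gene),
                  tier = NA_character_, moderate_count = 0L)
  for (col in c("insilico", "nmd_predicted", "segregation")) {
    if (!col %in% names(variants)) {
      variants[[col]] <- switch(col, insilico = "none",
                                nmd_predicted = NA, segregation = FALSE)
    }
  }
  state$variants <- dplyr::bind_rows(state$variants, variants)
  state$phenotypes <- dplyr::bind_rows(state$phenotypes,
                                       tibble::as_tibble(phenotypes))
  state <- reclassify_genes(state, state$snapshot,
                            genes = unique(variants$gene))
  # restrict tier refresh to the new patients' rows
  state <- refresh_reports(state, state$snapshot,
                           patients = unique(variants$patient_id),
                           date = as.Date(date))
  state$first_report <- dplyr::bind_rows(
    state$first_report,
    tibble::tibble(patient_id = unique(variants$patient_id),
                   first_report_date = as.Date(date)))
  state
}

#' End-to-end synthetic replay
#'
#' Generates a cohort and knowledge-base timeline, runs initial triage at
#' each patient's enrolment, advances the daily reanalysis loop across
#' the timeline (auto-confirming events, as in simulation mode) and
#' compares the emitted diagnoses with the planted ground truth.
#'
#' @param config a [simulation_config()].
#' @param full_scan force whole-cohort re-evaluation each day instead of
#'   delta-scoped re-evaluation.
#' @return object of class `replay_result`: `state`, `ground_truth`,
#'   `recovery` (per-patient outcome tibble), `recall`, `false_early`,
#'   `metrics` ([cohort_metrics()]), `events`.
#' @export
replay <- function(config, full_scan = FALSE) {
  skeleton <- make_toy_ontology()
  seeds <- stream_seeds(config$seed)
  corpus <- make_disease_corpus(skeleton, n_diseases = 50,
                                seed = seeds[["cohort"]])
  ontology <- hpo_ontology(skeleton$terms, skeleton$edges,
                           corpus$annotations)
  cohort <- generate_cohort(config, corpus, skeleton)
  tl <- generate_kb_timeline(config, cohort$ground_truth, corpus, skeleton)
  truth <- tl$ground_truth
  snapshots <- tl$snapshots
  snap_dates <- as.Date(purrr::map_dbl(snapshots, "date"),
                        origin = "1970-01-01")

  state <- new_cohort_state(
    cohort$variants[0, ], cohort$phenotypes[0, ],
    snapshots[[1]], ontology, config = acmg_config(),
    date = snapshots[[1]]$date)

  all_dates <- sort(unique(c(truth$enrollment_date, snap_dates)))
  snap_idx <- 1L
  for (d in as.list(all_dates)) {
    enrol <- truth$patient_id[truth$enrollment_date == d]
    if (length(enrol) > 0) {
      state <- enroll_cases(
        state,
        cohort$variants[cohort$variants$patient_id %in% enrol, ],
        cohort$phenotypes[cohort$phenotypes$patient_id %in% enrol, ],
        date = d)
    }
    k <- which(snap_dates == d)
    if (length(k) == 1 && k > 1) {
      delta <- diff_snapshots(snapshots[[k - 1L]], snapshots[[k]])
      res <- daily_run(state, delta, snapshots[[k]], run_date = d,
                       full_scan = full_scan, auto_confirm = TRUE)
      state <- res$state
    }
  }

  recovery <- truth |>
    dplyr::left_join(state$diagnoses, by = "patient_id") |>
    dplyr::mutate(
      available_date = dplyr::coalesce(.data$discovery_date,
                                       .data$enrollment_date),
      expected_positive = .data$plantable,
      diagnosed = !is.na(.data$diagnosis_date),
      anticipated = .data$diagnosed &
        .data$diagnosis_date < pmax(.data$available_date,
                                    .data$enrollment_date),
      delay_days = as.numeric(.data$diagnosis_date -
                                .data$enrollment_date))
  expected <- recovery |> dplyr::filter(.data$expected_positive)
  metrics <- cohort_metrics(state$events, state$first_report,
                            state$diagnoses)
  structure(
    list(state = state, ground_truth = truth, recovery = recovery,
         recall = if (nrow(expected)) mean(expected$diagnosed) else NA_real_,
         false_early = sum(recovery$anticipated, na.rm = TRUE),
         metrics = metrics, events = state$events),
    class = "replay_result"
  )
}

#' @export
print.replay_result <- function(x, ...) {
  cat(sprintf(
    "<replay_result> %d patients, %d events; recall %.3f, %d anticipated\n",
    nrow(x$recovery), nrow(x$events), x$recall, x$false_early))
  invisible(x)
}
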