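#' Triage one patient's classified variants into a report
#'
#' Applies the reporting rules to a patient's variant set, per implicated
#' gene-disease entry, and emits a positive, inconclusive or negative
#' report:
#'
#' * **Positive** - in a phenotype-fitting, OMIM-registered entry: one
#'   heterozygous/hemizygous P or LP variant for dominant, X-linked or
#'   digenic conditions; for recessive conditions a homozygous P/LP
#'   variant, two P/LP (potential) compound heterozygotes, or a P/LP plus
#'   a VUS carrying at least two moderate pathogenic criteria.
#' * **Inconclusive** - a single heterozygous/hemizygous VUS in a fitting
#'   dominant or X-linked entry; recessive (potential) compound
#'   heterozygotes of a P/LP with a VUS carrying at most one moderate
#'   criterion, or multiple VUS; any P/LP in a literature-candidate (not
#'   yet OMIM-registered) entry; a P/LP in a registered entry whose
#'   phenotype fit is below threshold, pending additional phenotyping.
#' * **Negative** - otherwise.
#'
#' Phenotype fit means a symptom-similarity score at or above the
#' configured threshold (default 5 on the 0-10 scale); when no score is
#' computable for an entry the fit requirement is assumed satisfied.
#' Entries with both dominant and recessive inheritance are tested under
#' both rule sets and the more conclusive outcome wins. All qualifying
#' entries are reported, so dual diagnoses are supported.
#'
#' @param variants tibble of one patient's variants with columns
#'   `patient_id`, `gene`, `variant_key`, `zygosity`, `allele_origin`,
#'   `tier` (P/LP/VUS/LB/B) and optionally `moderate_count` (moderate
#'   pathogenic criteria carried by a VUS; default 0).
#' @param snapshot a [kb_snapshot()].
#' @param similarity optional tibble `disease_id`, `score` for this
#'   patient; missing entries are assumed to fit.
#' @param config an [acmg_config()]; supplies the fit threshold.
#' @param report_date date stamped on the report.
#' @return object of class `triage_report`: `patient_id`, `category`,
#'   `reported_variants` (tibble with `variant_key`, `gene`, `role`,
#'   `tier`, `zygosity`, `disease_id`), `rule_citations`,
#'   `similarity_scores`, `report_date`.
#' @export
triage_case <- function(variants, snapshot, similarity = NULL,
                        config = acmg_config(), report_date = Sys.Date()) {
  stopifnot(inherits(snapshot, "kb_snapshot"))
  patient_id <- unique(variants$patient_id)
  if (length(patient_id) > 1) {
    stop("triage_case expects variants of a single patient", call. = FALSE)
  }
  if (length(patient_id) == 0) patient_id <- NA_character_
  variants <- prepare_case_variants(variants)

  outcomes <- list()
  sim_scores <- tibble::tibble(disease_id = character(), score = numeric())
  if (nrow(variants) > 0) {
    for (g in unique(variants$gene)) {
      gv <- variants[variants$gene == g, ]
      entries <- snapshot$entries[snapshot$entries$gene == g, ]
      if (nrow(entries) == 0) {
        warning("gene ", g, " absent from snapshot; variants ignored ",
                "for triage", call. = FALSE)
        next
      }
      for (i in seq_len(nrow(entries))) {
        entry <- entries[i, ]
        score <- entry_similarity(similarity, entry$disease_id)
        sim_scores <- dplyr::bind_rows(
          sim_scores,
          tibble::tibble(disease_id = entry$disease_id, score = score))
        outcomes[[length(outcomes) + 1L]] <-
          triage_entry(gv, entry, score, config)
      }
    }
  }

  cats <- purrr::map_chr(outcomes, "category")
  category <- if (any(cats == "positive")) "positive"
              else if (any(cats == "inconclusive")) "inconclusive"
              else "negative"
  keep <- outcomes[cats == category & cats != "negative"]
  reported <- if (length(keep) == 0) empty_reported() else
    purrr::map_dfr(keep, "variants") |> dplyr::distinct()
  rules <- unique(purrr::map_chr(keep, "rule"))

  structure(
    list(patient_id = patient_id, category = category,
         reported_variants = reported, rule_citations = rules,
         similarity_scores = dplyr::distinct(sim_scores),
         report_date = as.Date(report_date)),
    class = "triage_report"
  )
}

prepare_case_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) == 0) return(variants)
  if (!"moderate_count" %in% names(variants)) variants$moderate_count <- 0L
  variants$moderate_count <- tidyr::replace_na(
    as.integer(variants$moderate_count), 0L)
  variants$gene <- normalize_gene(variants$gene)
  if (anyDuplicated(variants$variant_key)) {
    stop("duplicate variant_key within one patient", call. = FALSE)
  }
  # deterministic evaluation order regardless of input order
  dplyr::arrange(variants, .data$gene, .data$variant_key)
}

entry_similarity <- function(similarity, disease_id) {
  if (is.null(similarity)) return(NA_real_)
  hit <- similarity$score[similarity$disease_id == disease_id]
  if (length(hit) == 0) NA_real_ else hit[1]
}

empty_reported <- function() {
  tibble::tibble(variant_key = character(), gene = character(),
                 role = character(), tier = character(),
                 zygosity = character(), disease_id = character())
}

reported_rows <- function(gv, keys, roles, disease_id) {
  idx <- match(keys, gv$variant_key)
  tibble::tibble(variant_key = keys, gene = gv$gene[idx], role = roles,
                 tier = gv$tier[idx], zygosity = gv$zygosity[idx],
                 disease_id = disease_id)
}

# evaluate one gene-disease entry against the patient's variants in that
# gene; returns list(category, variants, rule)
triage_entry <- function(gv, entry, score, config) {
  fit <- is.na(score) || score >= config$fit_threshold
  plp <- gv[gv$tier %in% c("P", "LP"), ]
  vus <- gv[gv$tier == "VUS", ]
  negative <- list(category = "negative", variants = empty_reported(),
                   rule = NA_character_)

  if (entry$registration == "literature_candidate") {
    if (nrow(plp) > 0) {
      return(list(
        category = "inconclusive",
        variants = reported_rows(gv, plp$variant_key,
                                 rep("primary", nrow(plp)),
                                 entry$disease_id),
        rule = "P/LP in a gene reported in the literature but not yet an OMIM-registered disease association"))
    }
    return(negative)
  }

  dominant <- entry$inheritance %in% c("AD", "XL", "AD_AR") ||
    isTRUE(entry$digenic)
  recessive <- entry$inheritance %in% c("AR", "AD_AR")

  if (fit) {
    if (dominant && nrow(plp) > 0) {
      return(list(
        category = "positive",
        variants = reported_rows(gv, plp$variant_key,
                                 rep("primary", nrow(plp)),
                                 entry$disease_id),
        rule = if (isTRUE(entry$digenic) && !entry$inheritance %in% c("AD", "XL", "AD_AR"))
          "one P/LP variant in a digenic disease gene fitting the phenotype"
        else
          "one heterozygous or hemizygous P/LP variant in a dominant or X-linked disease gene fitting the phenotype"))
    }
    if (recessive) {
      pairs <- potential_comp_het(gv, "AR")
      hom_plp <- plp[plp$zygosity == "homozygous", ]
      if (nrow(hom_plp) > 0) {
        return(list(
          category = "positive",
          variants = reported_rows(gv, hom_plp$variant_key,
                                   rep("primary", nrow(hom_plp)),
                                   entry$disease_id),
          rule = "one homozygous P/LP variant in a recessive disease gene fitting the phenotype"))
      }
      if (nrow(pairs) > 0) {
        tier_of <- function(k) gv$tier[match(k, gv$variant_key)]
        mod_of <- function(k) gv$moderate_count[match(k, gv$variant_key)]
        for (j in seq_len(nrow(pairs))) {
          t1 <- tier_of(pairs$key1[j]); t2 <- tier_of(pairs$key2[j])
          both_plp <- all(c(t1, t2) %in% c("P", "LP"))
          mixed <- xor(t1 %in% c("P", "LP"), t2 %in% c("P", "LP")) &&
            ("VUS" %in% c(t1, t2))
          if (both_plp && !pairs$homozygous[j]) {
            return(list(
              category = "positive",
              variants = reported_rows(
                gv, c(pairs$key1[j], pairs$key2[j]),
                c("primary", "comp_het_partner"), entry$disease_id),
              rule = "two P/LP (potential) compound heterozygous variants in a recessive disease gene fitting the phenotype"))
          }
          if (mixed) {
            vkey <- if (t1 == "VUS") pairs$key1[j] else pairs$key2[j]
            pkey <- setdiff(c(pairs$key1[j], pairs$key2[j]), vkey)
            if (mod_of(vkey) >= 2L) {
              return(list(
                category = "positive",
                variants = reported_rows(
                  gv, c(pkey, vkey), c("primary", "comp_het_partner"),
                  entry$disease_id),
                rule = "potential compound heterozygote: one P/LP variant with a VUS carrying 2 moderate pathogenic criteria in a recessive disease gene"))
            }
          }
        }
        # no pair qualified as positive; inconclusive patterns
        for (j in seq_len(nrow(pairs))) {
          t1 <- tier_of(pairs$key1[j]); t2 <- tier_of(pairs$key2[j])
          mixed <- xor(t1 %in% c("P", "LP"), t2 %in% c("P", "LP")) &&
            ("VUS" %in% c(t1, t2))
          if (mixed) {
            vkey <- if (t1 == "VUS") pairs$key1[j] else pairs$key2[j]
            pkey <- setdiff(c(pairs$key1[j], pairs$key2[j]), vkey)
            return(list(
              category = "inconclusive",
              variants = reported_rows(
                gv, c(pkey, vkey), c("primary", "comp_het_partner"),
                entry$disease_id),
              rule = "potential compound heterozygote: one P/LP variant with a VUS carrying at most one moderate pathogenic criterion in a recessive disease gene"))
          }
          if (all(c(t1, t2) == "VUS") && !pairs$homozygous[j]) {
            return(list(
              category = "inconclusive",
              variants = reported_rows(
                gv, c(pairs$key1[j], pairs$key2[j]),
                c("primary", "comp_het_partner"), entry$disease_id),
              rule = "multiple VUS forming a potential compound heterozygote in a recessive disease gene"))
          }
        }
      }
    }
    if (dominant) {
      vus_single <- vus[vus$zygosity %in% c("heterozygous", "hemizygous"), ]
      if (nrow(vus_single) > 0) {
        return(list(
          category = "inconclusive",
          variants = reported_rows(gv, vus_single$variant_key,
                                   rep("primary", nrow(vus_single)),
                                   entry$disease_id),
          rule = "heterozygous or hemizygous VUS in a dominant or X-linked disease gene fitting the phenotype"))
      }
    }
    return(negative)
  }

  # registered entry, below-threshold phenotype fit
  if (nrow(plp) > 0) {
    return(list(
      category = "inconclusive",
      variants = reported_rows(gv, plp$variant_key,
                               rep("primary", nrow(plp)),
                               entry$disease_id),
      rule = "P/LP variant in a registered disease gene; additional phenotyping needed to confirm the phenotypic match"))
  }
  negative
}

#' Triage a cohort of patients
#'
#' Runs [triage_case()] for every patient and aggregates the reports with
#' summary counts by report category and by variant tier. When `phenotypes`
#' and `ontology` are supplied, symptom-similarity scores against each
#' implicated entry's HPO profile are computed per patient; a precomputed
#' `similarity` table (`patient_id`, `disease_id`, `score`) can be passed
#' instead.
#'
#' @param variants cohort variant tibble (see [triage_case()]; multiple
#'   patients allowed).
#' @param snapshot a [kb_snapshot()].
#' @param phenotypes optional tibble `patient_id`, `term`.
#' @param ontology optional [hpo_ontology()] (required with `phenotypes`).
#' @param similarity optional precomputed score table.
#' @param sf_genes optional secondary-findings gene list; P/LP variants in
#'   these genes are annotated on the reports (see
#'   [flag_secondary_findings()]).
#' @param config an [acmg_config()].
#' @param report_date report date.
#' @return object of class `triage_result` with `reports` (one row per
#'   patient: `patient_id`, `category`, `n_reported`, `reported` and
#'   `rules` list-columns), `summary` (`by_category`, `by_tier`) and
#'   `report_date`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
triage_cohort <- function(variants, snapshot, phenotypes = NULL,
                          ontology = NULL, similarity = NULL,
                          sf_genes = NULL, config = acmg_config(),
                          report_date = Sys.Date()) {
  variants <- tibble::as_tibble(variants)
  if (is.null(similarity) && !is.null(phenotypes)) {
    stopifnot(!is.null(ontology))
    similarity <- cohort_similarity(variants, phenotypes, snapshot, ontology,
                                    config)
  }
  ids <- unique(variants$patient_id)
  reports <- purrr::map(ids, function(id) {
    sim <- if (is.null(similarity)) NULL else
      similarity[similarity$patient_id == id, c("disease_id", "score")]
    rep <- triage_case(variants[variants$patient_id == id, ], snapshot,
                       similarity = sim, config = config,
                       report_date = report_date)
    if (!is.null(sf_genes)) {
      rep <- flag_secondary_findings(
        rep, variants[variants$patient_id == id, ], sf_genes)
    }
    rep
  })
  report_tbl <- purrr::map_dfr(reports, function(r) {
    tibble::tibble(
      patient_id = r$patient_id, category = r$category,
      n_reported = nrow(r$reported_variants),
      reported = list(r$reported_variants),
      rules = list(r$rule_citations)
    )
  })
  by_category <- report_tbl |>
    dplyr::count(.data$category, name = "patients") |>
    tidyr::complete(category = c("positive", "inconclusive", "negative"),
                    fill = list(patients = 0L))
  by_tier <- variants |>
    dplyr::count(.data$tier, name = "variants")
  structure(
    list(reports = report_tbl,
         summary = list(by_category = by_category, by_tier = by_tier),
         report_date = as.Date(report_date)),
    class = "triage_result"
  )
}

cohort_similarity <- function(variants, phenotypes, snapshot, ontology,
                              config = acmg_config()) {
  genes <- normalize_gene(variants$gene)
  purrr::map_dfr(unique(variants$patient_id), function(id) {
    terms <- phenotypes$term[phenotypes$patient_id == id]
    pat_genes <- unique(genes[variants$patient_id == id])
    entries <- snapshot$entries[snapshot$entries$gene %in% pat_genes, ]
    if (nrow(entries) == 0 || length(terms) == 0) return(NULL)
    scores <- purrr::map_dbl(entries$hpo_profile, function(profile) {
      res <- tryCatch(
        suppressWarnings(similarity_score(terms, profile, ontology,
                                          config$fit_threshold)),
        error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$score
    })
    tibble::tibble(patient_id = id, disease_id = entries$disease_id,
                   score = scores)
  })
}

#' Flag secondary findings on a report
#'
#' Annotates P/LP variants in a configured gene list as secondary
#' findings. Secondary findings never change the report category.
#'
#' @param report a `triage_report`.
#' @param variants the patient's variant tibble.
#' @param sf_genes character vector of secondary-findings genes.
#' @return the report with matching variants appended to
#'   `reported_variants` with role `secondary_finding`.
#' @export
flag_secondary_findings <- function(report, variants, sf_genes) {
  stopifnot(inherits(report, "triage_report"))
  if (length(sf_genes) == 0 || nrow(variants) == 0) return(report)
  variants <- prepare_case_variants(variants)
  hits <- variants |>
    dplyr::filter(.data$gene %in% normalize_gene(sf_genes),
                  .data$tier %in% c("P", "LP"))
  if (nrow(hits) == 0) return(report)
  sf <- tibble::tibble(
    variant_key = hits$variant_key, gene = hits$gene,
    role = "secondary_finding", tier = hits$tier,
    zygosity = hits$zygosity, disease_id = NA_character_
  )
  sf <- sf[!sf$variant_key %in%
             report$reported_variants$variant_key[
               report$reported_variants$role == "secondary_finding"], ]
  report$reported_variants <- dplyr::bind_rows(report$reported_variants, sf)
  report
}

#' Read a secondary-findings gene list
#'
#' One gene symbol per line; `#` comments allowed.
#' @param path text file.
#' @return character vector.
#' @export
read_sf_genes <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  normalize_gene(lines)
}

#' @export
print.triage_report <- function(x, ...) {
  cat("<triage_report>", x$patient_id, "-", toupper(x$category), "-",
      nrow(x$reported_variants), "reported variant(s)\n")
  invisible(x)
}

#' @export
print.triage_result <- function(x, ...) {
  cat("<triage_result>", nrow(x$reports), "patients:",
      paste(x$summary$by_category$patients,
            x$summary$by_category$category, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a report to machine-readable JSON
#' @param report a `triage_report`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  doc <- list(
    patient_id = report$patient_id,
    category = report$category,
    report_date = format(report$report_date),
    reported_variants = report$reported_variants,
    rule_citations = report$rule_citations,
    similarity_scores = report$similarity_scores
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Render a report as a plain-text narrative
#' @param report a `triage_report`.
#' @return character vector of lines.
#' @export
report_narrative <- function(report) {
  lines <- c(
    sprintf("Patient %s - %s report (%s)", report$patient_id,
            toupper(report$category), format(report$report_date))
  )
  if (nrow(report$reported_variants) > 0) {
    lines <- c(lines, purrr::pmap_chr(report$reported_variants,
      function(variant_key, gene, role, tier, zygosity, disease_id) {
        sprintf("  %s [%s] %s, %s (disease %s)", variant_key, tier, role,
                zygosity, disease_id %||% "-")
      }))
  } else {
    lines <- c(lines, "  No clinically significant variant was found.")
  }
  if (length(report$rule_citations) > 0 &&
      !all(is.na(report$rule_citations))) {
    lines <- c(lines, "Rules applied:",
               paste0("  - ", report$rule_citations))
  }
  lines
}
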