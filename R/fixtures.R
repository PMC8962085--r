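#' Path to the packaged reanalysis-cohort fixture
#'
#' The packaged TSV transcribes the published table of 49 variants found
#' in 45 patients by prospective reanalysis: patient, gene, transcript,
#' HGVS c. (printed spacing preserved), five-tier class, molecular
#' diagnosis, disease id (OMIM number or PMID), inheritance, allele
#' origin, the printed outcome column, and per-VUS moderate-criteria
#' counts required by the recessive compound-heterozygote rules.
#'
#' @return file path.
#' @export
table2_path <- function() {
  system.file("extdata", "table2.tsv", package = "varitriage",
              mustWork = TRUE)
}

#' Read the reanalysis-cohort fixture
#'
#' @param path fixture path (defaults to the packaged copy).
#' @return tibble with printed fields plus derived columns: `tier`,
#'   `moderate_count`, `zygosity` and `allele_origin` in engine
#'   vocabulary, `inheritance` normalised (`AD/AR` to `AD_AR`, `XD` to
#'   `XL`), `registration` (OMIM number vs PMID), `digenic` (parsed from
#'   the diagnosis name).
#' @export
read_table2 <- function(path = table2_path()) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character())) |>
    dplyr::mutate(
      tier = .data$class,
      moderate_count = tidyr::replace_na(
        suppressWarnings(as.integer(.data$vus_moderate_criteria)), 0L),
      zygosity = dplyr::recode(.data$zygosity, Het = "heterozygous",
                               Hom = "homozygous", Hemi = "hemizygous"),
      allele_origin = dplyr::recode(.data$allele_origin,
                                    "Unknown" = "unknown",
                                    "Assumed de novo" = "assumed_de_novo",
                                    "Trans phase" = "trans_confirmed"),
      inheritance = dplyr::recode(.data$inheritance,
                                  "AD/AR" = "AD_AR", "XD" = "XL"),
      registration = ifelse(grepl("^\\d+$", .data$disease_id),
                            "omim_registered", "literature_candidate"),
      digenic = grepl("digenic", .data$molecular_diagnosis,
                      ignore.case = TRUE)
    )
}

#' Build the knowledge context for the fixture cohort
#'
#' Constructs a snapshot holding one gene-disease entry per distinct
#' (gene, disease id) pair of the fixture, a toy ontology whose disease
#' corpus is exactly those entries, and patient phenotypes copied from
#' the profiles of each patient's implicated entries - so every fixture
#' patient's symptom-similarity score against their own entry is 10 and
#' the phenotype-fit requirement is satisfied, as the published outcomes
#' imply it was.
#'
#' @param tab fixture tibble from [read_table2()].
#' @param snapshot_date snapshot date.
#' @return list with `snapshot`, `ontology`, `phenotypes`.
#' @export
table2_knowledge <- function(tab = read_table2(),
                             snapshot_date = as.Date("2021-10-31")) {
  skeleton <- make_toy_ontology()
  subs <- unique(skeleton$edges$parent[
    skeleton$edges$child %in%
      setdiff(skeleton$edges$child, skeleton$edges$parent)])
  leaves_of <- function(s) {
    skeleton$edges$child[skeleton$edges$parent == s]
  }
  diseases <- tab |>
    dplyr::distinct(.data$gene, .data$disease_id, .keep_all = TRUE)
  profiles <- purrr::map(seq_len(nrow(diseases)), function(i) {
    s <- subs[((i - 1L) %% length(subs)) + 1L]
    lv <- leaves_of(s)
    rot <- ((i - 1L) %/% length(subs)) %% length(lv)
    c(s, lv[((seq_len(4L) + rot - 1L) %% length(lv)) + 1L])
  })
  entries <- diseases |>
    dplyr::transmute(
      gene = .data$gene, disease_id = .data$disease_id,
      disease_name = .data$molecular_diagnosis,
      inheritance = .data$inheritance,
      registration = .data$registration,
      hpo_profile = profiles,
      entry_date = snapshot_date,
      lof_mechanism = TRUE, missense_constrained = FALSE,
      digenic = .data$digenic)
  snapshot <- kb_snapshot(snapshot_date, entries)
  annotations <- entries |>
    dplyr::select("disease_id", term = "hpo_profile") |>
    dplyr::distinct(.data$disease_id, .keep_all = TRUE) |>
    tidyr::unnest_longer("term")
  ontology <- hpo_ontology(skeleton$terms, skeleton$edges, annotations)
  phenotypes <- tab |>
    dplyr::mutate(gene_key = normalize_gene(.data$gene)) |>
    dplyr::distinct(.data$patient_id, .data$gene_key, .data$disease_id) |>
    dplyr::inner_join(
      snapshot$entries |>
        dplyr::transmute(gene_key = .data$gene, .data$disease_id,
                         term = .data$hpo_profile),
      by = c("gene_key", "disease_id")) |>
    tidyr::unnest_longer("term") |>
    dplyr::distinct(.data$patient_id, .data$term)
  list(snapshot = snapshot, ontology = ontology, phenotypes = phenotypes)
}

#' Triage the packaged fixture cohort
#'
#' Loads the fixture, builds its knowledge context and runs
#' [triage_cohort()] on the 49 variants of the 45 patients. The printed
#' outcome column is not consulted; classes, zygosities, inheritance,
#' registration status, allele origins and per-VUS moderate-criteria
#' counts are the only inputs.
#'
#' @param path fixture path.
#' @param config an [acmg_config()].
#' @return a `triage_result`.
#' @export
table2_triage <- function(path = table2_path(), config = acmg_config()) {
  tab <- read_table2(path)
  kc <- table2_knowledge(tab)
  variants <- tab |>
    dplyr::select("patient_id", "gene", "transcript", "hgvs_c",
                  "zygosity", "allele_origin", "tier", "moderate_count") |>
    annotate_variants()
  triage_cohort(variants, kc$snapshot, phenotypes = kc$phenotypes,
                ontology = kc$ontology, config = config,
                report_date = kc$snapshot$date)
}
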