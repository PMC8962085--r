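#' Read patient variants from TSV or minimal VCF
#'
#' Two dialects are accepted:
#'
#' * a TSV with columns `patient_id`, `gene`, `transcript`, `hgvs_c` and
#'   `zygosity` (Het/Hom/Hemi or engine vocabulary), plus optional
#'   `hgvs_p`, `allele_origin`, `class`, `vus_moderate_criteria`;
#' * a minimal VCF carrying the annotations in INFO keys `GENE`,
#'   `TRANSCRIPT`, `HGVSC` (optional `HGVSP`), with zygosity derived from
#'   the GT field (0/1 heterozygous, 1/1 homozygous, haploid `1`
#'   hemizygous) and the sample name as patient id.
#'
#' Rows whose HGVS string does not parse are retained with consequence
#' `other`; a warning reports the count.
#'
#' @param path input file (`.vcf` or `.tsv`).
#' @return annotated variant tibble (see [annotate_variants()]).
#' @export
read_patient_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  variants <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    read_variants_vcf(path)
  } else {
    read_variants_tsv(path)
  }
  out <- annotate_variants(variants)
  n_bad <- sum(out$consequence == "other" & !is.na(out$hgvs_c))
  if (n_bad > 0) {
    warning(n_bad, " variant(s) with unresolved HGVS kept with ",
            "consequence 'other'", call. = FALSE)
  }
  out
}

read_variants_tsv <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  need <- c("patient_id", "gene", "transcript", "hgvs_c", "zygosity")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab |>
    dplyr::mutate(
      zygosity = dplyr::recode(.data$zygosity,
                               Het = "heterozygous", Hom = "homozygous",
                               Hemi = "hemizygous"),
      allele_origin = if ("allele_origin" %in% names(tab)) {
        dplyr::recode(.data$allele_origin,
                      "Unknown" = "unknown",
                      "Assumed de novo" = "assumed_de_novo",
                      "Trans phase" = "trans_confirmed")
      } else "unknown",
      tier = if ("class" %in% names(tab)) .data$class else NA_character_,
      moderate_count = if ("vus_moderate_criteria" %in% names(tab)) {
        tidyr::replace_na(
          suppressWarnings(as.integer(.data$vus_moderate_criteria)), 0L)
      } else 0L
    )
}

read_variants_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (length(header) != 1) {
    stop("format error: missing #CHROM header line", call. = FALSE)
  }
  cols <- strsplit(header, "\t")[[1]]
  if (length(cols) < 10) {
    stop("format error: VCF must carry one sample column (GT)",
         call. = FALSE)
  }
  patient <- cols[10]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble::tibble(patient_id = character(), gene = character(),
                          transcript = character(), hgvs_c = character(),
                          hgvs_p = character(), zygosity = character(),
                          allele_origin = character()))
  }
  purrr::map_dfr(body, function(line) {
    f <- strsplit(line, "\t")[[1]]
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
    get <- function(k) {
      v <- vals[keys == k]
      if (length(v) == 0) NA_character_ else v[1]
    }
    if (is.na(get("GENE")) || is.na(get("TRANSCRIPT")) ||
        is.na(get("HGVSC"))) {
      stop("format error: INFO must carry GENE, TRANSCRIPT and HGVSC",
           call. = FALSE)
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    sample <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    gt <- sample[which(fmt == "GT")[1]]
    alleles <- strsplit(gt, "[/|]")[[1]]
    zyg <- if (length(alleles) == 1 && alleles == "1") "hemizygous"
    else if (all(alleles == "1")) "homozygous"
    else "heterozygous"
    tibble::tibble(
      patient_id = patient, gene = get("GENE"),
      transcript = get("TRANSCRIPT"), hgvs_c = get("HGVSC"),
      hgvs_p = get("HGVSP"), zygosity = zyg, allele_origin = "unknown")
  })
}

#' Run configuration for the command-line surface
#'
#' Bundles paths, thresholds and toggles; round-trips through JSON
#' unchanged.
#'
#' @param snapshot_dir,cohort_file,ontology_file,annotations_file,ledger_file,output_dir paths.
#' @param config an [acmg_config()].
#' @param full_scan force whole-cohort re-evaluation in the daily loop.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(snapshot_dir = NULL, cohort_file = NULL,
                       ontology_file = NULL, annotations_file = NULL,
                       ledger_file = NULL, output_dir = ".",
                       config = acmg_config(), full_scan = FALSE,
                       seed = 1L) {
  structure(
    list(snapshot_dir = snapshot_dir, cohort_file = cohort_file,
         ontology_file = ontology_file,
         annotations_file = annotations_file,
         ledger_file = ledger_file, output_dir = output_dir,
         config = config, full_scan = isTRUE(full_scan),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON file.
#' @export
write_run_config <- function(x, path) {
  doc <- unclass(x)
  doc$config <- unclass(doc$config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- doc$config
  run_config(
    snapshot_dir = doc$snapshot_dir, cohort_file = doc$cohort_file,
    ontology_file = doc$ontology_file,
    annotations_file = doc$annotations_file,
    ledger_file = doc$ledger_file, output_dir = doc$output_dir %||% ".",
    config = acmg_config(
      pm2_strength = cfg$pm2_strength,
      pm2_af_dominant = cfg$pm2_af_dominant,
      pm2_af_recessive = cfg$pm2_af_recessive,
      ba1_af = cfg$ba1_af, bs1_af = cfg$bs1_af,
      enable_pp5 = isTRUE(cfg$enable_pp5),
      fit_threshold = cfg$fit_threshold),
    full_scan = isTRUE(doc$full_scan), seed = doc$seed %||% 1L)
}
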