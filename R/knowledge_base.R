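#' Construct a dated knowledge-base snapshot
#'
#' A snapshot is the state, on one calendar date, of the three knowledge
#' channels that drive reinterpretation: gene-disease entries (with
#' inheritance mode, OMIM-registration status and a disease HPO profile),
#' variant-level assertions, and population allele frequencies. Snapshots
#' are immutable value objects; the daily loop consumes the *difference*
#' between consecutive snapshots.
#'
#' @param date snapshot date (coerced with [as.Date()]).
#' @param entries tibble of gene-disease entries: `gene`, `disease_id`,
#'   `disease_name`, `inheritance` (AD/AR/XL/AD_AR), `registration`
#'   (omim_registered/literature_candidate), `hpo_profile` (list-column of
#'   term ids), `entry_date`, plus optional logical flags `lof_mechanism`,
#'   `missense_constrained`, `digenic`.
#' @param assertions tibble: `variant_key`, `asserted_class` (P/LP/VUS/LB/B),
#'   `protein_residue` (optional), `source`, `assertion_date`.
#' @param frequencies tibble: `variant_key`, `af` in \[0, 1\].
#' @return an object of class `kb_snapshot`.
#' @export
kb_snapshot <- function(date, entries = NULL, assertions = NULL,
                        frequencies = NULL) {
  date <- as.Date(date)
  stopifnot(length(date) == 1, !is.na(date))
  entries <- normalize_entries(entries)
  assertions <- normalize_assertions(assertions)
  frequencies <- normalize_frequencies(frequencies)
  validate_snapshot_tables(date, entries, assertions, frequencies)
  structure(
    list(date = date, entries = entries, assertions = assertions,
         frequencies = frequencies),
    class = "kb_snapshot"
  )
}

entry_cols <- c("gene", "disease_id", "disease_name", "inheritance",
                "registration", "hpo_profile", "entry_date",
                "lof_mechanism", "missense_constrained", "digenic")

normalize_entries <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0) {
    return(tibble::tibble(
      gene = character(), disease_id = character(),
      disease_name = character(), inheritance = character(),
      registration = character(), hpo_profile = list(),
      entry_date = as.Date(character()), lof_mechanism = logical(),
      missense_constrained = logical(), digenic = logical()
    ))
  }
  entries <- tibble::as_tibble(entries)
  for (flag in c("lof_mechanism", "missense_constrained", "digenic")) {
    if (!flag %in% names(entries)) entries[[flag]] <- FALSE
    entries[[flag]] <- tidyr::replace_na(as.logical(entries[[flag]]), FALSE)
  }
  entries |>
    dplyr::mutate(
      gene = normalize_gene(.data$gene),
      inheritance = sub("/", "_", .data$inheritance),
      entry_date = as.Date(.data$entry_date)
    ) |>
    dplyr::select(dplyr::all_of(entry_cols)) |>
    dplyr::arrange(.data$gene, .data$disease_id)
}

normalize_assertions <- function(assertions) {
  if (is.null(assertions) || nrow(assertions) == 0) {
    return(tibble::tibble(
      variant_key = character(), asserted_class = character(),
      protein_residue = character(), source = character(),
      assertion_date = as.Date(character())
    ))
  }
  assertions <- tibble::as_tibble(assertions)
  if (!"protein_residue" %in% names(assertions)) {
    assertions$protein_residue <- NA_character_
  }
  assertions |>
    dplyr::mutate(
      variant_key = gsub("\\s+", "", .data$variant_key),
      assertion_date = as.Date(.data$assertion_date)
    ) |>
    dplyr::select("variant_key", "asserted_class", "protein_residue",
                  "source", "assertion_date") |>
    dplyr::arrange(.data$variant_key)
}

normalize_frequencies <- function(frequencies) {
  if (is.null(frequencies) || nrow(frequencies) == 0) {
    return(tibble::tibble(variant_key = character(), af = numeric()))
  }
  tibble::as_tibble(frequencies) |>
    dplyr::mutate(variant_key = gsub("\\s+", "", .data$variant_key),
                  af = as.numeric(.data$af)) |>
    dplyr::select("variant_key", "af") |>
    dplyr::arrange(.data$variant_key)
}

validate_snapshot_tables <- function(date, entries, assertions, frequencies) {
  if (nrow(entries) > 0) {
    dup <- entries |> dplyr::count(.data$gene, .data$disease_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop("snapshot schema error: duplicate entry for (",
           dup$gene[1], ", ", dup$disease_id[1], ")", call. = FALSE)
    }
    is_omim <- grepl("^\\d+$", entries$disease_id)
    bad <- which((entries$registration == "omim_registered") != is_omim)
    if (length(bad) > 0) {
      stop("snapshot schema error: entry ", bad[1],
           " (field registration): omim_registered requires a numeric ",
           "OMIM id and vice versa", call. = FALSE)
    }
    if (any(lengths(entries$hpo_profile) == 0)) {
      stop("snapshot schema error: empty hpo_profile (entry ",
           which(lengths(entries$hpo_profile) == 0)[1], ")", call. = FALSE)
    }
    if (any(is.na(entries$entry_date))) {
      stop("snapshot schema error: missing entry_date", call. = FALSE)
    }
    if (any(entries$entry_date > date)) {
      stop("snapshot schema error: entry_date after snapshot_date",
           call. = FALSE)
    }
    if (!all(entries$inheritance %in% c("AD", "AR", "XL", "AD_AR"))) {
      stop("snapshot schema error: invalid inheritance value", call. = FALSE)
    }
  }
  if (nrow(assertions) > 0 &&
      !all(assertions$asserted_class %in% c("P", "LP", "VUS", "LB", "B"))) {
    stop("snapshot schema error: invalid asserted_class", call. = FALSE)
  }
  if (nrow(frequencies) > 0 &&
      (any(is.na(frequencies$af)) ||
       any(frequencies$af < 0 | frequencies$af > 1))) {
    stop("snapshot schema error: allele frequency outside [0, 1] (field af)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.kb_snapshot <- function(x, ...) {
  cat("<kb_snapshot>", format(x$date), "-",
      nrow(x$entries), "entries,",
      nrow(x$assertions), "assertions,",
      nrow(x$frequencies), "frequencies\n")
  invisible(x)
}

#' Read a knowledge-base snapshot from disk
#'
#' Accepts the JSON layout (one document with `date`, `entries`,
#' `assertions`, `frequencies`) or the sectioned TSV dialect written by
#' [write_snapshot()] (sections introduced by `#entries`, `#assertions`,
#' `#frequencies`; HPO profiles semicolon-joined).
#'
#' @param path file path (`.json` or `.tsv`).
#' @param expected_date optional date; a mismatch with the file's own date
#'   is an error.
#' @return a [kb_snapshot()].
#' @export
read_snapshot <- function(path, expected_date = NULL) {
  if (!file.exists(path)) stop("snapshot file not found: ", path, call. = FALSE)
  snap <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_snapshot_json(path)
  } else {
    read_snapshot_tsv(path)
  }
  if (!is.null(expected_date) && snap$date != as.Date(expected_date)) {
    stop("snapshot date mismatch: file says ", snap$date,
         ", expected ", as.Date(expected_date), call. = FALSE)
  }
  snap
}

read_snapshot_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- purrr::map_dfr(doc$entries, function(e) {
    tibble::tibble(
      gene = e$gene, disease_id = as.character(e$disease_id),
      disease_name = e$disease_name %||% NA_character_,
      inheritance = e$inheritance,
      registration = e$registration,
      hpo_profile = list(as.character(unlist(e$hpo_profile))),
      entry_date = e$entry_date,
      lof_mechanism = isTRUE(e$lof_mechanism),
      missense_constrained = isTRUE(e$missense_constrained),
      digenic = isTRUE(e$digenic)
    )
  })
  assertions <- purrr::map_dfr(doc$assertions, function(a) {
    tibble::tibble(
      variant_key = a$variant_key, asserted_class = a$asserted_class,
      protein_residue = a$protein_residue %||% NA_character_,
      source = a$source %||% NA_character_,
      assertion_date = a$assertion_date
    )
  })
  freqs <- tibble::tibble(
    variant_key = names(doc$frequencies %||% list()),
    af = as.numeric(unlist(doc$frequencies %||% list(), use.names = FALSE))
  )
  kb_snapshot(doc$date,
              if (nrow(entries)) entries else NULL,
              if (nrow(assertions)) assertions else NULL,
              if (nrow(freqs)) freqs else NULL)
}

read_snapshot_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  date_line <- grep("^#snapshot_date\t", lines, value = TRUE)
  if (length(date_line) != 1) {
    stop("snapshot schema error: missing #snapshot_date line", call. = FALSE)
  }
  date <- strsplit(date_line, "\t")[[1]][2]
  section_of <- function(name) {
    hdr <- which(lines == paste0("#", name))
    if (length(hdr) == 0) return(NULL)
    end <- c(grep("^#", lines), length(lines) + 1L)
    end <- min(end[end > hdr]) - 1L
    block <- lines[(hdr + 1L):end]
    block <- block[nzchar(block)]
    if (length(block) <= 1) return(NULL)
    readr::read_tsv(I(block), show_col_types = FALSE, progress = FALSE)
  }
  entries <- section_of("entries")
  if (!is.null(entries)) {
    entries <- entries |>
      dplyr::mutate(
        disease_id = as.character(.data$disease_id),
        hpo_profile = strsplit(as.character(.data$hpo_profile), ";",
                               fixed = TRUE)
      )
  }
  freqs <- section_of("frequencies")
  kb_snapshot(date, entries, section_of("assertions"), freqs)
}

#' Write a snapshot to disk
#'
#' @param snap a [kb_snapshot()].
#' @param path destination; `.json` or `.tsv` chooses the format.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snap, path) {
  stopifnot(inherits(snap, "kb_snapshot"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    entries <- purrr::pmap(snap$entries, function(...) {
      e <- list(...)
      e$entry_date <- format(e$entry_date)
      e$hpo_profile <- as.list(e$hpo_profile)
      e
    })
    assertions <- purrr::pmap(snap$assertions, function(...) {
      a <- list(...)
      a$assertion_date <- format(a$assertion_date)
      a
    })
    freqs <- as.list(stats::setNames(snap$frequencies$af,
                                     snap$frequencies$variant_key))
    doc <- list(date = format(snap$date), entries = entries,
                assertions = assertions, frequencies = freqs)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#snapshot_date\t", format(snap$date)), con)
    writeLines("#entries", con)
    ent <- snap$entries |>
      dplyr::mutate(hpo_profile = purrr::map_chr(.data$hpo_profile,
                                                 paste, collapse = ";"))
    writeLines(readr::format_tsv(ent), con, sep = "")
    writeLines("#assertions", con)
    writeLines(readr::format_tsv(snap$assertions), con, sep = "")
    writeLines("#frequencies", con)
    writeLines(readr::format_tsv(snap$frequencies), con, sep = "")
  }
  invisible(path)
}

#' Allele-frequency threshold bin
#'
#' Bins an allele frequency by the criterion boundaries that matter for
#' classification (PM2 dominant, PM2 recessive, BS1, BA1). Frequency
#' updates that stay inside one bin cannot change any criterion call, so
#' only bin-crossing updates mark a gene as affected in a delta.
#'
#' @param af numeric allele frequencies (`NA` = absent from population data).
#' @param config an [acmg_config()].
#' @return integer bin index (0 = absent).
#' @export
af_bin <- function(af, config = acmg_config()) {
  cuts <- c(config$pm2_af_dominant, config$pm2_af_recessive,
            config$bs1_af, config$ba1_af)
  b <- findInterval(af, cuts, left.open = TRUE) + 1L
  b[is.na(af)] <- 0L
  b
}

#' Difference between two knowledge-base snapshots
#'
#' Computes the day-over-day delta that drives reanalysis: entries present
#' or field-changed in `new` but not in `old` (keyed on gene + disease id),
#' assertions added or changed (keyed on variant key), and allele-frequency
#' updates. `affected_genes` collects every gene touched by an entry or
#' assertion change, plus genes whose frequency update crosses a criterion
#' threshold bin (see [af_bin()]); within-bin frequency churn is recorded
#' in the delta but does not mark the gene as affected.
#'
#' @param old,new [kb_snapshot()] objects with `old$date <= new$date`.
#' @param config an [acmg_config()] supplying the frequency bins.
#' @return an object of class `kb_delta` with fields `added_entries`,
#'   `changed_or_added_assertions`, `changed_frequencies`,
#'   `affected_genes`, `from`, `to`.
#' @export
diff_snapshots <- function(old, new, config = acmg_config()) {
  stopifnot(inherits(old, "kb_snapshot"), inherits(new, "kb_snapshot"))
  if (old$date > new$date) {
    stop("snapshot ordering error: old snapshot (", old$date,
         ") dated after new (", new$date, ")", call. = FALSE)
  }

  entry_sig <- function(e) {
    paste(e$disease_name, e$inheritance, e$registration,
          purrr::map_chr(e$hpo_profile, ~ paste(sort(.x), collapse = ",")),
          e$entry_date, e$lof_mechanism, e$missense_constrained, e$digenic,
          sep = "\r")
  }
  old_ent <- old$entries |> dplyr::mutate(.sig = entry_sig(old$entries))
  new_ent <- new$entries |> dplyr::mutate(.sig = entry_sig(new$entries))
  added_entries <- new_ent |>
    dplyr::anti_join(old_ent, by = c("gene", "disease_id", ".sig")) |>
    dplyr::select(-".sig")

  asrt_sig <- function(a) {
    paste(a$asserted_class, a$protein_residue, a$source, a$assertion_date,
          sep = "\r")
  }
  old_as <- old$assertions |> dplyr::mutate(.sig = asrt_sig(old$assertions))
  new_as <- new$assertions |> dplyr::mutate(.sig = asrt_sig(new$assertions))
  changed_assertions <- new_as |>
    dplyr::anti_join(old_as, by = c("variant_key", ".sig")) |>
    dplyr::select(-".sig")

  freq_join <- dplyr::full_join(
    old$frequencies |> dplyr::rename(old_af = "af"),
    new$frequencies |> dplyr::rename(new_af = "af"),
    by = "variant_key"
  ) |>
    dplyr::filter(is.na(.data$old_af) != is.na(.data$new_af) |
                    (!is.na(.data$old_af) & .data$old_af != .data$new_af)) |>
    dplyr::filter(!is.na(.data$new_af)) |>
    dplyr::mutate(crossed_threshold =
                    af_bin(.data$old_af, config) != af_bin(.data$new_af, config))

  gene_of_key <- function(key) sub("\\|.*$", "", key)
  affected <- sort(unique(c(
    added_entries$gene,
    gene_of_key(changed_assertions$variant_key),
    gene_of_key(freq_join$variant_key[freq_join$crossed_threshold])
  )))

  structure(
    list(
      added_entries = added_entries,
      changed_or_added_assertions = changed_assertions,
      changed_frequencies = freq_join,
      affected_genes = affected,
      from = old$date, to = new$date
    ),
    class = "kb_delta"
  )
}

#' @export
print.kb_delta <- function(x, ...) {
  cat("<kb_delta>", format(x$from), "->", format(x$to), "-",
      nrow(x$added_entries), "entries,",
      nrow(x$changed_or_added_assertions), "assertions,",
      nrow(x$changed_frequencies), "frequencies;",
      length(x$affected_genes), "affected genes\n")
  invisible(x)
}

#' Is a delta empty?
#' @param delta a `kb_delta`.
#' @return logical.
#' @export
delta_is_empty <- function(delta) {
  nrow(delta$added_entries) == 0 &&
    nrow(delta$changed_or_added_assertions) == 0 &&
    nrow(delta$changed_frequencies) == 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
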