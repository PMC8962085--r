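#' Build a phenotype ontology with a disease-annotation corpus
#'
#' Constructs the ontology object used for symptom-similarity scoring: a
#' directed acyclic is-a graph with a single root, plus a disease corpus
#' annotating terms. Information content is precomputed for every term as
#' \deqn{IC(t) = -\ln\frac{n_{t} + 1}{N + 1}}
#' where \eqn{n_t} is the number of distinct diseases annotated to the term
#' or any of its descendants and \eqn{N} the corpus size (add-one smoothing
#' keeps leaves finite on tiny corpora; the root has IC 0 whenever every
#' disease is under it).
#'
#' @param terms tibble with columns `id` and optionally `name`.
#' @param edges tibble with columns `child`, `parent` (is-a edges).
#' @param annotations tibble with columns `disease_id`, `term`.
#' @return an object of class `hpo_ontology`.
#' @export
hpo_ontology <- function(terms, edges, annotations) {
  terms <- tibble::as_tibble(terms)
  if (!"name" %in% names(terms)) terms$name <- terms$id
  edges <- tibble::as_tibble(edges)
  annotations <- tibble::as_tibble(annotations)

  ids <- terms$id
  stopifnot(!anyDuplicated(ids))
  if (!all(edges$child %in% ids) || !all(edges$parent %in% ids)) {
    stop("ontology error: edge references unknown term", call. = FALSE)
  }
  if (!all(annotations$term %in% ids)) {
    stop("ontology error: annotation references unknown term: ",
         setdiff(annotations$term, ids)[1], call. = FALSE)
  }
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  roots <- ids[lengths(parents) == 0]
  if (length(roots) != 1) {
    stop("ontology error: expected a single root, found ",
         length(roots), call. = FALSE)
  }

  # ancestor closure (including self); also detects cycles
  anc <- vector("list", length(ids))
  names(anc) <- ids
  state <- integer(length(ids))  # 0 unvisited, 1 in progress, 2 done
  names(state) <- ids
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("ontology error: cycle at ", t, call. = FALSE)
    state[[t]] <<- 1L
    up <- unique(unlist(lapply(parents[[t]], visit), use.names = FALSE))
    anc[[t]] <<- unique(c(t, up))
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in ids) visit(t)

  n_dis <- length(unique(annotations$disease_id))
  # diseases annotated to t or any descendant == diseases whose annotated
  # terms have t among their ancestors
  prop <- annotations |>
    dplyr::mutate(.anc = anc[.data$term]) |>
    tidyr::unnest_longer(".anc") |>
    dplyr::distinct(.data$disease_id, .data$.anc) |>
    dplyr::count(.data$.anc)
  counts <- stats::setNames(rep(0L, length(ids)), ids)
  counts[prop$.anc] <- prop$n
  ic <- -log((counts + 1) / (n_dis + 1))
  ic[ic < 0] <- 0

  structure(
    list(terms = terms, parents = parents, ancestors = anc,
         root = roots, annotations = annotations,
         n_diseases = n_dis, counts = counts, ic = ic),
    class = "hpo_ontology"
  )
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat("<hpo_ontology>", nrow(x$terms), "terms, root", x$root, "-",
      x$n_diseases, "diseases annotated\n")
  invisible(x)
}

#' Read an ontology from OBO format
#'
#' Minimal OBO reader covering `[Term]` stanzas with `id`, `name` and
#' `is_a` tags (trailing `!` comments stripped). Obsolete terms and other
#' relationship types are ignored.
#'
#' @param path OBO file.
#' @return list with `terms` and `edges` tibbles, ready for
#'   [hpo_ontology()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) stop("no [Term] stanzas in ", path,
                                     call. = FALSE)
  bounds <- c(term_starts, length(lines) + 1L)
  stanzas <- purrr::map(seq_along(term_starts), function(i) {
    lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
  })
  tag <- function(block, key) {
    v <- block[startsWith(block, paste0(key, ": "))]
    v <- sub(paste0("^", key, ": "), "", v)
    trimws(sub("!.*$", "", v))
  }
  terms <- purrr::map_dfr(stanzas, function(b) {
    id <- tag(b, "id")
    if (length(id) == 0 || any(tag(b, "is_obsolete") == "true")) return(NULL)
    nm <- tag(b, "name")
    tibble::tibble(id = id[1],
                   name = if (length(nm)) nm[1] else id[1])
  })
  edges <- purrr::map_dfr(stanzas, function(b) {
    id <- tag(b, "id")
    if (length(id) == 0 || any(tag(b, "is_obsolete") == "true")) return(NULL)
    isa <- tag(b, "is_a")
    if (length(isa) == 0) return(NULL)
    tibble::tibble(child = id[1], parent = isa)
  })
  list(terms = terms, edges = edges)
}

#' Read disease-term annotations from a TSV sidecar
#'
#' @param path TSV with columns `disease_id` and `term` (one row per
#'   annotation) or `terms` (semicolon-joined).
#' @return tibble with `disease_id`, `term`.
#' @export
read_disease_annotations <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if ("terms" %in% names(tab)) {
    tab <- tab |>
      dplyr::mutate(term = strsplit(as.character(.data$terms), ";",
                                    fixed = TRUE)) |>
      tidyr::unnest_longer("term")
  }
  tab |>
    dplyr::transmute(disease_id = as.character(.data$disease_id),
                     term = trimws(.data$term))
}

#' Load an ontology plus corpus from files
#'
#' @param obo_path OBO ontology file.
#' @param annotations_path disease-annotation TSV ([read_disease_annotations()]).
#' @return an [hpo_ontology()].
#' @export
load_ontology <- function(obo_path, annotations_path) {
  g <- read_obo(obo_path)
  hpo_ontology(g$terms, g$edges, read_disease_annotations(annotations_path))
}

#' Information content of ontology terms
#'
#' @param term character vector of term ids.
#' @param ontology an [hpo_ontology()].
#' @return numeric vector of nonnegative information contents.
#' @export
information_content <- function(term, ontology) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  unknown <- setdiff(term, names(ontology$ic))
  if (length(unknown) > 0) {
    stop("unknown term: ", unknown[1], call. = FALSE)
  }
  unname(ontology$ic[term])
}

lin_similarity <- function(a, b, ontology) {
  ia <- ontology$ic[[a]]
  ib <- ontology$ic[[b]]
  common <- intersect(ontology$ancestors[[a]], ontology$ancestors[[b]])
  mica <- max(c(0, ontology$ic[common]))
  if (ia + ib == 0) return(0)
  2 * mica / (ia + ib)
}

#' Symptom similarity score between a patient and a disease profile
#'
#' Asymmetric best-match average Lin similarity on a 0-10 scale: each
#' patient term is matched to its most similar profile term using the Lin
#' measure \eqn{2\,IC(\mathrm{MICA})/(IC(a)+IC(b))} (0 when both terms are
#' uninformative), and the score is ten times the mean best-match
#' similarity. A score of 10 means every patient term has an exact,
#' informative counterpart; disjoint branches meeting only at the root
#' score 0. Scores at or above the flagging threshold (default 5) mark the
#' disease as phenotypically fitting.
#'
#' @param patient_terms character vector of the patient's term ids.
#' @param disease_profile character vector of the disease's term ids.
#' @param ontology an [hpo_ontology()].
#' @param threshold flagging threshold on the 0-10 scale.
#' @return object of class `similarity_result`: `score`, `flagged`,
#'   `matches` tibble (`patient_term`, `disease_term`, `similarity`),
#'   `dropped` (unknown terms removed).
#' @export
similarity_score <- function(patient_terms, disease_profile, ontology,
                             threshold = 5) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  known <- names(ontology$ic)
  dropped <- unique(c(setdiff(patient_terms, known),
                      setdiff(disease_profile, known)))
  if (length(dropped) > 0) {
    warning("dropping unknown terms: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  pt <- unique(intersect(patient_terms, known))
  dp <- unique(intersect(disease_profile, known))
  if (length(pt) == 0) {
    stop("empty phenotype: no patient terms found in the ontology",
         call. = FALSE)
  }
  if (length(dp) == 0) {
    stop("empty disease profile after dropping unknown terms",
         call. = FALSE)
  }
  matches <- purrr::map_dfr(pt, function(a) {
    sims <- vapply(dp, function(b) lin_similarity(a, b, ontology), numeric(1))
    best <- which.max(sims)
    tibble::tibble(patient_term = a, disease_term = dp[best],
                   similarity = sims[best])
  })
  score <- 10 * mean(matches$similarity)
  structure(
    list(score = score, flagged = score >= threshold,
         matches = matches, dropped = dropped),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> score %.3f%s\n", x$score,
              if (x$flagged) " (flagged)" else ""))
  invisible(x)
}

#' Rank a snapshot's gene-disease entries by phenotype fit
#'
#' Scores every entry's HPO profile against the patient's terms and
#' returns the top matches, sorted by score descending with ties broken by
#' disease id ascending.
#'
#' @param patient_terms character vector of patient term ids.
#' @param snapshot a [kb_snapshot()].
#' @param ontology an [hpo_ontology()].
#' @param k number of entries to return (default all).
#' @param threshold flagging threshold.
#' @return tibble: `gene`, `disease_id`, `disease_name`, `score`,
#'   `flagged`.
#' @export
best_disease_matches <- function(patient_terms, snapshot, ontology,
                                 k = Inf, threshold = 5) {
  stopifnot(inherits(snapshot, "kb_snapshot"))
  if (k <= 0 || nrow(snapshot$entries) == 0) {
    return(tibble::tibble(gene = character(), disease_id = character(),
                          disease_name = character(), score = numeric(),
                          flagged = logical()))
  }
  scores <- purrr::map_dbl(snapshot$entries$hpo_profile, function(profile) {
    res <- tryCatch(
      suppressWarnings(
        similarity_score(patient_terms, profile, ontology, threshold)),
      error = function(e) NULL
    )
    if (is.null(res)) 0 else res$score
  })
  out <- snapshot$entries |>
    dplyr::transmute(.data$gene, .data$disease_id, .data$disease_name,
                     score = scores, flagged = scores >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$disease_id)
  utils::head(out, n = if (is.finite(k)) k else nrow(out))
}
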