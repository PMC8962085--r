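#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a triage result into one row per reported variant
#'
#' @param x a `triage_result`.
#' @param ... unused.
#' @return tibble: `patient_id`, `category`, `variant_key`, `gene`,
#'   `role`, `tier`, `zygosity`, `disease_id`.
#' @export
tidy.triage_result <- function(x, ...) {
  x$reports |>
    dplyr::select("patient_id", "category", "reported") |>
    tidyr::unnest("reported", keep_empty = FALSE)
}

#' One-row summary of a triage result
#'
#' @param x a `triage_result`.
#' @param ... unused.
#' @return tibble with patient counts per category and the number of
#'   variants reported in positive reports.
#' @export
glance.triage_result <- function(x, ...) {
  by_cat <- stats::setNames(x$summary$by_category$patients,
                            x$summary$by_category$category)
  pos_variants <- tidy(x) |>
    dplyr::filter(.data$category == "positive",
                  .data$role %in% c("primary", "comp_het_partner")) |>
    nrow()
  tibble::tibble(
    n_patients = nrow(x$reports),
    positive = by_cat[["positive"]],
    inconclusive = by_cat[["inconclusive"]],
    negative = by_cat[["negative"]],
    positive_variants = pos_variants
  )
}

#' @export
autoplot.triage_result <- function(object, ...) {
  dat <- object$summary$by_category |>
    dplyr::mutate(category = factor(.data$category,
                                    c("positive", "inconclusive",
                                      "negative")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category,
                                    y = .data$patients,
                                    fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "patients",
                  title = "Report triage outcome") +
    ggplot2::theme_minimal()
}

#' Tidy cohort metrics into the daily event series
#' @param x a `cohort_metrics`.
#' @param ... unused.
#' @export
tidy.cohort_metrics <- function(x, ...) {
  x$per_day
}

#' One-row summary of cohort metrics
#' @param x a `cohort_metrics`.
#' @param ... unused.
#' @export
glance.cohort_metrics <- function(x, ...) {
  tibble::tibble(
    event_days = nrow(x$per_day),
    mean_variants_per_day = x$mean_variants_per_day,
    mean_patients_per_day = x$mean_patients_per_day,
    diagnosed = nrow(x$time_to_diagnosis),
    mean_years_to_diagnosis = x$mean_years,
    sd_years_to_diagnosis = x$sd_years
  )
}

#' @export
autoplot.cohort_metrics <- function(object, ...) {
  dat <- object$per_day |>
    tidyr::pivot_longer(c("variants", "patients"),
                        names_to = "series", values_to = "n")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$event_date, y = .data$n,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "newly reclassified per day",
                  title = "Daily reanalysis activity") +
    ggplot2::theme_minimal()
}

#' Tidy a replay result into the per-patient recovery table
#' @param x a `replay_result`.
#' @param ... unused.
#' @export
tidy.replay_result <- function(x, ...) {
  x$recovery
}

#' One-row summary of a replay
#' @param x a `replay_result`.
#' @param ... unused.
#' @export
glance.replay_result <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$recovery),
    n_events = nrow(x$events),
    recall = x$recall,
    false_early = x$false_early,
    diagnosed = sum(x$recovery$diagnosed, na.rm = TRUE),
    mean_years_to_diagnosis = x$metrics$mean_years
  )
}

#' @export
autoplot.replay_result <- function(object, ...) {
  dat <- object$metrics$cumulative
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$diagnosis_date,
                                    y = .data$diagnosed)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = NULL, y = "cumulative diagnoses",
                  title = "Diagnoses recovered by daily reanalysis") +
    ggplot2::theme_minimal()
}
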