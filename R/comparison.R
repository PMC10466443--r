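# Structured vs narrative documentation comparison ------------------------

# percentages are presented half-up at 2 decimals, the convention of the
# published prevalence table (R's round() is half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reference cohort counts from the published validation study
#'
#' Per-domain patient counts for a 4283-patient primary-care diabetes
#' cohort: structured (Z-coded) patients, rule-flagged patients, the
#' review-confirmed subset, and the overlap between rule-flagged and coded
#' patients. Used for worked examples and as printed inputs to the
#' reporting functions.
#'
#' @return data frame with columns `domain`, `n_structured`, `n_confirmed`,
#'   `n_nlp_positive`, `n_overlap_structured`, `cohort_n`.
#' @export
published_counts <- function() {
  utils::read.csv(system.file("extdata", "published_counts.csv",
                              package = "sdohscan"),
                  stringsAsFactors = FALSE)
}

check_flags <- function(flags, cohort, domains, arm) {
  stopifnot(is.data.frame(flags), "patient_id" %in% names(flags))
  outside <- setdiff(flags$patient_id, cohort)
  if (length(outside) > 0L) {
    stop(arm, " flags reference ", length(outside),
         " patient(s) outside the cohort, e.g. ", outside[1])
  }
  missing <- setdiff(cohort, flags$patient_id)
  if (length(missing) > 0L) {
    stop(arm, " flags missing for ", length(missing),
         " cohort patient(s), e.g. ", missing[1])
  }
  if (!all(domains %in% names(flags))) {
    stop(arm, " flags missing domain column(s): ",
         paste(setdiff(domains, names(flags)), collapse = ", "))
  }
  flags
}

#' Per-domain prevalence of SDOH documentation in both arms
#'
#' One row per domain with patient counts and percentages (of the full
#' cohort, half-up at 2 decimals) for the structured (coded) and
#' unstructured (narrative) arms.
#'
#' @param structured_flags,unstructured_flags data frames with `patient_id`
#'   and one logical column per domain, covering every cohort patient
#'   (see [structured_sdoh_flags()], [patient_sdoh_flags()]).
#' @param cohort character vector of cohort patient ids (the denominator).
#' @param domains domains to report.
#' @return data frame: domain, n_structured, pct_structured,
#'   n_unstructured, pct_unstructured, cohort_n.
#' @export
prevalence_table <- function(structured_flags, unstructured_flags, cohort,
                             domains = sdoh_domains) {
  check_flags(structured_flags, cohort, domains, "structured")
  check_flags(unstructured_flags, cohort, domains, "unstructured")
  n <- length(cohort)
  s <- structured_flags[match(cohort, structured_flags$patient_id), , drop = FALSE]
  u <- unstructured_flags[match(cohort, unstructured_flags$patient_id), , drop = FALSE]
  out <- data.frame(domain = domains, stringsAsFactors = FALSE)
  out$n_structured <- vapply(domains, function(d) sum(s[[d]]), integer(1))
  out$pct_structured <- round_half_up(100 * out$n_structured / max(n, 1L))
  out$n_unstructured <- vapply(domains, function(d) sum(u[[d]]), integer(1))
  out$pct_unstructured <- round_half_up(100 * out$n_unstructured / max(n, 1L))
  out$cohort_n <- n
  rownames(out) <- NULL
  out
}

#' Decompose rule-positive patients by structured documentation
#'
#' Partitions the narrative-rule-positive patients of one domain into those
#' with and without a corresponding structured code.
#'
#' @param domain domain name.
#' @param nlp_positive character vector (or set) of rule-positive patients.
#' @param structured_positive character vector of coded patients.
#' @return one-row data frame: domain, n_nlp_positive,
#'   n_with_structured_code, n_without_structured_code.
#' @export
overlap_summary <- function(domain, nlp_positive, structured_positive) {
  nlp_positive <- unique(nlp_positive)
  with_code <- sum(nlp_positive %in% structured_positive)
  data.frame(domain = domain,
             n_nlp_positive = length(nlp_positive),
             n_with_structured_code = with_code,
             n_without_structured_code = length(nlp_positive) - with_code,
             stringsAsFactors = FALSE)
}

#' Run the full structured-vs-narrative comparison
#'
#' The package's headline analysis: selects (or accepts) a cohort, flags
#' each patient's SDOH documentation from diagnosis codes and from
#' clinical-note rule matches, and reports per-domain prevalence and the
#' overlap decomposition. When review labels are supplied the unstructured
#' arm counts review-confirmed patients; otherwise raw rule-positive
#' patients (the mode is stamped on the result).
#'
#' @param notes notes data frame (see [read_notes_jsonl()]).
#' @param diagnoses,encounters record data frames.
#' @param rules named list of rules, default the packaged seven.
#' @param code_map Z-code map, default [sdoh_code_map()].
#' @param cohort optional pre-selected patient ids; computed with
#'   [select_diabetes_cohort()] when `NULL`.
#' @param window study window passed to cohort selection.
#' @param labels optional review labels (`unit_id`, `domain`, `reviewer_id`,
#'   `label`) from the adjudicating reviewer; confirmed notes are those
#'   labelled "confirmed".
#' @param eligible_types note types searched.
#' @return an object of class `sdoh_comparison`: list with `cohort`,
#'   `matches`, `prevalence`, `overlap`, `no_notes`, `mode`.
#' @export
sdoh_compare <- function(notes, diagnoses, encounters,
                         rules = sdoh_rules(), code_map = sdoh_code_map(),
                         cohort = NULL,
                         window = as.Date(c("2018-01-01", "2019-12-31")),
                         labels = NULL,
                         eligible_types = eligible_note_types) {
  if (is.null(cohort)) {
    cohort <- select_diabetes_cohort(encounters, diagnoses, window)
  }
  notes <- notes[notes$patient_id %in% cohort, , drop = FALSE]
  diagnoses <- diagnoses[diagnoses$patient_id %in% cohort, , drop = FALSE]
  matches <- sdoh_note_matches(rules, notes, eligible_types)
  mode <- "raw_nlp_positive"
  confirmed_ids <- NULL
  if (!is.null(labels)) {
    conf <- labels[labels$label == "confirmed", , drop = FALSE]
    confirmed_ids <- unique(conf$unit_id)
    mode <- "review_confirmed"
  }
  unstr <- patient_sdoh_flags(matches, patients = cohort,
                              domains = names(rules), note_ids = confirmed_ids)
  str <- structured_sdoh_flags(diagnoses, patients = cohort, code_map = code_map)
  prev <- prevalence_table(str, unstr, cohort, domains = names(rules))
  raw_flags <- patient_sdoh_flags(matches, patients = cohort,
                                  domains = names(rules))
  overlap <- do.call(rbind, lapply(names(rules), function(d) {
    overlap_summary(d, raw_flags$patient_id[raw_flags[[d]]],
                    str$patient_id[str[[d]]])
  }))
  no_notes <- setdiff(cohort, unique(notes$patient_id))
  structure(list(cohort = cohort, matches = matches, prevalence = prev,
                 overlap = overlap, structured_flags = str,
                 unstructured_flags = unstr, no_notes = no_notes,
                 mode = mode),
            class = "sdoh_comparison")
}

#' @export
print.sdoh_comparison <- function(x, ...) {
  cat("SDOH documentation comparison\n")
  cat("  cohort: ", length(x$cohort), " patients (",
      length(x$no_notes), " without notes)\n", sep = "")
  cat("  unstructured arm: ", x$mode, "\n\n", sep = "")
  print(x$prevalence, row.names = FALSE)
  cat("\nOverlap of rule-positive patients with structured codes:\n")
  print(x$overlap, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to CSV and JSON
#' @param x an `sdoh_comparison`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_comparison_report <- function(x, dir) {
  stopifnot(inherits(x, "sdoh_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$prevalence, file.path(dir, "prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(x$overlap, file.path(dir, "overlap.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mode = x$mode, cohort_n = length(x$cohort),
         no_notes = x$no_notes, prevalence = x$prevalence,
         overlap = x$overlap),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
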