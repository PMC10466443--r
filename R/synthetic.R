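# Synthetic EHR cohort generator ------------------------------------------
#
# Emulates the statistical structure the comparison pipeline assumes: a
# primary-care diabetes cohort in which each SDOH domain has a latent true
# prevalence, true cases are documented as a Z code with one (small)
# probability and as a narrative mention with another (larger) probability,
# and notes additionally carry confusable (false-positive) and
# exclusion-protected (negation) snippets. Filler text is drawn from a
# vocabulary disjoint from every token of every rule, so planted-evidence
# properties hold by construction rather than with high probability.

#' Build a validated synthetic-cohort configuration
#'
#' Defaults are calibrated so that, for a primary-care diabetes cohort, the
#' expected coded (structured) prevalence per domain falls around 0.1-0.7%
#' and the expected narrative-detectable prevalence around 0.8-5.2%,
#' reproducing the magnitude and direction of the documentation gap reported
#' for real cohorts.
#'
#' @param n_patients number of patients.
#' @param notes_per_patient mean of the Poisson note-count distribution.
#' @param true_prevalence per-domain probability of being a true case;
#'   scalar or named vector over [sdoh_domains].
#' @param structured_doc_rate probability a true case receives a Z code.
#' @param narrative_doc_rate probability a true case receives a
#'   true-positive snippet in at least one note.
#' @param fp_snippet_rate per-domain probability a patient receives a
#'   confusable (rule-matchable but spurious) snippet.
#' @param negation_rate per-domain probability a non-case receives an
#'   exclusion-protected negation snippet.
#' @param reviewer_error_rate per-label flip probability in
#'   [simulate_review()].
#' @param seed integer seed; generation is a pure function of the config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_patients = 500,
                         notes_per_patient = 7,
                         true_prevalence = c(social_connections = 0.0575,
                                             employment = 0.0575,
                                             housing = 0.0324,
                                             food = 0.0298,
                                             education = 0.0103,
                                             finance = 0.0330,
                                             stress = 0.0648),
                         structured_doc_rate = 0.10,
                         narrative_doc_rate = 0.80,
                         fp_snippet_rate = 0.02,
                         negation_rate = 0.02,
                         reviewer_error_rate = 0.02,
                         seed = 1L) {
  if (length(true_prevalence) == 1L && is.null(names(true_prevalence))) {
    true_prevalence <- setNames(rep(true_prevalence, length(sdoh_domains)),
                                sdoh_domains)
  }
  stopifnot(n_patients >= 1,
            notes_per_patient > 0,
            setequal(names(true_prevalence), sdoh_domains))
  props <- c(true_prevalence, structured_doc_rate, narrative_doc_rate,
             fp_snippet_rate, negation_rate, reviewer_error_rate)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient = notes_per_patient,
                 true_prevalence = true_prevalence[sdoh_domains],
                 structured_doc_rate = structured_doc_rate,
                 narrative_doc_rate = narrative_doc_rate,
                 fp_snippet_rate = fp_snippet_rate,
                 negation_rate = negation_rate,
                 reviewer_error_rate = reviewer_error_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# every token (stem) appearing anywhere in the rules, plus wildcard stems
rule_vocabulary <- function(rules) {
  stems <- character(); wild <- character()
  walk <- function(e) {
    if (e$kind == "phrase") {
      for (tp in e$terms) {
        if (tp$wildcard) wild <<- c(wild, tp$stem) else stems <<- c(stems, tp$stem)
      }
    } else if (e$kind %in% c("or", "and")) {
      lapply(e$children, walk)
    } else {
      walk(e$include); walk(e$exclude)
    }
    invisible(NULL)
  }
  for (r in rules) walk(r$expr)
  list(stems = unique(stems), wildcard_stems = unique(wild))
}

filler_candidates <- c(
  "patient", "clinic", "visit", "followup", "medication", "refill", "stable",
  "continue", "daily", "morning", "evening", "dose", "tablet", "blood",
  "pressure", "glucose", "cholesterol", "checked", "reviewed", "discussed",
  "routine", "chronic", "wellness", "improving", "tolerating", "denied",
  "returns", "weeks", "months", "appointment", "scheduled", "immunization",
  "influenza", "metformin", "insulin", "lisinopril", "diet", "ambulating",
  "alert", "oriented", "afebrile", "abdomen", "benign", "exam",
  "unremarkable", "cardiac", "pulmonary", "clear", "extremities", "edema",
  "gait", "steady", "hydration", "counseled", "portal", "message",
  "pharmacy", "instructions", "provided", "tolerated")

#' Filler vocabulary disjoint from every rule token
#'
#' Drops any candidate word equal to a rule term or matching a wildcard
#' stem, so filler text can never create or veto a rule match.
#' @param rules named list of rules.
#' @return character vector of safe filler words.
#' @export
filler_vocabulary <- function(rules = sdoh_rules()) {
  voc <- rule_vocabulary(rules)
  ok <- !(filler_candidates %in% voc$stems)
  for (w in voc$wildcard_stems) ok <- ok & !startsWith(filler_candidates, w)
  filler_candidates[ok]
}

# published example snippets used to seed the banks: narrative mentions the
# rules should confirm (true positives) and confusable phrasings the rules
# flag but review rejects (false positives)
example_true_positive <- c(
  social_connections = "Pt has difficulties with her mother and social isolation",
  employment = "Currently unemployed",
  housing = "Pt with unstable housing situation, homeless",
  food = "Diet remains problem with severe food insecurity",
  education = "Never went to school and cannot read",
  finance = "Pt has low income subsidy, financial difficulties",
  stress = "Feeling very stressed")

example_false_positive <- c(
  social_connections = "She is deeply concerned about her son's social isolation",
  employment = "Unemployed son",
  housing = "Volunteers at the animal shelter",
  food = "Food insecurity: none",
  education = "Cannot read fine print as well, notes older glasses work better at near",
  finance = "Withdrawn cognition: poverty of thought",
  stress = "Wife is stressed or complaining")

# flatten the include side of a rule into one snippet string per top-level
# entry (an AND group contributes all of its phrases in one snippet)
include_entry_snippets <- function(rule) {
  expr <- if (rule$expr$kind == "not") rule$expr$include else rule$expr
  entries <- if (expr$kind %in% c("or", "and")) expr$children else list(expr)
  phrase_text <- function(e) {
    if (e$kind == "phrase") {
      paste(vapply(e$terms, function(tp) tp$stem, character(1)), collapse = " ")
    } else {
      paste(vapply(e$children, phrase_text, character(1)), collapse = " ")
    }
  }
  vapply(entries, phrase_text, character(1))
}

exclude_entry_snippets <- function(rule) {
  if (rule$expr$kind != "not") return(character())
  expr <- rule$expr$exclude
  entries <- if (expr$kind %in% c("or", "and")) expr$children else list(expr)
  phrase_text <- function(e) {
    if (e$kind == "phrase") {
      paste(vapply(e$terms, function(tp) tp$stem, character(1)), collapse = " ")
    } else {
      paste(vapply(e$children, phrase_text, character(1)), collapse = " ")
    }
  }
  vapply(entries, phrase_text, character(1))
}

#' Snippet bank for one SDOH domain
#'
#' True-positive templates are the published example mentions plus one
#' snippet per include entry of the domain rule; every template is verified
#' to classify positive under the rule (a template vetoed by the rule's own
#' exclusion list is dropped). Confusable templates are the published
#' false-positive examples. Negation templates embed the rule's NOT-list
#' phrases and always classify negative.
#'
#' @param domain one of [sdoh_domains].
#' @param rules named rule list (packaged rules by default).
#' @return list with `true_positive`, `confusable`, `negation` character
#'   vectors.
#' @export
snippet_bank <- function(domain, rules = sdoh_rules()) {
  if (!domain %in% names(rules)) stop("unknown domain: ", domain)
  rule <- rules[[domain]]
  tp <- unique(c(example_true_positive[[domain]], include_entry_snippets(rule)))
  tp_ok <- vapply(tp, function(s) {
    classify_note_norms(rule, token_norms(s))$positive
  }, logical(1))
  neg <- exclude_entry_snippets(rule)
  list(true_positive = unname(tp[tp_ok]),
       confusable = unname(example_false_positive[[domain]]),
       negation = unname(neg))
}

#' Generate a synthetic EHR cohort
#'
#' Every patient satisfies the diabetes-cohort criteria (two completed
#' primary-care encounters on distinct dates plus an E10/E11 diagnosis in
#' the window). For each domain, a true case independently receives a Z code
#' with probability `structured_doc_rate` and a true-positive snippet in an
#' eligible-type note with probability `narrative_doc_rate`; confusable and
#' negation snippets are planted per config. At most one snippet is planted
#' per note, so planted evidence is never vetoed by an unrelated snippet's
#' tokens. Deterministic for a fixed config.
#'
#' @param config a [synth_config()].
#' @param rules named rule list used for snippet banks and filler safety.
#' @param window study window for dates.
#' @return list with `notes`, `diagnoses`, `encounters` data frames, and
#'   `truth`: a list of `cases` (patient x domain logicals) and `inventory`
#'   (patient_id, domain, note_id, kind of every planted snippet).
#' @export
generate_cohort <- function(config, rules = sdoh_rules(),
                            window = as.Date(c("2018-01-01", "2019-12-31"))) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, generate_cohort_impl(config, rules, window))
}

generate_cohort_impl <- function(config, rules, window) {
  n <- config$n_patients
  domains <- names(rules)
  pid <- sprintf("P%05d", seq_len(n))
  filler <- filler_vocabulary(rules)
  banks <- lapply(setNames(domains, domains), snippet_bank, rules = rules)
  code_map <- sdoh_code_map()
  day_pool <- seq(window[1], window[2], by = "day")
  random_dates <- function(k, replace = TRUE) {
    day_pool[sample.int(length(day_pool), k, replace = replace)]
  }

  # encounters: the two qualifying visits, plus occasional extras
  enc <- list()
  for (i in seq_len(n)) {
    d2 <- random_dates(2L, replace = FALSE)  # distinct dates of service
    rows <- data.frame(patient_id = pid[i], department_class = "primary care",
                       date = d2, completed = TRUE, stringsAsFactors = FALSE)
    if (runif(1) < 0.25) {
      rows <- rbind(rows, data.frame(patient_id = pid[i],
                                     department_class = "specialty",
                                     date = random_dates(1L),
                                     completed = TRUE, stringsAsFactors = FALSE))
    }
    if (runif(1) < 0.15) {
      rows <- rbind(rows, data.frame(patient_id = pid[i],
                                     department_class = "primary care",
                                     date = random_dates(1L),
                                     completed = FALSE, stringsAsFactors = FALSE))
    }
    enc[[i]] <- rows
  }
  encounters <- do.call(rbind, enc)

  # diabetes diagnoses
  dm_codes <- c("E11.9", "E11.65", "E10.9")
  diagnoses <- data.frame(
    patient_id = pid,
    code = sample(dm_codes, n, replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    date = random_dates(n), stringsAsFactors = FALSE)

  # latent truth
  cases <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
  for (d in domains) cases[[d]] <- runif(n) < config$true_prevalence[[d]]

  # structured documentation of true cases
  z_rows <- list()
  for (d in domains) {
    stems <- code_map$code_stem[code_map$domain == d]
    doc <- cases[[d]] & (runif(n) < config$structured_doc_rate)
    idx <- which(doc)
    if (length(idx)) {
      z_rows[[d]] <- data.frame(
        patient_id = pid[idx],
        code = sample(stems, length(idx), replace = TRUE),
        date = random_dates(length(idx)), stringsAsFactors = FALSE)
    }
  }
  if (length(z_rows)) diagnoses <- rbind(diagnoses, do.call(rbind, z_rows))
  rownames(diagnoses) <- NULL

  # notes: filler text, Poisson counts, mostly eligible types
  type_pool <- c(eligible_note_types, "other")
  type_prob <- c(0.45, 0.20, 0.15, 0.10, 0.10)
  note_rows <- list()
  note_counter <- 0L
  new_note <- function(p, type) {
    note_counter <<- note_counter + 1L
    k <- sample(8:25, 1L)
    data.frame(note_id = sprintf("N%06d", note_counter), patient_id = p,
               note_type = type, date = random_dates(1L),
               text = paste(sample(filler, k, replace = TRUE), collapse = " "),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    k <- stats::rpois(1L, config$notes_per_patient)
    if (k > 0L) {
      types <- sample(type_pool, k, replace = TRUE, prob = type_prob)
      note_rows[[i]] <- do.call(rbind, lapply(types, function(tt) new_note(pid[i], tt)))
    }
  }
  notes <- if (length(note_rows)) do.call(rbind, note_rows[!vapply(note_rows, is.null, logical(1))])
           else new_note(pid[1], "progress note")[0, ]
  rownames(notes) <- NULL

  # snippet planting: one snippet per note; extra eligible notes are
  # appended when a patient runs out of unoccupied eligible notes
  occupied <- character()
  inventory <- list()
  plant <- function(p, d, kind, snippet) {
    cand <- which(notes$patient_id == p &
                    notes$note_type %in% eligible_note_types &
                    !(notes$note_id %in% occupied))
    if (length(cand) == 0L) {
      nn <- new_note(p, "progress note")
      notes <<- rbind(notes, nn)
      cand <- nrow(notes)
    }
    j <- cand[sample.int(length(cand), 1L)]
    lead <- paste(sample(filler, 3L, replace = TRUE), collapse = " ")
    tail_ <- paste(sample(filler, 3L, replace = TRUE), collapse = " ")
    notes$text[j] <<- paste(lead, snippet, tail_)
    occupied <<- c(occupied, notes$note_id[j])
    inventory[[length(inventory) + 1L]] <<-
      data.frame(patient_id = p, domain = d, note_id = notes$note_id[j],
                 kind = kind, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    for (d in domains) {
      bank <- banks[[d]]
      if (cases[[d]][i] && runif(1) < config$narrative_doc_rate) {
        plant(pid[i], d, "true_positive",
              bank$true_positive[sample.int(length(bank$true_positive), 1L)])
      }
      if (runif(1) < config$fp_snippet_rate) {
        plant(pid[i], d, "confusable",
              bank$confusable[sample.int(length(bank$confusable), 1L)])
      }
      if (!cases[[d]][i] && length(bank$negation) > 0L &&
            runif(1) < config$negation_rate) {
        plant(pid[i], d, "negation",
              bank$negation[sample.int(length(bank$negation), 1L)])
      }
    }
  }
  rownames(notes) <- NULL
  inventory <- if (length(inventory)) do.call(rbind, inventory) else
    data.frame(patient_id = character(), domain = character(),
               note_id = character(), kind = character(),
               stringsAsFactors = FALSE)

  list(notes = notes, diagnoses = diagnoses, encounters = encounters,
       truth = list(cases = cases, inventory = inventory))
}

#' Simulate the two-reviewer chart review
#'
#' Reviewer labels follow the planted ground truth (a flagged note is truly
#' positive iff it carries a planted true-positive snippet for the domain),
#' with each label independently flipped with probability
#' `reviewer_error_rate`, independently for the two reviewers.
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param matches positive note-level matches from [sdoh_note_matches()].
#' @param reviewer_error_rate per-label flip probability.
#' @param seed integer seed.
#' @return data frame of `ReviewLabel`s: unit_id, domain, reviewer_id,
#'   label ("confirmed"/"not_confirmed"), plus `truth` (the planted status).
#' @export
simulate_review <- function(truth, matches, reviewer_error_rate, seed) {
  stopifnot(reviewer_error_rate >= 0, reviewer_error_rate <= 1)
  pos <- matches[matches$positive, , drop = FALSE]
  inv <- truth$inventory
  tp_key <- paste(inv$note_id[inv$kind == "true_positive"],
                  inv$domain[inv$kind == "true_positive"])
  is_tp <- paste(pos$note_id, pos$domain) %in% tp_key
  local_seed(seed, {
    out <- lapply(c("R1", "R2"), function(rev) {
      flip <- stats::runif(nrow(pos)) < reviewer_error_rate
      lab <- ifelse(xor(is_tp, flip), "confirmed", "not_confirmed")
      data.frame(unit_id = pos$note_id, domain = pos$domain,
                 reviewer_id = rev, label = lab, truth = is_tp,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Write a synthetic cohort to disk
#'
#' Notes as JSONL; diagnoses, encounters, cases and planted-snippet
#' inventory as CSV.
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_notes_jsonl(cohort$notes, file.path(dir, "notes.jsonl"))
  utils::write.csv(cohort$diagnoses, file.path(dir, "diagnoses.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$encounters, file.path(dir, "encounters.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$cases, file.path(dir, "truth_cases.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$inventory,
                   file.path(dir, "truth_inventory.csv"), row.names = FALSE)
  invisible(dir)
}
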