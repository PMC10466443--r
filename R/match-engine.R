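# Proximity match engine ---------------------------------------------------
#
# Matching operates on the normalized token stream of one note. A phrase with
# k terms and slop s matches every minimal token window of length <= k + s
# that contains all terms (each term matched by a distinct token, by equality
# or wildcard prefix). With slop 0 the terms must be adjacent and in order.
# Boolean NOT is document-scoped: one exclusion hit anywhere in the note
# vetoes the rule for that note.

term_hit_positions <- function(tp, norms) {
  if (tp$wildcard) which(startsWith(norms, tp$stem)) else which(norms == tp$stem)
}

# Can the terms be assigned to distinct matching positions within [s, e]?
# Backtracking assignment, terms ordered by fewest candidates first.
window_covers <- function(hits, s, e) {
  avail <- lapply(hits, function(h) h[h >= s & h <= e])
  if (any(lengths(avail) == 0L)) return(NULL)
  ord <- order(lengths(avail))
  avail <- avail[ord]
  assign_rec <- function(k, used) {
    if (k > length(avail)) return(used)
    for (p in avail[[k]]) {
      if (!(p %in% used)) {
        res <- assign_rec(k + 1L, c(used, p))
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  assign_rec(1L, integer())
}

empty_spans <- function() {
  data.frame(start = integer(), end = integer(), matched = character(),
             stringsAsFactors = FALSE)
}

make_spans <- function(starts, ends, norms) {
  if (length(starts) == 0L) return(empty_spans())
  matched <- mapply(function(s, e) paste(norms[s:e], collapse = " "),
                    starts, ends)
  # token positions are 0-based, matching tokenize()
  data.frame(start = starts - 1L, end = ends - 1L,
             matched = as.character(matched), stringsAsFactors = FALSE)
}

#' Find phrase matches in a tokenized note
#'
#' Reports a span for every minimal token window containing all phrase terms
#' within the slop-bounded window length. With `slop = 0` the terms must be
#' adjacent, in order; with `slop > 0` they may appear in any order within a
#' window of at most `length(terms) + slop` tokens. Overlapping windows are
#' deduplicated to minimal ones (no reported window strictly contains
#' another matching window).
#'
#' @param phrase a phrase query node, e.g. from [parse_rule()].
#' @param tokens a data frame from [tokenize()], or a character vector of
#'   normalized tokens.
#' @return data frame of spans with 0-based `start`, `end` token positions
#'   and the `matched` window text.
#' @export
phrase_matches <- function(phrase, tokens) {
  norms <- if (is.data.frame(tokens)) tokens$norm else tokens
  terms <- phrase$terms
  k <- length(terms)
  L <- length(norms)
  if (L < k) return(empty_spans())
  hits <- lapply(terms, term_hit_positions, norms = norms)
  if (any(lengths(hits) == 0L)) return(empty_spans())
  if (phrase$slop == 0L) {
    starts <- hits[[1L]][hits[[1L]] <= L - k + 1L]
    if (k > 1L) {
      for (j in 2:k) starts <- starts[(starts + j - 1L) %in% hits[[j]]]
    }
    return(make_spans(starts, starts + k - 1L, norms))
  }
  cap <- k + phrase$slop
  active <- sort(unique(unlist(hits)))
  starts <- integer()
  ends <- integer()
  for (s in active) {
    e_max <- min(L, s + cap - 1L)
    e_min <- s + k - 1L
    if (e_min > e_max) next
    for (e in e_min:e_max) {
      if (!is.null(window_covers(hits, s, e))) {
        # minimal iff neither trimming side still covers; e is already the
        # smallest end for this start
        if (is.null(window_covers(hits, s + 1L, e))) {
          starts <- c(starts, s)
          ends <- c(ends, e)
        }
        break
      }
    }
  }
  make_spans(starts, ends, norms)
}

#' Evaluate a query expression against a tokenized note
#'
#' Phrase nodes are true iff they have at least one match; `or`/`and` combine
#' children; a `not` node is true iff its include side matches and its
#' exclude side has no match anywhere in the note. Evidence spans are the
#' include-side matches when the expression is true.
#'
#' @inheritParams phrase_matches
#' @param expr a `query_expr`.
#' @return list with `hit` (logical) and `spans` (data frame).
#' @export
evaluate_query <- function(expr, tokens) {
  norms <- if (is.data.frame(tokens)) tokens$norm else tokens
  switch(expr$kind,
    phrase = {
      spans <- phrase_matches(expr, norms)
      list(hit = nrow(spans) > 0L, spans = spans)
    },
    or = {
      spans <- empty_spans()
      hit <- FALSE
      for (ch in expr$children) {
        res <- evaluate_query(ch, norms)
        if (res$hit) { hit <- TRUE; spans <- rbind(spans, res$spans) }
      }
      list(hit = hit, spans = spans)
    },
    and = {
      spans <- empty_spans()
      for (ch in expr$children) {
        res <- evaluate_query(ch, norms)
        if (!res$hit) return(list(hit = FALSE, spans = empty_spans()))
        spans <- rbind(spans, res$spans)
      }
      list(hit = TRUE, spans = spans)
    },
    not = {
      inc <- evaluate_query(expr$include, norms)
      if (!inc$hit) return(list(hit = FALSE, spans = empty_spans()))
      exc <- evaluate_query(expr$exclude, norms)
      if (exc$hit) list(hit = FALSE, spans = empty_spans()) else inc
    },
    stop("unknown query node kind: ", expr$kind)
  )
}

#' Classify one clinical note against one rule
#'
#' @param rule an `sdoh_rule`.
#' @param note a list or one-row data frame with at least `note_id` and
#'   `text` fields.
#' @return a `match_result`: note_id, domain, include_hit, exclude_hit,
#'   positive (`include_hit & !exclude_hit`) and the evidence spans.
#' @export
classify_note <- function(rule, note) {
  norms <- token_norms(as.character(note$text))
  if (rule$expr$kind == "not") {
    inc <- evaluate_query(rule$expr$include, norms)
    exclude_hit <- if (inc$hit) evaluate_query(rule$expr$exclude, norms)$hit else FALSE
  } else {
    inc <- evaluate_query(rule$expr, norms)
    exclude_hit <- FALSE
  }
  positive <- inc$hit && !exclude_hit
  structure(list(note_id = note$note_id, domain = rule$domain,
                 include_hit = inc$hit, exclude_hit = exclude_hit,
                 positive = positive,
                 evidence = if (positive) inc$spans else empty_spans()),
            class = "match_result")
}

#' Note types searched by default
#'
#' The four note categories the narrative search is restricted to; notes of
#' any other type are ignored when aggregating to patient level.
#' @export
eligible_note_types <- c("progress note", "telephone encounter",
                         "history and physical", "assessment and plan")

#' Patient-level SDOH flags from one patient's notes
#'
#' A domain flag is true iff at least one note of an eligible type is
#' positive for that domain's rule (patient-level OR over notes).
#'
#' @param rules named list of `sdoh_rule`s (see [sdoh_rules()]).
#' @param notes data frame of one patient's notes (`note_id`, `patient_id`,
#'   `note_type`, `text`); zero rows allowed.
#' @param eligible_types note types considered; others are skipped.
#' @return named logical vector over the rules' domains, with attribute
#'   `no_notes = TRUE` when the patient had no notes at all.
#' @export
classify_patient_unstructured <- function(rules, notes,
                                          eligible_types = eligible_note_types) {
  stopifnot(length(unique(notes$patient_id)) <= 1L)
  flags <- setNames(rep(FALSE, length(rules)), names(rules))
  no_notes <- nrow(notes) == 0L
  if (!no_notes) {
    keep <- notes$note_type %in% eligible_types
    for (i in which(keep)) {
      todo <- names(flags)[!flags]
      if (length(todo) == 0L) break
      norms <- token_norms(as.character(notes$text[i]))
      for (d in todo) {
        if (evaluate_rule_hit(rules[[d]], norms)) flags[d] <- TRUE
      }
    }
  }
  attr(flags, "no_notes") <- no_notes
  flags
}

# boolean-only evaluation (no evidence assembly), used on hot paths
evaluate_rule_hit <- function(rule, norms) {
  expr <- rule$expr
  if (expr$kind == "not") {
    hit_query(expr$include, norms) && !hit_query(expr$exclude, norms)
  } else {
    hit_query(expr, norms)
  }
}

hit_query <- function(expr, norms) {
  switch(expr$kind,
    phrase = {
      for (tp in expr$terms) {
        present <- if (tp$wildcard) any(startsWith(norms, tp$stem))
                   else tp$stem %in% norms
        if (!present) return(FALSE)
      }
      if (length(expr$terms) == 1L) return(TRUE)
      nrow(phrase_matches(expr, norms)) > 0L
    },
    or = {
      for (ch in expr$children) if (hit_query(ch, norms)) return(TRUE)
      FALSE
    },
    and = {
      for (ch in expr$children) if (!hit_query(ch, norms)) return(FALSE)
      TRUE
    },
    not = stop("NOT below the root is not supported"),
    stop("unknown query node kind: ", expr$kind)
  )
}

#' Note-level match results over a corpus
#'
#' Runs every rule over every note (tokenizing each note once) and returns
#' one row per note and domain, with evidence spans serialized as
#' semicolon-joined `window@start-end` strings for chart review.
#'
#' @inheritParams classify_patient_unstructured
#' @param notes data frame of notes for any number of patients.
#' @param keep_negative keep rows for negative notes (default `FALSE`).
#' @return data frame: note_id, patient_id, note_type, domain, include_hit,
#'   exclude_hit, positive, evidence.
#' @export
sdoh_note_matches <- function(rules, notes,
                              eligible_types = eligible_note_types,
                              keep_negative = FALSE) {
  req <- c("note_id", "patient_id", "note_type", "text")
  stopifnot(all(req %in% names(notes)))
  if (anyDuplicated(notes$note_id)) stop("note_id must be unique within a corpus")
  keep <- which(notes$note_type %in% eligible_types)
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    norms <- token_norms(as.character(notes$text[i]))
    recs <- lapply(rules, function(rule) {
      res <- classify_note_norms(rule, norms)
      if (!res$positive && !res$include_hit && !keep_negative) return(NULL)
      data.frame(note_id = notes$note_id[i], patient_id = notes$patient_id[i],
                 note_type = notes$note_type[i], domain = rule$domain,
                 include_hit = res$include_hit, exclude_hit = res$exclude_hit,
                 positive = res$positive,
                 evidence = serialize_spans(res$evidence),
                 stringsAsFactors = FALSE)
    })
    recs <- recs[!vapply(recs, is.null, logical(1))]
    rows[[j]] <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(note_id = character(), patient_id = character(),
                      note_type = character(), domain = character(),
                      include_hit = logical(), exclude_hit = logical(),
                      positive = logical(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

classify_note_norms <- function(rule, norms) {
  expr <- rule$expr
  if (expr$kind == "not") {
    # cheap boolean screen before assembling evidence
    if (!hit_query(expr$include, norms)) {
      return(list(include_hit = FALSE, exclude_hit = FALSE, positive = FALSE,
                  evidence = empty_spans()))
    }
    inc <- evaluate_query(expr$include, norms)
    exclude_hit <- hit_query(expr$exclude, norms)
  } else {
    if (!hit_query(expr, norms)) {
      return(list(include_hit = FALSE, exclude_hit = FALSE, positive = FALSE,
                  evidence = empty_spans()))
    }
    inc <- evaluate_query(expr, norms)
    exclude_hit <- FALSE
  }
  positive <- inc$hit && !exclude_hit
  list(include_hit = inc$hit, exclude_hit = exclude_hit, positive = positive,
       evidence = if (positive) inc$spans else empty_spans())
}

serialize_spans <- function(spans) {
  if (nrow(spans) == 0L) return("")
  paste(sprintf("%s@%d-%d", gsub(" ", "+", spans$matched),
                spans$start, spans$end), collapse = ";")
}

#' Patient-level SDOH flags for a whole cohort
#'
#' Aggregates note-level matches to per-patient, per-domain flags. Patients
#' listed in `patients` but absent from the notes (no notes at all) get
#' all-false flags and are reported in the `no_notes` attribute.
#'
#' @param matches output of [sdoh_note_matches()].
#' @param patients character vector of all patient ids in the cohort;
#'   defaults to the patients appearing in `matches`.
#' @param domains domains to report columns for.
#' @param note_ids optional character vector restricting which notes count
#'   (e.g. only review-confirmed notes).
#' @return data frame with `patient_id` and one logical column per domain;
#'   attribute `no_notes` lists patients without notes.
#' @export
patient_sdoh_flags <- function(matches, patients = NULL,
                               domains = sdoh_domains, note_ids = NULL) {
  if (is.null(patients)) patients <- sort(unique(matches$patient_id))
  pos <- matches[matches$positive, , drop = FALSE]
  if (!is.null(note_ids)) pos <- pos[pos$note_id %in% note_ids, , drop = FALSE]
  flags <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (d in domains) {
    hit_pat <- unique(pos$patient_id[pos$domain == d])
    flags[[d]] <- flags$patient_id %in% hit_pat
  }
  flags
}

#' Read clinical notes from JSONL
#'
#' One JSON object per line with fields `note_id`, `patient_id`, `note_type`,
#' `date` (ISO-8601) and `text`.
#' @param path file path.
#' @return notes data frame with `date` parsed to `Date`.
#' @export
read_notes_jsonl <- function(path) {
  notes <- jsonlite::stream_in(file(path), verbose = FALSE)
  notes$date <- as.Date(notes$date)
  notes
}

#' Write clinical notes to JSONL
#' @param notes notes data frame.
#' @param path file path.
#' @export
write_notes_jsonl <- function(notes, path) {
  notes$date <- as.character(notes$date)
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(notes, con, verbose = FALSE)
  invisible(path)
}

#' Write note-level matches to CSV
#' @param matches output of [sdoh_note_matches()].
#' @param path file path.
#' @export
write_matches_csv <- function(matches, path) {
  utils::write.csv(matches, path, row.names = FALSE)
  invisible(path)
}
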