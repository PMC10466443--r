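rules <- sdoh_rules()

token_norms_pub <- function(x) tokenize(x)$norm

phrase_of <- function(stems, slop = 0L) {
  structure(list(kind = "phrase",
                 terms = lapply(stems, function(s) list(stem = s, wildcard = FALSE)),
                 slop = as.integer(slop)),
            class = "query_expr")
}

test_that("phrase matching honours slop-bounded windows", {
  tk <- tokenize("pt reports social isolation at home")
  sp <- phrase_matches(phrase_of(c("social", "isolation"), 10L), tk)
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$start, sp$end), c(2L, 3L))

  # terms separated by 11 fillers exceed a slop-10 window of length 12
  far <- c("social", paste0("w", 1:11), "isolation")
  expect_equal(nrow(phrase_matches(phrase_of(c("social", "isolation"), 10L), far)), 0L)
  # ... but a slop-11 window reaches
  expect_equal(nrow(phrase_matches(phrase_of(c("social", "isolation"), 11L), far)), 1L)

  sp2 <- phrase_matches(phrase_of(c("isolation", "14"), 6L),
                        token_norms_pub("isolation precautions for 14 days"))
  expect_equal(nrow(sp2), 1L)

  # slop 0 needs exact in-order adjacency
  expect_equal(nrow(phrase_matches(phrase_of(c("food", "insecurity")),
                                   c("insecurity", "food"))), 0L)
  expect_equal(nrow(phrase_matches(phrase_of(c("food", "insecurity")),
                                   c("x", "food", "insecurity", "y"))), 1L)
})

test_that("phrase matching agrees with the exhaustive window oracle", {
  set.seed(301)
  for (i in 1:400) expect_spans_equal_oracle(random_phrase_instance())
})

test_that("query evaluation applies document-level exclusion", {
  hit <- function(rule, text) classify_note(rule, make_note(text))$positive
  # include term fires, no exclusion phrase present
  expect_true(hit(rules$housing, "Volunteers at the animal shelter"))
  # include fires but the negated phrasing vetoes the whole note
  res <- classify_note(rules$food, make_note("Denies food insecurity at this time"))
  expect_true(res$include_hit)
  expect_true(res$exclude_hit)
  expect_false(res$positive)
  expect_true(hit(rules$education, "Never went to school and cannot read"))
  expect_true(hit(rules$employment, "Currently unemployed"))
  # the rule cannot tell whose unemployment it is; review catches it later
  expect_true(hit(rules$employment, "Unemployed son"))
  expect_false(hit(rules$stress, "cardiac stress test ordered"))
  # an exclusion hit anywhere in the note vetoes an include hit elsewhere
  expect_false(hit(rules$food,
                   paste("severe food insecurity today.",
                         "Intake form: FOOD INSECURITY: Negative")))
})

test_that("positive results always carry evidence spans", {
  res <- classify_note(rules$social_connections,
                       make_note("Pt has difficulties with her mother and social isolation"))
  expect_true(res$positive)
  expect_gt(nrow(res$evidence), 0L)
  expect_true(all(res$evidence$start <= res$evidence$end))
  neg <- classify_note(rules$food, make_note(""))
  expect_false(neg$positive)
  expect_equal(nrow(neg$evidence), 0L)
})

test_that("patient-level flags OR over eligible notes only", {
  notes <- rbind(
    make_note("routine visit, stable", "n1"),
    make_note("Diet remains problem with severe food insecurity", "n2"),
    make_note(paste(rep("clinic followup", 5), collapse = " "), "n3"))
  flags <- classify_patient_unstructured(rules, notes)
  expect_true(flags[["food"]])
  expect_false(any(flags[setdiff(sdoh_domains, "food")]))
  expect_false(attr(flags, "no_notes"))

  # the same mention in an ineligible note type does not count
  notes2 <- make_note("severe food insecurity", "n1", note_type = "other")
  expect_false(classify_patient_unstructured(rules, notes2)[["food"]])

  # zero notes: all flags false, and the absence is reported
  empty <- make_note("x")[0, ]
  flags0 <- classify_patient_unstructured(rules, empty)
  expect_false(any(flags0))
  expect_true(attr(flags0, "no_notes"))

  # a coded-looking false positive still flags: review exists for a reason
  expect_true(classify_patient_unstructured(
    rules, make_note("Food insecurity: none"))[["food"]])
})

test_that("NOT-list phrases embedded in disjoint filler always classify negative", {
  set.seed(21)
  for (d in sdoh_domains) {
    rule <- rules[[d]]
    for (snip in sdohscan:::exclude_entry_snippets(rule)) {
      note <- make_note(embed_in_filler(snip))
      expect_false(classify_note(rule, note)$positive,
                   info = paste(d, "/", snip))
    }
  }
})

test_that("filler insertion never flips a classification", {
  set.seed(22)
  voc <- filler_vocabulary()
  for (d in sdoh_domains) {
    bank <- snippet_bank(d)
    for (snip in bank$true_positive[seq_len(min(3, length(bank$true_positive)))]) {
      base <- classify_note(rules[[d]], make_note(snip))$positive
      expect_true(base, info = paste(d, snip))
      padded <- embed_in_filler(snip, 8, 8)
      expect_true(classify_note(rules[[d]], make_note(padded))$positive,
                  info = paste(d, padded))
    }
    # pure filler never matches anything
    blank <- paste(sample(voc, 40, replace = TRUE), collapse = " ")
    expect_false(classify_note(rules[[d]], make_note(blank))$include_hit)
  }
})

test_that("corpus matching yields one row per flagged note and domain", {
  notes <- rbind(
    make_note("Feeling very stressed", "n1", "p1"),
    make_note("Currently unemployed", "n2", "p1"),
    make_note("routine followup", "n3", "p2"),
    make_note("Currently unemployed", "n4", "p2", note_type = "other"))
  m <- sdoh_note_matches(rules, notes)
  expect_setequal(m$note_id[m$positive], c("n1", "n2"))
  expect_setequal(m$domain[m$positive], c("stress", "employment"))
  expect_true(all(m$positive == (m$include_hit & !m$exclude_hit)))
  expect_true(all(nzchar(m$evidence[m$positive])))
  flags <- patient_sdoh_flags(m, patients = c("p1", "p2"))
  expect_true(flags$stress[flags$patient_id == "p1"])
  expect_false(any(flags$employment[flags$patient_id == "p2"]))
  expect_error(sdoh_note_matches(rules, rbind(notes, notes[1, ])), "unique")
})

test_that("notes survive a JSONL round trip", {
  notes <- rbind(make_note("Feeling very stressed", "n1"),
                 make_note("”curly“ quotes — and émojis", "n2"))
  f <- tempfile(fileext = ".jsonl")
  on.exit(unlink(f))
  write_notes_jsonl(notes, f)
  back <- read_notes_jsonl(f)
  expect_equal(back$text, notes$text)
  expect_equal(back$date, notes$date)
})
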