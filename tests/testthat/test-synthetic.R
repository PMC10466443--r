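rules <- sdoh_rules()

test_that("config invariants are enforced before generation", {
  expect_error(synth_config(n_patients = 0), "n_patients")
  expect_error(synth_config(narrative_doc_rate = 1.2), "proportions")
  expect_error(synth_config(true_prevalence = c(food = 0.1)), "setequal")
  cfg <- synth_config(true_prevalence = 0.05)
  expect_equal(unname(cfg$true_prevalence), rep(0.05, 7))
})

test_that("generation is a pure function of the config", {
  cfg <- synth_config(n_patients = 60, seed = 14)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c_ <- generate_cohort(synth_config(n_patients = 60, seed = 15))
  expect_false(identical(a$notes$text, c_$notes$text))
})

test_that("every synthetic patient satisfies the cohort criteria", {
  coh <- generate_cohort(synth_config(n_patients = 80, seed = 3))
  suppressMessages(
    sel <- select_diabetes_cohort(coh$encounters, coh$diagnoses))
  expect_setequal(sel, coh$truth$cases$patient_id)
})

test_that("snippet banks contain the published terminologies", {
  food <- snippet_bank("food")
  expect_true("Diet remains problem with severe food insecurity" %in%
                food$true_positive)
  housing <- snippet_bank("housing")
  expect_true("Volunteers at the animal shelter" %in% housing$confusable)
  stress <- snippet_bank("stress")
  expect_true(any(grepl("stressed importance", stress$negation)))
  expect_error(snippet_bank("transport"), "unknown domain")
  # every true-positive template really is detected by its rule,
  # and no template leaks into other domains' rules
  for (d in sdoh_domains) {
    bank <- snippet_bank(d)
    for (snip in bank$true_positive) {
      expect_true(classify_note(rules[[d]], make_note(snip))$positive,
                  info = paste(d, snip))
    }
    for (snip in bank$negation) {
      expect_false(classify_note(rules[[d]], make_note(snip))$positive,
                   info = paste(d, snip))
    }
  }
})

test_that("filler vocabulary is disjoint from every rule token", {
  voc <- filler_vocabulary(rules)
  expect_gt(length(voc), 20L)
  rv <- sdohscan:::rule_vocabulary(rules)
  expect_length(intersect(voc, rv$stems), 0L)
  for (w in rv$wildcard_stems) expect_false(any(startsWith(voc, w)))
})

test_that("documentation rates recover their configured products", {
  cfg <- synth_config(n_patients = 500, true_prevalence = 0.05,
                      structured_doc_rate = 0.1, narrative_doc_rate = 0.8,
                      seed = 1)
  coh <- generate_cohort(cfg)
  n <- cfg$n_patients
  map <- sdoh_code_map()
  sflags <- structured_sdoh_flags(coh$diagnoses,
                                  patients = coh$truth$cases$patient_id, map)
  inv <- coh$truth$inventory
  for (d in sdoh_domains) {
    p_struct <- 0.05 * 0.1
    se <- sqrt(p_struct * (1 - p_struct) / n)
    expect_lt(abs(sum(sflags[[d]]) / n - p_struct), 3 * se + 1e-9)
    p_narr <- 0.05 * 0.8
    se_n <- sqrt(p_narr * (1 - p_narr) / n)
    n_tp <- length(unique(inv$patient_id[inv$domain == d &
                                           inv$kind == "true_positive"]))
    expect_lt(abs(n_tp / n - p_narr), 3 * se_n)
  }
})

test_that("planted true-positive evidence is always recalled", {
  coh <- generate_cohort(synth_config(n_patients = 150, seed = 9))
  m <- sdoh_note_matches(rules, coh$notes)
  pos_key <- paste(m$note_id[m$positive], m$domain[m$positive])
  inv <- coh$truth$inventory
  tp <- inv[inv$kind == "true_positive", ]
  expect_gt(nrow(tp), 0L)
  expect_true(all(paste(tp$note_id, tp$domain) %in% pos_key))
  # and every positive is explained by a planted snippet (filler is inert)
  expect_true(all(pos_key %in% paste(inv$note_id, inv$domain)))
  # negation plants never flag
  ng <- inv[inv$kind == "negation", ]
  expect_false(any(paste(ng$note_id, ng$domain) %in% pos_key))
})

test_that("with no narrative documentation only confusables flag", {
  coh <- generate_cohort(synth_config(n_patients = 120, narrative_doc_rate = 0,
                                      fp_snippet_rate = 0.1, seed = 4))
  m <- sdoh_note_matches(rules, coh$notes)
  inv <- coh$truth$inventory
  expect_false(any(inv$kind == "true_positive"))
  pos_key <- paste(m$note_id[m$positive], m$domain[m$positive])
  conf_key <- paste(inv$note_id[inv$kind == "confusable"],
                    inv$domain[inv$kind == "confusable"])
  expect_true(all(pos_key %in% conf_key))
})

test_that("simulated review behaves like reviewers with the configured error", {
  coh <- generate_cohort(synth_config(n_patients = 400, fp_snippet_rate = 0.05,
                                      seed = 6))
  m <- sdoh_note_matches(rules, coh$notes)

  # perfect reviewers reproduce ground truth exactly
  lab0 <- simulate_review(coh$truth, m, reviewer_error_rate = 0, seed = 2)
  expect_true(all((lab0$label == "confirmed") == lab0$truth))
  r1 <- lab0[lab0$reviewer_id == "R1", ]
  if (length(unique(r1$label)) > 1) {
    ks <- agreement_from_labels(lab0[, c("unit_id", "domain", "reviewer_id", "label")],
                                domain = r1$domain[1])
    expect_equal(ks$kappa, 1)
  }

  # error rate e gives observed agreement about (1-e)^2 + e^2
  e <- 0.02
  lab <- simulate_review(coh$truth, m, reviewer_error_rate = e, seed = 2)
  r1 <- lab[lab$reviewer_id == "R1", ]
  r2 <- lab[lab$reviewer_id == "R2", ]
  p_o <- proportional_agreement(r1$label, r2$label)
  target <- (1 - e)^2 + e^2
  se <- sqrt(target * (1 - target) / nrow(r1))
  expect_lt(abs(p_o - target), 3 * se + 1e-9)
  # determinism
  expect_identical(lab, simulate_review(coh$truth, m, e, seed = 2))
})
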