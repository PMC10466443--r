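# Independent brute-force oracle for proximity matching: enumerate every
# window, check term containment by exhaustive assignment, keep minimal
# windows. Shares no code with the engine's scan.

oracle_term_ok <- function(tp, norm) {
  if (tp$wildcard) startsWith(norm, tp$stem) else norm == tp$stem
}

# exhaustive: can terms be assigned to distinct positions in positions[[t]]?
oracle_assignable <- function(cand) {
  if (length(cand) == 0L) return(TRUE)
  grid <- do.call(expand.grid, cand)
  if (nrow(grid) == 0L) return(FALSE)
  any(apply(grid, 1L, function(r) !anyDuplicated(r)))
}

oracle_phrase_matches <- function(phrase, norms) {
  k <- length(phrase$terms)
  L <- length(norms)
  out <- data.frame(start = integer(), end = integer())
  if (L < k) return(out)
  if (phrase$slop == 0L) {
    for (s in seq_len(L - k + 1L)) {
      ok <- all(vapply(seq_len(k), function(j) {
        oracle_term_ok(phrase$terms[[j]], norms[s + j - 1L])
      }, logical(1)))
      if (ok) out <- rbind(out, data.frame(start = s - 1L, end = s + k - 2L))
    }
    return(out)
  }
  cap <- k + phrase$slop
  pos <- lapply(phrase$terms, function(tp) {
    which(vapply(norms, oracle_term_ok, logical(1), tp = tp))
  })
  wins <- list()
  for (s in seq_len(L)) {
    for (e in s:min(L, s + cap - 1L)) {
      if (e - s + 1L < k) next
      cand <- lapply(pos, function(p) p[p >= s & p <= e])
      if (any(lengths(cand) == 0L)) next
      if (oracle_assignable(cand)) wins[[length(wins) + 1L]] <- c(s, e)
    }
  }
  if (length(wins) == 0L) return(out)
  keep <- vapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    !any(vapply(seq_along(wins), function(j) {
      v <- wins[[j]]
      !identical(i, j) && v[1] >= w[1] && v[2] <= w[2] &&
        (v[1] > w[1] || v[2] < w[2])
    }, logical(1)))
  }, logical(1))
  wins <- wins[keep]
  data.frame(start = vapply(wins, `[`, integer(1), 1L) - 1L,
             end = vapply(wins, `[`, integer(1), 2L) - 1L)
}

# random proximity-test instance over a small vocabulary
random_phrase_instance <- function(vocab = c("alpha", "bravo", "casa", "cedar",
                                             "delta", "dome", "echoa", "fog")) {
  L <- sample(0:30, 1L)
  norms <- if (L > 0L) sample(vocab, L, replace = TRUE) else character()
  k <- sample(2:4, 1L)
  terms <- lapply(seq_len(k), function(i) {
    w <- sample(vocab, 1L)
    if (stats::runif(1) < 0.3) {
      list(stem = substr(w, 1L, sample(1:3, 1L)), wildcard = TRUE)
    } else {
      list(stem = w, wildcard = FALSE)
    }
  })
  slop <- sample(0:10, 1L)
  list(phrase = structure(list(kind = "phrase", terms = terms,
                               slop = as.integer(slop)),
                          class = "query_expr"),
       norms = norms)
}

sorted_spans <- function(df) {
  df <- df[order(df$start, df$end), c("start", "end"), drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_spans_equal_oracle <- function(inst) {
  got <- sorted_spans(phrase_matches(inst$phrase, inst$norms))
  want <- sorted_spans(oracle_phrase_matches(inst$phrase, inst$norms))
  expect_equal(got, want,
               info = paste("phrase:", render_rule(inst$phrase),
                            "tokens:", paste(inst$norms, collapse = " ")))
}

# wrap a snippet in filler words that no rule can see
.filler_voc <- filler_vocabulary()
embed_in_filler <- function(snippet, n_lead = 4, n_tail = 4) {
  paste(c(sample(.filler_voc, n_lead, replace = TRUE), snippet,
          sample(.filler_voc, n_tail, replace = TRUE)), collapse = " ")
}

make_note <- function(text, note_id = "n1", patient_id = "p1",
                      note_type = "progress note") {
  data.frame(note_id = note_id, patient_id = patient_id,
             note_type = note_type, date = as.Date("2018-06-01"),
             text = text, stringsAsFactors = FALSE)
}
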