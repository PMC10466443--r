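# Chart-review validation statistics --------------------------------------

#' Sample rule-positive notes for manual review
#'
#' Simple random sample without replacement, drawn independently within each
#' domain, of size `ceiling(fraction * n)` (so small domains still
#' contribute at least one note). Deterministic for a fixed seed.
#'
#' @param positives data frame of rule-positive units with at least
#'   `note_id` and `domain` columns (e.g. the positive rows of
#'   [sdoh_note_matches()]).
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return the sampled rows, in stable (original) order within domain.
#' @export
sample_for_review <- function(positives, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(positives) == 0L) return(positives)
  rows <- local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(positives)), positives$domain),
                  function(idx) {
                    k <- ceiling(fraction * length(idx))
                    sort(sample(idx, k))
                  }), use.names = FALSE)
  })
  positives[sort(rows), , drop = FALSE]
}

# evaluate `expr` under a private RNG state, restoring the caller's
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Positive predictive value of a rule against review labels
#'
#' PPV = confirmed / flagged, with a 95% Wilson score interval. Inputs are
#' either raw counts (`confirmed`, `flagged`) or a label table from the
#' adjudicating reviewer.
#'
#' @param confirmed number of flagged units confirmed on review, or a data
#'   frame of `ReviewLabel`s (`unit_id`, `label` in
#'   \{"confirmed", "not_confirmed"\}) covering every flagged unit.
#' @param flagged total number of rule-flagged units (ignored when
#'   `confirmed` is a label table).
#' @param conf confidence level for the interval.
#' @return list with `ppv`, `confirmed`, `flagged`, `lower`, `upper`, and
#'   `undefined` (`TRUE` when nothing was flagged).
#' @export
ppv <- function(confirmed, flagged = NULL, conf = 0.95) {
  if (is.data.frame(confirmed)) {
    labels <- confirmed
    stopifnot(all(c("unit_id", "label") %in% names(labels)))
    flagged <- length(unique(labels$unit_id))
    confirmed <- length(unique(labels$unit_id[labels$label == "confirmed"]))
  }
  if (is.null(flagged) || flagged == 0L) {
    return(list(ppv = NA_real_, confirmed = 0L, flagged = 0L,
                lower = NA_real_, upper = NA_real_, undefined = TRUE))
  }
  stopifnot(confirmed >= 0, confirmed <= flagged)
  ci <- wilson_interval(confirmed, flagged, conf)
  list(ppv = confirmed / flagged, confirmed = as.integer(confirmed),
       flagged = as.integer(flagged),
       lower = unname(ci["lower"]), upper = unname(ci["upper"]),
       undefined = FALSE)
}

#' Observed proportional agreement between two reviewers
#'
#' @param l1,l2 aligned label vectors (same units, same order); any type
#'   comparable with `==`.
#' @return fraction of units with identical labels.
#' @export
proportional_agreement <- function(l1, l2) {
  if (length(l1) != length(l2)) stop("label lists differ in length")
  if (length(l1) == 0L) stop("need at least one labelled unit")
  mean(l1 == l2)
}

#' Cohen kappa for two aligned binary label lists
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), with p_e the
#' agreement expected from the reviewers' marginal rates. When both
#' reviewers are constant and equal (p_e = 1) kappa is undefined and
#' reported as such, never as a number.
#'
#' @param l1,l2 aligned binary label vectors; the levels are taken from the
#'   data (`positive` names the "+" level, default the larger level).
#' @param positive value counted as the positive label; defaults to `TRUE`
#'   for logical input, otherwise the first of `sort(unique(c(l1, l2)))`.
#' @return an `agreement_stats` object: n_units, the 2x2 concordance counts
#'   a (both +), b (+/-), c (-/+), d (both -), p_o, p_e, kappa and an
#'   `undefined` flag.
#' @export
cohen_kappa <- function(l1, l2, positive = NULL) {
  if (length(l1) != length(l2)) stop("label lists differ in length")
  n <- length(l1)
  if (n == 0L) stop("need at least one labelled unit")
  if (is.null(positive)) {
    positive <- if (is.logical(l1)) TRUE else sort(unique(c(l1, l2)))[1L]
  }
  p1 <- l1 == positive
  p2 <- l2 == positive
  a <- sum(p1 & p2); b <- sum(p1 & !p2); c_ <- sum(!p1 & p2); d <- sum(!p1 & !p2)
  p_o <- (a + d) / n
  p_e <- ((a + b) / n) * ((a + c_) / n) + ((c_ + d) / n) * ((b + d) / n)
  undefined <- isTRUE(all.equal(p_e, 1))
  kappa <- if (undefined) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(n_units = n, a = a, b = b, c = c_, d = d,
                 p_o = p_o, p_e = p_e, kappa = kappa, undefined = undefined),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, digits = 3, ...) {
  cat("Interrater agreement (", x$n_units, " units)\n", sep = "")
  cat(sprintf("  2x2: a=%d b=%d c=%d d=%d\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  observed agreement p_o = %.*f\n", digits, x$p_o))
  if (x$undefined) {
    cat("  kappa undefined (chance agreement p_e = 1)\n")
  } else {
    cat(sprintf("  Cohen kappa = %.*f (p_e = %.*f)\n",
                digits, x$kappa, digits, x$p_e))
  }
  invisible(x)
}

#' Pairwise agreement from a long label table
#'
#' Aligns two reviewers' labels by unit within one domain and computes
#' [proportional_agreement()] and [cohen_kappa()].
#'
#' @param labels data frame with `unit_id`, `domain`, `reviewer_id`,
#'   `label`; exactly two reviewers, at most one label per
#'   (unit, domain, reviewer).
#' @param domain domain to evaluate.
#' @return `agreement_stats` for the units labelled by both reviewers.
#' @export
agreement_from_labels <- function(labels, domain) {
  lab <- labels[labels$domain == domain, , drop = FALSE]
  revs <- sort(unique(lab$reviewer_id))
  if (length(revs) != 2L) stop("need exactly two reviewers, got ", length(revs))
  if (anyDuplicated(lab[c("unit_id", "reviewer_id")])) {
    stop("more than one label per (unit, reviewer)")
  }
  l1 <- lab[lab$reviewer_id == revs[1L], c("unit_id", "label")]
  l2 <- lab[lab$reviewer_id == revs[2L], c("unit_id", "label")]
  units <- intersect(l1$unit_id, l2$unit_id)
  cohen_kappa(l1$label[match(units, l1$unit_id)],
              l2$label[match(units, l2$unit_id)],
              positive = "confirmed")
}
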