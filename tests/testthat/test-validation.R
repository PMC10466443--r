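fake_positives <- function(n, domain = "food") {
  data.frame(note_id = sprintf("%s_%03d", domain, seq_len(n)),
             domain = domain, stringsAsFactors = FALSE)
}

test_that("review sampling is per-domain, ceiling-sized and deterministic", {
  pos <- rbind(fake_positives(157, "food"), fake_positives(7, "education"))
  s1 <- sample_for_review(pos, 0.10, seed = 99)
  expect_equal(sum(s1$domain == "food"), 16L)       # ceiling(15.7)
  expect_equal(sum(s1$domain == "education"), 1L)   # ceiling(0.7)
  expect_identical(s1, sample_for_review(pos, 0.10, seed = 99))
  expect_false(identical(s1$note_id, sample_for_review(pos, 0.10, seed = 100)$note_id))
  # fraction 1 returns everything in stable order
  expect_equal(sample_for_review(pos, 1, seed = 1), pos)
  expect_equal(nrow(sample_for_review(pos[0, ], 0.5, seed = 1)), 0L)
  expect_error(sample_for_review(pos, 0, seed = 1))
  # sampling must not disturb the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(sample_for_review(pos, 0.1, seed = 5)); b <- runif(1)
  expect_equal(a, b)
})

test_that("PPV reproduces printed review percentages with Wilson intervals", {
  p <- ppv(102, 157)
  expect_equal(round(100 * p$ppv, 1), 65.0)
  expect_equal(round(ppv(197, 313)$ppv, 3), 0.629)
  expect_equal(ppv(0, 10)$ppv, 0)
  expect_true(ppv(0, 0)$undefined)
  expect_true(p$lower < p$ppv && p$ppv < p$upper)

  # label-table interface
  labs <- data.frame(unit_id = sprintf("n%02d", 1:10), domain = "food",
                     label = c(rep("confirmed", 7), rep("not_confirmed", 3)))
  expect_equal(ppv(labs)$ppv, 0.7)

  # Wilson interval cross-check against prop.test's score interval
  for (case in list(c(102, 157), c(1, 10), c(0, 25), c(25, 25), c(197, 358))) {
    got <- ppv(case[1], case[2])
    ref <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(c(got$lower, got$upper), as.numeric(ref), tolerance = 1e-10,
                 info = paste(case, collapse = "/"))
  }
})

test_that("proportional agreement counts identical labels", {
  expect_equal(proportional_agreement(c("+", "+", "-"), c("+", "+", "-")), 1)
  expect_equal(proportional_agreement(c("+", "+", "-", "-"),
                                      c("+", "-", "-", "-")), 0.75)
  expect_equal(proportional_agreement(c(TRUE, TRUE), c(FALSE, FALSE)), 0)
  expect_error(proportional_agreement(1:3, 1:2), "length")
})

test_that("Cohen kappa matches the closed form and its invariances", {
  # a=40 b=10 c=10 d=40: p_o = 0.8, p_e = 0.5, kappa = 0.6
  l1 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 10, 40))
  l2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
  ks <- cohen_kappa(l1, l2)
  expect_equal(ks$p_o, 0.8)
  expect_equal(ks$p_e, 0.5)
  expect_equal(ks$kappa, 0.6)
  expect_equal(ks$n_units, 100L)
  expect_false(ks$undefined)

  # identical non-constant labels
  expect_equal(cohen_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))$kappa, 1)

  # invariance under simultaneous label swap, and the defining identity
  set.seed(31)
  for (i in 1:20) {
    a <- runif(30) < 0.4; b <- runif(30) < 0.6
    k1 <- cohen_kappa(a, b); k2 <- cohen_kappa(!a, !b)
    expect_equal(k1$kappa, k2$kappa)
    expect_equal(k1$p_o, k1$kappa * (1 - k1$p_e) + k1$p_e)
    expect_true(k1$kappa <= 1)
  }

  # degenerate case: both reviewers constant and equal
  kd <- cohen_kappa(rep(TRUE, 8), rep(TRUE, 8))
  expect_true(kd$undefined)
  expect_equal(kd$p_o, 1)
  expect_true(is.na(kd$kappa))

  expect_error(cohen_kappa(c(TRUE, FALSE), TRUE), "length")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(41)
  for (i in 1:15) {
    a <- factor(runif(50) < 0.5, levels = c(FALSE, TRUE))
    b <- factor(runif(50) < 0.5, levels = c(FALSE, TRUE))
    tab <- table(a, b)
    if (min(rowSums(tab)) == 0 || min(colSums(tab)) == 0) next
    expect_equal(cohen_kappa(a == TRUE, b == TRUE)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("kappa tends to zero under reviewer independence", {
  set.seed(42)
  n <- 10000
  a <- runif(n) < 0.5; b <- runif(n) < 0.5
  ks <- cohen_kappa(a, b)
  # under independence at 50/50, SE(kappa) is about 1/sqrt(n)
  expect_lt(abs(ks$kappa), 3 / sqrt(n))
})

test_that("long label tables align by unit before agreement", {
  labels <- rbind(
    data.frame(unit_id = c("n1", "n2", "n3"), domain = "food",
               reviewer_id = "R1", label = c("confirmed", "confirmed", "not_confirmed")),
    data.frame(unit_id = c("n3", "n1", "n2"), domain = "food",
               reviewer_id = "R2", label = c("not_confirmed", "confirmed", "not_confirmed")))
  ks <- agreement_from_labels(labels, "food")
  expect_equal(ks$n_units, 3L)
  expect_equal(ks$p_o, 2 / 3)
  expect_error(agreement_from_labels(labels[labels$reviewer_id == "R1", ], "food"),
               "two reviewers")
  dup <- rbind(labels, labels[1, ])
  expect_error(agreement_from_labels(dup, "food"), "more than one label")
})
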