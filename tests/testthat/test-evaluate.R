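test_that("confusion tables count per-recording agreement", {
  ids <- sprintf("r%02d", 1:8)
  ref <- tibble::tibble(recording_id = ids,
                        present = c(rep(TRUE, 3), rep(FALSE, 5)))
  perfect <- confusion(ref, ref)
  expect_equal(unlist(perfect), c(tp = 3, fp = 0, tn = 5, fn = 0))

  none <- tibble::tibble(recording_id = ids, present = FALSE)
  ct <- confusion(none, ref)
  expect_equal(unlist(ct), c(tp = 0, fp = 0, tn = 5, fn = 3))

  other <- tibble::tibble(recording_id = paste0("x", ids), present = FALSE)
  expect_error(confusion(other, ref), "different recording sets")
})

test_that("PPA/NPA/TPR follow their definitions, undefined on empty margins", {
  m <- ppa_npa(tibble::tibble(tp = 19, fn = 1, tn = 99, fp = 1))
  expect_equal(m$ppa, 0.95)
  expect_equal(m$npa, 0.99)
  expect_equal(m$tpr, m$ppa)

  nopos <- ppa_npa(tibble::tibble(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_true(is.na(nopos$ppa))
  expect_equal(nopos$npa, 1)

  prec <- ppa_npa(tibble::tibble(tp = 5, fn = 0, tn = 1, fp = 5),
                  tpr_definition = "precision")
  expect_equal(prec$tpr, 0.5)
})

test_that("roc enumerates exactly the achievable strict-cutoff points", {
  d <- tibble::tibble(s = c(0, 0.3, 0.5), y = c(FALSE, TRUE, TRUE))
  pts <- roc(d, s, y)
  expect_equal(nrow(pts), 4) # sentinel + three distinct scores
  expect_true(all(diff(pts$cutoff) > 0))
  at0 <- pts[pts$cutoff == 0, ]
  expect_equal(c(at0$ppa, at0$npa), c(1, 1))
  # the sentinel point calls everything positive
  expect_equal(pts$fn[1] + pts$tn[1], 0)

  # all scores equal: only all-negative and (below the minimum) all-positive
  same <- tibble::tibble(s = rep(0.2, 4), y = c(TRUE, TRUE, FALSE, FALSE))
  pts2 <- roc(same, s, y)
  expect_equal(nrow(pts2), 2)
  expect_equal(pts2$tp, c(2, 0))
  expect_equal(pts2$tn, c(0, 2))

  sep <- tibble::tibble(s = c(0.1, 0.2, 0.8, 0.9),
                        y = c(FALSE, FALSE, TRUE, TRUE))
  pts3 <- roc(sep, s, y)
  expect_true(any(pts3$ppa == 1 & pts3$npa == 1))

  expect_error(roc(tibble::tibble(s = 1:3 / 3, y = rep(TRUE, 3)), s, y),
               "positive and")
})

test_that("roc equals brute-force cutoff enumeration on random fixtures", {
  # oracle: evaluate the strict-'>' confusion table on a dense cutoff grid
  # (midpoints between consecutive distinct scores plus points beyond both
  # ends) and collect the distinct tables
  brute_force_tables <- function(s, y) {
    d <- sort(unique(s))
    grid <- c(d[1] - 1, d, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2,
              d[length(d)] + 1)
    tabs <- unique(t(vapply(grid, function(cut) {
      pred <- s > cut
      c(tp = sum(pred & y), fp = sum(pred & !y),
        tn = sum(!pred & !y), fn = sum(!pred & y))
    }, numeric(4))))
    tabs[order(tabs[, "tp"], tabs[, "fp"]), , drop = FALSE]
  }

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:100, 1)
    s <- round(stats::runif(n), sample(c(1, 2, 6), 1)) # ties at low precision
    y <- stats::runif(n) < 0.4
    if (all(y) || !any(y)) next
    pts <- roc(tibble::tibble(s = s, y = y), s, y)
    got <- as.matrix(pts[, c("tp", "fp", "tn", "fn")])
    got <- got[order(got[, "tp"], got[, "fp"]), , drop = FALSE]
    expect_equal(unname(got), unname(brute_force_tables(s, y)),
                 label = paste("seed", seed))
    # monotone: increasing cutoff can only lose positives and gain negatives
    expect_true(all(diff(pts$tp) <= 0))
    expect_true(all(diff(pts$tn) >= 0))
  }
})

test_that("optimal cutoff interval maximizes ppa+npa with documented ties", {
  d <- tibble::tibble(s = c(0, 0.3, 0.5), y = c(FALSE, TRUE, TRUE))
  best <- optimal_cutoff_interval(roc(d, s, y))
  expect_equal(best$cutoff_lo, 0)
  expect_equal(best$cutoff_hi, 0.3)
  expect_equal(c(best$ppa, best$npa), c(1, 1))

  # cutoffs strictly inside the interval reproduce the same confusion table
  for (cut in c(0.01, 0.15, 0.29)) {
    pred <- tibble::tibble(recording_id = as.character(1:3),
                           present = d$s > cut)
    ref <- tibble::tibble(recording_id = as.character(1:3), present = d$y)
    expect_equal(unlist(confusion(pred, ref)),
                 c(tp = best$tp, fp = best$fp, tn = best$tn, fn = best$fn))
  }

  # ties break toward higher npa
  pts <- tibble::tibble(
    cutoff = c(0.1, 0.2), tp = c(9, 8), fp = c(4, 1), tn = c(96, 99),
    fn = c(1, 2), ppa = c(0.96, 0.93), npa = c(0.96, 0.99),
    tpr = c(0.96, 0.93)
  )
  pts$ppa <- c(0.99, 0.96) # equal ppa + npa = 1.95
  chosen <- optimal_cutoff_interval(pts)
  expect_equal(chosen$npa, 0.99)
  expect_equal(chosen$cutoff_lo, 0.2)

  single <- pts[1, ]
  deg <- optimal_cutoff_interval(single)
  expect_equal(deg$cutoff_lo, deg$cutoff_hi)
})

test_that("Cohen's kappa matches hand computations and e1071", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(cohen_kappa(a, a), 1)

  # 2x2 table (25,5 / 5,25): p_o = 5/6, p_e = 1/2, kappa = 2/3
  x <- rep(c("p", "p", "n", "n"), c(25, 5, 5, 25))
  y <- rep(c("p", "n", "p", "n"), c(25, 5, 5, 25))
  expect_equal(cohen_kappa(x, y), 2 / 3)

  # p_o = 0.8 with balanced marginals: p_e = 0.5, kappa = 0.6
  r1 <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  r2 <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(cohen_kappa(r1, r2), 0.6)

  # both raters constant and identical: kappa 1 by convention, with a note
  expect_message(k <- cohen_kappa(rep("a", 5), rep("a", 5)), "convention")
  expect_equal(k, 1)

  # independent oracle on a random contingency
  set.seed(9)
  u <- sample(c("a", "b", "c"), 200, replace = TRUE)
  v <- ifelse(stats::runif(200) < 0.7, u,
              sample(c("a", "b", "c"), 200, replace = TRUE))
  expect_equal(
    cohen_kappa(u, v),
    e1071::classAgreement(table(u, v))$kappa,
    tolerance = 1e-12
  )
})

test_that("cohort summary reports Table-1 style statistics", {
  m <- cohort_manifest(seed = 1)
  cs <- cohort_summary(m)
  expect_equal(cs$n_participants, 25)
  expect_equal(cs$n_recordings, 192)
  expect_equal(cs$demographics$pct_female, 28) # 7 of 25
  expect_equal(cs$groups$pct[cs$groups$group == "cf_clear"], 24)
  expect_output(print(cs), "25 participants")

  # median conventions: midpoint of central order statistics
  fake <- tibble::tibble(
    participant_id = c("a", "b", "c", "d"), group = "normal",
    sex = c("female", "male", "male", "male"),
    age_years = c(1, 2, 3, 4), weight_kg = c(10, 20, 30, 40),
    excluded = FALSE
  )
  cs4 <- cohort_summary(fake)
  expect_equal(cs4$demographics$age_median, 2.5)
  expect_equal(cs4$demographics$pct_female, 25)
  cs3 <- cohort_summary(fake[1:3, ])
  expect_equal(cs3$demographics$age_median, 2)
  # IQR via linear interpolation: quartiles of 1..3 are 1.5 and 2.5
  expect_equal(cs3$demographics$age_iqr, 1)
})
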