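param_row <- function(recording, foot, parameter, value, time,
                      subject = "s1", system = "A") {
  tibble::tibble(subject_id = subject, recording_id = recording,
                 system = system, sides_used = "both", foot = foot,
                 parameter = parameter, value = value, time = time)
}

test_that("steps pair by rank when counts match and by time otherwise", {
  a <- param_row("r1", "L", "step_length", c(70, 71, 72), c(1, 2, 3))
  b <- param_row("r1", "L", "step_length", c(70.5, 71.5, 72.5), c(1.02, 2.02, 3.02))
  p <- pair_steps(a, b)
  expect_equal(nrow(p), 3)
  expect_equal(p$value_a, c(70, 71, 72))
  expect_equal(p$value_b, c(70.5, 71.5, 72.5))
  expect_equal(attr(p, "dropped"), 0L)

  # system B misses the middle step: remaining two match by nearest time
  b2 <- b[-2, ]
  p2 <- pair_steps(a, b2)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$value_a, c(70, 72))
  expect_equal(p2$value_b, c(70.5, 72.5))
  expect_equal(attr(p2, "dropped"), 1L)

  expect_error(pair_steps(a, dplyr::mutate(b, recording_id = "zzz")),
               "no shared recordings")
})

test_that("greedy time pairing agrees with exhaustive optimal matching on small cases", {
  set.seed(31)
  for (trial in 1:15) {
    # step-like event times: one per ~0.6 s with jitter, random dropouts
    base <- (1:8) * 0.6
    keep_a <- runif(8) < 0.8; keep_b <- runif(8) < 0.8
    ta <- sort(base[keep_a] + runif(sum(keep_a), -0.05, 0.05))
    tb <- sort(base[keep_b] + runif(sum(keep_b), -0.05, 0.05))
    na <- length(ta); nb <- length(tb)
    if (na < 2 || nb < 2) next
    a <- param_row("r", "L", "step_length", seq_len(na), ta)
    b <- param_row("r", "L", "step_length", seq_len(nb) + 100, tb)
    p <- pair_steps(a, b, max_dt = 0.2)
    if (na == nb) next   # rank pairing; only ragged cases exercise greedy
    # oracle: enumerate all injective matchings within the window, keep the
    # ones with maximal cardinality; greedy must reach that cardinality
    cand <- which(abs(outer(ta, tb, "-")) <= 0.2, arr.ind = TRUE)
    best <- 0L
    if (nrow(cand)) {
      combos <- function(rows, used_a, used_b, depth) {
        best <<- max(best, depth)
        for (r in rows) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (!used_a[i] && !used_b[j]) {
            ua <- used_a; ua[i] <- TRUE; ub <- used_b; ub[j] <- TRUE
            combos(rows[rows > r], ua, ub, depth + 1L)
          }
        }
      }
      combos(seq_len(nrow(cand)), rep(FALSE, na), rep(FALSE, nb), 0L)
    }
    expect_equal(nrow(p), best, info = paste("trial", trial))
  }
})

test_that("Bland-Altman statistics obey their defining identities", {
  x <- c(10, 12, 13, 15)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$rpc, 0)
  expect_equal(ba$cv_percent, 0)

  ba2 <- bland_altman(x + 0.5, x)
  expect_equal(ba2$bias, 0.5)
  expect_equal(ba2$rpc, 0)

  # bias is exactly the difference of the two system means
  set.seed(32)
  a <- rnorm(40, 100, 5); b <- rnorm(40, 99, 5)
  expect_equal(bland_altman(a, b)$bias, mean(a) - mean(b), tolerance = 1e-12)

  # zero grand mean flags the undefined CV
  ba3 <- bland_altman(c(-1, 1), c(1, -1))
  expect_true(ba3$flagged)
  expect_true(is.nan(ba3$cv_percent))
})

test_that("the RPC/CV identity reproduces a published stride-length row", {
  # construct pairs with sd(d) = 13.43 / 1.96 and system means 145.95 / 145.36:
  # the implementation must return RPC 13.43 and CV ~4.70 on its own output
  z <- c(-1, -1, 1, 1) / stats::sd(c(-1, -1, 1, 1))
  d <- 0.59 + (13.43 / 1.96) * z
  b <- 145.36 + c(-8, -3, 3, 8)
  a <- b + d
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0.59, tolerance = 1e-9)
  expect_equal(ba$rpc, 13.43, tolerance = 1e-9)
  expect_equal(mean((a + b) / 2), (145.95 + 145.36) / 2, tolerance = 1e-9)
  expect_equal(ba$cv_percent, 4.71, tolerance = 0.02)
})

test_that("ICC(A,1) matches an independent two-way ANOVA oracle", {
  set.seed(33)
  for (trial in 1:30) {
    n <- sample(5:40, 1)
    subj <- rnorm(n, sd = runif(1, 0.5, 3))
    a <- subj + rnorm(n, sd = 0.5)
    b <- subj + rnorm(n, sd = 0.5) + runif(1, -1, 1)
    expect_equal(icc_a1(a, b), icc_a1_aov_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("ICC(A,1) behaves as an absolute-agreement coefficient", {
  x <- c(1, 5, 9, 13)
  expect_equal(icc_a1(x, x), 1)

  # independent noise: near-zero ICC at large n
  set.seed(34)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(icc_a1(a, b)), 0.05)

  # invariant under a common shift; decreased by a one-system offset
  set.seed(35)
  subj <- rnorm(30, sd = 2)
  a <- subj + rnorm(30, sd = 0.3); b <- subj + rnorm(30, sd = 0.3)
  expect_equal(icc_a1(a + 7, b + 7), icc_a1(a, b), tolerance = 1e-12)
  expect_lt(icc_a1(a + 2, b), icc_a1(a, b))

  expect_warning(v <- icc_a1(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_true(is.nan(v))
})

test_that("ICC categories use half-open intervals covering the unit range", {
  expect_equal(classify_icc(0.910), "excellent")
  expect_equal(classify_icc(0.452), "fair")
  expect_equal(classify_icc(0.297), "poor")
  expect_equal(classify_icc(c(0, 0.399, 0.4, 0.599, 0.6, 0.749, 0.75, 1)),
               c("poor", "poor", "fair", "fair", "good", "good",
                 "excellent", "excellent"))
  expect_equal(classify_icc(-0.3), "poor")
  # monotone in its argument
  v <- sort(runif(50, -0.5, 1))
  lv <- factor(classify_icc(v), levels = c("poor", "fair", "good", "excellent"),
               ordered = TRUE)
  expect_true(!is.unsorted(lv))
})

test_that("Pearson statistics match the covariance-formula oracle", {
  expect_equal(pearson_stats(1:10, 2 * (1:10))$r, 1, tolerance = 1e-12)
  expect_equal(pearson_stats(1:10, -3 * (1:10))$r, -1, tolerance = 1e-12)
  set.seed(36)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  ps <- pearson_stats(a, b)
  expect_equal(ps$r, r_oracle, tolerance = 1e-12)
  tstat <- r_oracle * sqrt(48 / (1 - r_oracle^2))
  expect_equal(ps$p, 2 * stats::pt(-abs(tstat), df = 48), tolerance = 1e-12)
  expect_error(pearson_stats(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("agreement statistics are invariant to subject order", {
  set.seed(37)
  a <- rnorm(20, 50, 4); b <- a + rnorm(20, 0.3, 1)
  perm <- sample(20)
  s1 <- agreement_stats(a, b)
  s2 <- agreement_stats(a[perm], b[perm])
  expect_equal(s1$bias, s2$bias, tolerance = 1e-12)
  expect_equal(s1$rpc, s2$rpc, tolerance = 1e-12)
  expect_equal(s1$icc_a1, s2$icc_a1, tolerance = 1e-12)
  expect_equal(s1$r, s2$r, tolerance = 1e-12)
})

test_that("the agreement table reports perfect agreement for identical systems", {
  set.seed(38)
  rows <- list()
  for (s in 1:3) for (r in 1:2) {
    truth <- simulate_gait(step_length = 0.70 + 0.02 * s, n_strides = 4,
                           cadence = 96 + 2 * s)
    gp <- analyze_gait(truth$trajectory)
    rows[[length(rows) + 1]] <- gait_parameter_table(
      gp, paste0("s", s, "r", r), "A", subject_id = paste0("s", s))
  }
  tbl <- dplyr::bind_rows(rows)
  at <- agreement_table(tbl, dplyr::mutate(tbl, system = "B"))
  expect_true(all(at$bias == 0))
  expect_true(all(at$rpc == 0))
  ok <- !is.na(at$icc_a1)
  expect_true(all(abs(at$icc_a1[ok] - 1) < 1e-9))
  # N bookkeeping: single-step rows count the paired steps after exclusions
  single <- at[at$level == "single" & at$parameter == "step_length", ]
  steps_per_rec <- tbl |>
    dplyr::filter(parameter == "step_length") |>
    dplyr::count(foot)
  expect_equal(sum(single$n), sum(steps_per_rec$n))
  txt <- format_agreement_table(at)
  expect_true(any(grepl("AV step length AVG", txt)))
})
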