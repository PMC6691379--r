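test_that("z-scores use the n-1 SD and zero out constant genes", {
  m <- matrix(c(0, 2, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("p1", "p2")))
  expect_message(z <- zscore_matrix(m), "1 constant gene")
  expect_equal(unname(z["g1", ]), c(-1, 1) / sqrt(2))
  expect_equal(unname(z["g2", ]), c(0, 0))
  set.seed(21)
  m2 <- matrix(rnorm(50), 5, 10)
  z2 <- zscore_matrix(m2)
  expect_equal(unname(rowMeans(z2)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 5), tolerance = 1e-12)
})

test_that("burden counts respect the threshold boundary and orderings", {
  z <- matrix(c(1.5, 0.2, 2.0, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("p1", "p2")))
  expect_equal(unname(burden_scores(z, c("g1", "g2"), 1.5)), c(2L, 0L))
  expect_equal(unname(burden_scores(z, c("g1", "g2"), 1.5,
                                    strict = TRUE)), c(1L, 0L))
  expect_equal(unname(burden_scores(z, "g1", 5)), c(0L, 0L))
  ## brute-force double-loop oracle + permutation invariance
  set.seed(22)
  zz <- matrix(rnorm(200), 20, 10,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("p%02d", 1:10)))
  panel <- sample(rownames(zz), 8)
  got <- burden_scores(zz, panel, 1.0)
  want <- integer(10)
  for (j in 1:10) for (g in panel) {
    if (zz[g, j] >= 1.0) want[j] <- want[j] + 1L
  }
  expect_equal(unname(got), want)
  perm_g <- sample.int(20)
  perm_p <- sample.int(10)
  got_perm <- burden_scores(zz[perm_g, perm_p], panel, 1.0)
  expect_equal(got_perm[names(got)], got)
})

test_that("Kaplan-Meier estimator matches the hand product-limit values", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  none <- km_curve(c(4, 9, 11), c(0, 0, 0))
  expect_true(all(none$surv == 1))
  set.seed(23)
  km2 <- km_curve(rexp(50), rbinom(50, 1, 0.7))
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_lte(km2$surv[1], 1)
})

test_that("log-rank test matches an independent oracle and is symmetric", {
  ## frozen from an independent implementation (lifelines 0.30.3)
  time <- c(6, 13, 21, 30, 37, 42, 10, 15, 25, 40, 44, 48)
  event <- c(1, 1, 1, 0, 1, 1, 1, 1, 0, 1, 0, 1)
  group <- rep(c("A", "B"), each = 6)
  lr <- logrank_test(group, time, event)
  expect_equal(lr$statistic, 1.38125197661492, tolerance = 1e-6)
  expect_equal(lr$p, 0.2398880052706991, tolerance = 1e-6)
  swapped <- logrank_test(ifelse(group == "A", "B", "A"), time, event)
  expect_equal(swapped$statistic, lr$statistic)
  ## identical data in both strata: no separation
  lr0 <- logrank_test(rep(c("A", "B"), 5), rep(c(1, 2, 3, 4, 5), 2),
                      rep(1, 10))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
})

test_that("Cox fit equals the grid-search partial-likelihood oracle", {
  for (s in 1:5) {
    set.seed(s)
    time <- round(rexp(6, 0.2), 2)
    event <- rbinom(6, 1, 0.8)
    x <- c(0, 1, 0, 1, 1, 0)
    if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0) next
    fit <- cox_binary(time, event, x)
    if (fit$infinite) next
    beta_star <- cox_grid_oracle(time, event, x)
    expect_equal(fit$loghr, beta_star, tolerance = 2e-3)
  }
})

test_that("Cox relabeling antisymmetry and null behavior", {
  set.seed(24)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1)
  event <- rbinom(n, 1, 0.8)
  f1 <- cox_binary(time, event, x)
  f2 <- cox_binary(time, event, 1 - x)
  expect_equal(f1$loghr, -f2$loghr, tolerance = 1e-8)
  expect_lt(abs(f1$loghr), 3 * f1$se)  # planted HR = 1
})

test_that("monotone likelihood is flagged, not silently returned", {
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_binary(time, event, x)
  expect_true(fit$infinite)
  expect_true(is.infinite(fit$loghr))
})

test_that("cutoff scan reports all cutoffs and localizes a planted threshold", {
  seeds <- child_seeds(3003, 10)
  hits <- 0
  for (s in seeds) {
    pe <- simulate_panel_expression(400, seed = s)
    sv <- simulate_survival(pe$matrix, survival_spec(), seed = s + 1)
    burden <- sv$truth$burden
    scan <- suppressMessages(
      cutoff_scan(burden, sv$survival$time, sv$survival$event))
    expect_true(all(diff(scan$n_high) <= 0))          # monotone
    expect_equal(scan$n_high + scan$n_low,
                 rep(length(burden), nrow(scan)))     # partition
    best <- attr(scan, "best")
    if (abs(best$cutoff - 7) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("degenerate cutoffs are skipped with a reason", {
  burden <- c(3, 3, 4, 5)
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 0)
  scan <- suppressMessages(cutoff_scan(burden, time, event,
                                       cutoffs = c(1, 5, 6)))
  expect_equal(scan$note[scan$cutoff == 1], "degenerate stratum, skipped")
  expect_equal(scan$note[scan$cutoff == 6], "degenerate stratum, skipped")
  expect_true(is.na(scan$p[scan$cutoff == 1]))
})

test_that("log-rank and Cox Wald p agree in order of magnitude", {
  pe <- simulate_panel_expression(300, seed = 77)
  sv <- simulate_survival(pe$matrix, survival_spec(), seed = 78)
  high <- sv$truth$high
  lr <- logrank_test(ifelse(high, "high", "low"), sv$survival$time,
                     sv$survival$event)
  cx <- cox_binary(sv$survival$time, sv$survival$event, high)
  expect_lt(abs(log10(lr$p) - log10(cx$p)), 1.5)
})

test_that("burden_table joins strata to survival outcomes", {
  pe <- simulate_panel_expression(100, seed = 80)
  sv <- simulate_survival(pe$matrix, survival_spec(), seed = 81)
  bt <- burden_table(pe$matrix, sv$survival, sprintf("WNT%02d", 1:44))
  expect_equal(bt$burden, unname(sv$truth$burden[bt$patient]))
  expect_equal(bt$stratum == "high", unname(sv$truth$high[bt$patient]))
})

test_that("IHC combined score is the product over its full domain", {
  expect_equal(ihc_combined_score(0, 3), 0L)
  expect_equal(ihc_combined_score(6, 3), 18L)
  grid <- expand.grid(pos = 0:6, int = 0:3)
  expect_equal(ihc_combined_score(grid$pos, grid$int),
               as.integer(grid$pos * grid$int))
  expect_error(ihc_combined_score(7, 1), "0..6")
  expect_error(ihc_combined_score(3, 4), "0..3")
  expect_error(ihc_combined_score(2.5, 1), "integers")
})
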