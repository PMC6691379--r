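test_that("annotation simulator: determinism, spacing, infeasibility", {
  expect_equal(nrow(simulate_annotation(0, seed = 1)), 0L)
  a1 <- simulate_annotation(200, seed = 7)
  a2 <- simulate_annotation(200, seed = 7)
  expect_identical(a1, a2)
  ann <- simulate_annotation(500, c(chrA = 3e6, chrB = 3e6),
                             min_spacing = 10000, seed = 3)
  ## exhaustive pairwise gap check per chromosome
  for (chr in unique(ann$chrom)) {
    pos <- sort(ann$tss[ann$chrom == chr])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 10000))
  }
  expect_error(simulate_annotation(1000, c(chr1 = 1e6),
                                   min_spacing = 10000),
               "cannot place")
})

test_that("peak simulator honors binding probability and degenerate offsets", {
  ann <- simulate_annotation(50, c(chr1 = 2e6), min_spacing = 20000,
                             seed = 2)
  none <- simulate_peaks(ann, binding_spec("TF", "h", ann$gene_id,
                                           binding_prob = 0), seed = 1)
  expect_equal(nrow(none$peaks), 0L)
  expect_false(any(none$truth$bound))
  spec0 <- binding_spec("TF", "h", ann$gene_id,
                        offset_intervals = matrix(c(0, 0), ncol = 2),
                        peak_halfwidth = 50)
  at0 <- simulate_peaks(ann, spec0, seed = 1)
  expect_equal(sort(at0$peaks$summit), sort(ann$tss))
})

test_that("planted summit offsets reproduce the uniform mixture", {
  ann <- simulate_annotation(10000, c(chr1 = 2e8), min_spacing = 15000,
                             seed = 5)
  spec <- binding_spec("TF", "h", ann$gene_id,
                       offset_intervals = matrix(c(-40, 0), ncol = 2))
  sim <- simulate_peaks(ann, spec, seed = 6)
  ## recover offsets from the data (strand-aware), not the truth record
  asn <- assign_peaks(sim$peaks, ann, c(-100, 100))
  off <- asn$distance
  expect_equal(length(off), 10000L)
  ## multinomial oracle: 4 bins over the rounded U(-40, 0) support
  bins <- cut(off, breaks = c(-40.5, -30.5, -20.5, -10.5, 0.5))
  counts <- as.numeric(table(bins))
  p <- c(10, 10, 10, 11) / 41  # integer offsets -40..0 after rounding
  expected <- 10000 * p
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("expression simulator plants exact group effects", {
  spec <- expression_spec(groups = c(a = 3, b = 3), n_genes = 20,
                          signature_size = 5, log2_effect = c(b = 1),
                          noise_sd = 1e-9)
  sim <- simulate_expression(spec, seed = 1)
  sig <- sim$truth$signature_genes
  diff <- rowMeans(sim$matrix[, sim$labels$group == "b"]) -
    rowMeans(sim$matrix[, sim$labels$group == "a"])
  expect_equal(unname(diff[sig]), rep(1, 5), tolerance = 1e-6)
  expect_equal(unname(diff[setdiff(rownames(sim$matrix), sig)]),
               rep(0, 15), tolerance = 1e-6)
})

test_that("expression simulator group difference obeys the CLT", {
  spec <- expression_spec(groups = c(a = 50, b = 50), n_genes = 10,
                          signature_size = 10, log2_effect = c(b = 2),
                          noise_sd = 1)
  sim <- simulate_expression(spec, seed = 9)
  diff <- rowMeans(sim$matrix[, sim$labels$group == "b"]) -
    rowMeans(sim$matrix[, sim$labels$group == "a"])
  se <- sqrt(1 / 50 + 1 / 50)
  expect_true(all(abs(diff - 2) <= 3 * se))
})

test_that("survival simulator: censoring control and null hazards", {
  pe <- simulate_panel_expression(300, seed = 11)
  sv0 <- simulate_survival(pe$matrix,
                           survival_spec(censoring_rate = 0), seed = 2)
  expect_true(all(sv0$survival$event == 1))
  svc <- simulate_survival(pe$matrix,
                           survival_spec(censoring_rate = 0.4), seed = 2)
  expect_gt(mean(svc$survival$event == 0), 0.25)
  expect_lt(mean(svc$survival$event == 0), 0.55)
  ## zero planted effect -> Cox estimate compatible with HR = 1
  svnull <- simulate_survival(pe$matrix,
                              survival_spec(burden_log_hazard = 0),
                              seed = 3)
  fit <- cox_binary(svnull$survival$time, svnull$survival$event,
                    svnull$truth$high)
  expect_lt(abs(fit$loghr), 3 * fit$se)
})

test_that("survival simulator recovers a planted hazard ratio", {
  seeds <- child_seeds(404, 10)
  covered <- vapply(seeds, function(s) {
    pe <- simulate_panel_expression(400, seed = s)
    sv <- simulate_survival(pe$matrix, survival_spec(), seed = s + 1)
    fit <- cox_binary(sv$survival$time, sv$survival$event, sv$truth$high)
    fit$ci95[1] <= log(3) && log(3) <= fit$ci95[2]
  }, logical(1))
  expect_gte(sum(covered), 8)
})

test_that("dilution simulator follows the single-hit Poisson model", {
  sim <- simulate_dilution(dilution_spec(1, doses = c(0, 100)), seed = 1)
  expect_equal(sim$negative[sim$dose == 0], 96L)   # control row
  expect_equal(sim$negative[sim$dose == 100], 0L)  # exp(-100) ~ 0
  spec <- dilution_spec(0.01, doses = c(0, 50, 100, 200, 500))
  sim2 <- simulate_dilution(spec, seed = 4)
  p <- exp(-0.01 * spec$doses)
  lo <- qbinom(0.005, 96, p)
  hi <- qbinom(0.995, 96, p)
  expect_true(all(sim2$negative >= lo & sim2$negative <= hi))
})

test_that("simulators are pure functions of (spec, seed)", {
  ann <- simulate_annotation(30, c(chr1 = 1e6), min_spacing = 20000,
                             seed = 1)
  spec <- binding_spec("TF", "h", ann$gene_id, background_per_mb = 5)
  expect_identical(simulate_peaks(ann, spec, seed = 8),
                   simulate_peaks(ann, spec, seed = 8))
  es <- expression_spec(groups = c(a = 2, b = 2), n_genes = 10,
                        signature_size = 2)
  expect_identical(simulate_expression(es, seed = 8),
                   simulate_expression(es, seed = 8))
  expect_identical(simulate_dilution(dilution_spec(0.02), seed = 8),
                   simulate_dilution(dilution_spec(0.02), seed = 8))
})
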