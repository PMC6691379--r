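make_track <- function(ann, offsets, factor, condition = "h",
                       halfwidth = 100) {
  sign <- ifelse(ann$strand == "+", 1, -1)
  summit <- ann$tss + sign * offsets
  data.frame(chrom = ann$chrom, start = summit - halfwidth,
             end = summit + halfwidth,
             name = paste0(factor, "_", seq_len(nrow(ann))), score = 1,
             summit = summit, factor = factor, condition = condition,
             stringsAsFactors = FALSE)
}

test_that("cobound_genes is the intersection of bound sets", {
  set.seed(31)
  ann <- random_annotation(100)
  pa <- make_track(ann[1:60, ], rep(0, 60), "A")
  pb <- make_track(ann[31:100, ], rep(10, 70), "B")
  aa <- assign_peaks(pa, ann)
  ab <- assign_peaks(pb, ann)
  pairs <- cobound_genes(aa, ab)
  expect_equal(pairs$gene_id,
               sort(intersect(bound_gene_set(aa), bound_gene_set(ab))))
  ## gene bound by A only is excluded
  expect_false(ann$gene_id[1] %in% pairs$gene_id)
  ## identical peak sets: co-bound set equals bound set
  same <- cobound_genes(aa, aa)
  expect_equal(same$gene_id, bound_gene_set(aa))
  expect_equal(same$summit_a, same$summit_b)
})

test_that("localization density conserves mass and bins single genes", {
  set.seed(8)
  ann <- random_annotation(80)
  aa <- assign_peaks(make_track(ann, rep(-500, 80), "A"), ann)
  ab <- assign_peaks(make_track(ann, rep(1500, 80), "B"), ann)
  pairs <- cobound_genes(aa, ab)
  dg <- localization_density(pairs, binwidth = 250, window = c(-2000, 6000))
  expect_equal(sum(dg$counts), nrow(pairs))
  one <- localization_density(pairs[1, ], binwidth = 250,
                              window = c(-2000, 6000))
  expect_equal(sum(one$counts), 1L)
  expect_equal(sum(one$counts > 0), 1L)
})

test_that("uniform pairs fill the density grid uniformly", {
  set.seed(12)
  n <- 10000
  pairs <- data.frame(gene_id = sprintf("g%d", 1:n),
                      d_a = runif(n, -2000, 2000),
                      d_b = runif(n, -2000, 2000))
  dg <- localization_density(pairs, binwidth = 1000,
                             window = c(-2000, 2000))
  p <- 1 / length(dg$counts)
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(dg$counts - n * p) <= 4 * sigma))
})

test_that("anchors are the floored mean of the representative summits", {
  pairs <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = "+", summit_a = c(100L, 500L),
                      summit_b = c(200L, 500L), d_a = 0, d_b = 0)
  anc <- anchor_positions(pairs)
  expect_equal(anc$anchor, c(150, 500))
  ## hand-computed means on a random fixture
  set.seed(2)
  sa <- sample.int(1e6, 50); sb <- sample.int(1e6, 50)
  pf <- data.frame(gene_id = sprintf("g%d", 1:50), chrom = "chr1",
                   strand = "+", summit_a = sa, summit_b = sb,
                   d_a = 0, d_b = 0)
  expect_equal(anchor_positions(pf)$anchor, floor((sa + sb) / 2))
})

test_that("composite profiles count summits per anchor per bin", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000L,
                    strand = "+", stringsAsFactors = FALSE)
  pk <- make_track(ann, 0, "A")
  prof <- composite_profiles(pk, tss_anchors(ann), halfwidth = 100,
                             binwidth = 10)
  expect_equal(sum(prof$value), 1)
  expect_equal(prof$offset[prof$value == 1], 5)  # bin [0, 10)
})

test_that("shifting all summits shifts the profile by whole bins", {
  set.seed(14)
  ## anchors spaced far beyond the profile window so every summit pairs
  ## with exactly one anchor and the shift is a pure translation
  ann <- data.frame(gene_id = sprintf("g%03d", 1:200), chrom = "chr1",
                    tss = seq(10000L, by = 5000L, length.out = 200),
                    strand = sample(c("+", "-"), 200, replace = TRUE),
                    stringsAsFactors = FALSE)
  pk <- make_track(ann, sample(-50:50, 200, replace = TRUE), "A")
  anchors <- tss_anchors(ann)
  p0 <- composite_profiles(pk, anchors, 400, 10)
  pk2 <- pk
  sign <- ifelse(ann$strand == "+", 1, -1)
  pk2$summit <- pk$summit + sign * 30L  # +3 bins in transcription direction
  pk2$start <- pk2$summit - 100L
  pk2$end <- pk2$summit + 100L
  p3 <- composite_profiles(pk2, anchors, 400, 10)
  n <- nrow(p0)
  expect_equal(p3$value[4:n], p0$value[1:(n - 3)])
})

test_that("profile mass equals the number of summit-anchor pairs in range", {
  set.seed(15)
  ann <- random_annotation(300)
  pk <- make_track(ann, sample(-600:600, 300, replace = TRUE), "A")
  anchors <- tss_anchors(ann)
  prof <- composite_profiles(pk, anchors, 400, 10)
  ## oracle count by direct loop over anchors
  inrange <- 0L
  for (i in seq_len(nrow(anchors))) {
    off <- (pk$summit[pk$chrom == anchors$chrom[i]] - anchors$anchor[i]) *
      ifelse(anchors$strand[i] == "+", 1, -1)
    inrange <- inrange + sum(off >= -400 & off < 400)
  }
  expect_equal(sum(prof$value) * nrow(anchors), inrange)
})

test_that("architecture detection handles degenerate geometries", {
  ann <- random_annotation(300)
  set.seed(16)
  offs <- sample(-40:0, 300, replace = TRUE)
  pk <- rbind(make_track(ann, offs, "A"), make_track(ann, offs, "B"))
  prof <- composite_profiles(pk, tss_anchors(ann), 400, 10)
  arch <- detect_architecture(prof)
  ## integer offsets -40..0: the [0,10) bin holds only offset 0 (~1/41
  ## of the mass) and stays below the 50% occupancy threshold
  expect_equal(unname(arch$overlap_window), c(-40, 0))
  expect_equal(nrow(arch$specific_windows[["A:h"]]), 0L)
  expect_equal(nrow(arch$specific_windows[["B:h"]]), 0L)
  ## disjoint supports: no shared window
  pk2 <- rbind(make_track(ann, sample(-40:-10, 300, TRUE), "A"),
               make_track(ann, sample(10:40, 300, TRUE), "B"))
  arch2 <- detect_architecture(composite_profiles(pk2, tss_anchors(ann),
                                                  400, 10))
  expect_null(arch2$overlap_window)
  expect_equal(arch2$overlap_width, 0)
  ## flat profile is an error (track B has no summit near any anchor)
  pk3 <- rbind(make_track(ann, offs, "A"),
               data.frame(chrom = "chrZZ", start = 1L, end = 100L,
                          name = "far", score = 1, summit = 50L,
                          factor = "B", condition = "h",
                          stringsAsFactors = FALSE))
  expect_error(
    suppressWarnings(
      detect_architecture(composite_profiles(pk3, tss_anchors(ann), 400, 10))),
    "flat profile")
})

test_that("planted shared+flank architecture is recovered with exact order", {
  ann <- simulate_annotation(5000, c(chr1 = 8e7), min_spacing = 15000,
                             seed = 21)
  specs <- planted_architecture_specs(ann$gene_id)
  pa <- simulate_peaks(ann, specs$a, seed = 22)
  pb <- simulate_peaks(ann, specs$b, seed = 23)
  prof <- composite_profiles(rbind(pa$peaks, pb$peaks), tss_anchors(ann),
                             400, 10)
  arch <- detect_architecture(prof)
  expect_equal(unname(arch$overlap_window), c(-40, 0), tolerance = 1e-9)
  a_spec <- arch$specific_windows[["TCF1:hypoxia"]]
  b_spec <- arch$specific_windows[["HIF1A:hypoxia"]]
  expect_equal(nrow(a_spec), 1L)
  expect_equal(nrow(b_spec), 1L)
  expect_equal(c(a_spec$lo, a_spec$hi), c(0, 20))
  expect_equal(c(b_spec$lo, b_spec$hi), c(20, 40))
})

test_that("architecture output is invariant to peak-file ordering", {
  ann <- simulate_annotation(1000, c(chr1 = 2e7), min_spacing = 15000,
                             seed = 31)
  specs <- planted_architecture_specs(ann$gene_id)
  pa <- simulate_peaks(ann, specs$a, seed = 32)
  pb <- simulate_peaks(ann, specs$b, seed = 33)
  peaks <- rbind(pa$peaks, pb$peaks)
  set.seed(34)
  shuffled <- peaks[sample.int(nrow(peaks)), ]
  anchors <- tss_anchors(ann)
  expect_equal(detect_architecture(composite_profiles(peaks, anchors, 400, 10)),
               detect_architecture(composite_profiles(shuffled, anchors, 400, 10)))
})

test_that("gene membership in the called architecture matches interval oracle", {
  ann <- simulate_annotation(800, c(chr1 = 2e7), min_spacing = 15000,
                             seed = 41)
  specs <- planted_architecture_specs(ann$gene_id)
  pa <- simulate_peaks(ann, specs$a, seed = 42)
  pb <- simulate_peaks(ann, specs$b, seed = 43)
  aa <- assign_peaks(pa$peaks, ann)
  ab <- assign_peaks(pb$peaks, ann)
  pairs <- cobound_genes(aa, ab)
  anchors <- tss_anchors(ann, pairs$gene_id)
  prof <- composite_profiles(rbind(pa$peaks, pb$peaks), anchors, 400, 10)
  arch <- detect_architecture(prof)
  anchored <- merge(pairs, anchors[, c("gene_id", "anchor")], by = "gene_id")
  attr(anchored, "tracks") <- attr(pairs, "tracks")
  got <- genes_with_architecture(anchored, arch)
  ## membership oracle: explicit per-gene interval tests
  windows <- function(track) {
    w <- arch$specific_windows[[track]]
    rbind(matrix(arch$overlap_window, ncol = 2),
          as.matrix(w[, c("lo", "hi")]))
  }
  inw <- function(off, w) any(off >= w[, 1] & off <= w[, 2])
  wa <- windows("TCF1:hypoxia"); wb <- windows("HIF1A:hypoxia")
  want <- character(0)
  for (i in seq_len(nrow(anchored))) {
    sgn <- if (anchored$strand[i] == "+") 1 else -1
    offa <- (anchored$summit_a[i] - anchored$anchor[i]) * sgn
    offb <- (anchored$summit_b[i] - anchored$anchor[i]) * sgn
    if (inw(offa, wa) && inw(offb, wb)) want <- c(want, anchored$gene_id[i])
  }
  expect_equal(got, sort(want))
  expect_gt(length(got), 0)
  ## a gene whose factor-A summit sits 500 bp outside all windows is excluded
  far <- anchored[1, ]
  far$summit_a <- far$anchor + 500
  attr(far, "tracks") <- attr(pairs, "tracks")
  expect_equal(length(genes_with_architecture(far, arch)), 0L)
})
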