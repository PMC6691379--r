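## Independent brute-force oracles and random fixture builders shared
## across the suite. The oracles deliberately use naive all-pairs /
## exhaustive algorithms, never the package's own code paths.

## all-pairs peak-to-TSS assignment oracle: one explicit loop per gene
brute_assign <- function(peaks, annotation, tss_window, stranded = TRUE) {
  rows <- list()
  for (g in seq_len(nrow(annotation))) {
    sign <- if (!stranded || annotation$strand[g] == "+") 1 else -1
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] != annotation$chrom[g]) next
      d <- (peaks$summit[p] - annotation$tss[g]) * sign
      if (d >= tss_window[1] && d <= tss_window[2]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = annotation$gene_id[g], peak_name = peaks$name[p],
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), peak_name = character(),
               distance = numeric())
  out[order(out$gene_id, out$peak_name), , drop = FALSE]
}

random_annotation <- function(n_genes, chrom = "chr1", size = 5e6) {
  data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
             chrom = chrom,
             tss = sort(sample.int(size, n_genes)),
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_peaks <- function(n_peaks, chrom = "chr1", size = 5e6,
                         factor = "TF", condition = "cond") {
  start <- sample.int(size, n_peaks)
  width <- sample(100:400, n_peaks, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             name = sprintf("p%03d", seq_len(n_peaks)), score = 1,
             summit = start + floor(width / 2),
             factor = factor, condition = condition,
             stringsAsFactors = FALSE)
}

## exhaustive greedy Ward.D2 agglomeration via the Lance-Williams update
ward_d2_oracle <- function(m) {
  n <- nrow(m)
  d2 <- as.matrix(stats::dist(m))^2
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bestv <- Inf
    for (i in which(alive)) for (j in which(alive)) {
      if (i < j && d2[i, j] < bestv) {
        bestv <- d2[i, j]
        best <- c(i, j)
      }
    }
    heights[step] <- sqrt(bestv)
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(alive)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2new <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                  nk * d2[i, j]) / (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- d2new
    }
    sizes[i] <- ni + nj
    alive[j] <- FALSE
    d2[j, ] <- d2[, j] <- Inf
  }
  heights
}

## Breslow partial log-likelihood for a binary covariate, maximized by
## grid search — independent of coxph's Newton iterations
cox_grid_oracle <- function(time, event, x, grid = seq(-5, 5, by = 1e-3)) {
  loglik <- function(beta) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      dead <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + beta * sum(x[dead]) -
        length(dead) * log(sum(exp(beta * x[risk])))
    }
    ll
  }
  grid[which.max(vapply(grid, loglik, numeric(1)))]
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
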