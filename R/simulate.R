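## Synthetic-data generators. Every simulator is a pure function of
## (spec, seed) and returns its planted ground truth alongside the data,
## so each pipeline stage can be validated by parameter recovery.

#' Simulate a gene/TSS annotation
#'
#' Places `n_genes` non-overlapping gene anchors with pairwise spacing
#' at least `min_spacing` bp, distributed across chromosomes
#' proportionally to size, with random strands.
#'
#' @param n_genes number of genes.
#' @param chrom_sizes named numeric vector of chromosome sizes (bp).
#' @param min_spacing minimum pairwise anchor distance (bp).
#' @param seed integer seed (optional).
#' @return Annotation `data.frame` (`gene_id`, `chrom`, `tss`,
#'   `strand`) with the chromosome sizes kept in the `"chrom_sizes"`
#'   attribute.
#' @export
simulate_annotation <- function(n_genes,
                                chrom_sizes = c(chr1 = 2e7, chr2 = 2e7),
                                min_spacing = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 0, all(chrom_sizes > 0), min_spacing > 0)
  capacity <- floor(chrom_sizes / min_spacing)
  if (n_genes > sum(capacity)) {
    stop("cannot place ", n_genes, " genes at spacing ", min_spacing,
         " bp in ", sum(chrom_sizes), " bp of sequence", call. = FALSE)
  }
  ## proportional allocation, clipped to capacity
  alloc <- floor(n_genes * chrom_sizes / sum(chrom_sizes))
  alloc <- pmin(alloc, capacity)
  while (sum(alloc) < n_genes) {
    room <- which(alloc < capacity)
    k <- room[which.max((capacity - alloc)[room])]
    alloc[k] <- alloc[k] + 1L
  }
  width <- max(4L, nchar(as.character(max(n_genes, 1L))))
  rows <- list()
  idx <- 0L
  for (chr in names(chrom_sizes)) {
    nc <- alloc[[chr]]
    if (nc == 0L) next
    slack <- chrom_sizes[[chr]] - nc * min_spacing
    u <- sort(stats::runif(nc, 0, slack))
    pos <- floor(u + (seq_len(nc) - 1L) * min_spacing + min_spacing / 2)
    rows[[chr]] <- data.frame(
      gene_id = sprintf("g%0*d", width, idx + seq_len(nc)),
      chrom = chr, tss = as.integer(pos),
      strand = sample(c("+", "-"), nc, replace = TRUE),
      stringsAsFactors = FALSE)
    idx <- idx + nc
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), chrom = character(),
               tss = integer(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  attr(ann, "chrom_sizes") <- chrom_sizes
  attr(ann, "min_spacing") <- min_spacing
  ann
}

#' Binding specification for the peak simulator
#'
#' Summit offsets are defined in transcription-direction coordinates
#' relative to each target gene's anchor (its TSS) and drawn from a
#' mixture of uniform intervals; they are reflected for `-` strand
#' genes by [simulate_peaks()].
#'
#' @param factor,condition track labels.
#' @param target_genes gene ids eligible for a planted peak.
#' @param offset_intervals 2-column matrix of signed bp intervals
#'   `[lo, hi]`, one mixture component per row.
#' @param offset_weights mixture weights (normalized to sum to 1).
#' @param peak_halfwidth half-width of the emitted peak interval (bp).
#' @param binding_prob per-gene probability that a target gene receives
#'   a peak.
#' @param background_per_mb expected uniformly placed background peaks
#'   per megabase.
#' @param extra_peak_rate Poisson rate of additional (independently
#'   drawn) peaks per bound gene; 0 (default) keeps one peak per bound
#'   gene so the co-binding truth stays unambiguous.
#' @return A `binding_spec` object.
#' @export
binding_spec <- function(factor, condition, target_genes,
                         offset_intervals = matrix(c(-40, 0), ncol = 2),
                         offset_weights = NULL,
                         peak_halfwidth = 150, binding_prob = 1,
                         background_per_mb = 0, extra_peak_rate = 0) {
  offset_intervals <- matrix(as.numeric(offset_intervals), ncol = 2)
  if (any(!is.finite(offset_intervals)) ||
      any(offset_intervals[, 1] > offset_intervals[, 2])) {
    stop("offset intervals must be finite with lo <= hi", call. = FALSE)
  }
  offset_weights <- offset_weights %||%
    rep(1 / nrow(offset_intervals), nrow(offset_intervals))
  if (length(offset_weights) != nrow(offset_intervals) ||
      any(offset_weights < 0) || sum(offset_weights) <= 0) {
    stop("offset_weights must be non-negative, one per interval", call. = FALSE)
  }
  stopifnot(peak_halfwidth >= 1, binding_prob >= 0, binding_prob <= 1,
            background_per_mb >= 0, extra_peak_rate >= 0)
  structure(list(factor = factor, condition = condition,
                 target_genes = target_genes,
                 offset_intervals = offset_intervals,
                 offset_weights = offset_weights / sum(offset_weights),
                 peak_halfwidth = as.integer(peak_halfwidth),
                 binding_prob = binding_prob,
                 background_per_mb = background_per_mb,
                 extra_peak_rate = extra_peak_rate),
            class = "binding_spec")
}

#' Canonical two-factor shared-window-plus-flanks geometry
#'
#' Returns binding specifications for two factors that plant, around
#' each target gene's anchor, a 40 bp shared-occupancy window upstream
#' of the anchor (`[-40, 0]` bp, both factors) followed by two
#' consecutive 20 bp factor-specific windows downstream: `(0, +20]` bp
#' occupied only by factor A and `(+20, +40]` bp only by factor B.
#'
#' @param target_genes gene ids receiving the planted geometry.
#' @param factor_a,factor_b factor labels (A carries the proximal
#'   flank, B the distal one).
#' @param condition shared condition label.
#' @param ... passed on to [binding_spec()] (e.g. `binding_prob`,
#'   `background_per_mb`).
#' @return List of two `binding_spec`s, named `a` and `b`.
#' @export
planted_architecture_specs <- function(target_genes,
                                       factor_a = "TCF1",
                                       factor_b = "HIF1A",
                                       condition = "hypoxia", ...) {
  list(
    a = binding_spec(factor_a, condition, target_genes,
                     offset_intervals = matrix(c(-40, 20), ncol = 2), ...),
    b = binding_spec(factor_b, condition, target_genes,
                     offset_intervals = matrix(c(-40, 0, 20, 40), ncol = 2,
                                               byrow = TRUE),
                     offset_weights = c(2 / 3, 1 / 3), ...)
  )
}

#' Simulate ChIP-seq peak calls with planted summit offsets
#'
#' Each target gene receives a peak with probability
#' `spec$binding_prob`; its summit offset is drawn from the spec's
#' uniform mixture (transcription-direction, reflected on `-` strand
#' genes) and rounded to an integer coordinate. Background peaks are
#' placed uniformly at `background_per_mb` per megabase.
#'
#' @param annotation annotation from [simulate_annotation()] (target
#'   genes must be a subset of its genes).
#' @param spec a [binding_spec()].
#' @param seed integer seed (optional).
#' @param chrom_sizes chromosome sizes; defaults to the annotation's
#'   `"chrom_sizes"` attribute.
#' @return List with `peaks` (a peak table as from [read_peaks()])
#'   and `truth` (per target gene: `bound`, planted `offset`, `summit`).
#' @export
simulate_peaks <- function(annotation, spec, seed = NULL,
                           chrom_sizes = attr(annotation, "chrom_sizes")) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "binding_spec"))
  if (!all(spec$target_genes %in% annotation$gene_id)) {
    stop("target_genes must be a subset of the annotation's genes",
         call. = FALSE)
  }
  tgt <- annotation[match(spec$target_genes, annotation$gene_id), , drop = FALSE]
  nt <- nrow(tgt)
  bound <- stats::runif(nt) < spec$binding_prob
  draw_offsets <- function(n) {
    comp <- sample.int(nrow(spec$offset_intervals), n, replace = TRUE,
                       prob = spec$offset_weights)
    round(stats::runif(n, spec$offset_intervals[comp, 1],
                       spec$offset_intervals[comp, 2]))
  }
  n_extra <- if (spec$extra_peak_rate > 0)
    stats::rpois(sum(bound), spec$extra_peak_rate) else rep(0L, sum(bound))
  gi <- c(which(bound), rep(which(bound), n_extra))
  off <- draw_offsets(length(gi))
  sign <- ifelse(tgt$strand[gi] == "+", 1, -1)
  summit <- tgt$tss[gi] + sign * off
  hw <- spec$peak_halfwidth
  planted <- data.frame(chrom = tgt$chrom[gi],
                        start = pmax(0L, as.integer(summit - hw)),
                        end = as.integer(summit + hw),
                        summit = as.integer(summit),
                        stringsAsFactors = FALSE)
  bg <- NULL
  if (spec$background_per_mb > 0) {
    if (is.null(chrom_sizes)) {
      stop("chrom_sizes needed for background peaks", call. = FALSE)
    }
    nbg <- stats::rpois(length(chrom_sizes),
                        spec$background_per_mb * chrom_sizes / 1e6)
    pos <- unlist(lapply(seq_along(chrom_sizes), function(i) {
      floor(stats::runif(nbg[i], hw, chrom_sizes[i] - hw))
    }))
    if (length(pos)) {
      bg <- data.frame(chrom = rep(names(chrom_sizes), nbg),
                       start = as.integer(pos - hw),
                       end = as.integer(pos + hw),
                       summit = as.integer(pos),
                       stringsAsFactors = FALSE)
    }
  }
  peaks <- rbind(planted, bg)
  peaks <- data.frame(chrom = peaks$chrom, start = peaks$start,
                      end = peaks$end,
                      name = sprintf("%s_%s_p%d", spec$factor,
                                     spec$condition,
                                     seq_len(nrow(peaks))),
                      score = rep(1, nrow(peaks)),
                      summit = peaks$summit,
                      factor = rep(spec$factor, nrow(peaks)),
                      condition = rep(spec$condition, nrow(peaks)),
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  validate_peaks(peaks)
  first_idx <- match(seq_len(nt), gi)  # first (non-extra) peak per gene
  truth <- data.frame(gene_id = tgt$gene_id, bound = bound,
                      offset = ifelse(bound, off[first_idx], NA_real_),
                      summit = ifelse(bound, summit[first_idx], NA_integer_),
                      stringsAsFactors = FALSE)
  list(peaks = peaks, truth = truth)
}

#' Expression specification for the group-structured simulator
#'
#' Emulates a cohort with a planted signature: signature genes carry a
#' per-group log2 shift (e.g. a grade-wise silencing gradient), all
#' other genes are pure noise.
#'
#' @param groups named integer vector of group sizes, in group order;
#'   the first group is the reference. All sizes must be >= 2 so group
#'   variances are estimable.
#' @param n_genes total number of genes.
#' @param signature_size number of signature genes (the first
#'   `signature_size` gene ids).
#' @param log2_effect named numeric: planted log2 shift of signature
#'   genes per non-reference group.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param baseline_mean baseline log2 expression level.
#' @return An `expression_spec` object.
#' @export
expression_spec <- function(groups = c(core = 4, periphery = 4),
                            n_genes = 1000, signature_size = 50,
                            log2_effect = NULL,
                            noise_sd = 0.5, baseline_mean = 7) {
  stopifnot(length(groups) >= 2, all(groups >= 2), noise_sd > 0,
            signature_size >= 0, signature_size <= n_genes)
  if (is.null(names(groups))) stop("groups must be named", call. = FALSE)
  log2_effect <- log2_effect %||% setNames(1, names(groups)[2])
  if (!all(names(log2_effect) %in% names(groups)[-1])) {
    stop("log2_effect names must be non-reference group names", call. = FALSE)
  }
  structure(list(groups = groups, n_genes = as.integer(n_genes),
                 signature_size = as.integer(signature_size),
                 log2_effect = log2_effect, noise_sd = noise_sd,
                 baseline_mean = baseline_mean),
            class = "expression_spec")
}

#' Simulate a group-structured expression matrix
#'
#' `value = baseline + group effect (signature genes only) + N(0, sd)`.
#'
#' @param spec an [expression_spec()].
#' @param seed integer seed (optional).
#' @return List with `matrix` (genes x samples), `labels`
#'   (`sample`, `group`) and `truth` (signature gene ids and the
#'   per-group planted effects).
#' @export
simulate_expression <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "expression_spec"))
  width <- max(4L, nchar(as.character(spec$n_genes)))
  genes <- sprintf("g%0*d", width, seq_len(spec$n_genes))
  sig <- genes[seq_len(spec$signature_size)]
  group <- rep(names(spec$groups), spec$groups)
  samples <- paste0(group, "_", unlist(lapply(spec$groups, seq_len)))
  mat <- matrix(stats::rnorm(spec$n_genes * length(samples),
                             spec$baseline_mean, spec$noise_sd),
                nrow = spec$n_genes,
                dimnames = list(genes, samples))
  for (g in names(spec$log2_effect)) {
    mat[sig, group == g] <- mat[sig, group == g] + spec$log2_effect[[g]]
  }
  list(matrix = mat,
       labels = data.frame(sample = samples, group = group,
                           stringsAsFactors = FALSE),
       truth = list(signature_genes = sig, log2_effect = spec$log2_effect))
}

#' Simulate cohort expression with graded panel activation
#'
#' Companion generator for the burden-survival stage: every patient
#' carries a continuous pathway-activation level
#' `w ~ U(activation[1], activation[2])`, and each panel gene is
#' up-shifted by `effect` noise-SD units with probability `w`. The
#' realized z-score burden therefore spreads smoothly over the panel
#' range instead of splitting into two separated modes, which is what a
#' cutoff scan needs in order to localize a planted threshold.
#' Background genes are pure noise.
#'
#' @param n_patients cohort size.
#' @param panel_genes panel gene ids (default 44, the size of a Wnt
#'   signaling component panel).
#' @param n_background number of non-panel noise genes.
#' @param activation length-2 range of the per-patient activation
#'   probability.
#' @param effect up-shift of an activated panel gene, in noise-SD units.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed (optional).
#' @return List with `matrix` (genes x patients) and `truth`
#'   (per-patient `activation`, logical `shifted` matrix).
#' @export
simulate_panel_expression <- function(n_patients = 519,
                                      panel_genes = sprintf("WNT%02d", 1:44),
                                      n_background = 156,
                                      activation = c(0, 0.5),
                                      effect = 6, noise_sd = 1,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_patients > 0, length(panel_genes) > 0, effect >= 0,
            noise_sd > 0)
  patients <- sprintf("pt%04d", seq_len(n_patients))
  np <- length(panel_genes)
  w <- stats::runif(n_patients, activation[1], activation[2])
  shifted <- matrix(stats::runif(np * n_patients) <
                      rep(w, each = np), nrow = np)
  panel <- matrix(stats::rnorm(np * n_patients, 0, noise_sd), nrow = np) +
    shifted * effect * noise_sd
  bg <- matrix(stats::rnorm(n_background * n_patients, 0, noise_sd),
               nrow = n_background)
  mat <- rbind(panel, bg)
  dimnames(mat) <- list(c(panel_genes,
                          sprintf("bg%04d", seq_len(n_background))),
                        patients)
  list(matrix = mat,
       truth = list(activation = setNames(w, patients),
                    shifted = shifted))
}

#' Survival specification for the burden-driven simulator
#'
#' @param panel_genes gene panel whose z-score burden drives the hazard
#'   (default size 44).
#' @param burden_log_hazard log hazard ratio of high- versus low-burden
#'   patients (default `log(3)`).
#' @param baseline_hazard baseline exponential hazard (> 0), per time
#'   unit (months).
#' @param censoring_rate expected fraction of censored patients in
#'   `[0, 1)`; censoring is independent uniform.
#' @param z_threshold,burden_cutoff burden definition: count of panel
#'   genes with cohort z-score `>= z_threshold`; high burden means
#'   count `>= burden_cutoff`.
#' @return A `survival_spec` object.
#' @export
survival_spec <- function(panel_genes = sprintf("WNT%02d", 1:44),
                          burden_log_hazard = log(3),
                          baseline_hazard = 0.1,
                          censoring_rate = 0.2,
                          z_threshold = 1.5, burden_cutoff = 7) {
  stopifnot(baseline_hazard > 0, censoring_rate >= 0, censoring_rate < 1)
  structure(list(panel_genes = panel_genes,
                 burden_log_hazard = burden_log_hazard,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 z_threshold = z_threshold,
                 burden_cutoff = as.integer(burden_cutoff)),
            class = "survival_spec")
}

#' Simulate survival outcomes driven by a planted burden threshold
#'
#' Computes every patient's panel burden from the supplied expression
#' matrix (cohort z-scores via [zscore_matrix()], counts via
#' [burden_scores()]), then draws exponential event times with
#' `log-hazard = log(baseline) + burden_log_hazard x 1(burden >= cutoff)`
#' and independent uniform censoring calibrated to the requested
#' censoring fraction.
#'
#' @param expression genes x patients matrix containing the panel genes.
#' @param spec a [survival_spec()].
#' @param seed integer seed (optional).
#' @return List with `survival` (`patient`, `time`, `event`) and
#'   `truth` (`burden`, logical `high`, the planted log HR and cutoff).
#' @export
simulate_survival <- function(expression, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "survival_spec"))
  z <- zscore_matrix(expression)
  burden <- burden_scores(z, spec$panel_genes, spec$z_threshold)
  high <- burden >= spec$burden_cutoff
  lambda <- spec$baseline_hazard * exp(spec$burden_log_hazard * high)
  n <- length(lambda)
  t_event <- stats::rexp(n, lambda)
  if (spec$censoring_rate > 0) {
    ## P(censored | U(0, m) censoring) = mean_i (1 - exp(-lambda_i m)) / (lambda_i m)
    f <- function(m) mean((1 - exp(-lambda * m)) / (lambda * m)) -
      spec$censoring_rate
    upper <- 1 / min(lambda)
    while (f(upper) > 0) upper <- upper * 2
    m <- stats::uniroot(f, c(1e-9, upper))$root
    t_cens <- stats::runif(n, 0, m)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  surv <- data.frame(patient = colnames(expression) %||%
                       sprintf("pt%04d", seq_len(n)),
                     time = time,
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)
  list(survival = surv,
       truth = list(burden = burden, high = high,
                    burden_log_hazard = spec$burden_log_hazard,
                    burden_cutoff = spec$burden_cutoff))
}

#' Dilution specification for the single-hit Poisson simulator
#'
#' @param true_frequency initiating-cell frequency `f` in (0, 1].
#' @param doses cells per well at each dilution (0 allowed: control
#'   row, always all-negative).
#' @param wells_per_dose wells seeded per dose (96-well layout).
#' @return A `dilution_spec` object.
#' @export
dilution_spec <- function(true_frequency,
                          doses = c(0, 10, 25, 50, 100, 250, 500),
                          wells_per_dose = 96) {
  stopifnot(true_frequency > 0, true_frequency <= 1, all(doses >= 0),
            wells_per_dose > 0)
  structure(list(true_frequency = true_frequency, doses = doses,
                 wells_per_dose = as.integer(wells_per_dose)),
            class = "dilution_spec")
}

#' Simulate limiting-dilution well counts
#'
#' Under the single-hit Poisson model a well seeded with `n` cells stays
#' sphere-negative with probability `exp(-f n)`; negative-well counts
#' are Binomial(`wells`, `exp(-f n)`).
#'
#' @param spec a [dilution_spec()].
#' @param seed integer seed (optional).
#' @return A `data.frame` (`dose`, `wells`, `negative`) with the true
#'   frequency in the `"truth"` attribute.
#' @export
simulate_dilution <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "dilution_spec"))
  p_neg <- exp(-spec$true_frequency * spec$doses)
  out <- data.frame(dose = spec$doses,
                    wells = spec$wells_per_dose,
                    negative = stats::rbinom(length(spec$doses),
                                             spec$wells_per_dose, p_neg))
  attr(out, "truth") <- list(true_frequency = spec$true_frequency)
  out
}
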