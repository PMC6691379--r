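## Two-factor co-localization: joint TSS-distance density, composite
## summit profiles around shared anchors, and detection of the composite
## binding-window architecture (a shared-occupancy window plus
## factor-specific flanks).

track_label <- function(factor, condition) paste(factor, condition, sep = ":")

#' Genes co-bound by two factors, with representative distances
#'
#' Intersects the bound gene sets of two assignment tables and pairs
#' each common gene with the representative (nearest) peak of either
#' factor ([nearest_assignment_per_gene()]).
#'
#' @param assign_a,assign_b assignment tables from [assign_peaks()],
#'   one per factor (or factor/condition track).
#' @return A `data.frame` with one row per co-bound gene: `gene_id`,
#'   `chrom`, `strand`, `summit_a`, `summit_b`, `d_a`, `d_b`. The
#'   factor/condition labels of the two tracks are kept in the
#'   `"tracks"` attribute.
#' @export
cobound_genes <- function(assign_a, assign_b) {
  na <- nearest_assignment_per_gene(assign_a)
  nb <- nearest_assignment_per_gene(assign_b)
  common <- sort(intersect(na$gene_id, nb$gene_id))
  ia <- match(common, na$gene_id)
  ib <- match(common, nb$gene_id)
  out <- data.frame(gene_id = common,
                    chrom = na$chrom[ia],
                    strand = na$strand[ia],
                    summit_a = na$summit[ia],
                    summit_b = nb$summit[ib],
                    d_a = na$distance[ia],
                    d_b = nb$distance[ib],
                    stringsAsFactors = FALSE)
  attr(out, "tracks") <- c(
    a = track_label(assign_a$factor[1] %||% "A", assign_a$condition[1] %||% ""),
    b = track_label(assign_b$factor[1] %||% "B", assign_b$condition[1] %||% "")
  )
  out
}

#' Joint TSS-distance density of two factors
#'
#' Bins the paired representative distances `(d_a, d_b)` of co-bound
#' genes on a square grid. Contour levels are reported at the given
#' density quantiles of the occupied cells.
#'
#' @param pairs co-bound pair table from [cobound_genes()].
#' @param binwidth bin width in bp.
#' @param window length-2 numeric: the distance range binned on both
#'   axes (pairs outside it are dropped, with a message).
#' @param contour_quantiles density quantiles at which contour levels
#'   are reported.
#' @return A `density_grid` object: list with `bin_edges_x`,
#'   `bin_edges_y`, `counts` (matrix, x = rows), `contour_levels`, `n`.
#' @export
localization_density <- function(pairs, binwidth = 250,
                                 window = c(-2000, 6000),
                                 contour_quantiles = c(0.5, 0.75, 0.9)) {
  stopifnot(binwidth > 0, window[1] < window[2])
  nb <- ceiling((window[2] - window[1]) / binwidth)
  edges <- window[1] + 0:nb * binwidth
  inside <- pairs$d_a >= window[1] & pairs$d_a <= edges[nb + 1] &
    pairs$d_b >= window[1] & pairs$d_b <= edges[nb + 1]
  if (any(!inside)) {
    message("localization_density: ", sum(!inside),
            " pair(s) outside the window were dropped")
  }
  px <- pairs$d_a[inside]
  py <- pairs$d_b[inside]
  ## right-closed last bin so the upper edge is included
  bx <- pmin(floor((px - window[1]) / binwidth) + 1L, nb)
  by <- pmin(floor((py - window[1]) / binwidth) + 1L, nb)
  counts <- matrix(0L, nb, nb)
  for (k in seq_along(bx)) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1L
  pos <- counts[counts > 0]
  levels <- if (length(pos)) stats::quantile(pos, contour_quantiles) else
    setNames(numeric(0), character(0))
  structure(list(bin_edges_x = edges, bin_edges_y = edges, counts = counts,
                 contour_levels = levels, n = sum(counts)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("density_grid: ", x$n, " pairs on a ",
      nrow(x$counts), "x", ncol(x$counts), " grid [",
      x$bin_edges_x[1], ", ", x$bin_edges_x[length(x$bin_edges_x)],
      "] bp\n", sep = "")
  invisible(x)
}

#' Per-gene co-binding anchors (mean of the two representative summits)
#'
#' The anchor of a co-bound gene is the arithmetic mean of its two
#' representative summits, rounded half-down (`floor`). Note that with
#' exactly two summits per gene, summit offsets relative to this anchor
#' are antisymmetric between the factors (`off_a = -off_b`), so
#' profiles around pair-mean anchors are mirror images; use
#' [tss_anchors()] when an asymmetric architecture relative to a
#' summit-independent reference is of interest (see the vignette).
#'
#' @param pairs co-bound pair table from [cobound_genes()].
#' @return The pair table with an added `anchor` column (a gene ->
#'   anchor map with the pairing kept for downstream use).
#' @export
anchor_positions <- function(pairs) {
  pairs$anchor <- floor((pairs$summit_a + pairs$summit_b) / 2)
  pairs
}

#' Gene TSS positions as profile anchors
#'
#' @param annotation TSS annotation table.
#' @param genes optional subset of gene ids (e.g. the co-bound set).
#' @return A `data.frame` with `gene_id`, `chrom`, `anchor`, `strand`.
#' @export
tss_anchors <- function(annotation, genes = NULL) {
  if (!is.null(genes)) {
    annotation <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  }
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             anchor = annotation$tss, strand = annotation$strand,
             stringsAsFactors = FALSE)
}

#' Composite summit profiles around shared anchors
#'
#' For every factor/condition track in `peaks`, counts summits at each
#' binned transcription-direction offset from each anchor and averages
#' over anchors. Offsets live in `[-halfwidth, halfwidth)`; tracks
#' beyond the anchor-defining pair (e.g. a third factor in another
#' condition) can be profiled on the same anchors by concatenating
#' their peak tables.
#'
#' @param peaks one peak table, possibly the `rbind` of several
#'   factors/conditions.
#' @param anchors anchor table with columns `gene_id`, `chrom`,
#'   `anchor`, `strand` ([tss_anchors()]), or the output of
#'   [anchor_positions()].
#' @param halfwidth profile half-width in bp (multiple of `binwidth`).
#' @param binwidth bin width in bp.
#' @return A `composite_profile` data.frame with columns `factor`,
#'   `condition`, `offset` (bin centers) and `value` (mean summit count
#'   per anchor per bin); attributes `halfwidth`, `binwidth`,
#'   `n_anchors`.
#' @export
composite_profiles <- function(peaks, anchors, halfwidth = 400, binwidth = 10) {
  stopifnot(halfwidth > 0, binwidth > 0, halfwidth %% binwidth == 0)
  stop_if_not_cols(anchors, c("chrom", "anchor", "strand"), "anchor table")
  validate_peaks(peaks)
  n_anchors <- nrow(anchors)
  if (n_anchors == 0L) stop("no anchors supplied", call. = FALSE)
  nb <- as.integer(2 * halfwidth / binwidth)
  centers <- -halfwidth + (seq_len(nb) - 0.5) * binwidth
  sign <- ifelse(anchors$strand == "+", 1, -1)
  win <- GenomicRanges::GRanges(anchors$chrom,
                                IRanges::IRanges(anchors$anchor - halfwidth + 1,
                                                 anchors$anchor + halfwidth + 1))
  tracks <- unique(peaks[, c("factor", "condition")])
  out <- vector("list", nrow(tracks))
  for (t in seq_len(nrow(tracks))) {
    p <- peaks[peaks$factor == tracks$factor[t] &
                 peaks$condition == tracks$condition[t], , drop = FALSE]
    qry <- GenomicRanges::GRanges(p$chrom,
                                  IRanges::IRanges(p$summit + 1, width = 1))
    ov <- GenomicRanges::findOverlaps(qry, win)
    off <- (p$summit[S4Vectors::queryHits(ov)] -
              anchors$anchor[S4Vectors::subjectHits(ov)]) *
      sign[S4Vectors::subjectHits(ov)]
    off <- off[off >= -halfwidth & off < halfwidth]
    counts <- tabulate(floor((off + halfwidth) / binwidth) + 1L, nbins = nb)
    out[[t]] <- data.frame(factor = tracks$factor[t],
                           condition = tracks$condition[t],
                           offset = centers, value = counts / n_anchors,
                           stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out)
  attr(prof, "halfwidth") <- halfwidth
  attr(prof, "binwidth") <- binwidth
  attr(prof, "n_anchors") <- n_anchors
  class(prof) <- c("composite_profile", "data.frame")
  prof
}

#' Detect the composite binding-window architecture
#'
#' Per track, a bin is *occupied* when its profile value reaches
#' `threshold_frac` of that track's own maximum (a scale-free,
#' per-factor relative threshold). The overlap window is the longest
#' contiguous run of bins occupied by *all* tracks; factor-specific
#' windows are maximal runs occupied by *exactly one* track. The
#' per-track offset estimate is the occupancy-weighted mean offset over
#' its occupied bins.
#'
#' @param profiles `composite_profile` from [composite_profiles()]
#'   (at least two tracks on identical bins).
#' @param threshold_frac fraction in (0, 1] of each track's own profile
#'   maximum.
#' @param gap_tolerance number of consecutive sub-threshold bins
#'   bridged inside a run (0 = strict runs).
#' @return An `architecture_call`: list with `tracks`,
#'   `overlap_window` (`c(lo, hi)` in bp, or `NULL` when empty),
#'   `overlap_width`, `specific_windows` (per track, a data.frame of
#'   `lo`, `hi`, `width`), `offset_estimate`, `threshold_frac`,
#'   `binwidth`.
#' @export
detect_architecture <- function(profiles, threshold_frac = 0.5,
                                gap_tolerance = 0L) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  key <- track_label(profiles$factor, profiles$condition)
  tracks <- unique(key)
  if (length(tracks) < 2L) {
    stop("architecture detection needs at least two profiles", call. = FALSE)
  }
  offs <- sort(unique(profiles$offset))
  bw <- attr(profiles, "binwidth") %||% diff(offs[1:2])
  vals <- sapply(tracks, function(tr) {
    p <- profiles[key == tr, , drop = FALSE]
    if (!identical(sort(p$offset), offs)) {
      stop("profiles are not on identical bins", call. = FALSE)
    }
    p$value[order(p$offset)]
  })
  active <- matrix(FALSE, length(offs), length(tracks),
                   dimnames = list(NULL, tracks))
  for (j in seq_along(tracks)) {
    mx <- max(vals[, j])
    if (mx <= 0) stop("flat profile for track '", tracks[j], "'", call. = FALSE)
    active[, j] <- close_gaps(vals[, j] >= threshold_frac * mx,
                              as.integer(gap_tolerance))
  }
  n_active <- rowSums(active)
  interval_of <- function(run) {
    c(lo = offs[run[1]] - bw / 2, hi = offs[run[2]] + bw / 2)
  }
  ## overlap: longest run occupied by all tracks (first on ties)
  all_runs <- runs_of(n_active == length(tracks))
  overlap <- NULL
  if (nrow(all_runs)) {
    lens <- all_runs[, "end"] - all_runs[, "start"] + 1L
    overlap <- interval_of(all_runs[which.max(lens), ])
  }
  specific <- lapply(seq_along(tracks), function(j) {
    rr <- runs_of(active[, j] & n_active == 1L)
    if (!nrow(rr)) {
      return(data.frame(lo = numeric(), hi = numeric(), width = numeric()))
    }
    iv <- t(apply(rr, 1L, interval_of))
    data.frame(lo = iv[, 1], hi = iv[, 2], width = iv[, 2] - iv[, 1])
  })
  names(specific) <- tracks
  offset_est <- vapply(seq_along(tracks), function(j) {
    stats::weighted.mean(offs[active[, j]], vals[active[, j], j])
  }, numeric(1))
  names(offset_est) <- tracks
  structure(list(tracks = tracks,
                 overlap_window = overlap,
                 overlap_width = if (is.null(overlap)) 0 else
                   unname(overlap["hi"] - overlap["lo"]),
                 specific_windows = specific,
                 offset_estimate = offset_est,
                 threshold_frac = threshold_frac,
                 binwidth = bw),
            class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat("architecture_call (threshold ", x$threshold_frac, " x track max)\n",
      sep = "")
  if (is.null(x$overlap_window)) {
    cat("  shared window: none\n")
  } else {
    cat(sprintf("  shared window: [%g, %g] bp (width %g)\n",
                x$overlap_window["lo"], x$overlap_window["hi"],
                x$overlap_width))
  }
  for (tr in x$tracks) {
    sw <- x$specific_windows[[tr]]
    iv <- if (nrow(sw)) paste(sprintf("[%g, %g]", sw$lo, sw$hi), collapse = " ")
      else "none"
    cat(sprintf("  %s specific: %s; mean offset %.1f bp\n", tr, iv,
                x$offset_estimate[[tr]]))
  }
  invisible(x)
}

#' Genes whose own summits respect a called architecture
#'
#' A co-bound gene is kept when, for each of the two tracks, its
#' representative summit offset (transcription-direction, relative to
#' the gene's anchor) lies inside the shared window or that track's own
#' specific window(s) (closed intervals).
#'
#' @param pairs anchored pair table: [cobound_genes()] output with an
#'   `anchor` column (from [anchor_positions()], or merged from
#'   [tss_anchors()]).
#' @param architecture an `architecture_call` from
#'   [detect_architecture()].
#' @param tracks length-2 character: the architecture track labels
#'   corresponding to factors a and b of `pairs`; defaults to the
#'   pair table's `"tracks"` attribute.
#' @return Sorted character vector of gene identifiers.
#' @export
genes_with_architecture <- function(pairs, architecture, tracks = NULL) {
  tracks <- tracks %||% attr(pairs, "tracks")
  if (is.null(tracks) || length(tracks) != 2L) {
    stop("supply the two track labels matching the architecture call",
         call. = FALSE)
  }
  stop_if_not_cols(pairs, c("anchor", "summit_a", "summit_b", "strand"),
                   "anchored pair table")
  sign <- ifelse(pairs$strand == "+", 1, -1)
  off_a <- (pairs$summit_a - pairs$anchor) * sign
  off_b <- (pairs$summit_b - pairs$anchor) * sign
  windows_for <- function(track) {
    w <- architecture$specific_windows[[track]]
    if (is.null(w)) {
      stop("track '", track, "' not present in the architecture call",
           call. = FALSE)
    }
    ov <- architecture$overlap_window
    if (!is.null(ov)) w <- rbind(data.frame(lo = ov["lo"], hi = ov["hi"],
                                            width = NA_real_), w)
    w
  }
  inside <- function(off, w) {
    if (nrow(w) == 0L) return(rep(FALSE, length(off)))
    Reduce(`|`, lapply(seq_len(nrow(w)),
                       function(i) off >= w$lo[i] & off <= w$hi[i]))
  }
  keep <- inside(off_a, windows_for(tracks[1])) &
    inside(off_b, windows_for(tracks[2]))
  sort(pairs$gene_id[keep])
}
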