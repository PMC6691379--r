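## Strand-aware assignment of peaks to genes within a window around the
## TSS. Membership is decided by the peak summit by default (the summit
## is what the downstream profile analysis uses); interval-overlap
## membership is available via `mode = "overlap"`.

#' Assign peaks to genes around transcription start sites
#'
#' A peak is assigned to a gene when its strand-oriented summit distance
#' from the gene's TSS falls inside the closed window
#' `[tss_window[1], tss_window[2]]` (bp; negative = upstream in
#' transcription direction). A peak may be assigned to several genes and
#' a gene may receive several peaks.
#'
#' @param peaks peak table ([read_peaks()] / [simulate_peaks()]).
#' @param annotation TSS annotation ([read_tss()] /
#'   [simulate_annotation()]).
#' @param tss_window length-2 numeric window in bp, lower < upper.
#' @param mode `"summit"` (default): the summit must fall in the window;
#'   `"overlap"`: any overlap between the peak interval and the window
#'   suffices (the reported `distance` is still summit-based).
#' @param stranded logical; if `TRUE` (default) the window is oriented
#'   by gene strand, if `FALSE` it is applied in genomic coordinates and
#'   `distance` is the unoriented `summit - tss`.
#' @return A `data.frame` with one row per (gene, peak) assignment:
#'   `gene_id`, `factor`, `condition`, `chrom`, `peak_name`,
#'   `peak_start`, `peak_end`, `summit`, `strand`, `distance`.
#'   Chromosomes present in the peaks but absent from the annotation
#'   raise a warning and their peaks are skipped.
#' @export
assign_peaks <- function(peaks, annotation, tss_window = c(-2000, 6000),
                         mode = c("summit", "overlap"), stranded = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(tss_window) == 2L, tss_window[1] < tss_window[2])
  validate_peaks(peaks)
  stop_if_not_cols(annotation, c("gene_id", "chrom", "tss", "strand"),
                   "annotation")
  orphan <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(orphan)) {
    warning("skipping ", sum(peaks$chrom %in% orphan),
            " peak(s) on chromosome(s) absent from the annotation: ",
            paste(orphan, collapse = ", "), call. = FALSE)
    peaks <- peaks[!peaks$chrom %in% orphan, , drop = FALSE]
  }
  empty <- data.frame(gene_id = character(), factor = character(),
                      condition = character(), chrom = character(),
                      peak_name = character(), peak_start = integer(),
                      peak_end = integer(), summit = integer(),
                      strand = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(annotation) == 0L) return(empty)

  sign <- ifelse(annotation$strand == "+", 1, -1)
  if (stranded) {
    lo <- ifelse(sign > 0, annotation$tss + tss_window[1],
                 annotation$tss - tss_window[2])
    hi <- ifelse(sign > 0, annotation$tss + tss_window[2],
                 annotation$tss - tss_window[1])
  } else {
    lo <- annotation$tss + tss_window[1]
    hi <- annotation$tss + tss_window[2]
  }
  ## 0-based closed position range [lo, hi] -> 1-based IRanges [lo+1, hi+1]
  win <- GenomicRanges::GRanges(annotation$chrom, IRanges::IRanges(lo + 1, hi + 1))
  qry <- if (mode == "summit") {
    GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$summit + 1, width = 1))
  } else {
    ## [start, end) 0-based -> 1-based closed [start+1, end]
    GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  }
  ov <- GenomicRanges::findOverlaps(qry, win)
  pi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  d <- (peaks$summit[pi] - annotation$tss[gi]) * (if (stranded) sign[gi] else 1)
  out <- data.frame(gene_id = annotation$gene_id[gi],
                    factor = peaks$factor[pi],
                    condition = peaks$condition[pi],
                    chrom = peaks$chrom[pi],
                    peak_name = peaks$name[pi],
                    peak_start = peaks$start[pi],
                    peak_end = peaks$end[pi],
                    summit = peaks$summit[pi],
                    strand = annotation$strand[gi],
                    distance = d,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$peak_start, out$summit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Representative (nearest) assignment per gene
#'
#' Keeps, for every gene, the assignment with minimal `|distance|`.
#' Ties are broken toward the more upstream peak (smaller signed
#' distance), then by peak start.
#'
#' @param assignments output of [assign_peaks()].
#' @return One-row-per-gene `data.frame` with the same columns.
#' @export
nearest_assignment_per_gene <- function(assignments) {
  if (nrow(assignments) == 0L) return(assignments)
  o <- order(assignments$gene_id, abs(assignments$distance),
             assignments$distance, assignments$peak_start)
  a <- assignments[o, , drop = FALSE]
  a <- a[!duplicated(a$gene_id), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Genes bound by at least one peak
#'
#' @param assignments output of [assign_peaks()].
#' @return Sorted character vector of gene identifiers.
#' @export
bound_gene_set <- function(assignments) {
  sort(unique(assignments$gene_id))
}
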