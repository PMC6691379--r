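## Readers and writers for the external formats consumed and produced by
## the pipeline. All genomic coordinates are 0-based half-open internally
## (BED convention); 1-based formats (GFF3) are converted at this boundary
## and nowhere else.

bed6_cols <- c("chrom", "start", "end", "name", "score", "strand")
narrowpeak_cols <- c(bed6_cols, "signal", "pvalue", "qvalue", "peak")

#' Read ChIP-seq peak calls (BED6 or ENCODE narrowPeak)
#'
#' narrowPeak column 10 holds the summit offset from `start`; an offset
#' of -1 (summit not called) falls back to the interval midpoint,
#' `floor((start + end) / 2)`. For BED6 input the summit is always the
#' midpoint. For narrowPeak the `signalValue` column is kept as the
#' peak score; BED6 keeps its score column.
#'
#' @param path peak file (tab-separated, 6 or 10 columns).
#' @param factor transcription-factor label attached to every peak.
#' @param condition condition label (e.g. `"hypoxia"`).
#' @param score_min optional: drop peaks with score below this value.
#'   Peak callers emit scores but no filtering rule is assumed; by
#'   default all records are kept.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `summit`, `factor`, `condition`, sorted by
#'   (`chrom`, `start`). Coordinates are 0-based half-open; `summit`
#'   is a 0-based genomic coordinate inside `[start, end)`.
#' @export
read_peaks <- function(path, factor, condition, score_min = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  if (length(nf) == 0L) stop("empty peak file: ", path, call. = FALSE)
  ncols <- nf[!is.na(nf)][1]
  bad <- which(is.na(nf) | nf != ncols)
  if (length(bad)) {
    stop("malformed peak file '", path, "': line ", bad[1],
         " has a different number of fields", call. = FALSE)
  }
  if (!ncols %in% c(6L, 10L)) {
    stop("peak file must be BED6 (6 columns) or narrowPeak (10 columns), got ",
         ncols, " columns: ", path, call. = FALSE)
  }
  cols <- if (ncols == 6L) bed6_cols else narrowpeak_cols
  tb <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          col.names = cols, stringsAsFactors = FALSE)
  if (!is.numeric(tb$start) || !is.numeric(tb$end)) {
    stop("non-numeric coordinates in peak file: ", path, call. = FALSE)
  }
  bad <- which(tb$start >= tb$end)
  if (length(bad)) {
    stop("peak with start >= end at line ", bad[1], " of ", path, call. = FALSE)
  }
  if (ncols == 10L) {
    summit <- ifelse(tb$peak >= 0, tb$start + tb$peak,
                     floor((tb$start + tb$end) / 2))
    score <- tb$signal
  } else {
    summit <- floor((tb$start + tb$end) / 2)
    score <- tb$score
  }
  out <- data.frame(chrom = as.character(tb$chrom),
                    start = as.integer(tb$start),
                    end = as.integer(tb$end),
                    name = as.character(tb$name),
                    score = as.numeric(score),
                    summit = as.integer(summit),
                    factor = factor, condition = condition,
                    stringsAsFactors = FALSE)
  if (!is.null(score_min)) out <- out[out$score >= score_min, , drop = FALSE]
  validate_peaks(out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_peaks <- function(peaks) {
  stop_if_not_cols(peaks, c("chrom", "start", "end", "summit"), "peak table")
  if (any(!nzchar(peaks$chrom))) stop("empty chromosome name in peaks", call. = FALSE)
  if (any(peaks$start >= peaks$end)) stop("peak with start >= end", call. = FALSE)
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
    stop("peak summit outside [start, end)", call. = FALSE)
  }
  invisible(peaks)
}

#' Write peaks as ENCODE narrowPeak
#'
#' Inverse of [read_peaks()]: column 10 is `summit - start`.
#'
#' @param peaks peak table as returned by [read_peaks()] or
#'   [simulate_peaks()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    0L, ".", peaks$score, -1, -1, peaks$summit - peaks$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene/TSS annotation (GFF3 or 4-column TSV)
#'
#' GFF3 input uses the feature start as the TSS for `+` features and the
#' feature end for `-` features, converting 1-based inclusive coordinates
#' to the package's 0-based convention. When the GFF3 carries a `type`
#' column, only `gene` features are used. TSV input has columns
#' `gene_id`, `chrom`, `tss`, `strand` (already 0-based); a header line
#' is detected and skipped.
#'
#' @param path annotation file. Files ending in `.gff`/`.gff3` (or whose
#'   first line starts with `##gff`) are parsed as GFF3.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `tss`,
#'   `strand`. `gene_id` is unique; `strand` is `+` or `-`.
#' @export
read_tss <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    startsWith(first, "##gff")
  ann <- if (is_gff) read_tss_gff3(path) else read_tss_tsv(path)
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id in annotation: ", dup[1], call. = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    bad <- setdiff(unique(ann$strand), c("+", "-"))
    stop("unknown strand symbol in annotation: '", bad[1], "'", call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

read_tss_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  id <- NULL
  for (col in c("ID", "gene_id", "Name")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      id <- as.character(md[[col]])
      break
    }
  }
  if (is.null(id)) stop("no gene identifier attribute (ID/gene_id/Name) in GFF3",
                        call. = FALSE)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand symbol in annotation: '",
         setdiff(unique(strand), c("+", "-"))[1], "'", call. = FALSE)
  }
  tss <- ifelse(strand == "+",
                BiocGenerics::start(gr) - 1L,  # 1-based -> 0-based
                BiocGenerics::end(gr) - 1L)
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             tss = as.integer(tss), strand = strand,
             stringsAsFactors = FALSE)
}

read_tss_tsv <- function(path) {
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1]]
  has_header <- identical(first[1], "gene_id")
  tb <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          header = has_header, stringsAsFactors = FALSE)
  if (ncol(tb) != 4L) stop("TSS table must have 4 columns", call. = FALSE)
  names(tb) <- c("gene_id", "chrom", "tss", "strand")
  tb$gene_id <- as.character(tb$gene_id)
  tb$chrom <- as.character(tb$chrom)
  tb$tss <- as.integer(tb$tss)
  tb$strand <- as.character(tb$strand)
  tb
}

#' Write a TSS annotation as 4-column TSV
#'
#' @param annotation annotation as returned by [read_tss()] or
#'   [simulate_annotation()].
#' @param path output path.
#' @export
write_tss <- function(annotation, path) {
  stop_if_not_cols(annotation, c("gene_id", "chrom", "tss", "strand"),
                   "annotation")
  utils::write.table(annotation[, c("gene_id", "chrom", "tss", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a normalized expression matrix
#'
#' TSV with a header row of sample identifiers and gene identifiers in
#' the first column. Genes with any non-numeric cell are dropped with a
#' message reporting the count.
#'
#' @param path expression TSV.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  tb <- utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  genes <- tb[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier in expression matrix: ",
         genes[duplicated(genes)][1], call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(tb[-1], as.numeric, numeric(nrow(tb)))
  )
  if (nrow(tb) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(tb)[-1]))
  bad <- apply(is.na(vals), 1L, any)
  if (any(bad)) {
    message("read_expression: dropped ", sum(bad),
            " gene(s) with non-numeric values")
  }
  mat <- vals[!bad, , drop = FALSE]
  rownames(mat) <- genes[!bad]
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix, genes in rows (rownames), samples in
#'   columns (colnames).
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ## full-precision formatting so write -> read is bitwise lossless
  df[-1] <- lapply(df[-1], function(col) sprintf("%.17g", col))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample-to-group labels
#'
#' Two-column TSV mapping sample identifiers to group labels.
#'
#' @param path label TSV.
#' @param samples optional character vector of sample ids that must all
#'   be present (e.g. the columns of an expression matrix); a missing or
#'   empty label is an error.
#' @return A `data.frame` with columns `sample`, `group`.
#' @export
read_sample_labels <- function(path, samples = NULL) {
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1]]
  has_header <- identical(first[1], "sample")
  tb <- utils::read.table(path, sep = "\t", quote = "", header = has_header,
                          stringsAsFactors = FALSE, na.strings = "",
                          fill = TRUE)
  if (ncol(tb) < 2L) stop("label file must have two columns", call. = FALSE)
  names(tb)[1:2] <- c("sample", "group")
  tb <- tb[, c("sample", "group")]
  if (any(is.na(tb$group) | !nzchar(tb$group))) {
    stop("empty group label for sample '",
         tb$sample[which(is.na(tb$group) | !nzchar(tb$group))[1]], "'",
         call. = FALSE)
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, tb$sample)
    if (length(miss)) {
      stop("sample(s) missing from label file: ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
  }
  tb
}

#' Write sample-to-group labels
#' @param labels data.frame with columns `sample`, `group`.
#' @param path output path.
#' @export
write_sample_labels <- function(labels, path) {
  utils::write.table(labels[, c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Comment lines starting with `#` are skipped; a
#' `# provenance: <expression>` line, as written by
#' [write_gene_list()], is preserved as the `"provenance"` attribute.
#'
#' @param path gene-list file.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  prov <- grep("^#\\s*provenance:", lines, value = TRUE)
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(prov)) {
    attr(genes, "provenance") <- trimws(sub("^#\\s*provenance:", "", prov[1]))
  }
  genes
}

#' Write a gene list (one symbol per line)
#'
#' @param genes character vector, or a `gene_signature` from
#'   [derive_signature()] (its provenance is recorded as a header).
#' @param path output path.
#' @param provenance optional provenance expression written as a
#'   `# provenance:` header line.
#' @export
write_gene_list <- function(genes, path, provenance = NULL) {
  if (inherits(genes, "gene_signature")) {
    provenance <- provenance %||% genes$provenance
    genes <- genes$genes
  }
  header <- if (!is.null(provenance)) paste0("# provenance: ", provenance)
  writeLines(c(header, genes), path)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns `patient`, `time`, `event` (`event` 1 = observed,
#' 0 = censored).
#'
#' @param path survival TSV.
#' @return A `data.frame` with columns `patient`, `time`, `event`.
#' @export
read_survival <- function(path) {
  tb <- utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE)
  stop_if_not_cols(tb, c("patient", "time", "event"), "survival table")
  if (any(tb$time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(tb$event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  tb
}

#' Write a survival table
#' @param surv data.frame with columns `patient`, `time`, `event`.
#' @param path output path.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv[, c("patient", "time", "event")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a limiting-dilution well-count table
#'
#' TSV with columns `dose` (cells/well), `wells` (wells seeded) and
#' `negative` (wells without sphere formation); an optional `condition`
#' column separates experimental arms.
#'
#' @param path well-count TSV.
#' @return A `data.frame` with the columns above.
#' @export
read_dilution <- function(path) {
  tb <- utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE)
  stop_if_not_cols(tb, c("dose", "wells", "negative"), "dilution table")
  if (any(tb$negative > tb$wells)) {
    stop("negative well count exceeds wells seeded", call. = FALSE)
  }
  tb
}

#' Write a limiting-dilution well-count table
#' @param wells data.frame with columns `dose`, `wells`, `negative` and
#'   optionally `condition`.
#' @param path output path.
#' @export
write_dilution <- function(wells, path) {
  utils::write.table(wells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulator truth record
#'
#' Truth records are TSVs with a leading `#truth` line so they cannot be
#' mistaken for pipeline inputs.
#'
#' @param truth data.frame of planted ground truth.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#truth", con)
  suppressWarnings(
    utils::write.table(truth, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  )
  invisible(path)
}
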