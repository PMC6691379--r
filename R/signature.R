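## Gene-signature derivation by set algebra over named gene sets, plus
## fold-change summaries used to rank and evaluate signatures.

#' Derive a gene signature by set algebra
#'
#' Evaluates a provenance expression over named gene sets. Operators are
#' intersection (`∩` or `&`), union (`∪` or `|`) and difference
#' (`\` or `-`), applied left-to-right with parentheses for grouping
#' (no operator precedence). The result is sorted lexicographically and
#' carries the expression as its provenance.
#'
#' @param sets named list of character vectors.
#' @param provenance expression string, e.g. `"(hif ∩ tcf1) \\ tcf4"`.
#' @param name signature name.
#' @return A `gene_signature`: list with `name`, `genes`, `provenance`.
#' @export
#' @examples
#' derive_signature(list(A = c("g1", "g2"), B = c("g2", "g3")), "A & B")
derive_signature <- function(sets, provenance, name = "signature") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  toks <- tokenize_set_expr(provenance)
  parsed <- parse_set_expr(toks, 1L, sets)
  if (parsed$pos <= length(toks)) {
    stop("unexpected token '", toks[parsed$pos], "' in set expression",
         call. = FALSE)
  }
  structure(list(name = name, genes = sort(unique(parsed$value)),
                 provenance = provenance),
            class = "gene_signature")
}

tokenize_set_expr <- function(expr) {
  pat <- "[()]|∩|∪|\\\\|&|\\||-|[A-Za-z0-9_.]+"
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  leftover <- gsub(pat, "", expr)
  leftover <- gsub("[[:space:]]", "", leftover)
  if (nzchar(leftover)) {
    stop("unparseable characters in set expression: '", leftover, "'",
         call. = FALSE)
  }
  toks
}

set_ops <- c("∩" = "intersect", "&" = "intersect",
             "∪" = "union", "|" = "union",
             "\\" = "setdiff", "-" = "setdiff")

## left-to-right evaluation: term (op term)*
parse_set_expr <- function(toks, pos, sets) {
  term <- parse_set_term(toks, pos, sets)
  value <- term$value
  pos <- term$pos
  while (pos <= length(toks) && toks[pos] %in% names(set_ops)) {
    op <- set_ops[[toks[pos]]]
    term <- parse_set_term(toks, pos + 1L, sets)
    value <- get(op, mode = "function")(value, term$value)
    pos <- term$pos
  }
  list(value = value, pos = pos)
}

parse_set_term <- function(toks, pos, sets) {
  if (pos > length(toks)) stop("incomplete set expression", call. = FALSE)
  tok <- toks[pos]
  if (tok == "(") {
    inner <- parse_set_expr(toks, pos + 1L, sets)
    if (inner$pos > length(toks) || toks[inner$pos] != ")") {
      stop("unbalanced parentheses in set expression", call. = FALSE)
    }
    return(list(value = inner$value, pos = inner$pos + 1L))
  }
  if (tok %in% c(")", names(set_ops))) {
    stop("unexpected token '", tok, "' in set expression", call. = FALSE)
  }
  if (!tok %in% names(sets)) {
    stop("unknown set name '", tok, "' in set expression", call. = FALSE)
  }
  list(value = unique(sets[[tok]]), pos = pos + 1L)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "': ", length(x$genes), " genes\n",
      "  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Median fold change per gene and group relative to a reference group
#'
#' For each gene, subtracts the median of the reference samples and
#' reports the per-group median of the differences (on the log scale of
#' the input matrix, so differences are log fold changes). The
#' reference column is identically 0.
#'
#' @param mat log-scale expression matrix (genes x samples).
#' @param genes genes to summarize (default: all rows); genes absent
#'   from the matrix are an error.
#' @param groups group label per column of `mat` (character/factor).
#' @param reference reference group label.
#' @return Numeric matrix, genes x groups (reference first).
#' @export
median_foldchange <- function(mat, genes = rownames(mat), groups, reference) {
  stopifnot(length(groups) == ncol(mat))
  groups <- as.character(groups)
  if (!reference %in% groups) stop("reference group not found", call. = FALSE)
  miss <- setdiff(genes, rownames(mat))
  if (length(miss)) {
    stop("gene(s) absent from the matrix: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  x <- mat[genes, , drop = FALSE]
  ref_med <- apply(x[, groups == reference, drop = FALSE], 1L, stats::median)
  lvls <- c(reference, setdiff(unique(groups), reference))
  out <- vapply(lvls, function(g) {
    apply(x[, groups == g, drop = FALSE] - ref_med, 1L, stats::median)
  }, numeric(length(genes)))
  if (length(genes) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(genes, lvls))
  out
}

#' Top-n genes by fold change
#'
#' Sorts genes by fold change in the requested direction; ties are
#' broken lexicographically by gene id. If `n` exceeds the number of
#' genes, all genes are returned with a message.
#'
#' @param fc named numeric vector of (log) fold changes, or a matrix
#'   from [median_foldchange()] together with `group`.
#' @param n number of genes to keep.
#' @param direction `"down"` (most negative first) or `"up"`.
#' @param group column to use when `fc` is a matrix.
#' @return Character vector of gene ids, most extreme first.
#' @export
top_n_by_foldchange <- function(fc, n, direction = c("down", "up"),
                                group = NULL) {
  direction <- match.arg(direction)
  if (is.matrix(fc)) {
    if (is.null(group)) stop("supply 'group' for a fold-change matrix",
                             call. = FALSE)
    fc <- setNames(fc[, group], rownames(fc))
  }
  if (n > length(fc)) {
    message("top_n_by_foldchange: only ", length(fc),
            " genes available (requested ", n, ")")
    n <- length(fc)
  }
  key <- if (direction == "down") fc else -fc
  names(fc)[order(key, names(fc))][seq_len(n)]
}

#' Ward hierarchical clustering (Euclidean, Ward.D2)
#'
#' Agglomerative clustering with Euclidean distances under the Ward
#' variance criterion on unsquared distances (`hclust` method
#' `"ward.D2"`). Merge order is deterministic, with `hclust`'s index
#' tie-break.
#'
#' @param mat numeric matrix.
#' @param k number of clusters to cut (optional).
#' @param h cut height (optional alternative to `k`).
#' @param margin cluster `"columns"` (samples; default) or `"rows"`
#'   (genes).
#' @return List with the `hclust` object (`tree`), the cut `labels`
#'   (or `NULL` if neither `k` nor `h` given), and the clustered
#'   `margin`.
#' @export
ward_cluster <- function(mat, k = NULL, h = NULL,
                         margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  m <- if (margin == "columns") t(mat) else mat
  tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "ward.D2")
  labels <- if (!is.null(k) || !is.null(h)) {
    stats::cutree(tree, k = k, h = h)
  }
  list(tree = tree, labels = labels, margin = margin)
}
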