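`%||%` <- function(a, b) if (is.null(a)) b else a

## maximal runs of TRUE in a logical vector -> matrix with columns start, end
runs_of <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

## bridge FALSE gaps of length <= tol that are flanked by TRUE on both sides
close_gaps <- function(active, tol) {
  if (tol <= 0L || !any(active)) return(active)
  r <- rle(active)
  n <- length(r$values)
  fill <- !r$values & r$lengths <= tol &
    seq_len(n) > 1L & seq_len(n) < n
  r$values[fill] <- TRUE
  inverse.rle(r)
}

stop_if_not_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

## reproducible child seeds below 2^31 derived from one master seed
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
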