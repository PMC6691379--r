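#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline in one validated object.
#' Defaults reflect the promoter-window and scoring conventions used
#' throughout the package: peaks are assigned to genes whose
#' strand-oriented summit distance from the TSS falls in
#' `tss_window` (bp, closed interval, negative = upstream), composite
#' summit profiles span `+/- profile_halfwidth` bp in
#' `profile_binwidth` bins, a factor "occupies" a bin when its profile
#' reaches `occupancy_threshold_frac` of its own maximum, panel genes
#' count toward a patient's burden at cohort z-score `>= z_threshold`,
#' patients are called high-burden at `>= burden_cutoff` panel genes,
#' and permutation differential expression uses `sam_permutations`
#' label permutations at target FDR `sam_fdr`.
#'
#' @param tss_window length-2 numeric, window around the TSS in bp
#'   (lower < upper).
#' @param profile_halfwidth half-width of composite profiles in bp.
#' @param profile_binwidth profile bin width in bp; must divide
#'   `profile_halfwidth`.
#' @param occupancy_threshold_frac fraction in (0, 1] of a factor's own
#'   profile maximum above which a bin counts as occupied.
#' @param z_threshold cohort z-score threshold for panel-gene burden.
#' @param burden_cutoff burden count at or above which a patient is
#'   called high-burden.
#' @param sam_permutations number of label permutations for the
#'   permutation FDR.
#' @param sam_fdr target false discovery rate in (0, 1).
#' @param top_n number of genes kept by fold-change ranking.
#' @param seed integer seed recorded with the run.
#' @return An object of class `analysis_config` (a named list).
#' @export
#' @examples
#' cfg <- analysis_config(tss_window = c(-2000, 6000))
#' cfg$burden_cutoff
analysis_config <- function(tss_window = c(-2000, 6000),
                            profile_halfwidth = 400,
                            profile_binwidth = 10,
                            occupancy_threshold_frac = 0.5,
                            z_threshold = 1.5,
                            burden_cutoff = 7,
                            sam_permutations = 100,
                            sam_fdr = 0.05,
                            top_n = 20,
                            seed = 1) {
  tss_window <- as.numeric(tss_window)
  if (length(tss_window) != 2L || tss_window[1] >= tss_window[2]) {
    stop("tss_window must be two numbers with lower < upper", call. = FALSE)
  }
  if (profile_halfwidth <= 0 || profile_binwidth <= 0) {
    stop("profile widths must be positive", call. = FALSE)
  }
  if (profile_halfwidth %% profile_binwidth != 0) {
    stop("profile_halfwidth must be a multiple of profile_binwidth",
         call. = FALSE)
  }
  if (occupancy_threshold_frac <= 0 || occupancy_threshold_frac > 1) {
    stop("occupancy_threshold_frac must be in (0, 1]", call. = FALSE)
  }
  if (sam_fdr <= 0 || sam_fdr >= 1) stop("sam_fdr must be in (0, 1)", call. = FALSE)
  if (sam_permutations < 1) stop("sam_permutations must be >= 1", call. = FALSE)
  cfg <- list(
    tss_window = tss_window,
    profile_halfwidth = as.integer(profile_halfwidth),
    profile_binwidth = as.integer(profile_binwidth),
    occupancy_threshold_frac = occupancy_threshold_frac,
    z_threshold = z_threshold,
    burden_cutoff = as.integer(burden_cutoff),
    sam_permutations = as.integer(sam_permutations),
    sam_fdr = sam_fdr,
    top_n = as.integer(top_n),
    seed = as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Read a flat key-value configuration file
#'
#' The file holds one `key = value` pair per line; `#` starts a comment
#' and blank lines are ignored. Multi-valued keys (e.g. `tss_window`)
#' use comma-separated values. Unknown keys are an error. Values are
#' merged over the defaults of [analysis_config()].
#'
#' @param path path to the configuration file.
#' @param overrides optional named list applied after the file (e.g.
#'   command-line flags).
#' @return An `analysis_config` object.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key = value): '", ln, "'",
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    vals[[key]] <- as.numeric(strsplit(val, ",")[[1]])
  }
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (k in names(unclass(x))) {
    cat(sprintf("  %-24s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  invisible(x)
}
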