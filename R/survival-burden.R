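## Gene-panel z-score burden scoring and survival stratification:
## Kaplan-Meier curves, the two-group log-rank test, single-covariate
## Cox proportional hazards (Breslow ties) and the Wald cutoff scan.

#' Per-gene cohort z-scores
#'
#' `z = (x - gene mean) / gene SD` with the sample (n-1) standard
#' deviation, computed across the cohort. Genes with zero SD get
#' `z = 0` and are reported with a message.
#'
#' @param mat expression matrix (genes x patients).
#' @return Matrix of the same shape.
#' @export
zscore_matrix <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  flat <- sdv == 0 | is.na(sdv)
  if (any(flat)) {
    message("zscore_matrix: ", sum(flat),
            " constant gene(s) set to z = 0")
    sdv[flat] <- 1
  }
  z <- (mat - mu) / sdv
  z[flat, ] <- 0
  z
}

#' Per-patient panel burden
#'
#' Counts, for each patient, the panel genes whose z-score reaches the
#' threshold (`>=` by default; `strict = TRUE` uses `>`).
#'
#' @param z z-score matrix from [zscore_matrix()].
#' @param panel panel gene ids; genes absent from `z` raise a warning
#'   and are ignored.
#' @param z_threshold z-score threshold (default 1.5).
#' @param strict use strict `>` instead of `>=`.
#' @return Named integer vector, one burden per patient.
#' @export
burden_scores <- function(z, panel, z_threshold = 1.5, strict = FALSE) {
  miss <- setdiff(panel, rownames(z))
  if (length(miss)) {
    warning(length(miss), " panel gene(s) absent from the matrix",
            call. = FALSE)
    panel <- setdiff(panel, miss)
  }
  if (length(panel) == 0L) stop("no panel genes in the matrix", call. = FALSE)
  zz <- z[panel, , drop = FALSE]
  hits <- if (strict) zz > z_threshold else zz >= z_threshold
  colSums(hits)
}

#' Kaplan-Meier product-limit curve
#'
#' Censored observations tied with events at the same time are handled
#' after the events (standard product-limit convention).
#'
#' @param time survival times (> 0).
#' @param event event indicator (1 = observed, 0 = censored).
#' @return A `data.frame` step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_curve <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param group two-level group label per patient.
#' @param time,event survival outcome.
#' @return List with `statistic` (chi-square, 1 df), `p`, and the
#'   per-group observed/expected event counts.
#' @export
logrank_test <- function(group, time, event) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Single-covariate Cox proportional hazards (Wald test)
#'
#' Partial-likelihood fit for a binary indicator with Breslow tie
#' handling. A monotone likelihood (one stratum holds all the early
#' events) is flagged rather than silently returned: `infinite = TRUE`
#' and the log hazard ratio is the +/-Inf sentinel.
#'
#' @param time,event survival outcome.
#' @param x binary covariate (0/1 or logical); both levels must be
#'   present and at least one event observed.
#' @return List with `loghr`, `se`, `hr`, `wald` (z-squared), `p`,
#'   `ci95` (for the log HR), `n`, `events`, `infinite`.
#' @export
cox_binary <- function(time, event, x) {
  x <- as.numeric(x)
  if (length(unique(x)) != 2L) {
    stop("covariate must take exactly two values", call. = FALSE)
  }
  if (sum(event) < 1) stop("at least one event required", call. = FALSE)
  infinite <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        infinite <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  if (!infinite && (abs(beta) > 15 || se > 100)) infinite <- TRUE
  if (infinite) beta <- sign(beta) * Inf
  wald <- (beta / se)^2
  list(loghr = beta, se = se, hr = exp(beta), wald = wald,
       p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
       ci95 = beta + c(-1, 1) * stats::qnorm(0.975) * se,
       n = length(time), events = sum(event), infinite = infinite)
}

#' Wald cutoff scan over burden thresholds
#'
#' Runs [cox_binary()] with the high-burden indicator
#' `burden >= cutoff` at every candidate cutoff for which both strata
#' are non-empty, and reports the full table. The minimal-p cutoff is
#' highlighted in the `"best"` attribute, with a logged reminder that
#' scanning cutoffs is a multiple-testing exercise; no cutoff is
#' auto-selected silently.
#'
#' @param burden per-patient burden counts.
#' @param time,event survival outcome, aligned with `burden`.
#' @param cutoffs candidate cutoffs; defaults to every achievable
#'   threshold `min(burden)+1 ... max(burden)`.
#' @return A `cutoff_scan` data.frame: `cutoff`, `n_high`, `n_low`,
#'   `loghr`, `hr`, `se`, `wald`, `p`, `note`; attribute `best` holds
#'   the minimal-p row.
#' @export
cutoff_scan <- function(burden, time, event, cutoffs = NULL) {
  stopifnot(length(burden) == length(time), length(time) == length(event))
  cutoffs <- cutoffs %||% seq(min(burden) + 1L, max(burden))
  rows <- lapply(cutoffs, function(cc) {
    high <- burden >= cc
    base <- data.frame(cutoff = cc, n_high = sum(high), n_low = sum(!high),
                       loghr = NA_real_, hr = NA_real_, se = NA_real_,
                       wald = NA_real_, p = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (!any(high) || all(high)) {
      base$note <- "degenerate stratum, skipped"
      return(base)
    }
    if (sum(event[high]) == 0 && sum(event[!high]) == 0) {
      base$note <- "no events, skipped"
      return(base)
    }
    fit <- cox_binary(time, event, high)
    base$loghr <- fit$loghr
    base$hr <- fit$hr
    base$se <- fit$se
    base$wald <- fit$wald
    base$p <- fit$p
    if (fit$infinite) base$note <- "monotone likelihood (infinite HR)"
    base
  })
  scan <- do.call(rbind, rows)
  fitted <- which(is.finite(scan$p))
  if (length(fitted)) {
    best <- scan[fitted[which.min(scan$p[fitted])], , drop = FALSE]
    attr(scan, "best") <- best
    message("cutoff_scan: minimal Wald p at cutoff ", best$cutoff,
            " (p = ", signif(best$p, 3),
            "); p-values are not adjusted for scanning multiple cutoffs")
  }
  class(scan) <- c("cutoff_scan", "data.frame")
  scan
}

#' @export
print.cutoff_scan <- function(x, ...) {
  print.data.frame(x, ...)
  best <- attr(x, "best")
  if (!is.null(best)) {
    cat("best (unadjusted) cutoff: ", best$cutoff,
        ", HR = ", signif(best$hr, 3), ", p = ", signif(best$p, 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Build a per-patient burden table joined to survival outcomes
#'
#' Convenience wrapper chaining [zscore_matrix()], [burden_scores()]
#' and the survival join; the high/low stratum is
#' `burden >= burden_cutoff`.
#'
#' @param expression genes x patients matrix.
#' @param surv survival table (`patient`, `time`, `event`).
#' @param panel panel gene ids.
#' @param z_threshold,strict passed to [burden_scores()].
#' @param burden_cutoff stratum threshold.
#' @return A `data.frame`: `patient`, `burden`, `stratum`
#'   (`"high"`/`"low"`), `time`, `event`.
#' @export
burden_table <- function(expression, surv, panel, z_threshold = 1.5,
                         strict = FALSE, burden_cutoff = 7) {
  burden <- burden_scores(zscore_matrix(expression), panel,
                          z_threshold, strict)
  idx <- match(surv$patient, names(burden))
  if (any(is.na(idx))) {
    stop("patient(s) missing from the expression matrix: ",
         paste(utils::head(surv$patient[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  data.frame(patient = surv$patient,
             burden = as.integer(burden[idx]),
             stratum = ifelse(burden[idx] >= burden_cutoff, "high", "low"),
             time = surv$time, event = surv$event,
             stringsAsFactors = FALSE)
}
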