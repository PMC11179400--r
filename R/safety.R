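#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval: with `x` events in `n` trials
#' and level `1 - alpha`, the lower bound is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x == 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x == n`). Exact
#' intervals are the appropriate choice for the 0- and 1-event counts this
#' surveillance produces.
#'
#' @param x event count.
#' @param n trial count (> 0).
#' @param conf confidence level, default 0.95.
#' @return named numeric `c(lower, upper)` on the proportion scale.
#' @examples
#' clopper_pearson(0, 100)   # upper bound 1 - 0.025^(1/100)
#' clopper_pearson(1, 1418)
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n, conf > 0, conf < 1)
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# display rows of the safety table, mapped from lexicon terms
.complication_rows <- c(
  "endophthalmitis" = "Endophthalmitis (postoperative)",
  "lens touch" = "Lens touch/trauma",
  "iris touch" = "Iris touch/trauma",
  "hyphema" = "Hyphema",
  "tear" = "Descemet membrane tear",
  "cornea touch" = "Other corneal trauma",
  "leak" = "Entry site leak",
  "shallow" = "Anterior chamber shallowing forcing termination",
  "suprachoroidal" = "Suprachoroidal hemorrhage",
  "movement" = "Problems caused by patient's movements",
  "bleeding" = "Bleeding (other)",
  "hemorrhage" = "Hemorrhage (other)")

#' Compile the safety report
#'
#' Per-complication counts and rates with exact 95% intervals. The
#' endophthalmitis row counts *postoperative* cases only, taken from the
#' temporal classification; every other row comes from the adjudicated
#' text flags. The total row counts distinct cases with any biopsy-related
#' complication.
#'
#' @param flags flag data.frame from [flag_corpus()] (`case_id` plus one
#'   logical column per term).
#' @param temporal per-case data.frame from [endophthalmitis_temporal()].
#' @param conf confidence level for the intervals.
#' @return list of class `safety_report`: `n`, `table` (complication,
#'   count, rate_pct, rate_display, ci_lower_pct, ci_upper_pct),
#'   `total_count`, `total_rate_pct`, `total_ci_pct`,
#'   `postop_endophthalmitis`.
#' @export
complication_report <- function(flags, temporal, conf = 0.95) {
  n <- nrow(flags)
  if (n == 0L) stop("no cases: cannot compile a safety report", call. = FALSE)
  terms <- setdiff(names(flags), "case_id")
  postop_ids <- temporal$case_id[temporal$classification == "postoperative"]
  count_for <- function(t) {
    if (t == "endophthalmitis") length(postop_ids) else sum(flags[[t]])
  }
  tab <- do.call(rbind, lapply(terms, function(t) {
    x <- count_for(t)
    ci <- clopper_pearson(x, n, conf)
    data.frame(term = t,
               complication = unname(.complication_rows[t]) %||% t,
               count = x,
               rate_pct = 100 * x / n,
               rate_display = format_rate(100 * x / n),
               ci_lower_pct = 100 * ci[["lower"]],
               ci_upper_pct = 100 * ci[["upper"]],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  intra <- setdiff(terms, "endophthalmitis")
  any_flag <- rowSums(as.data.frame(flags[intra])) > 0
  total_ids <- union(flags$case_id[any_flag], postop_ids)
  total <- length(total_ids)
  ci <- clopper_pearson(total, n, conf)
  structure(list(n = n, table = tab,
                 total_count = total,
                 total_rate_pct = 100 * total / n,
                 total_ci_pct = 100 * ci,
                 postop_endophthalmitis = length(postop_ids)),
            class = "safety_report")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

# rates below 1% shown to 2 significant figures, else 1 decimal
format_rate <- function(pct) {
  vapply(pct, function(p) {
    if (p == 0) "0%" else if (p < 1) sprintf("%.2f%%", signif(p, 2)) else
      sprintf("%.1f%%", p)
  }, character(1))
}

#' @export
print.safety_report <- function(x, ...) {
  cat(sprintf("<safety_report> n = %d cases\n", x$n))
  cat(sprintf("  total complications: %d (%s), 95%% CI [%.3f%%, %.3f%%]\n",
              x$total_count, format_rate(x$total_rate_pct),
              x$total_ci_pct[["lower"]], x$total_ci_pct[["upper"]]))
  cat(sprintf("  postoperative endophthalmitis: %d\n",
              x$postop_endophthalmitis))
  nonzero <- x$table[x$table$count > 0, , drop = FALSE]
  for (i in seq_len(nrow(nonzero))) {
    cat(sprintf("  %s: %d (%s)\n", nonzero$complication[i], nonzero$count[i],
                nonzero$rate_display[i]))
  }
  invisible(x)
}

#' Seeded manual-audit protocol
#'
#' Draws a uniform random sample of `round(audit_fraction * n)` cases
#' without replacement and compares each sampled case's per-term flags with
#' the reviewer table (in synthetic runs, the planted ground truth). The
#' expected raw flag for a term is its presence in `complications_true`,
#' except `endophthalmitis`, whose expected raw flag is the planted
#' pre-existing or postoperative disease history.
#'
#' @param flags flag data.frame from [flag_corpus()].
#' @param truth ground-truth data.frame (columns `case_id`,
#'   `complications_true`, `has_preexisting_endophthalmitis`).
#' @param audit_fraction proportion of cases to review, in (0, 1].
#' @param seed integer seed for the sample.
#' @return list of class `audit_result`: `audit_n`, `audit_fraction`,
#'   `sampled_case_ids`, `per_flag` (term, agreements, accuracy,
#'   false_positives, false_negatives), `overall_accuracy` (fraction of
#'   sampled cases whose whole flag set matches), `intraop_accuracy` (same,
#'   endophthalmitis excluded).
#' @export
run_audit <- function(flags, truth, audit_fraction, seed = 1L) {
  if (is.na(audit_fraction) || audit_fraction <= 0 || audit_fraction > 1) {
    stop("audit_fraction must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(flags)
  audit_n <- as.integer(round(audit_fraction * n))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  idx <- sample.int(n, audit_n)
  terms <- setdiff(names(flags), "case_id")
  tr <- truth[match(flags$case_id[idx], truth$case_id), , drop = FALSE]
  expected <- vapply(terms, function(t) {
    base <- mapply(function(s) t %in% strsplit(s, ";")[[1]],
                   tr$complications_true)
    if (t == "endophthalmitis") {
      base <- base | tr$has_preexisting_endophthalmitis
    }
    as.logical(base)
  }, logical(audit_n))
  observed <- as.matrix(as.data.frame(flags[idx, terms, drop = FALSE]))
  agree <- observed == expected
  per_flag <- data.frame(
    term = terms,
    agreements = as.integer(colSums(agree)),
    accuracy = colMeans(agree),
    false_positives = as.integer(colSums(observed & !expected)),
    false_negatives = as.integer(colSums(!observed & expected)),
    stringsAsFactors = FALSE)
  rownames(per_flag) <- NULL
  intra <- setdiff(terms, "endophthalmitis")
  structure(list(audit_n = audit_n,
                 audit_fraction = audit_fraction,
                 sampled_case_ids = flags$case_id[idx],
                 per_flag = per_flag,
                 overall_accuracy = mean(rowSums(!agree) == 0L),
                 intraop_accuracy =
                   mean(rowSums(!agree[, intra, drop = FALSE]) == 0L)),
            class = "audit_result")
}

#' @export
print.audit_result <- function(x, ...) {
  cat(sprintf("<audit_result> %d cases audited (%.1f%% of cohort)\n",
              x$audit_n, 100 * x$audit_fraction))
  cat(sprintf("  complication-flag accuracy: %.1f%% (intraoperative terms: %.1f%%)\n",
              100 * x$overall_accuracy, 100 * x$intraop_accuracy))
  invisible(x)
}
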