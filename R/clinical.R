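# Trial endpoint summaries from a per-patient table: RECIST best response on
# a single target lesion, CA19-9 biochemical response with the bilirubin
# evaluability rule, pathology proportions, adverse-event tabulation, and
# Kaplan-Meier medians.

# nearest-integer percent, half away from zero
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den)
}

#' RECIST 1.1 best response for a single target lesion
#'
#' Baseline is the first measurement. Partial response (PR) iff the best
#' percent change from baseline is at or below `pr_threshold` (-30%);
#' progressive disease (PD) iff any measurement is at least `pd_threshold`
#' (+20%) above the nadir (the smallest prior measurement, including
#' baseline) AND at least 5 mm above it in absolute terms; otherwise stable
#' disease (SD). Fewer than 2 measurements gives NE (no on-treatment
#' imaging).
#'
#' @param diameters Longest diameters (mm) in chronological order.
#' @param pr_threshold,pd_threshold Percent-change thresholds; defaults -30
#'   and +20.
#' @return List with `response` (`"PR"`, `"SD"`, `"PD"`, `"NE"`) and
#'   `best_change_pct` (NA for NE).
#' @export
#' @examples
#' recist_best_response(c(40, 28))$response # "PR": -30% inclusive
recist_best_response <- function(diameters, pr_threshold = -30,
                                 pd_threshold = 20) {
  d <- as.numeric(diameters)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("recist_best_response: diameters must be positive")
  }
  if (length(d) < 2L) {
    return(list(response = "NE", best_change_pct = NA_real_))
  }
  base <- d[1]
  change <- 100 * (d - base) / base
  best <- min(change[-1])
  nadir <- cummin(d)
  later <- 2:length(d)
  from_nadir_pct <- 100 * (d[later] - nadir[later - 1L]) / nadir[later - 1L]
  from_nadir_abs <- d[later] - nadir[later - 1L]
  pd <- any(from_nadir_pct >= pd_threshold & from_nadir_abs >= 5)
  response <- if (best <= pr_threshold) "PR" else if (pd) "PD" else "SD"
  list(response = response, best_change_pct = best)
}

#' CA19-9 biochemical response
#'
#' Draws taken at total bilirubin at or above `bilirubin_max` (3 mg/dL) are
#' dropped as unevaluable. The course is evaluable iff at least 2 draws
#' remain; `decreased` iff the last remaining value is below the first;
#' `converted` iff the first is abnormal (strictly above `upper_normal`,
#' 37 U/mL) and the last is normal (at or below it).
#'
#' @param values CA19-9 values (U/mL) in chronological order.
#' @param bilirubin Total bilirubin (mg/dL) at each draw.
#' @param upper_normal Upper limit of normal; default 37.
#' @param bilirubin_max Evaluability cutoff; default 3.
#' @return List with `evaluable`, `decreased`, `converted`.
#' @export
#' @examples
#' ca199_response(c(232, 37), c(1, 1)) # decreased and converted
ca199_response <- function(values, bilirubin, upper_normal = 37,
                           bilirubin_max = 3) {
  stopifnot(length(values) == length(bilirubin), length(values) >= 1L)
  keep <- bilirubin < bilirubin_max
  v <- values[keep]
  if (length(v) < 2L) {
    return(list(evaluable = FALSE, decreased = NA, converted = NA))
  }
  list(evaluable = TRUE,
       decreased = v[length(v)] < v[1],
       converted = v[1] > upper_normal && v[length(v)] <= upper_normal)
}

#' Summarize a clinical cohort
#'
#' Computes the trial endpoint summary: resection rate over enrolled
#' patients; CAP score, margin (R0) and nodal (pN0) distributions over
#' resected patients; best-response and CA19-9 rates over patients
#' completing treatment (with the over-enrolled view also emitted); the
#' grade-4 adverse-event instance count; and Kaplan-Meier medians for
#' DFS/PFS/OS. Percentages are rounded to the nearest integer, half away
#' from zero.
#'
#' @param cohort A `clinical_cohort` (see [generate_clinical_cohort()]).
#' @param config An [la_config()] supplying the CA19-9 / bilirubin / RECIST
#'   thresholds.
#' @return Object of class `cohort_summary` (a named list of counts,
#'   percentages and KM medians).
#' @export
#' @examples
#' summarize_cohort(generate_clinical_cohort("trial_2026", seed = 1))
summarize_cohort <- function(cohort, config = la_config()) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  pts <- cohort$patients
  if (!nrow(pts)) stop("summarize_cohort: empty cohort")
  n_enrolled <- sum(pts$enrolled)
  n_resected <- sum(pts$resected)
  n_completed <- sum(pts$completed_treatment)

  res <- list(n_enrolled = n_enrolled, n_resected = n_resected,
              n_completed = n_completed,
              resection_rate = pct(n_resected, n_enrolled))

  resected <- pts[pts$resected, , drop = FALSE]
  cap_n <- table(factor(resected$cap_score, levels = 0:3))
  res$cap_counts <- stats::setNames(as.integer(cap_n), paste0("cap", 0:3))
  res$cap_distribution <- stats::setNames(
    vapply(as.integer(cap_n), pct, numeric(1), den = n_resected),
    paste0("cap", 0:3))
  res$r0_count <- sum(resected$margins == "R0", na.rm = TRUE)
  res$r0_rate <- pct(res$r0_count, n_resected)
  res$r1_count <- sum(resected$margins == "R1", na.rm = TRUE)
  pn_n <- table(factor(resected$pn_stage, levels = 0:2))
  res$pn_counts <- stats::setNames(as.integer(pn_n), paste0("pn", 0:2))
  res$pn0_rate <- pct(as.integer(pn_n)[1], n_resected)

  # best response and CA19-9 over patients completing treatment
  completed_ids <- pts$patient_id[pts$completed_treatment]
  responses <- character(0)
  shrank <- logical(0)
  for (pid in completed_ids) {
    les <- cohort$lesions[cohort$lesions$patient_id == pid, , drop = FALSE]
    les <- les[order(les$day), , drop = FALSE]
    if (!nrow(les)) {
      responses <- c(responses, "NE"); shrank <- c(shrank, NA)
      next
    }
    rb <- recist_best_response(les$longest_diameter,
                               pr_threshold = config$recist_pr,
                               pd_threshold = config$recist_pd)
    responses <- c(responses, rb$response)
    shrank <- c(shrank, if (is.na(rb$best_change_pct)) NA else
      rb$best_change_pct < 0)
  }
  imaged <- responses != "NE"
  n_response_eval <- sum(imaged)
  res$n_response_evaluable <- n_response_eval
  res$orr_count <- sum(responses == "PR")
  res$orr <- pct(res$orr_count, n_response_eval)
  res$orr_over_enrolled <- pct(res$orr_count, n_enrolled)
  res$sd_count <- sum(responses == "SD")
  res$sd_rate <- pct(res$sd_count, n_response_eval)
  res$pd_count <- sum(responses == "PD")
  res$ne_count <- sum(!imaged) + sum(!pts$completed_treatment)
  res$tumor_shrinkage_count <- sum(shrank, na.rm = TRUE)
  res$tumor_shrinkage_rate <- pct(res$tumor_shrinkage_count, n_response_eval)

  ca_eval <- 0L; ca_dec <- 0L; ca_conv <- 0L
  for (pid in completed_ids) {
    ca <- cohort$ca199[cohort$ca199$patient_id == pid, , drop = FALSE]
    ca <- ca[order(ca$day), , drop = FALSE]
    if (!nrow(ca)) next
    cr <- ca199_response(ca$value, ca$bilirubin,
                         upper_normal = config$ca199_upper_normal,
                         bilirubin_max = config$bilirubin_max)
    if (cr$evaluable) {
      ca_eval <- ca_eval + 1L
      ca_dec <- ca_dec + cr$decreased
      ca_conv <- ca_conv + cr$converted
    }
  }
  res$n_ca199_evaluable <- ca_eval
  res$ca199_decrease_count <- ca_dec
  res$ca199_decrease_rate <- pct(ca_dec, ca_eval)
  res$ca199_conversion_count <- ca_conv
  res$ca199_conversion_rate <- pct(ca_conv, ca_eval)

  res$grade4_ae_count <- sum(cohort$aes$grade == 4L)
  res$grade3plus_ae_count <- sum(cohort$aes$grade >= 3L)

  km <- function(time, event) {
    ok <- !is.na(time) & !is.na(event)
    if (sum(ok) < 2L) return(list(median = NA_real_, lower = NA_real_,
                                  upper = NA_real_))
    km_median(time[ok], event[ok])
  }
  res$dfs <- km(pts$dfs_time, pts$dfs_event)
  res$pfs <- km(pts$pfs_time, pts$pfs_event)
  res$os <- km(pts$os_time, pts$os_event)

  class(res) <- "cohort_summary"
  res
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  enrolled %d; resected %d (%d%%); completed treatment %d\n",
              x$n_enrolled, x$n_resected, x$resection_rate, x$n_completed))
  cat(sprintf("  CAP 0/1/2/3: %s (%% of resected: %s)\n",
              paste(x$cap_counts, collapse = "/"),
              paste(x$cap_distribution, collapse = "/")))
  cat(sprintf("  R0 %d (%d%%); pN0/1/2: %s (pN0 %d%%)\n",
              x$r0_count, x$r0_rate, paste(x$pn_counts, collapse = "/"),
              x$pn0_rate))
  cat(sprintf("  ORR %d/%d (%d%%); SD %d (%d%%); shrinkage %d (%d%%)\n",
              x$orr_count, x$n_response_evaluable, x$orr, x$sd_count,
              x$sd_rate, x$tumor_shrinkage_count, x$tumor_shrinkage_rate))
  cat(sprintf("  CA19-9 decreased %d/%d (%d%%); normalized %d (%d%%)\n",
              x$ca199_decrease_count, x$n_ca199_evaluable,
              x$ca199_decrease_rate, x$ca199_conversion_count,
              x$ca199_conversion_rate))
  cat(sprintf("  grade-4 AEs: %d\n", x$grade4_ae_count))
  fm <- function(s) sprintf("%.1f [%.1f, %s]", s$median, s$lower,
                            if (is.na(s$upper)) "NR" else sprintf("%.1f", s$upper))
  cat(sprintf("  KM medians (months): DFS %s; PFS %s; OS %s\n",
              fm(x$dfs), fm(x$pfs), fm(x$os)))
  invisible(x)
}

#' Kaplan-Meier median with confidence interval
#'
#' Product-limit estimator (via the survival package) with a log-log
#' confidence interval; the median is the smallest time at which the
#' survival curve is at or below 0.5, NA ("not reached") when the curve
#' never crosses 0.5.
#'
#' @param times Follow-up times (>= 0).
#' @param events Logical/0-1 event indicators (FALSE = censored).
#' @param conf Confidence level; default 0.95.
#' @return List with `median`, `lower`, `upper` (NA where not reached).
#' @export
#' @examples
#' km_median(c(1, 2, 3, 4), c(1, 1, 1, 1))$median # 2
km_median <- function(times, events, conf = 0.95) {
  stopifnot(all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "log-log", conf.int = conf)
  crossing <- function(s, t) {
    i <- which(!is.na(s) & s <= 0.5 + 1e-12)
    if (!length(i)) NA_real_ else t[min(i)]
  }
  # median CI by inverting the pointwise log-log band at 0.5
  list(median = crossing(fit$surv, fit$time),
       lower = crossing(fit$upper, fit$time),
       upper = crossing(fit$lower, fit$time))
}
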