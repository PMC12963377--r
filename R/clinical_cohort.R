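# Synthetic clinical cohort generator. The "trial_2026" preset reproduces the
# analyzed structure of a 28-patient neoadjuvant chemoimmunotherapy trial in
# borderline-resectable pancreatic cancer: 22 resected, CAP treatment-response
# scores {0:2, 1:2, 2:16, 3:2}, margins {R0:19, R1:3}, nodal stage
# {pN0:11, pN1:7, pN2:4}, and among the 26 patients completing treatment a
# CA19-9 decrease for 19 with 8 normalizations, tumor shrinkage for 21 with 7
# partial responses, and 4 grade-4 adverse events (3 neutropenia, 1
# hypokalemia). Continuous values are randomized within those strata under
# the seed.

#' Generate a synthetic clinical cohort
#'
#' @param preset_or_params Either the string `"trial_2026"` (the 28-patient
#'   preset described above) or a list with explicit counts: `n` (cohort
#'   size), and optionally `n_resected`, `n_completed` (all default 0, giving
#'   rows with all flags false and empty series).
#' @param seed Integer seed for the within-stratum randomization.
#' @return An object of class `clinical_cohort`: a list of data frames
#'   `patients` (one row per patient), `ca199` (long: patient_id, day, value
#'   U/mL, bilirubin mg/dL), `lesions` (long: patient_id, day,
#'   longest_diameter mm), and `aes` (long: patient_id, term, grade).
#' @export
#' @examples
#' coh <- generate_clinical_cohort("trial_2026", seed = 1)
#' nrow(coh$patients) # 28
generate_clinical_cohort <- function(preset_or_params = "trial_2026",
                                     seed = 1) {
  set.seed(seed)
  if (is.character(preset_or_params)) {
    preset <- match.arg(preset_or_params, "trial_2026")
    return(.cohort_trial_2026())
  }
  p <- preset_or_params
  n <- p$n
  if (is.null(n) || n < 1) stop("generate_clinical_cohort: 'n' required")
  n_res <- if (is.null(p$n_resected)) 0L else p$n_resected
  n_comp <- if (is.null(p$n_completed)) 0L else p$n_completed
  if (n_res > n || n_comp > n) {
    stop("generate_clinical_cohort: counts exceed cohort size")
  }
  patients <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    enrolled = TRUE,
    completed_treatment = seq_len(n) <= n_comp,
    resected = seq_len(n) <= n_res,
    cap_score = NA_integer_, margins = NA_character_,
    pn_stage = NA_integer_,
    dfs_time = NA_real_, dfs_event = NA,
    pfs_time = NA_real_, pfs_event = NA,
    os_time = NA_real_, os_event = NA,
    stringsAsFactors = FALSE)
  empty_ca <- data.frame(patient_id = character(0), day = numeric(0),
                         value = numeric(0), bilirubin = numeric(0))
  empty_les <- data.frame(patient_id = character(0), day = numeric(0),
                          longest_diameter = numeric(0))
  empty_ae <- data.frame(patient_id = character(0), term = character(0),
                         grade = integer(0))
  structure(list(patients = patients, ca199 = empty_ca, lesions = empty_les,
                 aes = empty_ae), class = "clinical_cohort")
}

.cohort_trial_2026 <- function() {
  n <- 28L
  id <- sprintf("P%02d", seq_len(n))
  resected <- seq_len(n) <= 22L
  completed <- seq_len(n) <= 26L
  cap <- rep(NA_integer_, n)
  cap[1:2] <- 0L; cap[3:4] <- 1L; cap[5:20] <- 2L; cap[21:22] <- 3L
  margins <- rep(NA_character_, n)
  margins[1:19] <- "R0"; margins[20:22] <- "R1"
  pn <- rep(NA_integer_, n)
  pn[1:11] <- 0L; pn[12:18] <- 1L; pn[19:22] <- 2L

  # CA19-9 series (days 0, 28, ..., 140) for the 26 completing treatment:
  # strata 1-8 convert (>37 -> <=37), 9-19 decrease without converting,
  # 20-26 do not decrease. All draws at bilirubin < 3 mg/dL.
  days <- seq(0, 140, by = 28)
  ca_rows <- list()
  for (i in 1:26) {
    if (i <= 8) {
      first <- runif(1, 100, 600); last <- runif(1, 8, 36.5)
    } else if (i <= 19) {
      first <- runif(1, 120, 600); last <- runif(1, 38, first * 0.8)
    } else {
      first <- runif(1, 30, 200); last <- first * runif(1, 1.05, 1.6)
    }
    vals <- exp(seq(log(first), log(last), length.out = length(days)))
    vals[-c(1, length(vals))] <- vals[-c(1, length(vals))] *
      exp(rnorm(length(vals) - 2, 0, 0.05))
    ca_rows[[i]] <- data.frame(patient_id = id[i], day = days,
                               value = round(vals, 1),
                               bilirubin = round(runif(length(days), 0.3, 1.5), 2))
  }
  # the two patients not completing treatment: single draw, high bilirubin
  for (i in 27:28) {
    ca_rows[[i]] <- data.frame(patient_id = id[i], day = 0,
                               value = round(runif(1, 50, 300), 1),
                               bilirubin = 3.5)
  }
  ca199 <- do.call(rbind, ca_rows)

  # lesion series: 1-7 partial response (best change <= -30%), 8-21 shrink
  # without PR, 22-26 grow modestly (< +20% and < +5 mm: stable disease)
  les_rows <- list()
  for (i in 1:26) {
    base <- runif(1, 25, 45)
    best <- if (i <= 7) runif(1, -45, -31)
      else if (i <= 21) runif(1, -25, -5)
      else min(runif(1, 2, 12), 100 * 4.5 / base)
    mid <- base * (1 + best / 200)
    final <- base * (1 + best / 100)
    les_rows[[i]] <- data.frame(patient_id = id[i], day = c(0, 42, 84),
                                longest_diameter = round(c(base, mid, final), 1))
  }
  for (i in 27:28) { # no on-treatment imaging
    les_rows[[i]] <- data.frame(patient_id = id[i], day = 0,
                                longest_diameter = round(runif(1, 25, 45), 1))
  }
  lesions <- do.call(rbind, les_rows)

  # adverse events: 4 grade-4 instances (3 neutropenia, 1 hypokalemia) plus
  # low-grade background toxicity
  ae_rows <- list(
    data.frame(patient_id = id[1:3], term = "neutrophil count decreased",
               grade = 4L),
    data.frame(patient_id = id[4], term = "hypokalemia", grade = 4L))
  for (i in seq_len(n)) {
    k <- rpois(1, 1.5)
    if (k > 0) {
      ae_rows[[length(ae_rows) + 1L]] <- data.frame(
        patient_id = id[i],
        term = sample(c("nausea", "diarrhea", "fatigue", "neuropathy"), k,
                      replace = TRUE),
        grade = sample(1:2, k, replace = TRUE))
    }
  }
  aes <- do.call(rbind, ae_rows)

  # survival (months): plausible exponential times with administrative
  # censoring; not calibrated to any printed median
  surv_draw <- function(m, median_m) {
    t_ev <- rexp(m, log(2) / median_m)
    cens <- runif(m, 24, 60)
    data.frame(time = round(pmin(t_ev, cens), 1), event = t_ev <= cens)
  }
  dfs <- surv_draw(22, 20); pfs <- surv_draw(26, 26); os <- surv_draw(26, 38)
  patients <- data.frame(
    patient_id = id, enrolled = TRUE, completed_treatment = completed,
    resected = resected, cap_score = cap, margins = margins, pn_stage = pn,
    dfs_time = NA_real_, dfs_event = NA,
    pfs_time = NA_real_, pfs_event = NA,
    os_time = NA_real_, os_event = NA, stringsAsFactors = FALSE)
  patients$dfs_time[1:22] <- dfs$time; patients$dfs_event[1:22] <- dfs$event
  patients$pfs_time[1:26] <- pfs$time; patients$pfs_event[1:26] <- pfs$event
  patients$os_time[1:26] <- os$time; patients$os_event[1:26] <- os$event

  structure(list(patients = patients, ca199 = ca199, lesions = lesions,
                 aes = aes), class = "clinical_cohort")
}

#' @export
print.clinical_cohort <- function(x, ...) {
  cat(sprintf("<clinical_cohort: %d patients, %d resected, %d completed treatment>\n",
              nrow(x$patients), sum(x$patients$resected),
              sum(x$patients$completed_treatment)))
  invisible(x)
}

#' Write / read a clinical cohort as CSV files
#'
#' One wide per-patient table plus long-format companion files for the
#' CA19-9 series, lesion series and adverse events.
#'
#' @param cohort A `clinical_cohort`.
#' @param dir Directory (created if needed) holding `patients.csv`,
#'   `ca199.csv`, `lesions.csv`, `aes.csv`.
#' @return The directory (write) or a `clinical_cohort` (read).
#' @export
write_clinical_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "ca199", "lesions", "aes")) {
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_clinical_cohort
#' @export
read_clinical_cohort <- function(dir) {
  out <- lapply(c("patients", "ca199", "lesions", "aes"), function(nm) {
    utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                    stringsAsFactors = FALSE)
  })
  names(out) <- c("patients", "ca199", "lesions", "aes")
  out$patients$margins[out$patients$margins == ""] <- NA
  structure(out, class = "clinical_cohort")
}
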