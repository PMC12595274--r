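#' Resolve a final call under the borderline repeat policy
#'
#' Scores in the borderline zone trigger repeat testing. The decision
#' rules: a non-borderline primary result stands as is; a borderline
#' primary resolved by a non-borderline repeat takes the repeat's call;
#' and a borderline primary that could not be repeated, or whose repeat
#' remained borderline, is treated as MSI-high — the sensitive choice for
#' a screening test on low-tumour-content urine cfDNA.
#'
#' @param primary An `msi_score_result` with a call.
#' @param repeat_result Optional `msi_score_result` from a repeat
#'   specimen; may only be supplied when the primary result is borderline.
#' @param subject_id Optional identifier carried into the result.
#' @return An object of class `final_call` with `resolved_call`
#'   (`"MSI_H"`/`"MSS"`) and `resolution_path` (one of `clear_primary`,
#'   `repeat_confirmed`, `borderline_as_msih_no_repeat`,
#'   `borderline_as_msih_persistent`).
#' @export
resolve_call <- function(primary, repeat_result = NULL, subject_id = NULL) {
  stopifnot(inherits(primary, "msi_score_result"))
  if (is.na(primary$msi_score)) {
    stop("primary result has no call (QC failure); cannot resolve",
         call. = FALSE)
  }
  if (!primary$borderline) {
    if (!is.null(repeat_result)) {
      stop("repeat result supplied for a non-borderline primary",
           call. = FALSE)
    }
    resolved <- primary$call
    path <- "clear_primary"
  } else if (is.null(repeat_result)) {
    resolved <- "MSI_H"
    path <- "borderline_as_msih_no_repeat"
  } else {
    stopifnot(inherits(repeat_result, "msi_score_result"))
    if (is.na(repeat_result$msi_score) || repeat_result$borderline) {
      resolved <- "MSI_H"
      path <- "borderline_as_msih_persistent"
    } else {
      resolved <- repeat_result$call
      path <- "repeat_confirmed"
    }
  }
  structure(
    list(subject_id = subject_id %||% primary$sample_id,
         primary_result = primary, repeat_result = repeat_result,
         resolved_call = resolved, resolution_path = path),
    class = "final_call"
  )
}

#' @export
print.final_call <- function(x, ...) {
  cat(sprintf("<final_call> %s: %s via %s\n", x$subject_id,
              x$resolved_call, x$resolution_path))
  invisible(x)
}

#' Adjudicate a final call against the reference standard
#'
#' Positive calls are adjudicated against histological confirmation of
#' carcinoma; negative calls additionally require at least 365 days of
#' follow-up to count as true negatives, since an occult tumour may
#' surface later. Cases that cannot be adjudicated (unknown outcome, or a
#' negative with short follow-up) are `unevaluable` and excluded from
#' accuracy statistics.
#'
#' @param case A `case_record` with `outcome_cancer_within_followup`
#'   (logical or NA) and `followup_days`.
#' @param final A [resolve_call()] result for this case.
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`, `"unevaluable"`.
#' @export
adjudicate <- function(case, final) {
  stopifnot(inherits(case, "case_record"), inherits(final, "final_call"))
  outcome <- case$outcome_cancer_within_followup
  if (final$resolved_call == "MSI_H") {
    if (is.na(outcome)) return("unevaluable")
    if (outcome) "TP" else "FP"
  } else {
    if (!is.na(outcome) && outcome) return("FN")
    if (is.na(outcome) || case$followup_days < 365) return("unevaluable")
    "TN"
  }
}

#' Screen a whole cohort
#'
#' Scores every subject's primary urine sample, applies the borderline
#' repeat policy (for simulated cohorts, `repeat_policy = "simulate_repeat"`
#' draws a fresh specimen at the subject's true tumour fraction,
#' emulating re-collection), resolves final calls, adjudicates against the
#' recorded outcomes and aggregates the 2x2 contingency.
#'
#' @param cohort An `msi_cohort` (or plain list of `case_record`s).
#' @param model A trained `msi_classifier`.
#' @param repeat_policy `"simulate_repeat"` to generate a repeat specimen
#'   for borderline primaries, `"none"` to leave borderlines unrepeated
#'   (they are then called MSI-high).
#' @param panel Marker panel used to simulate repeats; defaults to the
#'   cohort's `panel` attribute.
#' @return An object of class `screening_report`: per-subject data frame
#'   (`subject_id`, `msi_score`, `call`, `borderline`, `resolved_call`,
#'   `resolution_path`, `adjudication`), the aggregate
#'   [contingency_table()], and `n_unevaluable`.
#' @export
run_screen <- function(cohort, model,
                       repeat_policy = c("simulate_repeat", "none"),
                       panel = NULL) {
  repeat_policy <- match.arg(repeat_policy)
  stopifnot(length(cohort) >= 1, inherits(model, "msi_classifier"))
  panel <- panel %||% attr(cohort, "panel") %||% default_panel()
  rows <- vector("list", length(cohort))
  adj <- character(length(cohort))
  for (i in seq_along(cohort)) {
    case <- cohort[[i]]
    urines <- Filter(function(s) s$sample_type == "urine", case$samples)
    if (!length(urines)) stop("case ", case$subject_id, " has no urine sample",
                              call. = FALSE)
    day <- vapply(urines, `[[`, integer(1), "collection_day")
    primary <- score_sample(model, urines[[which.min(day)]])
    rep_res <- NULL
    if (!is.na(primary$msi_score) && primary$borderline &&
        repeat_policy == "simulate_repeat" &&
        !is.null(case$true_tumour_fraction)) {
      rep_profile <- simulate_sample(
        panel, case$true_tumour_fraction,
        depth = urines[[which.min(day)]]$spectra[[1]]$depth,
        sample_type = "urine",
        seed = substream_seed(case$seed %||% i, 999L),
        sample_id = paste0(case$subject_id, "_urine_repeat"),
        subject_id = case$subject_id,
        marker_instability = case$marker_instability)
      rep_res <- score_sample(model, rep_profile)
    }
    final <- resolve_call(primary, rep_res, subject_id = case$subject_id)
    adj[i] <- adjudicate(case, final)
    rows[[i]] <- data.frame(
      subject_id = case$subject_id, msi_score = primary$msi_score,
      call = primary$call, borderline = primary$borderline,
      qc_pass = primary$qc_pass, resolved_call = final$resolved_call,
      resolution_path = final$resolution_path, adjudication = adj[i],
      stringsAsFactors = FALSE)
  }
  subjects <- do.call(rbind, rows)
  ct <- contingency_table(tp = sum(adj == "TP"), fp = sum(adj == "FP"),
                          fn = sum(adj == "FN"), tn = sum(adj == "TN"))
  structure(
    list(subjects = subjects, contingency = ct,
         n_unevaluable = sum(adj == "unevaluable")),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  ct <- x$contingency
  cat(sprintf(
    "<screening_report> %d subjects: TP %d, FP %d, FN %d, TN %d, unevaluable %d\n",
    nrow(x$subjects), ct$tp, ct$fp, ct$fn, ct$tn, x$n_unevaluable))
  invisible(x)
}
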