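#' Simulate an allele spectrum for one marker
#'
#' Draws `depth` reads as a multinomial over allele offsets from the
#' two-component mixture returned by [spectrum_pmf()]: background stutter
#' around the reference allele with weight `1 - tumour_fraction`, and the
#' unstable deletion-shifted allele with weight `tumour_fraction`.
#'
#' @param marker A [marker_def()].
#' @param tumour_fraction Fraction of reads originating from tumour DNA,
#'   in `[0, 1]`.
#' @param depth Number of reads to draw (> 0).
#' @param seed Optional integer; when supplied the draw is reproducible and
#'   the global RNG state is left untouched.
#' @param instability Per-marker scaling of the tumour fraction in
#'   `[0, 1]`; models markers where only part of the tumour-derived
#'   molecules carry the unstable allele (subclonal instability). The
#'   effective mixture weight is `tumour_fraction * instability`.
#' @return An [allele_spectrum()] whose counts sum to `depth`.
#' @export
#' @examples
#' m <- default_panel()[["AKMmono02"]]
#' simulate_spectrum(m, tumour_fraction = 0.3, depth = 2000, seed = 1)
simulate_spectrum <- function(marker, tumour_fraction, depth, seed = NULL,
                              instability = 1) {
  stopifnot(inherits(marker, "marker_def"))
  if (length(depth) != 1L || is.na(depth) || depth <= 0) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  if (length(tumour_fraction) != 1L || is.na(tumour_fraction) ||
      tumour_fraction < 0 || tumour_fraction > 1) {
    stop("tumour_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(instability >= 0, instability <= 1)
  pmf <- spectrum_pmf(marker, tumour_fraction * instability)
  counts <- with_seed(seed, as.vector(rmultinom(1, size = depth, prob = pmf$prob)))
  keep <- counts > 0
  allele_spectrum(marker$marker_id, pmf$offset[keep], counts[keep])
}

#' Simulate a biospecimen across a marker panel
#'
#' One independent spectrum per panel marker, with per-marker substream
#' seeds derived from `seed` so the profile is reproducible and
#' marker-order independent.
#'
#' @param panel A list of [marker_def()] objects with distinct ids.
#' @param tumour_fraction Tumour DNA fraction of the specimen, in `[0, 1]`.
#' @param depth Reads per marker.
#' @param sample_type One of `"urine"`, `"tumour"`, `"plasma"`, `"blood"`.
#' @param seed Integer master seed.
#' @param sample_id,subject_id Identifiers; `subject_id` defaults to
#'   `sample_id`.
#' @param collection_day Integer day relative to the subject's first urine
#'   sample (day 0).
#' @param marker_instability Optional named numeric vector (one entry per
#'   marker id) of per-marker instability fractions shared by all samples
#'   of one tumour; defaults to 1 for every marker.
#' @return An object of class `sample_profile`.
#' @export
simulate_sample <- function(panel, tumour_fraction, depth = 2000,
                            sample_type = c("urine", "tumour", "plasma", "blood"),
                            seed = NULL, sample_id = "S1",
                            subject_id = sample_id, collection_day = 0L,
                            marker_instability = NULL) {
  validate_panel(panel)
  sample_type <- match.arg(sample_type)
  ids <- panel_ids(panel)
  if (is.null(marker_instability)) {
    marker_instability <- setNames(rep(1, length(ids)), ids)
  }
  stopifnot(all(ids %in% names(marker_instability)))
  spectra <- lapply(seq_along(panel), function(i) {
    sub <- if (is.null(seed)) NULL else substream_seed(seed, i)
    simulate_spectrum(panel[[i]], tumour_fraction, depth, seed = sub,
                      instability = marker_instability[[ids[i]]])
  })
  names(spectra) <- ids
  structure(
    list(sample_id = sample_id, subject_id = subject_id,
         sample_type = sample_type, collection_day = as.integer(collection_day),
         spectra = spectra, true_tumour_fraction = tumour_fraction),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "<sample_profile> %s (%s, subject %s, day %d): %d markers%s\n",
    x$sample_id, x$sample_type, x$subject_id, x$collection_day,
    length(x$spectra),
    if (!is.null(x$true_tumour_fraction))
      sprintf(", true tumour fraction %.3g", x$true_tumour_fraction) else ""))
  invisible(x)
}

#' Configure a simulated cohort
#'
#' Two study designs are supported. `"symptomatic_utuc"` draws subjects
#' who each contribute a paired pre-operative urine and tumour specimen
#' (plus a blood cfDNA background specimen), with mismatch-repair-deficient
#' (MMRd) disease occurring at `mmrd_prevalence`. `"lynch_screening"` draws
#' asymptomatic carriers contributing a urine specimen, each harbouring an
#' occult urothelial carcinoma with probability
#' `1 - (1 - annual_incidence)^lead_time_years`.
#'
#' @param n_subjects Number of subjects (> 0).
#' @param design `"symptomatic_utuc"` or `"lynch_screening"`.
#' @param mmrd_prevalence MMRd prevalence (symptomatic design only).
#' @param annual_incidence,lead_time_years Annual carcinoma incidence and
#'   screening lead time in years (screening design only).
#' @param urine_tf_range Range of the log-uniform urine cfDNA tumour
#'   fraction for affected subjects.
#' @param tissue_tf_range Range of the uniform tumour-tissue tumour
#'   fraction.
#' @param depth_per_marker Reads per marker.
#' @param followup_days Follow-up recorded on every case; negatives are
#'   adjudicable only when this is at least 365.
#' @param fixed_n_affected Optional integer: condition the simulation on
#'   exactly this many affected subjects (positions chosen at random),
#'   e.g. to mirror an observed study outcome.
#' @param panel Marker panel; defaults to [default_panel()].
#' @param seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          design = c("symptomatic_utuc", "lynch_screening"),
                          mmrd_prevalence = NULL,
                          annual_incidence = NULL, lead_time_years = NULL,
                          urine_tf_range = c(0.01, 0.5),
                          tissue_tf_range = c(0.4, 0.9),
                          depth_per_marker = 2000,
                          followup_days = 567L,
                          fixed_n_affected = NULL,
                          panel = default_panel(),
                          seed = 1L) {
  design <- match.arg(design)
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects <= 0) {
    stop("n_subjects must be a positive integer", call. = FALSE)
  }
  if (design == "symptomatic_utuc") {
    if (is.null(mmrd_prevalence) || !is.null(annual_incidence) ||
        !is.null(lead_time_years)) {
      stop("symptomatic_utuc design requires mmrd_prevalence and no ",
           "incidence/lead-time parameters", call. = FALSE)
    }
    stopifnot(mmrd_prevalence >= 0, mmrd_prevalence <= 1)
  } else {
    if (!is.null(mmrd_prevalence) || is.null(annual_incidence) ||
        is.null(lead_time_years)) {
      stop("lynch_screening design requires annual_incidence and ",
           "lead_time_years and no mmrd_prevalence", call. = FALSE)
    }
    stopifnot(annual_incidence >= 0, annual_incidence <= 1,
              lead_time_years >= 0)
  }
  if (!is.null(fixed_n_affected)) {
    stopifnot(fixed_n_affected >= 0, fixed_n_affected <= n_subjects)
  }
  validate_panel(panel)
  structure(
    list(n_subjects = as.integer(n_subjects), design = design,
         mmrd_prevalence = mmrd_prevalence,
         annual_incidence = annual_incidence,
         lead_time_years = lead_time_years,
         urine_tf_range = urine_tf_range, tissue_tf_range = tissue_tf_range,
         depth_per_marker = depth_per_marker,
         followup_days = as.integer(followup_days),
         fixed_n_affected = fixed_n_affected,
         panel = panel, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# probability that one subject is affected under the config's design
affected_probability <- function(config) {
  if (config$design == "symptomatic_utuc") config$mmrd_prevalence
  else 1 - (1 - config$annual_incidence)^config$lead_time_years
}

rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Simulate a cohort of case records
#'
#' Draws disease status, tumour fractions, per-marker instability patterns
#' and specimen spectra for every subject under a [cohort_config()]. All
#' randomness flows from the config seed through per-subject substreams,
#' so identical configs reproduce identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A list of `case_record` objects (class `msi_cohort`) with the
#'   marker panel attached as attribute `panel`. Each record holds the
#'   subject's samples, `truth_mmrd_cancer`,
#'   `outcome_cancer_within_followup`, `followup_days`, the urine
#'   `true_tumour_fraction` and the shared `marker_instability` vector.
#' @export
#' @examples
#' cfg <- cohort_config(10, "lynch_screening", annual_incidence = 0.0075,
#'                      lead_time_years = 4, depth_per_marker = 200, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' sum(vapply(cohort, `[[`, logical(1), "truth_mmrd_cancer"))
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  p_aff <- affected_probability(config)
  affected <- with_seed(substream_seed(config$seed, 0L), {
    if (is.null(config$fixed_n_affected)) {
      runif(n) < p_aff
    } else {
      idx <- sample.int(n, config$fixed_n_affected)
      seq_len(n) %in% idx
    }
  })
  ids <- panel_ids(config$panel)
  cases <- lapply(seq_len(n), function(i) {
    subject_id <- sprintf("subj%03d", i)
    sseed <- substream_seed(config$seed, i)
    draws <- with_seed(substream_seed(sseed, 1L), list(
      urine_tf = rlogunif(1, config$urine_tf_range[1], config$urine_tf_range[2]),
      tissue_tf = runif(1, config$tissue_tf_range[1], config$tissue_tf_range[2]),
      instability = setNames(runif(length(ids), 0.3, 1), ids)
    ))
    aff <- affected[i]
    urine_tf <- if (aff) draws$urine_tf else 0
    instab <- if (aff) draws$instability else setNames(rep(1, length(ids)), ids)
    samples <- list(
      simulate_sample(config$panel, urine_tf, config$depth_per_marker,
                      "urine", seed = substream_seed(sseed, 2L),
                      sample_id = paste0(subject_id, "_urine"),
                      subject_id = subject_id, collection_day = 0L,
                      marker_instability = instab)
    )
    if (config$design == "symptomatic_utuc") {
      tissue_tf <- if (aff) draws$tissue_tf else 0
      samples <- c(samples, list(
        simulate_sample(config$panel, tissue_tf, config$depth_per_marker,
                        "tumour", seed = substream_seed(sseed, 3L),
                        sample_id = paste0(subject_id, "_tumour"),
                        subject_id = subject_id, collection_day = 0L,
                        marker_instability = instab),
        simulate_sample(config$panel, 0, config$depth_per_marker,
                        "blood", seed = substream_seed(sseed, 4L),
                        sample_id = paste0(subject_id, "_blood"),
                        subject_id = subject_id, collection_day = 0L)
      ))
    }
    structure(
      list(subject_id = subject_id,
           cohort = if (config$design == "symptomatic_utuc") "utuc" else "lynch",
           samples = samples,
           truth_mmrd_cancer = aff,
           outcome_cancer_within_followup = aff,
           followup_days = config$followup_days,
           true_tumour_fraction = urine_tf,
           marker_instability = instab,
           seed = sseed),
      class = "case_record"
    )
  })
  structure(cases, class = "msi_cohort", panel = config$panel)
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf(
    "<case_record> %s (%s cohort): %d sample(s), MMRd cancer: %s, urine tf %.3g\n",
    x$subject_id, x$cohort, length(x$samples), x$truth_mmrd_cancer,
    x$true_tumour_fraction))
  invisible(x)
}

#' @export
print.msi_cohort <- function(x, ...) {
  aff <- sum(vapply(x, `[[`, logical(1), "truth_mmrd_cancer"))
  cat(sprintf("<msi_cohort> %d subjects (%s design), %d affected\n",
              length(x), x[[1]]$cohort, aff))
  invisible(x)
}

#' Simulate a longitudinal sampling trajectory for one case
#'
#' Generates urine profiles at the requested days, with the tumour
#' fraction evolving through clinical events: after a `resection` or
#' `ablation` the urine tumour fraction drops to zero, and after a
#' `recurrence` it returns to the case's original fraction.
#'
#' @param case A `case_record` from [simulate_cohort()].
#' @param events Data frame with columns `day` (integer, sorted ascending)
#'   and `event` (`"resection"`, `"recurrence"` or `"ablation"`); may have
#'   zero rows.
#' @param sample_days Integer vector of days at which urine samples are
#'   drawn (day 0 = first urine).
#' @param depth Reads per marker.
#' @param panel Marker panel (defaults to [default_panel()]).
#' @return A list of `sample_profile` objects, one per sampling day.
#' @export
simulate_longitudinal <- function(case, events, sample_days, depth = 2000,
                                  panel = default_panel()) {
  stopifnot(inherits(case, "case_record"))
  if (nrow(events) > 0) {
    stopifnot(all(events$event %in% c("resection", "recurrence", "ablation")))
    if (is.unsorted(events$day)) {
      stop("events must be sorted by day", call. = FALSE)
    }
  }
  tf_at <- function(day) {
    tf <- case$true_tumour_fraction
    if (nrow(events) > 0) {
      for (j in seq_len(nrow(events))) {
        if (events$day[j] > day) break
        tf <- if (events$event[j] == "recurrence") case$true_tumour_fraction else 0
      }
    }
    tf
  }
  lapply(sample_days, function(day) {
    simulate_sample(panel, tf_at(day), depth, "urine",
                    seed = substream_seed(case$seed, 100L, day),
                    sample_id = sprintf("%s_d%d", case$subject_id, day),
                    subject_id = case$subject_id, collection_day = day,
                    marker_instability = case$marker_instability)
  })
}
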