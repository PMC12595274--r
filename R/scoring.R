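#' Train the naive Bayesian MSI classifier
#'
#' For every panel marker, fits class-conditional beta densities to the
#' per-sample variant allele frequencies (VAFs) observed under the MSI-high
#' and microsatellite-stable training classes, by the method of moments
#' with pseudocount smoothing. At scoring time each marker contributes
#' `log10` of the ratio of these densities at the observed VAF; the marker
#' contributions are summed (naive independence across markers) and the
#' sum is multiplied by `score_scale`, calibrated so that the 1st-99th
#' percentile of training-set scores spans approximately the reporting
#' range `[-25, +30]`.
#'
#' @param profiles List of `sample_profile` objects.
#' @param labels Character vector (same length), each `"MSI_H"` or `"MSS"`;
#'   both classes must be present with at least two samples each.
#' @param pseudocount Density-ratio floor: a single marker's log10 ratio
#'   is bounded at `-log10(pseudocount)` in either direction, keeping
#'   every marker contribution finite at boundary VAFs.
#' @param qc_min_depth Minimum reads for a marker to contribute evidence.
#' @param qc_min_markers Minimum contributing markers for a sample-level
#'   QC pass.
#' @param score_range Target reporting range for the score calibration.
#' @return An object of class `msi_classifier`.
#' @seealso [score_sample()], [marker_log_ratio()]
#' @export
train_classifier <- function(profiles, labels, pseudocount = 1e-6,
                             qc_min_depth = 100, qc_min_markers = 10,
                             score_range = c(-25, 30)) {
  stopifnot(length(profiles) == length(labels), length(profiles) >= 4)
  labels <- as.character(labels)
  if (!all(labels %in% c("MSI_H", "MSS"))) {
    stop("labels must be 'MSI_H' or 'MSS'", call. = FALSE)
  }
  if (sum(labels == "MSI_H") < 2 || sum(labels == "MSS") < 2) {
    stop("need at least two training samples per class", call. = FALSE)
  }
  marker_ids <- names(profiles[[1]]$spectra)
  markers <- list()
  for (mid in marker_ids) {
    vafs <- vapply(profiles, function(p) {
      sp <- p$spectra[[mid]]
      if (is.null(sp) || sp$depth < qc_min_depth) NA_real_
      else variant_allele_frequency(sp)
    }, numeric(1))
    v1 <- vafs[labels == "MSI_H" & !is.na(vafs)]
    v0 <- vafs[labels == "MSS" & !is.na(vafs)]
    if (length(v1) < 2 || length(v0) < 2) {
      warning("marker ", mid, " dropped: fewer than two passing samples ",
              "in a class", call. = FALSE)
      next
    }
    dens <- fit_class_densities(v1, v0)
    markers[[mid]] <- list(
      marker_id = mid,
      msih = dens$msih,
      mss = dens$mss,
      pseudocount = pseudocount
    )
  }
  if (!length(markers)) stop("no marker could be fitted", call. = FALSE)
  model <- structure(
    list(markers = markers, score_scale = 1,
         qc_min_depth = qc_min_depth, qc_min_markers = qc_min_markers,
         borderline_range = c(-5, 5), score_range = score_range),
    class = "msi_classifier"
  )
  raw <- vapply(profiles, function(p) score_sample(model, p)$msi_score,
                numeric(1))
  raw <- raw[is.finite(raw)]
  q <- quantile(raw, c(0.01, 0.99), names = FALSE, type = 7)
  cand <- c(if (q[1] < 0) score_range[1] / q[1],
            if (q[2] > 0) score_range[2] / q[2])
  model$score_scale <- if (length(cand)) min(cand) else 1
  model
}

# Method-of-moments estimates on [0,1], guarded for degenerate samples:
# values are pulled off the boundary and the variance is floored so the
# implied beta concentration stays finite.
beta_moments <- function(x, eps = 1e-4, min_var = 1e-7) {
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x)
  v <- max(var(x), min_var)
  v <- min(v, 0.999 * m * (1 - m))
  list(mean = m, concentration = m * (1 - m) / v - 1)
}

# Class-conditional beta pair with class-specific means and a pooled
# concentration. Pooling makes the log likelihood ratio monotone in the
# VAF whenever the MSI-H mean exceeds the MSS mean: log LR is then linear
# in logit(VAF) with positive slope, so more instability never reads as
# evidence *against* MSI — which class-specific dispersions do not
# guarantee (a tight MSS fit sends the ratio back down past the MSI-H
# mode). The smaller of the two class concentrations is used: the MSI-H
# spread is dominated by biology (tumour fraction), the MSS spread by
# sampling noise at one depth, and the wider class sets how sharply a VAF
# can be scored.
fit_class_densities <- function(v_msih, v_mss) {
  mh <- beta_moments(v_msih)
  ms <- beta_moments(v_mss)
  conc <- min(mh$concentration, ms$concentration)
  list(
    msih = list(shape1 = mh$mean * conc, shape2 = (1 - mh$mean) * conc,
                mean = mh$mean),
    mss = list(shape1 = ms$mean * conc, shape2 = (1 - ms$mean) * conc,
               mean = ms$mean)
  )
}

#' Per-marker instability log-likelihood ratio
#'
#' `log10` of the MSI-high class density over the MSS class density at the
#' observed VAF. The ratio is evaluated in log space (so extreme VAFs do
#' not underflow) and bounded by the model pseudocount: a single marker can
#' contribute at most `-log10(pseudocount)` in either direction, keeping
#' every log ratio finite at boundary VAFs.
#'
#' @param marker_model One element of an `msi_classifier`'s `markers` list.
#' @param vaf Variant allele frequency in `[0, 1]` (vectorised).
#' @return Signed log10 likelihood ratio; positive favours MSI-high.
#' @export
marker_log_ratio <- function(marker_model, vaf) {
  stopifnot(all(vaf >= 0), all(vaf <= 1))
  v <- pmin(pmax(vaf, 1e-6), 1 - 1e-6)
  lr <- (ldbeta(v, marker_model$msih$shape1, marker_model$msih$shape2) -
           ldbeta(v, marker_model$mss$shape1, marker_model$mss$shape2)) /
    log(10)
  cap <- -log10(marker_model$pseudocount)
  pmin(pmax(lr, -cap), cap)
}

# log beta density, stable for large shapes
ldbeta <- function(v, a, b) (a - 1) * log(v) + (b - 1) * log1p(-v) - lbeta(a, b)

#' Classify an MSI score
#'
#' Scores at or above zero are called MSI-high, below zero microsatellite
#' stable; zero itself is called MSI-high (the sensitive tie-break for a
#' screening test — and zero lies inside the borderline zone, so the call
#' triggers repeat testing regardless). Scores within the closed interval
#' `[-5, +5]` are flagged borderline.
#'
#' @param msi_score Finite numeric score on the reporting scale.
#' @param borderline_range Closed borderline interval, default `c(-5, 5)`.
#' @return A list with elements `call` (`"MSI_H"` or `"MSS"`) and
#'   `borderline` (logical).
#' @export
#' @examples
#' classify(12.3)
#' classify(-4.99)
classify <- function(msi_score, borderline_range = c(-5, 5)) {
  if (length(msi_score) != 1L || !is.finite(msi_score)) {
    stop("msi_score must be a single finite number", call. = FALSE)
  }
  list(
    call = if (msi_score >= 0) "MSI_H" else "MSS",
    borderline = msi_score >= borderline_range[1] &&
      msi_score <= borderline_range[2]
  )
}

#' Score a sample with a trained classifier
#'
#' Computes the per-marker VAFs of the profile, excludes markers below the
#' depth QC threshold, sums the per-marker log ratios and scales the sum to
#' the reporting scale. The sample-level QC flag is false when fewer than
#' `qc_min_markers` markers contributed; with zero usable markers no call
#' is made.
#'
#' @param model An `msi_classifier` from [train_classifier()].
#' @param profile A `sample_profile`.
#' @return An object of class `msi_score_result` with the per-marker log
#'   ratios, the scaled `msi_score`, `call`, `borderline`, `qc_pass` and
#'   `markers_used`.
#' @export
score_sample <- function(model, profile) {
  stopifnot(inherits(model, "msi_classifier"),
            inherits(profile, "sample_profile"))
  shared <- intersect(names(model$markers), names(profile$spectra))
  if (!length(shared)) {
    stop("profile shares no markers with the model", call. = FALSE)
  }
  lrs <- numeric(0)
  for (mid in shared) {
    sp <- profile$spectra[[mid]]
    if (sp$depth < model$qc_min_depth) next
    vaf <- variant_allele_frequency(sp)
    if (is.na(vaf)) next
    lrs[mid] <- marker_log_ratio(model$markers[[mid]], vaf)
  }
  markers_used <- length(lrs)
  if (markers_used == 0L) {
    res <- list(sample_id = profile$sample_id, per_marker_log_ratio = lrs,
                msi_score = NA_real_, call = NA_character_, borderline = NA,
                qc_pass = FALSE, markers_used = 0L)
    return(structure(res, class = "msi_score_result"))
  }
  score <- model$score_scale * sum(lrs)
  cl <- classify(score, model$borderline_range)
  structure(
    list(sample_id = profile$sample_id, per_marker_log_ratio = lrs,
         msi_score = score, call = cl$call, borderline = cl$borderline,
         qc_pass = markers_used >= model$qc_min_markers,
         markers_used = markers_used),
    class = "msi_score_result"
  )
}

#' @export
print.msi_score_result <- function(x, ...) {
  if (is.na(x$msi_score)) {
    cat(sprintf("<msi_score_result> %s: QC FAILURE, no call (0 markers)\n",
                x$sample_id))
  } else {
    cat(sprintf(
      "<msi_score_result> %s: score %.2f -> %s%s (markers %d, QC %s)\n",
      x$sample_id, x$msi_score, x$call,
      if (x$borderline) " [borderline]" else "", x$markers_used,
      if (x$qc_pass) "pass" else "FAIL"))
  }
  invisible(x)
}

#' @export
print.msi_classifier <- function(x, ...) {
  cat(sprintf(
    "<msi_classifier> %d markers, score_scale %.4g, QC: depth >= %d, markers >= %d\n",
    length(x$markers), x$score_scale, x$qc_min_depth, x$qc_min_markers))
  invisible(x)
}
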