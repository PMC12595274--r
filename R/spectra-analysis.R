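#' Background-normalise an allele spectrum
#'
#' Subtracts, per allele offset, the reference sample's allele frequency
#' from the sample's allele frequency, over the union of offsets observed
#' in either spectrum (an offset absent from one spectrum contributes
#' frequency 0). The reference is typically a matched blood cfDNA
#' specimen, taken to represent background amplification and sequencing
#' error rather than tumour signal. Negative deltas are preserved, never
#' truncated; the deltas sum to zero because both frequency vectors sum
#' to one.
#'
#' @param sample,reference [allele_spectrum()] objects for the same
#'   marker, both with positive depth.
#' @return An object of class `normalized_spectrum`: a data frame with
#'   columns `offset` and `delta_frequency`, with the marker id as
#'   attribute `marker_id`.
#' @export
#' @examples
#' s <- allele_spectrum("m", c(0L, -4L), c(50, 50))
#' r <- allele_spectrum("m", 0L, 100)
#' normalize_spectrum(s, r)
normalize_spectrum <- function(sample, reference) {
  stopifnot(inherits(sample, "allele_spectrum"),
            inherits(reference, "allele_spectrum"))
  if (sample$marker_id != reference$marker_id) {
    stop("marker mismatch: ", sample$marker_id, " vs ", reference$marker_id,
         call. = FALSE)
  }
  if (sample$depth <= 0 || reference$depth <= 0) {
    stop("both spectra must have positive depth", call. = FALSE)
  }
  offs <- sort(union(sample$offsets, reference$offsets))
  fs <- setNames(rep(0, length(offs)), offs)
  fr <- fs
  fs[as.character(sample$offsets)] <- sample$counts / sample$depth
  fr[as.character(reference$offsets)] <- reference$counts / reference$depth
  structure(
    data.frame(offset = offs, delta_frequency = unname(fs - fr)),
    marker_id = sample$marker_id,
    class = c("normalized_spectrum", "data.frame")
  )
}

# Per-marker VAFs of a profile as a named vector; markers under the depth
# threshold are NA. When a matched reference profile is given, its VAF is
# subtracted marker-wise (background-corrected VAF).
profile_vafs <- function(profile, qc_min_depth = 0, reference = NULL) {
  v <- vapply(profile$spectra, function(sp) {
    if (sp$depth < max(qc_min_depth, 1)) NA_real_
    else variant_allele_frequency(sp)
  }, numeric(1))
  if (!is.null(reference)) {
    rv <- profile_vafs(reference, qc_min_depth)
    shared <- intersect(names(v), names(rv))
    v[shared] <- v[shared] - rv[shared]
  }
  v
}

#' Cross-sample VAF concordance for tumour source attribution
#'
#' Correlates the per-marker variant allele frequencies of two profiles
#' across their shared markers. A urine MSI signal that originates from a
#' particular tumour shows the tumour's marker-wise instability pattern,
#' so the paired VAFs correlate strongly; profiles from unrelated tumours
#' do not. When matched background profiles (blood or plasma cfDNA) are
#' supplied, VAFs are background-corrected first, removing the shared
#' stutter floor that would otherwise inflate the correlation between
#' unrelated samples.
#'
#' @param profile_a,profile_b `sample_profile` objects.
#' @param reference_a,reference_b Optional matched background profiles.
#' @param method `"pearson"` (product-moment, default) or `"spearman"`
#'   (rank-based, robust option).
#' @param qc_min_depth Minimum per-marker depth in both profiles.
#' @return An object of class `concordance_result` with the sample pair,
#'   the per-marker VAF pairs, the correlation (NA with a `reason` when
#'   fewer than 3 shared markers pass QC or either VAF vector is
#'   constant) and `n_markers`.
#' @export
vaf_concordance <- function(profile_a, profile_b,
                            reference_a = NULL, reference_b = NULL,
                            method = c("pearson", "spearman"),
                            qc_min_depth = 100) {
  method <- match.arg(method)
  stopifnot(inherits(profile_a, "sample_profile"),
            inherits(profile_b, "sample_profile"))
  va <- profile_vafs(profile_a, qc_min_depth, reference_a)
  vb <- profile_vafs(profile_b, qc_min_depth, reference_b)
  shared <- intersect(names(va)[!is.na(va)], names(vb)[!is.na(vb)])
  pairs <- data.frame(marker_id = shared,
                      vaf_a = unname(va[shared]), vaf_b = unname(vb[shared]))
  res <- list(sample_pair = c(profile_a$sample_id, profile_b$sample_id),
              per_marker_vaf_pairs = pairs, correlation = NA_real_,
              n_markers = length(shared), method = method, reason = NULL)
  if (length(shared) < 3) {
    res$reason <- "fewer than 3 shared markers passing QC"
  } else if (sd(pairs$vaf_a) == 0 || sd(pairs$vaf_b) == 0) {
    res$reason <- "constant VAF vector"
  } else {
    res$correlation <- cor(pairs$vaf_a, pairs$vaf_b, method = method)
  }
  structure(res, class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  if (is.na(x$correlation)) {
    cat(sprintf("<concordance_result> %s vs %s: undefined (%s)\n",
                x$sample_pair[1], x$sample_pair[2], x$reason))
  } else {
    cat(sprintf("<concordance_result> %s vs %s: r = %.3f (%s, %d markers)\n",
                x$sample_pair[1], x$sample_pair[2], x$correlation,
                x$method, x$n_markers))
  }
  invisible(x)
}

#' Small-multiples plot of normalised allele spectra
#'
#' Bar panels of delta allele frequency by offset, markers as columns and
#' samples as rows, with the reference allele marked at offset zero.
#' Requires ggplot2.
#'
#' @param normalized Named list (by sample) of named lists (by marker) of
#'   `normalized_spectrum` objects, e.g. built with [normalize_spectrum()]
#'   over a profile's spectra.
#' @return A ggplot object.
#' @export
plot_normalized_spectra <- function(normalized) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_normalized_spectra requires the ggplot2 package",
         call. = FALSE)
  }
  rows <- list()
  for (s in names(normalized)) {
    for (m in names(normalized[[s]])) {
      ns <- normalized[[s]][[m]]
      rows[[paste(s, m)]] <- data.frame(sample = s, marker = m,
                                        offset = ns$offset,
                                        delta = ns$delta_frequency)
    }
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = offset, y = delta)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.3) +
    ggplot2::facet_grid(sample ~ marker) +
    ggplot2::labs(x = "allele length offset (nt)",
                  y = "normalised allele frequency")
}
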