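#' Construct an allele-length spectrum
#'
#' The atomic evidence unit of the assay: a histogram of read counts over
#' allele-length offsets for one marker in one sample. Offsets are signed
#' nucleotide differences from the reference repeat length (0 = reference,
#' negative = deletion, positive = insertion).
#'
#' @param marker_id Character scalar naming the marker.
#' @param offsets Integer vector of allele offsets (distinct).
#' @param counts Non-negative integer vector of read counts, same length as
#'   `offsets`.
#' @return An object of class `allele_spectrum` with elements `marker_id`,
#'   `offsets`, `counts` and `depth` (the total read count).
#' @export
#' @examples
#' sp <- allele_spectrum("AKMmono02", c(-4L, 0L), c(100L, 900L))
#' variant_allele_frequency(sp)
allele_spectrum <- function(marker_id, offsets, counts) {
  stopifnot(
    is.character(marker_id), length(marker_id) == 1L,
    length(offsets) == length(counts)
  )
  offsets <- as.integer(offsets)
  counts <- as.numeric(counts)
  if (anyNA(offsets) || anyNA(counts)) {
    stop("offsets and counts must not contain NA", call. = FALSE)
  }
  if (any(counts < 0)) stop("read counts must be non-negative", call. = FALSE)
  if (anyDuplicated(offsets)) stop("duplicate allele offsets", call. = FALSE)
  ord <- order(offsets)
  structure(
    list(marker_id = marker_id, offsets = offsets[ord], counts = counts[ord],
         depth = sum(counts)),
    class = "allele_spectrum"
  )
}

#' @export
print.allele_spectrum <- function(x, ...) {
  cat(sprintf("<allele_spectrum> %s, depth %d\n", x$marker_id,
              as.integer(x$depth)))
  print(setNames(as.integer(x$counts), x$offsets))
  invisible(x)
}

# Per-offset read frequencies; NULL when the spectrum is empty.
spectrum_frequencies <- function(spectrum) {
  if (spectrum$depth <= 0) return(NULL)
  setNames(spectrum$counts / spectrum$depth, spectrum$offsets)
}

#' Variant allele frequency of a spectrum
#'
#' The total frequency of non-reference alleles: one minus the fraction of
#' reads at offset 0. This is the per-marker evidence summary fed to the
#' naive Bayes classifier.
#'
#' @param spectrum An [allele_spectrum()].
#' @return A fraction in `[0, 1]`, or `NA_real_` (with a warning) when the
#'   spectrum has zero depth and the marker must be excluded by QC.
#' @export
variant_allele_frequency <- function(spectrum) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  if (spectrum$depth <= 0) {
    warning("zero-depth spectrum for marker ", spectrum$marker_id,
            "; VAF undefined", call. = FALSE)
    return(NA_real_)
  }
  ref <- spectrum$counts[spectrum$offsets == 0L]
  ref <- if (length(ref)) ref else 0
  1 - ref / spectrum$depth
}

#' Analytic allele-offset distribution of the mixture model
#'
#' The generative model behind [simulate_spectrum()]: reads are a two
#' component mixture over allele offsets. With weight `1 - tumour_fraction`
#' a read is background — the reference allele blurred by PCR stutter,
#' modelled as a geometric number of 1-nt slippage steps with
#' deletion:insertion odds 3:1 (mononucleotide stutter is empirically
#' deletion-dominated). With weight `tumour_fraction` the read carries the
#' unstable somatic allele — a deletion of discretised-normal size
#' (`mmrd_deletion_mean`, `mmrd_deletion_sd`) convolved with the same
#' stutter kernel.
#'
#' @param marker A [marker_def()].
#' @param tumour_fraction Mixture weight of the unstable component, in
#'   `[0, 1]`.
#' @param max_step Stutter steps beyond which geometric mass is truncated
#'   (renormalised).
#' @return A data frame with columns `offset` (integer) and `prob`, summing
#'   to 1.
#' @export
#' @examples
#' pmf <- spectrum_pmf(default_panel()[[1]], tumour_fraction = 0.3)
#' sum(pmf$prob)
spectrum_pmf <- function(marker, tumour_fraction, max_step = 8L) {
  stopifnot(inherits(marker, "marker_def"),
            tumour_fraction >= 0, tumour_fraction <= 1)
  comp <- spectrum_components(marker, max_step)
  p <- (1 - tumour_fraction) * comp$bg + tumour_fraction * comp$tum
  data.frame(offset = comp$offset, prob = p / sum(p))
}

# tumour-fraction-independent mixture components, cached per marker
.component_cache <- new.env(parent = emptyenv())

spectrum_components <- function(marker, max_step = 8L) {
  key <- paste(marker$marker_id, marker$stutter_rate,
               marker$mmrd_deletion_mean, marker$mmrd_deletion_sd, max_step,
               sep = "|")
  hit <- .component_cache[[key]]
  if (!is.null(hit)) return(hit)

  s <- marker$stutter_rate
  # geometric step-count pmf, truncated and renormalised
  k <- 0:max_step
  pk <- (1 - s) * s^k
  pk <- pk / sum(pk)
  # stutter kernel over offsets: 0 keeps p(0); step k>0 deletes w.p. 3/4
  kern_off <- c(0L, -(1:max_step), 1:max_step)
  kern_p <- c(pk[1], 0.75 * pk[-1], 0.25 * pk[-1])

  bg <- tapply(kern_p, kern_off, sum)

  # unstable component: deletion size ~ discretised normal, floored at 1 nt
  mu <- marker$mmrd_deletion_mean
  sdv <- marker$mmrd_deletion_sd
  if (sdv < 1e-9) {
    del <- max(1L, as.integer(round(mu)))
    wdel <- setNames(1, del)
  } else {
    dmax <- max(1L, as.integer(ceiling(mu + 4 * sdv)))
    dsz <- 1:dmax
    w <- dnorm(dsz, mean = mu, sd = sdv)
    wdel <- setNames(w / sum(w), dsz)
  }
  # convolve the point-deletion distribution with the stutter kernel
  tum_off <- as.vector(outer(-as.integer(names(wdel)), kern_off, `+`))
  tum_p <- as.vector(outer(as.numeric(wdel), kern_p, `*`))
  tum <- tapply(tum_p, tum_off, sum)

  all_off <- sort(unique(c(as.integer(names(bg)), as.integer(names(tum)))))
  out <- list(
    offset = all_off,
    bg = unname(bg[as.character(all_off)]) %na0% 0,
    tum = unname(tum[as.character(all_off)]) %na0% 0
  )
  .component_cache[[key]] <- out
  out
}

# elementwise NA -> replacement
`%na0%` <- function(x, repl) {
  x[is.na(x)] <- repl
  x
}
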