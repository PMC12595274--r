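#' Define a mononucleotide-repeat MSI marker
#'
#' A marker is an amplicon over a homopolymer run. Alleles are reported as
#' signed length offsets in nucleotides relative to the reference repeat
#' length (0 = reference, negative = deletion, positive = insertion).
#'
#' @param marker_id Character scalar, unique within a panel.
#' @param reference_repeat_length Reference homopolymer length in
#'   nucleotides (> 0).
#' @param stutter_rate Per-read probability parameter of the geometric
#'   slippage-step distribution modelling PCR/sequencing stutter; must lie
#'   in `[0, 0.5)`.
#' @param mmrd_deletion_mean Mean somatic deletion size (nucleotides, > 0)
#'   of the unstable allele carried by mismatch-repair-deficient tumour DNA.
#' @param mmrd_deletion_sd Standard deviation of the somatic deletion size;
#'   0 gives a fixed deletion of `round(mmrd_deletion_mean)`.
#'
#' @return An object of class `marker_def`.
#' @seealso [default_panel()], [simulate_spectrum()]
#' @export
#' @examples
#' marker_def("AKMmono02", 24, stutter_rate = 0.1)
marker_def <- function(marker_id, reference_repeat_length,
                       stutter_rate = 0.1,
                       mmrd_deletion_mean = 4,
                       mmrd_deletion_sd = 1.5) {
  stopifnot(
    is.character(marker_id), length(marker_id) == 1L, nzchar(marker_id),
    length(reference_repeat_length) == 1L, reference_repeat_length > 0,
    length(stutter_rate) == 1L, stutter_rate >= 0, stutter_rate < 0.5,
    length(mmrd_deletion_mean) == 1L, mmrd_deletion_mean > 0,
    length(mmrd_deletion_sd) == 1L, mmrd_deletion_sd >= 0
  )
  structure(
    list(
      marker_id = marker_id,
      reference_repeat_length = as.integer(reference_repeat_length),
      stutter_rate = stutter_rate,
      mmrd_deletion_mean = mmrd_deletion_mean,
      mmrd_deletion_sd = mmrd_deletion_sd
    ),
    class = "marker_def"
  )
}

#' Default 14-marker mononucleotide panel
#'
#' Fourteen mononucleotide-repeat markers with reference repeat lengths and
#' stutter rates in the range typical of clinical MSI amplicon panels.
#' Longer homopolymers slip more, so stutter rates increase with reference
#' length. Marker identifiers follow the field's naming style; the panel
#' composition itself is synthetic.
#'
#' @param stutter_rates Optional numeric vector of length 14 overriding the
#'   per-marker stutter rates.
#' @return A named list of 14 [marker_def()] objects (class `msi_panel`).
#' @export
#' @examples
#' panel <- default_panel()
#' length(panel)
default_panel <- function(stutter_rates = NULL) {
  ids <- c(sprintf("AKMmono%02d", 1:10), sprintf("EJmono%02d", 11:14))
  ref_len <- c(22L, 24L, 20L, 27L, 23L, 25L, 21L, 26L, 24L, 22L,
               23L, 25L, 21L, 24L)
  if (is.null(stutter_rates)) {
    # slippage grows with homopolymer length; 0.06-0.16 spans typical assays
    stutter_rates <- 0.06 + (ref_len - 20L) * 0.014
  }
  stopifnot(length(stutter_rates) == 14L)
  panel <- Map(function(id, rl, sr) marker_def(id, rl, stutter_rate = sr),
               ids, ref_len, stutter_rates)
  names(panel) <- ids
  structure(panel, class = "msi_panel")
}

panel_ids <- function(panel) vapply(panel, `[[`, character(1), "marker_id")

validate_panel <- function(panel) {
  stopifnot(length(panel) >= 1L)
  if (!all(vapply(panel, inherits, logical(1), "marker_def"))) {
    stop("panel must be a list of marker_def objects", call. = FALSE)
  }
  ids <- panel_ids(panel)
  if (anyDuplicated(ids)) {
    stop("duplicate marker_ids in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  invisible(panel)
}

#' @export
print.marker_def <- function(x, ...) {
  cat(sprintf(
    "<marker_def> %s: ref %d nt, stutter %.3f, deletion %0.1f +/- %0.1f nt\n",
    x$marker_id, x$reference_repeat_length, x$stutter_rate,
    x$mmrd_deletion_mean, x$mmrd_deletion_sd))
  invisible(x)
}

#' @export
print.msi_panel <- function(x, ...) {
  cat(sprintf("<msi_panel> %d markers: %s\n", length(x),
              paste(panel_ids(x), collapse = ", ")))
  invisible(x)
}
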