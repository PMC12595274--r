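#' Write sample spectra to a tab-separated table
#'
#' Long format, one row per (sample, marker, allele offset):
#' columns `sample_id`, `marker_id`, `allele_offset`, `read_count`.
#'
#' @param profiles List of `sample_profile` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    do.call(rbind, lapply(p$spectra, function(sp) {
      data.frame(sample_id = p$sample_id, marker_id = sp$marker_id,
                 allele_offset = sp$offsets,
                 read_count = as.integer(sp$counts))
    }))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample spectra from a tab-separated table
#'
#' Parses the long-format spectra table written by [write_spectra_table()]
#' and reassembles one `sample_profile` per sample. Metadata (sample type,
#' subject, collection day) are taken from an optional manifest data frame
#' (see [read_manifest()]); samples absent from the manifest default to
#' urine, day 0, subject = sample.
#'
#' @param path Input file path.
#' @param manifest Optional manifest data frame keyed by `sample_id`.
#' @param panel Optional panel; rows whose `marker_id` is not in the panel
#'   are dropped with a warning.
#' @return A list of `sample_profile` objects (possibly empty, with a
#'   warning, for a table with no rows).
#' @export
read_spectra_table <- function(path, manifest = NULL, panel = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", stringsAsFactors = FALSE)
  required <- c("sample_id", "marker_id", "allele_offset", "read_count")
  if (!all(required %in% names(df))) {
    stop("spectra table must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty spectra table: ", path, call. = FALSE)
    return(list())
  }
  df$allele_offset <- suppressWarnings(as.integer(df$allele_offset))
  df$read_count <- suppressWarnings(as.integer(df$read_count))
  bad <- which(is.na(df$allele_offset) | is.na(df$read_count))
  if (length(bad)) {
    stop("malformed spectra rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  if (any(df$read_count < 0)) {
    stop("negative read counts at line(s) ",
         paste(which(df$read_count < 0) + 1L, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(panel)) {
    known <- panel_ids(panel)
    unknown <- setdiff(unique(df$marker_id), known)
    if (length(unknown)) {
      warning("ignoring markers not in panel: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      df <- df[df$marker_id %in% known, , drop = FALSE]
    }
  }
  lapply(split(df, df$sample_id), function(sdf) {
    spectra <- lapply(split(sdf, sdf$marker_id), function(mdf) {
      allele_spectrum(mdf$marker_id[1], mdf$allele_offset, mdf$read_count)
    })
    sid <- sdf$sample_id[1]
    meta <- if (!is.null(manifest) && sid %in% manifest$sample_id) {
      manifest[manifest$sample_id == sid, , drop = FALSE]
    }
    structure(
      list(sample_id = sid,
           subject_id = if (!is.null(meta)) meta$subject_id[1] else sid,
           sample_type = if (!is.null(meta)) meta$sample_type[1] else "urine",
           collection_day = if (!is.null(meta))
             as.integer(meta$collection_day[1]) else 0L,
           spectra = spectra,
           true_tumour_fraction = NULL),
      class = "sample_profile"
    )
  })
}

#' Write a sample manifest
#'
#' Tab-separated table with columns `sample_id`, `subject_id`,
#' `sample_type`, `collection_day`, plus `true_tumour_fraction` where the
#' profiles carry simulated truth.
#'
#' @param profiles List of `sample_profile` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, subject_id = p$subject_id,
               sample_type = p$sample_type,
               collection_day = p$collection_day,
               true_tumour_fraction = p$true_tumour_fraction %||% NA_real_)
  }))
  rownames(df) <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' @param path Input file path.
#' @return A data frame with one row per sample.
#' @export
read_manifest <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Serialise a trained classifier to a versioned YAML document
#'
#' @param model An `msi_classifier`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "msi_classifier"))
  doc <- list(
    schema = "msiscreen_classifier/1",
    score_scale = model$score_scale,
    qc_min_depth = model$qc_min_depth,
    qc_min_markers = model$qc_min_markers,
    borderline_range = model$borderline_range,
    score_range = model$score_range,
    markers = lapply(model$markers, function(m) {
      list(msih = list(shape1 = m$msih$shape1, shape2 = m$msih$shape2,
                       mean = m$msih$mean),
           mss = list(shape1 = m$mss$shape1, shape2 = m$mss$shape2,
                      mean = m$mss$mean),
           pseudocount = m$pseudocount)
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a classifier from its YAML document
#'
#' @param path Path written by [write_classifier()].
#' @return An `msi_classifier`.
#' @export
read_classifier <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "msiscreen_classifier/1")) {
    stop("unrecognised classifier schema in ", path, call. = FALSE)
  }
  markers <- lapply(names(doc$markers), function(mid) {
    m <- doc$markers[[mid]]
    list(marker_id = mid,
         msih = list(shape1 = m$msih$shape1, shape2 = m$msih$shape2,
                     mean = m$msih$mean),
         mss = list(shape1 = m$mss$shape1, shape2 = m$mss$shape2,
                    mean = m$mss$mean),
         pseudocount = m$pseudocount)
  })
  names(markers) <- names(doc$markers)
  structure(
    list(markers = markers, score_scale = doc$score_scale,
         qc_min_depth = doc$qc_min_depth,
         qc_min_markers = doc$qc_min_markers,
         borderline_range = as.numeric(doc$borderline_range),
         score_range = as.numeric(doc$score_range)),
    class = "msi_classifier"
  )
}

#' Write score results to a tab-separated table
#'
#' @param results List of `msi_score_result` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_results <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id,
               msi_score = r$msi_score,
               call = r$call %||% NA_character_,
               borderline = r$borderline,
               qc_pass = r$qc_pass,
               markers_used = r$markers_used)
  }))
  rownames(df) <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
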