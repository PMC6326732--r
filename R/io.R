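# Delimited-text readers/writers for time courses, lead matrices, feature
# tables, cohorts, and the bundled region-of-interest table.

#' Write / read a multichannel time course as CSV
#'
#' Rows are channels (first column \code{channel} holds the label),
#' columns are samples.
#'
#' @param tc channels-by-samples matrix with row names.
#' @param path file path.
#' @return \code{read_timecourse} returns the matrix; the writer returns
#'   the path invisibly.
#' @export
write_timecourse <- function(tc, path) {
  tc <- .as_timecourse(tc)
  df <- data.frame(channel = rownames(tc), tc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("channel", paste0("t", seq_len(ncol(tc))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "channel")
    stop("malformed time course file (no channel column): ", path, call. = FALSE)
  labels <- df[[1L]]
  if (anyDuplicated(labels)) {
    dup <- which(duplicated(labels))[1L]
    stop("duplicate channel label '", labels[dup], "' at data line ", dup,
         " in ", path, call. = FALSE)
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(!vapply(df[-1L], is.numeric, TRUE))[1L]
    stop("non-numeric values in column ", bad + 1L, " of ", path, call. = FALSE)
  }
  rownames(x) <- labels
  colnames(x) <- NULL
  x
}

#' Write / read a lead matrix as square CSV
#'
#' Square table with channel labels as both header row and first column.
#'
#' @param lm antisymmetric matrix with dimnames.
#' @param path file path.
#' @export
write_leadmatrix <- function(lm, path) {
  utils::write.csv(as.data.frame(lm), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_leadmatrix
#' @export
read_leadmatrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  a <- as.matrix(df)
  if (nrow(a) != ncol(a)) stop("lead matrix file not square: ", path, call. = FALSE)
  colnames(a) <- rownames(a)
  a
}

#' Read a region-of-interest table
#'
#' Expects CSV columns \code{name}, \code{x}, \code{y}, \code{z} (MNI
#' coordinates, mm) and \code{network}.  The package bundles the
#' 33-region table used for the resting-state analysis as
#' \code{system.file("extdata", "roi_table.csv", package = "cyclicity")};
#' it is shipped verbatim, including two left-hemisphere entries whose
#' printed x coordinates are positive.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return data frame with columns name, x, y, z, network.
#' @export
read_roi_table <- function(path = system.file("extdata", "roi_table.csv",
                                              package = "cyclicity")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "network")
  if (!all(need %in% colnames(df)))
    stop("ROI table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$name)) {
    dup <- which(duplicated(df$name))[1L]
    stop("duplicate ROI name '", df$name[dup], "' at data line ", dup,
         " in ", path, call. = FALSE)
  }
  for (cc in c("x", "y", "z")) if (!is.numeric(df[[cc]]))
    stop("non-numeric ", cc, " coordinate in ", path, call. = FALSE)
  df[, need]
}

#' Write a synthetic cohort to disk
#'
#' One CSV per run (channels-by-samples, via [write_timecourse()]) plus a
#' \code{manifest.csv} with subject_id, group, session, run and relative
#' path.
#'
#' @param cohort result of [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel <- sprintf("%s_ses%d_run%d.csv", cohort$subject_id, cohort$session,
                 cohort$run)
  for (i in seq_len(nrow(cohort)))
    write_timecourse(cohort$timecourse[[i]], file.path(dir, rel[i]))
  manifest <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                         session = cohort$session, run = cohort$run,
                         path = rel, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing \code{manifest.csv}.
#' @return cohort data frame with a \code{timecourse} list column.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  out <- manifest[, c("subject_id", "group", "session", "run")]
  out$timecourse <- lapply(manifest$path, function(p)
    read_timecourse(file.path(dir, p)))
  class(out) <- c("cohort", class(out))
  out
}
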