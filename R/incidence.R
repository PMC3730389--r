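#' Construct a prescription incidence dataset
#'
#' A prescription dataset is an m x p binary incidence matrix recording, for
#' each of m clinical studies (rows), which of p acupoints (columns) its
#' acupuncture prescription used. Acupoints are identified by standard
#' meridian codes such as `"BL23"` or `"GB30"`.
#'
#' @param incidence numeric/integer matrix of 0/1 entries, studies in rows,
#'   acupoints in columns.
#' @param study_ids character vector of study identifiers, length `nrow(incidence)`.
#'   Defaults to existing rownames or `"S1"`, `"S2"`, ...
#' @param acupoint_labels character vector of unique acupoint codes, length
#'   `ncol(incidence)`. Defaults to existing colnames.
#' @return An object of class `"prescription_dataset"`: a list with elements
#'   `incidence` (integer matrix with dimnames), `study_ids`, and
#'   `acupoint_labels`.
#' @examples
#' ds <- prescription_dataset(rbind(c(1, 1), c(1, 0), c(0, 1)),
#'                            acupoint_labels = c("BL23", "GB30"))
#' ds
#' @export
prescription_dataset <- function(incidence, study_ids = NULL,
                                 acupoint_labels = NULL) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  m <- nrow(incidence)
  p <- ncol(incidence)
  if (m < 1L || p < 1L) {
    stop("incidence must have at least one study (row) and one acupoint (column)")
  }
  if (is.null(acupoint_labels)) acupoint_labels <- colnames(incidence)
  if (is.null(acupoint_labels)) {
    stop("acupoint_labels must be supplied when incidence has no column names")
  }
  if (is.null(study_ids)) study_ids <- rownames(incidence)
  if (is.null(study_ids)) study_ids <- paste0("S", seq_len(m))
  study_ids <- as.character(study_ids)
  acupoint_labels <- as.character(acupoint_labels)
  if (length(study_ids) != m) stop("study_ids length must equal nrow(incidence)")
  if (length(acupoint_labels) != p) {
    stop("acupoint_labels length must equal ncol(incidence)")
  }
  if (anyNA(incidence) || !all(incidence %in% c(0, 1))) {
    bad <- which(is.na(incidence) | !(incidence %in% c(0, 1)), arr.ind = TRUE)[1L, ]
    stop(sprintf("incidence entries must be 0 or 1; offending cell at row %d ('%s'), column %d ('%s')",
                 bad[1L], study_ids[bad[1L]], bad[2L], acupoint_labels[bad[2L]]))
  }
  if (anyDuplicated(acupoint_labels)) {
    dup <- acupoint_labels[duplicated(acupoint_labels)][1L]
    stop(sprintf("duplicate acupoint label: '%s'", dup))
  }
  if (any(!nzchar(acupoint_labels))) stop("acupoint labels must be non-empty")
  storage.mode(incidence) <- "integer"
  dimnames(incidence) <- list(study_ids, acupoint_labels)
  structure(list(incidence = incidence,
                 study_ids = study_ids,
                 acupoint_labels = acupoint_labels),
            class = "prescription_dataset")
}

#' @export
print.prescription_dataset <- function(x, ...) {
  cat(sprintf("Prescription incidence dataset: %d studies x %d acupoints\n",
              nrow(x$incidence), ncol(x$incidence)))
  cat(sprintf("Total usages: %d\n", sum(x$incidence)))
  lab <- x$acupoint_labels
  cat("Acupoints:", paste(utils::head(lab, 8L), collapse = ", "),
      if (length(lab) > 8L) sprintf("... (%d more)", length(lab) - 8L) else "",
      "\n")
  invisible(x)
}

#' @export
dim.prescription_dataset <- function(x) dim(x$incidence)

#' Read an incidence CSV
#'
#' Reads the package's incidence CSV dialect: comma-separated UTF-8 with a
#' header row of acupoint codes, the first column (`study_id`) holding study
#' identifiers, and every remaining cell 0 or 1.
#'
#' @param path path to a CSV file.
#' @return A [prescription_dataset()].
#' @seealso [write_incidence()]
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop(sprintf("'%s' holds no incidence data (need a study_id column plus at least one acupoint)", path))
  }
  labels <- colnames(df)[-1L]
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(as.numeric(cells))
  bad <- is.na(num) | !(num %in% c(0, 1))
  if (any(bad)) {
    at <- which(matrix(bad, nrow(cells)), arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed cell '%s' at data row %d, column '%s': expected 0 or 1",
                 cells[at[1L], at[2L]], at[1L], labels[at[2L]]))
  }
  prescription_dataset(matrix(as.integer(num), nrow(cells), ncol(cells)),
                       study_ids = ids, acupoint_labels = labels)
}

#' Write an incidence CSV
#'
#' Emits the dialect read by [read_incidence()] bit-exactly: comma-separated,
#' no quoting, LF line endings, header `study_id,<labels...>`.
#'
#' @param ds a [prescription_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(ds, path) {
  stopifnot(inherits(ds, "prescription_dataset"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("study_id", ds$acupoint_labels), collapse = ","),
             con, sep = "\n")
  body <- apply(ds$incidence, 1L, paste, collapse = ",")
  writeLines(paste(ds$study_ids, body, sep = ","), con, sep = "\n")
  invisible(path)
}

# round half up (away from zero for positives); base round() is half-to-even
round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Per-acupoint usage statistics
#'
#' Tallies, for each acupoint, the number of studies whose prescription used
#' it (`count`, the column sum of the incidence matrix), the usage frequency
#' `P(x) = count / m`, and a percentage rendering rounded half-up to one
#' decimal (so 27 of 53 studies renders as 50.9).
#'
#' @param ds a [prescription_dataset()].
#' @return A data frame with columns `acupoint`, `count`, `frequency`,
#'   `percent`, in dataset column order.
#' @examples
#' ds <- prescription_dataset(rbind(c(1, 1), c(1, 0), c(0, 1)),
#'                            acupoint_labels = c("BL23", "GB30"))
#' usage_stats(ds)
#' @export
usage_stats <- function(ds) {
  stopifnot(inherits(ds, "prescription_dataset"))
  m <- nrow(ds$incidence)
  counts <- as.integer(colSums(ds$incidence))
  freq <- counts / m
  data.frame(acupoint = ds$acupoint_labels,
             count = counts,
             frequency = freq,
             percent = round_half_up(100 * freq, 1L),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Drop rarely used acupoints
#'
#' Retains exactly the acupoints whose usage frequency strictly exceeds
#' `min_freq` (so with `min_freq = 0.05`, an acupoint at exactly 5% is
#' dropped), preserving column order. Studies are unchanged.
#'
#' @param ds a [prescription_dataset()].
#' @param min_freq frequency threshold in `[0, 1]`; default 0.05.
#' @return A filtered [prescription_dataset()].
#' @export
filter_by_frequency <- function(ds, min_freq = 0.05) {
  stopifnot(inherits(ds, "prescription_dataset"))
  if (!is.numeric(min_freq) || length(min_freq) != 1L ||
      min_freq < 0 || min_freq > 1) {
    stop("min_freq must be a single value in [0, 1]")
  }
  keep <- colSums(ds$incidence) / nrow(ds$incidence) > min_freq
  if (!any(keep)) stop("no acupoints survive filter")
  prescription_dataset(ds$incidence[, keep, drop = FALSE],
                       study_ids = ds$study_ids,
                       acupoint_labels = ds$acupoint_labels[keep])
}
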