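#' Pointwise mutual-information score for one acupoint pair
#'
#' Computes the co-occurrence statistic
#' \deqn{MI(x, y) = P(x, y) \, \ln\!\frac{P(x, y)}{P(x) P(y)}}{MI(x,y) = P(x,y) * ln(P(x,y) / (P(x) P(y)))}
#' with `P(x) = n_x / m`, `P(y) = n_y / m`, `P(x,y) = n_xy / m`, where `n_x`
#' and `n_y` are the number of studies using each acupoint, `n_xy` the number
#' using both, and `m` the total number of studies. This is a single
#' pointwise-mutual-information term weighted by the co-usage frequency (in
#' nats), not the full Shannon mutual information of the 2 x 2 table. The
#' limit convention `0 * ln(0) = 0` applies, so `n_xy = 0` scores 0; pairs
#' used together less often than independence predicts score negative.
#'
#' @param n_x,n_y marginal usage counts, each in `[1, m]`.
#' @param n_xy co-usage count, `0 <= n_xy <= min(n_x, n_y)`.
#' @param m total number of studies, `>= 1`.
#' @return The MI value (nats). Vectorized over counts.
#' @examples
#' pair_mi(17, 23, 17, 53)  # approx 0.2678
#' pair_mi(2, 2, 1, 4)      # exactly 0: co-usage at independence
#' @export
pair_mi <- function(n_x, n_y, n_xy, m) {
  if (any(m < 1)) stop("m must be >= 1")
  if (any(n_x < 1) || any(n_y < 1)) {
    stop("undefined marginal: n_x and n_y must be >= 1 (filter unused acupoints first)")
  }
  if (any(n_x > m) || any(n_y > m)) stop("marginal counts cannot exceed m")
  if (any(n_xy < 0) || any(n_xy > pmin(n_x, n_y))) {
    stop("n_xy must satisfy 0 <= n_xy <= min(n_x, n_y)")
  }
  pxy <- n_xy / m
  out <- ifelse(n_xy == 0, 0, pxy * log(pxy / ((n_x / m) * (n_y / m))))
  as.numeric(out)
}

#' Pairwise MI matrix of a dataset
#'
#' Assembles the symmetric p x p matrix of [pair_mi()] values over all
#' acupoint pairs of a dataset. The diagonal is fixed at 0 (self-pairs carry
#' no combination information).
#'
#' @param ds a [prescription_dataset()]; every acupoint must be used in at
#'   least one study (apply [filter_by_frequency()] first if needed).
#' @return A numeric matrix of class `"mi_matrix"` with acupoint labels as
#'   dimnames.
#' @export
mi_matrix <- function(ds) {
  stopifnot(inherits(ds, "prescription_dataset"))
  inc <- ds$incidence
  m <- nrow(inc)
  counts <- colSums(inc)
  if (any(counts == 0)) {
    stop(sprintf("acupoint '%s' has no usages; apply filter_by_frequency() before mi_matrix()",
                 ds$acupoint_labels[which(counts == 0)[1L]]))
  }
  co <- crossprod(inc)              # n_xy for all pairs, n_x on the diagonal
  pxy <- co / m
  px <- counts / m
  indep <- outer(px, px)
  vals <- matrix(0, ncol(inc), ncol(inc), dimnames = dimnames(co))
  nz <- pxy > 0
  vals[nz] <- pxy[nz] * log(pxy[nz] / indep[nz])
  diag(vals) <- 0
  class(vals) <- c("mi_matrix", class(vals))
  vals
}

#' Serialize an MI matrix
#'
#' `write_mi_matrix()` writes the labeled square matrix as CSV;
#' `write_mi_pairs()` writes the upper triangle in long format
#' (`acupoint_a`, `acupoint_b`, `mi`) as TSV, sorted by decreasing MI.
#'
#' @param mi an [mi_matrix()] result.
#' @param path output file path.
#' @param digits decimal places for the long format; default 4.
#' @return `path`, invisibly.
#' @export
write_mi_matrix <- function(mi, path) {
  stopifnot(inherits(mi, "mi_matrix"))
  df <- data.frame(acupoint = rownames(mi), unclass(mi), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
write_mi_pairs <- function(mi, path, digits = 4L) {
  stopifnot(inherits(mi, "mi_matrix"))
  lp <- mi_pair_table(mi)
  lp$mi <- formatC(lp$mi, digits = digits, format = "f")
  utils::write.table(lp, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

# upper-triangle long form, sorted by decreasing MI then labels
mi_pair_table <- function(mi) {
  idx <- which(upper.tri(mi), arr.ind = TRUE)
  out <- data.frame(acupoint_a = rownames(mi)[idx[, 1L]],
                    acupoint_b = colnames(mi)[idx[, 2L]],
                    mi = mi[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mi, out$acupoint_a, out$acupoint_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
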