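# Published summary statistics of the 53-trial low back pain acupuncture
# corpus (28 Korean + 25 international trials): per-acupoint usage
# percentages for the 33 acupoints used in more than 5% of trials, and the
# 13 acupoint pairs whose pointwise-MI value exceeded 0.17, with their
# published 4-decimal MI values. The raw trial-by-acupoint matrix itself was
# never deposited; these summaries are the only public anchors.

lbp_usage_percent <- c(
  BL23 = 50.9, BL25 = 43.4, BL40 = 32.1, BL60 = 32.1, GB30 = 32.1,
  BL24 = 32.1, BL32 = 28.3, BL26 = 28.3, GB34 = 20.8, ST36 = 15.1,
  BL57 = 11.3, BL62 = 11.3, BL52 = 11.3, GV3 = 11.3, KI3 = 11.3,
  GV4 = 9.4, LI4 = 9.4, BL31 = 9.4, BL33 = 9.4, BL34 = 9.4,
  BL22 = 7.5, SI6 = 7.5, LR3 = 7.5, SI3 = 7.5, BL27 = 7.5, KI7 = 7.5,
  BL37 = 5.7, SP9 = 5.7, LU8 = 5.7, SP3 = 5.7, HT8 = 5.7, SP2 = 5.7,
  KI10 = 5.7)

lbp_high_mi_pairs <- data.frame(
  a = c("BL24", "BL31", "BL31", "BL33", "BL32", "BL24", "BL25", "BL23",
        "BL40", "BL23", "GB34", "BL40", "GB30"),
  b = c("BL25", "BL33", "BL34", "BL34", "GB30", "BL26", "BL26", "BL25",
        "GB34", "BL32", "ST36", "BL60", "BL24"),
  mi = c(0.2678, 0.2227, 0.2227, 0.2227, 0.2069, 0.2069, 0.2023, 0.2018,
         0.1966, 0.1909, 0.1900, 0.1786, 0.1786),
  stringsAsFactors = FALSE)

# the three published prescription modules of the low back pain network
lbp_modules <- list(
  A = c("BL23", "BL25", "BL24", "BL26", "BL57", "BL32", "GV3", "GV4",
        "BL52", "BL22", "BL27", "BL31", "BL33", "BL34"),
  B = c("BL60", "GB30", "BL40", "GB34", "BL37", "ST36", "BL62", "SI3", "SI6"),
  C = c("LI4", "KI3", "LU8", "SP9", "LR3", "KI7", "SP3", "SP2", "HT8", "KI10"))

#' Lumbar-region acupoints used for local/distant pair tagging
#'
#' The default "local" set for [tag_pairs()]: the 14 acupoints of the
#' published local-acupoints module (lumbar Bladder-meridian and Governing-
#' vessel points) plus GB30, which sits on the gluteal region and is tagged
#' local in the published high-MI pair table.
#'
#' @return A character vector of acupoint codes.
#' @export
lbp_local_acupoints <- function() c(lbp_modules$A, "GB30")

#' Synthetic reference dataset for the low back pain corpus
#'
#' Reconstructs a 53-study, 33-acupoint incidence dataset consistent with
#' the published summaries of the low back pain acupuncture corpus: every
#' acupoint's usage count equals `round(percent * 53 / 100)` (which
#' round-trips to the published percentage at one decimal), and the co-usage
#' count of each of the 13 published high-MI pairs is the unique integer
#' whose [pair_mi()] value rounds to the published 4-decimal MI (see
#' [infer_pair_count()]). All other cells are an arbitrary deterministic
#' completion, so network-level quantities (degrees, betweenness, modules)
#' are NOT anchored to the published analysis — only marginals and the 13
#' pair MI values are.
#'
#' The dataset is synthetic: the underlying 53 clinical trials' prescriptions
#' were never published. A copy ships as
#' `inst/extdata/lbp_fixture_synthetic.csv`.
#'
#' @param from_file read the shipped CSV (default) instead of rebuilding via
#'   [build_fixture()]; both routes yield the identical dataset.
#' @return A [prescription_dataset()] with m = 53 studies, p = 33 acupoints.
#' @examples
#' ds <- lbp_fixture()
#' subset(usage_stats(ds), acupoint == "BL23")  # 27/53 = 50.9%
#' @export
lbp_fixture <- function(from_file = TRUE) {
  if (from_file) {
    path <- system.file("extdata", "lbp_fixture_synthetic.csv",
                        package = "acunet")
    if (nzchar(path)) return(read_incidence(path))
  }
  m <- 53L
  counts <- as.integer(round(lbp_usage_percent * m / 100))
  names(counts) <- names(lbp_usage_percent)
  stopifnot(all(round_half_up(counts / m * 100, 1L) == lbp_usage_percent))
  pairs <- lbp_high_mi_pairs
  pairs$count <- mapply(function(a, b, mi) {
    infer_pair_count(counts[[a]], counts[[b]], m, mi)
  }, pairs$a, pairs$b, pairs$mi)
  build_fixture(fixture_spec(m, counts, pairs, seed = 20130716L))
}
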