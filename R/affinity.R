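#' The 20 canonical amino acids
#'
#' One-letter codes in BLOSUM row order. This ordering fixes the index used by
#' the one-hot encoding and the learned (Deep) encoding table.
#'
#' @format A character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# IC50 (nM) at which the normalized affinity reaches 0.
.ic50_ceiling <- 50000

#' Normalize an IC50 affinity to the unit interval
#'
#' Maps a measured IC50 value `x` (nM) to `b = clamp(1 - log_50000(x), 0, 1)`.
#' Strong binders (small IC50) map near 1, non-binders near 0; the map is
#' monotone non-increasing in `x`.
#'
#' @param x Numeric vector of IC50 values in nM; all must be > 0.
#' @return Numeric vector of normalized affinities in `[0, 1]`.
#' @examples
#' normalize_affinity(c(1, 500, 50000))
#' @export
normalize_affinity <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort("`x` must be finite IC50 values > 0 nM.", class = "peprank_invalid_measurement")
  }
  pmin(pmax(1 - log(x) / log(.ic50_ceiling), 0), 1)
}

#' Invert the affinity normalization
#'
#' Returns the IC50 (nM) whose normalized affinity is `b`, i.e.
#' `x = 50000^(1 - b)`. Exact inverse of [normalize_affinity()] on `[0, 1]`.
#'
#' @param b Numeric vector of normalized affinities in `[0, 1]`.
#' @return IC50 values in nM.
#' @export
ic50_from_affinity <- function(b) {
  if (!is.numeric(b) || any(!is.finite(b)) || any(b < 0 | b > 1)) {
    abort("`b` must be in [0, 1].", class = "peprank_invalid_measurement")
  }
  .ic50_ceiling^(1 - b)
}

#' Map an IC50 affinity to a qualitative binding level
#'
#' Five-tier banding of IC50 values: level 5 ("Positive-high") for
#' IC50 in (0, 100] nM, 4 for (100, 500], 3 for (500, 1000], 2 for
#' (1000, 5000] and 1 ("Negative") above 5000 nM. Band boundaries are assigned
#' to the stronger-binding level.
#'
#' @param x Numeric vector of IC50 values in nM; all must be > 0.
#' @return Integer vector of binding levels in 1..5.
#' @examples
#' affinity_to_level(c(50, 750, 7000))
#' @export
affinity_to_level <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort("`x` must be finite IC50 values > 0 nM.", class = "peprank_invalid_measurement")
  }
  breaks <- c(0, 100, 500, 1000, 5000, Inf)
  # (0,100] -> 5 ... (5000, Inf) -> 1
  6L - as.integer(cut(x, breaks = breaks, labels = FALSE, right = TRUE))
}

#' IC50 threshold representing a qualitative binding level
#'
#' For entries known only by level, the level is represented by the IC50
#' bound it guarantees: levels 5..2 map to 100, 500, 1000 and 5000 nM (the
#' weak-side bound of each positive band), and level 1 ("Negative", IC50 >
#' 5000 nM) also maps to 5000 nM, where it acts as a one-sided constraint.
#'
#' @param l Integer vector of binding levels in 1..5.
#' @return IC50 thresholds in nM.
#' @export
level_threshold_ic50 <- function(l) {
  if (!all(l %in% 1:5)) {
    abort("levels must be integers in 1..5.", class = "peprank_invalid_measurement")
  }
  c(5000, 5000, 1000, 500, 100)[as.integer(l)]
}

#' Normalized affinity representing a qualitative binding level
#'
#' Composition of [level_threshold_ic50()] and [normalize_affinity()].
#'
#' @inheritParams level_threshold_ic50
#' @return Normalized affinities in `[0, 1]`.
#' @export
level_threshold_affinity <- function(l) {
  normalize_affinity(level_threshold_ic50(l))
}
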