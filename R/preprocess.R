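#' Read a peptide-MHC affinity table
#'
#' Reads a TSV or CSV table with header columns `allele`, `peptide`,
#' `measurement_kind` (`"quantitative"` or `"qualitative"`) and
#' `measurement_value` (IC50 in nM, or a level 1-5).
#'
#' @param path File path. The delimiter is taken from the extension
#'   (`.csv` for comma, anything else tab) unless `sep` is given.
#' @param sep Optional field separator override.
#' @return A tibble with the four raw columns.
#' @export
read_affinity_table <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  need <- c("allele", "peptide", "measurement_kind", "measurement_value")
  if (!all(need %in% names(df))) {
    abort(paste0("affinity table must have columns: ", paste(need, collapse = ", ")),
          class = "peprank_io_error")
  }
  tibble::as_tibble(df[need])
}

#' Write a table in the package's TSV/CSV dialect
#'
#' @param x A data frame.
#' @param path Output path; `.csv` selects comma separation, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.valid_peptide <- function(peptide, min_len = 8L, max_len = 15L) {
  n <- nchar(peptide)
  ok_len <- n >= min_len & n <= max_len
  ok_chr <- !grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), peptide)
  ok_len & ok_chr
}

#' Consolidate duplicate measurements of one peptide-MHC pair
#'
#' Maps every measurement of a single (allele, peptide) pair to a binding
#' level, takes the strict plurality (unique mode) of levels as the major
#' level, and returns one consolidated entry at that level. The consolidated
#' affinity is the normalization of the mean quantitative IC50 among the major
#' level's quantitative members; if the major level has no quantitative
#' member, the level's representative threshold is used. When no unique
#' plurality level exists the pair is conflicting and `NULL` is returned.
#'
#' @param entries Tibble of raw measurements for one (allele, peptide) pair,
#'   with columns `allele`, `peptide`, `measurement_kind`, `measurement_value`.
#' @return A one-row tibble with columns `allele`, `peptide`, `kind`, `ic50`,
#'   `b`, `level`, or `NULL` for a conflicting pair.
#' @export
consolidate_duplicates <- function(entries) {
  if (nrow(entries) == 0) {
    abort("`entries` must contain at least one measurement.", class = "peprank_invalid_measurement")
  }
  if (length(unique(entries$allele)) != 1 || length(unique(entries$peptide)) != 1) {
    abort("all entries must share one (allele, peptide) pair.", class = "peprank_invalid_measurement")
  }
  quant <- entries$measurement_kind == "quantitative"
  lvl <- integer(nrow(entries))
  lvl[quant] <- affinity_to_level(entries$measurement_value[quant])
  if (any(!quant)) {
    ql <- entries$measurement_value[!quant]
    if (!all(ql %in% 1:5)) {
      abort("qualitative levels must be in 1..5.", class = "peprank_invalid_measurement")
    }
    lvl[!quant] <- as.integer(ql)
  }
  tab <- table(lvl)
  top <- max(tab)
  winners <- as.integer(names(tab)[tab == top])
  if (length(winners) != 1) return(NULL)
  major <- winners
  qx <- entries$measurement_value[quant & lvl == major]
  if (length(qx) > 0) {
    xbar <- mean(qx)
    tibble::tibble(allele = entries$allele[1], peptide = entries$peptide[1],
                   kind = "quantitative", ic50 = xbar,
                   b = normalize_affinity(xbar), level = major)
  } else {
    tibble::tibble(allele = entries$allele[1], peptide = entries$peptide[1],
                   kind = "qualitative", ic50 = NA_real_,
                   b = level_threshold_affinity(major), level = major)
  }
}

#' Normalize, level-map and deduplicate an affinity table
#'
#' End-to-end preprocessing of raw per-allele affinity tables: peptides are
#' uppercased; peptides outside length 8-15 or containing non-canonical
#' letters are dropped with a warning; every entry gets a binding level
#' (from the IC50 bands for quantitative entries); duplicated (allele,
#' peptide) pairs are consolidated by majority voting over levels, and pairs
#' whose major level cannot be identified are removed.
#'
#' @param data Tibble with columns `allele`, `peptide`, `measurement_kind`,
#'   `measurement_value` (IC50 nM or level 1-5).
#' @return A tibble with columns `allele`, `peptide`, `kind`, `ic50`
#'   (`NA` for qualitative-only pairs), `b` (normalized affinity) and
#'   `level`, one row per retained (allele, peptide) pair. The removed
#'   conflicting pairs are attached as attribute `"removed"` and can be
#'   retrieved with [removed_conflicts()].
#' @examples
#' raw <- tibble::tibble(
#'   allele = "HLA-A*02:01",
#'   peptide = c("SLYNTVATL", "SLYNTVATL", "GILGFVFTL"),
#'   measurement_kind = c("quantitative", "quantitative", "qualitative"),
#'   measurement_value = c(20, 40, 5)
#' )
#' preprocess_affinities(raw)
#' @export
preprocess_affinities <- function(data) {
  need <- c("allele", "peptide", "measurement_kind", "measurement_value")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(need, collapse = ", ")),
          class = "peprank_io_error")
  }
  if (!all(data$measurement_kind %in% c("quantitative", "qualitative"))) {
    abort("`measurement_kind` must be 'quantitative' or 'qualitative'.",
          class = "peprank_invalid_measurement")
  }
  data <- dplyr::mutate(data, peptide = toupper(.data$peptide))
  keep <- .valid_peptide(data$peptide)
  if (any(!keep)) {
    warn(sprintf("dropping %d entries with peptides outside length 8-15 or with non-canonical letters",
                 sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0) {
    abort("no valid entries left after peptide filtering.", class = "peprank_invalid_measurement")
  }
  groups <- dplyr::group_split(dplyr::group_by(data, .data$allele, .data$peptide))
  consolidated <- purrr::map(groups, consolidate_duplicates)
  removed_idx <- purrr::map_lgl(consolidated, is.null)
  removed <- purrr::map_dfr(groups[removed_idx], function(g) {
    tibble::tibble(allele = g$allele[1], peptide = g$peptide[1], n_entries = nrow(g))
  })
  out <- dplyr::bind_rows(consolidated[!removed_idx])
  out <- dplyr::arrange(out, .data$allele, .data$peptide)
  attr(out, "removed") <- removed
  out
}

#' Conflicting pairs removed during preprocessing
#'
#' @param x The result of [preprocess_affinities()].
#' @return A tibble with columns `allele`, `peptide`, `n_entries`.
#' @export
removed_conflicts <- function(x) {
  attr(x, "removed") %||% tibble::tibble(allele = character(), peptide = character(),
                                         n_entries = integer())
}
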