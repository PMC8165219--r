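# Attention-weight extraction and motif recovery.

#' Collect attention weights over peptides
#'
#' Runs the model in evaluation mode and returns the attention weight placed
#' on every k-mer start position of every peptide. Weights of one peptide sum
#' to 1. With kernel size 1 the weights are per-residue.
#'
#' @param peptides Character vector of peptides, or a data frame with a
#'   `peptide` column.
#' @param model A `peprank_model`.
#' @return A tibble with columns `peptide`, `position` (k-mer start, 1-based)
#'   and `weight`.
#' @export
collect_attention <- function(peptides, model) {
  stopifnot(inherits(model, "peprank_model"))
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  if (!isTRUE(model$trained)) {
    warn("model is untrained; attention weights reflect the initializer.")
  }
  fw <- .forward(peptides, model$config, model$params, model$run_stats, mode = "eval")
  out <- tibble::tibble(peptide = peptides[fw$group],
                        position = unlist(lapply(fw$L, seq_len), use.names = FALSE),
                        weight = fw$w)
  class(out) <- c("peprank_attention", class(out))
  out
}

#' Attention-derived position x amino-acid motif matrix
#'
#' Accumulates per-residue attention weights into a 20 x L matrix: entry
#' (a, j) is the sum over peptides of the attention weight at position j
#' where amino acid a sits at that position. Requires kernel size 1 so that
#' positions are single residues. With `frame = "raw"` all peptides must
#' share one length L; with `frame = "padded"` positions are mapped into the
#' middle-padded 15-slot frame (padding slots receive no mass).
#'
#' @param attention A [collect_attention()] tibble from a `k = 1` model.
#' @param frame `"raw"` or `"padded"`.
#' @return A 20 x L numeric matrix with amino-acid rownames.
#' @export
smm_like_matrix <- function(attention, frame = c("raw", "padded")) {
  frame <- match.arg(frame)
  if (nrow(attention) == 0) {
    abort("empty attention table.", class = "peprank_io_error")
  }
  nvec <- nchar(attention$peptide)
  npos <- vapply(split(attention$position, attention$peptide), max, numeric(1))
  if (any(npos != nchar(names(npos)))) {
    abort("attention positions do not cover the peptides; need a k = 1 model.",
          class = "peprank_config_error")
  }
  if (frame == "raw") {
    L <- unique(nvec)
    if (length(L) != 1) {
      abort("raw frame needs peptides of one common length; use frame = 'padded'.",
            class = "peprank_config_error")
    }
    col <- attention$position
  } else {
    L <- 15L
    col <- integer(nrow(attention))
    for (n in unique(nvec)) {
      sel <- nvec == n
      col[sel] <- .pad_slots(n)[attention$position[sel]]
    }
  }
  aa <- substr(attention$peptide, attention$position, attention$position)
  row <- match(aa, aa_alphabet())
  m <- matrix(0, 20, L, dimnames = list(aa_alphabet(), NULL))
  for (t in seq_along(row)) {
    m[row[t], col[t]] <- m[row[t], col[t]] + attention$weight[t]
  }
  m
}

#' Correlation between a motif matrix and an external scoring matrix
#'
#' Pearson correlation of the flattened matrices (optionally restricted to a
#' subset of position columns, e.g. anchors). External stabilized-matrix
#' scores mark preferred residues with small values, so a strong motif match
#' shows as a strongly negative correlation.
#'
#' @param smm_l A [smm_like_matrix()] (20 x L).
#' @param external An external 20 x L scoring matrix (rows in the same
#'   amino-acid order).
#' @param columns Optional integer vector of columns to correlate.
#' @return Pearson correlation in `[-1, 1]`, or `NA` with a warning when
#'   either matrix has zero variance.
#' @export
motif_correlation <- function(smm_l, external, columns = NULL) {
  if (!all(dim(smm_l) == dim(external))) {
    abort("matrices must share dimensions.", class = "peprank_io_error")
  }
  if (!is.null(columns)) {
    smm_l <- smm_l[, columns, drop = FALSE]
    external <- external[, columns, drop = FALSE]
  }
  x <- as.vector(smm_l)
  y <- as.vector(external)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(.undefined_metric("zero variance in a motif matrix."))
  }
  stats::cor(x, y)
}

#' Read an external position x amino-acid scoring matrix
#'
#' Plain TSV with amino-acid row names and one column per position.
#'
#' @param path File path.
#' @return A 20 x L numeric matrix in [aa_alphabet()] row order.
#' @export
read_scoring_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  if (!all(aa_alphabet() %in% rownames(m))) {
    abort("scoring matrix must have the 20 amino acids as row names.",
          class = "peprank_io_error")
  }
  m[aa_alphabet(), , drop = FALSE]
}

#' Plot attention weights as a heatmap
#'
#' @param object A [collect_attention()] tibble.
#' @param max_peptides Cap on the number of peptides shown.
#' @param ... Unused.
#' @return A ggplot object: peptides as rows, positions as columns, fill =
#'   attention weight.
#' @export
autoplot.peprank_attention <- function(object, max_peptides = 50, ...) {
  plot_attention(object, max_peptides)
}

#' @rdname autoplot.peprank_attention
#' @param attention A [collect_attention()] tibble.
#' @export
plot_attention <- function(attention, max_peptides = 50) {
  peps <- unique(attention$peptide)
  peps <- peps[seq_len(min(length(peps), max_peptides))]
  d <- dplyr::filter(attention, .data$peptide %in% peps)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                  y = factor(.data$peptide, levels = rev(peps)),
                                  fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "weight") +
    ggplot2::labs(x = "k-mer start position", y = NULL,
                  title = "Attention weights") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a position x amino-acid motif matrix
#'
#' @param m A [smm_like_matrix()]-style matrix.
#' @return A ggplot heatmap.
#' @export
plot_motif_matrix <- function(m) {
  d <- tibble::as_tibble(as.data.frame.table(m, responseName = "value"))
  names(d) <- c("aa", "position", "value")
  d$position <- as.integer(d$position)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                  y = factor(.data$aa, levels = rev(aa_alphabet())),
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "summed\nweight") +
    ggplot2::labs(x = "position", y = "amino acid",
                  title = "Attention-derived motif matrix") +
    ggplot2::theme_minimal()
}
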