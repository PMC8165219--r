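# Residue encodings, dual-end position embeddings and feature matrices.

.peprank_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Parses the packaged NCBI-format BLOSUM62 asset and returns the 20x20
#' submatrix over the canonical amino acids, in [aa_alphabet()] order, as raw
#' integer half-bit scores.
#'
#' @return A 20x20 numeric matrix with amino-acid dimnames.
#' @export
blosum62_matrix <- function() {
  if (is.null(.peprank_env$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "peprank")
    if (path == "") path <- file.path("inst", "extdata", "BLOSUM62.txt")
    m <- utils::read.table(path, header = TRUE, comment.char = "#",
                           check.names = FALSE)
    m <- as.matrix(m)
    rownames(m) <- colnames(m)
    aa <- aa_alphabet()
    .peprank_env$blosum62 <- m[aa, aa]
  }
  .peprank_env$blosum62
}

#' Declare a residue encoding scheme
#'
#' An encoding scheme is an ordered subset of the components `"blosum"`
#' (rows of BLOSUM62), `"onehot"` (indicator of the residue identity) and
#' `"deep"` (a learnable 20-dimensional embedding per residue, owned by the
#' model). Components are concatenated in the declared order, 20 dimensions
#' each, so the residue-encoding dimension is `20 * length(components)`.
#'
#' @param components Character vector, e.g. `c("blosum", "onehot", "deep")`,
#'   or a single `"+"`-separated string like `"blosum+onehot+deep"`.
#' @return An object of class `peprank_scheme` with elements `components` and
#'   `d_e`.
#' @examples
#' encoding_scheme("blosum+onehot+deep")$d_e
#' @export
encoding_scheme <- function(components = "blosum+onehot+deep") {
  if (length(components) == 1 && grepl("\\+", components)) {
    components <- strsplit(components, "+", fixed = TRUE)[[1]]
  }
  components <- tolower(components)
  valid <- c("blosum", "onehot", "deep")
  if (length(components) < 1 || anyDuplicated(components) ||
      !all(components %in% valid)) {
    abort("components must be a non-repeating subset of {'blosum','onehot','deep'}.",
          class = "peprank_encoding_error")
  }
  structure(list(components = components, d_e = 20L * length(components)),
            class = "peprank_scheme")
}

# Fixed (non-learnable) part of the residue encoding: d_fix x 20 matrix whose
# column i encodes amino acid i. The learnable deep block is appended by
# .encoding_table().
.fixed_encoding <- function(scheme) {
  blocks <- list()
  for (comp in scheme$components) {
    if (comp == "blosum") blocks[[comp]] <- t(blosum62_matrix())
    if (comp == "onehot") blocks[[comp]] <- diag(20)
    if (comp == "deep")   blocks[[comp]] <- NULL
  }
  blocks
}

# Full d_e x 20 encoding table: per-component blocks in declared order, with
# the deep block taken from `deep_table` (20 x 20, column = amino acid).
.encoding_table <- function(scheme, deep_table = NULL) {
  out <- matrix(0, nrow = 0, ncol = 20)
  for (comp in scheme$components) {
    block <- switch(comp,
      blosum = t(blosum62_matrix()),
      onehot = diag(20),
      deep = {
        if (is.null(deep_table)) {
          abort("scheme includes 'deep' but no deep table was supplied.",
                class = "peprank_encoding_error")
        }
        deep_table
      })
    out <- rbind(out, block)
  }
  colnames(out) <- aa_alphabet()
  out
}

.peptide_indices <- function(peptides) {
  chars <- strsplit(toupper(peptides), "", fixed = TRUE)
  idx <- lapply(chars, function(ch) {
    i <- match(ch, aa_alphabet())
    if (anyNA(i)) {
      abort(paste0("unknown amino-acid letter in peptide: ",
                   paste(ch[is.na(i)], collapse = ",")),
            class = "peprank_encoding_error")
    }
    i
  })
  idx
}

#' Encode a single residue
#'
#' @param a One amino-acid letter.
#' @param scheme An [encoding_scheme()] (or string accepted by it).
#' @param deep_table Optional 20x20 learnable table (columns = amino acids);
#'   required when the scheme includes `"deep"`.
#' @return Numeric vector of length `scheme$d_e`.
#' @export
encode_residue <- function(a, scheme = encoding_scheme(), deep_table = NULL) {
  if (!inherits(scheme, "peprank_scheme")) scheme <- encoding_scheme(scheme)
  i <- match(toupper(a), aa_alphabet())
  if (length(a) != 1 || is.na(i)) {
    abort("`a` must be one of the 20 canonical amino-acid letters.",
          class = "peprank_encoding_error")
  }
  .encoding_table(scheme, deep_table)[, i]
}

#' Initialize the dual-end position embedding tables
#'
#' Two independent learnable tables of 15 vectors of dimension `d_o`: one
#' indexed by offset from the C-end of the peptide (position 1..n as written),
#' one by offset from the N-end (`n + 1 - j`). Sharing rows across peptides of
#' different lengths lets the pair of vectors encode where a residue sits
#' relative to both ends.
#'
#' @param d_o Embedding dimension (>= 1).
#' @param init_sd Standard deviation of the normal initializer.
#' @return List with `c_table` and `n_table`, each `d_o` x 15.
#' @export
position_tables <- function(d_o = 4L, init_sd = 0.1) {
  if (d_o < 1) abort("d_o must be >= 1.", class = "peprank_encoding_error")
  list(c_table = matrix(rnorm(d_o * 15, 0, init_sd), d_o, 15),
       n_table = matrix(rnorm(d_o * 15, 0, init_sd), d_o, 15))
}

#' Build the feature matrix of one peptide
#'
#' Column `j` is the concatenation of the residue encoding `e_j`, the C-end
#' position vector for offset `j` and the N-end position vector for offset
#' `n + 1 - j`. With positions disabled only the encoding block remains.
#'
#' @param peptide A peptide string of length 8-15.
#' @param scheme An [encoding_scheme()].
#' @param positions A [position_tables()] list, or `NULL` to disable the
#'   position block (ablation).
#' @param deep_table Optional 20x20 learnable table for the `"deep"` component.
#' @return A `(d_e + 2 d_o) x n` (or `d_e x n`) numeric matrix.
#' @export
build_feature_matrix <- function(peptide, scheme = encoding_scheme(),
                                 positions = NULL, deep_table = NULL) {
  if (!inherits(scheme, "peprank_scheme")) scheme <- encoding_scheme(scheme)
  n <- nchar(peptide)
  if (n < 8 || n > 15) {
    abort("peptide length must be 8-15.", class = "peprank_encoding_error")
  }
  idx <- .peptide_indices(peptide)[[1]]
  enc <- .encoding_table(scheme, deep_table)
  F <- enc[, idx, drop = FALSE]
  if (!is.null(positions)) {
    F <- rbind(F,
               positions$c_table[, seq_len(n), drop = FALSE],
               positions$n_table[, n + 1 - seq_len(n), drop = FALSE])
  }
  F
}

#' Pad a peptide to length 15 with middle insertions
#'
#' Keeps the first and last four residues in place and inserts `X` padding
#' characters into the middle so the result has length 15: with `n` residues
#' the `15 - n` pads split as `floor((15 - n) / 2)` on the left of the middle
#' block and the remainder on the right.
#'
#' @param peptide Peptide string of length 8-15.
#' @return A 15-character string over the amino-acid alphabet plus `X`.
#' @examples
#' pad_middle("GGFVPNMLSV")
#' @export
pad_middle <- function(peptide) {
  vapply(peptide, function(p) {
    n <- nchar(p)
    if (n < 8 || n > 15) {
      abort("peptide length must be 8-15.", class = "peprank_encoding_error")
    }
    if (n == 15L) return(p)
    pads <- 15L - n
    left <- pads %/% 2L
    paste0(substr(p, 1, 4),
           strrep("X", left),
           substr(p, 5, n - 4),
           strrep("X", pads - left),
           substr(p, n - 3, n))
  }, character(1), USE.NAMES = FALSE)
}

# Slot (1..15) occupied by each residue of a length-n peptide after middle
# padding; inverse view of pad_middle().
.pad_slots <- function(n) {
  if (n == 15L) return(1:15)
  left <- (15L - n) %/% 2L
  c(1:4,
    if (n > 8L) 4L + left + seq_len(n - 8L) else integer(0),
    12:15)
}

#' Build the padded global-input feature matrix
#'
#' Encodes the middle-padded 15-length sequence column by column; padding
#' slots are all-zero columns and position embeddings are not included. This
#' is the input of the global kernels in the local+global architecture.
#'
#' @inheritParams build_feature_matrix
#' @return A `d_e x 15` numeric matrix.
#' @export
build_global_feature_matrix <- function(peptide, scheme = encoding_scheme(),
                                        deep_table = NULL) {
  if (!inherits(scheme, "peprank_scheme")) scheme <- encoding_scheme(scheme)
  n <- nchar(peptide)
  if (n < 8 || n > 15) {
    abort("peptide length must be 8-15.", class = "peprank_encoding_error")
  }
  enc <- .encoding_table(scheme, deep_table)
  idx <- .peptide_indices(peptide)[[1]]
  FG <- matrix(0, nrow = scheme$d_e, ncol = 15)
  FG[, .pad_slots(n)] <- enc[, idx, drop = FALSE]
  FG
}

#' Read peptides from a FASTA file
#'
#' Minimal FASTA reader for prediction-time peptide lists: returns the
#' concatenated sequence of each record, uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `peptide`.
#' @export
read_peptide_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    abort("not a FASTA file: expected '>' header lines.", class = "peprank_io_error")
  }
  rec <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(trimws(x), collapse = "")), character(1))
  tibble::tibble(name = names, peptide = unname(seqs))
}
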