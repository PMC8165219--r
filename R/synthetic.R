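# Synthetic per-allele affinity tables with a planted anchor motif.
#
# The generator emulates the data regime of curated binding databases: a mix
# of quantitative IC50 and qualitative level entries, duplicated measurements
# with injected conflicts, peptide lengths 8-15 concentrated at 9-11, and
# affinities driven by a position-specific scoring profile whose mass sits at
# two anchor positions (the second residue and the terminal residue).

#' Define a synthetic allele
#'
#' Draws a planted 20 x 15 position-specific scoring profile with
#' large-magnitude, column-centred entries only at the anchor columns
#' (column 15 stands for the terminal position of a peptide of any length).
#' The profile score of a peptide is the sum of its residues' profile entries
#' at the anchor positions; the sigmoid-affine link mapping scores to
#' normalized affinities is calibrated analytically so that about
#' `frac_promising` of random peptides fall below 500 nM.
#'
#' @param name Allele name for the emitted tables.
#' @param anchors Profile columns carrying signal; `15` denotes the terminal
#'   position. Default: second and terminal.
#' @param anchor_sd Spread of the planted anchor entries.
#' @param noise_sd Gaussian noise added on the normalized-affinity scale.
#' @param qualitative_fraction Fraction of entries emitted as qualitative
#'   levels instead of IC50 values.
#' @param conflict_rate Fraction of peptides duplicated with a conflicting
#'   qualitative level (exercises deduplication).
#' @param length_probs Probabilities of peptide lengths 8..15.
#' @param frac_promising Calibration target for the fraction of peptides
#'   under 500 nM.
#' @param seed Integer seed for the profile draw.
#' @return An object of class `peprank_synthetic_allele`.
#' @export
synthetic_allele <- function(name = "SYN-A*01:01", anchors = c(2L, 15L),
                             anchor_sd = 1.5, noise_sd = 0.05,
                             qualitative_fraction = 0.2, conflict_rate = 0.05,
                             length_probs = c(0.08, 0.24, 0.20, 0.16,
                                              0.09, 0.08, 0.08, 0.07),
                             frac_promising = 0.30, seed = 1L) {
  if (any(anchors < 1 | anchors > 15)) {
    abort("anchors must lie in 1..15.", class = "peprank_config_error")
  }
  if (noise_sd < 0 || qualitative_fraction < 0 || qualitative_fraction > 1 ||
      conflict_rate < 0 || conflict_rate > 1) {
    abort("invalid generator configuration.", class = "peprank_config_error")
  }
  if (length(length_probs) != 8 || any(length_probs < 0)) {
    abort("length_probs must give 8 probabilities for lengths 8..15.",
          class = "peprank_config_error")
  }
  withr::with_seed(seed, {
    profile <- matrix(0, 20, 15, dimnames = list(aa_alphabet(), NULL))
    for (j in anchors) {
      v <- rnorm(20, 0, anchor_sd)
      profile[, j] <- v - mean(v)
    }
    # link: b* = plogis(score + a0); choose a0 so P(b* > b(500)) ~ frac_promising
    # under the normal approximation of the anchor-score sum.
    sd_score <- sqrt(sum(apply(profile[, anchors, drop = FALSE], 2,
                               function(v) mean(v^2))))
    a0 <- qlogis(normalize_affinity(500)) - qnorm(1 - frac_promising) * sd_score
    structure(list(name = name, anchors = sort(as.integer(anchors)),
                   profile = profile, intercept = a0, noise_sd = noise_sd,
                   qualitative_fraction = qualitative_fraction,
                   conflict_rate = conflict_rate,
                   length_probs = length_probs / sum(length_probs)),
              class = "peprank_synthetic_allele")
  })
}

# Profile score of peptides: sum over anchor positions of the profile entry
# of the residue there; column 15 of the profile reads the terminal residue.
.profile_score <- function(peptides, allele) {
  idx <- .peptide_indices(peptides)
  vapply(idx, function(ii) {
    n <- length(ii)
    s <- 0
    for (j in allele$anchors) {
      pos <- if (j == 15L) n else j
      if (pos <= n) s <- s + allele$profile[ii[pos], j]
    }
    s
  }, numeric(1))
}

#' Expected motif matrix of a synthetic allele at one peptide length
#'
#' Maps the planted 20 x 15 profile into the raw frame of length-`n`
#' peptides (the terminal column becomes column `n`), for comparison with
#' [smm_like_matrix()] outputs.
#'
#' @param allele A [synthetic_allele()].
#' @param n Peptide length.
#' @return A 20 x `n` matrix.
#' @export
planted_profile_matrix <- function(allele, n = 9L) {
  m <- matrix(0, 20, n, dimnames = list(aa_alphabet(), NULL))
  for (j in allele$anchors) {
    pos <- if (j == 15L) n else j
    if (pos <= n) m[, pos] <- m[, pos] + allele$profile[, j]
  }
  m
}

#' Generate a synthetic affinity table with ground truth
#'
#' Draws peptides uniformly over the alphabet (lengths per the allele's
#' length distribution), computes true normalized affinities
#' `b* = clamp(plogis(profile score + intercept) + N(0, sigma), 0, 1)`,
#' emits IC50 values through the inverse normalization `x = 50000^(1 - b*)`,
#' converts a fraction of entries to qualitative levels, and duplicates a
#' fraction of peptides with a conflicting level.
#'
#' @param allele A [synthetic_allele()].
#' @param n_peptides Number of distinct peptides (>= 1).
#' @param seed Integer seed.
#' @return A list with `data` (raw measurement tibble: `allele`, `peptide`,
#'   `measurement_kind`, `measurement_value`) and `truth` (tibble: `peptide`,
#'   `profile_score`, `b_star`, `ic50`, `level`).
#' @export
generate_dataset <- function(allele, n_peptides, seed = 1L) {
  stopifnot(inherits(allele, "peprank_synthetic_allele"))
  if (n_peptides < 1) abort("n_peptides must be >= 1.", class = "peprank_config_error")
  withr::with_seed(seed, {
    lens <- sample(8:15, n_peptides, replace = TRUE, prob = allele$length_probs)
    peptides <- vapply(lens, function(n) {
      paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
    }, character(1))
    dup <- duplicated(peptides)
    while (any(dup)) {
      peptides[dup] <- vapply(lens[dup], function(n) {
        paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
      }, character(1))
      dup <- duplicated(peptides)
    }
    score <- .profile_score(peptides, allele)
    b_star <- plogis(score + allele$intercept)
    if (allele$noise_sd > 0) b_star <- b_star + rnorm(n_peptides, 0, allele$noise_sd)
    b_star <- pmin(pmax(b_star, 0), 1)
    ic50 <- ic50_from_affinity(b_star)
    level <- affinity_to_level(ic50)
    truth <- tibble::tibble(peptide = peptides, profile_score = score,
                            b_star = b_star, ic50 = ic50, level = level)
    qual <- runif(n_peptides) < allele$qualitative_fraction
    data <- tibble::tibble(
      allele = allele$name, peptide = peptides,
      measurement_kind = ifelse(qual, "qualitative", "quantitative"),
      measurement_value = ifelse(qual, as.numeric(level), ic50))
    n_conf <- round(allele$conflict_rate * n_peptides)
    if (n_conf > 0) {
      who <- sample.int(n_peptides, n_conf)
      other <- vapply(level[who], function(l) {
        sample(setdiff(1:5, l), 1)
      }, numeric(1))
      data <- dplyr::bind_rows(data, tibble::tibble(
        allele = allele$name, peptide = peptides[who],
        measurement_kind = "qualitative", measurement_value = other))
    }
    list(data = data, truth = truth)
  })
}

#' Generate a labelled fixture of ranked predictions
#'
#' Random scores with known positive/negative labels under the 500 nM
#' threshold, for metric property tests: positives get IC50s in (1, 500),
#' negatives in [500, 50000).
#'
#' @param n_pos,n_neg Numbers of positive and negative peptides (>= 0).
#' @param seed Integer seed.
#' @return A tibble with columns `peptide`, `score`, `ic50`, `b`, `level`
#'   and `label` (`"positive"` / `"negative"`).
#' @export
generate_ranked_fixture <- function(n_pos, n_neg, seed = 1L) {
  if (n_pos < 0 || n_neg < 0) abort("counts must be >= 0.", class = "peprank_config_error")
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    ic50 <- c(runif(n_pos, 1, 499.5), runif(n_neg, 500, 50000))
    label <- rep(c("positive", "negative"), c(n_pos, n_neg))
    out <- tibble::tibble(
      peptide = sprintf("PEP%04d", seq_len(n)),
      score = runif(n),
      ic50 = ic50,
      b = if (n > 0) normalize_affinity(ic50) else numeric(0),
      level = if (n > 0) affinity_to_level(ic50) else integer(0),
      label = label)
    out[sample.int(n), , drop = FALSE]
  })
}
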