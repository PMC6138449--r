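# Test-retest reliability of functional connectomes across two sessions:
# connectome fingerprinting (identification success rate), reproducibility of
# the between-subject similarity structure, and reproducibility of the
# edgewise behavioral-utility map.

.check_edge_pair <- function(s1, s2, min_n = 2) {
  .assert(is.matrix(s1) && is.matrix(s2), "edge matrices required")
  .assert(all(dim(s1) == dim(s2)), "edge matrices have mismatched dimensions")
  .assert(identical(rownames(s1), rownames(s2)),
          "edge matrices cover different subjects (row names differ)")
  .assert(nrow(s1) >= min_n, "need at least %d subjects", min_n)
}

#' Connectome fingerprinting: identification success rate (ISR)
#'
#' Identification of a subject is successful when, out of all subjects'
#' session-2 edge vectors, their own is the one most highly Pearson-correlated
#' with their session-1 edge vector. Both identification directions are
#' reported. Ties are broken to the lowest roster index with a warning.
#'
#' @param s1,s2 `edge_matrix` objects (subjects x edges) for the two sessions,
#'   same subjects in the same row order.
#' @return list with `isr` (percentage, session1 -> session2), `isr_reverse`,
#'   `success` and `success_reverse` (logical per subject), and `match_index`
#'   (index of the best-matching session-2 subject per session-1 subject).
#' @export
identification_success_rate <- function(s1, s2) {
  .check_edge_pair(s1, s2)
  cc <- stats::cor(t(unclass(s1)), t(unclass(s2)))  # [i, j] = cor(s1_i, s2_j)
  pick <- function(row) {
    top <- which(row == max(row))
    if (length(top) > 1) .warnf("tie in fingerprint matching; lowest index used")
    top[1]
  }
  match_fwd <- unname(apply(cc, 1, pick))
  match_rev <- unname(apply(cc, 2, pick))
  success <- match_fwd == seq_len(nrow(cc))
  success_rev <- match_rev == seq_len(ncol(cc))
  list(isr = 100 * mean(success),
       isr_reverse = 100 * mean(success_rev),
       success = success, success_reverse = success_rev,
       match_index = match_fwd)
}

#' Test-retest reproducibility of pairwise subject similarity
#'
#' Builds the within-session subject x subject similarity matrix (Pearson
#' correlations between subjects' edge vectors) separately for each session
#' and returns the Pearson correlation between the two matrices over their
#' upper triangles (the diagonal, identically 1, is excluded).
#'
#' @inheritParams identification_success_rate
#' @return Pearson correlation (scalar).
#' @export
similarity_testretest <- function(s1, s2) {
  .check_edge_pair(s1, s2, min_n = 3)
  a1 <- stats::cor(t(unclass(s1)))
  a2 <- stats::cor(t(unclass(s2)))
  stats::cor(vectorize_upper(a1), vectorize_upper(a2))
}

#' Test-retest reproducibility of behavioral utility
#'
#' For each edge, correlates its value with a stable trait score across
#' subjects, separately per session, and returns the Pearson correlation of
#' the two edgewise correlation maps. The more edges relate reliably to the
#' trait, the higher the value.
#'
#' @inheritParams identification_success_rate
#' @param score per-subject trait score (deconfounded scores recommended).
#' @return Pearson correlation (scalar).
#' @export
behavioral_utility_testretest <- function(s1, s2, score) {
  .check_edge_pair(s1, s2, min_n = 3)
  .assert(length(score) == nrow(s1), "score length does not match subjects")
  .assert(stats::var(score) > 0, "trait score is constant")
  u1 <- as.vector(stats::cor(unclass(s1), score))
  u2 <- as.vector(stats::cor(unclass(s2), score))
  ok <- is.finite(u1) & is.finite(u2)   # zero-variance edges drop out
  stats::cor(u1[ok], u2[ok])
}
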