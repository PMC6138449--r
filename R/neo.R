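# NEO-FFI scoring: 60 five-point Likert items (0 = strongly disagree ...
# 4 = strongly agree) summed into the Big Five factor scores after reverse
# coding, plus internal consistency (Cronbach's alpha) and the two
# superordinate principal components of the factor scores.

# Published NEO-FFI item lists; negative sign marks a reverse-coded item
# (reversed value = 4 - raw). Item 59 (Agreeableness) is reverse-coded here;
# an early HCP database release had failed to reverse it.
NEO_ITEM_MAP <- list(
  O = c(-3, -8, 13, -18, -23, 28, -33, -38, 43, -48, 53, 58),
  C = c(5, 10, -15, 20, 25, -30, 35, 40, -45, 50, -55, 60),
  E = c(2, 7, -12, 17, 22, -27, 32, 37, -42, 47, 52, -57),
  A = c(4, -9, -14, 19, -24, -29, 34, -39, -44, 49, -54, -59),
  N = c(-1, 6, 11, -16, 21, 26, -31, 36, 41, -46, 51, 56)
)

NEO_FACTORS <- names(NEO_ITEM_MAP)

.item_cols <- function(items) {
  cols <- paste0("item_", 1:60)
  missing <- setdiff(cols, names(items))
  .assert(length(missing) == 0, "item table is missing columns: %s",
          paste(head(missing, 5), collapse = ", "))
  cols
}

.check_item_values <- function(m, subject_ids) {
  bad <- which(!is.finite(m) | m < 0 | m > 4 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    .stopf("invalid item value (must be integer in 0..4): subject %s, item %d",
           subject_ids[bad[1, 1]], bad[1, 2])
  }
}

# reverse-corrected ("coded") item scores for one factor, subjects x 12
.coded_items <- function(m, factor) {
  spec <- NEO_ITEM_MAP[[factor]]
  x <- m[, abs(spec), drop = FALSE]
  rev <- spec < 0
  x[, rev] <- 4 - x[, rev, drop = FALSE]
  x
}

#' Score NEO-FFI item responses into Big Five factor scores
#'
#' Each factor is the sum of its 12 items after reverse coding
#' (reversed value = 4 - raw value), giving integer scores in 0..48.
#'
#' @param items data frame with `subject_id` and `item_1` .. `item_60`
#'   columns, values integer in 0..4.
#' @return data frame with `subject_id` and integer columns `O`, `C`, `E`,
#'   `A`, `N`.
#' @export
score_neoffi <- function(items) {
  cols <- .item_cols(items)
  m <- as.matrix(items[, cols])
  ids <- as.character(items$subject_id %||% seq_len(nrow(m)))
  .check_item_values(m, ids)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (f in NEO_FACTORS) out[[f]] <- as.integer(rowSums(.coded_items(m, f)))
  out
}

#' Cronbach's alpha for one Big Five factor
#'
#' Internal consistency of the 12 reverse-corrected items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the sum)`,
#' with `k = 12` and n-1 sample variances.
#'
#' @param items item response table as for [score_neoffi()].
#' @param factor one of `"O"`, `"C"`, `"E"`, `"A"`, `"N"`.
#' @export
cronbach_alpha <- function(items, factor = NEO_FACTORS) {
  factor <- match.arg(factor)
  cols <- .item_cols(items)
  m <- as.matrix(items[, cols])
  .assert(nrow(m) >= 2, "need at least 2 subjects")
  x <- .coded_items(m, factor)
  total_var <- stats::var(rowSums(x))
  .assert(total_var > 0, "total score variance is zero; alpha is undefined")
  k <- ncol(x)
  item_var <- sum(apply(x, 2, stats::var))
  (k / (k - 1)) * (1 - item_var / total_var)
}

#' Superordinate personality components (alpha and beta)
#'
#' PCA of the five standardized factor scores (correlation-matrix PCA); the
#' first two components are retained as the superordinate dimensions
#' conventionally called alpha (loading mostly on Neuroticism, reversed, and
#' the socialization factors) and beta (loading mostly on Openness /
#' Extraversion). Each component's sign is fixed so its largest-|loading|
#' factor loads positively; scores are scaled to unit variance.
#'
#' @param scores data frame from [score_neoffi()] (columns `O`..`N`).
#' @return list with `scores` (data frame: `subject_id`, `alpha`, `beta`),
#'   `loadings` (5 x 2), `variance_explained` (length-2, fractions of 5).
#' @export
superordinate_pca <- function(scores) {
  x <- as.matrix(scores[, NEO_FACTORS])
  .assert(nrow(x) >= 5, "need at least 5 subjects")
  v <- apply(x, 2, stats::var)
  .assert(all(v > 0), "factor(s) with zero variance: %s",
          paste(NEO_FACTORS[v == 0], collapse = ", "))
  xs <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  .assert(eg$values[2] > 1e-10, "factor scores are rank-deficient")
  load <- eg$vectors[, 1:2, drop = FALSE]
  rownames(load) <- NEO_FACTORS
  colnames(load) <- c("alpha", "beta")
  for (k in 1:2) {                      # orient: top-|loading| factor positive
    top <- which.max(abs(load[, k]))
    if (load[top, k] < 0) load[, k] <- -load[, k]
  }
  comp <- xs %*% load
  comp <- sweep(comp, 2, sqrt(eg$values[1:2]), "/")  # unit-variance scores
  list(
    scores = data.frame(subject_id = as.character(scores$subject_id %||% seq_len(nrow(x))),
                        alpha = comp[, 1], beta = comp[, 2],
                        stringsAsFactors = FALSE),
    loadings = load,
    variance_explained = eg$values[1:2] / length(NEO_FACTORS)
  )
}
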