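# Functional connectome construction: Pearson FC over retained volumes,
# Fisher-z transform, run/session averaging in z-space, and upper-triangle
# edge vectorization into subject x edge matrices.

# guard against atanh(+-1) blowing up on (near-)perfectly correlated channels
.FC_R_CAP <- 1 - 1e-7

#' Number of unique edges of an undirected connectome
#'
#' @param n_parcels number of parcels (nodes); must be >= 2.
#' @return `n_parcels * (n_parcels - 1) / 2`.
#' @examples
#' n_edges(268) # 35778
#' n_edges(360) # 64620
#' @export
n_edges <- function(n_parcels) {
  .assert(length(n_parcels) == 1 && is.finite(n_parcels) && n_parcels >= 2 &&
            n_parcels == round(n_parcels),
          "n_parcels must be a single integer >= 2 (got %s)", format(n_parcels))
  as.integer(n_parcels * (n_parcels - 1) / 2)
}

#' Edge index pairs in canonical order
#'
#' Row-major upper-triangle order: (1,2), (1,3), ..., (1,p), (2,3), ...
#' This is the edge order used by [vectorize_upper()] and all edge matrices.
#'
#' @param n_parcels number of parcels.
#' @return two-column integer matrix (`i`, `j`) with `i < j`.
#' @export
edge_pairs <- function(n_parcels) {
  p <- n_parcels
  .assert(p >= 2, "n_parcels must be >= 2")
  i <- rep.int(seq_len(p - 1), times = (p - 1):1)
  j <- unlist(lapply(seq_len(p - 1), function(k) (k + 1):p), use.names = FALSE)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Fisher-z functional connectivity matrix of one run
#'
#' Pearson-correlates parcel channels over retained (non-censored) time
#' points, caps |r| at 1 - 1e-7, and applies the Fisher z transform
#' (`atanh`). The diagonal is set to 0.
#'
#' @param run a `run_timeseries` object (see [generate_run_timeseries()]).
#' @return an `fc_matrix`: symmetric `n_parcels x n_parcels` matrix of
#'   Fisher-z values with attributes `subject_id` and `session`.
#' @export
fc_matrix <- function(run) {
  .assert(inherits(run, "run_timeseries"), "run must be a run_timeseries")
  keep <- run$censor_mask
  .assert(sum(keep) >= 3, "need >= 3 retained time points (got %d)", sum(keep))
  x <- run$channels[keep, run$roles == "parcel", drop = FALSE]
  .assert(ncol(x) >= 2, "run has fewer than 2 parcel channels")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    .stopf("zero-variance parcel channel(s) over retained points: %s",
           paste(which(v == 0), collapse = ", "))
  }
  r <- stats::cor(x)
  r <- pmin(pmax(r, -.FC_R_CAP), .FC_R_CAP)
  z <- atanh(r)
  diag(z) <- 0
  structure(z, class = c("fc_matrix", "matrix"),
            subject_id = run$subject_id,
            session = sub("_(LR|RL)$", "", run$run_label))
}

#' Average FC matrices in Fisher-z space
#'
#' Element-wise arithmetic mean of already-z-transformed matrices; the result
#' stays on the Fisher-z scale.
#'
#' @param matrices list of `fc_matrix` objects from the same subject with the
#'   same dimension.
#' @param session optional session label for the result (e.g. "REST1",
#'   "REST12").
#' @export
average_fc <- function(matrices, session = NULL) {
  .assert(length(matrices) >= 1, "need at least one matrix")
  dims <- vapply(matrices, nrow, 1L)
  .assert(all(dims == dims[1]), "FC matrices have mismatched dimensions")
  ids <- unique(vapply(matrices, function(m) as.character(attr(m, "subject_id") %||% NA),
                       character(1)))
  .assert(length(ids) == 1, "FC matrices come from different subjects: %s",
          paste(ids, collapse = ", "))
  out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(out, class = c("fc_matrix", "matrix"),
            subject_id = attr(matrices[[1]], "subject_id"),
            session = session %||% attr(matrices[[1]], "session"))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Row-major order over `i < j`: (1,2), (1,3), ..., (1,p), (2,3), ... The
#' lower triangle is discarded (the matrix must be symmetric).
#'
#' @param m symmetric matrix.
#' @param tol maximum tolerated asymmetry.
#' @return numeric vector of length `n_edges(nrow(m))`.
#' @export
vectorize_upper <- function(m, tol = 1e-10) {
  m <- unclass(m)
  .assert(is.matrix(m) && nrow(m) == ncol(m), "m must be a square matrix")
  asym <- max(abs(m - t(m)))
  .assert(asym <= tol, "matrix is asymmetric (max |m - t(m)| = %g)", asym)
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' Inverse of [vectorize_upper()] on the upper triangle.
#'
#' @param v edge vector in canonical order.
#' @param n_parcels matrix dimension.
#' @export
unvectorize <- function(v, n_parcels) {
  .assert(length(v) == n_edges(n_parcels),
          "edge vector length %d does not match n_parcels=%d (expect %d)",
          length(v), n_parcels, n_edges(n_parcels))
  m <- matrix(0, n_parcels, n_parcels)
  m[lower.tri(m)] <- v          # column-major lower = row-major upper of t(m)
  m <- t(m)
  m + t(m)
}

#' Stack per-subject edge vectors into a subjects x edges matrix
#'
#' @param vectors list of edge vectors (or `fc_matrix` objects, which are
#'   vectorized first), in roster order.
#' @param subject_ids character vector of subject ids (row names).
#' @param session session label carried as an attribute.
#' @return an `edge_matrix`: numeric matrix, one row per subject.
#' @export
stack_subjects <- function(vectors, subject_ids = names(vectors), session = NULL) {
  vecs <- lapply(vectors, function(v) {
    if (inherits(v, "fc_matrix")) vectorize_upper(v) else as.numeric(v)
  })
  len <- unique(vapply(vecs, length, 1L))
  .assert(length(len) == 1, "edge vectors have differing lengths")
  x <- do.call(rbind, vecs)
  rownames(x) <- subject_ids %||% as.character(seq_len(nrow(x)))
  structure(x, class = c("edge_matrix", "matrix"), session = session)
}
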