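# Interchange I/O (plain TSV + JSON), table validation, and the end-to-end
# experiment driver tying simulation, denoising, connectome construction,
# prediction and permutation inference together.

#' Write / read a subject roster
#'
#' @param cohort cohort data frame.
#' @param path TSV path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("cohort", "data.frame")
  x
}

#' Write / read an item response table
#'
#' @param items item response table.
#' @param path TSV path.
#' @export
write_items_tsv <- function(items, path) {
  utils::write.table(items, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_items_tsv
#' @export
read_items_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a subjects x edges matrix
#'
#' Columns are named `e<i>_<j>` after the canonical edge order of
#' [edge_pairs()]; subject ids are stored in the first column.
#'
#' @param edges `edge_matrix`.
#' @param path TSV path.
#' @param n_parcels parcel count (to name edge columns); inferred on read.
#' @export
write_edges_tsv <- function(edges, path, n_parcels = NULL) {
  x <- as.data.frame(unclass(edges))
  if (!is.null(n_parcels)) {
    ep <- edge_pairs(n_parcels)
    names(x) <- sprintf("e%d_%d", ep[, 1], ep[, 2])
  }
  x <- cbind(subject_id = rownames(edges), x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$subject_id
  structure(m, class = c("edge_matrix", "matrix"))
}

#' Serialize / restore ground truth as JSON
#'
#' Ground truth round-trips exactly enough for parameter-recovery tests
#' (full double precision).
#'
#' @param truth `ground_truth` object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$traits <- as.matrix(x$traits)
  colnames(x$traits) <- NEO_FACTORS
  x$fam_comp <- as.matrix(x$fam_comp)
  x$sub_comp <- as.matrix(x$sub_comp)
  x$signal <- lapply(x$signal, function(s) {
    list(edges = as.integer(s$edges), effect = s$effect)
  })
  x$confound_edges <- lapply(x$confound_edges, function(s) {
    list(edges = as.integer(s$edges), effect = s$effect,
         latent = as.numeric(s$latent))
  })
  structure(x, class = "ground_truth")
}

#' Write / read one run's labeled time series
#'
#' Channels, motion parameters and the FD trace share one wide TSV; a
#' `#roles:` header line records each column's role.
#'
#' @param run `run_timeseries`.
#' @param path TSV path.
#' @export
write_run_tsv <- function(run, path) {
  m <- cbind(run$channels, run$motion, fd = run$fd,
             censor = as.integer(run$censor_mask))
  roles <- c(run$roles, rep("motion", 6), "fd", "censor")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#subject:%s run:%s tr_s:%g", run$subject_id,
                     run$run_label, run$tr_s), con)
  writeLines(paste0("#roles:", paste(roles, collapse = "\t")), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_tsv
#' @export
read_run_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- regmatches(hdr[1], regexec("#subject:(\\S+) run:(\\S+) tr_s:(\\S+)", hdr[1]))[[1]]
  roles <- strsplit(sub("^#roles:", "", hdr[2]), "\t")[[1]]
  m <- as.matrix(utils::read.delim(path, skip = 2, check.names = FALSE))
  ch <- roles %in% c("parcel", "wm", "csf", "global")
  structure(list(subject_id = meta[2], run_label = meta[3],
                 tr_s = as.numeric(meta[4]),
                 channels = m[, ch, drop = FALSE],
                 roles = roles[ch],
                 motion = m[, roles == "motion", drop = FALSE],
                 fd = m[, roles == "fd"],
                 censor_mask = m[, roles == "censor"] == 1),
            class = "run_timeseries")
}

#' Validate interchange tables
#'
#' Schema and cross-reference checks for the TSV/JSON interchange files:
#' required columns, integer 0..4 item values, subject-id agreement between
#' roster and edges/items files. Problems are reported, never silently
#' coerced.
#'
#' @param cohort_path subjects TSV (required).
#' @param items_path optional items TSV.
#' @param edges_path optional edges TSV.
#' @return character vector of problems (empty when everything checks out).
#' @export
validate_tables <- function(cohort_path, items_path = NULL, edges_path = NULL) {
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  cohort <- utils::read.delim(cohort_path, stringsAsFactors = FALSE)
  for (col in c("subject_id", "family_id", "mmse")) {
    if (!col %in% names(cohort)) note("subjects table: missing column '%s'", col)
  }
  ids <- as.character(cohort$subject_id)
  if (anyDuplicated(ids)) note("subjects table: duplicated subject ids")
  if (!is.null(items_path)) {
    items <- utils::read.delim(items_path, stringsAsFactors = FALSE)
    miss <- setdiff(paste0("item_", 1:60), names(items))
    if (length(miss) > 0) note("items table: missing %d item column(s)", length(miss))
    m <- as.matrix(items[, intersect(paste0("item_", 1:60), names(items))])
    if (any(!is.finite(m) | m != round(m) | m < 0 | m > 4)) {
      note("items table: non-integer or out-of-range item values")
    }
    extra <- setdiff(as.character(items$subject_id), ids)
    if (length(extra) > 0) {
      note("items table: subject(s) missing from roster: %s",
           paste(head(extra, 3), collapse = ", "))
    }
  }
  if (!is.null(edges_path)) {
    edges <- read_edges_tsv(edges_path)
    extra <- setdiff(rownames(edges), ids)
    if (length(extra) > 0) {
      note("edges table: subject(s) missing from roster: %s",
           paste(head(extra, 3), collapse = ", "))
    }
    if (any(!is.finite(edges))) note("edges table: non-finite edge values")
  }
  problems
}

#' Experiment configuration
#'
#' One cell of the analysis grid (session x denoising pipeline x model), plus
#' the synthetic-cohort parameters, fully serializable so that every result
#' embeds the configuration that produced it.
#'
#' @param n_subjects,n_parcels,n_timepoints,seed synthetic cohort and
#'   acquisition parameters.
#' @param pipeline denoising pipeline (`"A"`, `"B"`, `"C"`).
#' @param session `"REST1"`, `"REST2"` or `"REST12"`.
#' @param target predicted score: one of `"O","C","E","A","N"`, `"alpha"`,
#'   `"beta"`, `"gF"`.
#' @param model prediction model (see [model_config()]).
#' @param deconfound deconfounding set.
#' @param n_perm permutations for significance (0 to skip).
#' @param tr_s repetition time, seconds.
#' @export
experiment_config <- function(n_subjects = 60, n_parcels = 30,
                              n_timepoints = 300, seed = 1,
                              pipeline = "A",
                              session = c("REST12", "REST1", "REST2"),
                              target = "O",
                              model = "univariate_pos",
                              deconfound = "full",
                              n_perm = 0, tr_s = 0.72) {
  session <- match.arg(session)
  .assert(target %in% c(NEO_FACTORS, "alpha", "beta", "gF"),
          "unknown target '%s'", target)
  structure(list(n_subjects = n_subjects, n_parcels = n_parcels,
                 n_timepoints = n_timepoints, seed = seed,
                 pipeline = pipeline, session = session, target = target,
                 model = model, deconfound = deconfound, n_perm = n_perm,
                 tr_s = tr_s),
            class = "experiment_config")
}

# session label -> run labels entering the FC average
.session_runs <- function(session) {
  switch(session,
         REST1 = RUN_LABELS[1:2],
         REST2 = RUN_LABELS[3:4],
         REST12 = RUN_LABELS)
}

#' Run one end-to-end experiment
#'
#' Simulate -> denoise -> per-run FC -> Fisher-z session average -> score
#' items -> deconfound + leave-one-family-out prediction -> evaluation
#' (-> permutation test when `n_perm > 0`). Deterministic given the
#' configuration.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, result JSON and the
#'   observed/predicted table are written there.
#' @return list with `config`, `metrics`, `prediction` and (optionally)
#'   `permutation`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  .assert(inherits(config, "experiment_config"),
          "config must come from experiment_config()")
  sim <- generate_cohort(cohort_spec(n_subjects = config$n_subjects,
                                     n_parcels = config$n_parcels,
                                     seed = config$seed))
  cohort <- sim$cohort

  dcfg <- denoise_config(config$pipeline)
  clean_input <- config$pipeline == "C"   # pipeline C consumes FIX-like input
  per_run_fc <- lapply(.session_runs(config$session), function(lbl) {
    runs <- generate_run_timeseries(cohort, sim$truth, lbl,
                                    n_timepoints = config$n_timepoints,
                                    tr_s = config$tr_s, clean = clean_input)
    lapply(runs, function(r) fc_matrix(denoise(r, dcfg)))
  })
  fc <- lapply(seq_len(nrow(cohort)), function(s) {
    average_fc(lapply(per_run_fc, `[[`, s), session = config$session)
  })
  X <- stack_subjects(fc, cohort$subject_id, session = config$session)

  items <- generate_item_responses(cohort, latent_trait_model(),
                                   seed = config$seed)
  traits <- score_neoffi(items)
  y <- if (config$target %in% NEO_FACTORS) {
    traits[[config$target]]
  } else if (config$target %in% c("alpha", "beta")) {
    superordinate_pca(traits)$scores[[config$target]]
  } else {
    cohort$gF
  }

  mcfg <- model_config(config$model, deconfound_set = config$deconfound,
                       target = config$target)
  pred <- predict_cv(X, y, cohort, cohort$family_id, mcfg)
  metrics <- evaluate_predictions(pred$observed, pred$predicted)
  out <- list(config = unclass(config), metrics = metrics, prediction = pred)
  if (config$n_perm > 0) {
    out$permutation <- permutation_test(X, y, cohort, cohort$family_id, mcfg,
                                        n_perm = config$n_perm,
                                        seed = config$seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), metrics = metrics,
           p = out$permutation$p %||% NULL),
      file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(subject_id = cohort$subject_id, observed = pred$observed,
                 predicted = pred$predicted, fold = pred$fold),
      file.path(out_dir, "predictions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  out
}
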