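#' Score every dyad of a cohort
#'
#' For each manifest row, loads (or takes from memory) the maternal and
#' fetal beat series, converts them to tachograms, selects artifact-free
#' epochs and scores each with [score_epoch()]. Dyads that fail loading or
#' epoch selection are kept as rows flagged `excluded` with the reason
#' logged as a warning; the run continues.
#'
#' @param cohort an `mf_cohort` from [simulate_cohort()], or a manifest
#'   data.frame with columns `mother_id, fetus_id, ed, group,
#'   maternal_file, fetal_file` pointing at beat CSVs.
#' @param config a [similarity_config()].
#' @param epoch_len_ms,n_epochs,quality,discard_ms passed to
#'   [select_epochs()].
#' @param require_complete exclude dyads with fewer than `n_epochs` clean
#'   epochs (default `TRUE`, the conventional inclusion rule).
#' @return scores data.frame, one row per (dyad, epoch): `mother_id,
#'   fetus_id, epoch_index, start_ms, end_ms, ed, group, cc1, cc2, clf,
#'   chf, n_valid_windows, excluded, reason`.
#' @export
analyze_cohort <- function(cohort, config = similarity_config(),
                           epoch_len_ms = 180000, n_epochs = 2,
                           quality = quality_config(), discard_ms = 60000,
                           require_complete = TRUE) {
  if (inherits(cohort, "mf_cohort")) {
    manifest <- cohort$manifest
    dyads <- cohort$dyads
  } else {
    manifest <- cohort
    dyads <- NULL
  }
  needed <- c("mother_id", "fetus_id", "ed", "group")
  stopifnot(all(needed %in% names(manifest)))
  rows <- list()
  excluded_row <- function(mrow, reason) {
    warning("dyad ", mrow$fetus_id, " excluded: ", reason, call. = FALSE)
    data.frame(mother_id = mrow$mother_id, fetus_id = mrow$fetus_id,
               epoch_index = NA_integer_, start_ms = NA_real_,
               end_ms = NA_real_, ed = mrow$ed, group = mrow$group,
               cc1 = NA_real_, cc2 = NA_real_, clf = NA_real_,
               chf = NA_real_, n_valid_windows = NA_integer_,
               excluded = TRUE, reason = reason, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, , drop = FALSE]
    res <- tryCatch({
      if (!is.null(dyads)) {
        dy <- dyads[[mrow$fetus_id]]
        maternal <- beats_to_rri(dy$maternal)
        fetal <- beats_to_rri(dy$fetal)
      } else {
        maternal <- beats_to_rri(read_beats(mrow$maternal_file,
                                            role = "maternal"))
        fetal <- beats_to_rri(read_beats(mrow$fetal_file, role = "fetal"))
      }
      epochs <- select_epochs(maternal, fetal, epoch_len_ms = epoch_len_ms,
                              n_epochs = n_epochs, quality = quality,
                              discard_ms = discard_ms)
      if (length(epochs) == 0L)
        stop("no clean epoch found")
      if (require_complete && !attr(epochs, "complete"))
        stop("only ", length(epochs), " of ", n_epochs,
             " required clean epochs found")
      do.call(rbind, lapply(seq_along(epochs), function(k) {
        fit <- score_epoch(epochs[[k]], config = config)
        data.frame(mother_id = mrow$mother_id, fetus_id = mrow$fetus_id,
                   epoch_index = k, start_ms = epochs[[k]]$start_ms,
                   end_ms = epochs[[k]]$end_ms, ed = mrow$ed,
                   group = mrow$group, cc1 = fit$cc1, cc2 = fit$cc2,
                   clf = fit$clf, chf = fit$chf,
                   n_valid_windows = fit$n_valid_windows,
                   excluded = FALSE, reason = "", stringsAsFactors = FALSE)
      }))
    }, error = function(e) excluded_row(mrow, conditionMessage(e)))
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort to disk (pipeline command)
#'
#' Thin command wrapper over [cohort_scenario()] + [simulate_cohort()].
#'
#' @param scenario `"development"` or `"asd"`.
#' @param seed master seed.
#' @param outdir output directory for beat CSVs and `manifest.csv`.
#' @param overwrite allow writing into a non-empty directory.
#' @return the `mf_cohort`, invisibly.
#' @export
cmd_simulate <- function(scenario = "development", seed = 1, outdir,
                         overwrite = FALSE) {
  sc <- cohort_scenario(name = scenario)
  invisible(simulate_cohort(sc, seed = seed, outdir = outdir,
                            overwrite = overwrite))
}

#' Score a cohort from a manifest (pipeline command)
#'
#' Reads `manifest`, scores every dyad with [analyze_cohort()], and writes
#' `scores.csv` plus a small `run_info.txt` (seedless: the analysis is
#' deterministic) into `outdir`.
#'
#' @param manifest path to a manifest CSV.
#' @param outdir output directory (created if needed).
#' @param config a [similarity_config()].
#' @param ... passed to [analyze_cohort()].
#' @return the scores data.frame, invisibly.
#' @export
cmd_analyze <- function(manifest, outdir, config = similarity_config(),
                        ...) {
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  for (col in c("maternal_file", "fetal_file")) {
    rel <- !file.exists(man[[col]]) & file.exists(file.path(base, basename(man[[col]])))
    man[[col]][rel] <- file.path(base, basename(man[[col]])[rel])
  }
  scores <- analyze_cohort(man, config = config, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scores, file.path(outdir, "scores.csv"),
                   row.names = FALSE)
  writeLines(c(paste0("mfcoupling ", as.character(utils::packageVersion("mfcoupling"))),
               paste0("manifest: ", manifest),
               paste0("dyads: ", nrow(man)),
               paste0("rows: ", nrow(scores)),
               paste0("excluded dyads: ",
                      length(unique(scores$fetus_id[scores$excluded])))),
             file.path(outdir, "run_info.txt"))
  invisible(scores)
}

#' Run the statistical battery on a scores file (pipeline command)
#'
#' @param scores path to a `scores.csv` written by [cmd_analyze()].
#' @param design `"development"` or `"asd"`.
#' @param outdir output directory; writes `trends.csv` (development
#'   design), `comparisons.csv` and `report.txt`.
#' @param ... passed to [cohort_stats()].
#' @return the [cohort_stats()] list, invisibly.
#' @export
cmd_stats <- function(scores, design = c("development", "asd"), outdir,
                      ...) {
  design <- match.arg(design)
  if (!file.exists(scores))
    stop("scores file not found: ", scores)
  tab <- utils::read.csv(scores, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    stop("scores file is empty")
  st <- cohort_stats(tab, design = design, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(st$trends))
    utils::write.csv(st$trends, file.path(outdir, "trends.csv"),
                     row.names = FALSE)
  utils::write.csv(st$comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  rep <- utils::capture.output({
    cat("mfcoupling statistical report\n")
    cat("design:", design, "\n\n")
    if (!is.null(st$trends)) {
      cat("Trends with embryonic day:\n")
      print(st$trends, row.names = FALSE)
      cat("\n")
    }
    cat("Group comparisons:\n")
    print(st$comparisons, row.names = FALSE)
  })
  writeLines(rep, file.path(outdir, "report.txt"))
  invisible(st)
}
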