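# End-to-end orchestration: simulate -> build/filter -> metrics (+nulls) ->
# harmonize -> RCI -> mixed models / FDR / effect sizes -> results tables.
# All intermediate artifacts are plain text; a fixed config + seed reproduces
# every output byte-identically.

#' Pipeline run configuration
#'
#' @param out_dir Run directory (created; outputs written beneath it).
#' @param cohort A [cohort_config()] used when simulating; `NULL` to read
#'   existing `phenotype.csv` / `symptoms.csv` / `matrices/` from `in_dir`.
#' @param in_dir Input directory for non-simulated runs.
#' @param n_null Null networks per scan for small-worldness (production 1000;
#'   demo 50).
#' @param harmonize Apply site harmonization?
#' @param batch_column Phenotype column used as harmonization batch label.
#' @param rci_threshold Reliable-change cutoff z.
#' @param rci_reference `"all"` or `"oi"` reference sample.
#' @param fdr_alpha_injury,fdr_alpha_symptom FDR levels for the 2-level and
#'   3-level analyses.
#' @param groupings Analyses to run: subset of
#'   `c("injury", "symptom_parent", "symptom_child")`.
#' @param metric_names Metrics to model (default: all computed).
#' @param probe Probe significant interactions?
#' @param seed Global seed; per-stage and per-scan streams are derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_config(),
                       in_dir = NULL,
                       n_null = 1000L,
                       harmonize = TRUE,
                       batch_column = "site",
                       rci_threshold = 1.645,
                       rci_reference = "all",
                       fdr_alpha_injury = 0.05,
                       fdr_alpha_symptom = 0.025,
                       groupings = c("injury", "symptom_parent", "symptom_child"),
                       metric_names = NULL,
                       probe = TRUE,
                       seed = 1L) {
  if (fdr_alpha_injury <= 0 || fdr_alpha_injury >= 1 ||
      fdr_alpha_symptom <= 0 || fdr_alpha_symptom >= 1)
    stop("FDR alphas must lie in (0, 1)")
  if (is.null(cohort) && is.null(in_dir))
    stop("either a cohort config (simulate) or in_dir (load) is required")
  structure(list(out_dir = out_dir, cohort = cohort, in_dir = in_dir,
                 n_null = as.integer(n_null), harmonize = harmonize,
                 batch_column = batch_column, rci_threshold = rci_threshold,
                 rci_reference = rci_reference,
                 fdr_alpha_injury = fdr_alpha_injury,
                 fdr_alpha_symptom = fdr_alpha_symptom,
                 groupings = groupings, metric_names = metric_names,
                 probe = probe, seed = as.integer(seed)),
            class = "run_config")
}

#' Demo-scale run configuration
#'
#' Small cohort (60 TBI / 30 OI) with 50 null networks per scan and a
#' reduced metric set; completes in minutes and exercises every stage.
#'
#' @param out_dir Run directory.
#' @param seed Global seed.
#' @param ... Overrides passed to [run_config()].
#' @export
demo_run_config <- function(out_dir, seed = 1L, ...) {
  run_config(
    out_dir = out_dir,
    cohort = cohort_config(n_tbi = 60L, n_oi = 30L, seed = seed),
    n_null = 50L,
    metric_names = c("Cp", "Lp", "sigma", "Eg", "NCp"),
    groupings = c("injury", "symptom_parent"),
    seed = seed,
    ...
  )
}

pipeline_stage_error <- function(stage, e, context = NULL) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = paste0("stage '", stage, "' failed",
                                       if (!is.null(context)) paste0(" (", context, ")"),
                                       ": ", conditionMessage(e)),
                      call = NULL, stage = stage)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> connectome filter -> graph metrics with
#' null-network standardization -> site harmonization -> reliable-change
#' symptom classification -> mixed-effects inference with FDR, effect sizes
#' and interaction probes. Every stage writes its outputs under
#' `config$out_dir`; rerunning with an identical config and seed reproduces
#' `results.csv` byte-identically.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the run directory path.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[pedconnectome] ", ...)

  # -- stage: simulate or load ------------------------------------------------
  if (!is.null(config$cohort)) {
    say("simulating cohort")
    study <- tryCatch(simulate_study(config$cohort),
                      error = function(e) pipeline_stage_error("simulate", e))
    write_study(study, config$out_dir)
    participants <- study$participants
    visits <- study$visits
    symptoms <- study$symptoms
    matrices <- study$matrices
    phenotype <- merge(visits, participants, by = "participant_id")
  } else {
    say("loading inputs from ", config$in_dir)
    phenotype <- utils::read.csv(file.path(config$in_dir, "phenotype.csv"),
                                 stringsAsFactors = FALSE)
    symptoms <- utils::read.csv(file.path(config$in_dir, "symptoms.csv"),
                                stringsAsFactors = FALSE)
    participants <- unique(phenotype[, c("participant_id", "group", "site",
                                         "sex", "age_at_injury")])
    mfiles <- list.files(file.path(config$in_dir, "matrices"),
                         pattern = "\\.txt$", full.names = TRUE)
    matrices <- lapply(mfiles, read_matrix_txt)
    names(matrices) <- sub("\\.txt$", "", basename(mfiles))
  }

  # -- stage: connectedness filter -------------------------------------------
  say("filtering scans (fully-connected criterion)")
  flt <- tryCatch(filter_scans(matrices),
                  error = function(e) pipeline_stage_error("filter", e))
  utils::write.csv(flt$excluded, file.path(config$out_dir, "excluded_scans.csv"),
                   row.names = FALSE)
  say(length(flt$kept), " scans kept, ", nrow(flt$excluded), " excluded")
  if (length(flt$kept) == 0L)
    pipeline_stage_error("filter", simpleError("no fully connected scans"))

  # -- stage: graph metrics ---------------------------------------------------
  say("computing graph metrics (", config$n_null, " nulls/scan)")
  per_scan <- vector("list", length(flt$kept))
  for (i in seq_along(flt$kept)) {
    id <- names(flt$kept)[i]
    per_scan[[i]] <- tryCatch(
      compute_scan_metrics(flt$kept[[i]], n_null = config$n_null,
                           seed = derive_seed(config$seed, "null", id),
                           scan_id = id),
      error = function(e) pipeline_stage_error("metrics", e, context = id))
  }
  metrics <- metrics_long_table(per_scan)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  phenotype <- phenotype[phenotype$scan_id %in% names(flt$kept), ]

  # -- stage: harmonization ---------------------------------------------------
  if (config$harmonize) {
    say("harmonizing site effects")
    hz <- tryCatch(
      harmonize_metrics(metrics, phenotype, batch_column = config$batch_column),
      error = function(e) pipeline_stage_error("harmonize", e))
    metrics_h <- hz$metrics
    write_harmonization_model(hz$model,
                              file.path(config$out_dir, "harmonization_model.json"))
  } else {
    metrics_h <- metrics
  }
  utils::write.csv(metrics_h, file.path(config$out_dir, "metrics_harmonized.csv"),
                   row.names = FALSE)

  # -- stage: RCI -------------------------------------------------------------
  say("classifying symptom persistence (RCI)")
  rci <- tryCatch(
    rci_from_tables(symptoms, participants, reference = config$rci_reference,
                    threshold_z = config$rci_threshold),
    error = function(e) pipeline_stage_error("rci", e))
  utils::write.csv(rci$classifications,
                   file.path(config$out_dir, "classifications.csv"),
                   row.names = FALSE)
  write_rci_models(rci$models, file.path(config$out_dir, "rci_models.json"))
  symptom_groups <- assign_symptom_groups(rci$classifications, participants)

  # -- stage: inference -------------------------------------------------------
  say("fitting mixed-effects models")
  results <- list()
  for (g in config$groupings) {
    res <- tryCatch({
      if (g == "injury") {
        analyze_metrics(metrics_h, phenotype, grouping = "injury",
                        metric_names = config$metric_names,
                        fdr_alpha = config$fdr_alpha_injury,
                        probe = config$probe)
      } else {
        rater <- sub("^symptom_", "", g)
        analyze_metrics(metrics_h, phenotype, grouping = "symptom",
                        symptom_groups = symptom_groups, rater = rater,
                        metric_names = config$metric_names,
                        fdr_alpha = config$fdr_alpha_symptom,
                        probe = config$probe)
      }
    }, error = function(e) pipeline_stage_error("fit", e, context = g))
    results[[g]] <- res
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "pedconnectome",
    version = as.character(utils::packageVersion("pedconnectome")),
    seed = config$seed,
    n_null = config$n_null,
    harmonize = config$harmonize,
    groupings = config$groupings,
    rci_threshold = config$rci_threshold,
    fdr_alpha_injury = config$fdr_alpha_injury,
    fdr_alpha_symptom = config$fdr_alpha_symptom,
    n_scans_kept = length(flt$kept),
    n_scans_excluded = nrow(flt$excluded),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", config$out_dir)
  invisible(config$out_dir)
}

#' Validate pipeline input files
#'
#' Schema checks for `phenotype.csv`, `symptoms.csv` and matrix text files:
#' missing columns, malformed rows, asymmetric matrices and out-of-range FA
#' values are listed; nothing errors (report-only).
#'
#' @param dir Directory holding `phenotype.csv`, `symptoms.csv`, `matrices/`.
#' @return data.frame `file`, `issue` (zero rows when everything is well
#'   formed).
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(file, issue)
    issues[[length(issues) + 1L]] <<- data.frame(file = file, issue = issue,
                                                 stringsAsFactors = FALSE)
  ph_path <- file.path(dir, "phenotype.csv")
  if (!file.exists(ph_path)) note("phenotype.csv", "missing file")
  else {
    ph <- utils::read.csv(ph_path, stringsAsFactors = FALSE)
    need <- c("participant_id", "scan_id", "group", "site", "sex",
              "age_at_injury", "days_post_injury", "visit")
    miss <- setdiff(need, names(ph))
    if (length(miss)) note("phenotype.csv",
                           paste("missing columns:", paste(miss, collapse = ",")))
    if ("group" %in% names(ph) && !all(ph$group %in% c("TBI", "OI")))
      note("phenotype.csv", "group values outside {TBI, OI}")
    if ("days_post_injury" %in% names(ph) && any(ph$days_post_injury < 0, na.rm = TRUE))
      note("phenotype.csv", "negative days_post_injury")
  }
  sy_path <- file.path(dir, "symptoms.csv")
  if (!file.exists(sy_path)) note("symptoms.csv", "missing file")
  else {
    sy <- utils::read.csv(sy_path, stringsAsFactors = FALSE)
    need <- c("participant_id", "rater", "timepoint", "total_score")
    miss <- setdiff(need, names(sy))
    if (length(miss)) note("symptoms.csv",
                           paste("missing columns:", paste(miss, collapse = ",")))
    if ("total_score" %in% names(sy) && any(sy$total_score < 0, na.rm = TRUE))
      note("symptoms.csv", "negative total_score")
  }
  mdir <- file.path(dir, "matrices")
  if (dir.exists(mdir)) {
    for (f in list.files(mdir, pattern = "\\.txt$", full.names = TRUE)) {
      w <- try(as.matrix(utils::read.table(f, header = FALSE)), silent = TRUE)
      fname <- file.path("matrices", basename(f))
      if (inherits(w, "try-error")) { note(fname, "unreadable matrix"); next }
      if (nrow(w) != ncol(w)) { note(fname, "matrix not square"); next }
      if (max(abs(w - t(w))) > 1e-8) note(fname, "matrix not symmetric")
      if (any(w < 0) || any(w > 1)) note(fname, "FA weight outside [0, 1]")
      if (any(abs(diag(w)) > 1e-12)) note(fname, "nonzero diagonal")
    }
  }
  if (!length(issues))
    return(data.frame(file = character(0), issue = character(0)))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
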