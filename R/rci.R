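# Regression-based reliable change index (RCI) for post-concussive symptom
# ratings: 1-month scores are regressed on parent-rated premorbid scores in a
# reference sample; a child's change is the standardized residual
# z = (observed - predicted) / SEE, and a reliable increase (z >= cutoff)
# defines persistent symptoms.

#' Fit a reliable-change regression model
#'
#' Ordinary least squares of 1-month symptom totals on parent premorbid
#' totals, with the standard error of the estimate
#' `SEE = sqrt(sum(residual^2) / (n - 2))`.
#'
#' @param premorbid,post Paired reference-sample scores (equal length >= 3).
#' @param rater `"parent"` or `"child"` (which 1-month rating was regressed).
#' @param threshold_z Reliable-increase cutoff (default 1.645, one-tailed 5%).
#' @return Object of class `rci_model` with `slope`, `intercept`, `see`,
#'   `n_reference`, `rater`, `threshold_z`.
#' @export
fit_rci <- function(premorbid, post, rater = "parent", threshold_z = 1.645) {
  stopifnot(length(premorbid) == length(post))
  keep <- stats::complete.cases(premorbid, post)
  premorbid <- premorbid[keep]; post <- post[keep]
  n <- length(premorbid)
  if (n < 3L) stop("need at least 3 complete reference pairs")
  if (stats::var(premorbid) == 0) stop("premorbid scores are constant; slope unidentifiable")
  fit <- stats::lm(post ~ premorbid)
  see <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  if (see < 1e-10)
    stop("degenerate reference sample: standard error of the estimate is zero")
  structure(list(
    rater = rater,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    see = see,
    n_reference = n,
    threshold_z = threshold_z
  ), class = "rci_model")
}

#' Score reliable change and classify symptom persistence
#'
#' `z = (post - (intercept + slope * premorbid)) / SEE`; a participant is
#' classified persistent iff `z >= threshold_z`.
#'
#' @param model A fitted `rci_model`.
#' @param premorbid,post Scores to classify.
#' @param participant_id Optional ids carried into the output.
#' @return data.frame `participant_id`, `rater`, `z`, `status`
#'   (`"persistent"`/`"nonpersistent"`).
#' @export
score_and_classify <- function(model, premorbid, post,
                               participant_id = seq_along(premorbid)) {
  stopifnot(inherits(model, "rci_model"))
  z <- (post - (model$intercept + model$slope * premorbid)) / model$see
  data.frame(
    participant_id = participant_id,
    rater = model$rater,
    z = z,
    status = ifelse(z >= model$threshold_z, "persistent", "nonpersistent"),
    stringsAsFactors = FALSE
  )
}

#' Fit RCI models and classify a symptom table
#'
#' Builds the parent and child reliable-change models from a long symptom
#' table (`participant_id, rater, timepoint, total_score`): both 1-month
#' ratings are regressed on the parent premorbid rating. The reference
#' sample is either all participants with complete pairs (default) or the
#' OI group only.
#'
#' @param symptoms Long symptom table.
#' @param participants Participants table (`participant_id`, `group`).
#' @param reference `"all"` or `"oi"`.
#' @param threshold_z Reliable-increase cutoff.
#' @return List: `models` (per rater), `classifications` (data.frame for all
#'   scored participants, both raters).
#' @export
rci_from_tables <- function(symptoms, participants, reference = c("all", "oi"),
                            threshold_z = 1.645) {
  reference <- match.arg(reference)
  pre <- symptoms[symptoms$rater == "parent" & symptoms$timepoint == "premorbid", ]
  models <- list()
  classifications <- list()
  for (rater in c("parent", "child")) {
    post <- symptoms[symptoms$rater == rater & symptoms$timepoint == "1month", ]
    pairs <- merge(pre[, c("participant_id", "total_score")],
                   post[, c("participant_id", "total_score")],
                   by = "participant_id", suffixes = c("_pre", "_post"))
    pairs <- merge(pairs, participants[, c("participant_id", "group")],
                   by = "participant_id")
    ref <- if (reference == "oi") pairs[pairs$group == "OI", ] else pairs
    models[[rater]] <- fit_rci(ref$total_score_pre, ref$total_score_post,
                               rater = rater, threshold_z = threshold_z)
    classifications[[rater]] <- score_and_classify(
      models[[rater]], pairs$total_score_pre, pairs$total_score_post,
      participant_id = pairs$participant_id)
  }
  list(models = models,
       classifications = do.call(rbind, classifications))
}

#' Assign three-level symptom groups per rater
#'
#' TBI participants are labelled `TBI-persistent` or `TBI-nonpersistent`
#' from their reliable-change classification; OI participants keep the `OI`
#' label and are never reclassified. TBI participants without a 1-month
#' rating are excluded (`NA`) and logged in the `excluded` attribute.
#'
#' @param classifications Output of [score_and_classify()] /
#'   [rci_from_tables()] (columns `participant_id`, `rater`, `status`).
#' @param participants Participants table.
#' @return data.frame `participant_id`, `rater`, `symptom_group` (one row per
#'   participant x rater), with attribute `excluded`.
#' @export
assign_symptom_groups <- function(classifications, participants) {
  raters <- unique(classifications$rater)
  out <- list()
  excluded <- character(0)
  for (r in raters) {
    cl <- classifications[classifications$rater == r, ]
    g <- merge(participants[, c("participant_id", "group")],
               cl[, c("participant_id", "status")],
               by = "participant_id", all.x = TRUE)
    lab <- ifelse(g$group == "OI", "OI",
                  ifelse(is.na(g$status), NA_character_,
                         ifelse(g$status == "persistent",
                                "TBI-persistent", "TBI-nonpersistent")))
    excluded <- c(excluded, g$participant_id[g$group == "TBI" & is.na(lab)])
    out[[r]] <- data.frame(participant_id = g$participant_id, rater = r,
                           symptom_group = lab, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- unique(excluded)
  res
}

#' Serialize RCI models to JSON
#'
#' @param models Named list of `rci_model` objects.
#' @param path Output path.
#' @export
write_rci_models <- function(models, path) {
  jsonlite::write_json(lapply(models, unclass), path,
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
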