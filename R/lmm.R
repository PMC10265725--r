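# Longitudinal inference on harmonized network metrics: linear mixed-effects
# models with a random participant intercept,
#   metric ~ Group * (Time + Time^2) * (Age + Sex) [+ Hemisphere] + (1|participant)
# Benjamini-Hochberg FDR over group-involving terms, Cohen's d standardized
# by the total random SD with a 95% CI robustness gate, and follow-up probing
# of significant interactions at specified time/sex/age points.

#' Build the model frame for one metric
#'
#' One row per scan for global metrics; for nodal metrics, one row per scan
#' and hemisphere of the homologous region pair. Time is days post-injury
#' centred at the sample mean and scaled by its SD before squaring; age at
#' injury is centred at the sample mean (both centrings are stored for
#' probing and back-transformation), so the Group main effect is the group
#' difference at the average age and time. Codings: Group reference = OI,
#' Sex reference = M, Hemisphere reference = L.
#'
#' @param metrics Harmonized long metrics table.
#' @param phenotype Phenotype table (one row per scan).
#' @param metric Metric name (e.g. `"Cp"`, `"NCp"`).
#' @param level `"global"` or `"nodal"`.
#' @param region Region stem (e.g. `"THA"`) for nodal models.
#' @param grouping `"injury"` (TBI vs OI) or `"symptom"` (3-level).
#' @param symptom_groups Output of [assign_symptom_groups()] (required for
#'   `grouping = "symptom"`).
#' @param rater Rater whose symptom grouping to use.
#' @return data.frame with attributes `time_center`, `time_scale`.
#' @export
build_design <- function(metrics, phenotype, metric,
                         level = c("global", "nodal"), region = NULL,
                         grouping = c("injury", "symptom"),
                         symptom_groups = NULL, rater = "parent") {
  level <- match.arg(level)
  grouping <- match.arg(grouping)
  sub <- metrics[metrics$metric == metric & metrics$level == level, ]
  if (level == "nodal") {
    if (is.null(region)) stop("nodal models need a region stem")
    sub <- sub[region_stems(sub$region) == region, ]
  }
  if (nrow(sub) == 0L) stop("no rows for metric ", metric)
  df <- merge(sub, phenotype, by = "scan_id")
  if (nrow(df) < nrow(sub))
    stop("phenotype table is missing scans present in the metric table")
  if (anyNA(df$days_post_injury) || anyNA(df$age_at_injury) || anyNA(df$sex))
    stop("missing covariates in the phenotype table")
  if (grouping == "injury") {
    df$Group <- factor(df$group, levels = c("OI", "TBI"))
  } else {
    if (is.null(symptom_groups)) stop("symptom grouping needs symptom_groups")
    sg <- symptom_groups[symptom_groups$rater == rater,
                         c("participant_id", "symptom_group")]
    df <- merge(df, sg, by = "participant_id")
    df <- df[!is.na(df$symptom_group), ]
    df$Group <- factor(df$symptom_group,
                       levels = c("OI", "TBI-nonpersistent", "TBI-persistent"))
  }
  mu <- mean(df$days_post_injury)
  sdv <- stats::sd(df$days_post_injury)
  if (sdv == 0) sdv <- 1
  df$Time <- (df$days_post_injury - mu) / sdv
  df$Time2 <- df$Time^2
  age_mu <- mean(df$age_at_injury)
  df$Age <- df$age_at_injury - age_mu  # centred: Group main effect sits at the sample mean age
  df$Sex <- factor(df$sex, levels = c("M", "F"))
  if (level == "nodal") df$Hemisphere <- factor(df$hemisphere, levels = c("L", "R"))
  keep <- c("participant_id", "scan_id", "value", "Group", "Time", "Time2",
            "Age", "Sex", if (level == "nodal") "Hemisphere",
            "visit", "days_post_injury",
            if ("assigned_chronic_day" %in% names(df)) "assigned_chronic_day")
  out <- df[, keep]
  attr(out, "time_center") <- mu
  attr(out, "time_scale") <- sdv
  attr(out, "age_center") <- age_mu
  attr(out, "level") <- level
  attr(out, "metric") <- metric
  attr(out, "region") <- region
  attr(out, "grouping") <- grouping
  attr(out, "rater") <- if (grouping == "symptom") rater else NA_character_
  out
}

#' Fit the longitudinal mixed-effects model
#'
#' REML fit (lme4/lmerTest) of
#' `value ~ Group*(Time+Time2)*(Age+Sex) [+ Hemisphere] + (1|participant_id)`
#' with Satterthwaite degrees of freedom for the fixed-effect t-tests. When
#' fewer than two participants have repeated rows, the participant variance
#' component is unidentifiable: the model degenerates to ordinary least
#' squares with zero participant variance and a warning.
#'
#' @param frame Model frame from [build_design()].
#' @return Object of class `lmm_fit`: `terms` data.frame (term, estimate, se,
#'   df, t, p), variance components, convergence flag, and the fitted model.
#' @export
fit_lmm <- function(frame) {
  has_hemi <- "Hemisphere" %in% names(frame)
  rhs <- paste("Group * (Time + Time2) * (Age + Sex)",
               if (has_hemi) "+ Hemisphere" else "")
  n_rep <- sum(table(frame$participant_id) > 1L)
  converged <- TRUE
  if (n_rep >= 2L) {
    form <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant_id)"))
    fit <- lmerTest::lmer(form, data = frame, REML = TRUE)
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
    co <- as.data.frame(summary(fit)$coefficients)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_part <- vc$vcov[vc$grp == "participant_id"]
    var_resid <- vc$vcov[vc$grp == "Residual"]
  } else {
    warning("fewer than 2 participants with repeated rows; ",
            "fitting fixed-effects-only model (participant variance = 0)")
    form <- stats::as.formula(paste("value ~", rhs))
    fit <- stats::lm(form, data = frame)
    s <- summary(fit)$coefficients
    co <- data.frame(Estimate = s[, 1], `Std. Error` = s[, 2],
                     df = fit$df.residual, `t value` = s[, 3],
                     `Pr(>|t|)` = s[, 4], check.names = FALSE)
    var_part <- 0
    var_resid <- summary(fit)$sigma^2
  }
  terms_df <- data.frame(
    term = rownames(co),
    estimate = co[["Estimate"]],
    se = co[["Std. Error"]],
    df = co[["df"]],
    t = co[["t value"]],
    p = co[["Pr(>|t|)"]],
    stringsAsFactors = FALSE
  )
  rownames(terms_df) <- NULL
  structure(list(
    model = fit,
    terms = terms_df,
    var_participant = var_part,
    var_resid = var_resid,
    converged = converged,
    frame = frame
  ), class = "lmm_fit")
}

#' Benjamini-Hochberg FDR correction within a declared family
#'
#' Step-up adjustment; a hypothesis is rejected when its BH-adjusted p-value
#' is at most `alpha`.
#'
#' @param p Vector of p-values in \[0,1\].
#' @param alpha Family FDR level.
#' @return List: `p_adjusted`, `rejected` (logical).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("empty p-value family")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= alpha)
}

band_of <- function(d) {
  a <- abs(d)
  ifelse(a < 0.2, "negligible",
         ifelse(a < 0.5, "small", ifelse(a < 0.8, "medium", "large")))
}

#' Standardized effect size with CI robustness gate
#'
#' Cohen's d for a model term or contrast: the estimate divided by the total
#' random SD `sqrt(participant variance + residual variance)`; its 95% CI is
#' `(estimate +/- 1.96 SE)` on the same scale. Bands at |0.20| (small),
#' |0.50| (medium), |0.80| (large); an effect is robust when the CI
#' excludes 0.
#'
#' @param fit An `lmm_fit`.
#' @param term Fixed-effect term name (row of `fit$terms`).
#' @return data.frame `term`, `d`, `d_lo`, `d_hi`, `robust`, `band`.
#' @export
effect_size <- function(fit, term) {
  stopifnot(inherits(fit, "lmm_fit"))
  sd_tot <- sqrt(fit$var_participant + fit$var_resid)
  if (sd_tot <= 0) stop("zero total variance; effect size undefined")
  row <- fit$terms[fit$terms$term == term, ]
  if (nrow(row) != 1L) stop("unknown term: ", term)
  d <- row$estimate / sd_tot
  lo <- (row$estimate - 1.96 * row$se) / sd_tot
  hi <- (row$estimate + 1.96 * row$se) / sd_tot
  data.frame(term = term, d = d, d_lo = lo, d_hi = hi,
             robust = lo > 0 | hi < 0, band = band_of(d),
             stringsAsFactors = FALSE)
}

#' Default probe grid for a fitted model frame
#'
#' Time points are the mean observed days post-injury at each assessment
#' (post-acute, and the chronic visit separately for the ~3-month and
#' ~6-month assignments), computed from the analyzed sample; sex is probed
#' at M and F; age at the sample's 10th and 90th percentiles.
#'
#' @param frame Model frame from [build_design()].
#' @return data.frame crossing `day` (with `time_label`), `sex`, `age`
#'   (with `age_label`).
#' @export
probe_grid <- function(frame) {
  days <- frame$days_post_injury
  times <- c(postacute = mean(days[frame$visit == "postacute"]))
  if ("assigned_chronic_day" %in% names(frame) &&
      any(frame$visit == "chronic", na.rm = TRUE)) {
    ch <- frame$visit == "chronic"
    for (tgt in sort(unique(frame$assigned_chronic_day[ch]))) {
      sel <- ch & frame$assigned_chronic_day == tgt
      times[paste0("chronic", tgt)] <- mean(days[sel])
    }
  } else if (any(frame$visit == "chronic", na.rm = TRUE)) {
    times["chronic"] <- mean(days[frame$visit == "chronic"])
  }
  pp <- !duplicated(frame$participant_id)
  age_center <- attr(frame, "age_center")
  if (is.null(age_center)) age_center <- 0
  ages <- stats::quantile(frame$Age[pp], c(0.1, 0.9), names = FALSE, type = 7) +
    age_center
  grid <- expand.grid(time_label = names(times), sex = c("M", "F"),
                      age_label = c("younger", "older"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$day <- times[grid$time_label]
  grid$age <- ifelse(grid$age_label == "younger", ages[1], ages[2])
  grid
}

# Model matrix row(s) for new covariate points, matching the fitted model.
fixed_model_matrix <- function(fit, newdata) {
  model <- fit$model
  if (inherits(model, "merMod")) {
    tt <- stats::delete.response(stats::terms(model, fixed.only = TRUE))
  } else {
    tt <- stats::delete.response(stats::terms(model))
  }
  xlev <- stats::.getXlevels(tt, fit$frame)
  for (v in names(xlev)) newdata[[v]] <- factor(newdata[[v]], levels = xlev[[v]])
  stats::model.matrix(tt, newdata, xlev = xlev)
}

#' Probe group contrasts of a fitted model over a covariate grid
#'
#' Evaluates the group-difference contrast (a linear combination of fixed
#' effects) at each grid point, returning the contrast estimate with its
#' Cohen's d, 95% CI and robustness flag. Intended as the follow-up for
#' significant group interactions; with no interactions in the model the
#' probed contrast is constant over the grid.
#'
#' @param fit An `lmm_fit`.
#' @param grid Probe grid (see [probe_grid()]); columns `day`, `sex`, `age`
#'   plus optional labels.
#' @param contrasts List of `c(level_a, level_b)` group-level pairs; default
#'   all non-reference levels vs reference plus, for 3-level groupings, the
#'   persistent vs non-persistent contrast.
#' @param warn_outside Warn when a grid point lies outside the observed
#'   covariate range (still computed).
#' @return data.frame, one row per grid point x contrast.
#' @export
probe_interactions <- function(fit, grid = probe_grid(fit$frame),
                               contrasts = NULL, warn_outside = TRUE) {
  stopifnot(inherits(fit, "lmm_fit"))
  frame <- fit$frame
  lev <- levels(frame$Group)
  if (is.null(contrasts)) {
    contrasts <- lapply(lev[-1], function(l) c(l, lev[1]))
    if (length(lev) == 3L) contrasts <- c(contrasts, list(c(lev[3], lev[2])))
  }
  mu <- attr(frame, "time_center"); sdv <- attr(frame, "time_scale")
  age_center <- attr(frame, "age_center")
  if (is.null(age_center)) age_center <- 0
  sd_tot <- sqrt(fit$var_participant + fit$var_resid)
  beta <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model) else stats::coef(fit$model)
  beta <- beta[!is.na(beta)]  # aliased coefficients (rank deficiency) are dropped
  V <- as.matrix(stats::vcov(fit$model))
  if (warn_outside) {
    if (any(grid$day < min(frame$days_post_injury)) ||
        any(grid$day > max(frame$days_post_injury)) ||
        any(grid$age < min(frame$Age)) || any(grid$age > max(frame$Age)))
      warning("probe grid point outside the observed covariate range")
  }
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    tt <- (grid$day[gi] - mu) / sdv
    base <- data.frame(Time = tt, Time2 = tt^2,
                       Age = grid$age[gi] - age_center,
                       Sex = grid$sex[gi], stringsAsFactors = FALSE)
    if ("Hemisphere" %in% names(frame)) base$Hemisphere <- "L"
    for (ct in contrasts) {
      nd <- rbind(cbind(base, Group = ct[1]), cbind(base, Group = ct[2]))
      X <- fixed_model_matrix(fit, nd)
      L <- X[1, names(beta)] - X[2, names(beta)]
      est <- sum(L * beta)
      se <- sqrt(drop(t(L) %*% V %*% L))
      d <- est / sd_tot
      lo <- (est - 1.96 * se) / sd_tot
      hi <- (est + 1.96 * se) / sd_tot
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(ct[1], "vs", ct[2]),
        time_label = if ("time_label" %in% names(grid)) grid$time_label[gi] else NA,
        day = grid$day[gi], sex = grid$sex[gi],
        age_label = if ("age_label" %in% names(grid)) grid$age_label[gi] else NA,
        age = grid$age[gi],
        estimate = est, se = se, d = d, d_lo = lo, d_hi = hi,
        robust = lo > 0 | hi < 0, band = band_of(d),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit, correct and summarize models across metrics and regions
#'
#' Runs the mixed-model analysis for every requested metric (global metrics
#' once; nodal metrics per homologous region pair), applies BH correction
#' within the declared family — all group-involving terms across regions for
#' a given metric and grouping — computes CI-gated Cohen's d for every term,
#' and probes group contrasts over the time/sex/age grid for models whose
#' group interactions survive FDR.
#'
#' @param metrics Harmonized long metrics table.
#' @param phenotype Phenotype table.
#' @param grouping `"injury"` or `"symptom"`.
#' @param symptom_groups Required for symptom grouping.
#' @param rater Rater for symptom grouping.
#' @param metric_names Metrics to analyze (default: all present).
#' @param fdr_alpha FDR level (0.05 injury, 0.025 symptom groups).
#' @param probe Probe significant interactions?
#' @return data.frame of results rows (terms and probes).
#' @export
analyze_metrics <- function(metrics, phenotype,
                            grouping = c("injury", "symptom"),
                            symptom_groups = NULL, rater = "parent",
                            metric_names = NULL,
                            fdr_alpha = if (match.arg(grouping) == "injury") 0.05 else 0.025,
                            probe = TRUE) {
  grouping <- match.arg(grouping)
  rater_lab <- if (grouping == "symptom") rater else NA_character_
  if (is.null(metric_names)) metric_names <- unique(metrics$metric)
  res <- list()
  for (metric in metric_names) {
    level <- unique(metrics$level[metrics$metric == metric])
    if (length(level) != 1L) stop("metric ", metric, " appears at multiple levels")
    regions <- if (level == "nodal")
      unique(region_stems(metrics$region[metrics$metric == metric])) else NA_character_
    fits <- list()
    term_rows <- list()
    for (rg in regions) {
      frame <- build_design(metrics, phenotype, metric, level,
                            region = if (is.na(rg)) NULL else rg,
                            grouping = grouping,
                            symptom_groups = symptom_groups, rater = rater)
      fit <- fit_lmm(frame)
      if (!fit$converged) {
        warning("model for ", metric, "/", rg, " did not converge; excluded from FDR")
      }
      fits[[if (is.na(rg)) "_global" else rg]] <- fit
      tr <- fit$terms
      tr <- tr[tr$term != "(Intercept)", ]
      es <- do.call(rbind, lapply(tr$term, function(tm) effect_size(fit, tm)))
      tr <- cbind(tr, es[, c("d", "d_lo", "d_hi", "robust", "band")])
      tr$metric <- metric; tr$level <- level; tr$region <- rg
      tr$grouping <- grouping; tr$rater <- rater_lab
      tr$converged <- fit$converged
      term_rows[[as.character(rg)]] <- tr
    }
    tab <- do.call(rbind, term_rows)
    rownames(tab) <- NULL
    fam <- grepl("Group", tab$term) & tab$converged
    tab$p_fdr <- NA_real_
    tab$significant <- FALSE
    if (any(fam)) {
      fc <- fdr_correct(tab$p[fam], alpha = fdr_alpha)
      tab$p_fdr[fam] <- fc$p_adjusted
      tab$significant[fam] <- fc$rejected
    }
    res[[metric]] <- tab
    if (probe) {
      inter_sig <- tab$significant & grepl("Group", tab$term) &
        grepl("Time|Sex|Age", tab$term)
      for (rg in unique(tab$region[inter_sig])) {
        fit <- fits[[if (is.na(rg)) "_global" else rg]]
        pr <- probe_interactions(fit, warn_outside = FALSE)
        pr_tab <- data.frame(
          term = sprintf("probe[%s] %s sex=%s age=%.2f", pr$contrast,
                         pr$time_label, pr$sex, pr$age),
          estimate = pr$estimate, se = pr$se, df = NA_real_, t = NA_real_,
          p = NA_real_, d = pr$d, d_lo = pr$d_lo, d_hi = pr$d_hi,
          robust = pr$robust, band = pr$band,
          metric = metric, level = level, region = rg,
          grouping = grouping, rater = rater_lab, converged = TRUE,
          p_fdr = NA_real_, significant = NA,
          stringsAsFactors = FALSE
        )
        res[[paste0(metric, "_probe_", rg)]] <- pr_tab
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  cols <- c("metric", "level", "region", "grouping", "rater", "term",
            "estimate", "se", "df", "t", "p", "p_fdr", "significant",
            "d", "d_lo", "d_hi", "robust", "band", "converged")
  out[, cols]
}
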