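# Covariate-preserving empirical-Bayes site harmonization for metric tables.
# Location/scale batch model per feature v and site i:
#   y_giv = alpha_v + x_g' beta_v + gamma_iv + delta_iv * eps_giv
# Site effects are shrunk across features with parametric priors (normal for
# location, inverse-gamma for scale) and removed; modelled covariates
# (group, time, time^2, age, sex) are preserved.

#' Fit the site-harmonization model
#'
#' Per feature: least-squares fit of value on covariates plus site means,
#' standardization of residual variance, then empirical-Bayes shrinkage of
#' per-site location and scale effects by iterative conditional updates.
#'
#' @param values Numeric matrix, features x scans (rownames = feature ids).
#' @param batch Site/scanner label per scan (length `ncol(values)`).
#' @param design Numeric covariate matrix, scans x covariates (no intercept);
#'   may be `NULL` for an intercept-only model.
#' @param tol,max_iter Convergence control for the EB updates.
#' @return Object of class `harmonization_model`.
#' @export
fit_harmonization <- function(values, batch, design = NULL,
                              tol = 1e-6, max_iter = 100L) {
  stopifnot(is.matrix(values))
  n_array <- ncol(values)
  if (length(batch) != n_array) stop("batch length must match scan count")
  batchf <- factor(batch)
  n_batch <- nlevels(batchf)
  n_per <- as.numeric(table(batchf))
  if (any(n_per < 2)) stop("each site needs at least 2 observations")
  if (n_batch == 1L) {
    warning("single site: harmonization degenerates to the identity")
    batch_design <- matrix(1, n_array, 1L)
  } else {
    batch_design <- stats::model.matrix(~ -1 + batchf)
  }
  X <- if (is.null(design)) batch_design else cbind(batch_design, as.matrix(design))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (covariates confounded with site?)")
  n_cov <- ncol(X) - n_batch

  B_hat <- solve(crossprod(X), crossprod(X, t(values)))   # p x V
  grand_mean <- crossprod(n_per / n_array, B_hat[seq_len(n_batch), , drop = FALSE])
  resid <- values - t(X %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  ok <- var_pooled > 1e-12                                # constant features pass through

  beta <- if (n_cov > 0) B_hat[(n_batch + 1):ncol(X), , drop = FALSE] else NULL
  stand_mean <- matrix(grand_mean, nrow(values), n_array)
  if (n_cov > 0) stand_mean <- stand_mean + t(as.matrix(design) %*% beta)
  sdv <- sqrt(pmax(var_pooled, 1e-12))
  z <- (values - stand_mean) / sdv

  gamma_hat <- t(solve(crossprod(batch_design), crossprod(batch_design, t(z))))
  # features x batches
  delta_hat <- sapply(levels(batchf), function(b) {
    zz <- z[, batchf == b, drop = FALSE]
    apply(zz, 1, stats::var)
  })
  gamma_hat <- matrix(gamma_hat, nrow(values), n_batch)
  delta_hat <- matrix(delta_hat, nrow(values), n_batch)

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  if (n_batch == 1L) {
    # nothing to remove: adjusted output must equal the input exactly
    gamma_star[] <- 0
    delta_star[] <- 1
  }
  for (i in if (n_batch == 1L) integer(0) else seq_len(n_batch)) {
    g <- gamma_hat[ok, i]; d <- delta_hat[ok, i]
    if (sum(ok) < 3) { next }
    g_bar <- mean(g); t2 <- stats::var(g)
    m <- mean(d); s2 <- stats::var(d)
    if (!is.finite(t2) || !is.finite(s2) || s2 <= .Machine$double.eps ||
        t2 <= .Machine$double.eps) next
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    n_i <- n_per[i]
    zi <- z[ok, batchf == levels(batchf)[i], drop = FALSE]
    g_new <- g; d_new <- d
    for (it in seq_len(max_iter)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (n_i * t2 * g + d_new * g_bar) / (n_i * t2 + d_new)
      sum2 <- rowSums((zi - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (n_i / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      if (change < tol) break
    }
    gamma_star[ok, i] <- g_new
    delta_star[ok, i] <- d_new
  }
  delta_star <- pmax(delta_star, 1e-12)

  structure(list(
    features = rownames(values),
    batches = levels(batchf),
    n_per_batch = n_per,
    grand_mean = as.numeric(grand_mean),
    beta = beta,
    covariate_names = if (n_cov > 0) colnames(as.matrix(design)) else character(0),
    var_pooled = var_pooled,
    feature_ok = ok,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star
  ), class = "harmonization_model")
}

#' Remove fitted site effects from a metric table
#'
#' `adjusted = sd_v / sqrt(delta*_iv) * (z - gamma*_iv) + alpha_v + x' beta_v`
#' where `z` is the covariate- and variance-standardized value. Output schema
#' matches the input; constant features pass through unchanged.
#'
#' @param values Features x scans matrix (same features as the fit).
#' @param batch Site label per scan; must be among the fitted sites.
#' @param design Covariate matrix matching the fit.
#' @param model A `harmonization_model`.
#' @return Adjusted matrix, same dimensions as `values`.
#' @export
apply_harmonization <- function(values, batch, design = NULL, model) {
  stopifnot(inherits(model, "harmonization_model"))
  if (!is.null(model$features) && !is.null(rownames(values)) &&
      !identical(rownames(values), model$features))
    stop("feature set differs from the fitted model")
  batchf <- factor(batch, levels = model$batches)
  if (anyNA(batchf)) stop("unseen site label(s): ",
                          paste(unique(batch[is.na(batchf)]), collapse = ", "))
  n_array <- ncol(values)
  stand_mean <- matrix(model$grand_mean, nrow(values), n_array)
  if (!is.null(model$beta))
    stand_mean <- stand_mean + t(as.matrix(design) %*% model$beta)
  sdv <- sqrt(pmax(model$var_pooled, 1e-12))
  z <- (values - stand_mean) / sdv
  out <- values
  idx <- as.integer(batchf)
  for (i in seq_along(model$batches)) {
    cols <- which(idx == i)
    if (!length(cols)) next
    adj <- (z[, cols, drop = FALSE] - model$gamma_star[, i]) /
      sqrt(model$delta_star[, i]) * sdv + stand_mean[, cols, drop = FALSE]
    out[, cols] <- adj
  }
  out[!model$feature_ok, ] <- values[!model$feature_ok, ]
  out
}

#' Pivot a long metrics table to a features x scans matrix
#'
#' Feature ids are the metric name for global rows and `metric|region` for
#' nodal rows. Features with any missing value (e.g. unstandardized
#' small-worldness) are dropped with a message.
#'
#' @param metrics Long table from [metrics_long_table()].
#' @return List: `values` (features x scans matrix), `scan_ids`.
#' @export
metrics_wide <- function(metrics) {
  feature <- ifelse(metrics$level == "global", metrics$metric,
                    paste(metrics$metric, metrics$region, sep = "|"))
  scans <- sort(unique(metrics$scan_id))
  feats <- unique(feature)
  m <- matrix(NA_real_, length(feats), length(scans),
              dimnames = list(feats, scans))
  m[cbind(match(feature, feats), match(metrics$scan_id, scans))] <- metrics$value
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    message("dropping ", sum(bad), " feature(s) with missing values")
    m <- m[!bad, , drop = FALSE]
  }
  list(values = m, scan_ids = scans)
}

#' Rebuild the long metrics table from an adjusted wide matrix
#'
#' @param values Features x scans matrix (feature ids as from [metrics_wide()]).
#' @param template Original long table (used to restore row order and the
#'   region/hemisphere columns).
#' @return Long-format data.frame with adjusted values.
#' @export
metrics_long_from_wide <- function(values, template) {
  feature <- ifelse(template$level == "global", template$metric,
                    paste(template$metric, template$region, sep = "|"))
  keep <- feature %in% rownames(values)
  out <- template[keep, ]
  out$value <- values[cbind(match(feature[keep], rownames(values)),
                            match(out$scan_id, colnames(values)))]
  rownames(out) <- NULL
  out
}

#' Harmonization covariate matrix from a phenotype table
#'
#' Group (TBI = 1), days post-injury, days squared, age at injury and sex
#' (F = 1) — the biological covariates whose variance harmonization must
#' preserve.
#'
#' @param phenotype Phenotype table with one row per scan, ordered as the
#'   scan columns of the metric matrix.
#' @return Numeric matrix, scans x 5.
#' @export
harmonization_design <- function(phenotype) {
  cbind(
    group_tbi = as.numeric(phenotype$group == "TBI"),
    days = phenotype$days_post_injury,
    days2 = phenotype$days_post_injury^2,
    age = phenotype$age_at_injury,
    sex_f = as.numeric(phenotype$sex == "F")
  )
}

#' Harmonize a long metrics table against a phenotype table
#'
#' Convenience wrapper: pivots, fits, applies, and returns the adjusted long
#' table plus the fitted model.
#'
#' @param metrics Long metrics table.
#' @param phenotype Phenotype table (one row per scan in `metrics`).
#' @param batch_column Phenotype column holding the batch label (default
#'   `"site"`).
#' @return List: `metrics` (adjusted long table), `model`.
#' @export
harmonize_metrics <- function(metrics, phenotype, batch_column = "site") {
  wide <- metrics_wide(metrics)
  ph <- phenotype[match(wide$scan_ids, phenotype$scan_id), ]
  if (anyNA(ph$scan_id)) stop("phenotype table is missing scans present in the metric table")
  design <- harmonization_design(ph)
  model <- fit_harmonization(wide$values, ph[[batch_column]], design)
  adj <- apply_harmonization(wide$values, ph[[batch_column]], design, model)
  list(metrics = metrics_long_from_wide(adj, metrics), model = model)
}

#' Serialize a harmonization model to JSON
#'
#' @param model A `harmonization_model`.
#' @param path Output path.
#' @export
write_harmonization_model <- function(model, path) {
  obj <- unclass(model)
  obj$beta <- if (is.null(model$beta)) NULL else as.data.frame(model$beta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
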