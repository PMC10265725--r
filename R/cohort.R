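# Synthetic study generator: participants, visits, symptom ratings and
# per-scan FA connectomes with known ground truth, emulating a two-group
# (mild TBI vs orthopaedic injury) multi-site longitudinal design.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the target study design: ~65/35 TBI/OI split, five
#' scanner sites with additive and multiplicative edge-weight effects, ages
#' 8-16.99 years, a post-acute scan at 2-33 days post-injury, a second scan
#' randomly assigned to ~90 or ~180 days with attrition, ~59% male, and
#' parent premorbid plus parent/child 1-month symptom ratings generated from
#' the linear model the reliable change index assumes.
#'
#' @param n_tbi,n_oi Group sizes (default 360 / 196 participants).
#' @param sites Site labels (>= 1).
#' @param male_fraction Proportion male.
#' @param age_range Age-at-injury range in years, within \[8, 16.99\].
#' @param postacute_day_range Post-acute visit window in days post-injury.
#' @param chronic_days Candidate chronic-scan targets (days).
#' @param chronic_assign_prob Probability of the first element of
#'   `chronic_days`.
#' @param chronic_jitter_sd SD (days) of jitter around the assigned chronic day.
#' @param attrition_chronic Probability a participant misses the chronic scan.
#' @param site_additive,site_multiplicative Per-site edge-weight shift (FA
#'   units) and scale, recycled over `sites`.
#' @param effect_spec List of [injected_effect()] ground-truth effects.
#' @param noise_sd_edge Edge-weight noise SD (FA units).
#' @param age_slope Edge-weight increase per year of age (FA units/yr),
#'   giving harmonization a biological covariate signal to preserve.
#' @param template_degree,template_rewire Watts-Strogatz template: ring
#'   lattice mean degree and rewiring probability.
#' @param weight_range Template edge weights drawn from
#'   `Beta(beta_shape)` scaled into this range (FA-plausible).
#' @param beta_shape Two shape parameters of the template weight Beta law.
#' @param latent_persistent_prob Probability a TBI participant is latently
#'   symptomatic-persistent.
#' @param premorbid_shape,premorbid_rate Gamma law of (rounded) parent
#'   premorbid symptom totals.
#' @param symptom_slope,symptom_intercept Linear map premorbid -> 1-month.
#' @param symptom_noise_sd Rating noise SD.
#' @param symptom_shift_tbi Extra 1-month score for non-persistent TBI.
#' @param symptom_shift_persistent Extra 1-month score for latent-persistent
#'   TBI (default two residual SDs: a reliable increase).
#' @param isolate_prob Probability a scan has one node's edges zeroed
#'   (produces not-fully-connected matrices for filter testing).
#' @param n_nodes Parcellation size (default 90).
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_tbi = 360L, n_oi = 196L,
                          sites = paste0("S", 1:5),
                          male_fraction = 0.59,
                          age_range = c(8, 16.99),
                          postacute_day_range = c(2, 33),
                          chronic_days = c(90, 180),
                          chronic_assign_prob = 0.5,
                          chronic_jitter_sd = 7,
                          attrition_chronic = 0.25,
                          site_additive = c(-0.02, -0.01, 0, 0.01, 0.02),
                          site_multiplicative = c(0.95, 0.98, 1, 1.02, 1.05),
                          effect_spec = list(),
                          noise_sd_edge = 0.02,
                          age_slope = 0.002,
                          template_degree = 12L,
                          template_rewire = 0.1,
                          weight_range = c(0.2, 0.8),
                          beta_shape = c(8, 8),
                          latent_persistent_prob = 0.22,
                          premorbid_shape = 2, premorbid_rate = 0.4,
                          symptom_slope = 0.8, symptom_intercept = 1,
                          symptom_noise_sd = 3,
                          symptom_shift_tbi = 1,
                          symptom_shift_persistent = 6,
                          isolate_prob = 0,
                          n_nodes = 90L,
                          seed = 1L) {
  if (n_tbi < 1L || n_oi < 1L) stop("group sizes must be positive")
  if (length(sites) < 1L) stop("at least one site is required")
  if (male_fraction < 0 || male_fraction > 1) stop("male_fraction must be in [0,1]")
  if (attrition_chronic < 0 || attrition_chronic > 1) stop("attrition must be in [0,1]")
  if (latent_persistent_prob < 0 || latent_persistent_prob > 1)
    stop("latent_persistent_prob must be in [0,1]")
  if (age_range[1] < 8 || age_range[2] > 16.99 || age_range[1] > age_range[2])
    stop("age_range must lie within [8, 16.99]")
  cfg <- list(
    n_tbi = as.integer(n_tbi), n_oi = as.integer(n_oi), sites = sites,
    male_fraction = male_fraction, age_range = age_range,
    postacute_day_range = postacute_day_range, chronic_days = chronic_days,
    chronic_assign_prob = chronic_assign_prob,
    chronic_jitter_sd = chronic_jitter_sd,
    attrition_chronic = attrition_chronic,
    site_additive = rep_len(site_additive, length(sites)),
    site_multiplicative = rep_len(site_multiplicative, length(sites)),
    effect_spec = effect_spec, noise_sd_edge = noise_sd_edge,
    age_slope = age_slope, template_degree = as.integer(template_degree),
    template_rewire = template_rewire, weight_range = weight_range,
    beta_shape = beta_shape,
    latent_persistent_prob = latent_persistent_prob,
    premorbid_shape = premorbid_shape, premorbid_rate = premorbid_rate,
    symptom_slope = symptom_slope, symptom_intercept = symptom_intercept,
    symptom_noise_sd = symptom_noise_sd,
    symptom_shift_tbi = symptom_shift_tbi,
    symptom_shift_persistent = symptom_shift_persistent,
    isolate_prob = isolate_prob, n_nodes = as.integer(n_nodes),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Ground-truth effect injected on connectome edge weights
#'
#' Describes an edge-weight delta applied to all edges incident to the target
#' regions when a scan matches the condition. Used to give downstream
#' recovery tests a known truth.
#'
#' @param target_regions Region labels (must exist in the parcellation).
#' @param direction +1 or -1.
#' @param magnitude Non-negative edge-weight delta (FA units).
#' @param group,status,sex Optional condition: exact match required when given.
#' @param day_min,day_max Optional days-post-injury window.
#' @param age_min,age_max Optional age-at-injury band (years).
#' @return Object of class `injected_effect`.
#' @export
injected_effect <- function(target_regions, direction = -1, magnitude = 0.05,
                            group = NULL, status = NULL, sex = NULL,
                            day_min = NULL, day_max = NULL,
                            age_min = NULL, age_max = NULL) {
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  structure(list(target_regions = target_regions, direction = direction,
                 magnitude = magnitude,
                 condition = list(group = group, status = status, sex = sex,
                                  day_min = day_min, day_max = day_max,
                                  age_min = age_min, age_max = age_max)),
            class = "injected_effect")
}

effect_matches <- function(effect, group, status, sex, age, day) {
  cond <- effect$condition
  ok <- TRUE
  if (!is.null(cond$group)) ok <- ok && group %in% cond$group
  if (!is.null(cond$status)) ok <- ok && !is.na(status) && status %in% cond$status
  if (!is.null(cond$sex)) ok <- ok && sex %in% cond$sex
  if (!is.null(cond$day_min)) ok <- ok && day >= cond$day_min
  if (!is.null(cond$day_max)) ok <- ok && day <= cond$day_max
  if (!is.null(cond$age_min)) ok <- ok && age >= cond$age_min
  if (!is.null(cond$age_max)) ok <- ok && age <= cond$age_max
  ok
}

#' Shared small-world connectome template
#'
#' Watts-Strogatz-style base topology used by every synthetic scan: a ring
#' lattice over `n_nodes` nodes with the configured mean degree, each edge
#' rewired with the configured probability (avoiding self-loops and
#' duplicates), and edge weights drawn once from a scaled Beta distribution.
#' The template is connected and small-world, with FA-plausible weights.
#'
#' @param config A [cohort_config()].
#' @return A `connectivity_matrix` (the template).
#' @export
connectome_template <- function(config) {
  n <- config$n_nodes
  khalf <- config$template_degree %/% 2L
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(config$seed, "template"))
  # ring lattice edge list
  el <- do.call(rbind, lapply(seq_len(khalf), function(o) {
    i <- seq_len(n)
    cbind(i, (i + o - 1L) %% n + 1L)
  }))
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE
  adj[el[, c(2L, 1L)]] <- TRUE
  # Watts-Strogatz rewiring: each edge moves its second endpoint w.p. p
  for (e in seq_len(nrow(el))) {
    if (stats::runif(1) < config$template_rewire) {
      a <- el[e, 1L]; b <- el[e, 2L]
      cand <- which(!adj[a, ] & seq_len(n) != a)
      if (!length(cand)) next
      newb <- cand[sample.int(length(cand), 1L)]
      adj[a, b] <- adj[b, a] <- FALSE
      adj[a, newb] <- adj[newb, a] <- TRUE
      el[e, 2L] <- newb
    }
  }
  wr <- config$weight_range
  wts <- wr[1] + (wr[2] - wr[1]) *
    stats::rbeta(nrow(el), config$beta_shape[1], config$beta_shape[2])
  w <- matrix(0, n, n)
  w[el] <- wts
  w[el[, c(2L, 1L)]] <- wts
  labels <- if (n == 90L) aal90_labels() else paste0("N", seq_len(n))
  dimnames(w) <- list(labels, labels)
  new_connectivity_matrix(w, scan_id = "template")
}

#' Generate participant, visit and symptom tables
#'
#' Every participant receives a post-acute visit at 2-33 days post-injury;
#' participants surviving attrition receive exactly one chronic visit near 90
#' or 180 days (random assignment). Symptom totals follow the linear
#' premorbid -> 1-month model the RCI assumes, with latent-persistent TBI
#' cases shifted upwards by `symptom_shift_persistent` rating points.
#'
#' @param config A [cohort_config()].
#' @return List of data.frames: `participants` (participant_id, group, site,
#'   sex, age_at_injury, latent_status), `visits` (participant_id, scan_id,
#'   visit, days_post_injury, assigned_chronic_day), `symptoms`
#'   (participant_id, rater, timepoint, total_score).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_tbi + config$n_oi
  pid <- sprintf("P%04d", seq_len(n))
  group <- c(rep("TBI", config$n_tbi), rep("OI", config$n_oi))
  site <- sample(config$sites, n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  latent <- ifelse(
    group == "TBI",
    ifelse(stats::runif(n) < config$latent_persistent_prob,
           "persistent", "nonpersistent"),
    NA_character_
  )
  participants <- data.frame(
    participant_id = pid, group = group, site = site, sex = sex,
    age_at_injury = age, latent_status = latent, stringsAsFactors = FALSE
  )

  pr <- config$postacute_day_range
  pa_day <- round(pmin(pr[2], pmax(pr[1], stats::rgamma(n, shape = 6, scale = 1.6))))
  assigned <- ifelse(stats::runif(n) < config$chronic_assign_prob,
                     config$chronic_days[1], config$chronic_days[2])
  keep_chronic <- stats::runif(n) >= config$attrition_chronic
  ch_day <- round(assigned + stats::rnorm(n, 0, config$chronic_jitter_sd))
  ch_day <- pmax(ch_day, pr[2] + 7)  # chronic visits stay after the post-acute window
  visits <- data.frame(participant_id = pid, scan_id = paste0(pid, "_postacute"),
                       visit = "postacute", days_post_injury = pa_day,
                       assigned_chronic_day = NA_real_, stringsAsFactors = FALSE)
  if (any(keep_chronic)) {
    visits <- rbind(visits, data.frame(
      participant_id = pid[keep_chronic],
      scan_id = paste0(pid[keep_chronic], "_chronic"),
      visit = "chronic", days_post_injury = ch_day[keep_chronic],
      assigned_chronic_day = assigned[keep_chronic],
      stringsAsFactors = FALSE))
  }
  visits <- visits[order(visits$participant_id, visits$visit), ]
  rownames(visits) <- NULL

  shift <- ifelse(group == "OI", 0,
                  ifelse(latent == "persistent",
                         config$symptom_shift_persistent,
                         config$symptom_shift_tbi))
  premorbid <- round(stats::rgamma(n, config$premorbid_shape,
                                   rate = config$premorbid_rate))
  post_parent <- pmax(0, round(
    config$symptom_intercept + config$symptom_slope * premorbid + shift +
      stats::rnorm(n, 0, config$symptom_noise_sd)))
  post_child <- pmax(0, round(
    config$symptom_intercept + config$symptom_slope * premorbid + shift +
      stats::rnorm(n, 0, config$symptom_noise_sd)))
  symptoms <- rbind(
    data.frame(participant_id = pid, rater = "parent", timepoint = "premorbid",
               total_score = premorbid, stringsAsFactors = FALSE),
    data.frame(participant_id = pid, rater = "parent", timepoint = "1month",
               total_score = post_parent, stringsAsFactors = FALSE),
    data.frame(participant_id = pid, rater = "child", timepoint = "1month",
               total_score = post_child, stringsAsFactors = FALSE)
  )
  rownames(symptoms) <- NULL
  list(participants = participants, visits = visits, symptoms = symptoms)
}

#' Generate one synthetic FA connectome
#'
#' Starts from the cohort-shared small-world template, applies the linear age
#' effect and any matching injected ground-truth effects to edge weights,
#' then the scan site's additive and multiplicative effects, then edge noise,
#' and finally clips weights to (0.01, 1\] so FA stays bounded and no edge is
#' deleted. Topology is the template's; with `isolate_prob > 0` a scan may
#' have one node isolated (for exclusion-filter tests).
#'
#' @param participant One row of the participants table.
#' @param visit One row of the visits table for that participant.
#' @param config A [cohort_config()].
#' @param template Optional precomputed [connectome_template()].
#' @param scan_index Integer used to derive the per-scan random stream.
#' @return A `connectivity_matrix`.
#' @export
generate_connectome <- function(participant, visit, config,
                                template = connectome_template(config),
                                scan_index = 1L) {
  if (!participant$site %in% config$sites)
    stop("unknown site: ", participant$site)
  labels <- rownames(template)
  for (ef in config$effect_spec) {
    if (!all(ef$target_regions %in% labels))
      stop("unknown target region(s): ",
           paste(setdiff(ef$target_regions, labels), collapse = ", "))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(config$seed, "scan", scan_index))

  w <- unclass(template)
  attr(w, "scan_id") <- NULL; attr(w, "hemisphere") <- NULL
  edge <- w > 0
  age_mid <- mean(config$age_range)
  delta <- matrix(0, nrow(w), ncol(w))
  delta[edge] <- config$age_slope * (participant$age_at_injury - age_mid)
  for (ef in config$effect_spec) {
    if (effect_matches(ef, participant$group, participant$latent_status,
                       participant$sex, participant$age_at_injury,
                       visit$days_post_injury)) {
      idx <- match(ef$target_regions, labels)
      hit <- matrix(FALSE, nrow(w), ncol(w))
      hit[idx, ] <- TRUE
      hit[, idx] <- TRUE
      delta[edge & hit] <- delta[edge & hit] + ef$direction * ef$magnitude
    }
  }
  si <- match(participant$site, config$sites)
  w2 <- w
  w2[edge] <- (w[edge] + delta[edge] + config$site_additive[si]) *
    config$site_multiplicative[si]
  if (config$noise_sd_edge > 0) {
    noise <- matrix(0, nrow(w), ncol(w))
    ut <- upper.tri(w) & edge
    noise[ut] <- stats::rnorm(sum(ut), 0, config$noise_sd_edge)
    noise <- noise + t(noise)
    w2 <- w2 + noise * edge
  }
  w2[edge] <- pmin(1, pmax(0.01, w2[edge]))
  if (config$isolate_prob > 0 && stats::runif(1) < config$isolate_prob) {
    drop <- sample.int(nrow(w2), 1L)
    w2[drop, ] <- 0
    w2[, drop] <- 0
  }
  dimnames(w2) <- dimnames(template)
  new_connectivity_matrix(w2, scan_id = visit$scan_id)
}

#' Simulate a complete study
#'
#' Runs [generate_cohort()] and [generate_connectome()] for every visit.
#'
#' @param config A [cohort_config()].
#' @return List: `participants`, `visits`, `symptoms`, `matrices` (named list
#'   of connectivity matrices keyed by scan id), `template`.
#' @export
simulate_study <- function(config) {
  tabs <- generate_cohort(config)
  template <- connectome_template(config)
  mats <- vector("list", nrow(tabs$visits))
  for (i in seq_len(nrow(tabs$visits))) {
    v <- tabs$visits[i, ]
    p <- tabs$participants[tabs$participants$participant_id == v$participant_id, ]
    mats[[i]] <- generate_connectome(p, v, config, template, scan_index = i)
  }
  names(mats) <- tabs$visits$scan_id
  c(tabs, list(matrices = mats, template = template))
}

#' Write a simulated study to disk
#'
#' Writes `phenotype.csv`, `symptoms.csv` and one whitespace-delimited matrix
#' text file per scan (`<participant>_<visit>.txt`) under `dir`.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pheno <- merge(study$visits, study$participants, by = "participant_id")
  pheno <- pheno[order(pheno$scan_id),
                 c("participant_id", "scan_id", "group", "site", "sex",
                   "age_at_injury", "days_post_injury", "visit",
                   "assigned_chronic_day")]
  utils::write.csv(pheno, file.path(dir, "phenotype.csv"), row.names = FALSE)
  utils::write.csv(study$symptoms, file.path(dir, "symptoms.csv"),
                   row.names = FALSE)
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  for (id in names(study$matrices)) {
    write_matrix_txt(study$matrices[[id]], file.path(mdir, paste0(id, ".txt")))
  }
  invisible(dir)
}
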