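# Direct construction of model frames with known generating coefficients,
# bypassing the connectome stages, to test the inference machinery on its own.
sim_frame <- function(n_participants, sd_participant = 0.5, sd_resid = 0.5,
                      gen = function(G, T, A, S) 0) {
  n <- n_participants
  pid <- sprintf("P%03d", seq_len(n))
  group <- sample(rep(c("TBI", "OI"), length.out = n))
  sex <- sample(rep(c("M", "F"), length.out = n))
  age <- runif(n, 8, 17)
  pa_day <- round(runif(n, 2, 33))
  ch_assigned <- sample(c(90, 180), n, replace = TRUE)
  ch_day <- ch_assigned + round(rnorm(n, 0, 7))
  df <- data.frame(
    participant_id = rep(pid, 2),
    scan_id = c(paste0(pid, "_postacute"), paste0(pid, "_chronic")),
    visit = rep(c("postacute", "chronic"), each = n),
    days_post_injury = c(pa_day, ch_day),
    assigned_chronic_day = c(rep(NA, n), ch_assigned),
    Group = factor(rep(group, 2), levels = c("OI", "TBI")),
    Sex = factor(rep(sex, 2), levels = c("M", "F")),
    Age = rep(age, 2)
  )
  mu <- mean(df$days_post_injury); sdv <- sd(df$days_post_injury)
  df$Time <- (df$days_post_injury - mu) / sdv
  df$Time2 <- df$Time^2
  b_i <- rnorm(n, 0, sd_participant)
  df$value <- gen(as.numeric(df$Group == "TBI"), df$Time, df$Age,
                  as.numeric(df$Sex == "F")) +
    rep(b_i, 2) + rnorm(2 * n, 0, sd_resid)
  attr(df, "time_center") <- mu
  attr(df, "time_scale") <- sdv
  df
}

test_that("build_design produces the documented rows, codings and centring", {
  cfg <- cohort_config(n_tbi = 12L, n_oi = 8L, seed = 31L)
  st <- simulate_study(cfg)
  per_scan <- lapply(names(st$matrices), function(id)
    compute_scan_metrics(st$matrices[[id]], n_null = 0, scan_id = id))
  metrics <- metrics_long_table(per_scan)
  metrics <- metrics[!is.na(metrics$value), ]
  phenotype <- merge(st$visits, st$participants, by = "participant_id")
  n_scans <- length(st$matrices)

  fr_g <- build_design(metrics, phenotype, "Cp", "global")
  expect_equal(nrow(fr_g), n_scans)
  expect_lt(abs(mean(fr_g$Time)), 1e-12)
  expect_equal(levels(fr_g$Group), c("OI", "TBI"))
  expect_equal(levels(fr_g$Sex), c("M", "F"))
  expect_false("Hemisphere" %in% names(fr_g))

  fr_n <- build_design(metrics, phenotype, "NCp", "nodal", region = "THA")
  expect_equal(nrow(fr_n), 2 * n_scans)
  expect_equal(levels(fr_n$Hemisphere), c("L", "R"))
  expect_setequal(unique(as.character(fr_n$Hemisphere)), c("L", "R"))
})

test_that("pure fixed-effect data is recovered exactly by the degenerate fit", {
  set.seed(7)
  fr <- sim_frame(80, sd_participant = 0, sd_resid = 0,
                  gen = function(G, T, A, S) 0.4 * G + 0.2 * G * T - 0.1 * G * S)
  fr <- fr[fr$visit == "postacute", ]  # single scan per participant
  expect_warning(fit <- fit_lmm(fr), "repeated")
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_lt(abs(est[["GroupTBI"]] - 0.4), 1e-8)
  expect_lt(abs(est[["GroupTBI:Time"]] - 0.2), 1e-8)
  expect_lt(abs(est[["GroupTBI:SexF"]] + 0.1), 1e-8)
  expect_lt(max(abs(est[setdiff(names(est), c("GroupTBI", "GroupTBI:Time",
                                              "GroupTBI:SexF", "(Intercept)"))])),
            1e-8)
})

test_that("variance components and Satterthwaite df are produced by the mixed fit", {
  set.seed(13)
  fr <- sim_frame(60, sd_participant = 0.6, sd_resid = 0.4,
                  gen = function(G, T, A, S) 0.3 * G)
  fit <- fit_lmm(fr)
  expect_true(fit$converged)
  expect_gt(fit$var_participant, 0)
  expect_gt(fit$var_resid, 0)
  expect_true(all(is.finite(fit$terms$df)))
  expect_true(all(fit$terms$p >= 0 & fit$terms$p <= 1))
  # participant variance dominates residual by construction
  expect_gt(fit$var_participant, fit$var_resid)
})

test_that("type-I error of the group term is controlled under the null", {
  set.seed(29)
  n_rep <- 200
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    fr <- sim_frame(100, sd_participant = 0.5, sd_resid = 0.5)
    fit <- suppressMessages(fit_lmm(fr))
    p <- fit$terms$p[fit$terms$term == "GroupTBI"]
    rej[r] <- p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})

test_that("an injected three-way group-time-sex coefficient is recovered", {
  set.seed(97)
  ests <- vapply(1:25, function(r) {
    fr <- sim_frame(275, sd_participant = 0.5477, sd_resid = 0.8367,
                    gen = function(G, T, A, S) 0.3 * G * T * S)
    fit <- fit_lmm(fr)
    fit$terms$estimate[fit$terms$term == "GroupTBI:Time:SexF"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.3) / 0.3, 0.10)
})

test_that("BH correction follows its step-up definition and controls FDR", {
  # worked examples
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$rejected))
  expect_false(any(fdr_correct(rep(1, 6), alpha = 0.05)$rejected))
  expect_true(fdr_correct(0.04, alpha = 0.05)$rejected)
  expect_false(fdr_correct(0.04, alpha = 0.025)$rejected)
  expect_error(fdr_correct(numeric(0)), "empty")

  # literal step-up oracle on random p-vectors
  set.seed(11)
  for (i in 1:1000) {
    m <- sample(1:60, 1)
    p <- runif(m)^runif(1, 0.5, 2)
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(fdr_correct(p, alpha)$rejected, oracle_bh_reject(p, alpha))
  }

  # empirical FDR on 45-feature null families
  set.seed(45)
  fdr_hat <- mean(vapply(1:2000, function(r) {
    rej <- fdr_correct(runif(45), alpha = 0.05)$rejected
    as.numeric(any(rej))  # all features null: V/max(R,1) is 0 or 1
  }, numeric(1)))
  expect_lte(fdr_hat, 0.05 + 0.02)
})

test_that("effect sizes are banded, gated and recovered", {
  set.seed(13)
  fr <- sim_frame(50, gen = function(G, T, A, S) 0.2 * G)
  fit <- fit_lmm(fr)
  # synthetic term table entries exercise banding/gating exactly
  fit0 <- fit
  fit0$terms <- data.frame(term = c("a", "b"), estimate = c(0, 0.35),
                           se = c(0.1, 0.12), df = 10, t = 0, p = 1)
  fit0$var_participant <- 0.5; fit0$var_resid <- 0.5
  es_a <- effect_size(fit0, "a")
  expect_equal(es_a$d, 0)
  expect_false(es_a$robust)
  es_b <- effect_size(fit0, "b")
  expect_equal(es_b$band, "small")
  expect_true(es_b$robust)
  expect_equal(es_b$d_lo, (0.35 - 1.96 * 0.12) / 1, tolerance = 1e-12)

  # recovery of a known standardized difference at large n
  set.seed(31)
  ds <- vapply(1:8, function(r) {
    fr <- sim_frame(400, sd_participant = sqrt(0.5), sd_resid = sqrt(0.5),
                    gen = function(G, T, A, S) 0.5 * G)
    effect_size(fit_lmm(fr), "GroupTBI")$d
  }, numeric(1))
  expect_lt(abs(mean(ds) - 0.5), 0.05)
})

test_that("probed contrasts are flat without interactions and exact when noiseless", {
  set.seed(41)
  fr <- sim_frame(120, sd_participant = 0.4, sd_resid = 0.4,
                  gen = function(G, T, A, S) 0.5 * G)
  full <- fit_lmm(fr)
  # a model holding only the group main effect probes identically everywhere
  main_only <- full
  main_only$model <- lmerTest::lmer(value ~ Group + (1 | participant_id),
                                    data = fr, REML = TRUE)
  pr <- probe_interactions(main_only)
  expect_equal(nrow(pr), 12)  # 3 times x 2 sexes x 2 ages, one contrast
  expect_lt(diff(range(pr$estimate)), 1e-8)  # no interaction: flat

  # deterministic group differences recovered exactly at each probe point
  set.seed(43)
  fr2 <- sim_frame(150, sd_participant = 0, sd_resid = 0,
                   gen = function(G, T, A, S) 0.3 * G + 0.2 * G * T - 0.25 * G * S)
  suppressWarnings(fit2 <- fit_lmm(fr2[fr2$visit == "postacute", ]))
  grid <- data.frame(day = c(10, 10), sex = c("M", "F"), age = c(12, 12))
  pr2 <- probe_interactions(fit2, grid)
  tt <- (10 - attr(fr2, "time_center")) / attr(fr2, "time_scale")
  expect_equal(pr2$estimate[pr2$sex == "M"], 0.3 + 0.2 * tt, tolerance = 1e-6)
  expect_equal(pr2$estimate[pr2$sex == "F"], 0.3 + 0.2 * tt - 0.25,
               tolerance = 1e-6)
})

test_that("three-level symptom grouping probes all pairwise contrasts", {
  cfg <- cohort_config(n_tbi = 40L, n_oi = 20L, seed = 61L)
  st <- simulate_study(cfg)
  per_scan <- lapply(names(st$matrices), function(id)
    compute_scan_metrics(st$matrices[[id]], n_null = 0, scan_id = id))
  metrics <- metrics_long_table(per_scan)
  metrics <- metrics[!is.na(metrics$value), ]
  phenotype <- merge(st$visits, st$participants, by = "participant_id")
  rci <- rci_from_tables(st$symptoms, st$participants)
  sg <- assign_symptom_groups(rci$classifications, st$participants)
  fr <- build_design(metrics, phenotype, "Cp", "global", grouping = "symptom",
                     symptom_groups = sg, rater = "parent")
  expect_equal(levels(fr$Group),
               c("OI", "TBI-nonpersistent", "TBI-persistent"))
  fit <- fit_lmm(fr)
  pr <- probe_interactions(fit)
  expect_setequal(unique(pr$contrast),
                  c("TBI-nonpersistent vs OI", "TBI-persistent vs OI",
                    "TBI-persistent vs TBI-nonpersistent"))
})

test_that("refitting with relabelled participants reproduces the estimates", {
  set.seed(53)
  fr <- sim_frame(60, gen = function(G, T, A, S) 0.2 * G)
  fit1 <- fit_lmm(fr)
  fr2 <- fr
  map <- setNames(sprintf("Q%03d", seq_along(unique(fr$participant_id))),
                  sample(unique(fr$participant_id)))
  fr2$participant_id <- unname(map[fr2$participant_id])
  fit2 <- fit_lmm(fr2)
  expect_equal(fit2$terms$estimate, fit1$terms$estimate, tolerance = 1e-8)
  expect_equal(fit2$var_participant, fit1$var_participant, tolerance = 1e-8)
})

test_that("analyze_metrics assembles families, FDR and probes into one table", {
  eff <- injected_effect(c("THA.L", "THA.R"), direction = -1, magnitude = 0.12,
                         group = "TBI")
  cfg <- cohort_config(n_tbi = 40L, n_oi = 20L, effect_spec = list(eff),
                       noise_sd_edge = 0.01, seed = 71L)
  st <- simulate_study(cfg)
  per_scan <- lapply(names(st$matrices), function(id)
    compute_scan_metrics(st$matrices[[id]], n_null = 0, scan_id = id))
  metrics <- metrics_long_table(per_scan)
  metrics <- metrics[!is.na(metrics$value), ]
  metrics <- metrics[metrics$metric %in% c("Eg", "NCp"), ]
  metrics <- metrics[metrics$level == "global" |
                       region_stems(metrics$region) %in%
                       c("THA", "PreCG", "HIP", "CAL"), ]
  phenotype <- merge(st$visits, st$participants, by = "participant_id")
  res <- analyze_metrics(metrics, phenotype, grouping = "injury")
  expect_true(all(c("metric", "term", "p", "p_fdr", "d", "robust", "band")
                  %in% names(res)))
  # FDR family: group-involving terms only
  expect_true(all(is.na(res$p_fdr[!grepl("Group|probe", res$term)])))
  ncp <- res[res$metric == "NCp" & res$term == "GroupTBI", ]
  expect_equal(nrow(ncp), 4)
  # the thalamic deficit is the strongest and negative
  expect_equal(ncp$region[which.min(ncp$p)], "THA")
  expect_lt(ncp$estimate[ncp$region == "THA"], 0)
  expect_true(ncp$significant[ncp$region == "THA"])
})
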