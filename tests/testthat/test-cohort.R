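test_that("cohort counts follow the configuration", {
  cfg <- cohort_config(n_tbi = 10L, n_oi = 5L, attrition_chronic = 0, seed = 1L)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$participants), 15)
  expect_equal(nrow(coh$visits), 30)
  expect_equal(sum(coh$participants$group == "TBI"), 10)
  expect_true(all(coh$visits$days_post_injury[coh$visits$visit == "postacute"] %in% 2:33))
  expect_true(all(table(coh$visits$participant_id) == 2))
  # OI participants carry no latent TBI symptom status
  expect_true(all(is.na(coh$participants$latent_status[coh$participants$group == "OI"])))
  expect_false(anyNA(coh$participants$latent_status[coh$participants$group == "TBI"]))
  # premorbid ratings exist only for the parent rater
  pre <- coh$symptoms[coh$symptoms$timepoint == "premorbid", ]
  expect_true(all(pre$rater == "parent"))
  expect_true(all(coh$symptoms$total_score >= 0))
})

test_that("identical config and seed reproduce identical outputs", {
  cfg <- cohort_config(n_tbi = 6L, n_oi = 4L, seed = 42L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$symptoms, s2$symptoms)
  expect_identical(s1$matrices, s2$matrices)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_tbi = 0), "positive")
  expect_error(cohort_config(sites = character(0)), "site")
  expect_error(cohort_config(male_fraction = 1.5), "male_fraction")
  expect_error(cohort_config(age_range = c(5, 16)), "age_range")
})

test_that("marginal rates match the configuration at large n", {
  cfg <- cohort_config(n_tbi = 1300L, n_oi = 700L, attrition_chronic = 0.25,
                       seed = 8L)
  coh <- generate_cohort(cfg)
  p <- coh$participants
  expect_equal(mean(p$sex == "M"), 0.59, tolerance = 0.05)
  expect_true(all(p$age_at_injury >= 8 & p$age_at_injury <= 16.99))
  chron <- coh$visits[coh$visits$visit == "chronic", ]
  expect_equal(nrow(chron) / nrow(p), 0.75, tolerance = 0.05)
  expect_equal(mean(chron$assigned_chronic_day == 90), 0.5, tolerance = 0.05)
  expect_lt(abs(mean(p$latent_status == "persistent", na.rm = TRUE) - 0.22), 0.04)
})

test_that("with no site/age/noise effects the connectome equals the template", {
  cfg <- cohort_config(n_tbi = 2L, n_oi = 1L, site_additive = 0,
                       site_multiplicative = 1, noise_sd_edge = 0,
                       age_slope = 0, seed = 2L)
  tpl <- connectome_template(cfg)
  coh <- generate_cohort(cfg)
  w <- generate_connectome(coh$participants[1, ], coh$visits[1, ], cfg, tpl)
  expect_equal(unclass(w), unclass(tpl), ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("site additive shifts are recovered in mean edge weights", {
  cfg <- cohort_config(n_tbi = 200L, n_oi = 200L, sites = c("A", "B"),
                       site_additive = c(0, 0.05), site_multiplicative = c(1, 1),
                       noise_sd_edge = 0.01, age_slope = 0,
                       attrition_chronic = 1, seed = 7L)
  tpl <- connectome_template(cfg)
  coh <- generate_cohort(cfg)
  idx <- seq_len(nrow(coh$visits))
  means <- vapply(idx, function(i) {
    v <- coh$visits[i, ]
    p <- coh$participants[coh$participants$participant_id == v$participant_id, ]
    w <- generate_connectome(p, v, cfg, tpl, scan_index = i)
    mean(w[w > 0])
  }, numeric(1))
  site <- coh$participants$site[match(coh$visits$participant_id,
                                      coh$participants$participant_id)]
  diff_ba <- mean(means[site == "B"]) - mean(means[site == "A"])
  expect_equal(diff_ba, 0.05, tolerance = 0.002)
})

test_that("injected effects are local to edges incident to target regions", {
  eff <- injected_effect("THA.L", direction = -1, magnitude = 0.08,
                         group = "TBI")
  cfg <- cohort_config(n_tbi = 500L, n_oi = 500L, site_additive = 0,
                       site_multiplicative = 1, noise_sd_edge = 0.02,
                       age_slope = 0, attrition_chronic = 1,
                       effect_spec = list(eff), seed = 21L)
  tpl <- connectome_template(cfg)
  coh <- generate_cohort(cfg)
  labels <- rownames(tpl)
  tha <- which(labels == "THA.L")
  # a template edge incident to the target and one far from it
  inc_j <- which(tpl[tha, ] > 0)[1]
  far <- which(labels == "PreCG.L")
  far_j <- setdiff(which(tpl[far, ] > 0), tha)[1]
  pa <- coh$visits[coh$visits$visit == "postacute", ]
  vals <- t(vapply(seq_len(nrow(pa)), function(i) {
    v <- pa[i, ]
    p <- coh$participants[coh$participants$participant_id == v$participant_id, ]
    w <- generate_connectome(p, v, cfg, tpl, scan_index = i)
    c(w[tha, inc_j], w[far, far_j])
  }, numeric(2)))
  grp <- coh$participants$group[match(pa$participant_id,
                                      coh$participants$participant_id)]
  # incident edge shifts by the injected magnitude in the TBI stratum
  expect_lt(abs(mean(vals[grp == "TBI", 1]) - mean(vals[grp == "OI", 1]) + 0.08),
            0.005)
  # non-incident edge distributions are indistinguishable across strata
  ks <- suppressWarnings(ks.test(vals[grp == "TBI", 2], vals[grp == "OI", 2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a conditioned thalamic deficit lowers thalamic clustering in its stratum", {
  eff <- injected_effect(c("THA.L", "THA.R"), direction = -1, magnitude = 0.10,
                         group = "TBI", status = "persistent", sex = "F",
                         day_min = 150)
  cfg <- cohort_config(n_tbi = 500L, n_oi = 500L, male_fraction = 0,
                       latent_persistent_prob = 1, chronic_assign_prob = 0,
                       attrition_chronic = 0, effect_spec = list(eff),
                       site_additive = 0, site_multiplicative = 1,
                       age_slope = 0, seed = 12L)
  tpl <- connectome_template(cfg)
  coh <- generate_cohort(cfg)
  ch <- coh$visits[coh$visits$visit == "chronic" &
                     coh$visits$days_post_injury >= 150, ]
  tha <- which(rownames(tpl) %in% c("THA.L", "THA.R"))
  ncp_tha <- vapply(seq_len(nrow(ch)), function(i) {
    v <- ch[i, ]
    p <- coh$participants[coh$participants$participant_id == v$participant_id, ]
    w <- generate_connectome(p, v, cfg, tpl, scan_index = 1000L + i)
    mean(clustering_coefficients(w)$NCp[tha])
  }, numeric(1))
  grp <- coh$participants$group[match(ch$participant_id,
                                      coh$participants$participant_id)]
  expect_lt(mean(ncp_tha[grp == "TBI"]), mean(ncp_tha[grp == "OI"]))
  expect_gt(t.test(ncp_tha[grp == "OI"], ncp_tha[grp == "TBI"])$statistic, 3)
})

test_that("unknown sites and target regions are rejected", {
  cfg <- cohort_config(n_tbi = 2L, n_oi = 1L, seed = 1L)
  coh <- generate_cohort(cfg)
  tpl <- connectome_template(cfg)
  p <- coh$participants[1, ]
  p$site <- "nowhere"
  expect_error(generate_connectome(p, coh$visits[1, ], cfg, tpl), "unknown site")
  cfg2 <- cohort_config(n_tbi = 2L, n_oi = 1L, seed = 1L,
                        effect_spec = list(injected_effect("NOT_A_REGION")))
  expect_error(generate_connectome(coh$participants[1, ], coh$visits[1, ],
                                   cfg2, tpl), "unknown target region")
})

test_that("latent persistent cases with a 2-SEE shift are mostly classified persistent", {
  # With the reliable-change reference fitted on the uncontaminated OI group,
  # a +2*SEE generating shift implies a persistent-classification probability
  # of about pnorm(2 - 1.645) ~= 0.64 for latent-persistent cases.
  rates <- vapply(1:3, function(s) {
    cfg <- cohort_config(n_tbi = 2000L, n_oi = 1000L, seed = s,
                         symptom_shift_tbi = 0,
                         symptom_shift_persistent = 6, symptom_noise_sd = 3)
    coh <- generate_cohort(cfg)
    rci <- rci_from_tables(coh$symptoms, coh$participants, reference = "oi")
    cl <- rci$classifications
    cl <- cl[cl$rater == "parent", ]
    lat <- coh$participants$latent_status[match(cl$participant_id,
                                                coh$participants$participant_id)]
    mean(cl$status[!is.na(lat) & lat == "persistent"] == "persistent")
  }, numeric(1))
  expect_gt(mean(rates), 0.60)
})

test_that("write_study emits the documented file contract", {
  cfg <- cohort_config(n_tbi = 3L, n_oi = 2L, attrition_chronic = 0, seed = 4L)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "phenotype.csv")))
  expect_true(file.exists(file.path(dir, "symptoms.csv")))
  mats <- list.files(file.path(dir, "matrices"), pattern = "\\.txt$")
  expect_length(mats, 10)
  ph <- read.csv(file.path(dir, "phenotype.csv"))
  expect_true(all(c("participant_id", "scan_id", "group", "site", "sex",
                    "age_at_injury", "days_post_injury", "visit") %in% names(ph)))
  expect_equal(nrow(validate_inputs(dir)), 0)
})
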