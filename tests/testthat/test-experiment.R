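small_cfg <- function(paradigm, ...) {
  simulation_config(paradigm,
    n_patients = 120, horizon_years = 10,
    n_replications = 2, seed = 5, ...
  )
}

test_that("configurations validate their fields", {
  cfg <- simulation_config()
  expect_s3_class(cfg, "menisim_config")
  expect_equal(cfg$n_patients, 1040L)
  expect_equal(cfg$horizon_years, 20L)
  expect_equal(cfg$wait_threshold, 104)
  expect_equal(cfg$n_replications, 10L)
  expect_error(simulation_config(scenario = "bogus"), "unknown scenario")
  expect_error(simulation_config(n_patients = 0))
  expect_error(simulation_config(wait_threshold = 5000)) # beyond the horizon
  expect_error(simulation_config(costs = list(cost_r = 1)), "must provide")
})

test_that("configurations round-trip through YAML and JSON files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(
    c(
      "paradigm: 3dp",
      "scenario: s5",
      "n_patients: 200",
      "horizon_years: 10",
      "n_replications: 3",
      "seed: 99",
      "costs:",
      "  cost_ni: 0",
      "  cost_r: 2760",
      "  cost_ro: 1770",
      "  cost_tka: 14167",
      "  cost_wait: 30",
      "  cost_transplant: 7249"
    ),
    path
  )
  cfg <- read_simulation_config(path)
  expect_equal(cfg$paradigm, "3dp")
  expect_equal(cfg$scenario, "s5")
  expect_equal(cfg$n_patients, 200L)
  expect_equal(cfg$costs$cost_transplant, 7249)

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"paradigm": "traditional", "seed": 3, "n_patients": 50}', jpath)
  jcfg <- read_simulation_config(jpath)
  expect_equal(jcfg$paradigm, "traditional")
  expect_equal(jcfg$n_patients, 50L)

  writeLines('{"paradgim": "traditional"}', jpath)
  expect_error(read_simulation_config(jpath), "unknown configuration keys")
})

test_that("replication outputs are cumulative, decomposed and reproducible", {
  for (paradigm in c("traditional", "3dp")) {
    cfg <- small_cfg(paradigm)
    y <- run_replication(cfg, seed = 17)
    expect_equal(nrow(y), cfg$horizon_years)
    for (col in c("cum_tka_waiting", "cum_tka_post", "cum_tka_total", "cum_cost_usd")) {
      expect_true(all(y[[col]] >= 0))
      expect_true(all(diff(y[[col]]) >= 0))
    }
    expect_equal(y$cum_tka_total, y$cum_tka_waiting + y$cum_tka_post)
    expect_identical(run_replication(cfg, seed = 17), y)
  }
  # no queue in the 3DP pathway: waiting TKA identically zero
  y3 <- run_replication(small_cfg("3dp"), seed = 4)
  expect_true(all(y3$cum_tka_waiting == 0))
})

test_that("instant donors and an uneventful matrix leave only transplant fees", {
  cfg <- simulation_config("traditional",
    n_patients = 150, horizon_years = 20, n_replications = 1, seed = 8,
    donor_mean_range = c(0.01, 0.02),
    transition_matrix = all_ni_matrix()
  )
  y <- run_replication(cfg, seed = 21)
  expect_equal(y$cum_cost_usd[20], 150 * 8875)
  expect_equal(y$cum_tka_total[20], 0)
})

test_that("replication cost totals match independent per-patient accrual", {
  cfg <- small_cfg("traditional")
  y <- run_replication(cfg, seed = 31, keep_details = TRUE)
  det <- attr(y, "details")
  costs <- cost_table("traditional")
  horizon <- cfg$horizon_years * cfg$weeks_per_year
  total <- 0
  for (i in seq_len(nrow(det$dispositions))) {
    d <- det$dispositions[i, ]
    traj <- NULL
    if (d$outcome == "TRANSPLANTED") {
      evs <- dplyr::filter(det$state_events, patient == i)
      traj <- tibble::tibble(cycle = evs$cycle, state = evs$state)
    }
    total <- total + sum(accrue_patient_cost(d, traj, costs, horizon)$cost)
  }
  expect_equal(total, y$cum_cost_usd[cfg$horizon_years], tolerance = 1e-9)
})

test_that("experiments average replications and are seed-deterministic", {
  cfg <- small_cfg("3dp")
  exp1 <- run_experiment(cfg)
  expect_s3_class(exp1, "menisim_experiment")
  expect_equal(nrow(exp1$yearly), cfg$horizon_years)
  expect_true(all(c("se_cum_cost_usd", "se_cum_tka_total") %in% names(exp1$yearly)))

  exp2 <- run_experiment(cfg)
  expect_equal(exp1$yearly, exp2$yearly)

  single <- small_cfg("3dp")
  single$n_replications <- 1L
  got <- run_experiment(single)
  seed1 <- menisim:::.replication_seeds(single$seed, 1L)
  expect_equal(
    got$yearly$cum_cost_usd,
    run_replication(single, seed1)$cum_cost_usd
  )

  # averaged series keep the decomposition identity
  expect_equal(
    exp1$yearly$cum_tka_total,
    exp1$yearly$cum_tka_waiting + exp1$yearly$cum_tka_post
  )
})

test_that("sensitivity sweeps share random numbers and order by quality", {
  cfg <- small_cfg("3dp")
  sens <- run_sensitivity(cfg, c("s8", "original", "s7"))
  expect_s3_class(sens, "menisim_sensitivity")
  g <- glance(sens)
  expect_equal(g$scenario, c("s8", "original", "s7"))
  # original run in a sweep is bitwise-identical to a standalone experiment
  expect_equal(sens$results$original$yearly, run_experiment(cfg)$yearly)
  # under common random numbers a better implant never does worse
  y7 <- sens$results$s7$yearly
  y8 <- sens$results$s8$yearly
  expect_true(all(y8$cum_tka_total <= y7$cum_tka_total))
  expect_true(all(y8$cum_cost_usd <= y7$cum_cost_usd))
  expect_error(run_sensitivity(small_cfg("traditional")), "3dp")
  expect_error(run_sensitivity(cfg, "s99"), "unknown scenarios")
})

test_that("tidiers and plots expose the result objects", {
  cfg <- small_cfg("3dp")
  res <- run_experiment(cfg)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), cfg$horizon_years)
  expect_equal(nrow(tidy(res, replications = TRUE)), cfg$horizon_years * cfg$n_replications)
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  expect_equal(g$cum_cost_musd, g$cum_cost_usd / 1e6)
  expect_s3_class(autoplot(res), "ggplot")

  sens <- run_sensitivity(cfg, c("original", "s2"))
  expect_equal(sort(unique(tidy(sens)$scenario)), c("original", "s2"))
  expect_equal(nrow(glance(sens)), 2L)
  expect_s3_class(autoplot(sens), "ggplot")
  expect_output(print(res), "Pathway experiment")
  expect_output(print(cfg), "3dp")
})

test_that("still-waiting patients at the horizon follow the chosen policy", {
  # arrivals span well past week 52, so some timeouts fall beyond the
  # 156-week horizon; the queue is starved so those patients stay waiting
  base <- list(
    paradigm = "traditional", n_patients = 150, horizon_years = 3,
    wait_threshold = 104, n_replications = 1, seed = 2,
    donor_mean_range = c(30, 40)
  )
  censor <- do.call(simulation_config, c(base, list(horizon_queue_policy = "censor")))
  force <- do.call(simulation_config, c(base, list(horizon_queue_policy = "force_tka")))
  y_censor <- run_replication(censor, seed = 6)
  y_force <- run_replication(force, seed = 6)
  # forcing can only add waiting TKAs, and only at the final year
  expect_gte(y_force$cum_tka_waiting[3], y_censor$cum_tka_waiting[3])
  expect_equal(y_force$cum_tka_waiting[1:2], y_censor$cum_tka_waiting[1:2])
  expect_gt(y_force$cum_tka_waiting[3], y_censor$cum_tka_waiting[3])
})
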