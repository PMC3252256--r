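test_that("the same seed reproduces a simulation exactly; seeds differ", {
  cfg <- random_small_config(1)
  a <- simulate_wards(cfg)
  b <- simulate_wards(cfg)
  expect_identical(a$true_consumption, b$true_consumption)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$flows, b$flows)
  expect_identical(a$sales, b$sales)
  c2 <- simulate_wards(cfg, seed = cfg$seed + 1)
  expect_false(identical(a$sales, c2$sales))
})

test_that("per-cell random streams are stable under config extension", {
  cfg <- default_study_config(seed = 5)
  small <- sim_config(
    dplyr::filter(cfg$demand, agent_id != "meropenem"),
    seed = 5
  )
  a <- simulate_wards(cfg)
  b <- simulate_wards(small)
  keep <- a$true_consumption$agent_id != "meropenem"
  expect_identical(a$true_consumption[keep, ], b$true_consumption)
})

test_that("zero demand yields zero consumption, zero sales, flat stock", {
  cfg <- sim_config(
    tibble::tibble(
      ward_id = "w1",
      agent_id = c("cefuroxime", "ciprofloxacin_oral"),
      mean_weekly_ddd = 0
    ),
    weeks = 6, missing_blocks = NULL, seed = 9
  )
  sim <- simulate_wards(cfg)
  expect_true(all(sim$true_consumption$ddd == 0))
  expect_equal(nrow(sim$sales), 0)
  per_agent <- split(sim$snapshots$packs, sim$snapshots$agent_id)
  for (p in per_agent) expect_equal(length(unique(p)), 1)
})

test_that("stock balance holds at every simulated week boundary", {
  sim <- simulate_wards(default_study_config(seed = 3, missing_blocks = NULL))
  ref <- sim$config$ref
  snaps <- sim$snapshots |>
    dplyr::mutate(ddd = packs_to_ddd(packs, agent_id, ref))
  for (cell in split(snaps, interaction(snaps$ward_id, snaps$agent_id))) {
    cell <- cell[order(cell$week), ]
    fl <- sim$flows[
      sim$flows$ward_id == cell$ward_id[1] &
        sim$flows$agent_id == cell$agent_id[1],
    ]
    tr <- sim$true_consumption[
      sim$true_consumption$ward_id == cell$ward_id[1] &
        sim$true_consumption$agent_id == cell$agent_id[1],
    ]
    for (w in seq_len(max(cell$week))) {
      fw <- fl[fl$week == w, ]
      signed <- sum(ifelse(
        fw$flow_type %in% c("delivery", "loan_in"),
        fw$amount_ddd, -fw$amount_ddd
      ))
      expect_equal(
        cell$ddd[cell$week == w],
        cell$ddd[cell$week == w - 1] + signed - tr$ddd[tr$week == w],
        tolerance = 1e-9
      )
    }
  }
})

test_that("ward accounting recovers simulated truth exactly, both demand models", {
  for (model in c("poisson_daily", "patient_courses")) {
    cfg <- default_study_config(
      seed = 17, missing_blocks = NULL, demand_model = model
    )
    sim <- simulate_wards(cfg)
    ward <- ward_consumption(sim$snapshots, sim$flows, cfg$ref)
    j <- dplyr::inner_join(
      ward, sim$true_consumption,
      by = c("ward_id", "agent_id", "week"), suffix = c("_acc", "_true")
    )
    expect_equal(nrow(j), nrow(sim$true_consumption))
    expect_lt(max(abs(j$ddd_acc - j$ddd_true)), 1e-9)
  }
})

test_that("sales equal consumption plus stock change plus net non-consumption", {
  sim <- simulate_wards(default_study_config(seed = 23, missing_blocks = NULL))
  ref <- sim$config$ref
  snaps <- sim$snapshots |>
    dplyr::mutate(ddd = packs_to_ddd(packs, agent_id, ref))
  w_max <- max(snaps$week)
  stock_change <- sum(snaps$ddd[snaps$week == w_max]) -
    sum(snaps$ddd[snaps$week == 0])
  out_flows <- sum(sim$flows$amount_ddd[
    sim$flows$flow_type %in%
      c("loan_out", "discharge_takeaway", "discard", "return_to_pharmacy")
  ])
  in_flows <- sum(sim$flows$amount_ddd[sim$flows$flow_type == "loan_in"])
  expect_equal(
    sum(sim$sales$ddd),
    sum(sim$true_consumption$ddd) + stock_change + out_flows - in_flows,
    tolerance = 1e-9
  )
})

test_that("holiday blocks suppress interior count boundaries only", {
  sim <- simulate_wards(default_study_config(seed = 2))
  bounds <- sort(unique(sim$snapshots$week))
  expect_false(any(c(10, 11, 25) %in% bounds))
  expect_true(all(c(0, 9, 12, 24, 26) %in% bounds))
  # gap averaging redistributes within blocks but never creates mass:
  # the accounted total still equals the simulated truth
  series <- sim_to_series(sim)
  expect_equal(sum(series$ward$ddd), sum(sim$true_consumption$ddd),
    tolerance = 1e-9
  )
})

test_that("default scenario reproduces the study's structural magnitudes", {
  cfg <- default_study_config()
  # analytic expectation from the configured rates
  expected_total <- sum(cfg$demand$mean_weekly_ddd) * cfg$weeks
  expect_gt(expected_total, 3500)
  expect_lt(expected_total, 4500)
  # urology wards order no carbapenems at all
  uro <- dplyr::filter(
    cfg$demand, ward_id %in% c("urology_1", "urology_2"),
    agent_id %in% c("meropenem", "imipenem_cilastatin")
  )
  expect_true(all(uro$mean_weekly_ddd == 0))
  sim <- simulate_wards(cfg)
  expect_true(all(
    sim$true_consumption$ddd[
      sim$true_consumption$ward_id %in% c("urology_1", "urology_2") &
        sim$true_consumption$agent_id %in%
          c("meropenem", "imipenem_cilastatin")
    ] == 0
  ))
  # 5 wards x 8 agents x 26 weeks of paired output
  series <- sim_to_series(sim)
  expect_equal(
    nrow(build_paired_registrations(series$pharm, series$ward, k = 1)),
    1040
  )
})

test_that("order sizes match the configured route profiles", {
  sim <- simulate_wards(default_study_config(seed = 31))
  ref <- sim$config$ref
  sales <- dplyr::inner_join(
    sim$sales, tibble::as_tibble(ref)[c("agent_id", "route")],
    by = "agent_id"
  )
  par <- sales$ddd[sales$route == "parenteral"]
  oral <- sales$ddd[sales$route == "oral"]
  expect_true(all(par >= 5 - 1e-9 & par <= 10 + 1e-9))
  expect_true(all(oral >= 5 - 1e-9 & oral <= 50 + 1e-9))
  expect_gte(median(par), 5)
  expect_lte(median(par), 10)
  expect_gt(median(oral), median(par)) # bulkier oral orders
})

test_that("non-consumption flows average about 1% of use across replicates", {
  shares <- vapply(1:20, function(s) {
    sim <- simulate_wards(default_study_config(seed = 100 + s))
    non_consumption_share(sim$flows, sum(sim$true_consumption$ddd))
  }, numeric(1))
  expect_equal(mean(shares), 1, tolerance = 0.5)
})

test_that("dropping manual flow records degrades accounting accuracy", {
  cfg <- default_study_config(seed = 4, missing_blocks = NULL)
  sim <- simulate_wards(cfg)
  err <- function(s) {
    ward <- ward_consumption(s$snapshots, s$flows, cfg$ref)
    j <- dplyr::inner_join(
      ward, s$true_consumption,
      by = c("ward_id", "agent_id", "week"), suffix = c("_acc", "_true")
    )
    sum(abs(j$ddd_acc - j$ddd_true))
  }
  full <- err(sim)
  half <- err(degrade_to_observed(sim, 0.5))
  none <- err(degrade_to_observed(sim, 1))
  expect_lt(full, 1e-9)
  expect_gt(half, full)
  expect_gte(none, half)
  # fraction 0 is the identity; fraction 1 removes every manual record
  expect_identical(degrade_to_observed(sim, 0)$flows, sim$flows)
  left <- degrade_to_observed(sim, 1)$flows
  expect_false(any(
    left$flow_type %in% c("loan_in", "loan_out", "discharge_takeaway")
  ))
  expect_true(all(c("delivery", "discard") %in% left$flow_type))
})

test_that("invalid configurations are rejected", {
  expect_error(
    sim_config(
      tibble::tibble(
        ward_id = "w", agent_id = "cefuroxime", mean_weekly_ddd = -1
      )
    ),
    class = "abxflow_error_validation"
  )
  bad_policy <- default_order_policy()
  bad_policy$sizes[[1]] <- numeric(0)
  expect_error(
    sim_config(default_study_demand(), order_policy = bad_policy),
    class = "abxflow_error_validation"
  )
  expect_error(
    sim_config(default_study_demand(), missing_blocks = list(25:30)),
    class = "abxflow_error_validation"
  )
  expect_error(
    sim_config(
      tibble::tibble(
        ward_id = "w", agent_id = "unknown", mean_weekly_ddd = 1
      )
    ),
    class = "abxflow_error_lookup"
  )
})
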