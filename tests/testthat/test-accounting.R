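# tiny_ref(): cefA packs are 0.5 DDD, cipO packs 1 DDD

test_that("single-week ward balance reproduces hand-computed consumption", {
  ref <- tiny_ref()
  # nothing moved
  out <- weekly_ward_consumption(
    snap_row("w1", 0, "cefA", 20), snap_row("w1", 1, "cefA", 20),
    no_flows(), ref
  )
  expect_equal(out$ddd, 0)
  # prev 30 DDD (60 packs), curr 12 DDD, delivery 10, discard 2 -> 26
  out <- weekly_ward_consumption(
    snap_row("w1", 0, "cefA", 60), snap_row("w1", 1, "cefA", 24),
    dplyr::bind_rows(
      flow_row("w1", 1, "cefA", "delivery", 10),
      flow_row("w1", 1, "cefA", "discard", 2)
    ),
    ref
  )
  expect_equal(out$ddd, 26)
  # prev 5, curr 20, delivery 10, loan_in 9, loan_out 3 -> 1
  out <- weekly_ward_consumption(
    snap_row("w1", 0, "cipO", 5), snap_row("w1", 1, "cipO", 20),
    dplyr::bind_rows(
      flow_row("w1", 1, "cipO", "delivery", 10),
      flow_row("w1", 1, "cipO", "loan_in", 9),
      flow_row("w1", 1, "cipO", "loan_out", 3)
    ),
    ref
  )
  expect_equal(out$ddd, 1)
  # returns to pharmacy net out like discards on the ward side
  out <- weekly_ward_consumption(
    snap_row("w1", 0, "cipO", 10), snap_row("w1", 1, "cipO", 4),
    flow_row("w1", 1, "cipO", "return_to_pharmacy", 2), ref
  )
  expect_equal(out$ddd, 4)
})

test_that("ward balance rejects mismatched wards, gaps and unknown agents", {
  ref <- tiny_ref()
  expect_error(
    weekly_ward_consumption(
      snap_row("w1", 0, "cefA", 1), snap_row("w2", 1, "cefA", 1),
      no_flows(), ref
    ),
    class = "abxflow_error_sequencing"
  )
  expect_error(
    weekly_ward_consumption(
      snap_row("w1", 0, "cefA", 1), snap_row("w1", 2, "cefA", 1),
      no_flows(), ref
    ),
    class = "abxflow_error_sequencing"
  )
  expect_error(
    weekly_ward_consumption(
      snap_row("w1", 0, "mystery", 1), snap_row("w1", 1, "mystery", 1),
      no_flows(), ref
    ),
    class = "abxflow_error_lookup"
  )
})

test_that("pharmacy series nets returns against orders on a complete grid", {
  # empty ledger -> all-zero series on the requested grid
  out <- pharmacy_consumption(
    no_sales(),
    wards = c("w1", "w2"), agents = "cefA", weeks = 1:4
  )
  expect_equal(nrow(out), 8)
  expect_true(all(out$ddd == 0))
  # orders 10 + 5, return 5 -> 10
  sales <- tibble::tibble(
    ward_id = "w1", week = c(2L, 2L), agent_id = "cefA",
    order_id = c("a", "b"), ddd = c(10, 5)
  )
  ret <- flow_row("w1", 2, "cefA", "return_to_pharmacy", 5)
  out <- pharmacy_consumption(sales, ret)
  expect_equal(out$ddd[out$week == 2], 10)
  # a return-heavy week may go negative and is kept
  out <- pharmacy_consumption(
    sales, flow_row("w1", 1, "cefA", "return_to_pharmacy", 3),
    weeks = 1:2
  )
  expect_equal(out$ddd[out$week == 1], -3)
})

test_that("pharmacy cell sums equal a per-record brute-force accumulation", {
  set.seed(42)
  wards <- paste0("w", 1:3)
  agents <- c("cefA", "cipO")
  n <- 200
  sales <- tibble::tibble(
    ward_id = sample(wards, n, TRUE),
    week = sample(1:4, n, TRUE),
    agent_id = sample(agents, n, TRUE),
    order_id = sprintf("o%03d", 1:n),
    ddd = round(runif(n, 0.5, 30), 2)
  )
  out <- pharmacy_consumption(sales, wards = wards, agents = agents, weeks = 1:4)
  # oracle: explicit loop over records
  acc <- array(0, dim = c(3, 2, 4), dimnames = list(wards, agents, 1:4))
  for (i in seq_len(n)) {
    acc[sales$ward_id[i], sales$agent_id[i], sales$week[i]] <-
      acc[sales$ward_id[i], sales$agent_id[i], sales$week[i]] + sales$ddd[i]
  }
  for (j in seq_len(nrow(out))) {
    expect_equal(
      out$ddd[j],
      acc[out$ward_id[j], out$agent_id[j], as.character(out$week[j])]
    )
  }
})

test_that("block imputation averages in-block weeks and conserves totals", {
  s <- constant_series("pharmacy", "w1", "cefA", 8, value = 0)
  s$ddd <- c(1, 2, 3, 12, 6, 12, 7, 8)
  # single-week block is the identity
  expect_equal(impute_missing_blocks(s, list(4))$ddd, s$ddd)
  # block {4,5,6} totalling 30 -> each week 10
  out <- impute_missing_blocks(s, list(4:6))
  expect_equal(out$ddd[4:6], c(10, 10, 10))
  expect_equal(out$ddd[-(4:6)], s$ddd[-(4:6)])
  expect_true(all(out$imputed[4:6]))
  expect_equal(sum(out$ddd), sum(s$ddd)) # conservation
  # idempotent
  expect_equal(impute_missing_blocks(out, list(4:6))$ddd, out$ddd)
  # window and contiguity checks
  expect_error(impute_missing_blocks(s, list(7:9)),
    class = "abxflow_error_validation"
  )
  expect_error(impute_missing_blocks(s, list(c(2, 4))),
    class = "abxflow_error_validation"
  )
})

test_that("interval aggregation partitions retained weeks and conserves mass", {
  set.seed(7)
  s <- constant_series("ward", c("w1", "w2"), c("cefA", "cipO"), 26)
  s$ddd <- runif(nrow(s), 0, 20)
  # k = 1, no omission: identity on weeks
  a1 <- aggregate_intervals(s, 1)
  expect_equal(nrow(a1), 26 * 4)
  expect_equal(sort(a1$ddd), sort(s$ddd))
  # k = 2: 13 intervals per cell
  a2 <- aggregate_intervals(s, 2)
  expect_equal(dplyr::n_distinct(a2$interval), 13)
  expect_equal(sum(a2$ddd), sum(s$ddd))
  # k = 4 with weeks 12 and 26 omitted: 6 intervals; block sums match a
  # brute-force re-summation
  a4 <- aggregate_intervals(s, 4, omit_weeks = c(12, 26))
  expect_equal(dplyr::n_distinct(a4$interval), 6)
  retained <- setdiff(1:26, c(12, 26))
  blocks <- split(retained, rep(1:6, each = 4))
  for (cell in split(s, interaction(s$ward_id, s$agent_id))) {
    got <- a4[a4$ward_id == cell$ward_id[1] &
      a4$agent_id == cell$agent_id[1], ]
    got <- got[order(got$interval), ]
    want <- vapply(
      blocks, function(b) sum(cell$ddd[cell$week %in% b]), numeric(1)
    )
    expect_equal(got$ddd, unname(want))
  }
  # conservation for every k after omission
  for (k in 1:4) {
    omit <- if (26 %% k == 0) integer() else c(12, 26)
    ak <- aggregate_intervals(s, k, omit)
    expect_equal(sum(ak$ddd), sum(s$ddd[s$week %in% setdiff(1:26, omit)]))
  }
  # indivisible length is a configuration error naming the remainder
  expect_error(aggregate_intervals(s, 3), "remainder 2",
    class = "abxflow_error_config"
  )
})

test_that("dual registration counts follow wards x stratum agents x intervals", {
  ref <- default_ddd_reference()
  wards <- paste0("w", 1:5)
  pharm <- constant_series("pharmacy", wards, ref$agent_id, 26)
  ward <- constant_series("ward", wards, ref$agent_id, 26)
  expect_equal(nrow(build_paired_registrations(pharm, ward, k = 1)), 1040)
  expect_equal(
    nrow(build_paired_registrations(
      pharm, ward,
      k = 1, stratum = "oral", ref = ref
    )),
    130 # 1 oral agent x 5 wards x 26 weeks
  )
  expect_equal(
    nrow(build_paired_registrations(
      pharm, ward,
      k = 1, stratum = "parenteral", ref = ref
    )),
    910 # 7 parenteral agents x 5 wards x 26 weeks
  )
  # double-zero registrations are retained
  pharm0 <- dplyr::mutate(pharm, ddd = 0)
  ward0 <- dplyr::mutate(ward, ddd = 0)
  expect_equal(nrow(build_paired_registrations(pharm0, ward0, k = 2)), 520)
  # grid mismatch is rejected
  expect_error(
    build_paired_registrations(pharm[-1, ], ward, k = 1),
    class = "abxflow_error_validation"
  )
})

test_that("grand-total identity: sum of pair differences is k-invariant", {
  set.seed(11)
  wards <- c("w1", "w2")
  agents <- c("cefA", "cipO")
  pharm <- constant_series("pharmacy", wards, agents, 26)
  ward <- constant_series("ward", wards, agents, 26)
  pharm$ddd <- runif(nrow(pharm), 0, 15)
  ward$ddd <- runif(nrow(ward), 0, 15)
  omit <- c(12, 26)
  retained <- setdiff(1:26, omit)
  expected <- sum(pharm$ddd[pharm$week %in% retained]) -
    sum(ward$ddd[ward$week %in% retained])
  for (k in 1:4) {
    pairs <- build_paired_registrations(pharm, ward, k = k, omit_weeks = omit)
    expect_equal(sum(pairs$pharmacy_ddd - pairs$ward_ddd), expected)
  }
})

test_that("percent difference has the pharmacy-anchored form and sign", {
  expect_equal(percent_difference(100, 100), 0)
  expect_equal(round_half_out(percent_difference(200, 150), 1), 25)
  expect_true(is.na(percent_difference(0, 5)))
  # strictly decreasing in the ward value at fixed pharmacy value
  w <- seq(0, 200, by = 10)
  d <- percent_difference(rep(120, length(w)), w)
  expect_true(all(diff(d) < 0))
})

test_that("non-consumption share is the flow sum over total use", {
  flows <- dplyr::bind_rows(
    flow_row("w1", 1, "cefA", "discard", 10.5),
    flow_row("w1", 2, "cefA", "discharge_takeaway", 18.0),
    flow_row("w2", 3, "cipO", "loan_out", 14.5),
    flow_row("w2", 3, "cipO", "delivery", 500), # not counted
    flow_row("w2", 4, "cipO", "loan_in", 9) # not counted
  )
  expect_equal(round_half_out(non_consumption_share(flows, 3969.9), 1), 1.1)
  expect_equal(non_consumption_share(no_flows(), 100), 0)
  expect_equal(non_consumption_share(
    flow_row("w1", 1, "cefA", "discard", 50), 1000
  ), 5)
  expect_error(non_consumption_share(no_flows(), 0),
    class = "abxflow_error_validation"
  )
})

test_that("ward series handles count gaps by block-balance averaging", {
  ref <- tiny_ref()
  # one ward, one agent, 4 weeks, counts missing at boundaries 2 and 3
  snaps <- dplyr::bind_rows(
    snap_row("w1", 0, "cefA", 40), # 20 DDD
    snap_row("w1", 1, "cefA", 30), # 15 DDD
    snap_row("w1", 4, "cefA", 10) # 5 DDD
  )
  flows <- flow_row("w1", 3, "cefA", "delivery", 8)
  out <- ward_consumption(snaps, flows, ref)
  expect_equal(out$ddd[out$week == 1], 5)
  # weeks 2-4: balance over the gap = 15 - 5 + 8 = 18, split into 6 each
  expect_equal(out$ddd[out$week %in% 2:4], rep(6, 3))
  expect_equal(out$imputed, c(FALSE, TRUE, TRUE, TRUE))
  # totals conserved: sum equals whole-window balance
  expect_equal(sum(out$ddd), 20 - 5 + 8)
  # missing terminal boundary is a sequencing error
  expect_error(
    ward_consumption(snaps[2:3, ], flows, ref),
    class = "abxflow_error_sequencing"
  )
})
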