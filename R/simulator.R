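#' Configure a ward/pharmacy simulation
#'
#' The simulator realises the mechanism that makes pharmacy sales an
#' imperfect proxy for consumption: patients draw drugs from a ward-held
#' stock smoothly (daily demand), while the ward replenishes the stock in
#' lumps under a reorder-point policy, so weekly sales fluctuate around
#' true use with the stock as a buffer. Small non-consumption flows
#' (loans, discards, discharge take-aways, returns) and holiday gaps in the
#' count series complete the picture.
#'
#' @param demand tibble `ward_id`, `agent_id`, `mean_weekly_ddd` (>= 0):
#'   expected true consumption per ward x agent per week.
#' @param ref a [ddd_reference()] table covering every agent in `demand`.
#' @param weeks study length in weeks.
#' @param order_policy tibble `route`, `reorder_point_ddd`, `sizes`
#'   (list-column of admissible order sizes in DDDs), `weights` (list-column
#'   of sampling weights). An order is placed whenever shelf stock falls
#'   below the reorder point; it is delivered the same day.
#' @param flow_fractions named list of expected non-consumption flow DDDs
#'   as a fraction of demand: `discard`, `discharge_takeaway`, `loan_out`,
#'   `loan_in`, `return_to_pharmacy` (all >= 0).
#' @param missing_blocks list of consecutive-week ranges during which no
#'   shelf count is taken (holidays), e.g. `list(10:12, 25:26)`; `NULL` for
#'   a complete count series.
#' @param burn_in_weeks unrecorded warm-up weeks simulated before the study
#'   window so ward stock starts in its reorder-policy steady state rather
#'   than at an arbitrary initial level.
#' @param demand_model `"poisson_daily"` (independent daily Poisson draws,
#'   the default) or `"patient_courses"` (Poisson patient arrivals, each
#'   consuming a multi-day course — burstier weekly totals).
#' @param seed integer; fully determines the output.
#' @return an `abx_sim_config` object.
#' @export
sim_config <- function(demand, ref = default_ddd_reference(), weeks = 26,
                       order_policy = default_order_policy(),
                       flow_fractions = default_flow_fractions(),
                       missing_blocks = list(10:12, 25:26),
                       burn_in_weeks = 8,
                       demand_model = c("poisson_daily", "patient_courses"),
                       seed = 1L) {
  demand_model <- match.arg(demand_model)
  demand <- as_tibble(demand)
  check_columns(demand, c("ward_id", "agent_id", "mean_weekly_ddd"), "demand")
  if (any(demand$mean_weekly_ddd < 0)) {
    abort("mean_weekly_ddd must be nonnegative",
      class = "abxflow_error_validation"
    )
  }
  lookup_agents(unique(demand$agent_id), ref)
  op <- as_tibble(order_policy)
  check_columns(op, c("route", "reorder_point_ddd", "sizes", "weights"),
    "order policy"
  )
  for (i in seq_len(nrow(op))) {
    sz <- op$sizes[[i]]
    if (length(sz) == 0 || any(sz <= 0)) {
      abort("order sizes must be a nonempty set of positive DDD amounts",
        class = "abxflow_error_validation"
      )
    }
    if (length(op$weights[[i]]) != length(sz)) {
      abort("order size weights must match sizes in length",
        class = "abxflow_error_validation"
      )
    }
  }
  ff <- flow_fractions
  needed <- c(
    "discard", "discharge_takeaway", "loan_out", "loan_in",
    "return_to_pharmacy"
  )
  if (!all(needed %in% names(ff)) || any(unlist(ff[needed]) < 0)) {
    abort("flow_fractions must name all five flow rates, each >= 0",
      class = "abxflow_error_validation"
    )
  }
  weeks <- as.integer(weeks)
  stopifnot(weeks >= 1)
  missing_blocks <- missing_blocks %||% list()
  for (block in missing_blocks) {
    if (min(block) < 1 || max(block) > weeks) {
      abort("missing_blocks must lie within the study window",
        class = "abxflow_error_validation"
      )
    }
  }
  structure(
    list(
      demand = demand, ref = ref, weeks = weeks, order_policy = op,
      flow_fractions = ff[needed], missing_blocks = missing_blocks,
      burn_in_weeks = as.integer(burn_in_weeks),
      demand_model = demand_model, seed = as.integer(seed)
    ),
    class = "abx_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_order_policy <- function() {
  tibble(
    route = c("parenteral", "oral"),
    reorder_point_ddd = c(8, 15),
    # parenteral: small frequent orders, 5-10 DDDs; oral: bulk orders
    # 5-50 DDDs with the sampling weights peaked so the median is 20
    sizes = list(5:10, seq(5, 50, by = 5)),
    weights = list(rep(1, 6), c(2, 3, 4, 3, 2, 2, 1, 1, 1, 1))
  )
}

#' @rdname sim_config
#' @export
default_flow_fractions <- function() {
  # roughly 1% of use never reaches a patient, split across discards,
  # discharge take-aways and loans out; borrowing and returns are rarer
  list(
    discard = 0.00265, discharge_takeaway = 0.00453, loan_out = 0.00365,
    loan_in = 0.00227, return_to_pharmacy = 0.001
  )
}

#' Default study scenario: five wards, eight broad-spectrum agents
#'
#' Mean weekly demand calibrated to a 26-week surveillance profile of a
#' mid-size tertiary-care hospital: a cephalosporin-heavy pulmonary ward, a
#' mixed gastro/infectious-diseases ward, an endocrinology/haematology
#' ward, and two urology wards where ciprofloxacin dominates and
#' carbapenems are unused. Expected grand total is close to 3 970 DDDs over
#' 26 weeks; about half of all use is ciprofloxacin, of which roughly 77%
#' is oral. Class totals are split across agents 50/30/20 (3rd-generation
#' cephalosporins) and 60/40 (carbapenems).
#'
#' @param seed integer simulation seed.
#' @param ... passed on to [sim_config()] (e.g. `missing_blocks = NULL`).
#' @return an `abx_sim_config` object.
#' @export
default_study_config <- function(seed = 1L, ...) {
  sim_config(default_study_demand(), seed = seed, ...)
}

#' @rdname default_study_config
#' @export
default_study_demand <- function() {
  class_totals <- tribble(
    ~ward_id, ~class, ~total_ddd,
    "pulmonary", "2nd generation cephalosporins", 432.5,
    "pulmonary", "3rd generation cephalosporins", 360.3,
    "pulmonary", "Carbapenems", 171.0,
    "pulmonary", "Ciprofloxacin parenteral", 26.4,
    "pulmonary", "Ciprofloxacin oral", 204.0,
    "gastro_inf", "2nd generation cephalosporins", 231.0,
    "gastro_inf", "3rd generation cephalosporins", 152.5,
    "gastro_inf", "Carbapenems", 96.3,
    "gastro_inf", "Ciprofloxacin parenteral", 130.0,
    "gastro_inf", "Ciprofloxacin oral", 288.3,
    "endo_haem", "2nd generation cephalosporins", 128.0,
    "endo_haem", "3rd generation cephalosporins", 111.3,
    "endo_haem", "Carbapenems", 76.0,
    "endo_haem", "Ciprofloxacin parenteral", 46.8,
    "endo_haem", "Ciprofloxacin oral", 314.0,
    "urology_1", "2nd generation cephalosporins", 62.5,
    "urology_1", "3rd generation cephalosporins", 32.8,
    "urology_1", "Carbapenems", 0,
    "urology_1", "Ciprofloxacin parenteral", 131.2,
    "urology_1", "Ciprofloxacin oral", 346.3,
    "urology_2", "2nd generation cephalosporins", 63.0,
    "urology_2", "3rd generation cephalosporins", 19.0,
    "urology_2", "Carbapenems", 0,
    "urology_2", "Ciprofloxacin parenteral", 144.4,
    "urology_2", "Ciprofloxacin oral", 402.3
  )
  splits <- tribble(
    ~class, ~agent_id, ~share,
    "2nd generation cephalosporins", "cefuroxime", 1,
    "3rd generation cephalosporins", "cefotaxime", 0.5,
    "3rd generation cephalosporins", "ceftazidime", 0.3,
    "3rd generation cephalosporins", "ceftriaxone", 0.2,
    "Carbapenems", "meropenem", 0.6,
    "Carbapenems", "imipenem_cilastatin", 0.4,
    "Ciprofloxacin parenteral", "ciprofloxacin_iv", 1,
    "Ciprofloxacin oral", "ciprofloxacin_oral", 1
  )
  class_totals |>
    inner_join(splits, by = "class", relationship = "many-to-many") |>
    transmute(
      ward_id = .data$ward_id,
      agent_id = .data$agent_id,
      mean_weekly_ddd = .data$total_ddd * .data$share / 26
    ) |>
    arrange(.data$ward_id, .data$agent_id)
}

# deterministic per-cell seed: djb2 string hash folded with the base seed
cell_seed <- function(seed, ward_id, agent_id) {
  h <- 5381
  for (b in utf8ToInt(paste0(ward_id, "/", agent_id))) {
    h <- (h * 33 + b) %% 268435399
  }
  as.integer((h + (seed %% 100000) * 21001) %% 2147483587)
}

# one ward x agent series, day by day
simulate_cell <- function(mean_weekly_ddd, pack_strength_mg, ddd_mg,
                          reorder_point_ddd, sizes, weights,
                          flow_fractions, weeks, demand_model, seed,
                          burn_in_weeks = 0) {
  set.seed(seed)
  to_ddd <- function(packs) packs * pack_strength_mg / ddd_mg
  pack_ddd <- pack_strength_mg / ddd_mg
  burn_days <- 7 * burn_in_weeks
  n_days <- burn_days + 7 * weeks
  rate_daily_packs <- mean_weekly_ddd / pack_ddd / 7

  # per-type daily event probabilities; each event moves one pack
  p_flow <- vapply(
    flow_fractions,
    function(f) min(f * mean_weekly_ddd / pack_ddd / 7, 1),
    numeric(1)
  )

  if (demand_model == "patient_courses") {
    course_len <- 4:8
    lambda_adm <- rate_daily_packs / mean(course_len)
    pending <- numeric(n_days + max(course_len))
  }

  init_packs <- ceiling((reorder_point_ddd + mean(sizes)) / pack_ddd)
  if (mean_weekly_ddd == 0) init_packs <- ceiling(reorder_point_ddd / pack_ddd)
  stock <- init_packs
  backlog <- 0

  true_packs <- numeric(weeks)
  snap_packs <- rep(NA_real_, weeks + 1)
  if (burn_days == 0) snap_packs[1] <- stock # boundary 0
  sales_week <- integer(0)
  sales_ddd <- numeric(0)
  flow_week <- integer(0)
  flow_type <- character(0)
  flow_ddd <- numeric(0)

  for (day in seq_len(n_days)) {
    w <- (day - burn_days - 1) %/% 7 + 1 # <= 0 during burn-in
    # morning doses
    dem <- if (demand_model == "poisson_daily") {
      rpois(1, rate_daily_packs)
    } else {
      n_adm <- rpois(1, lambda_adm)
      for (a in seq_len(n_adm)) {
        len <- sample(course_len, 1)
        idx <- day:(day + len - 1)
        pending[idx] <- pending[idx] + 1
      }
      pending[day]
    }
    need <- backlog + dem
    used <- min(stock, need)
    stock <- stock - used
    backlog <- need - used
    if (w >= 1) true_packs[w] <- true_packs[w] + used
    # daily order to the pharmacy, same-day delivery
    if (to_ddd(stock) < reorder_point_ddd) {
      q_ddd <- if (length(sizes) == 1) sizes else {
        sample(sizes, 1, prob = weights)
      }
      q_packs <- max(1, round(q_ddd / pack_ddd))
      stock <- stock + q_packs
      if (w >= 1) {
        sales_week <- c(sales_week, w)
        sales_ddd <- c(sales_ddd, to_ddd(q_packs))
        flow_week <- c(flow_week, w)
        flow_type <- c(flow_type, "delivery")
        flow_ddd <- c(flow_ddd, to_ddd(q_packs))
      }
      if (backlog > 0) {
        extra <- min(stock, backlog)
        stock <- stock - extra
        backlog <- backlog - extra
        if (w >= 1) true_packs[w] <- true_packs[w] + extra
      }
    }
    # incidental stock flows (one pack each)
    u <- runif(5)
    out_types <- c(
      "loan_out", "discharge_takeaway", "discard", "return_to_pharmacy"
    )
    for (i in seq_along(out_types)) {
      if (u[i] < p_flow[[out_types[i]]] && stock >= 1) {
        stock <- stock - 1
        if (w >= 1) {
          flow_week <- c(flow_week, w)
          flow_type <- c(flow_type, out_types[i])
          flow_ddd <- c(flow_ddd, to_ddd(1))
        }
      }
    }
    if (u[5] < p_flow[["loan_in"]]) {
      stock <- stock + 1
      if (w >= 1) {
        flow_week <- c(flow_week, w)
        flow_type <- c(flow_type, "loan_in")
        flow_ddd <- c(flow_ddd, to_ddd(1))
      }
    }
    if (day %% 7 == 0 && day >= burn_days) {
      snap_packs[(day - burn_days) / 7 + 1] <- stock
    }
  }

  list(
    true_ddd = to_ddd(true_packs),
    snap_packs = snap_packs,
    sales = tibble(week = sales_week, ddd = sales_ddd),
    flows = tibble(
      week = flow_week, flow_type = flow_type, amount_ddd = flow_ddd
    )
  )
}

#' Run the ward/pharmacy simulation
#'
#' Day by day, for every ward x agent: morning doses draw packs from the
#' shelf (unmet demand is backordered and served as soon as stock arrives);
#' whenever shelf stock falls below the route's reorder point a pharmacy
#' order of a sampled size is placed and delivered the same day (one sales
#' record, one delivery flow); incidental loans, discards, discharge
#' take-aways and returns occur at their configured rates; stock is counted
#' at every week boundary, except boundaries falling inside a configured
#' missing-count block. Random streams are split per ward x agent, so
#' adding an agent to the configuration does not perturb the other series.
#'
#' @param config an [sim_config()] object.
#' @param seed optional override of `config$seed`.
#' @return an `abx_sim` list: `true_consumption` (a consumption series with
#'   `method = "truth"`), `snapshots` (with missing-block gaps applied),
#'   `snapshots_full` (complete count series), `flows`, `sales`, `config`.
#' @export
simulate_wards <- function(config, seed = NULL) {
  stopifnot(inherits(config, "abx_sim_config"))
  seed <- as.integer(seed %||% config$seed)
  ref <- config$ref
  cells <- config$demand |>
    inner_join(
      ref |> select("agent_id", "route", "ddd_mg", "pack_strength_mg"),
      by = "agent_id"
    ) |>
    inner_join(config$order_policy, by = "route")

  results <- purrr::pmap(cells, function(ward_id, agent_id, mean_weekly_ddd,
                                         route, ddd_mg, pack_strength_mg,
                                         reorder_point_ddd, sizes, weights,
                                         ...) {
    out <- simulate_cell(
      mean_weekly_ddd, pack_strength_mg, ddd_mg, reorder_point_ddd,
      sizes, weights, config$flow_fractions, config$weeks,
      config$demand_model, cell_seed(seed, ward_id, agent_id),
      burn_in_weeks = config$burn_in_weeks
    )
    list(
      true = tibble(
        method = "truth", ward_id = ward_id, agent_id = agent_id,
        week = seq_len(config$weeks), ddd = out$true_ddd, imputed = FALSE
      ),
      snaps = tibble(
        ward_id = ward_id, week = 0:config$weeks, agent_id = agent_id,
        packs = out$snap_packs
      ),
      sales = out$sales |> mutate(
        ward_id = ward_id, agent_id = agent_id, .before = 1
      ),
      flows = out$flows |> mutate(
        ward_id = ward_id, agent_id = agent_id, .before = 1
      )
    )
  })

  sales <- map(results, "sales") |> list_rbind()
  if (nrow(sales) > 0) {
    sales <- sales |>
      mutate(order_id = sprintf("o%05d", row_number())) |>
      select("ward_id", "week", "agent_id", "order_id", "ddd")
  } else {
    sales <- tibble(
      ward_id = character(), week = integer(), agent_id = character(),
      order_id = character(), ddd = double()
    )
  }
  flows <- map(results, "flows") |> list_rbind() |>
    select("ward_id", "week", "agent_id", "flow_type", "amount_ddd")
  snapshots_full <- map(results, "snaps") |> list_rbind()

  suppressed <- unlist(lapply(
    config$missing_blocks,
    function(b) setdiff(sort(b), max(b)) # interior boundaries of the gap
  ))
  snapshots <- snapshots_full |> filter(!(.data$week %in% suppressed))

  structure(
    list(
      true_consumption = map(results, "true") |> list_rbind(),
      snapshots = snapshots,
      snapshots_full = snapshots_full,
      flows = flows,
      sales = sales,
      config = config,
      seed = seed
    ),
    class = "abx_sim"
  )
}

#' @export
print.abx_sim <- function(x, ...) {
  cat(sprintf(
    paste0(
      "ward/pharmacy simulation: %d wards x %d agents x %d weeks",
      " (seed %d)\n  true consumption %.1f DDDs, pharmacy sales %.1f DDDs,",
      " %d orders, %d stock-flow events\n"
    ),
    n_distinct(x$config$demand$ward_id),
    n_distinct(x$config$demand$agent_id),
    x$config$weeks, x$seed,
    sum(x$true_consumption$ddd), sum(x$sales$ddd), nrow(x$sales),
    sum(x$flows$flow_type != "delivery")
  ))
  invisible(x)
}

#' Degrade a simulation to imperfectly observed records
#'
#' Shelf counts and pharmacy records are electronic, but loans and
#' discharge take-aways are registered manually by ward nurses and may be
#' missed. This drops a random fraction of the manually registered flow
#' records (loans in/out, discharge take-aways), leaving discards, returns,
#' deliveries and sales intact, to stress-test the stock accounting against
#' incomplete registration.
#'
#' @param sim an `abx_sim` object.
#' @param drop_flow_fraction probability in \[0, 1\] that a manual record is
#'   lost.
#' @param seed RNG seed for the drop draws (default derived from the
#'   simulation seed).
#' @return the simulation with thinned `flows`.
#' @export
degrade_to_observed <- function(sim, drop_flow_fraction, seed = NULL) {
  stopifnot(inherits(sim, "abx_sim"))
  if (drop_flow_fraction < 0 || drop_flow_fraction > 1) {
    abort("drop_flow_fraction must be in [0, 1]",
      class = "abxflow_error_validation"
    )
  }
  set.seed(as.integer(seed %||% (sim$seed + 77777L)))
  manual <- sim$flows$flow_type %in%
    c("loan_in", "loan_out", "discharge_takeaway")
  drop <- manual & (runif(nrow(sim$flows)) < drop_flow_fraction)
  if (drop_flow_fraction == 1) drop <- manual
  sim$flows <- sim$flows[!drop, , drop = FALSE]
  sim
}
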