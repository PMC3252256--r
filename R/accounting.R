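#' @name accounting-data
#' @title Input record formats for consumption accounting
#'
#' @description
#' Three tidy record tables drive the accounting stage. Weeks are 1-based
#' (`1..W`); stock snapshots sit on week *boundaries* `0..W`, where boundary
#' `b` is the shelf count between week `b` and week `b + 1` (boundary 0 is
#' the baseline count before the study starts).
#'
#' * **Snapshots** — `ward_id`, `week` (boundary index), `agent_id`,
#'   `packs` (pack units on the shelf, >= 0; fractions allowed).
#' * **Flows** — `ward_id`, `week` (1..W), `agent_id`, `flow_type` (one of
#'   `delivery`, `loan_in`, `loan_out`, `discharge_takeaway`, `discard`,
#'   `return_to_pharmacy`), `amount_ddd` (> 0).
#' * **Sales** — `ward_id`, `week`, `agent_id`, `order_id`, `ddd` (> 0),
#'   one row per pharmacy order.
#'
#' Deliveries and loans-in increase ward stock; loans-out, discharge
#' take-aways, discards and returns to the pharmacy decrease it.
NULL

FLOW_TYPES <- c(
  "delivery", "loan_in", "loan_out",
  "discharge_takeaway", "discard", "return_to_pharmacy"
)

# sign of each flow type in the ward balance equation
flow_sign <- function(flow_type) {
  s <- c(
    delivery = 1, loan_in = 1, loan_out = -1,
    discharge_takeaway = -1, discard = -1, return_to_pharmacy = -1
  )
  unname(s[flow_type])
}

check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(
      paste0(what, " lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "abxflow_error_validation"
    )
  }
  invisible(df)
}

validate_flows <- function(flows) {
  flows <- as_tibble(flows)
  check_columns(
    flows, c("ward_id", "week", "agent_id", "flow_type", "amount_ddd"),
    "flow table"
  )
  bad <- setdiff(unique(flows$flow_type), FLOW_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown flow_type: ", paste(bad, collapse = ", ")),
      class = "abxflow_error_validation"
    )
  }
  if (nrow(flows) > 0 && any(flows$amount_ddd <= 0)) {
    abort("flow amount_ddd must be positive (direction is carried by flow_type)",
      class = "abxflow_error_validation"
    )
  }
  flows
}

validate_snapshots <- function(snapshots) {
  snapshots <- as_tibble(snapshots)
  check_columns(
    snapshots, c("ward_id", "week", "agent_id", "packs"), "snapshot table"
  )
  if (nrow(snapshots) > 0 && any(snapshots$packs < 0)) {
    abort("snapshot packs must be nonnegative",
      class = "abxflow_error_validation"
    )
  }
  if (anyDuplicated(snapshots[c("ward_id", "week", "agent_id")])) {
    abort("duplicate (ward_id, week, agent_id) snapshot rows",
      class = "abxflow_error_validation"
    )
  }
  snapshots
}

validate_sales <- function(sales) {
  sales <- as_tibble(sales)
  check_columns(sales, c("ward_id", "week", "agent_id", "ddd"), "sales ledger")
  if (nrow(sales) > 0 && any(sales$ddd <= 0)) {
    abort("sales ddd must be positive; returns are flow records",
      class = "abxflow_error_validation"
    )
  }
  sales
}

# net signed flow DDDs per ward x agent over a set of weeks
net_flow_ddd <- function(flows, weeks) {
  flows |>
    filter(.data$week %in% .env$weeks) |>
    mutate(signed = flow_sign(.data$flow_type) * .data$amount_ddd) |>
    group_by(.data$ward_id, .data$agent_id) |>
    summarise(net_ddd = sum(.data$signed), .groups = "drop")
}

#' Consumption for one week from two consecutive shelf counts
#'
#' The single-week ward balance: consumption equals the stock decrease
#' between the previous and current count plus stock received (deliveries,
#' loans in) minus non-consumption removals (loans out, discharge
#' take-aways, discards, returns to the pharmacy), all in DDDs.
#'
#' @param prev,curr snapshot tables for one ward at consecutive boundaries
#'   (`curr` boundary = `prev` boundary + 1); the week computed is the
#'   `curr` boundary index.
#' @param flows flow records; only rows for that ward and week are used.
#' @param ref a [ddd_reference()] table.
#' @return tibble `ward_id`, `agent_id`, `week`, `ddd` covering every agent
#'   present in either snapshot.
#' @export
weekly_ward_consumption <- function(prev, curr, flows, ref) {
  prev <- validate_snapshots(prev)
  curr <- validate_snapshots(curr)
  flows <- validate_flows(flows)
  ward <- unique(c(prev$ward_id, curr$ward_id))
  if (length(ward) != 1) {
    abort("prev and curr snapshots must belong to a single common ward",
      class = "abxflow_error_sequencing"
    )
  }
  b_prev <- unique(prev$week)
  b_curr <- unique(curr$week)
  if (length(b_prev) != 1 || length(b_curr) != 1 || b_curr != b_prev + 1) {
    abort("snapshots must be at consecutive week boundaries",
      class = "abxflow_error_sequencing"
    )
  }
  week_w <- b_curr
  agents <- union(prev$agent_id, curr$agent_id)
  stock <- tibble(ward_id = ward, agent_id = agents) |>
    left_join(prev |> select("agent_id", prev_packs = "packs"),
      by = "agent_id"
    ) |>
    left_join(curr |> select("agent_id", curr_packs = "packs"),
      by = "agent_id"
    ) |>
    mutate(
      prev_packs = coalesce(.data$prev_packs, 0),
      curr_packs = coalesce(.data$curr_packs, 0)
    )
  net <- net_flow_ddd(flows |> filter(.data$ward_id == ward), week_w)
  stock |>
    left_join(net, by = c("ward_id", "agent_id")) |>
    mutate(
      net_ddd = coalesce(.data$net_ddd, 0),
      ddd = packs_to_ddd(.data$prev_packs, .data$agent_id, ref) -
        packs_to_ddd(.data$curr_packs, .data$agent_id, ref) +
        .data$net_ddd,
      week = week_w
    ) |>
    select("ward_id", "agent_id", "week", "ddd")
}

#' Ward-side weekly consumption series from shelf counts and flows
#'
#' Applies the stock balance between every pair of *adjacent available*
#' count boundaries. When counts are missing for a run of weeks (holiday
#' gaps), the balance is applied across the whole gap — boundary stock
#' difference plus all in-gap flows — and the gap total is split evenly
#' over its weeks, which are flagged `imputed`. This is the only gap total
#' computable without the missing counts, and it conserves the series sum.
#'
#' @param snapshots snapshot table (see [accounting-data]); boundaries 0 and
#'   `W` must be present for every ward.
#' @param flows flow records for weeks `1..W`.
#' @param ref a [ddd_reference()] table.
#' @param weeks integer study weeks, default inferred as `1..max boundary`.
#' @return a consumption series tibble: `method` (`"ward"`), `ward_id`,
#'   `agent_id`, `week`, `ddd`, `imputed`.
#' @export
ward_consumption <- function(snapshots, flows, ref, weeks = NULL) {
  snapshots <- validate_snapshots(snapshots)
  flows <- validate_flows(flows)
  w_max <- max(snapshots$week)
  weeks <- weeks %||% seq_len(w_max)
  agents <- sort(unique(c(snapshots$agent_id, flows$agent_id)))
  out <- snapshots |>
    group_by(.data$ward_id) |>
    group_map(function(snap, key) {
      ward <- key$ward_id
      bounds <- sort(unique(snap$week))
      if (bounds[1] != 0 || max(bounds) != w_max) {
        abort(
          paste0(
            "ward ", ward, ": snapshots must include boundaries 0 and ",
            w_max
          ),
          class = "abxflow_error_sequencing"
        )
      }
      # wide stock in DDDs: one row per boundary, one column per agent
      stock_ddd <- expand_grid(week = bounds, agent_id = agents) |>
        left_join(snap |> select("week", "agent_id", "packs"),
          by = c("week", "agent_id")
        ) |>
        mutate(
          packs = coalesce(.data$packs, 0),
          ddd = packs_to_ddd(.data$packs, .data$agent_id, ref)
        )
      ward_flows <- flows |> filter(.data$ward_id == ward)
      purrr::map2(
        head(bounds, -1), tail(bounds, -1),
        function(b0, b1) {
          gap_weeks <- as.integer(seq(b0 + 1, b1))
          s0 <- stock_ddd |> filter(.data$week == b0)
          s1 <- stock_ddd |> filter(.data$week == b1)
          net <- net_flow_ddd(ward_flows, gap_weeks)
          tibble(ward_id = ward, agent_id = agents) |>
            left_join(net, by = c("ward_id", "agent_id")) |>
            mutate(
              net_ddd = coalesce(.data$net_ddd, 0),
              total = s0$ddd[match(.data$agent_id, s0$agent_id)] -
                s1$ddd[match(.data$agent_id, s1$agent_id)] +
                .data$net_ddd
            ) |>
            expand_grid(week = gap_weeks) |>
            mutate(
              ddd = .data$total / length(gap_weeks),
              imputed = length(gap_weeks) > 1
            ) |>
            select("ward_id", "agent_id", "week", "ddd", "imputed")
        }
      ) |>
        list_rbind()
    }) |>
    list_rbind()
  out |>
    filter(.data$week %in% weeks) |>
    mutate(method = "ward", .before = 1) |>
    arrange(.data$ward_id, .data$agent_id, .data$week)
}

#' Pharmacy-side weekly consumption series: sales net of returns
#'
#' Sums the DDDs of every order per ward x agent x week and subtracts DDDs
#' returned to the pharmacy. Cells with no records are zero. Weeks where
#' returns exceed orders come out negative and are kept as-is.
#'
#' @param sales sales ledger (see [accounting-data]).
#' @param flows flow records; only `return_to_pharmacy` rows are used (a
#'   pre-filtered return table is accepted too). `NULL` for no returns.
#' @param wards,agents,weeks the grid to fill; defaults are inferred from
#'   the records, but pass them explicitly when empty cells at the margins
#'   matter.
#' @return a consumption series tibble: `method` (`"pharmacy"`), `ward_id`,
#'   `agent_id`, `week`, `ddd`, `imputed` (all `FALSE`).
#' @export
pharmacy_consumption <- function(sales, flows = NULL, wards = NULL,
                                 agents = NULL, weeks = NULL) {
  sales <- validate_sales(sales)
  returns <- if (is.null(flows)) {
    tibble(
      ward_id = character(), week = integer(),
      agent_id = character(), amount_ddd = double()
    )
  } else {
    validate_flows(flows) |> filter(.data$flow_type == "return_to_pharmacy")
  }
  wards <- wards %||% sort(unique(c(sales$ward_id, returns$ward_id)))
  agents <- agents %||% sort(unique(c(sales$agent_id, returns$agent_id)))
  weeks <- weeks %||% seq_len(max(c(sales$week, returns$week, 0L)))
  sold <- sales |>
    group_by(.data$ward_id, .data$agent_id, .data$week) |>
    summarise(sold = sum(.data$ddd), .groups = "drop")
  ret <- returns |>
    group_by(.data$ward_id, .data$agent_id, .data$week) |>
    summarise(returned = sum(.data$amount_ddd), .groups = "drop")
  expand_grid(ward_id = wards, agent_id = agents, week = weeks) |>
    left_join(sold, by = c("ward_id", "agent_id", "week")) |>
    left_join(ret, by = c("ward_id", "agent_id", "week")) |>
    mutate(
      method = "pharmacy",
      ddd = coalesce(.data$sold, 0) - coalesce(.data$returned, 0),
      imputed = FALSE,
      .keep = "unused"
    ) |>
    select("method", "ward_id", "agent_id", "week", "ddd", "imputed") |>
    arrange(.data$ward_id, .data$agent_id, .data$week)
}

#' Replace weeks inside missing-count blocks by the block average
#'
#' For each block of consecutive weeks, every in-block weekly value is set
#' to the block mean, so the series total over the study window is
#' unchanged. Applied to the pharmacy series so that both methods receive
#' the same smoothing over holiday gaps; the ward series produced by
#' [ward_consumption()] is already block-averaged by construction (the
#' operation is idempotent there).
#'
#' @param series a consumption series tibble.
#' @param blocks list of integer vectors of consecutive weeks, e.g.
#'   `list(10:12, 25:26)`.
#' @return the series with in-block values averaged and `imputed` set.
#' @export
impute_missing_blocks <- function(series, blocks) {
  series <- as_tibble(series)
  check_columns(series, c("ward_id", "agent_id", "week", "ddd"), "series")
  if (!"imputed" %in% names(series)) series$imputed <- FALSE
  keys <- intersect(c("method", "ward_id", "agent_id"), names(series))
  window <- range(series$week)
  for (block in blocks) {
    block <- sort(unique(as.integer(block)))
    if (length(block) == 0) next
    if (!identical(block, seq(min(block), max(block)))) {
      abort("imputation blocks must be consecutive weeks",
        class = "abxflow_error_validation"
      )
    }
    if (min(block) < window[1] || max(block) > window[2]) {
      abort(
        paste0(
          "block ", min(block), "-", max(block),
          " extends beyond the study window ", window[1], "-", window[2]
        ),
        class = "abxflow_error_validation"
      )
    }
    series <- series |>
      group_by(across(all_of(keys))) |>
      mutate(
        in_block = .data$week %in% block,
        ddd = if_else(.data$in_block,
          mean(.data$ddd[.data$in_block]), .data$ddd
        ),
        imputed = .data$imputed | (.data$in_block & length(block) > 1)
      ) |>
      ungroup() |>
      select(-"in_block")
  }
  series
}

#' Sum a weekly series over registration intervals
#'
#' After dropping `omit_weeks`, the remaining weeks (sorted) are partitioned
#' into consecutive non-overlapping blocks of `k` weeks and summed per
#' ward x agent. The number of retained weeks must be divisible by `k`;
#' `k = 1` is the identity on retained weeks.
#'
#' @param series a consumption series tibble.
#' @param k registration interval length in weeks (1--4 in the study design,
#'   any positive integer accepted).
#' @param omit_weeks weeks dropped before partitioning (e.g. `c(12, 26)` to
#'   make 26 study weeks divisible by 3 and 4).
#' @return tibble `ward_id`, `agent_id`, `interval`, `k`, `ddd` (plus
#'   `method` if present in the input).
#' @export
aggregate_intervals <- function(series, k, omit_weeks = integer()) {
  series <- as_tibble(series)
  check_columns(series, c("ward_id", "agent_id", "week", "ddd"), "series")
  k <- as.integer(k)
  retained <- sort(setdiff(unique(series$week), omit_weeks))
  r <- length(retained) %% k
  if (r != 0) {
    abort(
      paste0(
        length(retained), " retained weeks are not divisible by k = ", k,
        " (remainder ", r, "); adjust omit_weeks"
      ),
      class = "abxflow_error_config"
    )
  }
  interval_of <- setNames(
    rep(seq_len(length(retained) %/% k), each = k), retained
  )
  keys <- intersect(c("method", "ward_id", "agent_id"), names(series))
  series |>
    filter(.data$week %in% retained) |>
    mutate(interval = unname(interval_of[as.character(.data$week)])) |>
    group_by(across(all_of(c(keys, "interval")))) |>
    summarise(ddd = sum(.data$ddd), .groups = "drop") |>
    mutate(k = .env$k, .after = "interval")
}

#' Pair pharmacy and ward registrations per ward x agent x interval
#'
#' Aggregates both series over `k`-week intervals and joins them into dual
#' registrations. One pair per (ward, agent-in-stratum, interval);
#' registrations where both methods record zero use are retained — absence
#' of use is information, not missing data.
#'
#' @param pharm,ward consumption series tibbles covering the same wards,
#'   agents and weeks.
#' @inheritParams aggregate_intervals
#' @param stratum `"all"`, `"parenteral"` or `"oral"`; agent membership is
#'   looked up by route in `ref`.
#' @param ref a [ddd_reference()] table (needed unless `stratum = "all"`).
#' @return tibble `ward_id`, `agent_id`, `interval`, `k`, `stratum`,
#'   `pharmacy_ddd`, `ward_ddd`.
#' @export
build_paired_registrations <- function(pharm, ward, k = 1,
                                       omit_weeks = integer(),
                                       stratum = c("all", "parenteral", "oral"),
                                       ref = NULL) {
  stratum <- match.arg(stratum)
  pharm <- as_tibble(pharm)
  ward <- as_tibble(ward)
  same_grid <- function(a, b) {
    key <- function(x) {
      x[c("ward_id", "agent_id", "week")] |>
        mutate(week = as.integer(.data$week)) |>
        distinct() |>
        arrange(.data$ward_id, .data$agent_id, .data$week)
    }
    identical(key(a), key(b))
  }
  if (!same_grid(pharm, ward)) {
    abort("pharmacy and ward series cover different ward/agent/week grids",
      class = "abxflow_error_validation"
    )
  }
  if (stratum != "all") {
    if (is.null(ref)) {
      abort("ref is required for route strata",
        class = "abxflow_error_validation"
      )
    }
    keep_agents <- ref$agent_id[ref$route == stratum]
    pharm <- pharm |> filter(.data$agent_id %in% keep_agents)
    ward <- ward |> filter(.data$agent_id %in% keep_agents)
  }
  p <- aggregate_intervals(pharm, k, omit_weeks) |>
    select("ward_id", "agent_id", "interval", "k", pharmacy_ddd = "ddd")
  w <- aggregate_intervals(ward, k, omit_weeks) |>
    select("ward_id", "agent_id", "interval", ward_ddd = "ddd")
  p |>
    inner_join(w, by = c("ward_id", "agent_id", "interval")) |>
    mutate(stratum = .env$stratum, .after = "k")
}

#' Relative difference between the two methods, in percent
#'
#' `100 * (pharmacy - ward) / pharmacy`, the deviation of the ward figure
#' from the pharmacy figure it is benchmarked against. Undefined (and
#' returned as `NA`) when the pharmacy denominator is zero, as for agents a
#' ward never ordered. Full precision is returned; report tables round to
#' one decimal with [round_half_out()].
#'
#' @param pharmacy_ddd,ward_ddd paired DDD totals (vectorised).
#' @return percent differences.
#' @export
percent_difference <- function(pharmacy_ddd, ward_ddd) {
  if_else(
    pharmacy_ddd == 0,
    NA_real_,
    100 * (pharmacy_ddd - ward_ddd) / pharmacy_ddd
  )
}

#' Share of ward stock turnover that never reached a patient
#'
#' Discards, discharge take-aways and loans to other wards, as a percentage
#' of total ward-accounted consumption.
#'
#' @param flows flow records (only the three non-consumption removal types
#'   are summed).
#' @param total_ward_ddd positive total ward consumption in DDDs.
#' @return percent (full precision).
#' @export
non_consumption_share <- function(flows, total_ward_ddd) {
  flows <- validate_flows(flows)
  if (total_ward_ddd <= 0) {
    abort("total_ward_ddd must be positive",
      class = "abxflow_error_validation"
    )
  }
  lost <- flows |>
    filter(.data$flow_type %in% c("discard", "discharge_takeaway", "loan_out"))
  100 * sum(lost$amount_ddd) / total_ward_ddd
}
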