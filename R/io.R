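#' Read accounting input tables from CSV
#'
#' Readers for the three record formats documented in [accounting-data].
#' Enumerations are lowercase tokens, weeks are integers, amounts are
#' decimal DDDs or pack units as labelled per file. Each reader validates
#' its table on the way in.
#'
#' @param path file path.
#' @return a validated tibble.
#' @name read-inputs
NULL

#' @rdname read-inputs
#' @export
read_snapshots <- function(path) {
  validate_snapshots(read_csv(
    path,
    col_types = cols(
      ward_id = col_character(), week = col_integer(),
      agent_id = col_character(), packs = col_double()
    )
  ))
}

#' @rdname read-inputs
#' @export
read_flows <- function(path) {
  validate_flows(read_csv(
    path,
    col_types = cols(
      ward_id = col_character(), week = col_integer(),
      agent_id = col_character(), flow_type = col_character(),
      amount_ddd = col_double()
    )
  ))
}

#' @rdname read-inputs
#' @export
read_sales <- function(path) {
  validate_sales(read_csv(
    path,
    col_types = cols(
      ward_id = col_character(), week = col_integer(),
      agent_id = col_character(), order_id = col_character(),
      ddd = col_double()
    )
  ))
}

#' Write simulation output as the accounting CSV input set
#'
#' Serialises a simulation to the four delimited files the accounting stage
#' reads back (`snapshots.csv`, `flows.csv`, `sales.csv`,
#' `ddd_reference.csv`), so a simulated study round-trips through the
#' file-based pipeline.
#'
#' @param sim an `abx_sim` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "abx_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv(sim$snapshots, file.path(dir, "snapshots.csv"))
  write_csv(sim$flows, file.path(dir, "flows.csv"))
  write_csv(sim$sales, file.path(dir, "sales.csv"))
  write_csv(
    as_tibble(sim$config$ref),
    file.path(dir, "ddd_reference.csv")
  )
  invisible(dir)
}

#' Bundled 26-week surveillance profile
#'
#' Per-ward, per-class pharmacy and ward DDD totals (and the matching
#' non-consumption flow totals) from a 26-week broad-spectrum antibiotic
#' surveillance of five wards in a Norwegian tertiary-care hospital. These
#' tables are the package's worked real-data example: the percent
#' differences, mean interval uses and per-registration mean difference in
#' the README are computed from them.
#'
#' @return `study_consumption_totals()`: tibble `ward_id`, `ward_label`,
#'   `class`, `pharmacy_ddd`, `ward_ddd` (25 rows).
#'   `study_flow_totals()`: tibble `flow_type`, `amount_ddd` (whole-study
#'   totals of the non-consumption flows).
#' @export
study_consumption_totals <- function() {
  read_csv(
    system.file("extdata", "study_totals.csv",
      package = "abxflow", mustWork = TRUE
    ),
    col_types = cols(
      ward_id = col_character(), ward_label = col_character(),
      class = col_character(), pharmacy_ddd = col_double(),
      ward_ddd = col_double()
    )
  )
}

#' @rdname study_consumption_totals
#' @export
study_flow_totals <- function() {
  read_csv(
    system.file("extdata", "study_flow_totals.csv",
      package = "abxflow", mustWork = TRUE
    ),
    col_types = cols(flow_type = col_character(), amount_ddd = col_double())
  )
}

#' Expand class-level study totals to an agent-level weekly series
#'
#' Turns per-ward per-class study-period totals into a constant weekly
#' consumption series at agent resolution, splitting each class across its
#' agents by the default demand shares. Weekly structure is flat by
#' construction — only quantities that depend on totals (grand totals,
#' interval mean use, mean per-registration difference) are meaningful on
#' the result.
#'
#' @param totals tibble as [study_consumption_totals()].
#' @param value_col `"pharmacy_ddd"` or `"ward_ddd"`.
#' @param weeks number of study weeks the totals cover.
#' @return a consumption series tibble (method `"pharmacy"` or `"ward"`).
#' @export
totals_to_series <- function(totals, value_col = c("pharmacy_ddd", "ward_ddd"),
                             weeks = 26) {
  value_col <- match.arg(value_col)
  method <- if (value_col == "pharmacy_ddd") "pharmacy" else "ward"
  splits <- default_study_demand() |>
    inner_join(
      default_ddd_reference() |> select("agent_id", "atc_code", "route"),
      by = "agent_id"
    ) |>
    mutate(class = reporting_class(.data$atc_code, .data$route)) |>
    group_by(.data$ward_id, .data$class) |>
    mutate(share = if (sum(.data$mean_weekly_ddd) > 0) {
      .data$mean_weekly_ddd / sum(.data$mean_weekly_ddd)
    } else {
      1 / n()
    }) |>
    ungroup() |>
    select("ward_id", "class", "agent_id", "share")
  totals |>
    inner_join(splits, by = c("ward_id", "class")) |>
    expand_grid(week = seq_len(weeks)) |>
    transmute(
      method = .env$method,
      ward_id = .data$ward_id,
      agent_id = .data$agent_id,
      week = .data$week,
      ddd = .data[[value_col]] * .data$share / .env$weeks,
      imputed = FALSE
    ) |>
    arrange(.data$ward_id, .data$agent_id, .data$week)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_sim_config()]: an `abx_sim_config`;
#'   [write_sim_config()]: `path`, invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- if (!is.null(raw$ddd_reference)) {
    ddd_reference(bind_rows(lapply(raw$ddd_reference, as_tibble)))
  } else {
    default_ddd_reference()
  }
  policy <- if (!is.null(raw$order_policy)) {
    tibble(
      route = vapply(raw$order_policy, `[[`, character(1), "route"),
      reorder_point_ddd = vapply(
        raw$order_policy, `[[`, numeric(1), "reorder_point_ddd"
      ),
      sizes = lapply(raw$order_policy, function(x) as.numeric(x$sizes)),
      weights = lapply(raw$order_policy, function(x) as.numeric(x$weights))
    )
  } else {
    default_order_policy()
  }
  sim_config(
    demand = bind_rows(lapply(raw$demand, as_tibble)),
    ref = ref,
    weeks = raw$weeks %||% 26,
    order_policy = policy,
    flow_fractions = raw$flow_fractions %||% default_flow_fractions(),
    missing_blocks = lapply(raw$missing_blocks, function(b) {
      seq(b[[1]], b[[length(b)]])
    }),
    demand_model = raw$demand_model %||% "poisson_daily",
    seed = raw$seed %||% 1L
  )
}

#' @rdname read_sim_config
#' @param config an `abx_sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "abx_sim_config"))
  row_list <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  policy <- lapply(seq_len(nrow(config$order_policy)), function(i) {
    list(
      route = config$order_policy$route[i],
      reorder_point_ddd = config$order_policy$reorder_point_ddd[i],
      sizes = config$order_policy$sizes[[i]],
      weights = config$order_policy$weights[[i]]
    )
  })
  yaml::write_yaml(
    list(
      weeks = config$weeks,
      seed = config$seed,
      demand_model = config$demand_model,
      missing_blocks = lapply(config$missing_blocks, function(b) range(b)),
      flow_fractions = config$flow_fractions,
      demand = row_list(config$demand),
      ddd_reference = row_list(as_tibble(config$ref)),
      order_policy = policy
    ),
    path,
    precision = 17L # doubles round-trip exactly
  )
  invisible(path)
}
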