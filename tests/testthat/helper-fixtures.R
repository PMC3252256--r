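# in-code fixtures shared across the suite

# two-agent reference with easy hand arithmetic (1 pack = 0.5 / 1 DDD)
tiny_ref <- function() {
  ddd_reference(tibble::tibble(
    agent_id = c("cefA", "cipO"),
    atc_code = c("J01DC02", "J01MA02"),
    name = c("Cefalosporin A", "Ciprofloxacin"),
    route = c("parenteral", "oral"),
    ddd_mg = c(3000, 1000),
    pack_strength_mg = c(1500, 1000),
    is_bsa = c(TRUE, TRUE)
  ))
}

# one-agent snapshot rows for a single ward
snap_row <- function(ward, boundary, agent, packs) {
  tibble::tibble(
    ward_id = ward, week = as.integer(boundary),
    agent_id = agent, packs = packs
  )
}

flow_row <- function(ward, week, agent, type, ddd) {
  tibble::tibble(
    ward_id = ward, week = as.integer(week), agent_id = agent,
    flow_type = type, amount_ddd = ddd
  )
}

no_flows <- function() {
  tibble::tibble(
    ward_id = character(), week = integer(), agent_id = character(),
    flow_type = character(), amount_ddd = double()
  )
}

no_sales <- function() {
  tibble::tibble(
    ward_id = character(), week = integer(), agent_id = character(),
    order_id = character(), ddd = double()
  )
}

# constant weekly series on a full grid, handy for aggregation tests
constant_series <- function(method, wards, agents, weeks, value = 1) {
  tidyr::expand_grid(
    ward_id = wards, agent_id = agents, week = as.integer(seq_len(weeks))
  ) |>
    dplyr::mutate(method = method, ddd = value, imputed = FALSE, .before = 1)
}

# small random simulation scenario for fuzz/property tests
random_small_config <- function(seed) {
  set.seed(seed)
  ref <- default_ddd_reference()
  n_wards <- sample(1:3, 1)
  agents <- sample(ref$agent_id, sample(2:4, 1))
  weeks <- sample(4:8, 1)
  demand <- tidyr::expand_grid(
    ward_id = paste0("w", seq_len(n_wards)), agent_id = agents
  ) |>
    dplyr::mutate(mean_weekly_ddd = round(runif(dplyr::n(), 0, 25), 1))
  sim_config(
    demand,
    ref = ref, weeks = weeks,
    missing_blocks = NULL, burn_in_weeks = 1,
    seed = sample.int(1e6, 1)
  )
}

# paired registrations straight from a simulation's two accounting routes
sim_to_series <- function(sim) {
  cfg <- sim$config
  weeks <- seq_len(cfg$weeks)
  ward <- ward_consumption(sim$snapshots, sim$flows, cfg$ref, weeks = weeks)
  pharm <- pharmacy_consumption(
    sim$sales, sim$flows,
    wards = sort(unique(cfg$demand$ward_id)),
    agents = sort(unique(cfg$demand$agent_id)),
    weeks = weeks
  ) |>
    impute_missing_blocks(cfg$missing_blocks)
  list(ward = ward, pharm = pharm)
}
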