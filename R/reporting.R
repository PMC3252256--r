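#' Map agents to reporting classes
#'
#' Report tables group the broad-spectrum agents by ATC prefix and route:
#' `J01DC*` second-generation cephalosporins, `J01DD*` third-generation
#' cephalosporins, `J01DH*` carbapenems (meropenem and
#' imipenem/cilastatin as one class), and ciprofloxacin (`J01MA*`) split
#' by route. An agent outside these groups is a configuration error.
#'
#' @param atc_code,route character vectors (recycled together).
#' @return character vector of class labels.
#' @export
reporting_class <- function(atc_code, route) {
  out <- case_when(
    startsWith(atc_code, "J01DC") ~ "2nd generation cephalosporins",
    startsWith(atc_code, "J01DD") ~ "3rd generation cephalosporins",
    startsWith(atc_code, "J01DH") ~ "Carbapenems",
    startsWith(atc_code, "J01MA") & route == "parenteral" ~
      "Ciprofloxacin parenteral",
    startsWith(atc_code, "J01MA") & route == "oral" ~ "Ciprofloxacin oral",
    .default = NA_character_
  )
  if (anyNA(out)) {
    abort(
      paste0(
        "no reporting class for ATC code(s): ",
        paste(unique(atc_code[is.na(out)]), collapse = ", ")
      ),
      class = "abxflow_error_config"
    )
  }
  out
}

#' Roll a consumption series up to reporting-class totals
#'
#' Sums DDDs per ward and reporting class; class totals sum exactly to the
#' all-agent total because every agent maps to exactly one class.
#'
#' @param series a consumption series tibble (or any tibble with
#'   `ward_id`, `agent_id`, `ddd`).
#' @param ref a [ddd_reference()] table covering every agent.
#' @return tibble with `ward_id`, `class`, `ddd` (plus `method` if
#'   present).
#' @export
class_rollup <- function(series, ref) {
  series <- as_tibble(series)
  check_columns(series, c("ward_id", "agent_id", "ddd"), "series")
  agents <- lookup_agents(unique(series$agent_id), ref)
  classes <- tibble(
    agent_id = agents$agent_id,
    class = reporting_class(agents$atc_code, agents$route)
  )
  keys <- intersect(c("method", "ward_id"), names(series))
  series |>
    inner_join(classes, by = "agent_id") |>
    group_by(across(all_of(c(keys, "class")))) |>
    summarise(ddd = sum(.data$ddd), .groups = "drop")
}

#' Study-period consumption table: pharmacy vs ward by ward and class
#'
#' The headline reconciliation table: study-period DDD totals per ward and
#' reporting class for both methods, per-ward all-class totals, a grand
#' total, and the percent difference `100 (pharmacy - ward) / pharmacy`
#' rounded half-away-from-zero to one decimal (`NA` where the pharmacy
#' total is zero). Rounding happens only here, at the reporting surface.
#'
#' @param pharm,ward consumption series tibbles.
#' @param ref a [ddd_reference()] table.
#' @return tibble `ward_id`, `class` (`"All BSAs"` for totals; ward
#'   `"all_wards"` for the grand total), `pharmacy_ddd`, `ward_ddd`,
#'   `diff_pct`.
#' @export
consumption_report <- function(pharm, ward, ref) {
  p <- class_rollup(pharm, ref) |> rename(pharmacy_ddd = "ddd")
  w <- class_rollup(ward, ref) |> rename(ward_ddd = "ddd")
  p$method <- NULL
  w$method <- NULL
  by_class <- full_join(p, w, by = c("ward_id", "class")) |>
    mutate(
      pharmacy_ddd = coalesce(.data$pharmacy_ddd, 0),
      ward_ddd = coalesce(.data$ward_ddd, 0)
    )
  ward_totals <- by_class |>
    group_by(.data$ward_id) |>
    summarise(
      class = "All BSAs",
      pharmacy_ddd = sum(.data$pharmacy_ddd),
      ward_ddd = sum(.data$ward_ddd),
      .groups = "drop"
    )
  grand <- ward_totals |>
    summarise(
      ward_id = "all_wards", class = "All BSAs",
      pharmacy_ddd = sum(.data$pharmacy_ddd),
      ward_ddd = sum(.data$ward_ddd)
    )
  bind_rows(by_class, ward_totals, grand) |>
    mutate(
      diff_pct = round_half_out(
        percent_difference(.data$pharmacy_ddd, .data$ward_ddd), 1
      )
    ) |>
    arrange(.data$ward_id != "all_wards", .data$ward_id,
      .data$class != "All BSAs", .data$class
    )
}

# omit weeks only when the window does not divide evenly by k
omit_for_k <- function(weeks_all, k, omit_weeks) {
  if (length(weeks_all) %% k == 0) integer() else omit_weeks
}

#' Reliability table: ICC by stratum and registration interval
#'
#' For each registration interval length `k` and each stratum, pairs the
#' two series into dual registrations and reports the intraclass
#' correlation with its confidence interval and the sufficiency verdict.
#' Weeks in `omit_weeks` are dropped only for interval lengths that do not
#' divide the study window evenly.
#'
#' @param pharm,ward consumption series tibbles.
#' @param ref a [ddd_reference()] table.
#' @param intervals interval lengths in weeks.
#' @param omit_weeks weeks to drop when needed for divisibility.
#' @param strata strata to report.
#' @param type ICC variant, see [icc()].
#' @return tibble `k`, `stratum`, `n`, `icc`, `ci_low`, `ci_high`,
#'   `sigma_s2`, `sigma_e2`, `sufficient`.
#' @export
reliability_report <- function(pharm, ward, ref, intervals = 1:4,
                               omit_weeks = c(12, 26),
                               strata = c("all", "parenteral", "oral"),
                               type = "consistency") {
  weeks_all <- sort(unique(pharm$week))
  crossing(k = intervals, stratum = strata) |>
    pmap(function(k, stratum) {
      pairs <- build_paired_registrations(
        pharm, ward,
        k = k, omit_weeks = omit_for_k(weeks_all, k, omit_weeks),
        stratum = stratum, ref = ref
      )
      fit <- tryCatch(
        icc(pairs, type = type),
        abxflow_error_insufficient = function(e) {
          icc_from_anova(NA_real_, NA_real_, n = nrow(pairs), degenerate = TRUE)
        }
      )
      verdict <- reliability_verdict(fit)
      tibble(
        k = k, stratum = stratum, n = nrow(pairs),
        icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
        sigma_s2 = fit$sigma_s2, sigma_e2 = fit$sigma_e2,
        sufficient = verdict$sufficient
      )
    }) |>
    list_rbind()
}

#' Agreement table: Bland-Altman bias and interval-level DDD use ranges
#'
#' For each interval length and stratum: the per-registration mean
#' difference and limits of agreement, the mean interval use across both
#' methods, and the per-registration limits added to the mean use as a DDD
#' use range with percent deviations (see [loa_to_use_range()];
#' `n_cells_per_interval = 1`, the convention the report tables follow).
#'
#' @inheritParams reliability_report
#' @return tibble `k`, `stratum`, `n`, `mean_use`, `range_low`,
#'   `range_high`, `percent_low`, `percent_high`, `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`.
#' @export
agreement_report <- function(pharm, ward, ref, intervals = 1:4,
                             omit_weeks = c(12, 26),
                             strata = c("all", "parenteral", "oral")) {
  weeks_all <- sort(unique(pharm$week))
  crossing(k = intervals, stratum = strata) |>
    pmap(function(k, stratum) {
      omit <- omit_for_k(weeks_all, k, omit_weeks)
      pairs <- build_paired_registrations(
        pharm, ward,
        k = k, omit_weeks = omit, stratum = stratum, ref = ref
      )
      ba <- bland_altman(pairs)
      stratum_agents <- if (stratum == "all") {
        unique(pharm$agent_id)
      } else {
        intersect(unique(pharm$agent_id), ref$agent_id[ref$route == stratum])
      }
      in_stratum <- function(s) filter(s, .data$agent_id %in% stratum_agents)
      mu <- mean_interval_use(
        in_stratum(pharm), in_stratum(ward),
        k = k, omit_weeks = omit
      )
      rng <- if (mu > 0) {
        loa_to_use_range(ba, 1, mu)
      } else {
        tibble(
          range_low = NA_real_, range_high = NA_real_,
          percent_low = NA_real_, percent_high = NA_real_
        )
      }
      tibble(
        k = k, stratum = stratum, n = ba$n_pairs,
        mean_use = mu,
        range_low = rng$range_low, range_high = rng$range_high,
        percent_low = rng$percent_low, percent_high = rng$percent_high,
        mean_difference = ba$mean_difference,
        sd_difference = ba$sd_difference,
        loa_low = ba$loa_low, loa_high = ba$loa_high
      )
    }) |>
    list_rbind()
}

#' Bland-Altman plot data per stratum and interval
#'
#' @inheritParams reliability_report
#' @return tibble `k`, `stratum`, `average`, `difference`,
#'   `mean_difference`, `loa_low`, `loa_high` — one row per dual
#'   registration, ready for plotting or CSV export.
#' @export
bland_altman_data <- function(pharm, ward, ref, intervals = 1:4,
                              omit_weeks = c(12, 26),
                              strata = c("all", "parenteral", "oral")) {
  weeks_all <- sort(unique(pharm$week))
  crossing(k = intervals, stratum = strata) |>
    pmap(function(k, stratum) {
      pairs <- build_paired_registrations(
        pharm, ward,
        k = k, omit_weeks = omit_for_k(weeks_all, k, omit_weeks),
        stratum = stratum, ref = ref
      )
      ba <- bland_altman(pairs)
      ba$data |>
        mutate(
          k = k, stratum = stratum, .before = 1
        ) |>
        mutate(
          mean_difference = ba$mean_difference,
          loa_low = ba$loa_low, loa_high = ba$loa_high
        )
    }) |>
    list_rbind()
}

#' Run the full surveillance pipeline
#'
#' Simulate (or ingest) a study, run both accounting routes, pair the
#' registrations and produce the three report tables plus Bland-Altman
#' plot data:
#'
#' * `consumption` — study-period totals by ward and class with percent
#'   differences;
#' * `reliability` — ICC by stratum x interval length;
#' * `agreement` — Bland-Altman bias, limits of agreement and DDD use
#'   ranges by stratum x interval length;
#' * `ba_data` — per-registration averages and differences.
#'
#' @param config an [sim_config()] (simulate mode); see
#'   [run_pipeline_files()] for the file-based mode.
#' @param seed optional seed override.
#' @param intervals registration interval lengths (weeks).
#' @param omit_weeks weeks dropped for interval lengths that do not divide
#'   the window (default the study's incompletely acquired weeks 12 and
#'   26).
#' @param strata strata to analyse.
#' @param drop_flow_fraction fraction of manually registered flow records
#'   to lose before accounting (see [degrade_to_observed()]).
#' @param outdir if non-NULL, report tables are written there as CSV along
#'   with a `manifest.json` naming seed, inputs and outputs.
#' @return an `abx_report_bundle` list: the four tables, the two
#'   consumption series, the simulation, and a `manifest`.
#' @export
run_pipeline <- function(config = default_study_config(), seed = NULL,
                         intervals = 1:4, omit_weeks = c(12, 26),
                         strata = c("all", "parenteral", "oral"),
                         drop_flow_fraction = 0, outdir = NULL) {
  sim <- simulate_wards(config, seed = seed)
  if (drop_flow_fraction > 0) {
    sim <- degrade_to_observed(sim, drop_flow_fraction)
  }
  ref <- config$ref
  weeks <- seq_len(config$weeks)
  ward <- ward_consumption(sim$snapshots, sim$flows, ref, weeks = weeks)
  pharm <- pharmacy_consumption(
    sim$sales, sim$flows,
    wards = sort(unique(config$demand$ward_id)),
    agents = sort(unique(config$demand$agent_id)),
    weeks = weeks
  ) |>
    impute_missing_blocks(config$missing_blocks)
  bundle <- analyze_series(
    pharm, ward, ref,
    intervals = intervals, omit_weeks = omit_weeks, strata = strata
  )
  bundle$sim <- sim
  bundle$manifest <- pipeline_manifest(
    mode = "simulate", seed = sim$seed, config = config, outdir = outdir
  )
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

#' Run the pipeline from CSV input files
#'
#' @param snapshots,flows,sales,ddd_reference paths to the four CSV inputs
#'   (formats in [accounting-data] and [read_ddd_reference()]).
#' @param missing_blocks count-gap blocks to average over, as in
#'   [sim_config()].
#' @inheritParams run_pipeline
#' @return an `abx_report_bundle`, as [run_pipeline()].
#' @export
run_pipeline_files <- function(snapshots, flows, sales, ddd_reference,
                               missing_blocks = list(),
                               intervals = 1:4, omit_weeks = c(12, 26),
                               strata = c("all", "parenteral", "oral"),
                               outdir = NULL) {
  ref <- read_ddd_reference(ddd_reference)
  snap <- read_snapshots(snapshots)
  flw <- read_flows(flows)
  sls <- read_sales(sales)
  weeks <- seq_len(max(snap$week))
  ward <- ward_consumption(snap, flw, ref, weeks = weeks)
  pharm <- pharmacy_consumption(
    sls, flw,
    wards = sort(unique(snap$ward_id)),
    agents = sort(unique(c(snap$agent_id, sls$agent_id, flw$agent_id))),
    weeks = weeks
  ) |>
    impute_missing_blocks(missing_blocks)
  bundle <- analyze_series(
    pharm, ward, ref,
    intervals = intervals, omit_weeks = omit_weeks, strata = strata
  )
  bundle$manifest <- pipeline_manifest(
    mode = "from_files", seed = NA_integer_, config = NULL, outdir = outdir,
    inputs = c(
      snapshots = snapshots, flows = flows, sales = sales,
      ddd_reference = ddd_reference
    )
  )
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

analyze_series <- function(pharm, ward, ref, intervals, omit_weeks, strata) {
  structure(
    list(
      consumption = consumption_report(pharm, ward, ref),
      reliability = reliability_report(
        pharm, ward, ref,
        intervals = intervals,
        omit_weeks = omit_weeks, strata = strata
      ),
      agreement = agreement_report(
        pharm, ward, ref,
        intervals = intervals,
        omit_weeks = omit_weeks, strata = strata
      ),
      ba_data = bland_altman_data(
        pharm, ward, ref,
        intervals = intervals,
        omit_weeks = omit_weeks, strata = strata
      ),
      pharmacy_series = pharm,
      ward_series = ward
    ),
    class = "abx_report_bundle"
  )
}

pipeline_manifest <- function(mode, seed, config, outdir, inputs = NULL) {
  list(
    mode = mode,
    seed = seed,
    package = "abxflow",
    version = as.character(utils::packageVersion("abxflow")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    weeks = if (!is.null(config)) config$weeks else NA_integer_,
    wards = if (!is.null(config)) {
      sort(unique(config$demand$ward_id))
    } else {
      NULL
    },
    inputs = as.list(inputs),
    outdir = outdir
  )
}

#' @export
print.abx_report_bundle <- function(x, ...) {
  grand <- x$consumption |> filter(.data$ward_id == "all_wards")
  cat(sprintf(
    paste0(
      "surveillance report bundle (%s mode)\n",
      "  grand totals: pharmacy %.1f DDDs, ward %.1f DDDs (diff %.1f%%)\n",
      "  reliability rows: %d, agreement rows: %d\n"
    ),
    x$manifest$mode, grand$pharmacy_ddd, grand$ward_ddd, grand$diff_pct,
    nrow(x$reliability), nrow(x$agreement)
  ))
  invisible(x)
}

write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_csv(bundle$consumption, file.path(outdir, "consumption.csv"))
  write_csv(bundle$reliability, file.path(outdir, "reliability.csv"))
  write_csv(bundle$agreement, file.path(outdir, "agreement.csv"))
  write_csv(bundle$ba_data, file.path(outdir, "bland_altman_data.csv"))
  write_csv(
    bundle$pharmacy_series,
    file.path(outdir, "pharmacy_series.csv")
  )
  write_csv(bundle$ward_series, file.path(outdir, "ward_series.csv"))
  manifest <- bundle$manifest
  manifest_chr <- vapply(
    manifest,
    function(x) paste(as.character(x), collapse = ";"), character(1)
  )
  write_csv(
    tibble(field = names(manifest_chr), value = unname(manifest_chr)),
    file.path(outdir, "manifest.csv")
  )
  invisible(outdir)
}
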