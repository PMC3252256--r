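#' Build and validate a DDD reference table
#'
#' The reference table maps each antibiotic item (an "agent") to its WHO
#' ATC/DDD conversion data: the defined daily dose in milligrams and the
#' strength of one physical pack unit (vial, infusion bag, or tablet). DDD
#' assignments change between ATC index years, so they are configuration
#' data rather than package constants; edit the CSV shipped under
#' `inst/extdata/ddd_reference.csv` to match the index year in force.
#'
#' @param entries data frame with columns `agent_id`, `atc_code`, `name`,
#'   `route` (`"parenteral"` or `"oral"`), `ddd_mg` (> 0),
#'   `pack_strength_mg` (> 0) and logical `is_bsa` (broad-spectrum flag).
#' @return A validated tibble with class `ddd_reference`.
#' @examples
#' ref <- ddd_reference(tibble::tibble(
#'   agent_id = "ceftriaxone", atc_code = "J01DD04", name = "Ceftriaxone",
#'   route = "parenteral", ddd_mg = 2000, pack_strength_mg = 2000,
#'   is_bsa = TRUE
#' ))
#' packs_to_ddd(3, "ceftriaxone", ref)
#' @export
ddd_reference <- function(entries) {
  entries <- as_tibble(entries)
  required <- c(
    "agent_id", "atc_code", "name", "route", "ddd_mg",
    "pack_strength_mg", "is_bsa"
  )
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "DDD reference table lacks column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "abxflow_error_validation"
    )
  }
  if (anyDuplicated(entries$agent_id)) {
    abort("duplicate agent_id in DDD reference table",
      class = "abxflow_error_validation"
    )
  }
  if (anyDuplicated(entries[c("atc_code", "route")])) {
    abort("duplicate (atc_code, route) pair in DDD reference table",
      class = "abxflow_error_validation"
    )
  }
  if (!all(entries$route %in% c("parenteral", "oral"))) {
    abort("route must be 'parenteral' or 'oral'",
      class = "abxflow_error_validation"
    )
  }
  if (!all(entries$ddd_mg > 0) || !all(entries$pack_strength_mg > 0)) {
    abort("ddd_mg and pack_strength_mg must be positive",
      class = "abxflow_error_validation"
    )
  }
  class(entries) <- c("ddd_reference", class(entries))
  entries
}

#' Read a DDD reference table from CSV
#'
#' @param path path to a UTF-8 CSV with the columns documented in
#'   [ddd_reference()].
#' @return a `ddd_reference` tibble.
#' @export
read_ddd_reference <- function(path) {
  entries <- read_csv(
    path,
    col_types = cols(
      agent_id = col_character(), atc_code = col_character(),
      name = col_character(), route = col_character(),
      ddd_mg = col_double(), pack_strength_mg = col_double(),
      is_bsa = col_logical()
    )
  )
  ddd_reference(entries)
}

#' Bundled WHO ATC/DDD reference for the eight study agents
#'
#' Convenience accessor for the reference table shipped with the package:
#' the broad-spectrum set used throughout (cefuroxime; cefotaxime,
#' ceftazidime, ceftriaxone; meropenem, imipenem/cilastatin; parenteral and
#' oral ciprofloxacin). Imipenem/cilastatin is a single item with the DDD
#' defined on the imipenem component.
#'
#' @return a `ddd_reference` tibble with eight rows.
#' @export
default_ddd_reference <- function() {
  read_ddd_reference(
    system.file("extdata", "ddd_reference.csv",
      package = "abxflow", mustWork = TRUE
    )
  )
}

lookup_agents <- function(agent_id, ref) {
  idx <- match(agent_id, ref$agent_id)
  if (anyNA(idx)) {
    abort(
      paste0(
        "unknown agent_id: ",
        paste(unique(agent_id[is.na(idx)]), collapse = ", ")
      ),
      class = "abxflow_error_lookup"
    )
  }
  ref[idx, , drop = FALSE]
}

#' Convert milligram amounts to defined daily doses
#'
#' @param amount_mg nonnegative milligram amounts (vectorised).
#' @param agent_id agent identifiers, recycled against `amount_mg`.
#' @param ref a [ddd_reference()] table; unknown identifiers are an error,
#'   never a silent zero.
#' @return DDDs, `amount_mg / ddd_mg`.
#' @export
mg_to_ddd <- function(amount_mg, agent_id, ref) {
  if (any(amount_mg < 0)) {
    abort("amount_mg must be nonnegative",
      class = "abxflow_error_validation"
    )
  }
  agents <- lookup_agents(agent_id, ref)
  amount_mg / agents$ddd_mg
}

#' Convert pack-unit counts (vials, bags, tablets) to defined daily doses
#'
#' Fractional pack counts are allowed (partially used blister packs).
#'
#' @inheritParams mg_to_ddd
#' @param pack_count nonnegative pack counts (vectorised).
#' @return DDDs, `pack_count * pack_strength_mg / ddd_mg`.
#' @export
packs_to_ddd <- function(pack_count, agent_id, ref) {
  if (any(pack_count < 0)) {
    abort("pack_count must be nonnegative",
      class = "abxflow_error_validation"
    )
  }
  agents <- lookup_agents(agent_id, ref)
  pack_count * agents$pack_strength_mg / agents$ddd_mg
}

#' DDDs per 100 occupied bed-days
#'
#' The standard hospital drug-utilisation rate: `100 * ddd_total /
#' bed_days`. Bed-day censuses enter only as a scalar denominator.
#'
#' @param ddd_total total consumption in DDDs.
#' @param bed_days positive count of occupied bed-days.
#' @return the utilisation rate (vectorised).
#' @export
ddd_per_100_bed_days <- function(ddd_total, bed_days) {
  if (any(bed_days <= 0)) {
    abort("bed_days must be positive", class = "abxflow_error_validation")
  }
  100 * ddd_total / bed_days
}

#' Round half away from zero
#'
#' Report-table rounding: 0.25 -> 0.3 and -0.25 -> -0.3, unlike base
#' [round()]'s round-half-to-even. Used only at serialization; internal
#' computation keeps full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_out <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
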