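# Cifuentes-style tourism carrying capacity: PCC -> RCC -> ECC.
#
# Each stage corrects the previous one, so for any zone
#   PCC >= RCC >= ECC
# (non-strict: with no limiting factors and no management deficit the three
# coincide). All intermediate values are kept at full precision; integer
# visitor counts are produced only through a configurable RoundingPolicy.

#' Rounding policy for daily visitor counts
#'
#' Integer rounding conventions applied to the daily capacity values, plus
#' the number of decimals for percentage quantities (correction factors and
#' the facility-management deficit). The defaults — floor for PCC and RCC,
#' ceiling for ECC, integer percentages — reproduce the published worked
#' values for the Tehran-province dataset.
#'
#' @param pcc_daily,rcc_daily,ecc_daily one of `"floor"`, `"half_up"`,
#'   `"ceiling"`.
#' @param percent_decimals integer decimals for percentages (default 0).
#' @return an object of class `rounding_policy`.
#' @export
rounding_policy <- function(pcc_daily = "floor", rcc_daily = "floor",
                            ecc_daily = "ceiling", percent_decimals = 0) {
  modes <- c("floor", "half_up", "ceiling")
  pcc_daily <- match.arg(pcc_daily, modes)
  rcc_daily <- match.arg(rcc_daily, modes)
  ecc_daily <- match.arg(ecc_daily, modes)
  stopifnot(is_count(percent_decimals))
  structure(
    list(pcc_daily = pcc_daily, rcc_daily = rcc_daily, ecc_daily = ecc_daily,
         percent_decimals = percent_decimals),
    class = "rounding_policy"
  )
}

#' @export
format.rounding_policy <- function(x, ...) {
  sprintf("rounding_policy(pcc=%s, rcc=%s, ecc=%s, percent_decimals=%d)",
          x$pcc_daily, x$rcc_daily, x$ecc_daily, x$percent_decimals)
}

#' @export
print.rounding_policy <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Rotation factor
#'
#' Number of permissible daily visits: site availability hours divided by
#' the average duration of one visit. With the 8 h availability and 8 h
#' average visit used for the worked dataset, Rf = 1.
#'
#' @param availability_hours hours/day the site is open, > 0.
#' @param average_visit_hours average visit length in hours, > 0.
#' @return unitless ratio.
#' @export
rotation_factor <- function(availability_hours, average_visit_hours) {
  if (!is.finite(availability_hours) || availability_hours <= 0) {
    stop_domain("availability_hours must be > 0")
  }
  if (!is.finite(average_visit_hours) || average_visit_hours <= 0) {
    stop_domain("average_visit_hours must be > 0")
  }
  availability_hours / average_visit_hours
}

#' Physical carrying capacity (daily)
#'
#' PCC = A / a x Rf, where A is the usable zone area, a the space one
#' visitor needs to move freely (V = 1 visitor per a m2), and Rf the
#' rotation factor. Returned as an integer visitor count under the policy's
#' PCC rounding (default floor).
#'
#' @param area_m2 zone area in m2, >= 0.
#' @param space_per_visitor_m2 per-visitor space standard in m2, > 0.
#' @param rf rotation factor, > 0.
#' @param policy a [rounding_policy()].
#' @return visitors/day (integer-valued numeric).
#' @export
physical_carrying_capacity <- function(area_m2, space_per_visitor_m2, rf = 1,
                                       policy = rounding_policy()) {
  if (!is.finite(area_m2) || area_m2 < 0) stop_domain("area_m2 must be >= 0")
  if (!is.finite(space_per_visitor_m2) || space_per_visitor_m2 <= 0) {
    stop_domain("space_per_visitor_m2 must be > 0")
  }
  if (!is.finite(rf) || rf <= 0) stop_domain("rf must be > 0")
  apply_rounding(area_m2 / space_per_visitor_m2 * rf, policy$pcc_daily)
}

#' Annualize a daily visitor capacity
#'
#' @param daily visitors/day, >= 0.
#' @param operating_days days/year the site operates, 0..366.
#' @return visitors/year (exact integer multiple).
#' @export
annualize <- function(daily, operating_days) {
  if (!is.finite(daily) || daily < 0) stop_domain("daily must be >= 0")
  if (!is_count(operating_days) || operating_days > 366) {
    stop_domain("operating_days must be an integer in 0..366")
  }
  daily * operating_days
}

#' Correction factor from a limiting variable
#'
#' Cf = (m / Mt) x 100, where m is the magnitude of the limiting variable
#' (e.g. days with frost) and Mt the total possible magnitude in the same
#' unit (365 days for day-count variables).
#'
#' @param magnitude_m limiting magnitude, `0 <= m <= Mt`.
#' @param total_mt total magnitude, > 0.
#' @param code variable code carried through to the result (default `""`).
#' @param percent_decimals decimals for the percentage (default 0).
#' @return data frame row with `code`, `percent`, `source_m`, `source_mt`.
#' @export
correction_factor <- function(magnitude_m, total_mt, code = "",
                              percent_decimals = 0) {
  if (!is.finite(total_mt) || total_mt <= 0) stop_domain("total_mt must be > 0")
  if (!is.finite(magnitude_m) || magnitude_m < 0 || magnitude_m > total_mt) {
    stop_domain("magnitude_m must satisfy 0 <= m <= total_mt")
  }
  data.frame(
    code = code,
    percent = round_half_up(magnitude_m / total_mt * 100, percent_decimals),
    source_m = magnitude_m,
    source_mt = total_mt,
    stringsAsFactors = FALSE
  )
}

#' Correction factors for one site's climate record
#'
#' Builds one correction factor per limiting variable, preserving input
#' order. Day-unit variables default to Mt = 365 when the record carries no
#' denominator; hour-unit variables have no natural default and must be
#' given an explicit Mt via `mt_defaults` or a direct percentage via
#' `percent_overrides` (the sunshine-hours variable of the worked dataset is
#' handled this way, since its published percentages are not derivable from
#' any natural hours base).
#'
#' @param record data frame of climate rows for one site (columns `code`,
#'   `magnitude`, `unit`, `total_mt`).
#' @param mt_defaults named numeric vector mapping code to Mt, consulted
#'   when `total_mt` is missing.
#' @param percent_overrides named numeric vector mapping code to a percent
#'   used verbatim (skips the m/Mt computation).
#' @param percent_decimals decimals for percentages (default 0).
#' @return data frame of correction factors, one row per variable.
#' @export
correction_set_from_climate <- function(record, mt_defaults = NULL,
                                        percent_overrides = NULL,
                                        percent_decimals = 0) {
  stopifnot(is.data.frame(record), nrow(record) >= 1)
  out <- vector("list", nrow(record))
  for (i in seq_len(nrow(record))) {
    r <- record[i, ]
    if (!is.null(percent_overrides) && r$code %in% names(percent_overrides)) {
      out[[i]] <- data.frame(
        code = r$code,
        percent = round_half_up(percent_overrides[[r$code]], percent_decimals),
        source_m = r$magnitude, source_mt = NA_real_,
        stringsAsFactors = FALSE
      )
      next
    }
    mt <- r$total_mt
    if (is.na(mt) && !is.null(mt_defaults) && r$code %in% names(mt_defaults)) {
      mt <- mt_defaults[[r$code]]
    }
    if (is.na(mt) && r$unit == "days") mt <- 365
    if (is.na(mt)) {
      stop_domain("no Mt configured for hour-unit variable '", r$code,
                  "'; supply mt_defaults or percent_overrides")
    }
    out[[i]] <- correction_factor(r$magnitude, mt, code = r$code,
                                  percent_decimals = percent_decimals)
  }
  do.call(rbind, out)
}

#' Real carrying capacity (daily)
#'
#' Reduces the PCC by the site's limiting factors. The default
#' multiplicative form applies each correction percentage as a survival
#' fraction, `PCC x prod((100 - Cfi)/100)`; the subtractive form, retained
#' for completeness, subtracts the raw terms, `PCC - sum(Cfi)`. Both floor
#' the result at zero; the multiplicative result is rounded once at the end
#' under the policy's RCC mode.
#'
#' @param pcc_daily visitors/day, >= 0.
#' @param cf_percents numeric vector of correction percentages (each in
#'   `[0, 100]` for the multiplicative mode; non-negative terms for the
#'   subtractive mode). May be empty (identity).
#' @param mode `"multiplicative"` (default) or `"subtractive"`.
#' @param policy a [rounding_policy()].
#' @return visitors/day.
#' @export
real_carrying_capacity <- function(pcc_daily, cf_percents = numeric(),
                                   mode = c("multiplicative", "subtractive"),
                                   policy = rounding_policy()) {
  mode <- match.arg(mode)
  if (!is.finite(pcc_daily) || pcc_daily < 0) stop_domain("pcc_daily must be >= 0")
  if (mode == "multiplicative") {
    if (length(cf_percents) && any(cf_percents < 0 | cf_percents > 100)) {
      stop_domain("each correction percent must be in [0, 100]")
    }
    raw <- pcc_daily * prod((100 - cf_percents) / 100)
    max(apply_rounding(raw, policy$rcc_daily), 0)
  } else {
    if (length(cf_percents) && any(cf_percents < 0)) {
      stop_domain("subtractive terms must be >= 0")
    }
    max(pcc_daily - sum(cf_percents), 0)
  }
}

#' Ideal management capacity from a staffing standard
#'
#' Number of environmental guardians a site of the given area needs under a
#' hectares-per-guardian standard (the Iranian Department of Environment
#' standard is one guardian per 1000 ha). Rounded half-up, with a floor of
#' one guardian.
#'
#' @param total_area_ha site area in hectares, > 0.
#' @param hectares_per_guardian standard, > 0 (default 1000).
#' @return integer number of guardians, >= 1.
#' @export
ideal_management_capacity <- function(total_area_ha, hectares_per_guardian = 1000) {
  if (!is.finite(total_area_ha) || total_area_ha <= 0) {
    stop_domain("total_area_ha must be > 0")
  }
  if (!is.finite(hectares_per_guardian) || hectares_per_guardian <= 0) {
    stop_domain("hectares_per_guardian must be > 0")
  }
  max(round_half_up(total_area_ha / hectares_per_guardian), 1)
}

#' Facility-management deficit percentage
#'
#' FM = ((Imc - Emc) / Imc) x 100: the fraction of the ideal management
#' capacity not met by the existing one, as a percentage.
#'
#' @param imc ideal management capacity, positive integer.
#' @param emc existing management capacity, `0 <= emc <= imc`.
#' @param percent_decimals decimals (default 0).
#' @return percentage in `[0, 100]`.
#' @export
facility_management <- function(imc, emc, percent_decimals = 0) {
  if (!is_count(imc) || imc <= 0) stop_domain("imc must be a positive integer")
  if (!is_count(emc)) stop_domain("emc must be a non-negative integer")
  if (emc > imc) stop_domain("emc exceeds imc")
  round_half_up((imc - emc) / imc * 100, percent_decimals)
}

#' Effective carrying capacity (daily)
#'
#' ECC = RCC x (100 - FM)/100: the real carrying capacity scaled down by
#' the management deficit. Rounded under the policy's ECC mode (default
#' ceiling, the convention that reproduces the published worked values).
#'
#' @param rcc_daily visitors/day, >= 0.
#' @param fm_percent management deficit percentage in `[0, 100]`.
#' @param policy a [rounding_policy()].
#' @return visitors/day.
#' @export
effective_carrying_capacity <- function(rcc_daily, fm_percent,
                                        policy = rounding_policy()) {
  if (!is.finite(rcc_daily) || rcc_daily < 0) stop_domain("rcc_daily must be >= 0")
  if (!is.finite(fm_percent) || fm_percent < 0 || fm_percent > 100) {
    stop_domain("fm_percent must be in [0, 100]")
  }
  max(apply_rounding(rcc_daily * (100 - fm_percent) / 100, policy$ecc_daily), 0)
}

#' Full carrying-capacity computation for one site
#'
#' Orchestrates the three stages for every recreation-zone class of a site:
#' rotation factor from the site profile, daily and annual PCC per zone,
#' correction factors from the site's climate record, daily and annual RCC,
#' the facility-management deficit from the management record, and daily
#' and annual ECC. Daily counts are rounded under `policy`; annual values
#' are daily x operating days. After rounding, the ordering
#' PCC >= RCC >= ECC is enforced by clamping (only reachable when a rounding
#' mode rounds a lower stage up past a higher one).
#'
#' @param profile one row of a sites table (see [load_site_dataset()]).
#' @param zones zones table (rows for other sites are ignored).
#' @param climate climate table.
#' @param management management table.
#' @param policy a [rounding_policy()].
#' @param options optional list:
#'   * `rcc_daily_override`: named numeric vector, zone key (e.g. `"ET1"`)
#'     to an externally observed daily RCC used in place of the computed
#'     one — the published RCC values of the worked dataset are not
#'     reproducible from the published correction factors, so driving the
#'     ECC stage from them requires injection;
#'   * `cf_percent_overrides`: named percent vector passed to
#'     [correction_set_from_climate()];
#'   * `mt_defaults`: named Mt vector, same destination;
#'   * `rcc_mode`: `"multiplicative"` (default) or `"subtractive"`.
#' @return data frame of class `capacity_result`, one row per zone class,
#'   carrying full-precision (`*_exact`) and policy-rounded values, with the
#'   site's correction-factor set in attribute `cf_set`.
#' @export
compute_site <- function(profile, zones, climate, management,
                         policy = rounding_policy(), options = list()) {
  stopifnot(is.data.frame(profile), nrow(profile) == 1)
  site <- profile$name
  z <- zones[zones$site_name == site, , drop = FALSE]
  if (nrow(z) == 0) stop_domain("no zones for site '", site, "'")
  cl <- climate[climate$site_name == site, , drop = FALSE]
  if (nrow(cl) == 0) stop_domain("no climate records for site '", site, "'")
  mg <- management[management$site_name == site, , drop = FALSE]
  if (nrow(mg) == 0) stop_domain("no management record for site '", site, "'")

  rf <- rotation_factor(profile$availability_hours, profile$average_visit_hours)
  cfs <- correction_set_from_climate(
    cl,
    mt_defaults = options$mt_defaults,
    percent_overrides = options$cf_percent_overrides,
    percent_decimals = policy$percent_decimals
  )
  fm <- facility_management(mg$imc, mg$emc, policy$percent_decimals)
  mode <- options$rcc_mode %||% "multiplicative"
  override <- options$rcc_daily_override

  rows <- vector("list", nrow(z))
  for (i in seq_len(nrow(z))) {
    zi <- z[i, ]
    key <- paste0(ifelse(zi$use_type == "extensive", "ET", "IT"), zi$class_label)
    pcc_exact <- zi$area_m2 / zi$space_per_visitor_m2 * rf
    pcc <- physical_carrying_capacity(zi$area_m2, zi$space_per_visitor_m2, rf, policy)
    if (mode == "multiplicative") {
      rcc_exact <- pcc * prod((100 - cfs$percent) / 100)
    } else {
      rcc_exact <- max(pcc - sum(cfs$percent), 0)
    }
    rcc <- real_carrying_capacity(pcc, cfs$percent, mode, policy)
    rcc_injected <- FALSE
    if (!is.null(override) && key %in% names(override)) {
      rcc <- override[[key]]
      rcc_exact <- rcc
      rcc_injected <- TRUE
    }
    rcc <- min(rcc, pcc)
    ecc_exact <- rcc_exact * (100 - fm) / 100
    ecc <- effective_carrying_capacity(rcc, fm, policy)
    ecc <- min(ecc, rcc)
    rows[[i]] <- data.frame(
      site_name = site, use_type = zi$use_type, class_label = zi$class_label,
      zone = key, area_m2 = zi$area_m2,
      space_per_visitor_m2 = zi$space_per_visitor_m2, rf = rf,
      operating_days = profile$operating_days,
      pcc_exact = pcc_exact, pcc_daily = pcc,
      pcc_annual = annualize(pcc, profile$operating_days),
      cf_total = sum(cfs$percent),
      rcc_exact = rcc_exact, rcc_daily = rcc,
      rcc_annual = annualize(rcc, profile$operating_days),
      rcc_injected = rcc_injected,
      imc = mg$imc, emc = mg$emc, fm_percent = fm,
      ecc_exact = ecc_exact, ecc_daily = ecc,
      ecc_annual = annualize(ecc, profile$operating_days),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  attr(res, "cf_set") <- cfs
  attr(res, "policy") <- policy
  class(res) <- c("capacity_result", "data.frame")
  res
}

#' Carrying capacity for every site of a dataset
#'
#' Convenience wrapper running [compute_site()] over all rows of the sites
#' table. Per-site options may be supplied as a named list keyed by site
#' name; entries common to all sites go in `options`.
#'
#' @inheritParams compute_site
#' @param sites sites table.
#' @param site_options named list of per-site `options` lists.
#' @return a `capacity_result` data frame covering all sites.
#' @export
compute_dataset <- function(sites, zones, climate, management,
                            policy = rounding_policy(), options = list(),
                            site_options = list()) {
  out <- lapply(seq_len(nrow(sites)), function(i) {
    opt <- utils::modifyList(options, site_options[[sites$name[i]]] %||% list())
    compute_site(sites[i, , drop = FALSE], zones, climate, management,
                 policy, opt)
  })
  res <- do.call(rbind, out)
  class(res) <- c("capacity_result", "data.frame")
  res
}
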