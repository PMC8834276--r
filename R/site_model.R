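# Typed tabular data model for protected-area sites, recreation zones,
# climatic limiting variables and management capacities.
#
# All four tables are plain tab-delimited UTF-8 text with a required header.
# Zone areas are stored in square metres, site totals in hectares; the
# conversion factor is fixed at 10,000 m2/ha.

M2_PER_HA <- 10000

# Column contracts, one per schema. Order is the canonical write order.
SITE_SCHEMAS <- list(
  sites = c(
    "name", "total_area_ha", "established_year", "guardians_count",
    "guard_stations", "reported_annual_visitors", "operating_days",
    "availability_hours", "average_visit_hours"
  ),
  zones = c(
    "site_name", "use_type", "class_label", "area_m2", "space_per_visitor_m2"
  ),
  climate = c(
    "site_name", "station_name", "elevation_m", "latitude", "longitude",
    "code", "magnitude", "unit", "total_mt"
  ),
  management = c("site_name", "imc", "emc")
)

#' Column names required by a dataset schema
#'
#' @param schema one of `"sites"`, `"zones"`, `"climate"`, `"management"`.
#' @return character vector of required column names, in canonical order.
#' @export
site_schema_columns <- function(schema) {
  schema <- match.arg(schema, names(SITE_SCHEMAS))
  SITE_SCHEMAS[[schema]]
}

#' Default climatic limiting-variable codes
#'
#' The eight-variable set used for Iranian protected areas: days with
#' lightning, fog, dust, visibility below 2000 m, frost, average cloud
#' cover, intense sunshine hours, and maximum wind speed. Variable codes are
#' free-form text; this set is only a convenient default, and sites may
#' carry fewer or more variables.
#'
#' @return named character vector mapping code to a short label.
#' @export
default_limiting_variables <- function() {
  c(
    Cf1 = "days with lightning",
    Cf2 = "days with fog",
    Cf3 = "days with dust",
    Cf4 = "days with visibility < 2000 m",
    Cf5 = "days with frost",
    Cf6 = "days with average cloud cover",
    Cf7 = "intense sunshine hours",
    Cf8 = "days with maximum wind speed"
  )
}

# ---- row-level validation ---------------------------------------------------

validate_sites_df <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is.finite(r$total_area_ha) || r$total_area_ha <= 0) {
      stop_domain("sites row ", i, ": total_area_ha must be > 0")
    }
    if (!is_count(r$guardians_count)) {
      stop_domain("sites row ", i, ": guardians_count must be a non-negative integer")
    }
    if (!is_count(r$guard_stations)) {
      stop_domain("sites row ", i, ": guard_stations must be a non-negative integer")
    }
    if (!is.na(r$reported_annual_visitors) && !is_count(r$reported_annual_visitors)) {
      stop_domain("sites row ", i, ": reported_annual_visitors must be a non-negative integer")
    }
    if (!is_count(r$operating_days) || r$operating_days < 1 || r$operating_days > 366) {
      stop_domain("sites row ", i, ": operating_days must be in 1..366")
    }
    if (!is.finite(r$availability_hours) || r$availability_hours <= 0 ||
        r$availability_hours > 24) {
      stop_domain("sites row ", i, ": availability_hours must be in (0, 24]")
    }
    if (!is.finite(r$average_visit_hours) || r$average_visit_hours <= 0) {
      stop_domain("sites row ", i, ": average_visit_hours must be > 0")
    }
  }
  if (anyDuplicated(df$name)) {
    stop_domain("sites: duplicate site name: ",
                df$name[duplicated(df$name)][1])
  }
  invisible(df)
}

validate_zones_df <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$use_type %in% c("extensive", "intensive")) {
      stop_domain("zones row ", i, ": use_type must be 'extensive' or 'intensive'")
    }
    if (!r$class_label %in% c(1L, 2L)) {
      stop_domain("zones row ", i, ": class_label must be 1 or 2")
    }
    if (!is.finite(r$area_m2) || r$area_m2 < 0) {
      stop_domain("zones row ", i, ": area_m2 must be >= 0")
    }
    if (!is.finite(r$space_per_visitor_m2) || r$space_per_visitor_m2 <= 0) {
      stop_domain("zones row ", i, ": space_per_visitor_m2 must be > 0")
    }
  }
  key <- paste(df$site_name, df$use_type, df$class_label)
  if (anyDuplicated(key)) {
    stop_domain("zones: duplicate (site_name, use_type, class_label): ",
                key[duplicated(key)][1])
  }
  invisible(df)
}

validate_climate_df <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!nzchar(r$code)) stop_domain("climate row ", i, ": empty variable code")
    if (!r$unit %in% c("days", "hours")) {
      stop_domain("climate row ", i, ": unit must be 'days' or 'hours'")
    }
    if (!is.finite(r$magnitude) || r$magnitude < 0) {
      stop_domain("climate row ", i, ": magnitude must be >= 0")
    }
    if (!is.na(r$total_mt)) {
      if (r$total_mt <= 0) stop_domain("climate row ", i, ": total_mt must be > 0")
      if (r$magnitude > r$total_mt) {
        stop_domain("climate row ", i, ": magnitude exceeds total_mt")
      }
    }
  }
  key <- paste(df$site_name, df$code)
  if (anyDuplicated(key)) {
    stop_domain("climate: duplicate (site_name, code): ", key[duplicated(key)][1])
  }
  invisible(df)
}

validate_management_df <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is_count(r$imc) || r$imc <= 0) {
      stop_domain("management row ", i, ": imc must be a positive integer")
    }
    if (!is_count(r$emc)) {
      stop_domain("management row ", i, ": emc must be a non-negative integer")
    }
    if (r$emc > r$imc) {
      stop_domain("management row ", i, ": emc exceeds imc")
    }
  }
  if (anyDuplicated(df$site_name)) {
    stop_domain("management: duplicate site_name: ",
                df$site_name[duplicated(df$site_name)][1])
  }
  invisible(df)
}

SITE_VALIDATORS <- list(
  sites = validate_sites_df, zones = validate_zones_df,
  climate = validate_climate_df, management = validate_management_df
)

# Column type coercion per schema; character columns are left as-is.
coerce_schema <- function(df, schema) {
  num_cols <- switch(schema,
    sites = c("total_area_ha", "established_year", "guardians_count",
              "guard_stations", "reported_annual_visitors", "operating_days",
              "availability_hours", "average_visit_hours"),
    zones = c("class_label", "area_m2", "space_per_visitor_m2"),
    climate = c("elevation_m", "latitude", "longitude", "magnitude", "total_mt"),
    management = c("imc", "emc")
  )
  for (col in num_cols) {
    v <- df[[col]]
    if (is.character(v)) v[v == ""] <- NA
    df[[col]] <- suppressWarnings(as.numeric(v))
  }
  df
}

#' Load one table of a site dataset
#'
#' Reads a tab-delimited UTF-8 file whose header must match the schema
#' exactly (missing or extra columns are a schema error naming the column).
#' Every row is checked against its type invariants; violations report the
#' offending row index. Row order is preserved.
#'
#' @param path path to the delimited file.
#' @param schema one of `"sites"`, `"zones"`, `"climate"`, `"management"`.
#' @return a `data.frame` with canonical column order and an added class
#'   `etcc_<schema>`.
#' @seealso [write_site_dataset()], [validate_dataset()]
#' @export
load_site_dataset <- function(path, schema) {
  schema <- match.arg(schema, names(SITE_SCHEMAS))
  if (!file.exists(path)) stop_domain("file does not exist: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8", na.strings = "NA")
  want <- SITE_SCHEMAS[[schema]]
  missing <- setdiff(want, names(df))
  extra <- setdiff(names(df), want)
  if (length(missing)) {
    stop_domain("schema '", schema, "': missing column(s): ",
                paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop_domain("schema '", schema, "': unexpected column(s): ",
                paste(extra, collapse = ", "))
  }
  df <- df[, want, drop = FALSE]
  df <- coerce_schema(df, schema)
  SITE_VALIDATORS[[schema]](df)
  class(df) <- c(paste0("etcc_", schema), "data.frame")
  df
}

#' Write one table of a site dataset
#'
#' Inverse of [load_site_dataset()]: tab-delimited UTF-8 text with header,
#' `NA` written as `NA`. A written-then-reloaded valid table reproduces
#' identical records.
#'
#' @param df a data frame with the schema's columns.
#' @param path output file path.
#' @param schema one of `"sites"`, `"zones"`, `"climate"`, `"management"`.
#' @return `path`, invisibly.
#' @export
write_site_dataset <- function(df, path, schema) {
  schema <- match.arg(schema, names(SITE_SCHEMAS))
  want <- SITE_SCHEMAS[[schema]]
  missing <- setdiff(want, names(df))
  if (length(missing)) {
    stop_domain("schema '", schema, "': missing column(s): ",
                paste(missing, collapse = ", "))
  }
  utils::write.table(df[, want, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-table consistency report for a site dataset
#'
#' Checks referential and accounting consistency across the four tables:
#' zones referencing unknown sites, sites lacking climate or management
#' records, and zone-area sums exceeding the site's total area. Problems are
#' reported, never thrown; an empty report means the dataset is consistent.
#'
#' @param sites,zones,climate,management data frames as returned by
#'   [load_site_dataset()].
#' @return data frame with columns `check`, `site_name`, `message`; zero
#'   rows when consistent.
#' @export
validate_dataset <- function(sites, zones, climate, management) {
  notes <- list()
  add <- function(check, site, msg) {
    notes[[length(notes) + 1]] <<- data.frame(
      check = check, site_name = site, message = msg,
      stringsAsFactors = FALSE
    )
  }
  for (s in setdiff(unique(zones$site_name), sites$name)) {
    add("dangling_zone", s, "zone references a site absent from the sites table")
  }
  for (s in setdiff(sites$name, unique(climate$site_name))) {
    add("missing_climate", s, "site has no climate records")
  }
  for (s in setdiff(sites$name, unique(management$site_name))) {
    add("missing_management", s, "site has no management record")
  }
  for (i in seq_len(nrow(sites))) {
    s <- sites$name[i]
    zsum_ha <- sum(zones$area_m2[zones$site_name == s]) / M2_PER_HA
    if (zsum_ha > sites$total_area_ha[i] + 1e-9) {
      add("zone_area_excess", s, sprintf(
        "zone areas sum to %.2f ha, exceeding the site total of %.2f ha",
        zsum_ha, sites$total_area_ha[i]
      ))
    }
  }
  if (length(notes)) do.call(rbind, notes) else data.frame(
    check = character(), site_name = character(), message = character(),
    stringsAsFactors = FALSE
  )
}

#' Environmental-guardian density of a site
#'
#' Guardians per hectare expressed on the conventional x100 scale, rounded
#' half-up to two decimals (14 guardians over 35,765 ha gives 0.04).
#'
#' @param guardians_count non-negative integer.
#' @param total_area_ha site area in hectares, > 0.
#' @return guardians per hectare x 100, two decimals.
#' @export
guardian_density <- function(guardians_count, total_area_ha) {
  if (!is.finite(total_area_ha) || total_area_ha <= 0) {
    stop_domain("total_area_ha must be > 0")
  }
  if (!is_count(guardians_count)) {
    stop_domain("guardians_count must be a non-negative integer")
  }
  round_half_up(guardians_count / total_area_ha * 100, 2)
}

#' Share of a site taken by a zone
#'
#' @param part_area zone area (any unit, same as `whole_area`).
#' @param whole_area reference area, > 0.
#' @return percentage rounded half-up to one decimal.
#' @export
zone_share <- function(part_area, whole_area) {
  if (!is.finite(whole_area) || whole_area <= 0) stop_domain("whole_area must be > 0")
  if (!is.finite(part_area) || part_area < 0) stop_domain("part_area must be >= 0")
  if (part_area > whole_area * (1 + 1e-12)) {
    stop_domain("part_area exceeds whole_area")
  }
  round_half_up(part_area / whole_area * 100, 1)
}

#' Worked dataset: three protected areas of Tehran province
#'
#' Loads the packaged dataset for Lar national park, Jajrud protected area
#' and Tangeh Vashi natural monument: site profiles, recreation zones (areas
#' in m2, per-visitor standards 2500 m2 extensive / 1500 m2 intensive),
#' climatic limiting variables from the nearest synoptic stations
#' (1996-2020 means), and management capacities. Also carries, as extra
#' elements, the published daily real-carrying-capacity values (not
#' derivable from the correction factors; used as optional injected data for
#' the ECC stage), the percent overrides for the sunshine-hours variable,
#' and the hectare-based recreation-class accounting table.
#'
#' @return named list with elements `sites`, `zones`, `climate`,
#'   `management`, `rcc_published`, `cf_percent_overrides`,
#'   `recreation_classes`.
#' @export
etcc_example_dataset <- function() {
  p <- function(f) system.file("extdata", f, package = "etcc", mustWork = TRUE)
  rcc <- utils::read.delim(p("rcc_published.tsv"), sep = "\t",
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  cf7 <- utils::read.delim(p("cf_percent_overrides.tsv"), sep = "\t",
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  rc <- utils::read.delim(p("recreation_classes.tsv"), sep = "\t",
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  list(
    sites = load_site_dataset(p("sites.tsv"), "sites"),
    zones = load_site_dataset(p("zones.tsv"), "zones"),
    climate = load_site_dataset(p("climate.tsv"), "climate"),
    management = load_site_dataset(p("management.tsv"), "management"),
    rcc_published = rcc,
    cf_percent_overrides = cf7,
    recreation_classes = rc
  )
}

#' Per-site computation options for the worked dataset
#'
#' Builds the `site_options` list for [compute_dataset()] from the extra
#' elements of [etcc_example_dataset()]: the published daily RCC values
#' injected into the ECC stage and the percent overrides for the
#' sunshine-hours variable.
#'
#' @param dataset a list as returned by [etcc_example_dataset()].
#' @return named list of per-site option lists.
#' @export
example_site_options <- function(dataset = etcc_example_dataset()) {
  out <- list()
  for (s in unique(dataset$sites$name)) {
    rcc <- dataset$rcc_published[dataset$rcc_published$site_name == s, ]
    cf <- dataset$cf_percent_overrides[
      dataset$cf_percent_overrides$site_name == s, ]
    out[[s]] <- list(
      rcc_daily_override = stats::setNames(rcc$rcc_daily, rcc$zone),
      cf_percent_overrides = stats::setNames(cf$percent, cf$code)
    )
  }
  out
}
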