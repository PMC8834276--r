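# Shared fixtures built in code.

# The packaged three-site worked dataset, loaded once per test file.
paper_dataset <- function() etcc_example_dataset()

# A tiny fully consistent two-site dataset built by hand (no files).
tiny_dataset <- function() {
  sites <- data.frame(
    name = c("alpha", "beta"),
    total_area_ha = c(10000, 2000),
    established_year = c(1990, 2005),
    guardians_count = c(5L, 1L),
    guard_stations = c(2L, 1L),
    reported_annual_visitors = c(20000L, 5000L),
    operating_days = c(365L, 120L),
    availability_hours = c(8, 8),
    average_visit_hours = c(8, 4),
    stringsAsFactors = FALSE
  )
  zones <- data.frame(
    site_name = c("alpha", "alpha", "beta"),
    use_type = c("extensive", "intensive", "extensive"),
    class_label = c(1L, 1L, 1L),
    area_m2 = c(500000, 30000, 125000),
    space_per_visitor_m2 = c(2500, 1500, 2500),
    stringsAsFactors = FALSE
  )
  climate <- data.frame(
    site_name = rep(c("alpha", "beta"), each = 2),
    station_name = "station", elevation_m = 1500,
    latitude = 35, longitude = 52,
    code = c("Cf1", "Cf5", "Cf1", "Cf5"),
    magnitude = c(10, 73, 0, 146),
    unit = "days", total_mt = 365,
    stringsAsFactors = FALSE
  )
  management <- data.frame(
    site_name = c("alpha", "beta"), imc = c(10L, 2L), emc = c(4L, 2L),
    stringsAsFactors = FALSE
  )
  list(sites = sites, zones = zones, climate = climate,
       management = management)
}

write_tiny_dataset <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ds <- tiny_dataset()
  for (schema in names(ds)) {
    write_site_dataset(ds[[schema]], file.path(dir, paste0(schema, ".tsv")),
                       schema)
  }
  dir
}

# Independent oracle for multiplicative RCC: apply one factor at a time at
# full precision, round once at the very end.
rcc_sequential_oracle <- function(pcc, percents, final = floor) {
  x <- pcc
  for (p in percents) x <- x * (100 - p) / 100
  max(final(x), 0)
}

# Independent oracle for the expected Likert score of the latent-Gaussian
# generator (direct CDF arithmetic, no package code).
likert_expectation_oracle <- function(mu, sd, cuts = c(1.5, 2.5, 3.5, 4.5)) {
  p <- c(
    pnorm(cuts[1], mu, sd),
    pnorm(cuts[2], mu, sd) - pnorm(cuts[1], mu, sd),
    pnorm(cuts[3], mu, sd) - pnorm(cuts[2], mu, sd),
    pnorm(cuts[4], mu, sd) - pnorm(cuts[3], mu, sd),
    1 - pnorm(cuts[4], mu, sd)
  )
  sum(1:5 * p)
}
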