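# Seeded generators for synthetic site datasets and Delphi expert panels.
#
# Sub-seeding rule: artifact i under master seed s uses the stream seeded
# with (s * 1009 + i) mod 2^31 - 1, so adding a site (or panel round) never
# perturbs the draws of earlier artifacts.

sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
}

with_sub_seed <- function(seed, i, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, i))
  expr
}

#' Configuration for the synthetic site-dataset generator
#'
#' Defaults describe a realistic mid-latitude protected-area system:
#' site areas from a few thousand to ~80,000 ha; a small fraction of each
#' site zoned for recreation (extensive classes larger than intensive
#' ones, with the 2500 / 1500 m2 per-visitor standards); climatic
#' limiting-day counts with intensities comparable to the synoptic-station
#' records of the worked dataset; operating seasons of roughly 110, 155 or
#' 365 days; guardian staffing near the one-per-1000-ha standard with the
#' existing capacity covering 20-60% of the ideal.
#'
#' @param seed master seed (integer).
#' @param n_sites number of sites.
#' @param area_range_ha length-2 interval of total site areas (ha).
#' @param zone_classes data frame with columns `use_type`, `class_label`,
#'   `frac_min`, `frac_max` (area fraction of the site), and
#'   `space_per_visitor_m2`.
#' @param climate_day_means named numeric vector: expected limiting days
#'   per variable code (Poisson intensities, truncated at 365).
#' @param operating_days_choices integer vector sampled per site.
#' @param guardians_per_1000ha_range interval for realized staffing density.
#' @param emc_fraction_range interval in `[0, 1]`: existing capacity as a
#'   fraction of the ideal.
#' @return list of class `site_gen_config`.
#' @export
site_gen_config <- function(seed = 1L,
                            n_sites = 3L,
                            area_range_ha = c(3000, 80000),
                            zone_classes = data.frame(
                              use_type = c("extensive", "extensive",
                                           "intensive", "intensive"),
                              class_label = c(1L, 2L, 1L, 2L),
                              frac_min = c(0.004, 0.004, 0.0001, 0.0001),
                              frac_max = c(0.015, 0.015, 0.0005, 0.0005),
                              space_per_visitor_m2 = c(2500, 2500, 1500, 1500),
                              stringsAsFactors = FALSE
                            ),
                            climate_day_means = c(Cf1 = 15, Cf2 = 7, Cf3 = 6,
                                                  Cf4 = 16, Cf5 = 105, Cf6 = 3,
                                                  Cf8 = 38),
                            operating_days_choices = c(109L, 155L, 365L),
                            guardians_per_1000ha_range = c(0.3, 1.2),
                            emc_fraction_range = c(0.2, 0.6)) {
  stopifnot(is_count(n_sites) || n_sites >= 1,
            length(area_range_ha) == 2, area_range_ha[1] <= area_range_ha[2],
            all(zone_classes$frac_min <= zone_classes$frac_max),
            all(zone_classes$frac_min >= 0),
            length(emc_fraction_range) == 2,
            all(emc_fraction_range >= 0 & emc_fraction_range <= 1))
  if (sum(zone_classes$frac_max) > 1) {
    stop_domain("zone area fractions may sum past 1; shrink frac_max")
  }
  structure(
    list(seed = as.integer(seed), n_sites = as.integer(n_sites),
         area_range_ha = area_range_ha, zone_classes = zone_classes,
         climate_day_means = climate_day_means,
         operating_days_choices = as.integer(operating_days_choices),
         guardians_per_1000ha_range = guardians_per_1000ha_range,
         emc_fraction_range = emc_fraction_range),
    class = "site_gen_config"
  )
}

#' Generate a synthetic site dataset
#'
#' Deterministic given the config's seed; every record satisfies the data
#' model's invariants with no post-hoc clipping (climate day counts are
#' drawn truncated at 365). The ideal management capacity follows the
#' one-guardian-per-1000-ha rule; the existing capacity is a drawn fraction
#' of it.
#'
#' @param config a [site_gen_config()].
#' @return named list of data frames: `sites`, `zones`, `climate`,
#'   `management` — the schemas consumed by [load_site_dataset()] /
#'   [validate_dataset()].
#' @export
generate_site_dataset <- function(config) {
  stopifnot(inherits(config, "site_gen_config"))
  sites <- zones <- climate <- management <- list()
  for (i in seq_len(config$n_sites)) {
    rec <- with_sub_seed(config$seed, i, {
      area_ha <- stats::runif(1, config$area_range_ha[1], config$area_range_ha[2])
      area_ha <- round(area_ha)
      operating <- sample(config$operating_days_choices, 1)
      dens <- stats::runif(1, config$guardians_per_1000ha_range[1],
                           config$guardians_per_1000ha_range[2])
      guardians <- max(round(dens * area_ha / 1000), 0)
      name <- sprintf("site%02d", i)
      zc <- config$zone_classes
      fr <- stats::runif(nrow(zc), zc$frac_min, zc$frac_max)
      zone_area_m2 <- round(fr * area_ha * M2_PER_HA)
      day_counts <- vapply(config$climate_day_means, function(mu) {
        min(stats::rpois(1, mu), 365)
      }, numeric(1))
      imc <- ideal_management_capacity(area_ha, 1000)
      emc_frac <- stats::runif(1, config$emc_fraction_range[1],
                               config$emc_fraction_range[2])
      emc <- min(round(emc_frac * imc), imc)
      list(
        site = data.frame(
          name = name, total_area_ha = area_ha,
          established_year = sample(1960:2015, 1),
          guardians_count = guardians,
          guard_stations = max(1, round(guardians / 4)),
          reported_annual_visitors = round(stats::runif(1, 10000, 300000)),
          operating_days = operating, availability_hours = 8,
          average_visit_hours = 8, stringsAsFactors = FALSE
        ),
        zones = data.frame(
          site_name = name, use_type = zc$use_type,
          class_label = zc$class_label, area_m2 = zone_area_m2,
          space_per_visitor_m2 = zc$space_per_visitor_m2,
          stringsAsFactors = FALSE
        ),
        climate = data.frame(
          site_name = name, station_name = paste0(name, " synoptic"),
          elevation_m = round(stats::runif(1, 900, 2600)),
          latitude = round(stats::runif(1, 30, 40), 4),
          longitude = round(stats::runif(1, 45, 60), 4),
          code = names(config$climate_day_means),
          magnitude = day_counts, unit = "days", total_mt = 365,
          stringsAsFactors = FALSE
        ),
        management = data.frame(
          site_name = name, imc = imc, emc = emc, stringsAsFactors = FALSE
        )
      )
    })
    sites[[i]] <- rec$site
    zones[[i]] <- rec$zones
    climate[[i]] <- rec$climate
    management[[i]] <- rec$management
  }
  out <- list(
    sites = validate_sites_df(do.call(rbind, sites)),
    zones = validate_zones_df(do.call(rbind, zones)),
    climate = validate_climate_df(do.call(rbind, climate)),
    management = validate_management_df(do.call(rbind, management))
  )
  rownames(out$sites) <- rownames(out$zones) <- NULL
  rownames(out$climate) <- rownames(out$management) <- NULL
  out
}

#' Configuration for the synthetic Delphi-panel generator
#'
#' Defaults mirror the structure of the expert survey the package's worked
#' dataset comes from: 38 experts over three rounds with nested attrition
#' of 0 / 3 / 2, and 40 items split across the three impact dimensions
#' (21 + 9 + 10 at round 1) with 2, 1 and 1 items retired after rounds
#' 1-3 respectively. Responses discretize a latent Gaussian score onto
#' 1..5 at the fixed cut-points 1.5, 2.5, 3.5, 4.5, clamping at the ends.
#'
#' @param seed master seed.
#' @param n_experts panel size at round 1.
#' @param dimension_items named integer vector: items per dimension.
#' @param latent_item_means numeric vector in `[1, 5]`, one per item
#'   (default: evenly spread over `[2.4, 4.4]` within each dimension).
#' @param dispersion standard deviation of the latent noise (default 1).
#' @param dropout_per_round integer vector: experts newly lost at each
#'   round (nested across rounds).
#' @param removals_per_round integer vector: items retired at the end of
#'   each round (the lowest-mean retained items are retired).
#' @param rounds number of rounds.
#' @param cutpoints increasing numeric vector of 4 discretization
#'   thresholds.
#' @return list of class `panel_gen_config`.
#' @export
panel_gen_config <- function(seed = 1L, n_experts = 38L,
                             dimension_items = c("environmental-physical" = 21L,
                                                 "socio-cultural" = 9L,
                                                 "economic-institutional" = 10L),
                             latent_item_means = NULL,
                             dispersion = 1,
                             dropout_per_round = c(0L, 3L, 2L),
                             removals_per_round = c(2L, 1L, 1L),
                             rounds = 3L,
                             cutpoints = c(1.5, 2.5, 3.5, 4.5)) {
  n_items <- sum(dimension_items)
  if (is.null(latent_item_means)) {
    latent_item_means <- unlist(lapply(dimension_items, function(k) {
      seq(2.4, 4.4, length.out = k)
    }), use.names = FALSE)
  }
  stopifnot(length(latent_item_means) == n_items,
            all(latent_item_means >= 1 & latent_item_means <= 5),
            dispersion > 0,
            length(cutpoints) == 4, !is.unsorted(cutpoints, strictly = TRUE),
            length(dropout_per_round) == rounds,
            length(removals_per_round) == rounds)
  if (sum(dropout_per_round) >= n_experts) {
    stop_domain("total dropout must be smaller than the panel")
  }
  if (sum(removals_per_round) >= n_items) {
    stop_domain("total removals must leave at least one item")
  }
  structure(
    list(seed = as.integer(seed), n_experts = as.integer(n_experts),
         dimension_items = dimension_items,
         latent_item_means = latent_item_means, dispersion = dispersion,
         dropout_per_round = as.integer(dropout_per_round),
         removals_per_round = as.integer(removals_per_round),
         rounds = as.integer(rounds), cutpoints = cutpoints),
    class = "panel_gen_config"
  )
}

# Discretize latent scores onto 1..5 by the fixed cut-points (clamped).
# Preserves dim/dimnames of matrix input.
discretize_likert <- function(latent, cutpoints) {
  out <- latent
  out[] <- 1 + findInterval(latent, cutpoints)
  out
}

#' Expected Likert score of the latent-Gaussian generator
#'
#' Closed-form expectation of the discretized response for a given latent
#' mean: `sum_k k P(score = k)` with the category probabilities from the
#' Gaussian CDF at the cut-points. Useful as an oracle when checking that
#' aggregated means recover the generator's parameters.
#'
#' @param mu latent mean (vectorized).
#' @param dispersion latent standard deviation.
#' @param cutpoints the 4 discretization thresholds.
#' @return expected score in `[1, 5]`.
#' @export
likert_expectation <- function(mu, dispersion = 1,
                               cutpoints = c(1.5, 2.5, 3.5, 4.5)) {
  vapply(mu, function(m) {
    p_le <- stats::pnorm(cutpoints, mean = m, sd = dispersion)
    probs <- diff(c(0, p_le, 1))
    sum(seq_len(5) * probs)
  }, numeric(1))
}

#' Generate a synthetic Delphi panel
#'
#' Draws one response matrix per round from the latent-Gaussian model,
#' with nested expert attrition (experts lost in round r stay lost) and
#' per-round item retirement (the lowest-latent-mean retained items are
#' retired, emulating a panel dropping the least influential impacts).
#' Deterministic given the config's seed; each round uses its own
#' sub-seeded stream.
#'
#' @param config a [panel_gen_config()].
#' @return named list: `items` (round-1 item table), `matrices` (list of
#'   [response_matrix()]), `plans` (list of [round_plan()]),
#'   `latent_means` (named by item id).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_gen_config"))
  dims <- rep(names(config$dimension_items), config$dimension_items)
  n_items <- length(dims)
  item_ids <- sprintf("item%02d", seq_len(n_items))
  items <- likert_items(item_ids, dims)
  mu <- stats::setNames(config$latent_item_means, item_ids)
  experts <- sprintf("expert%02d", seq_len(config$n_experts))

  # nested attrition: draw each round's newly lost experts from survivors
  lost <- character()
  nonresp_by_round <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    newly <- with_sub_seed(config$seed, 10000 + r, {
      sample(setdiff(experts, lost), config$dropout_per_round[r])
    })
    lost <- c(lost, newly)
    nonresp_by_round[[r]] <- lost
  }

  matrices <- vector("list", config$rounds)
  plans <- vector("list", config$rounds)
  retained <- item_ids
  for (r in seq_len(config$rounds)) {
    scores <- with_sub_seed(config$seed, 20000 + r, {
      latent <- matrix(
        stats::rnorm(config$n_experts * length(retained),
                     mean = rep(mu[retained], each = config$n_experts),
                     sd = config$dispersion),
        nrow = config$n_experts,
        dimnames = list(experts, retained)
      )
      discretize_likert(latent, config$cutpoints)
    })
    responders <- setdiff(experts, nonresp_by_round[[r]])
    matrices[[r]] <- response_matrix(r, scores[responders, , drop = FALSE])
    k <- config$removals_per_round[r]
    removed <- if (k > 0) {
      retained[order(mu[retained])][seq_len(k)]
    } else character()
    plans[[r]] <- round_plan(r, removed_item_ids = removed,
                             nonrespondent_expert_ids = character())
    retained <- setdiff(retained, removed)
  }
  list(items = items, matrices = matrices, plans = plans, latent_means = mu)
}
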