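# Multi-round Delphi aggregation of five-point Likert questionnaires.
#
# Responses are held as an experts x items integer matrix per round; items
# carry a dimension (environmental-physical, socio-cultural,
# economic-institutional, or any user-defined grouping). Aggregation is
# mean / sample SD / sample variance per item, competition ranking within
# each dimension, and an equally weighted dimension mean.

#' Likert item table constructor
#'
#' @param item_id character vector of unique item identifiers.
#' @param dimension character vector (recycled) naming each item's
#'   dimension.
#' @param label optional descriptive labels (default `item_id`).
#' @return data frame with columns `item_id`, `dimension`, `label`.
#' @export
likert_items <- function(item_id, dimension, label = item_id) {
  stopifnot(length(item_id) >= 1)
  if (anyDuplicated(item_id)) stop_domain("item_id values must be unique")
  data.frame(item_id = as.character(item_id),
             dimension = rep_len(as.character(dimension), length(item_id)),
             label = rep_len(as.character(label), length(item_id)),
             stringsAsFactors = FALSE)
}

#' Response matrix for one Delphi round
#'
#' @param round_number integer >= 1.
#' @param scores numeric matrix, experts in rows (unique rownames) and
#'   items in columns (colnames); entries in `{1..5}` or `NA`.
#' @return list of class `response_matrix`.
#' @export
response_matrix <- function(round_number, scores) {
  stopifnot(is.matrix(scores))
  if (!is_count(round_number) || round_number < 1) {
    stop_domain("round_number must be an integer >= 1")
  }
  if (is.null(rownames(scores)) || anyDuplicated(rownames(scores))) {
    stop_domain("scores must have unique expert rownames")
  }
  if (is.null(colnames(scores))) stop_domain("scores must have item colnames")
  v <- scores[!is.na(scores)]
  if (length(v) && (any(v < 1 | v > 5) || any(v != floor(v)))) {
    stop_domain("responses must be integers in 1..5")
  }
  structure(list(round_number = round_number, responses = scores),
            class = "response_matrix")
}

#' Round plan: items removed and experts not responding
#'
#' The published analysis removes items between rounds "according to the
#' experts' opinions" rather than by a numeric rule, so removals are an
#' explicit list of ids; attrition likewise.
#'
#' @param round_number integer >= 1.
#' @param removed_item_ids character vector of items removed at the end of
#'   this round (excluded from subsequent rounds and from the final table).
#' @param nonrespondent_expert_ids character vector of experts who did not
#'   answer this round.
#' @return list of class `round_plan`.
#' @export
round_plan <- function(round_number, removed_item_ids = character(),
                       nonrespondent_expert_ids = character()) {
  structure(list(round_number = round_number,
                 removed_item_ids = as.character(removed_item_ids),
                 nonrespondent_expert_ids = as.character(nonrespondent_expert_ids)),
            class = "round_plan")
}

#' Per-item Likert summary statistics
#'
#' Mean, sample standard deviation and sample variance (n - 1 denominator)
#' of one item's scores.
#'
#' @param values numeric vector of scores in `{1..5}`; `NA` entries are
#'   dropped (pairwise deletion).
#' @return named list with `n`, `mean`, `sd`, `variance`.
#' @export
item_statistics <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop_domain("no responses for item")
  if (any(values < 1 | values > 5)) stop_domain("scores must be in 1..5")
  n <- length(values)
  m <- mean(values)
  v <- if (n > 1) stats::var(values) else 0
  list(n = n, mean = m, sd = sqrt(v), variance = v)
}

#' Dimension total mean
#'
#' Equally weighted arithmetic mean of the item means of one dimension
#' (items are not weighted by their respondent counts), rounded half-up.
#'
#' @param item_means numeric vector of per-item mean scores.
#' @param decimals decimals for the reported value (default 2).
#' @return the total mean.
#' @export
dimension_summary <- function(item_means, decimals = 2) {
  if (length(item_means) == 0) stop_domain("item_means must be non-empty")
  round_half_up(mean(item_means), decimals)
}

#' Rank items within a dimension
#'
#' Competition ranking by descending mean: rank 1 is the highest mean, tied
#' means share the smallest rank of their block and the next rank skips.
#' Input order breaks presentation ties (the rank values themselves are
#' unaffected by input order).
#'
#' @param summaries data frame with at least `item_id`, `dimension`,
#'   `mean`; all rows must share one dimension.
#' @return `summaries` with an integer `rank` column added, sorted by rank
#'   then input order.
#' @export
rank_items <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  if (length(unique(summaries$dimension)) != 1) {
    stop_domain("rank_items expects items from a single dimension")
  }
  summaries$rank <- as.integer(rank(-summaries$mean, ties.method = "min"))
  summaries[order(summaries$rank, seq_len(nrow(summaries))), , drop = FALSE]
}

#' Run one Delphi round
#'
#' Computes item and dimension summaries for the items currently in play,
#' excluding the round's nonrespondents, then applies the round's removals
#' to produce the item set for the next round.
#'
#' @param matrix a [response_matrix()].
#' @param items item table ([likert_items()]) of the items current in this
#'   round.
#' @param plan a [round_plan()] (default: no removals, full response).
#' @return list with `item_summaries` (data frame: item_id, dimension,
#'   label, n, mean, sd, variance, rank), `dimension_summaries` (data
#'   frame: dimension, n_items, total_mean), `retained_items` (item table
#'   for the next round), `n_respondents`.
#' @export
run_round <- function(matrix, items, plan = round_plan(matrix$round_number)) {
  stopifnot(inherits(matrix, "response_matrix"), is.data.frame(items))
  unknown <- setdiff(plan$removed_item_ids, items$item_id)
  if (length(unknown)) {
    stop_domain("plan removes unknown item(s): ", paste(unknown, collapse = ", "))
  }
  scores <- matrix$responses
  keep_experts <- setdiff(rownames(scores), plan$nonrespondent_expert_ids)
  scores <- scores[keep_experts, , drop = FALSE]
  current <- items[items$item_id %in% colnames(scores), , drop = FALSE]
  if (nrow(current) == 0) stop_domain("no current items present in the matrix")

  stats_rows <- lapply(seq_len(nrow(current)), function(i) {
    st <- item_statistics(scores[, current$item_id[i]])
    data.frame(item_id = current$item_id[i], dimension = current$dimension[i],
               label = current$label[i], n = st$n, mean = st$mean, sd = st$sd,
               variance = st$variance, stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, stats_rows)
  ranked <- do.call(rbind, lapply(
    split(summaries, factor(summaries$dimension, unique(summaries$dimension))),
    rank_items
  ))
  rownames(ranked) <- NULL

  dims <- unique(summaries$dimension)
  dim_summ <- data.frame(
    dimension = dims,
    n_items = vapply(dims, function(d) sum(summaries$dimension == d), integer(1)),
    total_mean = vapply(dims, function(d) {
      dimension_summary(summaries$mean[summaries$dimension == d])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  retained <- items[!items$item_id %in% plan$removed_item_ids, , drop = FALSE]
  list(item_summaries = ranked, dimension_summaries = dim_summ,
       retained_items = retained, n_respondents = length(keep_experts))
}

#' Run a multi-round Delphi analysis
#'
#' Applies [run_round()] to each round in order, threading the retained
#' item set from one round into the next, and builds the final prioritized
#' table from the last round's statistics restricted to the items that
#' survive the last round's removals.
#'
#' @param matrices list of [response_matrix()] objects with consecutive
#'   round numbers starting at 1.
#' @param items item table for round 1.
#' @param plans list of [round_plan()] objects, matched to rounds by
#'   `round_number`; rounds without a plan get an empty one.
#' @return list with `rounds` (per-round [run_round()] outputs) and
#'   `final_table` (data frame: dimension, item_id, label, n, mean, sd,
#'   variance, rank, total_mean — the dimension mean repeated on its first
#'   row, NA elsewhere).
#' @export
run_delphi <- function(matrices, items, plans = list()) {
  stopifnot(length(matrices) >= 1)
  rounds_nums <- vapply(matrices, function(m) m$round_number, numeric(1))
  if (!identical(as.integer(rounds_nums), seq_along(matrices))) {
    stop_domain("rounds must be numbered consecutively from 1")
  }
  plan_for <- function(k) {
    for (p in plans) if (p$round_number == k) return(p)
    round_plan(k)
  }
  current <- items
  out <- vector("list", length(matrices))
  for (k in seq_along(matrices)) {
    out[[k]] <- run_round(matrices[[k]], current, plan_for(k))
    current <- out[[k]]$retained_items
  }
  last <- out[[length(out)]]
  fin <- last$item_summaries
  fin <- fin[fin$item_id %in% current$item_id, , drop = FALSE]
  # re-rank after the last round's removals so ranks stay a dense 1..k
  fin <- do.call(rbind, lapply(
    split(fin[, setdiff(names(fin), "rank")],
          factor(fin$dimension, unique(fin$dimension))),
    rank_items
  ))
  rownames(fin) <- NULL
  fin$total_mean <- NA_real_
  for (d in unique(fin$dimension)) {
    idx <- which(fin$dimension == d)
    fin$total_mean[idx[1]] <- dimension_summary(fin$mean[idx])
  }
  fin <- fin[, c("dimension", "item_id", "label", "n", "mean", "sd",
                 "variance", "rank", "total_mean")]
  list(rounds = out, final_table = fin)
}

# ---- delimited-file interfaces ---------------------------------------------

#' Read a Likert items file
#'
#' Tab-delimited with header `item_id`, `dimension`, `label`.
#' @param path file path.
#' @return item table.
#' @export
read_items <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          fileEncoding = "UTF-8")
  need <- c("item_id", "dimension", "label")
  if (!all(need %in% names(df))) {
    stop_domain("items file must have columns: ", paste(need, collapse = ", "))
  }
  likert_items(df$item_id, df$dimension, df$label)
}

#' Read one round's responses from a long-format file
#'
#' Tab-delimited with header `expert_id`, `item_id`, `score`; one row per
#' (expert, item) response.
#'
#' @param path file path.
#' @param round_number round the file belongs to.
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, round_number) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          fileEncoding = "UTF-8")
  need <- c("expert_id", "item_id", "score")
  if (!all(need %in% names(df))) {
    stop_domain("responses file must have columns: ", paste(need, collapse = ", "))
  }
  experts <- unique(df$expert_id)
  item_ids <- unique(df$item_id)
  m <- matrix(NA_real_, length(experts), length(item_ids),
              dimnames = list(experts, item_ids))
  m[cbind(df$expert_id, df$item_id)] <- as.numeric(df$score)
  response_matrix(round_number, m)
}

#' Write one round's responses in long format
#'
#' @param matrix a [response_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(matrix, path) {
  scores <- matrix$responses
  df <- data.frame(
    expert_id = rep(rownames(scores), times = ncol(scores)),
    item_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$score), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plans file
#'
#' Tab-delimited with header `round`, `removed_item_ids`,
#' `nonrespondent_ids`; id lists are comma-separated, empty for none.
#'
#' @param path file path.
#' @return list of [round_plan()] objects.
#' @export
read_plans <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          fileEncoding = "UTF-8")
  need <- c("round", "removed_item_ids", "nonrespondent_ids")
  if (!all(need %in% names(df))) {
    stop_domain("plans file must have columns: ", paste(need, collapse = ", "))
  }
  split_ids <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ",")[[1]])
  }
  lapply(seq_len(nrow(df)), function(i) {
    round_plan(as.integer(df$round[i]), split_ids(df$removed_item_ids[i]),
               split_ids(df$nonrespondent_ids[i]))
  })
}

#' Published round-3 item means for the Tehran-province expert panel
#'
#' The per-item mean scores, respondent count and within-dimension ranks of
#' the final Delphi round for the worked dataset (36 items across the three
#' impact dimensions; raw responses were never published, so only the means
#' and ranks are available). Useful for checking dimension means and
#' competition ranking against published values.
#'
#' @return data frame with columns `dimension`, `item_id`, `label`, `n`,
#'   `mean`, `rank`.
#' @export
delphi_published_means <- function() {
  utils::read.delim(
    system.file("extdata", "delphi_published_means.tsv", package = "etcc",
                mustWork = TRUE),
    sep = "\t", fileEncoding = "UTF-8", stringsAsFactors = FALSE
  )
}
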