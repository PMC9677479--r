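topk_method <- function(x) attr(x, "method")
topk_percentile <- function(x) attr(x, "percentile")

# Stack a list of per-model top-K tables (or accept one long table), checking
# that percentile and normalization method agree across members.
bind_topk <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0L) {
    abort("At least one member table is required.", class = "kge_config_error")
  }
  methods <- unique(vapply(
    tables, function(x) topk_method(x) %||% NA_character_, character(1)
  ))
  percs <- unique(vapply(
    tables, function(x) topk_percentile(x) %||% NA_real_, double(1)
  ))
  if (length(methods) > 1L) {
    abort(
      sprintf(
        "Member tables mix normalization methods (%s); ensembles must share one.",
        paste(methods, collapse = ", ")
      ),
      class = "kge_config_error"
    )
  }
  if (length(percs) > 1L) {
    abort("Member tables mix percentile thresholds; ensembles must share one.",
      class = "kge_config_error"
    )
  }
  out <- bind_rows(lapply(tables, as_tibble))
  assert_columns(out, c("model", "drug", "disease", "normalized"), "tables")
  structure(out, method = methods, percentile = percs)
}

finish_ranking <- function(scored, config) {
  out <- scored %>%
    arrange(
      desc(.data$score), desc(.data$n_models),
      .data$drug, .data$disease
    ) %>%
    mutate(rank = row_number()) %>%
    select("rank", "drug", "disease", "score", "n_models")
  structure(out,
    class = c("kge_ranking", class(out)),
    config = config
  )
}

#' Aggregate normalized per-model scores into an ensemble ranking
#'
#' Every pair appearing in at least one member's top-K list receives an
#' ensemble score; a pair absent from a member's list contributes 0 for that
#' member. Aggregations:
#'
#' * `sum` — \eqn{\sum_m s_m}; frequently occurring pairs accumulate support,
#'   so agreement across models is rewarded.
#' * `avg_zero` — \eqn{\sum_m s_m / M} with \eqn{M} the ensemble size
#'   (absence counts as a zero in the numerator); identical ordering to
#'   `sum`.
#' * `avg_present` — \eqn{\sum_m s_m / |\{m : present\}|}; averages only over
#'   the members that retained the pair, so a pair strongly scored by one
#'   model is not diluted by the others' absence.
#'
#' Ties are broken by `(score desc, n_models desc, drug asc, disease asc)`.
#'
#' @param tables A list of normalized top-K tables from [normalize_scores()]
#'   (or one long table stacking them). Members must share the percentile and
#'   normalization method; mixtures are rejected.
#' @param aggregation `"sum"`, `"avg_zero"` or `"avg_present"`.
#' @return A `kge_ranking` tibble: `rank`, `drug`, `disease`, `score`,
#'   `n_models` (supporting members), with the ensemble configuration in the
#'   `config` attribute.
#' @export
ensemble_rank <- function(tables, aggregation = c("sum", "avg_zero", "avg_present")) {
  aggregation <- match.arg(aggregation)
  long <- bind_topk(tables)
  m_total <- dplyr::n_distinct(long$model)
  scored <- long %>%
    group_by(.data$drug, .data$disease) %>%
    summarise(
      total = sum(.data$normalized),
      n_models = n(),
      .groups = "drop"
    ) %>%
    mutate(score = switch(aggregation,
      sum = .data$total,
      avg_zero = .data$total / m_total,
      avg_present = .data$total / .data$n_models
    )) %>%
    select(-"total")
  finish_ranking(scored, list(
    members = sort(unique(long$model)),
    aggregation = aggregation,
    normalization = attr(long, "method"),
    percentile = attr(long, "percentile")
  ))
}

#' Product-of-experts ensemble over full score tables
#'
#' Rather than thresholding, each model's entire score distribution over the
#' candidate space is turned into a probability distribution by a softmax,
#' and candidates are ranked by the sum of log-probabilities across models
#' (monotone-equivalent to the product of the experts' probabilities). A
#' candidate scored very low by any single model is effectively vetoed.
#'
#' @param tables A list of full score tables (`model`, `drug`, `disease`,
#'   `score`) or one long table. All models must cover exactly the same
#'   candidate pairs.
#' @return A `kge_ranking` tibble over the whole candidate space; `score` is
#'   the summed log-probability and `n_models` the ensemble size.
#' @export
product_of_experts <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  long <- bind_rows(lapply(tables, as_score_table))
  models <- unique(long$model)
  keysets <- split(paste(long$drug, long$disease, sep = "\r"), long$model)
  ref <- sort(keysets[[1]])
  for (m in models[-1]) {
    other <- sort(keysets[[m]])
    if (!identical(ref, other)) {
      sym <- length(union(ref, other)) - length(intersect(ref, other))
      abort(
        sprintf(
          "Candidate spaces differ between models '%s' and '%s' (symmetric difference: %d pairs).",
          models[1], m, sym
        ),
        class = "kge_config_error"
      )
    }
  }
  scored <- long %>%
    group_by(.data$model) %>%
    mutate(logp = {
      s <- .data$score - max(.data$score)
      s - log(sum(exp(s)))
    }) %>%
    ungroup() %>%
    group_by(.data$drug, .data$disease) %>%
    summarise(score = sum(.data$logp), n_models = n(), .groups = "drop")
  finish_ranking(scored, list(
    members = sort(models), aggregation = "poe",
    normalization = "softmax_full", percentile = NA_real_
  ))
}

#' Position-based ensemble (sum over rank-normalized scores)
#'
#' Prioritizes pairs by their ranked positions in each member's top-K list
#' rather than by score magnitudes: members must be rank-normalized top-K
#' tables, and their uniformly spaced position scores are sum-aggregated.
#'
#' @param tables Normalized top-K tables built with
#'   `normalize_scores(method = "rank")`.
#' @return A `kge_ranking` tibble, as [ensemble_rank()].
#' @export
position_ensemble <- function(tables) {
  long <- bind_topk(tables)
  if (!identical(attr(long, "method"), "rank")) {
    abort("`position_ensemble()` requires rank-normalized member tables.",
      class = "kge_config_error"
    )
  }
  ensemble_rank(long, aggregation = "sum")
}

#' Select the best member models by validation Precision@100
#'
#' Ensembles can be built from every available model (`ensemble-all`) or from
#' the few best ones; this picks the `n` models with the highest
#' Precision@100 on the validation set, breaking ties by model id (ascending).
#'
#' @param reports A long evaluation tibble (`subject`, `k`, `precision`) as
#'   produced by stacking [precision_at_k()] results, or a list of such
#'   reports; each subject must carry a `k == k` row.
#' @param n Number of models to select (default 5).
#' @param k The K at which validation precision is compared (default 100).
#' @return Character vector of the selected model ids, best first.
#' @export
select_top_models <- function(reports, n = 5L, k = 100L) {
  if (is.list(reports) && !is.data.frame(reports)) reports <- bind_rows(reports)
  assert_columns(reports, c("subject", "k", "precision"), "reports")
  at100 <- filter(reports, .data$k == !!k)
  missing <- setdiff(unique(reports$subject), at100$subject)
  if (length(missing) > 0L) {
    abort(
      sprintf(
        "Precision@%d missing for model(s): %s.",
        k, paste(missing, collapse = ", ")
      ),
      class = "kge_data_error"
    )
  }
  if (n > nrow(at100)) {
    abort("`n` exceeds the number of models with reports.", class = "kge_config_error")
  }
  at100 %>%
    arrange(desc(.data$precision), .data$subject) %>%
    slice(seq_len(n)) %>%
    pull("subject")
}

#' @export
print.kge_ranking <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<ensemble ranking> %d pairs, aggregation: %s, normalization: %s, %d member model(s)\n",
    nrow(x), cfg$aggregation, cfg$normalization, length(cfg$members)
  ))
  print(as_tibble(utils::head(as.data.frame(x), 10)))
  invisible(x)
}

#' Write / read an ensemble ranking as TSV with a JSON config sidecar
#'
#' @param ranking A `kge_ranking`.
#' @param path Output TSV path (`rank`, `drug`, `disease`, `score`,
#'   `n_models`); the configuration is echoed to `<path>.json`.
#' @return `ranking`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "kge_ranking"))
  readr::write_tsv(as_tibble(ranking), path, progress = FALSE)
  cfg <- attr(ranking, "config")
  jsonlite::write_json(cfg, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(ranking)
}
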