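#' Retain each model's top percentile of predictions
#'
#' Different embedding models produce score distributions lying in different
#' intervals and with different shapes, so scores are made comparable by
#' keeping only each model's most confident fraction and normalizing within
#' it. With \eqn{N} scored pairs and percentile \eqn{p} (e.g. 99 keeps the
#' top 1\%), exactly \eqn{k = \lfloor N (100 - p)/100 \rfloor} pairs with the
#' highest raw scores are retained. Ties at the boundary are broken
#' deterministically by `(score desc, drug asc, disease asc)`.
#'
#' @param scores A score table (`model`, `drug`, `disease`, `score`); several
#'   models may be stacked in one table, each is thresholded independently.
#'   A table without a `model` column is treated as a single anonymous model.
#' @param percentile Real in `(0, 100)`; e.g. `99` keeps the top 1%, `95` the
#'   top 5%.
#' @return A `kge_topk` tibble `model`, `drug`, `disease`, `score`, `rank`
#'   (1 = best within model) carrying the `percentile` attribute.
#' @examples
#' tab <- tibble::tibble(
#'   model = "m", drug = "d1", disease = paste0("x", 1:100),
#'   score = rnorm(100)
#' )
#' nrow(threshold_top_percentile(tab, 95)) # 5
#' @export
threshold_top_percentile <- function(scores, percentile) {
  scores <- as_score_table(scores)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
    percentile <= 0 || percentile >= 100) {
    abort("`percentile` must be a single number strictly between 0 and 100.",
      class = "kge_config_error"
    )
  }
  frac <- (100 - percentile) / 100
  out <- scores %>%
    group_by(.data$model) %>%
    arrange(desc(.data$score), .data$drug, .data$disease, .by_group = TRUE) %>%
    mutate(.n = n(), .k = floor(.data$.n * frac), rank = row_number()) %>%
    ungroup()
  if (any(out$.k < 1L)) {
    small <- unique(out$model[out$.k < 1L])
    abort(
      sprintf(
        "Percentile %s retains zero pairs for model(s) %s; use a lower percentile.",
        format(percentile), paste(small, collapse = ", ")
      ),
      class = "kge_threshold_error"
    )
  }
  out <- select(filter(out, .data$rank <= .data$.k), -".n", -".k")
  structure(out, class = c("kge_topk", class(out)), percentile = percentile)
}

as_score_table <- function(scores) {
  if (!is.data.frame(scores)) {
    abort("`scores` must be a data frame score table.", class = "kge_type_error")
  }
  scores <- as_tibble(scores)
  if (!"model" %in% names(scores)) scores$model <- "model"
  assert_columns(scores, c("model", "drug", "disease", "score"), "scores")
  assert_finite_scores(scores$score)
  if (anyDuplicated(scores[, c("model", "drug", "disease")])) {
    abort("Duplicate (model, drug, disease) keys in the score table.",
      class = "kge_data_error"
    )
  }
  scores
}

#' Normalize retained top-K scores onto \[0, 1\]
#'
#' Applied within each model's retained top-K set (never on the full score
#' distribution), so that per-model confidence scales become comparable:
#'
#' * `minmax` — affine map \eqn{x \mapsto (x - min)/(max - min)}; preserves
#'   relative distances between scores. A degenerate all-equal set maps to
#'   0.5.
#' * `sigmoid` — z-standardize within the retained set (population standard
#'   deviation) then apply the logistic \eqn{1/(1 + e^{-z})}; compresses the
#'   extremes into an S-shape. Zero spread degenerates to 0.5 with a warning.
#' * `rank` — min-max applied to the rank rather than the score: the best
#'   pair maps to 1, the worst to 0, with uniform spacing \eqn{1/(k-1)}.
#'   A single retained pair maps to 1 with a warning.
#'
#' All three are monotone: the ordering of normalized values equals the
#' ordering of the raw scores on the retained set.
#'
#' @param topk A [threshold_top_percentile()] result (or any tibble with
#'   `model`, `drug`, `disease`, `score`, `rank`).
#' @param method `"minmax"`, `"sigmoid"` or `"rank"`.
#' @return A `kge_topk` tibble with an added `normalized` column in `[0, 1]`,
#'   carrying `percentile` and `method` attributes.
#' @export
normalize_scores <- function(topk, method = c("minmax", "sigmoid", "rank")) {
  method <- match.arg(method)
  assert_columns(topk, c("model", "drug", "disease", "score", "rank"), "topk")
  percentile <- attr(topk, "percentile")
  fun <- switch(method,
    minmax = normalize_minmax,
    sigmoid = normalize_sigmoid,
    rank = normalize_rank
  )
  out <- topk %>%
    as_tibble() %>%
    group_by(.data$model) %>%
    arrange(.data$rank, .by_group = TRUE) %>%
    mutate(normalized = fun(.data$score)) %>%
    ungroup()
  structure(out,
    class = c("kge_topk", class(as_tibble(out))),
    percentile = percentile, method = method
  )
}

normalize_minmax <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    inform("All retained scores are equal; min-max normalization maps them to 0.5.")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

normalize_sigmoid <- function(x) {
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2)) # population sd within the retained set
  if (sigma == 0) {
    warn("Zero spread among retained scores; sigmoid normalization degenerates to 0.5.")
    return(rep(0.5, length(x)))
  }
  1 / (1 + exp(-(x - mu) / sigma))
}

normalize_rank <- function(x) {
  k <- length(x)
  if (k == 1L) {
    warn("A single retained pair; rank normalization maps it to 1.")
    return(1)
  }
  # x arrives sorted best-first (rank order)
  (k - seq_len(k)) / (k - 1)
}
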