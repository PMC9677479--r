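# Coerce rankings or raw score tables to an ordered (drug, disease) list.
ranked_pairs <- function(ranking) {
  if (inherits(ranking, "kge_ranking")) {
    return(as_tibble(ranking)[, c("drug", "disease")])
  }
  assert_columns(ranking, c("drug", "disease"), "ranking")
  ranking <- as_tibble(ranking)
  if ("rank" %in% names(ranking)) {
    return(arrange(ranking, .data$rank)[, c("drug", "disease")])
  }
  if ("score" %in% names(ranking)) {
    return(
      arrange(ranking, desc(.data$score), .data$drug, .data$disease)[, c("drug", "disease")]
    )
  }
  abort("`ranking` needs a `rank` or `score` column to define an ordering.",
    class = "kge_type_error"
  )
}

test_key <- function(df) paste(df$drug, df$disease, sep = "\r")

#' Precision@K of a ranking against held-out test positives
#'
#' Precision@K is the fraction of the top K ranked drug-disease pairs that
#' are present in the held-out test set — the quantity that matters when only
#' a handful of top predictions can be experimentally validated. This is
#' distinct from Hits@K, which measures where known triples rank among
#' corrupted alternatives; no Hits@K is computed anywhere in this package.
#'
#' @param ranking A `kge_ranking`, or any tibble with `drug`, `disease` and a
#'   `rank` or `score` column (raw per-model score tables work directly).
#' @param test Tibble of held-out positive pairs (`drug`, `disease`); a
#'   triple table with `head`/`tail` columns is also accepted.
#' @param k_values Integer K values; defaults to
#'   `c(1, 5, 10, 25, 50, 100, 250, 500)` clipped to none — a K exceeding the
#'   ranking length is an error, not a silent truncation.
#' @param subject Label for the evaluated ranking (defaults to the ensemble
#'   members or `"ranking"`).
#' @return A `kge_eval` tibble: `subject`, `k`, `tp`, `precision`.
#' @export
precision_at_k <- function(ranking, test,
                           k_values = c(1L, 5L, 10L, 25L, 50L, 100L, 250L, 500L),
                           subject = NULL) {
  pairs <- ranked_pairs(ranking)
  test <- as_test_set(test)
  if (nrow(test) == 0L) {
    abort("The test set is empty.", class = "kge_data_error")
  }
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 1L)) {
    abort("K values must be >= 1.", class = "kge_config_error")
  }
  if (max(k_values) > nrow(pairs)) {
    abort(
      sprintf(
        "K = %d exceeds the ranking length (%d).", max(k_values), nrow(pairs)
      ),
      class = "kge_eval_error"
    )
  }
  if (is.null(subject)) {
    cfg <- attr(ranking, "config")
    subject <- if (!is.null(cfg)) {
      paste0("ensemble_", cfg$aggregation)
    } else if ("model" %in% names(ranking)) {
      paste(unique(ranking$model), collapse = "+")
    } else {
      "ranking"
    }
  }
  hit <- test_key(pairs) %in% test_key(test)
  cum_tp <- cumsum(hit)
  out <- tibble(
    subject = subject,
    k = k_values,
    tp = cum_tp[k_values],
    precision = cum_tp[k_values] / k_values
  )
  structure(out, class = c("kge_eval", class(out)))
}

as_test_set <- function(test) {
  if (is.data.frame(test) && all(c("head", "tail") %in% names(test))) {
    test <- tibble(drug = test$head, disease = test$tail)
  }
  assert_columns(test, c("drug", "disease"), "test")
  distinct(as_tibble(test)[, c("drug", "disease")])
}

#' Pairwise top-K agreement between models, split into true and false positives
#'
#' For every pair of models, the top-K predictions are partitioned into true
#' positives (pairs present in the test set) and false positives, and the
#' size of the intersection is computed within each partition. Models tend to
#' agree far more on correctly prioritized pairs than on spurious ones, which
#' is the signal sum-aggregating ensembles exploit.
#'
#' @param rankings Named list of rankings/score tables, or one long score
#'   table with a `model` column.
#' @param test Held-out positive pairs, as in [precision_at_k()].
#' @param k Top-list size (every ranking must have at least `k` entries).
#' @return A `kge_agreement` object: list with `k` and symmetric integer
#'   matrices `tp` and `fp` (diagonals: each model's own TP / FP count at K).
#' @export
pairwise_overlap <- function(rankings, test, k) {
  if (is.data.frame(rankings)) {
    assert_columns(rankings, c("model"), "rankings")
    rankings <- split(as_tibble(rankings), rankings$model)
  }
  if (is.null(names(rankings)) || any(!nzchar(names(rankings)))) {
    names(rankings) <- paste0("model_", seq_along(rankings))
  }
  test <- as_test_set(test)
  tkeys <- test_key(test)
  tops <- lapply(rankings, function(rk) {
    pairs <- ranked_pairs(rk)
    if (nrow(pairs) < k) {
      abort(
        sprintf("A ranking has only %d entries; k = %d requested.", nrow(pairs), k),
        class = "kge_eval_error"
      )
    }
    keys <- test_key(pairs[seq_len(k), ])
    list(tp = keys[keys %in% tkeys], fp = keys[!keys %in% tkeys])
  })
  m <- length(tops)
  ids <- names(tops)
  tp <- matrix(0L, m, m, dimnames = list(ids, ids))
  fp <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in seq_len(i)) {
      tp[i, j] <- tp[j, i] <- length(intersect(tops[[i]]$tp, tops[[j]]$tp))
      fp[i, j] <- fp[j, i] <- length(intersect(tops[[i]]$fp, tops[[j]]$fp))
    }
  }
  structure(list(k = as.integer(k), tp = tp, fp = fp), class = "kge_agreement")
}

#' @export
print.kge_agreement <- function(x, ...) {
  off <- upper.tri(x$tp)
  cat(sprintf(
    "<agreement at k = %d> %d models; mean pairwise overlap TP: %.2f, FP: %.2f\n",
    x$k, nrow(x$tp),
    if (any(off)) mean(x$tp[off]) else NA_real_,
    if (any(off)) mean(x$fp[off]) else NA_real_
  ))
  invisible(x)
}

#' Write an agreement matrix pair as two TSV files
#'
#' @param agreement A [pairwise_overlap()] result.
#' @param tp_path,fp_path Output paths for the true-positive and
#'   false-positive overlap matrices (model ids as header and first column).
#' @return `agreement`, invisibly.
#' @export
write_agreement <- function(agreement, tp_path, fp_path) {
  stopifnot(inherits(agreement, "kge_agreement"))
  write_mat <- function(m, path) {
    df <- as_tibble(as.data.frame(m), rownames = "model")
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_mat(agreement$tp, tp_path)
  write_mat(agreement$fp, fp_path)
  invisible(agreement)
}

#' Correlation between predicted score and node degree
#'
#' Embedding models are known to favour high-degree entities; this measures
#' how strongly a ranking's scores track the combined degree
#' `deg(drug) + deg(disease)` of each pair, with degrees counted on the
#' training graph (each triple contributes one to both endpoints). Pearson by
#' default; Spearman by flag.
#'
#' @param ranking A `kge_ranking` or score table (needs a `score` column).
#' @param graph A [kg_new()] object or a `kg_split` (degrees then come from
#'   `$train`).
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `estimate`, `n`, `method`, `undefined`. With
#'   zero variance in either variable the correlation is undefined:
#'   `undefined` is `TRUE` and `estimate` is `NA`.
#' @export
degree_correlation <- function(ranking, graph, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_columns(ranking, c("drug", "disease", "score"), "ranking")
  if (inherits(graph, "kg_split")) {
    triples <- graph$train
    universe <- graph$entity_types$entity
  } else if (inherits(graph, "kg")) {
    triples <- graph$triples
    universe <- graph$entity_types$entity
  } else {
    assert_columns(graph, c("head", "relation", "tail"), "graph")
    triples <- as_tibble(graph)
    universe <- unique(c(triples$head, triples$tail))
  }
  deg <- table(c(triples$head, triples$tail))
  degree_of <- function(ids) {
    # entities unseen in the (training) graph have degree 0
    d <- as.integer(deg[ids])
    d[is.na(d)] <- 0L
    d
  }
  missing <- setdiff(unique(c(ranking$drug, ranking$disease)), universe)
  if (length(missing) > 0L) {
    abort(
      sprintf(
        "%d ranked entit%s absent from the graph, e.g.: %s.",
        length(missing), if (length(missing) > 1L) "ies are" else "y is",
        paste(head(missing, 5L), collapse = ", ")
      ),
      class = "kge_lookup_error"
    )
  }
  x <- as.numeric(ranking$score)
  y <- as.numeric(degree_of(ranking$drug) + degree_of(ranking$disease))
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(
      estimate = NA_real_, n = length(x), method = method, undefined = TRUE
    ))
  }
  tibble(
    estimate = cor(x, y, method = method),
    n = length(x), method = method, undefined = FALSE
  )
}

#' Mean rank of held-out positives within a score table
#'
#' Ranks every candidate by raw score (descending, deterministic tie-break)
#' and averages the positions of the held-out test positives. Under a random
#' scorer the expected position is \eqn{(N + 1)/2} over \eqn{N} candidates —
#' the analytic baseline any trained model should beat.
#'
#' @param scores A score table covering the candidate space.
#' @param test Held-out positive pairs; positives absent from the table are
#'   ignored (with a message) since they were never candidates.
#' @return A one-row tibble: `mean_rank`, `n_positives`, `n_candidates`,
#'   `random_baseline`.
#' @export
mean_test_rank <- function(scores, test) {
  pairs <- ranked_pairs(scores)
  test <- as_test_set(test)
  pos <- match(test_key(test), test_key(pairs))
  if (anyNA(pos)) {
    inform(sprintf("%d test positive(s) not in the candidate space; ignored.", sum(is.na(pos))))
    pos <- pos[!is.na(pos)]
  }
  if (length(pos) == 0L) {
    abort("No test positives present in the scored candidate space.",
      class = "kge_data_error"
    )
  }
  tibble(
    mean_rank = mean(pos),
    n_positives = length(pos),
    n_candidates = nrow(pairs),
    random_baseline = (nrow(pairs) + 1) / 2
  )
}
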