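#' Tidiers for kgensemble result objects
#'
#' `tidy()` returns the per-unit breakdown of an object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `kgem_model`, `kge_eval`, `kge_ranking` or `kge_agreement`
#'   object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name kgensemble-tidiers
NULL

#' @rdname kgensemble-tidiers
#' @method tidy kgem_model
#' @export
tidy.kgem_model <- function(x, ...) {
  tibble(epoch = seq_along(x$loss), loss = x$loss)
}

#' @rdname kgensemble-tidiers
#' @method glance kgem_model
#' @export
glance.kgem_model <- function(x, ...) {
  tibble(
    model = x$id, interaction = x$interaction, dim = x$dim,
    n_entities = length(x$entities), n_relations = length(x$relations),
    epochs = length(x$loss),
    final_loss = if (length(x$loss)) x$loss[length(x$loss)] else NA_real_
  )
}

#' @rdname kgensemble-tidiers
#' @method tidy kge_eval
#' @export
tidy.kge_eval <- function(x, ...) {
  as_tibble(x)
}

#' @rdname kgensemble-tidiers
#' @method glance kge_eval
#' @export
glance.kge_eval <- function(x, ...) {
  tibble(
    subject = x$subject[1],
    n_k = nrow(x),
    best_precision = max(x$precision),
    mean_precision = mean(x$precision)
  )
}

#' @rdname kgensemble-tidiers
#' @method tidy kge_ranking
#' @export
tidy.kge_ranking <- function(x, ...) {
  as_tibble(x)
}

#' @rdname kgensemble-tidiers
#' @method glance kge_ranking
#' @export
glance.kge_ranking <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_pairs = nrow(x),
    n_members = length(cfg$members),
    aggregation = cfg$aggregation,
    normalization = cfg$normalization %||% NA_character_,
    percentile = cfg$percentile %||% NA_real_
  )
}

#' @rdname kgensemble-tidiers
#' @method tidy kge_agreement
#' @export
tidy.kge_agreement <- function(x, ...) {
  ids <- rownames(x$tp)
  grid <- tidyr::expand_grid(model_i = ids, model_j = ids)
  mutate(grid,
    tp_overlap = as.vector(t(x$tp)),
    fp_overlap = as.vector(t(x$fp)),
    k = x$k
  )
}

#' @rdname kgensemble-tidiers
#' @method glance kge_agreement
#' @export
glance.kge_agreement <- function(x, ...) {
  off <- upper.tri(x$tp)
  tibble(
    k = x$k, n_models = nrow(x$tp),
    mean_tp_overlap = if (any(off)) mean(x$tp[off]) else NA_real_,
    mean_fp_overlap = if (any(off)) mean(x$fp[off]) else NA_real_
  )
}
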