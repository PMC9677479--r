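#' Simulate a toy knowledge graph with the drug/protein/disease schema
#'
#' Generates a typed, directed graph over three entity classes with four
#' relation families: drug-protein (`targets`), protein-protein
#' (`interacts_with`, ordered pairs), protein-disease (`associated_with`) and
#' drug-disease (`treats`). Each possible edge is included independently with
#' its relation-family density. With `n_blocks` set, drugs and diseases are
#' assigned to communities round-robin and drug-disease edges occur only
#' within a community — a planted structure that embedding models can learn
#' from held-out drug-disease pairs.
#'
#' @param n_drugs,n_proteins,n_diseases Entity counts (>= 1).
#' @param densities Named numeric vector in `(0, 1]` with entries
#'   `drug_protein`, `protein_protein`, `protein_disease`, `drug_disease`.
#' @param n_blocks Optional number of drug-disease communities.
#' @param seed Integer seed; identical configurations give identical graphs.
#' @return A [kg_new()] object.
#' @examples
#' kg <- simulate_kg(n_drugs = 10, n_proteins = 5, n_diseases = 10, seed = 1)
#' @export
simulate_kg <- function(n_drugs, n_proteins, n_diseases,
                        densities = c(
                          drug_protein = 0.2, protein_protein = 0.1,
                          protein_disease = 0.2, drug_disease = 0.2
                        ),
                        n_blocks = NULL, seed = 1L) {
  if (any(c(n_drugs, n_proteins, n_diseases) < 1L)) {
    abort("Entity counts must be >= 1.", class = "kge_config_error")
  }
  need <- c("drug_protein", "protein_protein", "protein_disease", "drug_disease")
  if (!all(need %in% names(densities))) {
    abort(
      sprintf("`densities` must name: %s.", paste(need, collapse = ", ")),
      class = "kge_config_error"
    )
  }
  if (any(densities[need] <= 0 | densities[need] > 1)) {
    abort("Densities must lie in (0, 1].", class = "kge_config_error")
  }
  drugs <- sprintf("drug_%04d", seq_len(n_drugs))
  proteins <- sprintf("protein_%04d", seq_len(n_proteins))
  diseases <- sprintf("disease_%04d", seq_len(n_diseases))

  sample_edges <- function(heads, tails, relation, density, mask = NULL) {
    grid <- tidyr::expand_grid(head = heads, tail = tails)
    if (relation == "interacts_with") grid <- filter(grid, .data$head != .data$tail)
    if (!is.null(mask)) grid <- grid[mask(grid), , drop = FALSE]
    keep <- runif(nrow(grid)) < density
    mutate(grid[keep, , drop = FALSE], relation = relation)
  }

  triples <- with_seed(seed, {
    dd_mask <- NULL
    if (!is.null(n_blocks)) {
      drug_block <- setNames((seq_len(n_drugs) - 1L) %% n_blocks, drugs)
      disease_block <- setNames((seq_len(n_diseases) - 1L) %% n_blocks, diseases)
      dd_mask <- function(grid) drug_block[grid$head] == disease_block[grid$tail]
    }
    bind_rows(
      sample_edges(drugs, proteins, "targets", densities[["drug_protein"]]),
      sample_edges(proteins, proteins, "interacts_with", densities[["protein_protein"]]),
      sample_edges(proteins, diseases, "associated_with", densities[["protein_disease"]]),
      sample_edges(drugs, diseases, "treats", densities[["drug_disease"]], dd_mask)
    )
  })
  if (!any(triples$relation == "treats")) {
    abort("The sampled graph has no drug-disease edges; raise `drug_disease` density.",
      class = "kge_data_error"
    )
  }
  kg_new(
    select(triples, "head", "relation", "tail"),
    tibble(
      entity = c(drugs, proteins, diseases),
      type = rep(c("drug", "protein", "disease"), c(n_drugs, n_proteins, n_diseases))
    )
  )
}

#' Simulate multi-model score tables with planted positives
#'
#' Emulates the statistical structure of scores produced by several
#' independently trained embedding models over one candidate space:
#'
#' * each model `m` places `Binomial(k_top, p_m)` planted true positives in
#'   its top-`k_top` list, so its Precision@`k_top` matches the configured
#'   target up to sampling error;
#' * true positives are drawn from a shared core pool with probability
#'   `tp_agreement` (and from the remaining positives otherwise), false
#'   positives from a shared spurious pool with probability `fp_agreement` —
#'   so cross-model overlap is high among correct predictions and low among
#'   spurious ones when `tp_agreement > fp_agreement`;
#' * raw scores are drawn from a per-model skew-normal, whose location, scale
#'   and skewness differ across models, so distributions lie in different
#'   intervals and have different shapes; the planted top-`k_top` members
#'   receive the `k_top` largest raw values, all other candidates receive
#'   background scores.
#'
#' @param n_models Number of models (default 10).
#' @param k_top Size of each model's planted top list (default 500, i.e. the
#'   top 0.5\% of the default candidate space — the retained list is kept
#'   several times larger than the largest evaluation cutoff, as in realistic
#'   percentile-thresholding setups).
#' @param n_candidates Candidate drug-disease pairs (default 100000).
#' @param n_positives Planted held-out positives (default 500).
#' @param precision_targets Per-model expected Precision@`k_top`, length
#'   `n_models`; defaults to an even spread over `[0.10, 0.60]`.
#' @param tp_agreement,fp_agreement Probability that a planted true/false
#'   positive is drawn from the shared pool (defaults 0.5 and 0.05).
#' @param score_params Optional data frame with `location`, `scale`, `skew`
#'   per model; defaults vary all three across models.
#' @param seed Integer seed.
#' @return A list: `tables` (long score table `model`, `drug`, `disease`,
#'   `score` over all candidates and models), `test` (the planted positive
#'   pairs) and `config` (the echoed parameters).
#' @export
simulate_score_tables <- function(n_models = 10L, k_top = 500L,
                                  n_candidates = 100000L, n_positives = 500L,
                                  precision_targets = NULL,
                                  tp_agreement = 0.5, fp_agreement = 0.05,
                                  score_params = NULL, seed = 1L) {
  precision_targets <- precision_targets %||%
    seq(0.10, 0.60, length.out = n_models)
  if (length(precision_targets) != n_models) {
    abort("`precision_targets` must have one entry per model.", class = "kge_config_error")
  }
  if (any(precision_targets < 0 | precision_targets > 1) ||
    tp_agreement < 0 || tp_agreement > 1 || fp_agreement < 0 || fp_agreement > 1) {
    abort("Precision targets and agreement rates must lie in [0, 1].",
      class = "kge_config_error"
    )
  }
  if (n_positives > n_candidates || k_top > n_candidates) {
    abort("`n_positives` and `k_top` must not exceed `n_candidates`.",
      class = "kge_config_error"
    )
  }
  if (any(precision_targets * k_top > n_positives)) {
    abort(
      "Cannot plant enough positives: some `precision_targets * k_top` exceed `n_positives`.",
      class = "kge_config_error"
    )
  }
  if (is.null(score_params)) {
    score_params <- tibble(
      location = seq(-5, 5, length.out = n_models),
      scale = seq(0.5, 3, length.out = n_models),
      skew = rep_len(c(-4, -1, 0, 1, 4), n_models)
    )
  }
  assert_columns(score_params, c("location", "scale", "skew"), "score_params")

  n_dr <- ceiling(sqrt(n_candidates))
  n_di <- ceiling(n_candidates / n_dr)
  candidates <- tidyr::expand_grid(
    drug = sprintf("d%05d", seq_len(n_dr)),
    disease = sprintf("s%05d", seq_len(n_di))
  )[seq_len(n_candidates), ]

  sim <- with_seed(seed, {
    positives <- sort(sample.int(n_candidates, n_positives))
    is_pos <- logical(n_candidates)
    is_pos[positives] <- TRUE
    mean_p <- mean(precision_targets)
    c_tp <- min(n_positives, max(1L, round(mean_p * k_top)))
    tp_pool <- sample_vec(positives, c_tp)
    tp_rest <- setdiff(positives, tp_pool)
    negatives_n <- n_candidates - n_positives
    c_fp <- max(1L, round((1 - mean_p) * k_top))
    neg_idx <- which(!is_pos)
    fp_pool <- sample_vec(neg_idx, c_fp)

    tabs <- vector("list", n_models)
    for (m in seq_len(n_models)) {
      t_m <- rbinom(1L, k_top, precision_targets[m])
      n_shared <- min(rbinom(1L, t_m, tp_agreement), c_tp)
      n_out <- min(t_m - n_shared, length(tp_rest))
      n_shared <- t_m - n_out
      tp_sel <- c(
        if (n_shared > 0L) sample_vec(tp_pool, n_shared) else integer(0),
        if (n_out > 0L) sample_vec(tp_rest, n_out) else integer(0)
      )
      f_m <- k_top - t_m
      n_shared_fp <- min(rbinom(1L, f_m, fp_agreement), c_fp)
      fp_fresh_pool <- setdiff(neg_idx, fp_pool)
      n_fresh <- f_m - n_shared_fp
      fp_sel <- c(
        if (n_shared_fp > 0L) sample_vec(fp_pool, n_shared_fp) else integer(0),
        if (n_fresh > 0L) sample_vec(fp_fresh_pool, n_fresh) else integer(0)
      )
      planted <- sample_vec(c(tp_sel, fp_sel)) # shuffled top-k members
      raw <- sort(
        rskewnorm(
          n_candidates, score_params$location[m],
          score_params$scale[m], score_params$skew[m]
        ),
        decreasing = TRUE
      )
      sc <- numeric(n_candidates)
      sc[planted] <- raw[seq_len(k_top)]
      rest <- setdiff(seq_len(n_candidates), planted)
      sc[sample_vec(rest)] <- raw[-seq_len(k_top)]
      tabs[[m]] <- tibble(
        model = sprintf("m%02d", m),
        drug = candidates$drug, disease = candidates$disease,
        score = sc
      )
    }
    list(tables = bind_rows(tabs), positives = positives)
  })

  list(
    tables = sim$tables,
    test = candidates[sim$positives, ],
    config = list(
      n_models = n_models, k_top = k_top, n_candidates = n_candidates,
      n_positives = n_positives, precision_targets = precision_targets,
      tp_agreement = tp_agreement, fp_agreement = fp_agreement,
      score_params = score_params, seed = as.integer(seed)
    )
  )
}
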