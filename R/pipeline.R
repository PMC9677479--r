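default_pipeline_config <- function() {
  list(
    out_dir = "kgensemble_run",
    seed = 1L,
    kg = list(
      n_drugs = 30L, n_proteins = 20L, n_diseases = 30L,
      densities = c(
        drug_protein = 0.2, protein_protein = 0.1,
        protein_disease = 0.2, drug_disease = 0.25
      ),
      n_blocks = 2L
    ),
    split = list(ratios = c(0.8, 0.1, 0.1)),
    train = list(
      interactions = c("transe", "distmult", "complex", "rotate"),
      dim = 16L, epochs = 150L, learning_rate = 0.02,
      negatives_per_positive = 1L, margin = 1
    ),
    score = list(relation = "treats", scope = "test_entities"),
    normalize = list(percentile = 95, method = "minmax"),
    ensemble = list(aggregation = "sum", selection = "all", n_top = 5L),
    evaluate = list(k_values = c(1L, 5L, 10L)),
    agreement = list(k = 10L)
  )
}

write_manifest <- function(dir, stage, params, files) {
  hashes <- as.list(tools::md5sum(file.path(dir, files)))
  names(hashes) <- files
  jsonlite::write_json(
    list(stage = stage, parameters = params, files = hashes),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
}

#' Run the full synthetic-to-evaluation pipeline
#'
#' Chains every stage of the package on one configuration: simulate a typed
#' knowledge graph, split it around the drug-disease relation, train the four
#' lightweight embedding models, score the candidate space, threshold and
#' normalize the per-model score tables, aggregate them into an ensemble
#' ranking, and evaluate Precision@K plus the pairwise top-K agreement. Every
#' stage writes its artifacts (TSV/JSON) into `out_dir` together with a JSON
#' manifest recording parameters and content hashes, so a rerun with an
#' identical configuration reproduces identical manifests. One global seed
#' expands deterministically into per-stage seeds.
#'
#' @param config A named list overriding entries of the default configuration
#'   (see `kgensemble:::default_pipeline_config()`), or a path to a YAML file
#'   with the same structure.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @param seed Global seed; overrides `config$seed`.
#' @return Invisibly, a list with the effective `config`, the `split`, the
#'   trained `models`, the ensemble `ranking`, the `evaluation` tibble and the
#'   `agreement` object.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config), class = "kge_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir <- cfg$out_dir
  yaml::write_yaml(cfg, file.path(dir, "effective_config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "kge_pipeline_error", parent = e
      )
    })
  }

  message("[simulate] generating knowledge graph")
  kg <- stage("simulate", simulate_kg(
    n_drugs = cfg$kg$n_drugs, n_proteins = cfg$kg$n_proteins,
    n_diseases = cfg$kg$n_diseases,
    densities = unlist(cfg$kg$densities), n_blocks = cfg$kg$n_blocks,
    seed = derive_seed(cfg$seed, 1L)
  ))
  write_triples(kg, file.path(dir, "kg.tsv"), file.path(dir, "entity_types.tsv"))
  write_manifest(dir, "simulate", cfg$kg, c("kg.tsv", "entity_types.tsv"))

  message("[split] train/validation/test around drug-disease triples")
  split <- stage("split", split_drug_disease(
    kg,
    ratios = as.numeric(unlist(cfg$split$ratios)),
    seed = derive_seed(cfg$seed, 2L)
  ))
  write_split(split, file.path(dir, "split"))
  write_manifest(
    dir, "split", cfg$split,
    file.path("split", c("train.tsv", "valid.tsv", "test.tsv", "manifest.json"))
  )

  message("[train] fitting embedding models: ",
    paste(cfg$train$interactions, collapse = ", "))
  candidates <- enumerate_candidates(split, scope = cfg$score$scope)
  models <- list()
  tables <- list()
  for (i in seq_along(cfg$train$interactions)) {
    ia <- cfg$train$interactions[[i]]
    model <- kgem_init(
      split$entity_types, unique(split$train$relation),
      interaction = ia, dim = cfg$train$dim,
      seed = derive_seed(cfg$seed, 10L + i)
    )
    model <- stage("train", kgem_train(
      model, split,
      epochs = cfg$train$epochs, learning_rate = cfg$train$learning_rate,
      negatives_per_positive = cfg$train$negatives_per_positive,
      margin = cfg$train$margin, seed = derive_seed(cfg$seed, 20L + i)
    ))
    models[[ia]] <- model
    tables[[ia]] <- stage(
      "score",
      score_candidates(model, candidates, cfg$score$relation)
    )
  }
  scores_long <- bind_rows(tables)
  readr::write_tsv(scores_long, file.path(dir, "scores.tsv"), progress = FALSE)
  write_manifest(dir, "score", cfg$score, "scores.tsv")

  message("[normalize] percentile ", cfg$normalize$percentile,
    ", method ", cfg$normalize$method)
  topk <- stage("normalize", normalize_scores(
    threshold_top_percentile(scores_long, cfg$normalize$percentile),
    method = cfg$normalize$method
  ))
  readr::write_tsv(as_tibble(topk), file.path(dir, "topk_normalized.tsv"), progress = FALSE)
  write_manifest(dir, "normalize", cfg$normalize, "topk_normalized.tsv")

  message("[ensemble] aggregation ", cfg$ensemble$aggregation,
    ", selection ", cfg$ensemble$selection)
  members <- topk
  if (identical(cfg$ensemble$selection, "top5")) {
    # model selection by validation precision: rank validation-entity pairs
    # unseen in training, score them per model, compare Precision@K
    val_grid <- tidyr::expand_grid(
      drug = sort(unique(split$validation$head)),
      disease = sort(unique(split$validation$tail))
    )
    seen <- tibble(drug = split$train$head, disease = split$train$tail)
    val_cand <- anti_join(val_grid, seen, by = c("drug", "disease"))
    k_sel <- min(100L, nrow(val_cand))
    val_reports <- bind_rows(lapply(names(models), function(id) {
      precision_at_k(
        score_candidates(models[[id]], val_cand, cfg$score$relation),
        split$validation,
        k_values = k_sel, subject = id
      )
    }))
    chosen <- select_top_models(val_reports,
      n = min(cfg$ensemble$n_top, length(tables)), k = k_sel
    )
    members <- structure(
      filter(as_tibble(topk), .data$model %in% chosen),
      method = attr(topk, "method"), percentile = attr(topk, "percentile")
    )
  }
  ranking <- stage("ensemble", ensemble_rank(members, aggregation = cfg$ensemble$aggregation))
  write_ranking(ranking, file.path(dir, "ensemble_ranking.tsv"))
  write_manifest(
    dir, "ensemble", cfg$ensemble,
    c("ensemble_ranking.tsv", "ensemble_ranking.tsv.json")
  )

  message("[evaluate] Precision@{", paste(cfg$evaluate$k_values, collapse = ","), "}")
  k_vals <- as.integer(unlist(cfg$evaluate$k_values))
  k_vals <- k_vals[k_vals <= nrow(ranking)]
  evaluation <- stage("evaluate", precision_at_k(
    ranking, split$test, k_values = k_vals, subject = "ensemble"
  ))
  readr::write_tsv(evaluation, file.path(dir, "evaluation.tsv"), progress = FALSE)
  write_manifest(dir, "evaluate", cfg$evaluate, "evaluation.tsv")

  message("[agreement] pairwise top-", cfg$agreement$k, " overlap")
  agreement <- stage("agreement", pairwise_overlap(
    scores_long, split$test, k = cfg$agreement$k
  ))
  write_agreement(
    agreement,
    file.path(dir, "agreement_tp.tsv"), file.path(dir, "agreement_fp.tsv")
  )
  write_manifest(
    dir, "agreement", cfg$agreement,
    c("agreement_tp.tsv", "agreement_fp.tsv")
  )

  invisible(list(
    config = cfg, split = split, models = models, scores = scores_long,
    topk = topk, ranking = ranking, evaluation = evaluation,
    agreement = agreement
  ))
}
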