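#' Split a knowledge graph into train/validation/test for drug-disease prediction
#'
#' The prediction target is the directed drug -> disease relation, so the
#' validation and test sets contain exclusively drug-disease triples while the
#' train set keeps every other edge type (drug-protein, protein-protein,
#' protein-disease) plus its share of drug-disease triples. Drug-disease
#' triples are first sorted lexicographically, then permuted with the given
#' seed, so identical inputs always give identical splits on any platform.
#' With \eqn{N} drug-disease triples and ratios \eqn{(f_{tr}, f_{va}, f_{te})},
#' the test set receives \eqn{\lfloor N f_{te} \rfloor} triples, validation
#' \eqn{\lfloor N f_{va} \rfloor}, and train the remainder. Inverse triples
#' are never generated: all drug-disease edges are directed.
#'
#' @param kg A [kg_new()] object with at least one drug-disease triple.
#' @param ratios Numeric length-3 vector `(train, validation, test)` summing
#'   to 1. Default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed controlling the permutation.
#' @return An object of class `kg_split`: a list with tibbles `$train`,
#'   `$validation`, `$test` (each `head`/`relation`/`tail`), the
#'   `$entity_types` table, and `$ratios`, `$seed`.
#' @examples
#' kg <- simulate_kg(n_drugs = 6, n_proteins = 4, n_diseases = 6, seed = 1)
#' sp <- split_drug_disease(kg, seed = 7)
#' @export
split_drug_disease <- function(kg, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(kg, "kg"))
  if (length(ratios) != 3L || any(ratios < 0)) {
    abort("`ratios` must be three non-negative fractions.", class = "kge_config_error")
  }
  if (abs(sum(ratios) - 1) > 1e-9) {
    abort("`ratios` must sum to 1.", class = "kge_config_error")
  }
  is_dd <- drug_disease_mask(kg)
  dd <- kg$triples[is_dd, , drop = FALSE]
  other <- kg$triples[!is_dd, , drop = FALSE]
  n <- nrow(dd)
  if (n == 0L) {
    abort("The knowledge graph has no drug-disease triples to split.",
      class = "kge_data_error"
    )
  }
  dd <- arrange(dd, .data$head, .data$relation, .data$tail)
  perm <- with_seed(seed, sample.int(n))
  dd <- dd[perm, , drop = FALSE]
  n_test <- floor(n * ratios[3])
  n_valid <- floor(n * ratios[2])
  test <- dd[seq_len(n_test), , drop = FALSE]
  validation <- dd[seq_len(n_valid) + n_test, , drop = FALSE]
  train_dd <- dd[seq_len(n - n_test - n_valid) + n_test + n_valid, , drop = FALSE]
  structure(
    list(
      train = arrange(bind_rows(train_dd, other), .data$head, .data$relation, .data$tail),
      validation = arrange(validation, .data$head, .data$relation, .data$tail),
      test = arrange(test, .data$head, .data$relation, .data$tail),
      entity_types = kg$entity_types,
      ratios = as.numeric(ratios),
      seed = as.integer(seed)
    ),
    class = "kg_split"
  )
}

#' @export
print.kg_split <- function(x, ...) {
  cat(sprintf(
    "<kg split> train: %d, validation: %d, test: %d triples (ratios %s, seed %d)\n",
    nrow(x$train), nrow(x$validation), nrow(x$test),
    paste(x$ratios, collapse = "/"), x$seed
  ))
  invisible(x)
}

#' Serialize / read a split as three TSV files plus a JSON manifest
#'
#' Writes `train.tsv`, `valid.tsv`, `test.tsv` (headerless triple TSVs),
#' `entity_types.tsv`, and `manifest.json` recording ratios, seed and counts.
#'
#' @param split A [split_drug_disease()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly (`write_split`); a `kg_split`
#'   (`read_split`).
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "kg_split"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(split$train, file.path(dir, "train.tsv"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(split$validation, file.path(dir, "valid.tsv"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(split$test, file.path(dir, "test.tsv"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(split$entity_types, file.path(dir, "entity_types.tsv"),
    col_names = FALSE, progress = FALSE
  )
  jsonlite::write_json(
    list(
      ratios = split$ratios, seed = split$seed,
      counts = list(
        train = nrow(split$train), validation = nrow(split$validation),
        test = nrow(split$test)
      )
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  read_part <- function(name) {
    readr::read_tsv(file.path(dir, name),
      col_names = c("head", "relation", "tail"),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(
    list(
      train = read_part("train.tsv"),
      validation = read_part("valid.tsv"),
      test = read_part("test.tsv"),
      entity_types = readr::read_tsv(file.path(dir, "entity_types.tsv"),
        col_names = c("entity", "type"),
        col_types = readr::cols(.default = readr::col_character()),
        progress = FALSE, show_col_types = FALSE
      ),
      ratios = as.numeric(unlist(manifest$ratios)),
      seed = as.integer(manifest$seed)
    ),
    class = "kg_split"
  )
}

#' Enumerate the candidate drug-disease prediction space
#'
#' The candidate space is every drug x disease pair a model may nominate,
#' excluding pairs already seen as triples in train or validation (those are
#' known, not predictions). With `scope = "test_entities"` (default) the
#' drugs and diseases are those appearing in the test set; with
#' `scope = "all_entities"` every typed drug and disease in the split's
#' entity table is used. Ordering is deterministic by `(drug, disease)`.
#'
#' @param split A [split_drug_disease()] result.
#' @param scope `"test_entities"` or `"all_entities"`.
#' @return A tibble with columns `drug`, `disease`.
#' @export
enumerate_candidates <- function(split, scope = c("test_entities", "all_entities")) {
  stopifnot(inherits(split, "kg_split"))
  scope <- match.arg(scope)
  if (nrow(split$test) == 0L) {
    abort("The test set is empty; no candidate space can be derived.",
      class = "kge_data_error"
    )
  }
  if (scope == "test_entities") {
    drugs <- sort(unique(split$test$head))
    diseases <- sort(unique(split$test$tail))
  } else {
    drugs <- sort(split$entity_types$entity[split$entity_types$type == "drug"])
    diseases <- sort(split$entity_types$entity[split$entity_types$type == "disease"])
  }
  pairs <- tidyr::expand_grid(drug = drugs, disease = diseases)
  seen <- bind_rows(
    select(rename(split$train, drug = "head", disease = "tail"), "drug", "disease"),
    select(rename(split$validation, drug = "head", disease = "tail"), "drug", "disease")
  )
  arrange(anti_join(pairs, seen, by = c("drug", "disease")), .data$drug, .data$disease)
}
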