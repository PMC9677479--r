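# Fixtures and independent oracles shared across test files.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# A small hand-typed KG with one of each relation family.
make_toy_kg <- function() {
  triples <- tibble::tribble(
    ~head, ~relation, ~tail,
    "dA", "treats", "xA",
    "dA", "treats", "xB",
    "dB", "treats", "xB",
    "dA", "targets", "pA",
    "pA", "interacts_with", "pB",
    "pB", "associated_with", "xA"
  )
  types <- tibble::tibble(
    entity = c("dA", "dB", "pA", "pB", "xA", "xB"),
    type = c("drug", "drug", "protein", "protein", "disease", "disease")
  )
  kg_new(triples, types)
}

# A KG holding n_dd drug-disease triples plus n_other protein-protein ones.
make_split_kg <- function(n_dd, n_other = 0L) {
  dd <- tibble::tibble(
    head = sprintf("drug_%05d", ((seq_len(n_dd) - 1L) %% max(1L, n_dd %/% 10L)) + 1L),
    relation = "treats",
    tail = sprintf("disease_%05d", seq_len(n_dd))
  )
  other <- if (n_other > 0L) {
    tibble::tibble(
      head = sprintf("protein_%05d", seq_len(n_other)),
      relation = "interacts_with",
      tail = sprintf("protein_%05d", (seq_len(n_other) %% n_other) + 1L)
    )
  } else {
    dd[0, ]
  }
  triples <- dplyr::bind_rows(dd, other)
  ents <- unique(c(triples$head, triples$tail))
  types <- tibble::tibble(
    entity = ents,
    type = dplyr::case_when(
      startsWith(ents, "drug_") ~ "drug",
      startsWith(ents, "protein_") ~ "protein",
      TRUE ~ "disease"
    )
  )
  kg_new(triples, types)
}

# Random single-model score table with distinct scores (a.s.).
make_score_table <- function(n, model = "m", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    model = model,
    drug = sprintf("d%05d", sample.int(n)),
    disease = sprintf("s%05d", sample.int(n)),
    score = rnorm(n)
  ))
}

# Brute-force top-k selection by full sort with the documented tie-break.
oracle_topk <- function(tab, k) {
  tab[order(-tab$score, tab$drug, tab$disease), ][seq_len(k), ]
}

# Hand-rolled Pearson correlation from the definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Build a normalized top-K table directly from (pair, normalized) values,
# bypassing thresholding, for ensemble arithmetic tests.
manual_topk <- function(model, drugs, diseases, normalized,
                        method = "minmax", percentile = 99) {
  tab <- tibble::tibble(
    model = model, drug = drugs, disease = diseases,
    score = normalized, rank = rank(-normalized), normalized = normalized
  )
  structure(tab,
    class = c("kge_topk", class(tab)),
    method = method, percentile = percentile
  )
}

block_of <- function(ids, n_blocks = 2L) {
  (as.integer(sub(".*_", "", ids)) - 1L) %% n_blocks
}

two_block_config <- list(
  n_drugs = 40L, n_proteins = 20L, n_diseases = 40L,
  densities = c(
    drug_protein = 0.2, protein_protein = 0.1,
    protein_disease = 0.2, drug_disease = 0.3
  ),
  n_blocks = 2L
)

make_two_block_split <- function(seed) {
  kg <- do.call(simulate_kg, c(two_block_config, list(seed = seed)))
  split_drug_disease(kg, seed = seed + 1L)
}
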