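test_that("read_triples drops duplicates and matches an independent file scan", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "triples.tsv")
  tmap <- file.path(dir, "types.tsv")
  writeLines(
    c("dA\ttreats\txA", "dA\ttreats\txA", "dB\ttreats\txB"),
    tsv
  )
  writeLines(c("dA\tdrug", "dB\tdrug", "xA\tdisease", "xB\tdisease"), tmap)
  expect_message(kg <- read_triples(tsv, tmap), "duplicate")
  expect_s3_class(kg, "kg")
  expect_equal(nrow(kg$triples), 2L)

  # 10-triple fixture: triple multiset equals a line-by-line strsplit read
  lines <- sprintf("d%d\ttreats\tx%d", rep(1:5, 2), 1:10)
  writeLines(lines, tsv)
  writeLines(
    c(sprintf("d%d\tdrug", 1:5), sprintf("x%d\tdisease", 1:10)), tmap
  )
  kg <- read_triples(tsv, tmap)
  manual <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  manual <- tibble(head = manual[, 1], relation = manual[, 2], tail = manual[, 3])
  expect_setequal(
    paste(kg$triples$head, kg$triples$relation, kg$triples$tail),
    paste(manual$head, manual$relation, manual$tail)
  )
})

test_that("malformed and untyped inputs raise informative errors", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "triples.tsv")
  tmap <- file.path(dir, "types.tsv")
  writeLines(c("dA\ttreats\txA", "dB\ttreats"), tsv)
  writeLines(c("dA\tdrug", "dB\tdrug", "xA\tdisease"), tmap)
  expect_error(read_triples(tsv, tmap), "line 2", class = "kge_parse_error")

  writeLines(c("dA\ttreats\txA", "dB\ttreats\txB"), tsv)
  writeLines(c("dA\tdrug", "dB\tdrug", "xA\tdisease"), tmap)
  expect_error(read_triples(tsv, tmap), "xB", class = "kge_typing_error")
})

test_that("reduce_schema filters node types and relations as a brute-force filter", {
  triples <- tibble(
    head = c("dA", "dA"),
    relation = c("causes_side_effect", "targets"),
    tail = c("sideE", "pA")
  )
  types <- tibble(
    entity = c("dA", "sideE", "pA"),
    type = c("drug", "side_effect", "protein")
  )
  kg <- kg_new(triples, types)
  red <- reduce_schema(kg)
  expect_equal(red$triples$relation, "targets")
  expect_setequal(red$entity_types$entity, c("dA", "pA"))

  # already conformant -> identity; and idempotence
  kg2 <- make_toy_kg()
  expect_equal(reduce_schema(kg2)$triples, kg2$triples)
  once <- reduce_schema(kg, keep_types = c("drug", "protein"))
  twice <- reduce_schema(once, keep_types = c("drug", "protein"))
  expect_equal(once$triples, twice$triples)
  expect_equal(once$entity_types, twice$entity_types)

  # 50 random triples: survivor count equals explicit vectorized filter
  set.seed(7)
  ents <- sprintf("e%02d", 1:20)
  tps <- sample(c("drug", "protein", "disease", "pathway"), 20, replace = TRUE)
  rnd <- tibble(
    head = sample(ents, 50, replace = TRUE),
    relation = sample(c("rel_a", "rel_b"), 50, replace = TRUE),
    tail = sample(ents, 50, replace = TRUE)
  )
  rnd <- rnd[rnd$head != rnd$tail, ]
  kg3 <- kg_new(rnd, tibble(entity = ents, type = tps))
  type_of <- setNames(tps, ents)
  keep <- c("drug", "protein", "disease")
  expected <- sum(
    type_of[kg3$triples$head] %in% keep & type_of[kg3$triples$tail] %in% keep
  )
  expect_equal(nrow(reduce_schema(kg3)$triples), expected)

  # relation whitelist on top of the type filter
  wl <- reduce_schema(kg3, keep_types = keep, keep_relations = "rel_a")
  expect_true(all(wl$triples$relation == "rel_a"))
})

test_that("splitting 52,060 drug-disease triples at 80/10/10 gives 41,648/5,206/5,206", {
  kg <- make_split_kg(52060L)
  sp <- split_drug_disease(kg, c(0.8, 0.1, 0.1), seed = 11)
  expect_equal(nrow(sp$test), 5206L)
  expect_equal(nrow(sp$validation), 5206L)
  expect_equal(nrow(sp$train), 41648L)
})

test_that("split is deterministic, conservative and routes non-drug-disease triples to train", {
  kg <- make_split_kg(100L, n_other = 900L)
  sp <- split_drug_disease(kg, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(nrow(sp$test), 10L)
  expect_equal(nrow(sp$validation), 10L)
  expect_equal(nrow(sp$train), 80L + 900L)

  key <- function(df) paste(df$head, df$relation, df$tail)
  expect_length(intersect(key(sp$train), key(sp$validation)), 0L)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_length(intersect(key(sp$validation), key(sp$test)), 0L)
  expect_setequal(
    c(key(sp$train), key(sp$validation), key(sp$test)),
    key(kg$triples)
  )
  # validation/test contain exclusively drug -> disease triples
  expect_true(all(startsWith(sp$test$head, "drug_")))
  expect_true(all(startsWith(sp$validation$tail, "disease_")))
  expect_true(all(key(kg$triples)[!startsWith(kg$triples$head, "drug_")] %in% key(sp$train)))

  # byte-for-byte determinism of the serialized bundle
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_split(split_drug_disease(kg, c(0.8, 0.1, 0.1), seed = 5), d1)
  write_split(split_drug_disease(kg, c(0.8, 0.1, 0.1), seed = 5), d2)
  for (f in c("train.tsv", "valid.tsv", "test.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed changes the partition
  sp2 <- split_drug_disease(kg, c(0.8, 0.1, 0.1), seed = 6)
  expect_false(identical(sp$test, sp2$test))

  # degenerate ratios
  sp3 <- split_drug_disease(make_split_kg(10L), c(1, 0, 0), seed = 1)
  expect_equal(
    c(nrow(sp3$train), nrow(sp3$validation), nrow(sp3$test)),
    c(10L, 0L, 0L)
  )
  expect_error(split_drug_disease(kg, c(0.5, 0.2, 0.2), seed = 1),
    class = "kge_config_error"
  )
  expect_error(
    split_drug_disease(
      kg_new(
        tibble(head = "pA", relation = "interacts_with", tail = "pB"),
        tibble(entity = c("pA", "pB"), type = "protein")
      ),
      seed = 1
    ),
    class = "kge_data_error"
  )
})

test_that("candidate space is the test cross product minus seen pairs, and pure", {
  # 3 drugs x 4 diseases with 2 pairs already in train -> 10 candidates
  dd <- tidyr::expand_grid(
    head = c("drug_1", "drug_2", "drug_3"),
    tail = c("disease_1", "disease_2", "disease_3", "disease_4")
  ) |> mutate(relation = "treats")
  types <- tibble(
    entity = unique(c(dd$head, dd$tail)),
    type = rep(c("drug", "disease"), c(3, 4))
  )
  split <- structure(
    list(
      train = dd[1:2, c("head", "relation", "tail")],
      validation = dd[0, c("head", "relation", "tail")],
      test = dd[3:12, c("head", "relation", "tail")],
      entity_types = types, ratios = c(0.8, 0.1, 0.1), seed = 1L
    ),
    class = "kg_split"
  )
  cand <- enumerate_candidates(split)
  manual <- tidyr::expand_grid(
    drug = sort(unique(split$test$head)),
    disease = sort(unique(split$test$tail))
  )
  manual <- manual[!paste(manual$drug, manual$disease) %in%
    paste(dd$head[1:2], dd$tail[1:2]), ]
  expect_equal(nrow(cand), 10L)
  expect_equal(cand, arrange(manual, drug, disease))

  # purity on a simulated split: no candidate is in train or validation
  sp <- make_two_block_split(seed = 31)
  cand2 <- enumerate_candidates(sp)
  seen <- c(
    paste(sp$train$head, sp$train$tail),
    paste(sp$validation$head, sp$validation$tail)
  )
  expect_length(intersect(paste(cand2$drug, cand2$disease), seen), 0L)

  # singleton case
  single <- split
  single$test <- dd[3, c("head", "relation", "tail")]
  single$train <- dd[0, c("head", "relation", "tail")]
  expect_equal(nrow(enumerate_candidates(single)), 1L)

  empty <- split
  empty$test <- dd[0, c("head", "relation", "tail")]
  expect_error(enumerate_candidates(empty), class = "kge_data_error")
})

test_that("split bundles round-trip through TSV serialization", {
  sp <- make_two_block_split(seed = 17)
  dir <- withr::local_tempdir()
  write_split(sp, dir)
  back <- read_split(dir)
  expect_equal(as.data.frame(back$train), as.data.frame(sp$train))
  expect_equal(as.data.frame(back$test), as.data.frame(sp$test))
  expect_equal(back$ratios, sp$ratios)
  expect_equal(back$seed, sp$seed)
})
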