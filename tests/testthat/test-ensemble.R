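test_that("sum aggregation rewards cross-model support and excludes unseen pairs", {
  # pair A in two models at {0.9, 0.2} -> 1.1; pair B in one at {1.0} -> 1.0
  t1 <- manual_topk("m1", c("dA", "dB"), c("sA", "sB"), c(0.9, 1.0))
  t2 <- manual_topk("m2", "dA", "sA", 0.2)
  rk <- ensemble_rank(list(t1, t2), "sum")
  expect_equal(rk$drug, c("dA", "dB"))
  expect_equal(rk$score, c(1.1, 1.0))
  expect_equal(rk$n_models, c(2L, 1L))
  # a pair in zero tables is absent
  expect_false("dC" %in% rk$drug)

  # single member: ranking equals the member's own ordering
  single <- manual_topk("m1", paste0("d", 1:5), "s", c(0.1, 0.9, 0.5, 1, 0))
  rk1 <- ensemble_rank(single, "sum")
  expect_equal(rk1$drug, paste0("d", c(4, 2, 3, 1, 5)))
})

test_that("average aggregation matches hand computation and its two modes differ", {
  # M = 10 models; pair A present in 2 at {0.9, 0.2}
  tabs <- c(
    list(
      manual_topk("m01", c("dA", "dB"), c("sA", "sB"), c(0.9, 1.0)),
      manual_topk("m02", "dA", "sA", 0.2)
    ),
    lapply(3:10, function(i) {
      manual_topk(sprintf("m%02d", i), "dZ", "sZ", 0.01)
    })
  )
  rz <- ensemble_rank(tabs, "avg_zero")
  rp <- ensemble_rank(tabs, "avg_present")
  a_z <- rz$score[rz$drug == "dA"]
  a_p <- rp$score[rp$drug == "dA"]
  expect_equal(a_z, 0.11)
  expect_equal(a_p, 0.55)
  # avg_present reverses A and B relative to sum: 0.55 < 1.0
  b_p <- rp$score[rp$drug == "dB"]
  expect_equal(b_p, 1.0)
  expect_lt(a_p, b_p)
  rs <- ensemble_rank(tabs, "sum")
  expect_gt(rs$score[rs$drug == "dA"], rs$score[rs$drug == "dB"])

  # single model: both modes reproduce the model's own ordering
  single <- manual_topk("m1", paste0("d", 1:4), "s", c(0.3, 0.8, 0.1, 0.6))
  for (mode in c("avg_zero", "avg_present")) {
    expect_equal(ensemble_rank(single, mode)$drug, paste0("d", c(2, 4, 1, 3)))
  }
})

test_that("avg_zero ordering is identical to sum ordering on random ensembles", {
  set.seed(21)
  for (s in 1:50) {
    n_m <- sample(2:6, 1)
    tabs <- lapply(seq_len(n_m), function(i) {
      k <- sample(5:30, 1)
      idx <- sample(100, k)
      manual_topk(
        sprintf("m%d", i), sprintf("d%03d", idx), sprintf("s%03d", idx),
        runif(k)
      )
    })
    sum_rk <- ensemble_rank(tabs, "sum")
    avg_rk <- ensemble_rank(tabs, "avg_zero")
    expect_identical(
      paste(sum_rk$drug, sum_rk$disease),
      paste(avg_rk$drug, avg_rk$disease)
    )
  }
})

test_that("mixed normalization settings are rejected", {
  t1 <- manual_topk("m1", "dA", "sA", 0.5, method = "minmax")
  t2 <- manual_topk("m2", "dA", "sA", 0.5, method = "rank")
  expect_error(ensemble_rank(list(t1, t2), "sum"), class = "kge_config_error")
  t3 <- manual_topk("m2", "dA", "sA", 0.5, method = "minmax", percentile = 95)
  expect_error(ensemble_rank(list(t1, t3), "sum"), class = "kge_config_error")
  expect_error(position_ensemble(list(t1)), class = "kge_config_error")
})

test_that("product of experts matches brute-force softmax products and vetoes", {
  # single model: ordering equals raw ordering (softmax + log is monotone)
  tab <- make_score_table(20, model = "m1", seed = 4)
  poe1 <- product_of_experts(tab)
  expect_equal(
    paste(poe1$drug, poe1$disease),
    paste(oracle_topk(tab, 20)$drug, oracle_topk(tab, 20)$disease)
  )

  # two models, 3 candidates: brute-force product of softmax probabilities
  mk <- function(model, scores) {
    tibble(model = model, drug = c("d1", "d2", "d3"), disease = "s", score = scores)
  }
  s1 <- c(2, 1, 0)
  s2 <- c(0.5, 3, 0.1)
  poe <- product_of_experts(list(mk("m1", s1), mk("m2", s2)))
  brute <- (exp(s1) / sum(exp(s1))) * (exp(s2) / sum(exp(s2)))
  expect_equal(poe$drug, c("d1", "d2", "d3")[order(-brute)])
  expect_equal(poe$score, log(brute)[order(-brute)])

  # a model assigning its minimum to d3 while the other is indifferent -> d3 last
  veto <- product_of_experts(list(mk("m1", c(0, 0, -10)), mk("m2", c(1, 1, 1))))
  expect_equal(veto$drug[3], "d3")

  # mismatched candidate spaces are rejected with the symmetric difference size
  bad <- tibble(model = "m2", drug = "d9", disease = "s", score = 1)
  expect_error(
    product_of_experts(list(mk("m1", s1), bad)),
    "symmetric difference",
    class = "kge_config_error"
  )
})

test_that("position ensemble aggregates rank-normalized positions", {
  # k = 5 lists; A is rank 1 in one model and rank 5 in the other,
  # B is rank 2 in both: B (0.75 * 2) outranks A (1.0 + 0.0)
  mk <- function(model, order_ids) {
    manual_topk(model, order_ids, "s", seq(1, 0, length.out = 5),
      method = "rank"
    )
  }
  t1 <- mk("m1", c("A", "B", "C", "D", "E"))
  t2 <- mk("m2", c("C", "B", "D", "E", "A"))
  rk <- position_ensemble(list(t1, t2))
  expect_equal(rk$drug[1], "B")
  expect_equal(rk$score[rk$drug == "B"], 1.5)
  expect_equal(rk$score[rk$drug == "A"], 1.0)

  # identical member tables -> the common ordering
  rk2 <- position_ensemble(list(t1, t1))
  expect_equal(rk2$drug, c("A", "B", "C", "D", "E"))
  # single table -> the table's own rank order
  expect_equal(position_ensemble(t1)$drug, c("A", "B", "C", "D", "E"))
})

test_that("select_top_models picks by validation Precision@100 with lexicographic ties", {
  set.seed(5)
  prec <- runif(10)
  reports <- tibble(
    subject = sprintf("m%02d", 1:10), k = 100L, precision = prec
  )
  got <- select_top_models(reports, 5)
  expect_equal(got, reports$subject[order(-prec)][1:5])

  five <- reports[1:5, ]
  expect_equal(select_top_models(five, 5), five$subject[order(-five$precision)])

  tied <- tibble(
    subject = c("mB", "mA", "mC"), k = 100L, precision = c(0.5, 0.5, 0.9)
  )
  expect_equal(select_top_models(tied, 2), c("mC", "mA"))

  no100 <- tibble(subject = "mX", k = 10L, precision = 1)
  expect_error(select_top_models(no100, 1), "mX", class = "kge_data_error")
  expect_error(select_top_models(reports, 11), class = "kge_config_error")
})

test_that("adding a member that only supports one pair cannot lower its rank", {
  set.seed(33)
  for (s in 1:10) {
    tabs <- lapply(1:3, function(i) {
      idx <- sample(50, 10)
      manual_topk(sprintf("m%d", i), sprintf("d%03d", idx), "s", runif(10))
    })
    base <- ensemble_rank(tabs, "sum")
    target <- base$drug[sample(nrow(base), 1)]
    extra <- manual_topk("m_extra", target, "s", runif(1))
    boosted <- ensemble_rank(c(tabs, list(extra)), "sum")
    expect_lte(
      boosted$rank[boosted$drug == target],
      base$rank[base$drug == target]
    )
  }
})

test_that("tie-breaking is deterministic across repeated runs", {
  t1 <- manual_topk("m1", c("dB", "dA"), c("sB", "sA"), c(0.5, 0.5))
  rk <- ensemble_rank(t1, "sum")
  expect_equal(rk$drug, c("dA", "dB")) # equal scores: drug id ascending
  expect_identical(rk, ensemble_rank(t1, "sum"))
})
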