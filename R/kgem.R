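#' Initialize a lightweight knowledge graph embedding model
#'
#' Four classic interaction functions are provided, spanning the translational
#' (TransE, RotatE) and semantic-matching (DistMult, ComplEx) paradigms. Each
#' model assigns every entity and relation a `dim`-dimensional (real or
#' complex) vector; a triple's plausibility is a real score where higher is
#' always more plausible (distance-based interactions are negated internally).
#'
#' Embedding layout: TransE/DistMult use real vectors of length `dim`;
#' ComplEx and RotatE entities use `2 * dim` columns (real parts then
#' imaginary parts); RotatE relations are phase vectors in `[0, 2*pi)`, i.e.
#' unit-modulus complex numbers.
#'
#' @param entity_types Data frame `entity`/`type` (types drive the type-aware
#'   negative sampling during training).
#' @param relations Character vector of relation labels.
#' @param interaction One of `"transe"`, `"distmult"`, `"complex"`, `"rotate"`.
#' @param dim Embedding dimension (>= 1).
#' @param seed Integer seed; identical arguments give identical embeddings.
#' @param id Model identifier used in score tables; defaults to `interaction`.
#' @return An object of class `kgem_model`.
#' @examples
#' m <- kgem_init(
#'   tibble::tibble(entity = c("d1", "x1"), type = c("drug", "disease")),
#'   relations = "treats", interaction = "transe", dim = 8, seed = 1
#' )
#' @export
kgem_init <- function(entity_types, relations,
                      interaction = c("transe", "distmult", "complex", "rotate"),
                      dim = 32L, seed = 1L, id = NULL) {
  interaction <- tryCatch(match.arg(interaction), error = function(e) {
    abort(sprintf("Unknown interaction '%s'.", paste(interaction, collapse = "/")),
      class = "kge_config_error"
    )
  })
  assert_columns(entity_types, c("entity", "type"), "entity_types")
  if (dim < 1L) abort("`dim` must be >= 1.", class = "kge_config_error")
  if (nrow(entity_types) == 0L || length(relations) == 0L) {
    abort("Entity and relation lists must be non-empty.", class = "kge_config_error")
  }
  entity_types <- distinct(as_tibble(entity_types)[, c("entity", "type")])
  entities <- sort(unique(entity_types$entity))
  relations <- sort(unique(as.character(relations)))
  d_ent <- if (interaction %in% c("complex", "rotate")) 2L * dim else dim
  d_rel <- switch(interaction,
    transe = dim, distmult = dim, complex = 2L * dim, rotate = dim
  )
  emb <- with_seed(seed, {
    E <- matrix(rnorm(length(entities) * d_ent, sd = 1 / sqrt(dim)),
      nrow = length(entities), dimnames = list(entities, NULL)
    )
    R <- if (interaction == "rotate") {
      matrix(runif(length(relations) * d_rel, 0, 2 * pi),
        nrow = length(relations), dimnames = list(relations, NULL)
      )
    } else {
      matrix(rnorm(length(relations) * d_rel, sd = 1 / sqrt(dim)),
        nrow = length(relations), dimnames = list(relations, NULL)
      )
    }
    list(E = E, R = R)
  })
  structure(
    list(
      id = id %||% interaction,
      interaction = interaction, dim = as.integer(dim), seed = as.integer(seed),
      entities = entities, relations = relations,
      types = setNames(entity_types$type, entity_types$entity)[entities],
      E = emb$E, R = emb$R, loss = numeric(0)
    ),
    class = "kgem_model"
  )
}

#' @export
print.kgem_model <- function(x, ...) {
  cat(sprintf(
    "<kgem '%s'> interaction: %s, dim: %d, %d entities, %d relations, %d epochs trained\n",
    x$id, x$interaction, x$dim, length(x$entities), length(x$relations), length(x$loss)
  ))
  invisible(x)
}

# Split a 2*dim entity/relation matrix into real and imaginary halves.
re_part <- function(M, dim) M[, seq_len(dim), drop = FALSE]
im_part <- function(M, dim) M[, dim + seq_len(dim), drop = FALSE]

# Raw interaction scores for index vectors h, r, t (higher = more plausible).
interaction_score <- function(model, h, r, t) {
  E <- model$E
  R <- model$R
  d <- model$dim
  unname(switch(model$interaction,
    transe = {
      diff <- E[h, , drop = FALSE] + R[r, , drop = FALSE] - E[t, , drop = FALSE]
      -sqrt(rowSums(diff^2))
    },
    distmult = rowSums(E[h, , drop = FALSE] * R[r, , drop = FALSE] * E[t, , drop = FALSE]),
    complex = {
      HR <- re_part(E[h, , drop = FALSE], d); HI <- im_part(E[h, , drop = FALSE], d)
      RR <- re_part(R[r, , drop = FALSE], d); RI <- im_part(R[r, , drop = FALSE], d)
      TR <- re_part(E[t, , drop = FALSE], d); TI <- im_part(E[t, , drop = FALSE], d)
      rowSums((HR * RR - HI * RI) * TR + (HR * RI + HI * RR) * TI)
    },
    rotate = {
      HR <- re_part(E[h, , drop = FALSE], d); HI <- im_part(E[h, , drop = FALSE], d)
      TR <- re_part(E[t, , drop = FALSE], d); TI <- im_part(E[t, , drop = FALSE], d)
      ph <- R[r, , drop = FALSE]
      co <- cos(ph); si <- sin(ph)
      dR <- HR * co - HI * si - TR
      dI <- HR * si + HI * co - TI
      -sqrt(rowSums(dR^2 + dI^2))
    }
  ))
}

# Partial derivatives of the score wrt the involved embedding rows.
interaction_grad <- function(model, h, r, t) {
  E <- model$E
  R <- model$R
  d <- model$dim
  eps <- 1e-12
  switch(model$interaction,
    transe = {
      diff <- E[h, , drop = FALSE] + R[r, , drop = FALSE] - E[t, , drop = FALSE]
      n <- sqrt(rowSums(diff^2)) + eps
      g <- diff / n
      list(dh = -g, dr = -g, dt = g)
    },
    distmult = {
      H <- E[h, , drop = FALSE]; Rm <- R[r, , drop = FALSE]; Tm <- E[t, , drop = FALSE]
      list(dh = Rm * Tm, dr = H * Tm, dt = H * Rm)
    },
    complex = {
      HR <- re_part(E[h, , drop = FALSE], d); HI <- im_part(E[h, , drop = FALSE], d)
      RR <- re_part(R[r, , drop = FALSE], d); RI <- im_part(R[r, , drop = FALSE], d)
      TR <- re_part(E[t, , drop = FALSE], d); TI <- im_part(E[t, , drop = FALSE], d)
      list(
        dh = cbind(RR * TR + RI * TI, -RI * TR + RR * TI),
        dr = cbind(HR * TR + HI * TI, -HI * TR + HR * TI),
        dt = cbind(HR * RR - HI * RI, HR * RI + HI * RR)
      )
    },
    rotate = {
      HR <- re_part(E[h, , drop = FALSE], d); HI <- im_part(E[h, , drop = FALSE], d)
      TR <- re_part(E[t, , drop = FALSE], d); TI <- im_part(E[t, , drop = FALSE], d)
      ph <- R[r, , drop = FALSE]
      co <- cos(ph); si <- sin(ph)
      hrR <- HR * co - HI * si
      hrI <- HR * si + HI * co
      dR <- hrR - TR
      dI <- hrI - TI
      n <- sqrt(rowSums(dR^2 + dI^2)) + eps
      list(
        dh = cbind(-(dR * co + dI * si) / n, -(-dR * si + dI * co) / n),
        dr = (dR * hrI - dI * hrR) / n,
        dt = cbind(dR / n, dI / n)
      )
    }
  )
}

lookup_index <- function(values, universe, what) {
  idx <- match(values, universe)
  if (anyNA(idx)) {
    missing <- unique(values[is.na(idx)])
    abort(
      sprintf(
        "Unknown %s: %s.", what,
        paste(head(missing, 5L), collapse = ", ")
      ),
      class = "kge_lookup_error"
    )
  }
  idx
}

#' Score triples with an embedding model
#'
#' Interaction functions, all oriented so that higher means more plausible:
#' TransE \eqn{-\|h + r - t\|_2}; DistMult \eqn{\sum_i h_i r_i t_i};
#' ComplEx \eqn{Re(\sum_i h_i r_i \bar t_i)}; RotatE
#' \eqn{-\|h \circ r - t\|} with the complex Hadamard product and
#' unit-modulus relation phases.
#'
#' @param model A [kgem_init()] model.
#' @param triples Data frame with columns `head`, `relation`, `tail`, all
#'   known to the model.
#' @return Numeric score vector, one per row of `triples`.
#' @export
kgem_score <- function(model, triples) {
  stopifnot(inherits(model, "kgem_model"))
  assert_columns(triples, c("head", "relation", "tail"), "triples")
  if (nrow(triples) == 0L) return(numeric(0))
  h <- lookup_index(triples$head, model$entities, "entity(ies)")
  t <- lookup_index(triples$tail, model$entities, "entity(ies)")
  r <- lookup_index(triples$relation, model$relations, "relation(s)")
  interaction_score(model, h, r, t)
}

#' Train an embedding model with margin ranking loss and negative sampling
#'
#' Stochastic gradient descent on the margin ranking loss
#' \eqn{\max(0, \gamma - s(pos) + s(neg))}, with one corrupted triple per
#' positive per epoch replicate. Corruption is type-aware: a head is replaced
#' only by another entity of the same type (a drug by a drug, a disease by a
#' disease), which keeps training meaningful on small typed graphs. The side
#' to corrupt is chosen uniformly unless only one side admits a same-typed
#' replacement. TransE entity embeddings are renormalized to the unit sphere
#' after each epoch; RotatE phases are wrapped into `[0, 2*pi)`.
#'
#' @param model A [kgem_init()] model.
#' @param split A [split_drug_disease()] result; training runs on
#'   `split$train`.
#' @param epochs Number of passes over the training triples; `0` returns the
#'   model unchanged.
#' @param learning_rate SGD step size.
#' @param negatives_per_positive Corrupted triples sampled per positive per
#'   epoch (>= 1).
#' @param margin Margin \eqn{\gamma} of the ranking loss.
#' @param batch_size Triples per gradient step; `NULL` (default) uses full
#'   batches.
#' @param seed Integer seed for the corruption sampling.
#' @return The trained `kgem_model`; `$loss` holds the per-epoch mean loss.
#' @export
kgem_train <- function(model, split, epochs = 100L, learning_rate = 0.02,
                       negatives_per_positive = 1L, margin = 1,
                       batch_size = NULL, seed = 1L) {
  stopifnot(inherits(model, "kgem_model"), inherits(split, "kg_split"))
  if (epochs < 0L) abort("`epochs` must be >= 0.", class = "kge_config_error")
  if (negatives_per_positive < 1L) {
    abort("`negatives_per_positive` must be >= 1.", class = "kge_config_error")
  }
  if (nrow(split$train) == 0L) {
    abort("The training split is empty.", class = "kge_data_error")
  }
  if (epochs == 0L) return(model)

  trip <- split$train
  h <- lookup_index(trip$head, model$entities, "entity(ies)")
  t <- lookup_index(trip$tail, model$entities, "entity(ies)")
  r <- lookup_index(trip$relation, model$relations, "relation(s)")

  # Same-type replacement pools for corruption.
  type_of <- model$types
  pools <- split(seq_along(model$entities), type_of)
  pool_size <- vapply(pools, length, integer(1))
  head_ok <- pool_size[type_of[h]] > 1L
  tail_ok <- pool_size[type_of[t]] > 1L
  if (any(!head_ok & !tail_ok)) {
    abort(
      "No negatives constructible: some training triples have a single entity of each endpoint type.",
      class = "kge_training_error"
    )
  }

  n_pos <- length(h)
  reps <- as.integer(negatives_per_positive)
  loss_log <- numeric(epochs)

  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      hh <- rep(h, reps); tt <- rep(t, reps); rr <- rep(r, reps)
      h_ok <- rep(head_ok, reps); t_ok <- rep(tail_ok, reps)
      corrupt_head <- ifelse(h_ok & t_ok, runif(length(hh)) < 0.5, h_ok)
      orig <- ifelse(corrupt_head, hh, tt)
      pool_of <- type_of[orig]
      repl <- integer(length(orig))
      for (g in unique(pool_of)) {
        pool <- pools[[g]]
        I <- which(pool_of == g)
        # uniform over the pool minus the original, via the skip trick
        u <- ceiling(runif(length(I)) * (length(pool) - 1L))
        pos_orig <- match(orig[I], pool)
        repl[I] <- pool[u + (u >= pos_orig)]
      }
      nh <- ifelse(corrupt_head, repl, hh)
      nt <- ifelse(corrupt_head, tt, repl)

      batches <- if (is.null(batch_size)) {
        list(seq_along(hh))
      } else {
        split(sample.int(length(hh)), ceiling(seq_along(hh) / batch_size))
      }
      epoch_loss <- 0
      for (b in batches) {
        s_pos <- interaction_score(model, hh[b], rr[b], tt[b])
        s_neg <- interaction_score(model, nh[b], rr[b], nt[b])
        hinge <- pmax(0, margin - s_pos + s_neg)
        epoch_loss <- epoch_loss + sum(hinge)
        v <- which(hinge > 0)
        if (length(v) > 0L) {
          bp <- b[v]
          gp <- interaction_grad(model, hh[bp], rr[bp], tt[bp])
          gn <- interaction_grad(model, nh[bp], rr[bp], nt[bp])
          # ascend s_pos, descend s_neg
          ent_idx <- c(hh[bp], tt[bp], nh[bp], nt[bp])
          ent_grad <- rbind(gp$dh, gp$dt, -gn$dh, -gn$dt)
          upd <- rowsum(ent_grad, ent_idx)
          rows <- as.integer(rownames(upd))
          model$E[rows, ] <- model$E[rows, , drop = FALSE] +
            learning_rate * upd / reps
          rel_grad <- rbind(gp$dr, -gn$dr)
          updr <- rowsum(rel_grad, c(rr[bp], rr[bp]))
          rrows <- as.integer(rownames(updr))
          model$R[rrows, ] <- model$R[rrows, , drop = FALSE] +
            learning_rate * updr / reps
        }
      }
      if (model$interaction == "transe") {
        nrm <- sqrt(rowSums(model$E^2))
        nrm[nrm < 1e-12] <- 1
        model$E <- model$E / nrm
      } else if (model$interaction == "rotate") {
        model$R <- model$R %% (2 * pi)
      }
      loss_log[epoch] <- epoch_loss / (n_pos * reps)
    }
  })
  model$loss <- c(model$loss, loss_log)
  model
}

#' Score every candidate drug-disease pair with one model
#'
#' @param model A [kgem_init()] (usually [kgem_train()]-ed) model.
#' @param candidates A tibble `drug`/`disease` from [enumerate_candidates()].
#' @param relation The relation label to score (e.g. `"treats"`).
#' @return A score table: tibble `model`, `drug`, `disease`, `score` with one
#'   row per candidate pair; deterministic given the model.
#' @export
score_candidates <- function(model, candidates, relation) {
  stopifnot(inherits(model, "kgem_model"))
  assert_columns(candidates, c("drug", "disease"), "candidates")
  if (nrow(candidates) == 0L) {
    abort("The candidate space is empty.", class = "kge_data_error")
  }
  if (length(relation) != 1L) {
    abort("`relation` must be a single label.", class = "kge_config_error")
  }
  scores <- kgem_score(model, tibble(
    head = candidates$drug, relation = relation, tail = candidates$disease
  ))
  tibble(
    model = model$id,
    drug = candidates$drug,
    disease = candidates$disease,
    score = scores
  )
}
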