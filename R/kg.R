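#' Build a knowledge graph from triples and an entity-type table
#'
#' A knowledge graph here is a set of directed `(head, relation, tail)`
#' triples over typed entities. Entities are opaque, case-sensitive strings;
#' the biomedical schema used throughout this package types every entity as
#' `drug`, `protein` or `disease`, but arbitrary type labels are accepted
#' until [reduce_schema()] is applied.
#'
#' @param triples A data frame with character columns `head`, `relation`,
#'   `tail`. Duplicate rows are dropped (with a message giving the count).
#' @param entity_types A data frame with columns `entity`, `type` covering
#'   every entity appearing in `triples`.
#' @return An object of class `kg`: a list with tibbles `$triples` and
#'   `$entity_types`.
#' @examples
#' kg <- kg_new(
#'   tibble::tibble(head = "d1", relation = "treats", tail = "x1"),
#'   tibble::tibble(entity = c("d1", "x1"), type = c("drug", "disease"))
#' )
#' @export
kg_new <- function(triples, entity_types) {
  assert_columns(triples, c("head", "relation", "tail"), "triples")
  assert_columns(entity_types, c("entity", "type"), "entity_types")
  triples <- as_tibble(triples)[, c("head", "relation", "tail")]
  triples <- mutate(triples, across(all_of(c("head", "relation", "tail")), as.character))
  if (any(!nzchar(triples$head)) || any(!nzchar(triples$tail))) {
    abort("Triples with empty head or tail identifiers are not allowed.",
      class = "kge_parse_error"
    )
  }
  n0 <- nrow(triples)
  triples <- distinct(triples)
  if (nrow(triples) < n0) {
    inform(sprintf("Dropped %d duplicate triple(s).", n0 - nrow(triples)))
  }
  entity_types <- distinct(as_tibble(entity_types)[, c("entity", "type")])
  entity_types <- mutate(entity_types, across(all_of(c("entity", "type")), as.character))
  if (anyDuplicated(entity_types$entity)) {
    dup <- unique(entity_types$entity[duplicated(entity_types$entity)])
    abort(
      sprintf("Conflicting types for entit%s: %s.",
        if (length(dup) > 1L) "ies" else "y", paste(head(dup, 5L), collapse = ", ")),
      class = "kge_typing_error"
    )
  }
  seen <- unique(c(triples$head, triples$tail))
  untyped <- setdiff(seen, entity_types$entity)
  if (length(untyped) > 0L) {
    abort(
      sprintf(
        "%d entit%s without a type, e.g.: %s.",
        length(untyped), if (length(untyped) > 1L) "ies" else "y",
        paste(head(untyped, 5L), collapse = ", ")
      ),
      class = "kge_typing_error"
    )
  }
  structure(
    list(
      triples = arrange(triples, .data$head, .data$relation, .data$tail),
      entity_types = arrange(
        filter(entity_types, .data$entity %in% seen),
        .data$entity
      )
    ),
    class = "kg"
  )
}

#' @export
print.kg <- function(x, ...) {
  tab <- table(x$entity_types$type)
  cat(sprintf(
    "<knowledge graph> %d triples, %d entities (%s), %d relation types\n",
    nrow(x$triples), nrow(x$entity_types),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    dplyr::n_distinct(x$triples$relation)
  ))
  invisible(x)
}

entity_type_lookup <- function(kg) {
  setNames(kg$entity_types$type, kg$entity_types$entity)
}

#' Read a knowledge graph from tab-separated triple and entity-type files
#'
#' The triple file holds one directed triple per line, tab-separated as
#' `head \t relation \t tail` (UTF-8, no header unless `header = TRUE`).
#' Entity types come from a separate two-column TSV `entity \t type`, because
#' neither common triple-file dialect encodes node types.
#'
#' @param path Path to the triple TSV.
#' @param type_map_path Path to the entity-type TSV.
#' @param header Do the files carry a header line? Default `FALSE`.
#' @return A [kg_new()] object. Duplicate triples are dropped with a message.
#' @export
read_triples <- function(path, type_map_path, header = FALSE) {
  for (p in c(path, type_map_path)) {
    if (!file.exists(p)) {
      abort(sprintf("File not found: %s", p), class = "kge_io_error")
    }
  }
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf < 3L)
  if (header) bad <- setdiff(bad, 1L)
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "Malformed triple line(s) with fewer than 3 tab-separated fields: line %s.",
        paste(head(bad, 5L), collapse = ", ")
      ),
      class = "kge_parse_error"
    )
  }
  triples <- readr::read_tsv(
    path,
    col_names = if (header) TRUE else c("head", "relation", "tail"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(triples)[1:3] <- c("head", "relation", "tail")
  types <- readr::read_tsv(
    type_map_path,
    col_names = if (header) TRUE else c("entity", "type"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(types)[1:2] <- c("entity", "type")
  kg_new(triples[, 1:3], types[, 1:2])
}

#' Write a knowledge graph to triple and entity-type TSV files
#'
#' @param kg A [kg_new()] object.
#' @param path Output path for the triple TSV (no header).
#' @param type_map_path Optional output path for the entity-type TSV.
#' @return `kg`, invisibly.
#' @export
write_triples <- function(kg, path, type_map_path = NULL) {
  stopifnot(inherits(kg, "kg"))
  readr::write_tsv(kg$triples, path, col_names = FALSE, progress = FALSE)
  if (!is.null(type_map_path)) {
    readr::write_tsv(kg$entity_types, type_map_path, col_names = FALSE, progress = FALSE)
  }
  invisible(kg)
}

#' Reduce a knowledge graph to a type and relation whitelist
#'
#' Heterogeneous biomedical graphs carry node types (side effects, pathways,
#' phenotypes, ...) that are irrelevant to a drug-disease prediction task.
#' This keeps only triples whose two endpoints are both typed within
#' `keep_types`, and optionally only whitelisted relations (e.g. restricting
#' protein-protein edges to causal `activates`/`inhibits` interactions).
#' The entity-type table is pruned to surviving entities. Idempotent.
#'
#' @param kg A [kg_new()] object.
#' @param keep_types Character vector of entity types to keep. Default is the
#'   drug/protein/disease schema.
#' @param keep_relations Optional character vector of relation labels to keep;
#'   `NULL` (default) keeps all relations between surviving entities.
#' @return A reduced `kg` object. An empty result triggers a warning, not an
#'   error.
#' @export
reduce_schema <- function(kg,
                          keep_types = c("drug", "protein", "disease"),
                          keep_relations = NULL) {
  stopifnot(inherits(kg, "kg"))
  if (length(keep_types) == 0L) {
    abort("`keep_types` must be non-empty.", class = "kge_config_error")
  }
  type_of <- entity_type_lookup(kg)
  keep <- type_of[kg$triples$head] %in% keep_types &
    type_of[kg$triples$tail] %in% keep_types
  if (!is.null(keep_relations)) {
    keep <- keep & kg$triples$relation %in% keep_relations
  }
  triples <- kg$triples[keep, , drop = FALSE]
  if (nrow(triples) == 0L) {
    warn("Schema reduction removed every triple.")
    return(structure(
      list(
        triples = triples,
        entity_types = kg$entity_types[0, , drop = FALSE]
      ),
      class = "kg"
    ))
  }
  kg_new(triples, kg$entity_types)
}

# Drug -> disease triples: head typed drug, tail typed disease (directed).
drug_disease_mask <- function(kg) {
  type_of <- entity_type_lookup(kg)
  type_of[kg$triples$head] == "drug" & type_of[kg$triples$tail] == "disease"
}
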