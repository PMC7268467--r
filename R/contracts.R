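# The two contract-storage designs.
#
# Both keep three inverted-index mappings from field value to an array of
# integer IDs and answer wildcard queries by intersecting the ID arrays of
# the specified fields, looping over the shortest array. They differ in what
# an ID points to: the per-observation design stores every observation in
# its own struct and pools matches at query time; the pooled design keeps
# one count struct per unique gene-variant-drug combination, updated at
# insert time, so queries only convert counts to percentages.

OBS_STRUCT_FIELDS <- 6L   # gene, variant, drug, outcome, relation, sideEffect
REL_STRUCT_FIELDS <- 9L   # 3 combination fields + 6 counts

#' Generic contract operations
#'
#' `contract_insert()` inserts one observation and returns the assigned ID
#' (per-observation ID for the index design, combination ID for the pooled
#' design). `contract_query()` answers a wildcard query and returns an
#' aggregate-result data frame. Both dispatch on the contract class.
#'
#' @param state a [challenge_contract()] or [fastquery_contract()] state.
#' @param gene,variant,drug,outcome,relation,sideEffect observation fields,
#'   validated as in [observation()].
#' @param ... passed to methods.
#' @return `contract_insert()`: the integer ID. `contract_query()`: a data
#'   frame with one row per matching combination (see [empty_aggregate()]
#'   for the columns), in first-insertion order of combinations.
#' @export
contract_insert <- function(state, gene, variant, drug, outcome, relation,
                            sideEffect, ...) {
  UseMethod("contract_insert")
}

#' @rdname contract_insert
#' @param q a [query_triple()]; alternatively give `gene`/`variant`/`drug`
#'   patterns directly (default `"*"`).
#' @export
contract_query <- function(state, gene = "*", variant = "*", drug = "*",
                           q = NULL, ...) {
  UseMethod("contract_query")
}

# ---------------------------------------------------------------------------
# Shared query front end: minimum-array set intersection
# ---------------------------------------------------------------------------

# Returns the candidate IDs for a query triple. Absent keys read as the
# empty array, so a query naming an unseen value matches nothing. Each
# specified field's array is fetched from storage once (length + elements);
# the intersection itself runs in memory: starting from the shortest array,
# an ID is kept iff present in every other specified field's array.
intersect_candidates <- function(st, q) {
  specs <- list(gene = q$gene, variant = q$variant, drug = q$drug)
  specs <- specs[vapply(specs, function(f) !identical(f, "*"), logical(1))]
  if (length(specs) == 0L) {
    count <- stor_read(st, "globals", "counter")
    return(seq_len(count))
  }
  maps <- c(gene = "gene_ids", variant = "variant_ids", drug = "drug_ids")
  arrays <- lapply(names(specs), function(f)
    stor_read_array(st, maps[[f]], specs[[f]]))
  lens <- vapply(arrays, length, integer(1))
  if (any(lens == 0L)) return(integer(0))
  ids <- arrays[[which.min(lens)]]
  for (j in seq_along(arrays)) {
    if (j == which.min(lens)) next
    ids <- ids[ids %in% arrays[[j]]]
  }
  ids
}

resolve_query <- function(gene, variant, drug, q) {
  if (is.null(q)) q <- query_triple(gene, variant, drug)
  stopifnot(inherits(q, "query_triple"))
  q
}

# ---------------------------------------------------------------------------
# Index-based per-observation design ("challenge" design)
# ---------------------------------------------------------------------------

#' Create a per-observation multi-mapping contract state
#'
#' The index-based design: every observation is stored in its own struct in
#' the `database` mapping under a unique integer ID (IDs start at 1; 0 is
#' reserved as the absent value), with three inverted-index mappings from
#' gene / variant / drug value to ID arrays, and an append-only array of the
#' unique gene-variant-drug combinations seen so far (used to pool query
#' results). A key-presence mapping makes the uniqueness check at insert
#' time a single storage read.
#'
#' @param costs a [gas_costs()] table for the attached meter.
#' @return an environment of class `challenge_contract`.
#' @seealso [fastquery_contract()], [contract_insert()], [contract_query()]
#' @export
challenge_contract <- function(costs = gas_costs()) {
  state <- new.env(parent = emptyenv())
  state$storage <- contract_storage(gas_meter(costs))
  class(state) <- c("challenge_contract", "pgx_contract")
  state
}

#' @rdname contract_insert
#' @export
contract_insert.challenge_contract <- function(state, gene, variant, drug,
                                               outcome, relation, sideEffect,
                                               ...) {
  # (1) field conversion and validation; errors here leave storage untouched
  obs <- observation(gene, variant, drug, outcome, relation, sideEffect)
  key <- make_combination_key(obs$gene, obs$variant, obs$drug)
  st <- state$storage
  id <- as.integer(stor_read(st, "globals", "counter")) + 1L
  # (2) extend the unique-combination array iff the combination is new
  if (stor_read(st, "combo_seen", key) == 0) {
    stor_write(st, "combo_seen", key, 1L)
    stor_array_append(st, "unique_combinations", "all", key)
  }
  # (3) append the ID to the three inverted indexes
  stor_array_append(st, "gene_ids", obs$gene, id)
  stor_array_append(st, "variant_ids", obs$variant, id)
  stor_array_append(st, "drug_ids", obs$drug, id)
  # (4) store the observation struct
  stor_write_struct(st, "database", id,
                    list(gene = obs$gene, variant = obs$variant,
                         drug = obs$drug, outcome = obs$outcome,
                         relation = obs$relation, sideEffect = obs$sideEffect))
  # (5) advance the counter (the slot holds the number inserted so far)
  stor_write(st, "globals", "counter", id)
  id
}

#' @rdname contract_insert
#' @export
contract_query.challenge_contract <- function(state, gene = "*", variant = "*",
                                              drug = "*", q = NULL, ...) {
  q <- resolve_query(gene, variant, drug, q)
  st <- state$storage
  ids <- intersect_candidates(st, q)
  structs <- lapply(ids, function(id)
    stor_read_struct(st, "database", id, OBS_STRUCT_FIELDS))
  # pool the matched structs by combination, iterating the stored
  # unique-combination array so output order is first-insertion order
  combos <- stor_read_array(st, "unique_combinations", "all")
  if (length(structs) == 0L || length(combos) == 0L) return(empty_aggregate())
  struct_keys <- vapply(structs, function(s)
    make_combination_key(s$gene, s$variant, s$drug), character(1))
  grouped <- split(structs, factor(struct_keys, levels = combos))
  hit <- combos[combos %in% struct_keys]
  rows <- lapply(hit, function(ck) {
    grp <- grouped[[ck]]
    outcomes <- vapply(grp, `[[`, character(1), "outcome")
    s <- grp[[1L]]
    list(gene = s$gene, variant = s$variant, drug = s$drug,
         n = length(grp),
         side_effect = sum(vapply(grp, `[[`, logical(1), "sideEffect")),
         suspected = sum(vapply(grp, `[[`, logical(1), "relation")),
         improved = sum(outcomes == "IMPROVED"),
         deteriorated = sum(outcomes == "DETERIORATED"),
         unchanged = sum(outcomes == "UNCHANGED"))
  })
  build_aggregate(
    gene = vapply(rows, `[[`, character(1), "gene"),
    variant = vapply(rows, `[[`, character(1), "variant"),
    drug = vapply(rows, `[[`, character(1), "drug"),
    n = vapply(rows, `[[`, numeric(1), "n"),
    side_effect = vapply(rows, `[[`, numeric(1), "side_effect"),
    suspected = vapply(rows, `[[`, numeric(1), "suspected"),
    improved = vapply(rows, `[[`, numeric(1), "improved"),
    deteriorated = vapply(rows, `[[`, numeric(1), "deteriorated"),
    unchanged = vapply(rows, `[[`, numeric(1), "unchanged"))
}

#' Inspect contract state
#'
#' Unmetered accessors used by tests and reports: `contract_size()` is the
#' number of stored database entries (observations for the per-observation
#' design, unique combinations for the pooled one); `contract_counter()` is
#' the next ID to be assigned (always `1 + entries`);
#' `unique_combination_count()` counts distinct gene-variant-drug
#' combinations seen; `storage_slot_count()` counts occupied storage slots
#' (array lengths and struct fields included), the design's persistent
#' footprint.
#'
#' @param state a contract state.
#' @return an integer scalar.
#' @export
contract_size <- function(state) {
  stopifnot(inherits(state, "pgx_contract"))
  m <- state$storage$maps[["database"]]
  if (is.null(m)) 0L else length(ls(m))
}

#' @rdname contract_size
#' @export
contract_counter <- function(state) {
  m <- state$storage$maps[["globals"]]
  count <- if (is.null(m)) 0L else m[["counter"]] %||% 0L
  as.integer(count) + 1L
}

#' @rdname contract_size
#' @export
unique_combination_count <- function(state) {
  if (inherits(state, "fastquery_contract")) return(contract_size(state))
  m <- state$storage$maps[["unique_combinations"]]
  if (is.null(m)) 0L else length(m[["all"]])
}

#' @rdname contract_size
#' @export
storage_slot_count <- function(state) {
  contents <- storage_contents(state$storage)
  total <- 0L
  for (mp in names(contents)) {
    for (v in contents[[mp]]) {
      total <- total + if (is.list(v)) length(v)
                       else if (length(v) > 1L) length(v) + 1L  # array + length slot
                       else 1L
    }
  }
  total
}

#' @export
print.challenge_contract <- function(x, ...) {
  cat(sprintf("<challenge_contract %d observations, %d combinations, gas=%g>\n",
              contract_size(x), unique_combination_count(x), gas_total(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pooled per-combination design ("fastQuery" design)
# ---------------------------------------------------------------------------

#' Create a pooled per-combination contract state
#'
#' The pooled design: one count struct per unique gene-variant-drug
#' combination, found through a fifth mapping from combination key to
#' record ID (0 = absent, IDs start at 1). Inserting an observation
#' increments the combination's total, outcome, suspected-relation, and
#' side-effect counts in place, so the database grows with distinct
#' combinations only — there is a finite number of unique gene-variant-drug
#' relations, but no bound on raw observations.
#'
#' @param costs a [gas_costs()] table for the attached meter.
#' @return an environment of class `fastquery_contract`.
#' @seealso [challenge_contract()], [contract_insert()], [contract_query()]
#' @export
fastquery_contract <- function(costs = gas_costs()) {
  state <- new.env(parent = emptyenv())
  state$storage <- contract_storage(gas_meter(costs))
  class(state) <- c("fastquery_contract", "pgx_contract")
  state
}

#' @rdname contract_insert
#' @export
contract_insert.fastquery_contract <- function(state, gene, variant, drug,
                                               outcome, relation, sideEffect,
                                               ...) {
  # (1) field conversion and validation
  obs <- observation(gene, variant, drug, outcome, relation, sideEffect)
  key <- make_combination_key(obs$gene, obs$variant, obs$drug)
  st <- state$storage
  # (2) look the combination up in the fifth mapping; 0 means absent
  id <- stor_read(st, "combo_to_id", key)
  if (id == 0) {
    # (3-4) allocate a new relation record and index it
    id <- as.integer(stor_read(st, "globals", "counter")) + 1L
    stor_write(st, "combo_to_id", key, id)
    stor_write_struct(st, "database", id,
                      list(gene = obs$gene, variant = obs$variant,
                           drug = obs$drug))
    stor_array_append(st, "gene_ids", obs$gene, id)
    stor_array_append(st, "variant_ids", obs$variant, id)
    stor_array_append(st, "drug_ids", obs$drug, id)
    stor_write(st, "globals", "counter", id)
  }
  # (5) increment the pooled counts
  stor_bump_field(st, "database", id, "total")
  stor_bump_field(st, "database", id, switch(obs$outcome,
                                             IMPROVED = "improved",
                                             DETERIORATED = "deteriorated",
                                             UNCHANGED = "unchanged"))
  if (obs$relation) stor_bump_field(st, "database", id, "suspected")
  if (obs$sideEffect) stor_bump_field(st, "database", id, "side_effect")
  as.integer(id)
}

#' @rdname contract_insert
#' @export
contract_query.fastquery_contract <- function(state, gene = "*", variant = "*",
                                              drug = "*", q = NULL, ...) {
  q <- resolve_query(gene, variant, drug, q)
  st <- state$storage
  ids <- sort(intersect_candidates(st, q))   # ascending relation ID
  if (length(ids) == 0L) return(empty_aggregate())
  recs <- lapply(ids, function(id)
    stor_read_struct(st, "database", id, REL_STRUCT_FIELDS))
  g0 <- function(rec, f) rec[[f]] %||% 0L
  build_aggregate(
    gene = vapply(recs, `[[`, character(1), "gene"),
    variant = vapply(recs, `[[`, character(1), "variant"),
    drug = vapply(recs, `[[`, character(1), "drug"),
    n = vapply(recs, g0, numeric(1), "total"),
    side_effect = vapply(recs, g0, numeric(1), "side_effect"),
    suspected = vapply(recs, g0, numeric(1), "suspected"),
    improved = vapply(recs, g0, numeric(1), "improved"),
    deteriorated = vapply(recs, g0, numeric(1), "deteriorated"),
    unchanged = vapply(recs, g0, numeric(1), "unchanged"))
}

#' Read one pooled relation record
#'
#' Unmetered accessor returning the stored counts for a relation ID in the
#' pooled design, for inspection and tests.
#'
#' @param state a [fastquery_contract()] state.
#' @param id relation ID.
#' @return a named list with the combination fields and the six counts, or
#'   `NULL` if the ID is unused.
#' @export
relation_record <- function(state, id) {
  stopifnot(inherits(state, "fastquery_contract"))
  m <- state$storage$maps[["database"]]
  rec <- if (is.null(m)) NULL else m[[as.character(id)]]
  if (is.null(rec)) return(NULL)
  for (f in c("total", "improved", "deteriorated", "unchanged",
              "suspected", "side_effect"))
    rec[[f]] <- rec[[f]] %||% 0L
  rec
}

#' @export
print.fastquery_contract <- function(x, ...) {
  cat(sprintf("<fastquery_contract %d relations, gas=%g>\n",
              contract_size(x), gas_total(x)))
  invisible(x)
}
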