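# Synthetic observation streams, the brute-force query oracle, and the
# gas-based benchmark harness.
#
# The generator emulates a stream of pharmacogenomics observations: fields
# drawn independently and uniformly from finite pools of gene symbols,
# variant numbers, and drug names, outcomes by configurable weights, and
# independent Bernoulli flags. Duplicate gene-variant-drug combinations
# arise naturally from the pool sizes (and can be forced exactly with
# generate_duplicated_observations()).

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration of the synthetic observation generator
#'
#' Pool sizes default to 50 genes x 20 variants x 30 drugs (30,000 possible
#' combinations, so databases of a few thousand observations contain mostly
#' distinct combinations with a realistic minority of duplicates). Outcomes
#' are drawn with equal weight by default; the suspected-relation and
#' serious-side-effect flags default to rates of 0.5 and 0.3.
#'
#' @param n_observations number of observations to generate.
#' @param n_genes,n_variants,n_drugs pool sizes (>= 1).
#' @param outcome_weights three non-negative weights for
#'   improved / unchanged / deteriorated, not all zero.
#' @param p_suspected,p_side_effect flag probabilities in `[0, 1]`.
#' @param seed integer RNG seed; identical configurations generate
#'   identical streams.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_observations = 1000L, n_genes = 50L,
                             n_variants = 20L, n_drugs = 30L,
                             outcome_weights = c(1, 1, 1),
                             p_suspected = 0.5, p_side_effect = 0.3,
                             seed = 1L) {
  if (n_observations < 0L)
    pgx_error("pgx_validation_error", "n_observations must be >= 0")
  if (min(n_genes, n_variants, n_drugs) < 1L)
    pgx_error("pgx_validation_error", "pool sizes must be >= 1")
  if (length(outcome_weights) != 3L || any(outcome_weights < 0) ||
      sum(outcome_weights) == 0)
    pgx_error("pgx_validation_error",
              "outcome_weights must be 3 non-negative weights, not all zero")
  if (p_suspected < 0 || p_suspected > 1 || p_side_effect < 0 || p_side_effect > 1)
    pgx_error("pgx_validation_error", "flag probabilities must be in [0, 1]")
  structure(list(n_observations = as.integer(n_observations),
                 n_genes = as.integer(n_genes),
                 n_variants = as.integer(n_variants),
                 n_drugs = as.integer(n_drugs),
                 outcome_weights = as.numeric(outcome_weights),
                 p_suspected = p_suspected, p_side_effect = p_side_effect,
                 seed = as.integer(seed)),
            class = "generator_config")
}

gene_pool <- function(cfg) sprintf("GENE%03d", seq_len(cfg$n_genes))
variant_pool <- function(cfg) seq_len(cfg$n_variants)
drug_pool <- function(cfg) sprintf("drug%03d", seq_len(cfg$n_drugs))

#' Generate a synthetic observation stream
#'
#' Draws `cfg$n_observations` observations with fields independent and
#' uniform over the configured pools, outcomes by `cfg$outcome_weights`, and
#' flags Bernoulli with the configured rates. Identical seeds yield
#' identical tables.
#'
#' @param cfg a [generator_config()].
#' @return a canonical observation data frame (see [read_observations()]).
#' @export
generate_observations <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_observations
  with_preserved_rng(cfg$seed, {
    data.frame(
      gene = sample(gene_pool(cfg), n, replace = TRUE),
      variant = sample(variant_pool(cfg), n, replace = TRUE),
      drug = sample(drug_pool(cfg), n, replace = TRUE),
      outcome = sample(OUTCOME_LEVELS, n, replace = TRUE,
                       prob = cfg$outcome_weights / sum(cfg$outcome_weights)),
      relation = stats::runif(n) < cfg$p_suspected,
      sideEffect = stats::runif(n) < cfg$p_side_effect,
      stringsAsFactors = FALSE)
  })
}

#' Generate observations with an exact duplicate structure
#'
#' Draws `n_combinations` distinct gene-variant-drug triples from the
#' configured pools (controlled by `combination_seed`, so the same
#' combination set can be reused while the duplication factor varies) and
#' emits each exactly `n_duplicates` times with freshly drawn outcomes and
#' flags, in shuffled order. Used to separate growth in raw observations
#' from growth in distinct combinations.
#'
#' @param cfg a [generator_config()]; pools must allow `n_combinations`
#'   distinct triples.
#' @param n_combinations number of distinct combinations.
#' @param n_duplicates observations per combination.
#' @param combination_seed seed controlling which combinations are drawn
#'   (defaults to `cfg$seed`).
#' @return a canonical observation data frame with
#'   `n_combinations * n_duplicates` rows.
#' @export
generate_duplicated_observations <- function(cfg, n_combinations, n_duplicates,
                                             combination_seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  n_pool <- cfg$n_genes * cfg$n_variants * cfg$n_drugs
  if (n_combinations > n_pool)
    pgx_error("pgx_validation_error",
              sprintf("pools support only %d distinct combinations", n_pool))
  combos <- with_preserved_rng(combination_seed, {
    idx <- sample.int(n_pool, n_combinations)
    g <- gene_pool(cfg)[((idx - 1L) %% cfg$n_genes) + 1L]
    v <- variant_pool(cfg)[(((idx - 1L) %/% cfg$n_genes) %% cfg$n_variants) + 1L]
    d <- drug_pool(cfg)[((idx - 1L) %/% (cfg$n_genes * cfg$n_variants)) + 1L]
    data.frame(gene = g, variant = v, drug = d, stringsAsFactors = FALSE)
  })
  n <- n_combinations * n_duplicates
  with_preserved_rng(cfg$seed, {
    rows <- sample(rep(seq_len(n_combinations), n_duplicates))
    data.frame(
      gene = combos$gene[rows], variant = combos$variant[rows],
      drug = combos$drug[rows],
      outcome = sample(OUTCOME_LEVELS, n, replace = TRUE,
                       prob = cfg$outcome_weights / sum(cfg$outcome_weights)),
      relation = stats::runif(n) < cfg$p_suspected,
      sideEffect = stats::runif(n) < cfg$p_side_effect,
      stringsAsFactors = FALSE)
  })
}

#' Generate random query triples
#'
#' Each triple specifies exactly `n_ands + 1` of the three fields; which
#' fields are specified is chosen uniformly, and specified values are drawn
#' uniformly from the generator pools (so a query can legitimately match
#' nothing).
#'
#' @param cfg a [generator_config()] supplying the value pools.
#' @param n_queries number of triples.
#' @param n_ands 0, 1, or 2 (a query naming k fields is a (k-1)-AND query).
#' @param seed RNG seed.
#' @param from optional observation data frame; when given, each query's
#'   specified values are taken from one uniformly drawn row (so the query
#'   is guaranteed to match at least that observation) instead of being
#'   drawn from the pools.
#' @return a list of [query_triple()] objects.
#' @export
generate_queries <- function(cfg, n_queries = 100L, n_ands = 0L,
                             seed = cfg$seed, from = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!n_ands %in% 0:2)
    pgx_error("pgx_validation_error", "n_ands must be 0, 1, or 2")
  k <- n_ands + 1L
  position_sets <- utils::combn(3L, k, simplify = FALSE)
  with_preserved_rng(seed, {
    lapply(seq_len(n_queries), function(i) {
      fields <- c("*", "*", "*")
      pos <- position_sets[[sample.int(length(position_sets), 1L)]]
      if (is.null(from)) {
        if (1L %in% pos) fields[1L] <- sample(gene_pool(cfg), 1L)
        if (2L %in% pos) fields[2L] <- as.character(sample(variant_pool(cfg), 1L))
        if (3L %in% pos) fields[3L] <- sample(drug_pool(cfg), 1L)
      } else {
        row <- from[sample.int(nrow(from), 1L), ]
        if (1L %in% pos) fields[1L] <- row$gene
        if (2L %in% pos) fields[2L] <- as.character(row$variant)
        if (3L %in% pos) fields[3L] <- row$drug
      }
      query_triple(fields[1L], fields[2L], fields[3L])
    })
  })
}

# ---------------------------------------------------------------------------
# Brute-force oracle
# ---------------------------------------------------------------------------

#' Brute-force reference query
#'
#' Independent ground truth for both contract designs: a linear scan over a
#' plain observation table, filtering on the non-wildcard fields, grouping
#' by gene-variant-drug combination (length-prefixed grouping keys, built
#' here without any contract code), counting, and converting counts to
#' percentages. It touches no contract storage and no gas meter.
#'
#' @param obs a canonical observation data frame.
#' @param q a [query_triple()].
#' @return an aggregate-result data frame in first-appearance order of
#'   combinations, identical in schema and content to [contract_query()].
#' @export
oracle_query <- function(obs, q) {
  stopifnot(inherits(q, "query_triple"))
  if (nrow(obs) == 0L) return(empty_aggregate())
  keep <- rep(TRUE, nrow(obs))
  if (q$gene != "*") keep <- keep & obs$gene == q$gene
  if (q$variant != "*") keep <- keep & as.character(obs$variant) == q$variant
  if (q$drug != "*") keep <- keep & obs$drug == q$drug
  hits <- obs[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_aggregate())
  gkey <- paste0(nchar(hits$gene, type = "bytes"), ".", hits$gene, "/",
                 nchar(as.character(hits$variant)), ".", hits$variant, "/",
                 nchar(hits$drug, type = "bytes"), ".", hits$drug)
  grp <- factor(gkey, levels = unique(gkey))   # first-appearance order
  first <- !duplicated(gkey)
  n <- as.vector(table(grp))
  sum_by <- function(x) as.vector(rowsum(as.numeric(x), grp))
  build_aggregate(
    gene = hits$gene[first], variant = hits$variant[first],
    drug = hits$drug[first], n = n,
    side_effect = sum_by(hits$sideEffect),
    suspected = sum_by(hits$relation),
    improved = sum_by(hits$outcome == "IMPROVED"),
    deteriorated = sum_by(hits$outcome == "DETERIORATED"),
    unchanged = sum_by(hits$outcome == "UNCHANGED"))
}

# ---------------------------------------------------------------------------
# Benchmark harness
# ---------------------------------------------------------------------------

#' Run the gas-based scaling benchmark
#'
#' For every design x database size, inserts a fresh synthetic database and
#' then runs `n_queries` seeded random queries in each query class,
#' recording storage-operation counts and gas. Wall-clock and memory are
#' deliberately not measured: per-operation storage counts and gas are
#' hardware-independent and capture the same asymptotic behaviour. One
#' record is emitted per design x size for insertion (totals over the whole
#' build) and one per design x size x query class (means per query).
#'
#' @param designs subset of `c("challenge", "fastquery")`.
#' @param db_sizes ascending database sizes.
#' @param n_ands_list query classes: 0, 1, 2, and/or `"full"` (the
#'   all-wildcard query).
#' @param cfg a [generator_config()] template; its `n_observations` is
#'   overridden per cell.
#' @param n_queries queries per cell.
#' @param costs gas cost table.
#' @param seed base seed; per-cell seeds are derived deterministically.
#' @return a data frame of benchmark records with columns `design`,
#'   `operation`, `n_ands`, `db_size`, `gas_total`, `sload`, `sstore_new`,
#'   `sstore_update`, `result_rows`, `n_queries`.
#' @export
run_benchmark <- function(designs = c("challenge", "fastquery"),
                          db_sizes = c(100L, 500L, 1000L),
                          n_ands_list = list(0L, 1L, 2L, "full"),
                          cfg = generator_config(),
                          n_queries = 100L, costs = gas_costs(),
                          seed = cfg$seed) {
  designs <- match.arg(designs, several.ok = TRUE)
  if (is.unsorted(db_sizes))
    pgx_error("pgx_validation_error", "db_sizes must be sorted ascending")
  records <- list()
  for (design in designs) {
    for (si in seq_along(db_sizes)) {
      size <- db_sizes[[si]]
      cell_cfg <- cfg
      cell_cfg$n_observations <- as.integer(size)
      cell_cfg$seed <- as.integer(seed + si)
      obs <- generate_observations(cell_cfg)
      state <- if (design == "challenge") challenge_contract(costs)
               else fastquery_contract(costs)
      before <- meter_snapshot(state)
      insert_batch(state, obs)
      after <- meter_snapshot(state)
      records[[length(records) + 1L]] <- data.frame(
        design = design, operation = "insert", n_ands = NA_character_,
        db_size = size,
        gas_total = after[["gas"]] - before[["gas"]],
        sload = after[["sload"]] - before[["sload"]],
        sstore_new = after[["sstore_new"]] - before[["sstore_new"]],
        sstore_update = after[["sstore_update"]] - before[["sstore_update"]],
        result_rows = NA_real_, n_queries = NA_integer_,
        stringsAsFactors = FALSE)

      for (na in n_ands_list) {
        queries <- if (identical(na, "full")) {
          replicate(n_queries, query_triple(), simplify = FALSE)
        } else {
          generate_queries(cell_cfg, n_queries, as.integer(na),
                           seed = as.integer(seed + 100L * si + 10L * (as.integer(na) + 1L)))
        }
        before <- meter_snapshot(state)
        rows <- 0
        for (qq in queries) rows <- rows + nrow(contract_query(state, q = qq))
        after <- meter_snapshot(state)
        records[[length(records) + 1L]] <- data.frame(
          design = design, operation = "query",
          n_ands = as.character(na), db_size = size,
          gas_total = (after[["gas"]] - before[["gas"]]) / n_queries,
          sload = (after[["sload"]] - before[["sload"]]) / n_queries,
          sstore_new = (after[["sstore_new"]] - before[["sstore_new"]]) / n_queries,
          sstore_update = (after[["sstore_update"]] - before[["sstore_update"]]) / n_queries,
          result_rows = rows / n_queries, n_queries = n_queries,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, records)
}

#' Write a benchmark table to a delimited file
#'
#' @param records a [run_benchmark()] data frame.
#' @param path output path (tab-delimited with header).
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Plot mean query gas against database size
#'
#' One line per design x query class, log-scaled gas axis; a visual
#' companion to the benchmark table.
#'
#' @param records a [run_benchmark()] data frame.
#' @param file optional PNG path; `NULL` draws on the active device.
#' @return `NULL`, invisibly.
#' @export
plot_benchmark <- function(records, file = NULL) {
  qr <- records[records$operation == "query", , drop = FALSE]
  if (nrow(qr) == 0L) return(invisible(NULL))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  groups <- split(qr, interaction(qr$design, qr$n_ands, drop = TRUE))
  cols <- seq_along(groups)
  graphics::plot(range(qr$db_size), range(qr$gas_total), type = "n",
                 log = "y", xlab = "database size (observations)",
                 ylab = "mean gas per query")
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    graphics::lines(g$db_size, g$gas_total, col = cols[i], type = "b",
                    pch = 19)
  }
  graphics::legend("topleft", legend = names(groups), col = cols, lty = 1,
                   pch = 19, cex = 0.8)
  invisible(NULL)
}
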