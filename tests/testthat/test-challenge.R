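insert_example <- function(state) {
  ex <- example_observation()
  contract_insert(state, ex$gene, ex$variant, ex$drug, ex$outcome,
                  ex$relation, ex$sideEffect)
}

test_that("inserting the worked example populates all four mappings", {
  ch <- challenge_contract()
  id <- insert_example(ch)
  expect_identical(id, 1L)
  expect_identical(contract_counter(ch), 2L)
  expect_identical(contract_size(ch), 1L)
  expect_identical(unique_combination_count(ch), 1L)
  maps <- ch$storage$maps
  expect_identical(maps$gene_ids[["CYP3A5"]], 1L)
  expect_identical(maps$variant_ids[["52"]], 1L)
  expect_identical(maps$drug_ids[["pegloticase"]], 1L)
  expect_identical(maps$database[["1"]]$outcome, "UNCHANGED")
})

test_that("duplicate combinations get fresh IDs but no new combination entry", {
  ch <- challenge_contract()
  insert_example(ch)
  id2 <- insert_example(ch)
  expect_identical(id2, 2L)
  expect_identical(contract_size(ch), 2L)
  expect_identical(unique_combination_count(ch), 1L)
  expect_identical(ch$storage$maps$gene_ids[["CYP3A5"]], c(1L, 2L))
})

test_that("combination count tracks distinct triples only", {
  obs <- rbind(obs_row("G1", 1, "d1"), obs_row("G1", 1, "d1"),
               obs_row("G1", 2, "d1"), obs_row("G2", 1, "d1"),
               obs_row("G1", 2, "d1"))
  ch <- insert_df(challenge_contract(), validate_observations(obs))
  expect_identical(contract_size(ch), 5L)
  # brute-force distinct-triple count on the same list
  expect_identical(unique_combination_count(ch),
                   nrow(unique(obs[c("gene", "variant", "drug")])))
})

test_that("queries on an empty database return an empty result", {
  ch <- challenge_contract()
  expect_same_aggregates(contract_query(ch), empty_aggregate())
  expect_same_aggregates(contract_query(ch, gene = "CYP3A5"),
                         empty_aggregate())
})

test_that("a single-field query aggregates the worked example", {
  ch <- challenge_contract()
  insert_example(ch)
  res <- contract_query(ch, gene = "CYP3A5")
  expect_identical(nrow(res), 1L)
  expect_identical(res$n_observations, 1L)
  expect_identical(res$unchanged_count, 1L)
  expect_identical(res$unchanged_pct, 100)
  expect_identical(res$side_effect_pct, 100)
  expect_identical(res$suspected_pct, 100)
  expect_identical(res$improved_pct, 0)
  # unknown values and malformed wildcard tokens are literal non-matches
  expect_identical(nrow(contract_query(ch, gene = "CYP3A4")), 0L)
  expect_identical(nrow(contract_query(ch, gene = "**")), 0L)
})

test_that("queries are read-only: storage is bit-identical afterwards", {
  ch <- insert_df(challenge_contract(),
                  validate_observations(adversarial_observations(25L, 31L)))
  before <- pgxchain:::storage_contents(ch$storage)
  gas_before <- gas_total(ch)
  contract_query(ch)
  contract_query(ch, gene = "G|1", variant = 2)
  expect_identical(pgxchain:::storage_contents(ch$storage), before)
  expect_gt(gas_total(ch), gas_before)  # reads were charged
})

test_that("a failed insert leaves no partial state", {
  ch <- challenge_contract()
  insert_example(ch)
  before <- pgxchain:::storage_contents(ch$storage)
  gas_before <- gas_total(ch)
  expect_error(contract_insert(ch, strrep("g", 33), 1, "d", "IMPROVED",
                               TRUE, FALSE),
               class = "pgx_encoding_error")
  expect_error(contract_insert(ch, "G", -1, "d", "IMPROVED", TRUE, FALSE),
               class = "pgx_validation_error")
  expect_identical(pgxchain:::storage_contents(ch$storage), before)
  expect_identical(gas_total(ch), gas_before)
})

test_that("intersection queries match the brute-force oracle", {
  cfg <- generator_config(n_observations = 200L, n_genes = 5L, n_variants = 4L,
                          n_drugs = 3L, seed = 41L)
  obs <- generate_observations(cfg)
  ch <- insert_df(challenge_contract(), obs)
  fq <- insert_df(fastquery_contract(), obs)
  for (ands in 0:2) {
    queries <- generate_queries(cfg, 30L, ands, seed = 50L + ands)
    for (q in queries) expect_matches_oracle(ch, fq, obs, q)
  }
  expect_matches_oracle(ch, fq, obs, query_triple())  # full database
})

test_that("2-AND query gas ignores unrelated duplicates but grows with matches", {
  base <- rbind(obs_row("G1", 1, "d1"), obs_row("G2", 2, "d2"),
                obs_row("G3", 3, "d3"))
  ch <- insert_df(challenge_contract(), validate_observations(base))
  q <- query_triple("G1", 1, "d1")
  g1 <- gas_of(ch, contract_query(ch, q = q))[["gas"]]

  # duplicates of other combinations share no queried value and no new
  # combination: the fixed query's gas must not move
  filler <- validate_observations(
    rbind(obs_row("G2", 2, "d2"), obs_row("G3", 3, "d3")))
  insert_df(ch, filler[rep(1:2, 10), ])
  g2 <- gas_of(ch, contract_query(ch, q = q))[["gas"]]
  expect_identical(g2, g1)

  # each additional matching observation adds a constant gas increment
  # (its index entries plus its struct read): at most linear growth
  deltas <- vapply(1:5, function(i) {
    insert_df(ch, validate_observations(obs_row("G1", 1, "d1")))
    gas_of(ch, contract_query(ch, q = q))[["gas"]]
  }, numeric(1))
  increments <- diff(c(g2, deltas))
  expect_true(all(increments > 0))
  expect_identical(length(unique(increments)), 1L)  # exactly linear
})

test_that("insertion gas does not grow with database size", {
  cfg <- generator_config(n_observations = 120L, n_genes = 4L,
                          n_variants = 3L, n_drugs = 3L, seed = 61L)
  obs <- generate_observations(cfg)
  ch <- challenge_contract()
  insert_df(ch, obs)
  # once every value and combination has been seen, a repeat insert costs a
  # fixed amount no matter how large the database already is
  rep_row <- obs[1, ]
  g_small <- gas_of(ch, insert_df(ch, rep_row))[["gas"]]
  insert_df(ch, obs)
  g_large <- gas_of(ch, insert_df(ch, rep_row))[["gas"]]
  expect_identical(g_small, g_large)
})
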