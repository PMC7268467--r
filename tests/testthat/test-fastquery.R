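test_that("the worked example creates one pooled relation with unit counts", {
  fq <- fastquery_contract()
  ex <- example_observation()
  id <- contract_insert(fq, ex$gene, ex$variant, ex$drug, ex$outcome,
                        ex$relation, ex$sideEffect)
  expect_identical(id, 1L)
  rec <- relation_record(fq, 1L)
  expect_identical(rec$gene, "CYP3A5")
  expect_identical(rec$total, 1L)
  expect_identical(rec$unchanged, 1L)
  expect_identical(rec$suspected, 1L)
  expect_identical(rec$side_effect, 1L)
  expect_identical(rec$improved, 0L)

  # a repeat insert pools into the same record; the counter does not move
  id2 <- contract_insert(fq, ex$gene, ex$variant, ex$drug, ex$outcome,
                         ex$relation, ex$sideEffect)
  expect_identical(id2, 1L)
  expect_identical(contract_size(fq), 1L)
  expect_identical(contract_counter(fq), 2L)
  rec2 <- relation_record(fq, 1L)
  expect_identical(rec2$total, 2L)
  expect_identical(rec2$unchanged, 2L)
})

test_that("pooled counts equal brute-force group-by tallies", {
  cfg <- generator_config(n_observations = 1000L, n_genes = 5L,
                          n_variants = 4L, n_drugs = 3L, seed = 13L)
  obs <- generate_observations(cfg)
  fq <- insert_df(fastquery_contract(), obs)
  expect_lte(contract_size(fq), 60L)  # at most 5 x 4 x 3 combinations
  expect_identical(contract_size(fq),
                   nrow(unique(obs[c("gene", "variant", "drug")])))
  # every pooled record against an independent linear-scan tally
  for (id in seq_len(contract_size(fq))) {
    rec <- relation_record(fq, id)
    rows <- obs[obs$gene == rec$gene &
                  as.character(obs$variant) == rec$variant &
                  obs$drug == rec$drug, ]
    expect_identical(rec$total, nrow(rows))
    expect_identical(rec$improved, sum(rows$outcome == "IMPROVED"))
    expect_identical(rec$deteriorated, sum(rows$outcome == "DETERIORATED"))
    expect_identical(rec$unchanged, sum(rows$outcome == "UNCHANGED"))
    expect_identical(rec$suspected, sum(rows$relation))
    expect_identical(rec$side_effect, sum(rows$sideEffect))
  }
})

test_that("stored counts convert to percentages on query", {
  fq <- fastquery_contract()
  rows <- rbind(obs_row("G", 5, "d", "IMPROVED", TRUE, FALSE),
                obs_row("G", 5, "d", "IMPROVED", TRUE, FALSE),
                obs_row("G", 5, "d", "UNCHANGED", TRUE, FALSE),
                obs_row("G", 5, "d", "DETERIORATED", FALSE, FALSE))
  insert_df(fq, validate_observations(rows))
  res <- contract_query(fq, "G", 5, "d")
  expect_identical(res$n_observations, 4L)
  expect_identical(res$improved_pct, 50)     # 100 * 2 / 4
  expect_identical(res$unchanged_pct, 25)
  expect_identical(res$deteriorated_pct, 25)
  expect_identical(res$suspected_pct, 75)    # 100 * 3 / 4
  expect_identical(res$side_effect_pct, 0)
  expect_identical(res$improved_count + res$deteriorated_count +
                     res$unchanged_count, res$n_observations)
})

test_that("empty and unmatched queries return empty results", {
  fq <- fastquery_contract()
  expect_same_aggregates(contract_query(fq), empty_aggregate())
  insert_df(fq, example_observation())
  expect_identical(nrow(contract_query(fq, gene = "ABCB1")), 0L)
})

test_that("both designs and the oracle agree on any insertion stream", {
  set.seed(23)
  for (scenario in 1:25) {
    n <- sample(0:30, 1)
    obs <- adversarial_observations(max(n, 1L), seed = 1000L + scenario)[seq_len(n), ]
    obs <- validate_observations(obs)
    ch <- insert_df(challenge_contract(), obs)
    fq <- insert_df(fastquery_contract(), obs)
    pick <- function() {
      if (nrow(obs) == 0L || runif(1) < 0.3) return(sample(c("Gx", "1", "zz"), 1))
      r <- obs[sample.int(nrow(obs), 1), ]
      sample(c(r$gene, as.character(r$variant), r$drug), 1)
    }
    for (j in 1:4) {
      fields <- c("*", "*", "*")
      for (pos in sample(1:3, sample(0:3, 1)))
        fields[pos] <- if (pos == 2 && runif(1) < 0.8 && nrow(obs) > 0)
          as.character(obs$variant[sample.int(nrow(obs), 1)]) else pick()
      q <- query_triple(fields[1], fields[2], fields[3])
      expect_matches_oracle(ch, fq, obs, q)
    }
  }
})

test_that("pooled storage grows with combinations, indexed with observations", {
  cfg <- generator_config(n_genes = 6L, n_variants = 3L, n_drugs = 3L,
                          seed = 77L)
  small <- generate_duplicated_observations(cfg, n_combinations = 20L,
                                            n_duplicates = 3L)
  big <- generate_duplicated_observations(cfg, n_combinations = 20L,
                                          n_duplicates = 30L)
  fq_small <- insert_df(fastquery_contract(), small)
  fq_big <- insert_df(fastquery_contract(), big)
  ch_small <- insert_df(challenge_contract(), small)
  ch_big <- insert_df(challenge_contract(), big)
  # pooled footprint is bounded by the distinct combinations alone: at most
  # 16 slots per relation (combination key slot, <= 9 struct fields, three
  # index entries and length slots) plus the counter, however many
  # duplicates arrive
  expect_identical(contract_size(fq_big), 20L)
  expect_identical(contract_size(fq_small), 20L)
  expect_lte(storage_slot_count(fq_big), 16L * 20L + 1L)
  # per-observation footprint keeps growing with duplicates
  expect_gt(storage_slot_count(ch_big), 5 * storage_slot_count(ch_small))
})

test_that("relation IDs appear exactly once per field index", {
  obs <- validate_observations(adversarial_observations(40L, seed = 3L))
  fq <- insert_df(fastquery_contract(), obs)
  for (mp in c("gene_ids", "variant_ids", "drug_ids")) {
    m <- fq$storage$maps[[mp]]
    all_ids <- sort(unlist(lapply(ls(m), function(k) m[[k]])))
    expect_identical(all_ids, seq_len(contract_size(fq)))
  }
})
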