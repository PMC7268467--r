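# Shared fixtures and comparison helpers, all built in code.

# Insert every row of a data frame into a contract, no ledger.
insert_df <- function(state, df) {
  for (i in seq_len(nrow(df)))
    contract_insert(state, df$gene[i], df$variant[i], df$drug[i],
                    df$outcome[i], df$relation[i], df$sideEffect[i])
  state
}

# One observation row with defaults, for terse test setup.
obs_row <- function(gene = "G1", variant = 1L, drug = "d1",
                    outcome = "IMPROVED", relation = FALSE,
                    sideEffect = FALSE) {
  data.frame(gene = gene, variant = variant, drug = drug, outcome = outcome,
             relation = relation, sideEffect = sideEffect,
             stringsAsFactors = FALSE)
}

# Observation stream with adversarial text fields: separators, quotes,
# whitespace-adjacent characters, and multibyte UTF-8 in drug names.
adversarial_observations <- function(n, seed) {
  genes <- c("G1", "G|1", "G:1", "1:G", "TP53", "BRCA1")
  drugs <- c("d", "d|2|x", "2:d", 'quo"ted', "comma,drug", "a b c",
             "naïve-42", "d1|", "|d1")
  set.seed(seed)
  data.frame(
    gene = sample(genes, n, replace = TRUE),
    variant = sample(0:3, n, replace = TRUE),
    drug = sample(drugs, n, replace = TRUE),
    outcome = sample(OUTCOME_LEVELS, n, replace = TRUE),
    relation = sample(c(TRUE, FALSE), n, replace = TRUE),
    sideEffect = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Aggregate-result equality up to row names.
expect_same_aggregates <- function(actual, expected) {
  rownames(actual) <- NULL
  rownames(expected) <- NULL
  expect_equal(actual, expected)
}

# Run the same query against both designs and the oracle; both designs must
# reproduce the oracle exactly.
expect_matches_oracle <- function(ch, fq, obs, q) {
  expected <- oracle_query(obs, q)
  expect_same_aggregates(contract_query(ch, q = q), expected)
  expect_same_aggregates(contract_query(fq, q = q), expected)
}

# Deterministic gas-hand-count helper: gas of one scoped expression.
gas_of <- function(state, expr) {
  before <- meter_snapshot(state)
  force(expr)
  meter_snapshot(state) - before
}
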