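# Minimal hash-linked, single-sealer ledger.
#
# Consensus is a single deterministic sealer (proof of authority with one
# authority): there is no transaction pool, voting, or networking, which
# leaves the storage and query semantics under study untouched. Blocks batch
# insert transactions; read-only query calls are metered but never recorded.

ZERO_DIGEST <- strrep("0", 64)

#' Cryptographic digests
#'
#' Hex digest of a character scalar (hashed as its UTF-8 bytes) or raw
#' vector. `keccak256()` is the original Keccak (the hash Ethereum uses, with
#' multi-rate padding 0x01, distinct from NIST SHA3); `sha256()` is FIPS
#' SHA-256.
#'
#' @param x a character scalar or raw vector.
#' @return a 64-character lower-case hex digest.
#' @examples
#' keccak256("")  # c5d2460186f7233c927e7db2dcc703c0e500b653ca82273b7bfad8045d85a456
#' @export
keccak256 <- function(x) pgx_digest(x, "keccak256")

#' @rdname keccak256
#' @export
sha256 <- function(x) pgx_digest(x, "sha256")

pgx_digest <- function(x, algorithm) {
  if (is.character(x)) x <- charToRaw(enc2utf8(x))
  if (!is.raw(x))
    pgx_error("pgx_validation_error", "digest input must be character or raw")
  .digest_hex(x, algorithm)
}

# ---------------------------------------------------------------------------
# Transactions
# ---------------------------------------------------------------------------

#' Create a transaction
#'
#' One contract call recorded on the ledger: an opaque submitter identifier,
#' the canonical serialization of the call (a JSON string), and the gas the
#' call consumed. The ledger assigns the strictly increasing `tx_index` when
#' the transaction is sealed into a block.
#'
#' @param payload canonical serialization of the contract call.
#' @param submitter opaque submitter identifier.
#' @param gas_used gas units charged to the call.
#' @return an object of class `pgx_transaction`.
#' @export
transaction <- function(payload, submitter = "client", gas_used = 0) {
  stopifnot(is.character(payload), length(payload) == 1L)
  structure(list(tx_index = NA_integer_, submitter = as.character(submitter),
                 payload = payload, gas_used = as.numeric(gas_used)),
            class = "pgx_transaction")
}

json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

tx_canonical <- function(tx) {
  sprintf('{"tx_index":%d,"submitter":"%s","payload":"%s","gas_used":%s}',
          tx$tx_index, json_escape(tx$submitter), json_escape(tx$payload),
          format(tx$gas_used, scientific = FALSE))
}

payload_digest <- function(txs, algorithm) {
  body <- paste(vapply(txs, tx_canonical, character(1)), collapse = "\n")
  pgx_digest(body, algorithm)
}

header_digest <- function(block_number, timestamp, prev_hash, payload_hash,
                          algorithm) {
  pgx_digest(sprintf("%d|%s|%s|%s", block_number,
                     format(timestamp, scientific = FALSE),
                     prev_hash, payload_hash),
             algorithm)
}

# ---------------------------------------------------------------------------
# Ledger
# ---------------------------------------------------------------------------

#' Create a ledger with its genesis block
#'
#' An append-only chain of blocks, each holding the hash of the previous
#' block's header, so that any alteration of a sealed block changes every
#' downstream hash. The genesis block (number 0, all-zero previous hash)
#' records the digest algorithm in its single configuration transaction, so
#' the algorithm choice is itself hash-protected.
#'
#' @param digest_algorithm `"keccak256"` (default, Ethereum's hash) or
#'   `"sha256"`.
#' @param timestamp either `NULL` (wall clock), a fixed integer used for all
#'   blocks (reproducible ledgers), or a zero-argument function returning
#'   seconds.
#' @return an environment of class `pgx_ledger`.
#' @seealso [ledger_append()], [ledger_verify()], [ledger_export()]
#' @export
ledger_create <- function(digest_algorithm = c("keccak256", "sha256"),
                          timestamp = NULL) {
  digest_algorithm <- match.arg(digest_algorithm)
  led <- new.env(parent = emptyenv())
  led$digest_algorithm <- digest_algorithm
  led$timestamp_fn <- make_timestamp_fn(timestamp)
  led$next_tx_index <- 1L
  led$blocks <- list()
  class(led) <- "pgx_ledger"

  genesis_tx <- transaction(
    sprintf('{"op":"genesis","digest":"%s"}', digest_algorithm),
    submitter = "sealer", gas_used = 0)
  genesis_tx$tx_index <- 0L
  led$blocks[[1L]] <- seal_block(led, 0L, ZERO_DIGEST, list(genesis_tx))
  led
}

make_timestamp_fn <- function(timestamp) {
  if (is.null(timestamp)) return(function() as.integer(Sys.time()))
  if (is.function(timestamp)) return(timestamp)
  force(timestamp)
  function() as.integer(timestamp)
}

seal_block <- function(led, block_number, prev_hash, txs) {
  ts <- led$timestamp_fn()
  ph <- payload_digest(txs, led$digest_algorithm)
  list(block_number = block_number,
       timestamp = as.integer(ts),
       prev_hash = prev_hash,
       payload_hash = ph,
       block_hash = header_digest(block_number, as.integer(ts), prev_hash, ph,
                                  led$digest_algorithm),
       transactions = txs)
}

#' Append a block of transactions
#'
#' Seals `transactions` into a new block whose `prev_hash` is the current
#' head's `block_hash`, assigning strictly increasing transaction indices.
#' An empty transaction list is rejected (blocks exist to carry
#' transactions).
#'
#' @param led a [ledger_create()] ledger.
#' @param transactions a non-empty list of [transaction()] objects.
#' @return the sealed block, invisibly.
#' @export
ledger_append <- function(led, transactions) {
  stopifnot(inherits(led, "pgx_ledger"))
  if (!is.list(transactions) || length(transactions) == 0L)
    pgx_error("pgx_validation_error",
              "a block must contain at least one transaction")
  for (i in seq_along(transactions)) {
    if (!inherits(transactions[[i]], "pgx_transaction"))
      pgx_error("pgx_validation_error", "transactions must be pgx_transaction objects")
    transactions[[i]]$tx_index <- led$next_tx_index
    led$next_tx_index <- led$next_tx_index + 1L
  }
  head_block <- led$blocks[[length(led$blocks)]]
  blk <- seal_block(led, head_block$block_number + 1L, head_block$block_hash,
                    transactions)
  led$blocks[[length(led$blocks) + 1L]] <- blk
  invisible(blk)
}

#' Number of blocks in the ledger (including genesis)
#' @param led a ledger.
#' @return integer block count.
#' @export
ledger_length <- function(led) length(led$blocks)

#' Verify the integrity of a ledger
#'
#' Recomputes every block's payload hash (from its transactions) and header
#' hash, and checks the hash linkage and block numbering. The smallest
#' alteration of any sealed field changes a recomputed digest, so tampering
#' is reported rather than silently accepted.
#'
#' @param led a ledger.
#' @return a list with `valid` (logical) and `first_invalid_block` (the
#'   lowest inconsistent block number, or `NA` when valid). Corruption is a
#'   report, not an error.
#' @export
ledger_verify <- function(led) {
  stopifnot(inherits(led, "pgx_ledger"))
  alg <- led$digest_algorithm
  prev <- NULL
  for (i in seq_along(led$blocks)) {
    b <- led$blocks[[i]]
    bad <- b$block_number != i - 1L
    if (!bad && i == 1L) bad <- b$prev_hash != ZERO_DIGEST
    if (!bad && i > 1L) bad <- b$prev_hash != prev$block_hash
    if (!bad) {
      ph <- payload_digest(b$transactions, alg)
      bad <- ph != b$payload_hash ||
        header_digest(b$block_number, b$timestamp, b$prev_hash, ph, alg) != b$block_hash
    }
    if (bad)
      return(list(valid = FALSE, first_invalid_block = i - 1L))
    prev <- b
  }
  list(valid = TRUE, first_invalid_block = NA_integer_)
}

#' @export
print.pgx_ledger <- function(x, ...) {
  n_tx <- sum(vapply(x$blocks, function(b) length(b$transactions), integer(1)))
  cat(sprintf("<pgx_ledger %d blocks, %d transactions, digest=%s>\n",
              length(x$blocks), n_tx, x$digest_algorithm))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Export / import: line-delimited canonical JSON records
# ---------------------------------------------------------------------------

block_to_json <- function(b) {
  txs <- paste(vapply(b$transactions, tx_canonical, character(1)),
               collapse = ",")
  sprintf(paste0('{"block_number":%d,"timestamp":%d,"prev_hash":"%s",',
                 '"payload_hash":"%s","block_hash":"%s","transactions":[%s]}'),
          b$block_number, b$timestamp, b$prev_hash, b$payload_hash,
          b$block_hash, txs)
}

#' Export a ledger to a line-delimited record file
#'
#' The first line is a header record naming the format and digest algorithm;
#' each following line is the canonical JSON serialization of one block with
#' its transactions. [ledger_import()] reconstructs an identical ledger.
#'
#' @param led a ledger.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
ledger_export <- function(led, path) {
  header <- sprintf('{"format":"pgxchain-ledger","version":1,"digest":"%s"}',
                    led$digest_algorithm)
  lines <- c(header, vapply(led$blocks, block_to_json, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname ledger_export
#' @param timestamp timestamp setting for blocks appended after import (see
#'   [ledger_create()]).
#' @return `ledger_import()`: the reconstructed ledger.
#' @export
ledger_import <- function(path, timestamp = NULL) {
  if (!file.exists(path))
    pgx_error("pgx_io_error", sprintf("no such ledger file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    pgx_error("pgx_parse_error", "ledger file must contain a header and a genesis block")
  header <- jsonlite::fromJSON(lines[[1L]])
  if (!identical(header$format, "pgxchain-ledger"))
    pgx_error("pgx_parse_error", "not a pgxchain ledger file")

  led <- new.env(parent = emptyenv())
  led$digest_algorithm <- header$digest
  led$timestamp_fn <- make_timestamp_fn(timestamp)
  class(led) <- "pgx_ledger"

  max_idx <- 0L
  led$blocks <- lapply(lines[-1L], function(line) {
    rec <- jsonlite::fromJSON(line, simplifyDataFrame = FALSE)
    txs <- lapply(rec$transactions, function(t) {
      tx <- transaction(t$payload, t$submitter, t$gas_used)
      tx$tx_index <- as.integer(t$tx_index)
      max_idx <<- max(max_idx, tx$tx_index)
      tx
    })
    list(block_number = as.integer(rec$block_number),
         timestamp = as.integer(rec$timestamp),
         prev_hash = rec$prev_hash,
         payload_hash = rec$payload_hash,
         block_hash = rec$block_hash,
         transactions = txs)
  })
  led$next_tx_index <- max_idx + 1L
  led
}

# ---------------------------------------------------------------------------
# Recording contract calls
# ---------------------------------------------------------------------------

insert_payload <- function(obs) {
  sprintf(paste0('{"op":"insert","gene":"%s","variant":%s,"drug":"%s",',
                 '"outcome":"%s","relation":%s,"sideEffect":%s}'),
          json_escape(obs$gene), obs$variant, json_escape(obs$drug),
          obs$outcome, tolower(obs$relation), tolower(obs$sideEffect))
}

#' Insert observations, recording transactions on a ledger
#'
#' Inserts every row of `obs` into the contract in order, one transaction
#' per observation (the call's gas is measured as the meter difference
#' around the insert). Transactions are sealed into blocks of `batch_size`
#' (200 by default). Query calls are read-only and are never recorded. All
#' rows are validated before any storage is touched, so a malformed table
#' commits nothing.
#'
#' @param state a [challenge_contract()] or [fastquery_contract()] state.
#' @param obs an observation data frame (see [read_observations()]).
#' @param ledger optional [ledger_create()] ledger to record transactions
#'   on; `NULL` inserts without a ledger.
#' @param batch_size transactions per sealed block (>= 1).
#' @param submitter opaque submitter identifier stored on each transaction.
#' @param gas_limit per-transaction gas limit; a transaction exceeding it
#'   logs a warning (the simulated network has no fee market, so nothing is
#'   rejected). Default 4712388, a development-network default.
#' @return a list: `ids` (assigned IDs), `rows`, `blocks_appended`,
#'   `gas_total` (gas charged by these inserts).
#' @export
insert_batch <- function(state, obs, ledger = NULL, batch_size = 200L,
                         submitter = "client", gas_limit = 4712388) {
  stopifnot(inherits(state, "pgx_contract"))
  if (batch_size < 1L)
    pgx_error("pgx_validation_error", "batch_size must be >= 1")
  obs <- validate_observations(obs)
  n <- nrow(obs)
  ids <- integer(n)
  start <- meter_snapshot(state)
  blocks <- 0L
  pending <- vector("list", min(n, batch_size))
  n_pending <- 0L

  for (i in seq_len(n)) {
    before <- meter_snapshot(state)
    ids[i] <- contract_insert(state, obs$gene[i], obs$variant[i], obs$drug[i],
                              obs$outcome[i], obs$relation[i], obs$sideEffect[i])
    gas_i <- meter_snapshot(state)[["gas"]] - before[["gas"]]
    if (gas_i > gas_limit)
      warning(sprintf("transaction %d used %g gas, above the %g gas limit",
                      i, gas_i, gas_limit), call. = FALSE)
    if (!is.null(ledger)) {
      n_pending <- n_pending + 1L
      pending[[n_pending]] <- transaction(
        insert_payload(list(gene = obs$gene[i], variant = obs$variant[i],
                            drug = obs$drug[i], outcome = obs$outcome[i],
                            relation = obs$relation[i],
                            sideEffect = obs$sideEffect[i])),
        submitter = submitter, gas_used = gas_i)
      if (n_pending == batch_size) {
        ledger_append(ledger, pending[seq_len(n_pending)])
        blocks <- blocks + 1L
        n_pending <- 0L
      }
    }
  }
  if (!is.null(ledger) && n_pending > 0L) {
    ledger_append(ledger, pending[seq_len(n_pending)])
    blocks <- blocks + 1L
  }
  list(ids = ids, rows = n, blocks_appended = blocks,
       gas_total = meter_snapshot(state)[["gas"]] - start[["gas"]])
}

#' Rebuild contract state by replaying a ledger
#'
#' Replays every insert transaction recorded on the ledger, in order, into a
#' fresh contract of the requested design — the way a node syncing the chain
#' reconstructs contract storage. The ledger's transaction log is the only
#' raw record of individual observations under the pooled design.
#'
#' @param led a ledger.
#' @param design `"challenge"` or `"fastquery"`.
#' @param costs gas cost table for the fresh state.
#' @return the populated contract state.
#' @export
ledger_replay <- function(led, design = c("challenge", "fastquery"),
                          costs = gas_costs()) {
  design <- match.arg(design)
  state <- if (design == "challenge") challenge_contract(costs)
           else fastquery_contract(costs)
  for (b in led$blocks) {
    for (tx in b$transactions) {
      call <- jsonlite::fromJSON(tx$payload)
      if (identical(call$op, "insert"))
        contract_insert(state, call$gene, call$variant, call$drug,
                        call$outcome, call$relation, call$sideEffect)
    }
  }
  state
}
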