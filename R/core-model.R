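#' @useDynLib pgxchain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Outcome categories of a pharmacogenomics observation
#'
#' The three possible outcomes of administering a drug to a carrier of a
#' gene variant: the patient improved, was unchanged, or deteriorated.
#' Tokens are canonicalized to upper case on input.
#'
#' @export
OUTCOME_LEVELS <- c("IMPROVED", "UNCHANGED", "DETERIORATED")

#' Canonical column names of an observation table
#' @keywords internal
OBS_COLUMNS <- c("gene", "variant", "drug", "outcome", "relation", "sideEffect")

`%||%` <- function(a, b) if (is.null(a)) b else a

pgx_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "pgx_error", "error", "condition"),
                 list(message = msg, call = NULL, ...)))
}

# ---------------------------------------------------------------------------
# Fixed-width 32-byte field encoding (the contract's bytes32 discipline)
# ---------------------------------------------------------------------------

#' Encode a short string as a fixed 32-byte field
#'
#' Contract storage keeps gene names, variant numbers, and outcomes in
#' fixed-size 32-byte slots (cheaper than dynamic strings and directly
#' comparable). The UTF-8 bytes of `value` are right-padded with zero bytes
#' to width 32. Values longer than 32 bytes do not fit and raise an error
#' naming the offending field.
#'
#' @param value a length-1 character vector whose UTF-8 encoding is at most
#'   32 bytes.
#' @param field name used in the error message when `value` does not fit.
#' @return a raw vector of exactly 32 bytes.
#' @seealso [decode_fixed32()] for the lossless inverse.
#' @examples
#' x <- encode_fixed32("CYP3A5")
#' length(x)            # 32
#' decode_fixed32(x)    # "CYP3A5"
#' @export
encode_fixed32 <- function(value, field = "value") {
  if (!is.character(value) || length(value) != 1L || is.na(value))
    pgx_error("pgx_encoding_error",
              sprintf("field '%s' must be a single non-NA string", field))
  bytes <- charToRaw(enc2utf8(value))
  if (length(bytes) > 32L)
    pgx_error("pgx_encoding_error",
              sprintf("field '%s' does not fit in a 32-byte slot (%d bytes, limit 32)",
                      field, length(bytes)),
              field = field, n_bytes = length(bytes))
  c(bytes, raw(32L - length(bytes)))
}

#' Decode a fixed 32-byte field back to a string
#'
#' Strips the zero-byte padding appended by [encode_fixed32()]. The
#' composition `decode_fixed32(encode_fixed32(x))` is the identity for every
#' valid input (zero bytes cannot occur inside a text field).
#'
#' @param bytes a raw vector of 32 bytes.
#' @return the decoded character scalar.
#' @export
decode_fixed32 <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) != 32L)
    pgx_error("pgx_encoding_error", "expected a raw vector of 32 bytes")
  used <- bytes[bytes != as.raw(0L)]
  nz <- which(bytes != as.raw(0L))
  if (length(nz) == 0L) return("")
  out <- rawToChar(bytes[seq_len(max(nz))])
  Encoding(out) <- "UTF-8"
  out
}

# ---------------------------------------------------------------------------
# Field canonicalization / validation
# ---------------------------------------------------------------------------

canonical_text <- function(x) trimws(as.character(x))

canonical_variant <- function(variant, field = "variant") {
  v <- suppressWarnings(as.numeric(variant))
  if (length(v) != 1L || is.na(v) || v < 0 || v != trunc(v))
    pgx_error("pgx_validation_error",
              sprintf("field '%s' must be a single non-negative integer (got %s)",
                      field, deparse(as.character(variant))),
              field = field)
  format(trunc(v), scientific = FALSE)
}

canonical_outcome <- function(outcome) {
  o <- toupper(canonical_text(outcome))
  if (length(o) != 1L || is.na(o) || !(o %in% OUTCOME_LEVELS))
    pgx_error("pgx_validation_error",
              sprintf("field 'outcome' must be one of %s (got %s)",
                      paste(OUTCOME_LEVELS, collapse = "/"),
                      deparse(as.character(outcome))),
              field = "outcome")
  o
}

canonical_bool <- function(x, field) {
  if (is.logical(x) && length(x) == 1L && !is.na(x)) return(x)
  token <- tolower(canonical_text(x))
  if (token %in% c("true", "1", "t")) return(TRUE)
  if (token %in% c("false", "0", "f")) return(FALSE)
  pgx_error("pgx_validation_error",
            sprintf("field '%s' must be a boolean (true/false or 1/0), got %s",
                    field, deparse(as.character(x))),
            field = field)
}

#' Validate and canonicalize one observation
#'
#' Applies the field rules shared by both contract designs: gene, the decimal
#' form of the variant number, and the outcome must each fit a 32-byte slot
#' (checked via [encode_fixed32()]); the drug name is unbounded but must be
#' non-empty; the outcome is one of [OUTCOME_LEVELS] (case-insensitive on
#' input); the two flags accept logicals, `true`/`false`, or `1`/`0`. Text
#' fields are compared byte-for-byte after trimming surrounding whitespace;
#' no further normalization is applied.
#'
#' @param gene gene symbol (at most 32 UTF-8 bytes after trimming).
#' @param variant non-negative integer variant number.
#' @param drug drug name, non-empty, any length.
#' @param outcome one of improved / unchanged / deteriorated (any case).
#' @param relation suspected gene-outcome relation flag.
#' @param sideEffect serious side-effect flag.
#' @return a named list with canonical fields: `gene`, `variant` (decimal
#'   string), `drug`, `outcome`, `relation`, `sideEffect`.
#' @export
observation <- function(gene, variant, drug, outcome, relation, sideEffect) {
  g <- canonical_text(gene)
  encode_fixed32(g, "gene")
  v <- canonical_variant(variant)
  encode_fixed32(v, "variant")
  d <- canonical_text(drug)
  if (!nzchar(d))
    pgx_error("pgx_validation_error", "field 'drug' must be non-empty",
              field = "drug")
  o <- canonical_outcome(outcome)
  encode_fixed32(o, "outcome")
  list(gene = g, variant = v, drug = d, outcome = o,
       relation = canonical_bool(relation, "relation"),
       sideEffect = canonical_bool(sideEffect, "sideEffect"))
}

# ---------------------------------------------------------------------------
# Combination keys
# ---------------------------------------------------------------------------

#' Build the injective key of a gene-variant-drug combination
#'
#' Both designs pool observations by unique (gene, variant, drug)
#' combination; the pooled design additionally uses the key to look up the
#' combination's record ID in its fifth mapping. The key is formed by
#' length-prefixed concatenation of the three canonical fields
#' (`<bytes>:<gene>|<bytes>:<variant>|<bytes>:<drug>`), so two distinct
#' triples can never collide even when a drug name contains the separator
#' characters. The variant is canonicalized to its decimal string, removing
#' `"52"` vs `"052"` ambiguity.
#'
#' @param gene,variant,drug the combination fields (validated as in
#'   [observation()]).
#' @return a character scalar key; identical inputs always yield identical
#'   keys.
#' @examples
#' make_combination_key("CYP3A5", 52, "pegloticase")
#' @export
make_combination_key <- function(gene, variant, drug) {
  g <- canonical_text(gene)
  encode_fixed32(g, "gene")
  v <- canonical_variant(variant)
  d <- canonical_text(drug)
  if (!nzchar(d))
    pgx_error("pgx_validation_error", "field 'drug' must be non-empty",
              field = "drug")
  paste0(nchar(g, type = "bytes"), ":", g, "|",
         nchar(v, type = "bytes"), ":", v, "|",
         nchar(d, type = "bytes"), ":", d)
}

# ---------------------------------------------------------------------------
# Parsing observation records
# ---------------------------------------------------------------------------

#' Parse one delimited observation record
#'
#' Parses a single CSV-formatted line with the six observation columns
#' (`gene,variant,drug,outcome,relation,sideEffect`) into a canonical
#' observation. Quoting follows CSV conventions, so drug names containing
#' commas are supported.
#'
#' @param record a length-1 character scalar, one CSV data row.
#' @param row row number reported in parse errors.
#' @return a canonical observation list, as from [observation()].
#' @export
parse_observation <- function(record, row = 1L) {
  fields <- tryCatch(
    as.character(utils::read.csv(textConnection(record), header = FALSE,
                                 colClasses = "character")[1L, ]),
    error = function(e) pgx_error("pgx_parse_error",
                                  sprintf("row %d: unparseable record", row),
                                  row = row))
  if (length(fields) != 6L)
    pgx_error("pgx_parse_error",
              sprintf("row %d: expected 6 columns, found %d", row, length(fields)),
              row = row)
  withCallingHandlers(
    observation(fields[1L], fields[2L], fields[3L], fields[4L], fields[5L], fields[6L]),
    pgx_error = function(e) {
      pgx_error("pgx_parse_error",
                sprintf("row %d, column '%s': %s",
                        row, e$field %||% "?", conditionMessage(e)),
                row = row, column = e$field)
    })
}

#' Read an observation table from CSV
#'
#' Reads a UTF-8 CSV file with header exactly
#' `gene,variant,drug,outcome,relation,sideEffect` and validates every row
#' (see [observation()] for the field rules). Validation failures carry the
#' offending row number and column name.
#'
#' @param path path to the CSV file.
#' @return a data frame with canonical columns: character `gene`, integer
#'   `variant`, character `drug`, character `outcome`, logical `relation`
#'   and `sideEffect`. Zero rows for a header-only file.
#' @seealso [write_observations()], [generate_observations()]
#' @export
read_observations <- function(path) {
  if (!file.exists(path))
    pgx_error("pgx_io_error", sprintf("no such file: %s", path))
  raw_df <- utils::read.csv(path, colClasses = "character",
                            check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(raw_df), OBS_COLUMNS))
    pgx_error("pgx_parse_error",
              sprintf("header must be exactly '%s' (found '%s')",
                      paste(OBS_COLUMNS, collapse = ","),
                      paste(names(raw_df), collapse = ",")))
  validate_observations(raw_df)
}

#' Validate a raw observation data frame
#'
#' Canonicalizes and validates all six columns of a table read from CSV or
#' assembled in R. The first invalid row raises an error naming the row and
#' column.
#'
#' @param df a data frame with the six observation columns.
#' @return the canonical observation data frame (see [read_observations()]).
#' @export
validate_observations <- function(df) {
  if (!all(OBS_COLUMNS %in% names(df)))
    pgx_error("pgx_parse_error",
              sprintf("missing columns: %s",
                      paste(setdiff(OBS_COLUMNS, names(df)), collapse = ", ")))
  df <- df[OBS_COLUMNS]
  n <- nrow(df)
  if (n == 0L) {
    return(data.frame(gene = character(), variant = integer(),
                      drug = character(), outcome = character(),
                      relation = logical(), sideEffect = logical(),
                      stringsAsFactors = FALSE))
  }
  first_bad <- function(bad, column, what) {
    if (any(bad))
      pgx_error("pgx_parse_error",
                sprintf("row %d, column '%s': %s", which(bad)[1L], column, what),
                row = which(bad)[1L], column = column)
  }

  gene <- trimws(as.character(df$gene))
  first_bad(is.na(gene) | nchar(gene, type = "bytes") > 32L, "gene",
            "gene must be a string of at most 32 bytes")

  vnum <- suppressWarnings(as.numeric(df$variant))
  first_bad(is.na(vnum) | vnum < 0 | vnum != trunc(vnum), "variant",
            "variant must be a non-negative integer")
  variant <- as.integer(vnum)

  drug <- trimws(as.character(df$drug))
  first_bad(is.na(drug) | !nzchar(drug), "drug", "drug must be non-empty")

  outcome <- toupper(trimws(as.character(df$outcome)))
  first_bad(!(outcome %in% OUTCOME_LEVELS), "outcome",
            sprintf("outcome must be one of %s",
                    paste(OUTCOME_LEVELS, collapse = "/")))

  parse_bool_col <- function(x, column) {
    token <- tolower(trimws(as.character(x)))
    out <- rep(NA, length(token))
    out[token %in% c("true", "1", "t")] <- TRUE
    out[token %in% c("false", "0", "f")] <- FALSE
    first_bad(is.na(out), column, "must be a boolean (true/false or 1/0)")
    out
  }

  data.frame(gene = gene, variant = variant, drug = drug, outcome = outcome,
             relation = parse_bool_col(df$relation, "relation"),
             sideEffect = parse_bool_col(df$sideEffect, "sideEffect"),
             stringsAsFactors = FALSE)
}

#' Write an observation table to CSV
#'
#' Inverse of [read_observations()]: writes the canonical six-column schema
#' with logical flags rendered as `true`/`false`.
#'
#' @param df a canonical observation data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(df, path) {
  out <- df[OBS_COLUMNS]
  out$relation <- ifelse(out$relation, "true", "false")
  out$sideEffect <- ifelse(out$sideEffect, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The worked single-observation example
#'
#' One pharmacogenomics observation used throughout the documentation and
#' tests: carriers of CYP3A5 variant 52 given pegloticase were unchanged,
#' with a suspected gene-outcome relation and a serious side effect.
#'
#' @return a one-row canonical observation data frame.
#' @export
example_observation <- function() {
  data.frame(gene = "CYP3A5", variant = 52L, drug = "pegloticase",
             outcome = "UNCHANGED", relation = TRUE, sideEffect = TRUE,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Query triples
# ---------------------------------------------------------------------------

#' Construct a query triple
#'
#' A query pattern over the three searchable fields. Each field is either a
#' concrete value or the wildcard `"*"`; any token other than the literal
#' `"*"` is treated as a value (numeric variant tokens are canonicalized to
#' their decimal form, anything else matches literally). The all-wildcard
#' triple is the full-database query.
#'
#' @param gene,variant,drug field patterns; default `"*"`.
#' @return an object of class `query_triple`.
#' @seealso [n_ands()]
#' @examples
#' query_triple("CYP3A5")                 # 0-AND: one field specified
#' query_triple("CYP3A5", 52, "pegloticase")  # 2-AND: all three
#' @export
query_triple <- function(gene = "*", variant = "*", drug = "*") {
  canon_q <- function(x) {
    x <- canonical_text(x)
    if (length(x) != 1L || is.na(x))
      pgx_error("pgx_validation_error", "query fields must be single strings")
    x
  }
  v <- canon_q(variant)
  if (v != "*" && grepl("^[0-9]+$", v))
    v <- canonical_variant(v)
  structure(list(gene = canon_q(gene), variant = v, drug = canon_q(drug)),
            class = "query_triple")
}

#' Number of ANDs in a query triple
#'
#' A query specifying k fields (1 <= k <= 3) is a (k-1)-AND query: one field
#' is a 0-AND query, all three a 2-AND query. The all-wildcard triple is the
#' full-database query, for which the AND count is undefined (`NA`).
#'
#' @param q a [query_triple()].
#' @return integer AND count, or `NA_integer_` for the all-wildcard triple.
#' @export
n_ands <- function(q) {
  stopifnot(inherits(q, "query_triple"))
  k <- sum(vapply(q, function(f) !identical(f, "*"), logical(1)))
  if (k == 0L) NA_integer_ else k - 1L
}

#' @export
print.query_triple <- function(x, ...) {
  cat(sprintf("<query gene=%s variant=%s drug=%s>\n", x$gene, x$variant, x$drug))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Aggregate results
# ---------------------------------------------------------------------------

AGG_COLUMNS <- c("gene", "variant", "drug", "n_observations",
                 "side_effect_count", "side_effect_pct",
                 "suspected_count", "suspected_pct",
                 "improved_count", "improved_pct",
                 "deteriorated_count", "deteriorated_pct",
                 "unchanged_count", "unchanged_pct")

#' An empty aggregate-result table
#'
#' Zero-row data frame with the aggregate query result schema: the
#' combination fields, the observation count, and count/percentage pairs for
#' serious side effects, suspected relations, and the three outcomes.
#'
#' @return a zero-row data frame with the 14 result columns.
#' @export
empty_aggregate <- function() {
  data.frame(gene = character(), variant = integer(), drug = character(),
             n_observations = integer(),
             side_effect_count = integer(), side_effect_pct = numeric(),
             suspected_count = integer(), suspected_pct = numeric(),
             improved_count = integer(), improved_pct = numeric(),
             deteriorated_count = integer(), deteriorated_pct = numeric(),
             unchanged_count = integer(), unchanged_pct = numeric(),
             stringsAsFactors = FALSE)
}

# rows: list of named lists with counts; percentages are derived here so the
# two designs and any caller share one percentage convention (fraction x 100,
# full precision).
build_aggregate <- function(gene, variant, drug, n, side_effect, suspected,
                            improved, deteriorated, unchanged) {
  if (length(n) == 0L) return(empty_aggregate())
  data.frame(gene = gene, variant = as.integer(variant), drug = drug,
             n_observations = as.integer(n),
             side_effect_count = as.integer(side_effect),
             side_effect_pct = 100 * side_effect / n,
             suspected_count = as.integer(suspected),
             suspected_pct = 100 * suspected / n,
             improved_count = as.integer(improved),
             improved_pct = 100 * improved / n,
             deteriorated_count = as.integer(deteriorated),
             deteriorated_pct = 100 * deteriorated / n,
             unchanged_count = as.integer(unchanged),
             unchanged_pct = 100 * unchanged / n,
             stringsAsFactors = FALSE)
}

#' Serialize aggregate results as JSON
#'
#' Canonical JSON rendering of a query result: an array of objects with the
#' aggregate columns, percentages rounded to 2 decimal places for display
#' (the data frame itself keeps full precision).
#'
#' @param results an aggregate-result data frame.
#' @param digits decimal places for percentage display.
#' @return a JSON string.
#' @export
aggregate_to_json <- function(results, digits = 2L) {
  out <- results
  pct_cols <- grep("_pct$", names(out))
  out[pct_cols] <- lapply(out[pct_cols], round, digits = digits)
  as.character(jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA))
}
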