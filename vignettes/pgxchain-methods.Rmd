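---
title: "Storage and query models in pgxchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storage and query models in pgxchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxchain)
```

## The problem

A pharmacogenomics observation is one empirical data point about a gene-drug
interaction: a gene symbol, a variant number, a drug name, an outcome
(improved, unchanged, or deteriorated), and two boolean flags — whether a
gene-outcome relation is suspected and whether a serious side effect
occurred. Databases of such observations inform prescribing decisions, so
their integrity matters: a silently altered record can translate into a
wrong treatment. Contract storage on a blockchain offers tamper-evident,
append-only persistence, but it charges for every storage access, which
makes the data-structure design the central question: how should
observations be laid out in key-value "mapping" storage so that wildcard
queries over gene, variant, and drug are answerable at acceptable cost?

pgxchain implements two such layouts as executable models, together with a
minimal hash-linked ledger and a gas meter, so that the layouts' correctness
and cost behaviour can be measured exactly, deterministically, and without
any blockchain network or wall clock.

## Contract storage and the gas model

A simulated contract persists only through named mappings from keys to
*slots*. The model follows the storage discipline of Ethereum-style
contracts:

* every mapping value, struct field, array element, and array length
  occupies one slot;
* reading a slot costs `SLOAD` gas; reading an absent key returns the
  type's zero value (0, zero bytes, empty array) *and is still charged*;
* writing a slot costs `SSTORE_NEW` when the slot previously held the zero
  value, `SSTORE_UPDATE` otherwise;
* reading a whole ID array (what a mapping access returning a memory array
  does) costs one length read plus one read per element; appending costs a
  length read, an element write (always "new"), and a length write ("new"
  exactly on the 0 to 1 transition).

The default fee schedule is `SLOAD = 200`, `SSTORE_NEW = 20000`,
`SSTORE_UPDATE = 5000` gas units (`gas_costs()`); every comparative claim
the package tests holds for any positive constants, and the whole table is
configurable. Two simplifications are deliberate: a drug name is charged as
one slot regardless of its length, and function-local ("memory")
computation is free, as it is orders of magnitude cheaper than storage on
the platforms being modelled.

Short text fields — gene, the decimal form of the variant number, and the
outcome — must fit a fixed 32-byte slot (`encode_fixed32()`), mirroring the
`bytes32` type that such contracts use for cheap fixed-size comparisons.
Drug names are unbounded, because real drug names routinely exceed 32
characters.

## The per-observation ("challenge") design

`challenge_contract()` stores every observation in its own struct:

* `database`: ID → observation struct (6 fields). IDs are consecutive
  integers starting at 1; 0 is reserved so that "absent" reads, which
  return zero, are unambiguous.
* `gene_ids`, `variant_ids`, `drug_ids`: field value → array of IDs
  (inverted indexes).
* `unique_combinations`: append-only array of the distinct
  (gene, variant, drug) combinations, in first-insertion order, plus a
  key-presence mapping so the "is this combination new?" check at insert
  time is a single storage read rather than an array scan (a scan would
  make building an n-observation database quadratic).
* a global counter slot. The slot stores the number of observations
  inserted so far, and the next ID is that value plus one; this keeps the
  "counter equals one plus database size" invariant without needing a
  constructor write to initialize the slot to 1.

A query is a triple of patterns, each a concrete value or the wildcard
`"*"`; only the literal `*` is a wildcard, any other token is matched
byte-for-byte (a malformed pattern simply matches nothing). A query naming
k fields is a (k-1)-AND query. The query algorithm:

1. If all three fields are wildcards, the candidates are all IDs in use.
2. Otherwise fetch the ID array for each specified field (absent value ⇒
   empty array ⇒ empty result), loop over the shortest array, and keep the
   IDs present in every other specified array. Each array is fetched from
   storage once and intersected in memory; re-reading the other arrays
   inside the outer loop would charge a product, not a sum, of array
   lengths for the identical result.
3. Fetch the matching structs, then loop over the stored
   `unique_combinations` array, pooling the matched structs of each
   combination into one aggregate row: the observation count and
   count/percentage pairs for side effects, suspected relations, and the
   three outcomes. Combinations with no match are omitted; output order is
   the array's first-insertion order, which makes results deterministic.

Step 3 is the design's structural weakness: the combination array is read
from storage in full — 1 + K `SLOAD`s for K distinct combinations — on
*every* query, however selective, so query gas grows with the diversity of
the whole database, not with the result size. The benchmark makes this cost
visible; it is the plausible mechanism behind this layout becoming
un-queryable on large databases in practice.

## The pooled ("fastQuery") design

`fastquery_contract()` removes both per-query costs at insert time. A fifth
mapping takes the injective combination key to a relation ID (0 = absent),
and `database` holds one struct per *unique combination*: the three name
fields plus six counts (total, improved, deteriorated, unchanged,
suspected, side effect). Inserting an observation either allocates a new
relation (and indexes its ID in the three field mappings, where each ID now
appears exactly once) or increments the existing relation's counts in
place. The unchanged count is stored explicitly even though it is derivable
from the other three; one extra slot per relation buys symmetric update
code and a cheap internal consistency check.

Queries use the same minimum-array intersection front end, then simply read
each matching relation struct and convert counts to percentages — no
combination array, no per-observation structs. Results are ordered by
ascending relation ID, which is again first-insertion order of
combinations, so the two designs produce byte-comparable output.

The storage consequence: the pooled database grows with distinct
combinations only — a finite set for real gene/variant/drug vocabularies —
while the per-observation database grows without bound. The pooling
deliberately discards individual records; the ledger's transaction log is
the only place raw observations survive.

## Combination keys

Both designs need an injective encoding of (gene, variant, drug).
`make_combination_key()` concatenates the three canonical fields with
*length prefixes* (`6:CYP3A5|2:52|11:pegloticase`), so a drug name
containing any separator character cannot create a collision; a plain
separator join would confuse `("A", 1, "B|2|C")` with `("A|1|B", 2, "C")`.
The variant is canonicalized to its decimal string first, removing the
`"52"` versus `"052"` ambiguity. Text matching throughout is exact and
case-sensitive after trimming surrounding whitespace — contract storage
compares keys byte-for-byte, so any name normalization (gene symbol or drug
vocabulary mapping) must happen upstream. Outcome tokens are the one
exception: they are canonicalized to upper case on input, since they form a
closed three-value vocabulary.

## The ledger

`ledger_create()` starts a hash-linked chain with a single deterministic
sealer — the degenerate but faithful form of proof-of-authority consensus
for a private network, which leaves the storage semantics under study
untouched while dropping networking, transaction pools, and sealer
rotation. Each block carries its number, a timestamp, the previous block's
header hash, and the digest of its canonically serialized transaction list;
each insert is one transaction recording the submitter, the canonical call
payload, and the gas the call consumed. Blocks seal 200 transactions by
default. Read-only query calls are metered but never recorded: they change
no state.

The digest is Keccak-256 — the hash Ethereum itself uses, with the original
multi-rate padding, implemented in C++ and verified against published and
independently recomputed vectors — with FIPS SHA-256 available as an
alternative; the chosen algorithm is recorded in the genesis block's
configuration transaction, so it is itself hash-protected.
`ledger_verify()` recomputes every digest and linkage and reports the
lowest inconsistent block; corruption is a report, not an error.
Timestamps are injectable (a fixed value in tests) so that ledgers are
bit-reproducible. The gas limit and price of the emulated development
network (4,712,388 and 100) are carried as configuration only: with no fee
market there is nothing to reject, so a transaction above the limit logs a
warning.

## The synthetic generator and the oracle

`generate_observations()` emulates an observation stream: fields drawn
independently and uniformly from pools of `n_genes` gene symbols,
`n_variants` variant numbers and `n_drugs` drug names; outcomes by weight;
flags Bernoulli. The defaults — 50 genes × 20 variants × 30 drugs, equal
outcome weights, suspected-relation rate 0.5, side-effect rate 0.3 — give
30,000 possible combinations, so databases of 10^2 to 10^4 rows contain
mostly distinct combinations with a realistic minority of duplicates; the
flag rates reflect that submitted observations are enriched for suspected
relations while serious side effects remain the minority. These are
modelling choices, fixed once; every experiment states its seed and is
bit-reproducible. `generate_duplicated_observations()` instead fixes the
number of distinct combinations and the duplication factor exactly, which
is what separates the two designs' scaling.

What the generator does *not* emulate: real gene/drug vocabulary skew
(uniform pools have no hot genes), correlated fields (in practice outcome
and side effect co-vary with particular drugs), longitudinal structure, or
adversarial text. Passing tests therefore demonstrate the storage and query
machinery, not epidemiological realism; the property tests compensate on
the text side by injecting separator characters, quotes, commas, and
multibyte UTF-8 into names.

`oracle_query()` is the correctness anchor: an independent linear scan over
the plain observation table — filter on the non-wildcard fields, group by
combination (its own length-prefixed grouping keys, no contract code),
count, convert to percentages. It touches neither contract storage nor the
gas meter. Every query answered by either design is required, in the tests,
to equal the oracle exactly.

## The benchmark

`run_benchmark()` reports storage-operation counts and gas — never
wall-clock time or megabytes, which are properties of a host machine, not
of the designs. For each design × database size it inserts a fresh seeded
database and runs 100 seeded queries per class (0-, 1-, 2-AND, and
full-wildcard), recording totals for insertion and per-query means
otherwise. Every record is a pure function of (design, data, query, cost
table), so reruns reproduce it bit-for-bit.

Problem sizes used by the shipped tests and the acceptance script, chosen
to exercise each claim at the smallest size where it is unambiguous:
accuracy on databases of 100 and 1,000 observations with 100 queries per
AND class; duplicate-scaling at 50 combinations × 20 and × 200; insertion
linearity at 100–1,000 (per-observation design) and 100–10,000 (pooled
design); query-class ordering at 100, 500, and 1,000; tamper detection
with 100 random single-field mutations of a 51-block ledger; and one
end-to-end 10,000-observation run through the command-line interface.

## Numerical and degenerate-input conventions

* Percentages are stored at full double precision (`100 * count / n`); the
  three outcome percentages always sum to 100 within 1e-9. Rendering
  rounds to two decimals (`aggregate_to_json()`), the data model does not.
* A query on an empty database, or naming unseen values, returns a
  zero-row aggregate table, never an error.
* Insertion is atomic: all field validation (32-byte limits, non-negative
  variant, non-empty drug, outcome vocabulary) happens before the first
  storage write, so a failed insert leaves storage and the gas meter
  untouched.
* An empty or header-only CSV inserts zero rows, appends zero blocks, and
  succeeds; an invalid row anywhere aborts the whole file before any
  ledger commit.
* Observation tables never record a per-observation submitter: the
  submitter is a property of the transaction, recorded at the ledger
  level, not of the scientific datum.

## Known limitations

The state model is a flat key-value store: Merkle-Patricia tries, state
roots, and disk layout are out of scope, as are consensus beyond one
sealer, networking, fee markets, and contract deployment. Gas constants are
a configurable schedule, not a claim about any particular client version;
conclusions should be drawn from comparisons and growth rates, which are
invariant to the constants, rather than from absolute gas values. The
per-observation design is modelled as specified, including the query-time
combination-array scan whose cost the benchmark quantifies — the package
reproduces that design's behaviour, it does not repair it.
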