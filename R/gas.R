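# Gas accounting and contract storage.
#
# Storage is modelled at slot granularity, the unit the fee schedule charges:
# every mapping value, array element, array length, and struct field occupies
# one slot. Reads cost SLOAD; a write costs SSTORE_NEW when the slot
# previously held the type's zero value and SSTORE_UPDATE otherwise. Reads of
# absent keys return the zero value and are still charged.

#' Gas cost table
#'
#' Per-operation costs, in gas units, for the three storage operation
#' classes: a storage read (`sload`), a write to a slot holding the zero
#' value (`sstore_new`), and a write to an occupied slot (`sstore_update`).
#' Defaults follow the Ethereum fee schedule (200 / 20000 / 5000). Every
#' scaling property measured by the package holds for any positive values.
#'
#' @param sload,sstore_new,sstore_update positive per-operation costs.
#' @return an object of class `gas_costs`.
#' @export
gas_costs <- function(sload = 200, sstore_new = 20000, sstore_update = 5000) {
  costs <- c(sload = as.numeric(sload), sstore_new = as.numeric(sstore_new),
             sstore_update = as.numeric(sstore_update))
  if (any(!is.finite(costs)) || any(costs <= 0))
    pgx_error("pgx_validation_error", "gas costs must be positive numbers")
  structure(as.list(costs), class = "gas_costs")
}

#' Create a gas meter
#'
#' Counts charged storage operations. Counters never decrease; the total is
#' always `sload*SLOAD + sstore_new*SSTORE_NEW + sstore_update*SSTORE_UPDATE`.
#'
#' @param costs a [gas_costs()] table.
#' @return an environment of class `gas_meter` with counters `sload`,
#'   `sstore_new`, `sstore_update`.
#' @seealso [gas_total()], [meter_snapshot()]
#' @export
gas_meter <- function(costs = gas_costs()) {
  stopifnot(inherits(costs, "gas_costs"))
  m <- new.env(parent = emptyenv())
  m$costs <- costs
  m$sload <- 0
  m$sstore_new <- 0
  m$sstore_update <- 0
  class(m) <- "gas_meter"
  m
}

meter_charge <- function(meter, sload = 0, sstore_new = 0, sstore_update = 0) {
  meter$sload <- meter$sload + sload
  meter$sstore_new <- meter$sstore_new + sstore_new
  meter$sstore_update <- meter$sstore_update + sstore_update
  invisible(meter)
}

#' Total gas charged on a meter
#'
#' @param x a `gas_meter`, or an object holding one (a contract state or
#'   contract storage).
#' @return total gas units charged since creation.
#' @export
gas_total <- function(x) {
  m <- resolve_meter(x)
  m$sload * m$costs$sload + m$sstore_new * m$costs$sstore_new +
    m$sstore_update * m$costs$sstore_update
}

#' Snapshot a gas meter's counters
#'
#' Used to measure the gas of a scoped operation as a difference of
#' snapshots.
#'
#' @param x a `gas_meter` or an object holding one.
#' @return named numeric vector with `sload`, `sstore_new`, `sstore_update`,
#'   `gas` totals at the time of the call.
#' @export
meter_snapshot <- function(x) {
  m <- resolve_meter(x)
  c(sload = m$sload, sstore_new = m$sstore_new,
    sstore_update = m$sstore_update, gas = gas_total(m))
}

resolve_meter <- function(x) {
  if (inherits(x, "gas_meter")) return(x)
  if (inherits(x, "contract_storage")) return(x$meter)
  if (inherits(x, "pgx_contract")) return(x$storage$meter)
  pgx_error("pgx_validation_error", "no gas meter attached to this object")
}

#' @export
print.gas_meter <- function(x, ...) {
  cat(sprintf("<gas_meter sload=%g sstore_new=%g sstore_update=%g total=%g>\n",
              x$sload, x$sstore_new, x$sstore_update, gas_total(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Contract storage: named mappings of slots, all access metered
# ---------------------------------------------------------------------------

#' Create metered contract storage
#'
#' The only persistence available to a simulated contract: named key-value
#' mappings whose every read and write is routed through a gas meter. Absent
#' keys read as the zero value of the slot type (0, zero bytes, empty array)
#' and the read is still charged; a write is classified as "new" exactly when
#' the slot previously held the zero value.
#'
#' @param meter a [gas_meter()].
#' @return an environment of class `contract_storage`.
#' @export
contract_storage <- function(meter = gas_meter()) {
  st <- new.env(parent = emptyenv())
  st$meter <- meter
  st$maps <- new.env(parent = emptyenv())
  class(st) <- "contract_storage"
  st
}

get_map <- function(st, mapping) {
  m <- st$maps[[mapping]]
  if (is.null(m)) {
    m <- new.env(parent = emptyenv())
    st$maps[[mapping]] <- m
  }
  m
}

#' Metered scalar slot access
#'
#' `stor_read()` returns the value in `mapping[key]` (or `zero` when absent)
#' and charges one SLOAD. `stor_write()` stores `value` and charges one
#' SSTORE, classified new/update by whether the slot previously held `zero`.
#'
#' @param st a [contract_storage()].
#' @param mapping mapping name.
#' @param key slot key (coerced to character).
#' @param value value to store.
#' @param zero the slot type's zero value (default `0`).
#' @return `stor_read()`: the stored or zero value; `stor_write()`: the
#'   storage, invisibly.
#' @export
stor_read <- function(st, mapping, key, zero = 0) {
  m <- get_map(st, mapping)
  st$meter$sload <- st$meter$sload + 1
  m[[as.character(key)]] %||% zero
}

#' @rdname stor_read
#' @export
stor_write <- function(st, mapping, key, value, zero = 0) {
  m <- get_map(st, mapping)
  key <- as.character(key)
  old <- m[[key]] %||% zero
  if (identical(old, zero))
    st$meter$sstore_new <- st$meter$sstore_new + 1
  else
    st$meter$sstore_update <- st$meter$sstore_update + 1
  m[[key]] <- value
  invisible(st)
}

# Array slots: a storage array is a length slot plus one slot per element.
# Reading the whole array (what a mapping access returning a memory array
# does) charges 1 + length SLOADs. Appending reads the length slot, writes
# the new element slot (always "new"), and writes the length slot back
# ("new" on the 0 -> 1 transition, "update" after).
stor_read_array <- function(st, mapping, key) {
  m <- get_map(st, mapping)
  arr <- m[[as.character(key)]] %||% integer(0)
  st$meter$sload <- st$meter$sload + 1 + length(arr)
  arr
}

stor_array_append <- function(st, mapping, key, id) {
  m <- get_map(st, mapping)
  key <- as.character(key)
  arr <- m[[key]] %||% integer(0)
  st$meter$sload <- st$meter$sload + 1            # length slot
  st$meter$sstore_new <- st$meter$sstore_new + 1  # element slot
  if (length(arr) == 0L)
    st$meter$sstore_new <- st$meter$sstore_new + 1
  else
    st$meter$sstore_update <- st$meter$sstore_update + 1
  m[[key]] <- c(arr, id)
  invisible(st)
}

# Struct slots: one slot per field. Writing a fresh struct charges one
# SSTORE_NEW per field written; reading charges one SLOAD per field read.
# Unwritten fields hold zero and can be bumped later (0 -> x is "new").
stor_write_struct <- function(st, mapping, key, fields) {
  m <- get_map(st, mapping)
  key <- as.character(key)
  existing <- m[[key]] %||% list()
  st$meter$sstore_new <- st$meter$sstore_new + length(fields)
  existing[names(fields)] <- fields
  m[[key]] <- existing
  invisible(st)
}

stor_read_struct <- function(st, mapping, key, n_fields) {
  m <- get_map(st, mapping)
  st$meter$sload <- st$meter$sload + n_fields
  m[[as.character(key)]]
}

# Read-increment of one numeric struct field (zero-default).
stor_bump_field <- function(st, mapping, key, field, by = 1L) {
  m <- get_map(st, mapping)
  key <- as.character(key)
  rec <- m[[key]] %||% list()
  old <- rec[[field]] %||% 0L
  st$meter$sload <- st$meter$sload + 1
  if (old == 0L)
    st$meter$sstore_new <- st$meter$sstore_new + 1
  else
    st$meter$sstore_update <- st$meter$sstore_update + 1
  rec[[field]] <- old + by
  m[[key]] <- rec
  invisible(st)
}

# Unmetered deep copy of the stored data, for read-only assertions.
storage_contents <- function(st) {
  lapply(sort(ls(st$maps)), function(mp) {
    m <- st$maps[[mp]]
    keys <- sort(ls(m))
    stats::setNames(lapply(keys, function(k) m[[k]]), keys)
  }) |> stats::setNames(sort(ls(st$maps)))
}
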