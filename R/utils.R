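# Internal helpers shared across modules.

# Valid factor levels for the annotation schema.
MODALITY_LEVELS <- c("ponss", "baseline")
BOUNDARY_LEVELS <- c("onset", "offset")
RATE_LEVELS <- c("fast", "medium", "slow")
TASK_LEVELS <- c("triage", "retrim", "baseline_trial")
OUTCOME_LEVELS <- c("accepted", "retrim_requested", "rejected", "flagged", "saved")
COMPONENT_LEVELS <- c("narrow", "medium", "wide")

# Run `code` under `seed` without disturbing the caller's RNG state.
# A NULL seed runs the code as-is.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a master seed and a counter, kept inside the
# 32-bit integer range so it is always a valid `set.seed()` argument.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 9973) %% 2147483629L)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}

assert_enum <- function(x, levels, field) {
  bad <- which(!(x %in% levels))
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value '%s' in row %d (allowed: %s)",
                  field, as.character(x[bad[1]]), bad[1],
                  paste(levels, collapse = ", ")))
  }
  invisible(x)
}

# Largest-remainder allocation of `size` into integer counts proportional
# to `props` (which need not sum exactly to 1). Counts differ from the
# exact products by at most 1 and sum to `size`.
largest_remainder <- function(size, props) {
  exact <- size * props / sum(props)
  base <- floor(exact)
  short <- size - sum(base)
  if (short > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  as.integer(base)
}
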