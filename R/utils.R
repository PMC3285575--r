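# Internal helpers shared across modules.

# Derive a child seed from (seed, index) so that any sub-computation is
# independently reproducible. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647L)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_gene_ids <- function(ids, what = "gene") {
  if (length(ids) == 0L) stop_format("no %s identifiers supplied", what)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_format("duplicate %s identifier: '%s'", what, dup[[1L]])
  }
  invisible(ids)
}
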