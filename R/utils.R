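.datatable.aware <- TRUE

# Run `expr` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Documented seed-splitting scheme: every per-sample (or per-replicate)
# stream is seeded as (97 * master + 7919 * index) mod (2^31 - 1), so any
# stage can be re-run in isolation reproducibly.
split_seed <- function(master, index) {
  as.integer((97 * (as.numeric(master) %% 2147483647) +
                7919 * as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All panel fluorescence channels, in canonical order. CD5 is part of the
# staining panel and carried through I/O but unused by gating.
panel_channels <- function() c("CD19", "IgD", "CD27", "CD25", "CD5", "Fluo4")

required_channels <- function() c("time", "CD19", "IgD", "CD27", "CD25", "Fluo4")
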