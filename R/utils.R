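# run code under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic seeded choice among tied candidates
pick_one <- function(candidates) {
  if (length(candidates) == 1) return(candidates)
  candidates[sample.int(length(candidates), 1)]
}
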