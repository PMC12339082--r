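# internal helpers

# classed errors so callers can distinguish failure modes
oq_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "osteoquant_error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
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

is_binary_matrix <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1, NA)))
}

as_int_mask <- function(m) {
  storage.mode(m) <- "integer"
  m[is.na(m)] <- 0L
  m
}
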