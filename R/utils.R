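# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a local RNG state seeded at `seed`; restores global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

state_index <- function(x) {
  idx <- match(x, DM_STATES)
  if (anyNA(idx)) stop_fmt("unknown sequence state(s): %s",
                           paste(unique(x[is.na(idx)]), collapse = ", "))
  idx
}

# format numbers for text output so that write -> read -> write is stable
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  ii <- is.finite(x) & x == round(x) & abs(x) < 2^31
  out[ii] <- sprintf("%d", as.integer(x[ii]))
  out
}
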