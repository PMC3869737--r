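# evaluate `code` under a temporary seed, restoring the caller's RNG
# state afterwards; seed = NULL uses (and advances) the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  x
}
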