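# internal utilities

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a stage seed from a global seed and a stage name, deterministically
# and independently of stage order (so adding a stage never perturbs others);
# kept below 2^31 for 32-bit R integers
stage_seed <- function(global_seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131L) %% 1000003L
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}
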