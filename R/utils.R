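#' @keywords internal
"_PACKAGE"

# Seed fan-out: one global seed deterministically derives per-stage seeds so
# individual stages can be re-run in isolation. Kept below 2^31 - 1.
stage_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(global_seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# MD5 of an R object via its canonical serialization (used to stamp artifacts
# with the configuration that produced them).
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_beat <- function(...) stop(sprintf(...), call. = FALSE)
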