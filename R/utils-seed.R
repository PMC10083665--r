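# Local seeding: functions that take a `seed` argument set it for their own
# draws and then restore the caller's RNG state, so an explicitly seeded
# call is reproducible without disturbing an enclosing simulation stream.
# Usage in a function body (save+set immediately, restore on exit):
#   old_rng <- save_rng(seed); on.exit(restore_rng(old_rng), add = TRUE)
# With seed = NULL this is a no-op and the ambient stream is used.
save_rng <- function(seed) {
  if (is.null(seed)) return(NULL)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NA
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) return(invisible(NULL))
  if (identical(old, NA)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
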