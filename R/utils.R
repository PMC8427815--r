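# Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of sub-seeds from a base seed, kept inside 32-bit range.
subSeeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 7919 + salt * 104729 + seq_len(n) * 131) %% 2147483647
}

clipHurst <- function(h) pmin(pmax(h, 0.05), 0.95)

# md5 of an R object via its canonical JSON rendering (config stamping).
objectHash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
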