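`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage seed from a top-level seed
#'
#' One top-level integer reproduces a whole pipeline run: each stage draws its
#' own seed through this splitmix-style 32-bit mixing function, so stages are
#' decoupled (re-running one stage does not perturb another's stream).
#'
#' @param seed integer top-level seed.
#' @param stage integer stage index (or a known stage name).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stages <- c(design = 1L, schedule = 2L, simulate = 3L, preprocess = 4L,
                bootstrap = 5L, mcmc = 6L, report = 7L)
    if (!stage %in% names(stages)) stop("unknown stage name: ", stage)
    stage <- stages[[stage]]
  }
  x <- (as.double(seed) * 2654435761 + as.double(stage) * 40503) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(max(1, x))
}

# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_columns <- function(df, cols, what = "trial table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

assert_emotions <- function(x, what = "emotion") {
  bad <- setdiff(unique(as.character(x)), EMOTIONS)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s label(s): %s (expected one of %s)", what,
                 paste(bad, collapse = ", "), paste(EMOTIONS, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
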