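#' Derive a reproducible sub-seed from a master seed and a string label
#'
#' Per-sample random-number substreams are derived by stable hashing of
#' artifact IDs, so that adding a donor or sample to a cohort does not
#' perturb the events generated for any other sample.
#'
#' @param master integer master seed.
#' @param ... character scalars (IDs, labels) hashed into the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "HD1", "blood")
substream_seed <- function(master, ...) {
  parts <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                 collapse = "\x1f")
  bytes <- utf8ToInt(parts)
  m <- 2^31 - 1
  h <- 17
  for (b in bytes) {
    # polynomial rolling hash; intermediate values stay < 2^53, exact in
    # double precision
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
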