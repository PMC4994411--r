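# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit sub-seed from a master seed and a stage label, so
# each pipeline stage draws from its own stream and adding a stage never
# perturbs another stage's randomness
stage_seed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1999999973
  s <- ((abs(seed) %% 65011 + 1) * 29761 + h) %% 21474832
  as.integer(s) + 1L
}

pad_id <- function(prefix, i, width = 4L) {
  paste0(prefix, formatC(i, width = width, flag = "0"))
}
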