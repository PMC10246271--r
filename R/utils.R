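# Deterministic derivation of stage/iteration seeds from a base seed.
# Lehmer-style step keeps everything inside 32-bit integer range so the
# same base seed reproduces the full analysis on any platform.
derive_seed <- function(seed, offset = 0) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(offset) * 7919 + 12345) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

logistic <- function(x) 1 / (1 + exp(-x))

# numeric 0/1 coding used in design matrices: sex "M" -> 1, "F" -> 0
sex_numeric <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(sex %in% c("M", "male", "Male", "1"))
}
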