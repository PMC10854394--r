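# shared helpers (internal)

.stop2 <- function(fmt, ..., class = "dwiQC_validation") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

# deterministic 31-bit seed derived from a base seed and a string tag, so
# per-subject / per-stage randomness is reproducible independent of order
.derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (seq_along(utf8ToInt(as.character(tag))) %% 31L + 1L))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}

# evaluate expr with a local RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.as_volume_array <- function(volumes) {
  if (is.array(volumes) && length(dim(volumes)) == 4L) return(volumes)
  if (is.array(volumes) && length(dim(volumes)) == 3L)
    return(array(volumes, c(dim(volumes), 1L)))
  if (is.list(volumes)) {
    d <- dim(volumes[[1L]])
    return(array(unlist(volumes, use.names = FALSE), c(d, length(volumes))))
  }
  .stop2("expected a 3D/4D array or a list of 3D arrays")
}
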