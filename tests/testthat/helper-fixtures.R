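# Shared fixtures: everything is generated in code at test time.

# minimal full-rank scheme: one b = 0 plus six non-collinear directions
tiny_scheme <- function(extra = 0L) {
  dirs <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  bv <- c(0, rep(800, 6L))
  vecs <- cbind(c(0, 0, 0), dirs)
  if (extra > 0L) {
    more <- dwiQC:::.sphere_dirs(extra)
    bv <- c(bv, rep(800, extra))
    vecs <- cbind(vecs, more)
  }
  acquisitionScheme(bv, vecs)
}

random_series <- function(n = 5L, dims = c(8L, 8L, 6L), labels = NULL,
                          subject = "sub01", session = "ses01", seed = 1L) {
  sch <- if (n == 7L) tiny_scheme() else
    acquisitionScheme(c(0, rep(700, n - 1L)),
                      cbind(c(0, 0, 0), dwiQC:::.sphere_dirs(n - 1L)))
  vols <- dwiQC:::.with_seed(seed, lapply(seq_len(n), function(i)
    array(runif(prod(dims), 10, 100), dims)))
  volumeSeries(vols, sch, subject = subject, session = session, labels = labels)
}

# labelled series where "artifact" volumes carry attenuated axial slices:
# an easy, learnable analogue of motion dropout for fast network tests
toy_task <- function(n = 32L, dims = c(24L, 24L, 16L), seed = 1L) {
  dwiQC:::.with_seed(seed, {
    x <- array(runif(prod(dims) * n), c(dims, n))
    y <- rep(c(0L, 1L), length.out = n)
    for (i in which(y == 1L)) {
      sl <- sample(dims[3L], 4L)
      x[, , sl, i] <- x[, , sl, i] * 0.1
    }
    list(x = x, y = y)
  })
}

# independent closed-form fractional anisotropy from eigenvalues
fa_oracle <- function(l) {
  md <- mean(l)
  sqrt(3 / 2) * sqrt(sum((l - md)^2) / sum(l^2))
}
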