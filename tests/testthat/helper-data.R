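# Shared in-code fixtures for the test suite.

# a tiny labelled matrix with explicit values
toyMatrix <- function(values, nrow, ids = NULL, samples = NULL) {
  m <- matrix(values, nrow = nrow)
  rownames(m) <- ids %||% sprintf("mir-%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-group random matrix with iid normal noise
nullTwoGroup <- function(m = 20, n1 = 4, n2 = 4, seed = 1) {
  set.seed(seed)
  x <- toyMatrix(rnorm(m * (n1 + n2), mean = 10), m)
  list(x = x, groups = factor(rep(c("a", "b"), c(n1, n2))))
}

quietFilter <- function(...) suppressMessages(filterInformative(...))

# drop dimnames and the floored-provenance attribute for value comparison
stripFloor <- function(x) {
  attr(x, "floored") <- NULL
  unname(x)
}

quietStudy <- function(cfg) suppressMessages(simulateStudy(cfg))

nullConfig <- function(seed, ...) {
  simConfig(nSpikedPerGroup = c(C = 0L, BD = 0L, SZ = 0L), seed = seed, ...)
}
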