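.onLoad <- function(libname, pkgname) {
  ## Small GEMMs dominate the training loops; a single BLAS thread avoids
  ## oversubscription and keeps results bit-reproducible across hosts.
  try(.setBlasThreads(1L), silent = TRUE)
  invisible()
}
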