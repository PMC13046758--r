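# Shared fixtures for the suite. The default desk-scale scenario run is
# memoized so the end-to-end tests and the acceptance checks reuse one
# pipeline execution.

default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- heattract_config(out_dir = tempfile("ht_run_"))
      cache <<- suppressMessages(run_pipeline(cfg))
    }
    cache
  }
})

oracle_path <- function(fn) {
  p <- system.file("extdata", "oracle", fn, package = "heattract")
  if (!nzchar(p)) p <- file.path("inst", "extdata", "oracle", fn)
  p
}

# independent brute-force IDW used as oracle in several tests
idw_brute <- function(sxy, vals, txy, cutoff, k = 4, power = 2) {
  out <- numeric(nrow(txy))
  for (i in seq_len(nrow(txy))) {
    d <- sqrt((sxy[, 1] - txy[i, 1])^2 + (sxy[, 2] - txy[i, 2])^2)
    ord <- order(d)[seq_len(min(k, length(d)))]
    ord <- ord[d[ord] <= cutoff & !is.na(vals[ord])]
    if (!length(ord)) { out[i] <- NA_real_; next }
    if (d[ord[1]] < 1e-9) { out[i] <- vals[ord[1]]; next }
    w <- 1 / d[ord]^power
    out[i] <- sum(w * vals[ord]) / sum(w)
  }
  out
}
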