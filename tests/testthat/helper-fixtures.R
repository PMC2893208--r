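# Brute-force run scanner: independent oracle for extract_bouts
scan_bouts <- function(stages) {
  out <- list()
  i <- 1L
  while (i <= length(stages)) {
    j <- i
    while (j < length(stages) && stages[j + 1L] == stages[i]) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(stage = stages[i],
                                          duration_epochs = j - i + 1L,
                                          start_epoch_index = i - 1L,
                                          stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}

random_stages <- function(n, alphabet = c("W", "N1", "N2", "R")) {
  sample(alphabet, n, replace = TRUE)
}

write_stage_file <- function(text) {
  f <- tempfile(fileext = ".txt")
  writeLines(text, f)
  f
}

# Exact sum-of-exponentials curve over integer bins
noiseless_hist <- function(taus, y0, n_bins = 60) {
  x <- seq_len(n_bins)
  y <- as.vector(y0 %*% exp(-(1 / taus) %o% x))
  histogram_from_rel_freq(x, y)
}
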