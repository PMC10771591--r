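# shared fixtures, built in code at test time

fixture_montage <- montage_63()

# small montage for fast simulation tests: Cz and its surroundings
mini_montage <- function() {
  keep <- c("Cz", "FCz", "C1", "C2", "CPz", "Fz", "Pz", "C3")
  idx <- match(keep, fixture_montage$labels)
  eeg_montage(keep, fixture_montage$positions[idx, ])
}

quick_epochs <- function(data, fs = 1000, t_start = NULL, channels = NULL,
                         condition = "active") {
  d <- dim(data)
  if (is.null(t_start)) t_start <- 0
  times <- seq(t_start, by = 1000 / fs, length.out = d[3L])
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2L]))
  eeg_epochs(data, times, fs, channels, condition)
}

# brute-force population-sd oracle for the global field amplitude
gmfa_oracle <- function(data) {
  apply(data, 2L, function(v) sqrt(mean((v - mean(v))^2)))
}

# brute-force CCC oracle, divisor-n moments written out directly
ccc_oracle <- function(x, y) {
  n <- length(x)
  s12 <- sum((x - mean(x)) * (y - mean(y))) / n
  s1 <- sum((x - mean(x))^2) / n
  s2 <- sum((y - mean(y))^2) / n
  2 * s12 / (s1 + s2 + (mean(x) - mean(y))^2)
}
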