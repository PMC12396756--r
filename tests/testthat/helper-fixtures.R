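# small deterministic fixtures shared across tests

tiny_pattern <- function() {
  as_cell_pattern(
    data.frame(x = c(10, 40, 80, 120, 200),
               y = c(10, 50, 20, 90, 150),
               type = c("A", "B", "A", "B", "A")),
    window = pattern_window(0, 250, 0, 250)
  )
}

# the worked multipartner example: one range, beta_B = 1,
# delta_AB = 0.1 (repulsion), delta_BC = 20 (attraction)
multipartner_model <- function() {
  mrss_model(c("A", "B", "C"), range_spec(1, 100),
             log_beta = log(c(A = 1, B = 1, C = 1)),
             log_delta = list("A|B" = log(0.1), "B|C" = log(20)))
}

# moderate CSR fixture for fitting tests
csr_fixture <- function(seed = 1, side = 1000,
                        intensity = c(A = 1e-3, B = 1e-3, C = 5e-4)) {
  synth_csr_pattern(pattern_window(0, side, 0, side), intensity, seed = seed)
}

# brute-force neighbor-bin counter, the O(n^2) oracle for the compiled path
oracle_counts <- function(cells, qx, qy, range_spec, exclude = 0L) {
  ts <- sort(unique(cells$type))
  m <- length(range_spec$breakpoints)
  out <- matrix(0L, length(ts), m, dimnames = list(ts, NULL))
  hard <- FALSE
  for (j in seq_len(nrow(cells))) {
    if (j == exclude) next
    d <- sqrt((cells$x[j] - qx)^2 + (cells$y[j] - qy)^2)
    if (d < range_spec$hardcore) { hard <- TRUE; next }
    if (d > max(range_spec$breakpoints)) next
    k <- which(d < range_spec$breakpoints)[1]
    if (is.na(k)) k <- m # d equals the outermost breakpoint
    out[cells$type[j], k] <- out[cells$type[j], k] + 1L
  }
  attr(out, "hardcore") <- hard
  out
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
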