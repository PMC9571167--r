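# Shared fixtures: small deterministic trials and a hand-rolled trial builder.

make_trial <- function(n = 500, fs = 100, fill = 0) {
  df <- tibble::tibble(time = (seq_len(n) - 1) / fs)
  for (col in c(paste0("R", 1:5), paste0("L", 1:5))) df[[col]] <- rep(fill, n)
  df
}

# brute-force Mann-Whitney enumeration oracle: two-sided p over all labelings
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= u_obs + 1e-12)
  p_ge <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Cartesian shoelace oracle for the polar closed-curve area: polygon through
# the curve samples closed through the origin
shoelace_area <- function(theta, r) {
  x <- c(0, r * cos(theta))
  y <- c(0, r * sin(theta))
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}
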