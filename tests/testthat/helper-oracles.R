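# Independent oracles and small utilities shared by the tests.

# Literal nested-loop transcription of the pooling summation, extended to
# three spatial axes with exclude-padded borders: each output voxel is the
# mean over kernel offsets p, q, r in 1..K (centered via the (K+1)/2 shift)
# of the in-bounds neighbors only.
pool_oracle <- function(x, K) {
  d <- dim(x)
  out <- array(0, d)
  off <- (K + 1) / 2
  for (c_ in seq_len(d[1])) {
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) for (l in seq_len(d[4])) {
      s <- 0; n <- 0
      for (p in seq_len(K)) for (q in seq_len(K)) for (r in seq_len(K)) {
        ii <- i + p - off; jj <- j + q - off; ll <- l + r - off
        if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3] &&
            ll >= 1 && ll <= d[4]) {
          s <- s + x[c_, ii, jj, ll]
          n <- n + 1
        }
      }
      out[c_, i, j, l] <- s / n
    }
  }
  out
}

pu <- asNamespace("poolunetr")

rand_map <- function(C, D, H, W, sd = 1) {
  array(stats::rnorm(C * D * H * W, sd = sd), c(C, D, H, W))
}

# central-difference derivative of f at x[i]
num_deriv <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

tiny_config <- function(mixer = "pooling", use_se = FALSE,
                        roi = c(32L, 32L, 32L), in_channels = 4L,
                        out_channels = 3L, head = "sigmoid", ...) {
  model_config(feature_size = 12L, in_channels = in_channels,
               out_channels = out_channels, mixer = mixer, use_se = use_se,
               roi = roi, head = head, ...)
}
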