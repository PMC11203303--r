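# Independent brute-force oracles. These deliberately use plain term-by-term
# loops (never the package's digamma/closed-form paths) so they stay a
# separate route to the same quantities.

loop_power_sum <- function(n, a = 1) {
  s <- 0
  for (t in seq_len(n)) s <- s + 1 / t^a
  s
}

loop_interval_sum <- function(t1, t2, a = 1) {
  s <- 0
  for (t in seq.int(t1 + 1, t2)) s <- s + 1 / t^a
  s
}

# brute-force partial sums of the two-clock future series sum 1/((t+k)(u+k))
loop_two_clock_future <- function(t, u, K) {
  s <- 0
  for (k in seq_len(K)) s <- s + 1 / ((t + k) * (u + k))
  s
}
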