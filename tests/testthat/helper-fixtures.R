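## Shared small fixtures, built once per test run.

# coarse reconstruction-scale mesh (~360 elements) and the standard protocol
coarse_mesh <- build_disk_mesh(42, 8, target_edge_mm = 8)
std_protocol <- adjacent_protocol(8, current_mA = 0.1)

# finer simulation mesh for inverse-crime-avoiding tests (~2x elements)
fine_mesh <- build_disk_mesh(42, 8, target_edge_mm = 5.5)

homog_sigma <- function(mesh, value = 0.1) rep(value, n_elements(mesh))

# brute-force adjacent-protocol enumeration, independent of the package code:
# loop over all ordered electrode pairs and keep adjacent drive/meas pairs
# sharing no electrode
enumerate_adjacent_oracle <- function(n) {
  pats <- 0L
  for (d in seq_len(n)) {
    dp <- d; dn <- d %% n + 1L
    for (m in seq_len(n)) {
      mp <- m; mn <- m %% n + 1L
      if (length(intersect(c(dp, dn), c(mp, mn))) == 0) pats <- pats + 1L
    }
  }
  pats
}
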