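# shared fixtures: the experiment's sampling design and published truths

paper_times_s <- function() time_to_seconds(default_sampling_times_h(), "h")

ref_row <- function(series_id) {
  p <- reference_kinetic_params()
  as.list(p[p$series == series_id, ])
}

berry_radius_m <- function() sphere_radius(6.65, 6.51)

# independent brute-force oracle for the Fickian sphere series: plain
# high-order partial sum, no shortcuts
crank_series_oracle <- function(t, De, r, n) {
  vapply(t, function(ti) {
    k <- seq_len(n)
    (6 / pi^2) * sum(exp(-k^2 * pi^2 * De * ti / r^2) / k^2)
  }, numeric(1))
}

# noise-free Peleg-true kinetics table at the paper design
peleg_true_series <- function(k1, k2, times = paper_times_s(),
                              col = "WL_pct") {
  out <- tibble::tibble(time_s = times)
  out[[col]] <- peleg_predict(times, k1, k2)
  out
}
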