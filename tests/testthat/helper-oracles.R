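# Brute-force Hochberg step-up from its definition: sort ascending,
# adj(m) = p(m), adj(i) = min(adj(i+1), (m - i + 1) p(i)), cap at 1,
# return in input order. Independent of stats::p.adjust.
hochberg_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  adj[m] <- ps[m]
  if (m > 1) {
    for (i in (m - 1):1) adj[i] <- min(adj[i + 1], (m - i + 1) * ps[i])
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Backing-time records with given times (and optional days), in the shape
# the scoring functions expect.
backing_records <- function(times, day = "day1") {
  tibble::tibble(
    animal_id = paste0("a", seq_along(times)),
    genotype = "wildtype", treatment = "x",
    day = rep_len(day, length(times)),
    backing_time_s = times, censored = FALSE
  )
}

# A noiseless dFF trace on the standard 0.5 s grid.
dff_trace <- function(dff_fun, worm_id = "w1", duration = 135) {
  t_s <- seq(0, duration, by = 0.5)
  tibble::tibble(worm_id = worm_id, genotype = "wildtype",
                 condition = "stimulus", t_s = t_s,
                 dff_percent = dff_fun(t_s), normalized = TRUE)
}
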