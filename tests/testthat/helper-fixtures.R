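# Small programmatic fixtures shared across test files.

# A tiny noise-free scenario: constant-free affine link between July
# precipitation and the proxy, no tree effects, no juvenile trend.
noise_free_dataset <- function(years = c(1850, 1999), n_trees = 5,
                               slope = -0.06, intercept = -21.4, seed = 7) {
  climate <- gen_climate(years, ar1_coeff = 0.3, seed = seed)
  trees <- gen_tree_series(climate, n_trees = n_trees,
                           slope = slope, intercept = intercept,
                           tree_sd = 0, noise_sd = 0,
                           juvenile_amplitude = 0, juvenile_length = 50,
                           lifespan_mean = diff(range(period_years_(years))) + 1,
                           min_lifespan = 100,
                           min_replication = min(4, n_trees), seed = seed)
  list(climate = climate, trees = trees,
       agg = climate_aggregate(climate, "precipitation", 7),
       slope = slope, intercept = intercept)
}

# period_years is internal; tests re-derive the expansion themselves.
period_years_ <- function(p) if (length(p) == 2) p[1]:p[2] else sort(unique(p))

# Hand-built trees with exact values on given year windows.
flat_tree <- function(id, first, n, value, pith = first, scale = "d13C") {
  tree_series(id, first, rep(value, n), pith_year = pith, scale = scale)
}
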