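# Small fixtures shared across test files; everything is generated in code.

tiny_scene <- function(seed = 3, responses = list(), ...) {
  args <- list(n_small = 4, n_medium = 2, n_large = 1, dim_px = c(40, 48),
               responses = responses, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(make_scene, args)
}

# A series whose "complex" data is a real-valued magnitude stack: handy for
# hand-computed angiogram arithmetic.
series_from_mags <- function(mags) {
  structure(list(data = array(complex(real = mags, imaginary = 0),
                              dim = dim(mags)),
                 scale = 4, frame_index = 1L, lateral_location_index = 1L),
            class = "bscan_series")
}

# Between-class variance of a 3-way partition of the value vector at
# thresholds (t1, t2): the quantity multilevel Otsu maximizes.
bcv3 <- function(v, t1, t2) {
  mu <- mean(v)
  out <- 0
  for (cls in list(v[v <= t1], v[v > t1 & v <= t2], v[v > t2]))
    if (length(cls)) out <- out + length(cls) / length(v) * (mean(cls) - mu)^2
  out
}

# Brute-force maximal between-class variance over all threshold pairs drawn
# from a small histogram's bin edges.
otsu3_bruteforce_value <- function(v, n_bins) {
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  cand <- edges[2:n_bins]
  best <- -Inf
  for (i in seq_along(cand)[-length(cand)]) for (j in seq(i + 1, length(cand)))
    best <- max(best, bcv3(v, cand[i], cand[j]))
  best
}

# Frames list (constant matrices) for mask/extraction arithmetic.
const_frames <- function(vals, nr = 8, nc = 8, scale = 4) {
  lapply(seq_along(vals), function(i)
    angiogram_frame(matrix(vals[i], nr, nc), scale = scale, frame_index = i))
}
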