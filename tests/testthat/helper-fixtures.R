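# deterministic random images on a given scale
random_image <- function(h, w, seed, lo = 0, hi = 1) {
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}

# small phantom used by the slower comparisons
test_phantom <- function(side = 128L, t = 150) {
  make_phantom(phantom_spec(side, side, t = t))
}
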