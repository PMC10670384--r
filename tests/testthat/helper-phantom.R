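# Shared phantom fixtures, generated once per test run and cached.
# The test phantom is a scaled-down grid (96^3 voxels at 2 mm) so the whole
# suite stays fast; electrode and registration behaviour is unchanged.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), .fixture_cache)
  .fixture_cache[[key]]
}

test_phantom_config <- function(seed = 7) {
  phantom_config(dims = c(96, 96, 96), spacing = c(2, 2, 2), seed = seed)
}

std_phantom <- function() {
  cached_fixture("phantom", make_head_phantom(test_phantom_config()))
}

std_electrodes <- function() {
  cached_fixture("electrodes", {
    ph <- std_phantom()
    insert_electrodes(ph$ct, ph$brain_mask, electrode_spec(), seed = 11)
  })
}

# small uniform-geometry volume from an array
tiny_volume <- function(arr, spacing = c(1, 1, 1)) {
  seeg_volume(arr, spacing = spacing)
}

random_volume <- function(dims, seed = 1, lo = 0, hi = 100) {
  set.seed(seed)
  tiny_volume(array(runif(prod(dims), lo, hi), dim = dims))
}
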