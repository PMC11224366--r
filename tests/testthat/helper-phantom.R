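## Memoized phantom datasets shared across test files (generated once
## per test run; all fixtures are built in code, nothing is stored).

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.phantom_cache[[key]]))
    assign(key, force(expr), envir = .phantom_cache)
  .phantom_cache[[key]]
}

get_minimal <- function() cached("minimal", generate_phantom(phantom_spec_minimal()))

get_minimal_noisy <- function()
  cached("minimal_noisy",
         generate_phantom(phantom_spec_minimal(seed = 3L, noise_sd_frac = 0.02)))

get_five_pattern <- function()
  cached("five_pattern", generate_phantom(phantom_spec_five_pattern()))

get_stir_phantom <- function()
  cached("stir", generate_phantom(phantom_spec_stir(seed = 7L)))

## A tiny three-voxel fixture with hand-computable fat fractions.
tiny_dixon <- function(fsi = c(10, 30, 60), wsi = c(90, 70, 40)) {
  d <- c(length(fsi), 1L, 1L)
  water <- volumetric_image(array(wsi, d), c(1, 1, 1), kind = "dixon_water")
  fat <- volumetric_image(array(fsi, d), c(1, 1, 1), kind = "dixon_fat")
  list(water = water, fat = fat, mask = array(TRUE, d))
}

## Uniform-FF cuboid muscle: n voxels of constant FF at given spacing.
uniform_muscle <- function(dims = c(10, 10, 1), spacing = c(1, 1, 3),
                           ff = 20, S0 = 500, codes = 1L) {
  water <- volumetric_image(array(S0 * (1 - ff / 100), dims), spacing,
                            kind = "dixon_water")
  fat <- volumetric_image(array(S0 * ff / 100, dims), spacing,
                          kind = "dixon_fat")
  labels <- array(codes, dims)
  dict <- data.frame(code = unique(codes), name = paste("m", unique(codes)),
                     side = "left")
  list(water = water, fat = fat,
       labelmap = muscle_labelmap(labels, dict, spacing))
}
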