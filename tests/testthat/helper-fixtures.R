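# Shared fixtures: tiny volumes, random masks, random similarity
# transforms, and a small-grid phantom spec used where full-scale anatomy
# is unnecessary.

tiny_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  volume(values, spacing, origin)
}

random_mask <- function(dim = c(10, 10, 10), p = 0.1,
                        spacing = c(1, 1, 1)) {
  v <- array(as.double(stats::runif(prod(dim)) < p), dim)
  if (!any(v == 1)) v[1, 1, 1] <- 1
  volume(v, spacing, type = "mask")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

random_similarity <- function(max_t = 20) {
  similarity_transform(s = stats::runif(1, 0.7, 1.4),
                       R = random_rotation(),
                       center = stats::rnorm(3, 0, 10),
                       t = stats::rnorm(3, 0, max_t))
}

# scaled-down phantom (1/2 resolution per axis) for fast structural tests
small_spec <- function(...) {
  phantom_spec(grid_dim = c(32, 32, 80), spacing = c(8, 8, 16), ...)
}

# brute-force distance transform oracle (exhaustive O(n^2) scan)
brute_force_dt <- function(mask) {
  ctr <- voxel_centers(mask)
  obj <- ctr[as.vector(mask$values == 1), , drop = FALSE]
  d <- apply(ctr, 1, function(p) sqrt(min(colSums((t(obj) - p)^2))))
  volume(array(d, dim(mask$values)), mask$spacing, mask$origin)
}
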