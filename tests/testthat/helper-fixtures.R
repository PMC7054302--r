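# Shared fixtures, generated in code (no binary test data).

# small deterministic reference library on a coarse grid
tiny_library <- function(seed = 7L) {
  make_reference_library(seed = seed, wavelengths = seq(400, 750, by = 2))
}

# small planar section render used across tests
tiny_render <- function(section = 1L, seed = 3L, nx = 8L, ny = 48L, nl = 242L,
                        noise_sd = 0.005, artifact_frac = 0.01,
                        geometry = scene_geometry("planar"), ...) {
  render_base_hypercube(chart_spec(), section, tiny_library(), geometry,
                        seed = seed, nx = nx, ny = ny, nl = nl,
                        noise_sd = noise_sd, artifact_frac = artifact_frac,
                        ...)
}

# random valid hypercube
random_cube <- function(seed, nx = 4L, ny = 6L, nl = 9L) {
  with_seed <- hyseclass:::with_seed
  with_seed(seed, hypercube(array(stats::runif(nx * ny * nl, 0, 100),
                                  c(nx, ny, nl)),
                            seq(400, 700, length.out = nl)))
}

# naive O(n * w^2) sliding-window median with symmetric reflection — the
# independent oracle for the C++ filter
naive_median_filter <- function(m, size) {
  half <- size %/% 2
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- stats::median(m[refl(i + (-half:half), nr),
                                 refl(j + (-half:half), nc)])
  }
  out
}

legend_19 <- function() {
  stats::setNames(c("background", paste0("class_", 1:18)), as.character(0:18))
}
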