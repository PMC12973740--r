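# Shared fixtures and independent oracles used across the suite.

# strip class/stage/provenance attributes for raw pixel comparisons
bare <- function(x) matrix(as.vector(x), nrow(x), ncol(x))

# Exhaustive per-box oracle: loops over every box of the grid and checks
# pixel membership directly. Independent of the tabulation used by
# box_count().
brute_box_count <- function(x, eps, off = c(0L, 0L)) {
  h <- nrow(x); w <- ncol(x)
  nbr <- (h - 1L + off[1]) %/% eps + 1L
  nbc <- (w - 1L + off[2]) %/% eps + 1L
  occupied <- 0L
  masses <- numeric(0)
  for (bi in 0:(nbr - 1L)) {
    for (bj in 0:(nbc - 1L)) {
      rs <- max(1L, bi * eps + 1L - off[1]):min(h, (bi + 1L) * eps - off[1])
      cs <- max(1L, bj * eps + 1L - off[2]):min(w, (bj + 1L) * eps - off[2])
      m <- sum(x[rs, cs])
      masses <- c(masses, m)
      if (m > 0L) occupied <- occupied + 1L
    }
  }
  list(occupied = occupied, masses = masses)
}

# single-offset fd on stated sizes, for closed-form checks
fd_single_origin <- function(x, sizes) {
  fractal_dimension(box_count(x, box_sizes = sizes, n_offsets = 1L))$fd
}

carpet_patch_64 <- function() {
  make_ifs_fractal(synth_params(texture_model = "ifs_fractal", size = 64))
}

has_2x2_block <- function(x) {
  any(x[-nrow(x), -ncol(x)] & x[-1, -ncol(x)] &
      x[-nrow(x), -1] & x[-1, -1])
}

anterior_fd_pvalue <- function(cohort) {
  ant <- cohort[cohort$region == "anterior", ]
  samples <- split(ant$fd,
                   factor(ant$group, c("normal", "borderline", "high")))
  kruskal_wallis(samples)$p
}
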