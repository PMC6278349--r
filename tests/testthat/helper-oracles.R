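# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Origin-constrained least-squares slope, closed form.
oracle_origin_slope <- function(x, y) sum(x * y) / sum(x * x)

# Ordinary least squares by explicit normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1L], slope = beta[2L])
}

# Monte-Carlo accessible-surface oracle: rejection sampling of uniformly
# random points on each probe-inflated sphere against all neighbour spheres.
oracle_mc_asa <- function(mol, probe = 1.4, n_per_atom = 1e5, seed = 1234) {
  at <- mol$atoms
  stopifnot(!anyNA(at$radius))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rexp <- at$radius + probe
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(at))) {
    # uniform points on the sphere via normalized Gaussians
    g <- matrix(rnorm(3 * n_per_atom), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    p <- sweep(g * rexp[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_per_atom)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & (dj2 >= rexp[j]^2)
    }
    total <- total + mean(exposed) * 4 * pi * rexp[i]^2
  }
  total
}

# Table-1 component fixture path (packaged with the installed package).
fixture_table_path <- function() {
  system.file("extdata", "aromatic_components.csv", package = "hydrodecomp")
}

fixture_geometry_dir <- function() {
  system.file("extdata", "geometries", package = "hydrodecomp")
}
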