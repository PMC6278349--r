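# Seeded synthetic component tables and idealized test geometries.
#
# The generator emulates the statistical structure of explicit-solvation
# component tables: an electrostatic component linear in an (unobserved in
# real tables) ensemble-averaged interaction energy, and dispersion /
# cavitation components each linear in surface area with opposing slopes
# whose sum leaves a small negative net slope. It exists so that every
# analysis stage can be validated by recovering known generator parameters;
# it does not simulate water structure or dynamics.

#' Configuration for the synthetic component-table generator
#'
#' Defaults encode the study conditions the analysis targets: surface areas
#' spanning 200-450 Angstrom^2 (bracketing benzene through pyrene),
#' electrostatic linear-response slope 0.41, dispersion slope -0.050 and
#' cavitation slope +0.0369 kcal/mol/A^2 (net -0.0131), intercepts summing
#' to 3.56 kcal/mol, reorganization energies in [0.3, 0.9] kcal/mol, and
#' modest Gaussian noise on each channel.
#'
#' @param n_solutes number of solutes to generate (>= 0).
#' @param seed integer seed; the generator is fully deterministic given
#'   (config, seed).
#' @param asa_range,reorg_range length-2 numeric ranges (min < max).
#' @param lrt_slope,lrt_noise_sd electrostatic response slope and noise sd.
#' @param disp_slope,disp_intercept dispersion-vs-ASA line (slope < 0 by
#'   default).
#' @param cav_slope,cav_intercept cavitation-vs-ASA line (slope > 0 by
#'   default).
#' @param component_noise_sd Gaussian sd added to each of the dispersion and
#'   cavitation components, kcal/mol.
#' @param exp_noise_sd Gaussian sd of the synthetic "experimental" totals
#'   about the noise-free component sum, kcal/mol.
#' @param u_es_coupling if `TRUE` (default) the ensemble-averaged
#'   electrostatic interaction energy scales with solute size:
#'   `u_es = -0.05 * asa * U(0.5, 1.5)`; if `FALSE`, `u_es ~ U(-25, -1)`.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_solutes = 500, seed = 1,
                             asa_range = c(200, 450),
                             lrt_slope = 0.41, lrt_noise_sd = 0.2,
                             disp_slope = -0.050, disp_intercept = 2.00,
                             cav_slope = 0.0369, cav_intercept = 1.56,
                             component_noise_sd = 0.1,
                             reorg_range = c(0.3, 0.9),
                             exp_noise_sd = 0.3,
                             u_es_coupling = TRUE) {
  n_solutes <- as.integer(n_solutes)
  if (is.na(n_solutes) || n_solutes < 0L) {
    stop("n_solutes must be a non-negative integer", call. = FALSE)
  }
  chk_range <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] >= r[2L]) {
      stop(what, " must be a finite (min, max) pair with min < max",
           call. = FALSE)
    }
    as.numeric(r)
  }
  chk_sd <- function(s, what) {
    if (!is.finite(s) || s < 0) stop(what, " must be >= 0", call. = FALSE)
    as.numeric(s)
  }
  structure(list(
    n_solutes = n_solutes, seed = as.integer(seed),
    asa_range = chk_range(asa_range, "asa_range"),
    lrt_slope = as.numeric(lrt_slope),
    lrt_noise_sd = chk_sd(lrt_noise_sd, "lrt_noise_sd"),
    disp_slope = as.numeric(disp_slope),
    disp_intercept = as.numeric(disp_intercept),
    cav_slope = as.numeric(cav_slope),
    cav_intercept = as.numeric(cav_intercept),
    component_noise_sd = chk_sd(component_noise_sd, "component_noise_sd"),
    reorg_range = chk_range(reorg_range, "reorg_range"),
    exp_noise_sd = chk_sd(exp_noise_sd, "exp_noise_sd"),
    u_es_coupling = isTRUE(u_es_coupling)),
    class = "generator_config")
}

# evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched. Each generated column uses its own substream so
# adding columns later cannot shift existing ones.
.with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.substream_seed <- function(root, k) {
  (as.integer(root) %% 100003L) * 10007L + 7919L * k
}

#' Generate a synthetic solute component table
#'
#' Per solute, in documented substream order:
#' `asa ~ U(asa_range)`;
#' `u_es = -0.05 * asa * U(0.5, 1.5)` (or `U(-25, -1)` without coupling);
#' `dA_es = lrt_slope * u_es + N(0, lrt_noise_sd)`;
#' `dA_disp = disp_slope * asa + disp_intercept + N(0, component_noise_sd)`;
#' `dA_cav = cav_slope * asa + cav_intercept + N(0, component_noise_sd)`;
#' `e_reorg ~ U(reorg_range)`;
#' `exp_dA_hyd = e_reorg + dA_es + dA_disp + dA_cav + N(0, exp_noise_sd)`.
#' The printed total `dA_hyd` is set to the noise-free sum of the stored
#' components (so the table passes [check_consistency()] exactly).
#'
#' @param config a [generator_config()].
#' @return List of class `synthetic_set` with elements `records` (a
#'   [solute_table()] carrying an extra `u_es` column) and `truth` (the
#'   config).
#' @examples
#' s <- generate_solute_set(generator_config(n_solutes = 5, seed = 42))
#' s$records$name
#' @export
generate_solute_set <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_solutes
  if (n == 0L) {
    tab <- solute_table(character(), numeric(), numeric(), numeric(),
                        numeric())
    tab$u_es <- numeric()
    return(structure(list(records = tab, truth = config),
                     class = "synthetic_set"))
  }
  s <- function(k) .substream_seed(config$seed, k)
  asa <- .with_substream(s(1L), runif(n, config$asa_range[1L],
                                      config$asa_range[2L]))
  u_es <- if (config$u_es_coupling) {
    -0.05 * asa * .with_substream(s(2L), runif(n, 0.5, 1.5))
  } else {
    .with_substream(s(2L), runif(n, -25, -1))
  }
  dA_es <- config$lrt_slope * u_es +
    .with_substream(s(3L), rnorm(n, 0, config$lrt_noise_sd))
  dA_disp <- config$disp_slope * asa + config$disp_intercept +
    .with_substream(s(4L), rnorm(n, 0, config$component_noise_sd))
  dA_cav <- config$cav_slope * asa + config$cav_intercept +
    .with_substream(s(5L), rnorm(n, 0, config$component_noise_sd))
  e_reorg <- .with_substream(s(6L), runif(n, config$reorg_range[1L],
                                          config$reorg_range[2L]))
  total <- e_reorg + dA_es + dA_disp + dA_cav
  exp_dA_hyd <- total + .with_substream(s(7L), rnorm(n, 0, config$exp_noise_sd))
  tab <- solute_table(name = sprintf("synthetic_%03d", seq_len(n)),
                      e_reorg = e_reorg, dA_es = dA_es, dA_disp = dA_disp,
                      dA_cav = dA_cav, dA_hyd = total,
                      exp_dA_hyd = exp_dA_hyd, asa = asa)
  tab$u_es <- u_es
  structure(list(records = tab, truth = config), class = "synthetic_set")
}

#' @export
print.synthetic_set <- function(x, ...) {
  cat(sprintf("<synthetic_set> %d solute(s), seed %d (net non-ES slope %.4g)\n",
              nrow(x$records), x$truth$seed,
              x$truth$disp_slope + x$truth$cav_slope))
  invisible(x)
}

#' Idealized rigid test geometries
#'
#' Deterministic coordinates for ASA testing: `benzene` (planar regular
#' hexagon, C-C 1.39 A, C-H 1.09 A, centroid at the origin, z = 0),
#' `naphthalene_like` (two idealized fused hexagons sharing an edge, planar),
#' and `methane_like` (tetrahedral, C-H 1.09 A). These are geometric
#' idealizations for exercising the surface engine, not optimized structures.
#'
#' @param name one of `"benzene"`, `"naphthalene_like"`, `"methane_like"`.
#' @return A [molecule()] (radii not yet assigned).
#' @examples
#' make_fixture_geometry("methane_like")
#' @export
make_fixture_geometry <- function(name = c("benzene", "naphthalene_like",
                                           "methane_like")) {
  name <- match.arg(name)
  cc <- 1.39; ch <- 1.09
  if (name == "benzene") {
    ang <- (0:5) * pi / 3
    el <- c(rep("C", 6), rep("H", 6))
    x <- c(cc * cos(ang), (cc + ch) * cos(ang))
    y <- c(cc * sin(ang), (cc + ch) * sin(ang))
    z <- rep(0, 12)
    return(molecule("benzene", el, x, y, z))
  }
  if (name == "methane_like") {
    d <- ch / sqrt(3)
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * d
    return(molecule("methane_like", c("C", rep("H", 4)),
                    x = c(0, dirs[, 1]), y = c(0, dirs[, 2]),
                    z = c(0, dirs[, 3])))
  }
  # naphthalene_like: hexagon centers at (+/- cc*cos(30), 0); the two
  # carbons at (0, +/- cc/2) are shared and carry no hydrogen
  d <- cc * cos(pi / 6)
  right <- (c(30, 90, 150, 210, 270, 330)) * pi / 180
  left <- (c(30, 90, 270, 330)) * pi / 180
  cx <- c(d + cc * cos(right), -d + cc * cos(pi - left))
  cy <- c(cc * sin(right), cc * sin(pi - left))
  # hydrogens on every carbon except the two shared ring-fusion atoms
  shared <- abs(cx) < 1e-9
  hx <- numeric(0); hy <- numeric(0)
  centers_x <- c(rep(d, 6), rep(-d, 4))
  for (i in which(!shared)) {
    ux <- cx[i] - centers_x[i]; uy <- cy[i]
    nrm <- sqrt(ux^2 + uy^2)
    hx <- c(hx, cx[i] + ch * ux / nrm)
    hy <- c(hy, cy[i] + ch * uy / nrm)
  }
  molecule("naphthalene_like",
           c(rep("C", length(cx)), rep("H", length(hx))),
           x = c(cx, hx), y = c(cy, hy), z = rep(0, length(cx) + length(hx)))
}

#' Generate synthetic linear-response energy pairs
#'
#' `u_mean ~ U(-25, -1)` kcal/mol (spanning the electrostatic interaction
#' magnitudes of small aromatic solutes) and
#' `dA = slope * u_mean + N(0, noise_sd)`.
#'
#' @param n number of pairs (>= 1).
#' @param slope true response slope.
#' @param noise_sd Gaussian noise sd, kcal/mol.
#' @param seed integer seed.
#' @return An [energy_pairs()] table.
#' @examples
#' fit_through_origin(make_lrt_pairs(200, 0.41, 0.2, seed = 11))
#' @export
make_lrt_pairs <- function(n, slope, noise_sd, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  u <- .with_substream(.substream_seed(seed, 1L), runif(n, -25, -1))
  dA <- slope * u +
    .with_substream(.substream_seed(seed, 2L), rnorm(n, 0, noise_sd))
  energy_pairs(dA, u, label = sprintf("pair_%03d", seq_len(n)))
}
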