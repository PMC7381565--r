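# Synthetic communities, environment tables and paleoclimate grids with known
# statistical structure, so every downstream stage is testable offline.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design the package targets: 16 natural sites on
#' a 22-40 degree N latitudinal gradient, three plots per site averaged to the
#' site level, roughly 150 identified individuals per plot sample, and 64
#' genera.  Each predictor set (climatic, soil, historical) is driven by one
#' latent factor tied to latitude; \code{cross_set_correlation} controls how
#' collinear the three latent drivers are (field data of this kind are highly
#' collinear, hence the default of 0.6).
#'
#' @param n_sites number of sites (>= 4).
#' @param n_plots plots per site, averaged to site level.
#' @param n_genera genus pool size.
#' @param individuals_identified individuals identified per plot sample
#'   (multinomial draw size).
#' @param lat_range latitudinal extent, degrees North.
#' @param lon_range longitudinal extent, degrees East.
#' @param effect_sizes named numeric vector over (a subset of)
#'   \code{c("climatic", "soil", "historical")}: standardized slope of the
#'   latent diversity driver on each set's latent factor.  Negative values
#'   give lower diversity at higher latitude (the latents are oriented
#'   northward).
#' @param cross_set_correlation pairwise correlation of the three latent set
#'   factors, in \code{[0, 1)}.
#' @param noise_sd standard deviation of the site-level noise added to the
#'   latent diversity driver.
#' @param var_loading loading of each observed variable on its set's latent
#'   factor (the rest is independent measurement noise).
#' @param niche_breadth baseline Gaussian niche breadth on the latent
#'   gradient.
#' @param evenness_gain how strongly the effective niche breadth (and hence
#'   richness/evenness) responds to the latent diversity driver.
#' @param plot_sd between-plot standard deviation of the gradient position
#'   within a site.
#' @param seed master seed; all components draw from named substreams of it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_sites = 16, n_plots = 3, n_genera = 64,
                       individuals_identified = 150,
                       lat_range = c(22, 40), lon_range = c(98, 122),
                       effect_sizes = c(climatic = -1, soil = -0.4,
                                        historical = -0.2),
                       cross_set_correlation = 0.6, noise_sd = 1.1,
                       var_loading = 0.9, niche_breadth = 0.35,
                       evenness_gain = 0.5, plot_sd = 0.15, seed = 1) {
  stopifnot(n_sites >= 4, n_plots >= 1, n_genera >= 2,
            individuals_identified >= 1, length(lat_range) == 2)
  if (!all(names(effect_sizes) %in% PREDICTOR_SETS))
    stop("effect_sizes names must be among: ",
         paste(PREDICTOR_SETS, collapse = ", "))
  if (cross_set_correlation < 0 || cross_set_correlation >= 1)
    stop("cross_set_correlation must be in [0, 1): values >= 1 give a ",
         "degenerate latent covariance")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  eff <- c(climatic = 0, soil = 0, historical = 0)
  eff[names(effect_sizes)] <- effect_sizes
  structure(list(n_sites = as.integer(n_sites), n_plots = as.integer(n_plots),
                 n_genera = as.integer(n_genera),
                 individuals_identified = as.integer(individuals_identified),
                 lat_range = lat_range, lon_range = lon_range,
                 effect_sizes = eff,
                 cross_set_correlation = cross_set_correlation,
                 noise_sd = noise_sd, var_loading = var_loading,
                 niche_breadth = niche_breadth, evenness_gain = evenness_gain,
                 plot_sd = plot_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Site coordinates: latitudes evenly spaced over the gradient, longitudes
# drawn once from their own substream.
sim_sites <- function(cfg) {
  lat <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = cfg$n_sites)
  lon <- with_seed(substream(cfg$seed, "coords"),
                   stats::runif(cfg$n_sites, cfg$lon_range[1], cfg$lon_range[2]))
  data.frame(site = sprintf("S%02d", seq_len(cfg$n_sites)),
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

# Observed-variable roster: name, set, intercept, scale, sign of the loading
# on the set latent (latents are oriented northward).
SIM_VARIABLES <- data.frame(
  variable = c("MAT", "MAP", "TS", "PS",
               "SOC", "TN", "pH",
               "TA", "PA", "TCV", "PCV"),
  set = c(rep("climatic", 4), rep("soil", 3), rep("historical", 4)),
  mu  = c(16, 900, 700, 55, 14, 1.4, 6.8, 5, 120, 2.6, 2.4),
  sc  = c(7, 450, 250, 15, 5, 0.5, 0.8, 1.5, 60, 0.5, 0.5),
  sgn = c(-1, -1, 1, 1, 1, 1, 1, 1, -1, 1, 1),
  stringsAsFactors = FALSE
)

#' Generate a synthetic environment table
#'
#' Builds the three latent set factors from standardized latitude plus
#' independent noise so that their pairwise correlation equals
#' \code{cfg$cross_set_correlation} (up to Monte-Carlo error), then emits the
#' 11 observed variables (4 climatic, 3 soil, 4 historical) as noisy linear
#' readouts of their set's latent.
#'
#' @param cfg a \code{sim_config}.
#' @param sites optional site table from \code{sim_sites}; regenerated from
#'   \code{cfg} if omitted.
#' @return A \code{predictor_table} with attributes \code{"latents"} (n x 3
#'   matrix) and \code{"coords"} (the site table).
#' @export
sim_env <- function(cfg, sites = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(sites)) sites <- sim_sites(cfg)
  n <- cfg$n_sites
  z <- as.vector(scale(sites$lat))
  rho <- cfg$cross_set_correlation
  latents <- with_seed(substream(cfg$seed, "env"), {
    eps <- matrix(stats::rnorm(n * 3), n, 3)
    sqrt(rho) * z + sqrt(1 - rho) * eps
  })
  colnames(latents) <- PREDICTOR_SETS
  w <- cfg$var_loading
  vars <- with_seed(substream(cfg$seed, "env_vars"), {
    out <- lapply(seq_len(nrow(SIM_VARIABLES)), function(k) {
      v <- SIM_VARIABLES[k, ]
      lat_k <- latents[, v$set]
      v$mu + v$sc * (v$sgn * w * lat_k + sqrt(1 - w^2) * stats::rnorm(n))
    })
    names(out) <- SIM_VARIABLES$variable
    as.data.frame(out, check.names = FALSE)
  })
  env <- predictor_table(vars, sets = SIM_VARIABLES$set, sites = sites$site)
  attr(env, "latents") <- latents
  attr(env, "coords") <- sites
  env
}

# Latent diversity driver for each site: weighted sum of set latents + noise.
sim_driver <- function(cfg, latents) {
  d <- as.vector(latents %*% cfg$effect_sizes[PREDICTOR_SETS])
  d + cfg$noise_sd * with_seed(substream(cfg$seed, "driver"),
                               stats::rnorm(nrow(latents)))
}

#' Generate a synthetic community
#'
#' Genus relative abundances follow Gaussian niche curves along a composite
#' latent gradient whose loadings implement \code{cfg$effect_sizes}; the
#' effective niche breadth widens with the latent diversity driver, so sites
#' high on the driver support richer, more even assemblages.  Each plot is a
#' multinomial draw of \code{individuals_identified} individuals; the site
#' matrix is the arithmetic mean of its plots (fractional counts allowed).
#'
#' @param cfg a \code{sim_config}.
#' @param env environment table from \code{sim_env} (its \code{"latents"}
#'   attribute defines the gradient).
#' @return A \code{community_matrix} with attribute \code{"plot_counts"}
#'   (n_sites x n_genera x n_plots integer array) and \code{"driver"}.
#' @export
sim_community <- function(cfg, env) {
  stopifnot(inherits(cfg, "sim_config"))
  latents <- attr(env, "latents")
  if (is.null(latents))
    stop("'env' must come from sim_env(): missing latent factors")
  if (nrow(env) != cfg$n_sites)
    stop("environment table rows do not match cfg$n_sites")
  d <- sim_driver(cfg, latents)
  dstd <- as.vector(scale(d))
  optima <- seq(-2.5, 2.5, length.out = cfg$n_genera)
  sad <- with_seed(substream(cfg$seed, "sad"),
                   stats::rlnorm(cfg$n_genera, 0, 0.5))
  sites <- rownames(env)
  plots <- with_seed(substream(cfg$seed, "community"), {
    arr <- array(0L, dim = c(cfg$n_sites, cfg$n_genera, cfg$n_plots))
    for (i in seq_len(cfg$n_sites)) {
      sigma_i <- cfg$niche_breadth * exp(cfg$evenness_gain * dstd[i])
      for (r in seq_len(cfg$n_plots)) {
        pos <- dstd[i] + cfg$plot_sd * stats::rnorm(1)
        wgt <- sad * exp(-(pos - optima)^2 / (2 * sigma_i^2))
        if (!any(wgt > 0))
          stop("all-zero niche weights at site '", sites[i], "'")
        arr[i, , r] <- stats::rmultinom(1, cfg$individuals_identified,
                                        wgt / sum(wgt))[, 1]
      }
    }
    arr
  })
  site_mat <- apply(plots, c(1, 2), mean)
  comm <- community_matrix(site_mat, sites = sites,
                           genera = sprintf("gen%02d", seq_len(cfg$n_genera)))
  attr(comm, "plot_counts") <- plots
  attr(comm, "driver") <- d
  comm
}

#' Generate a co-registered pair of current and LGM climate grids
#'
#' Supports analytic fields for oracle testing: \code{"planar"} gives
#' \code{T = a x + b y + c} (x, y in km from the lower-left corner, evaluated
#' at cell centres) with the LGM field offset by \code{lgm_offset};
#' \code{"noisy-planar"} adds i.i.d. Gaussian noise to both epochs.
#'
#' @param nx,ny grid dimensions (>= 3).
#' @param cellsize_km cell size in km.
#' @param field_spec list with \code{type} ("planar" or "noisy-planar"),
#'   plane coefficients \code{a}, \code{b}, \code{c}, \code{lgm_offset}, and
#'   \code{noise_sd} for the noisy variant.
#' @param seed seed for the noisy variant.
#' @param variable metadata tag for both grids.
#' @return List with elements \code{current} and \code{lgm}.
#' @export
sim_paleo_grids <- function(nx, ny, cellsize_km = 1,
                            field_spec = list(type = "planar", a = 0.003,
                                              b = 0.004, c = 10,
                                              lgm_offset = -4, noise_sd = 0.5),
                            seed = 1, variable = "MAT") {
  if (nx < 3 || ny < 3)
    stop("nx and ny must be >= 3 (gradient stencil undefined otherwise)")
  type <- match.arg(field_spec$type, c("planar", "noisy-planar"))
  a <- field_spec$a %||% 0.003
  b <- field_spec$b %||% 0.004
  cc <- field_spec$c %||% 10
  off <- field_spec$lgm_offset %||% -4
  x <- (seq_len(nx) - 0.5) * cellsize_km
  y <- (seq_len(ny) - 0.5) * cellsize_km
  # north-up storage: row 1 holds the largest y
  plane <- outer(rev(y), x, function(yy, xx) a * xx + b * yy + cc)
  cur <- plane
  lgm <- plane + off
  if (type == "noisy-planar") {
    sd <- field_spec$noise_sd %||% 0.5
    noise <- with_seed(substream(seed, "grids"),
                       list(cur = matrix(stats::rnorm(nx * ny, 0, sd), ny, nx),
                            lgm = matrix(stats::rnorm(nx * ny, 0, sd), ny, nx)))
    cur <- cur + noise$cur
    lgm <- lgm + noise$lgm
  }
  list(current = climate_grid(cur, cellsize_km, units = "km",
                              variable = variable, epoch = "current"),
       lgm = climate_grid(lgm, cellsize_km, units = "km",
                          variable = variable, epoch = "LGM"))
}

# Analytic generating fractions: population R^2 of the latent driver on each
# subset of latent factors under the known joint-normal structure, pushed
# through the same inclusion-exclusion used by the estimator.
sim_truth <- function(cfg) {
  rho <- cfg$cross_set_correlation
  e <- cfg$effect_sizes[PREDICTOR_SETS]
  Sigma <- matrix(rho, 3, 3, dimnames = list(PREDICTOR_SETS, PREDICTOR_SETS))
  diag(Sigma) <- 1
  var_d <- as.numeric(t(e) %*% Sigma %*% e) + cfg$noise_sd^2
  b <- as.vector(Sigma %*% e)
  names(b) <- PREDICTOR_SETS
  r2 <- function(subset) {
    if (var_d == 0) return(0)
    bs <- b[subset]
    as.numeric(t(bs) %*% solve(Sigma[subset, subset, drop = FALSE]) %*% bs) / var_d
  }
  R <- c(C = r2("climatic"), S = r2("soil"), H = r2("historical"),
         CS = r2(c("climatic", "soil")), CH = r2(c("climatic", "historical")),
         SH = r2(c("soil", "historical")), CSH = r2(PREDICTOR_SETS))
  partition_fractions(R)
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' @param cfg a \code{sim_config}.
#' @return List of class \code{synthetic_dataset}: \code{community},
#'   \code{env}, \code{sites} (coordinates), \code{driver} (latent diversity
#'   driver), and \code{truth} (the analytic generating pure/shared variance
#'   fractions of the driver).
#' @export
sim_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sites <- sim_sites(cfg)
  env <- sim_env(cfg, sites)
  comm <- sim_community(cfg, env)
  structure(list(community = comm, env = env, sites = sites,
                 driver = attr(comm, "driver"), truth = sim_truth(cfg),
                 config = cfg),
            class = "synthetic_dataset")
}

#' Generate a null dataset (no environment-diversity link)
#'
#' All effect sizes are zero, so the community is driven by pure site-level
#' noise independent of every predictor; the recorded truth fractions are all
#' zero.  Used as the type-I-error harness for the permutation tests.
#'
#' @param cfg a \code{sim_config}; its \code{effect_sizes} are overridden
#'   with zeros.
#' @return A \code{synthetic_dataset}.
#' @export
sim_null_dataset <- function(cfg) {
  cfg$effect_sizes[] <- 0
  sim_dataset(cfg)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d sites, %d genera, seed %d\n",
              x$config$n_sites, x$config$n_genera, x$config$seed))
  cat("Generating fractions (latent driver):\n")
  print(round(x$truth, 4))
  invisible(x)
}
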