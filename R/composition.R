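# Composition-side analyses: NMDS ordination, environmental vector fitting,
# Mantel tests and distance-based variation partitioning.

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Iterative stress minimization (isotonic regression of ordination distances
#' on the input dissimilarities) via \code{vegan::metaMDS}, taking the best
#' of \code{n_starts} random starts; deterministic under \code{seed}.
#'
#' @param d a \code{dist} or symmetric matrix of dissimilarities.
#' @param k number of ordination dimensions (default 2).
#' @param n_starts maximum number of random starts (default 50).
#' @param seed RNG seed for the random starts.
#' @return Object of class \code{nmds_ord}: centred \code{scores} (n x k),
#'   \code{stress} in [0, 1], \code{converged}, and the underlying vegan
#'   object as \code{engine}.
#' @export
nmds_ord <- function(d, k = 2, n_starts = 50, seed = NULL) {
  d <- as_dist_matrix(d, "dissimilarity matrix")
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 sites for a k-dimensional NMDS")
  m <- with_seed(seed, {
    vegan::metaMDS(d, k = k, trymax = n_starts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  })
  sc <- vegan::scores(m, display = "sites")
  sc <- scale(sc, center = TRUE, scale = FALSE)
  attr(sc, "scaled:center") <- NULL
  structure(list(scores = sc, stress = m$stress, k = k, n_starts = n_starts,
                 converged = isTRUE(m$converged) ||
                   (is.numeric(m$converged) && m$converged > 0),
                 seed = seed, engine = m),
            class = "nmds_ord")
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d sites, k = %d, stress = %.4f (%s, %d starts)\n",
              nrow(x$scores), x$k, x$stress,
              if (x$converged) "converged" else "no convergent solution",
              x$n_starts))
  invisible(x)
}

#' @export
plot.nmds_ord <- function(x, ...) {
  plot(x$scores[, 1], x$scores[, 2], xlab = "NMDS1", ylab = "NMDS2",
       main = sprintf("NMDS (stress %.3f)", x$stress), ...)
  graphics::text(x$scores[, 1], x$scores[, 2], rownames(x$scores), pos = 3,
                 cex = 0.7)
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' For each predictor, the least-squares fit of the variable on the
#' ordination scores gives a direction of steepest increase (unit vector) and
#' a goodness of fit r-squared; significance comes from permuting the
#' variable across sites (one-sided on r-squared).  Backed by
#' \code{vegan::envfit}.
#'
#' @param ord an \code{nmds_ord} (or a numeric score matrix).
#' @param env a \code{predictor_table} with sites in the same order.
#' @param n_perm number of permutations (default 999).
#' @param seed permutation seed.
#' @return Data frame of class \code{envfit_table}: one row per variable with
#'   its set label, unit direction components, \code{r2} and \code{p}
#'   (constant variables get \code{r2 = 0, p = 1} with a warning).
#' @export
env_vector_fit <- function(ord, env, n_perm = 999, seed = NULL) {
  scores <- if (inherits(ord, "nmds_ord")) ord$scores else as.matrix(ord)
  sets <- predictor_sets(env)
  if (nrow(env) != nrow(scores))
    stop("ordination and predictor table differ in site count")
  X <- as.data.frame(env)
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    warning("constant variable(s) cannot be fitted: ",
            paste(names(X)[const], collapse = ", "))
  fitted_vars <- names(X)[!const]
  ax_names <- paste0("axis", seq_len(ncol(scores)))
  rows <- list()
  if (length(fitted_vars)) {
    ef <- with_seed(seed, {
      vegan::envfit(scores, X[fitted_vars], permutations = n_perm)
    })
    arr <- ef$vectors$arrows
    pvals <- ef$vectors$pvals
    for (v in fitted_vars) {
      row <- data.frame(variable = v, set = unname(sets[v]),
                        r2 = unname(ef$vectors$r[v]),
                        p = if (is.null(pvals)) NA_real_ else unname(pvals[v]),
                        stringsAsFactors = FALSE)
      row[ax_names] <- as.list(arr[v, ])
      rows[[v]] <- row
    }
  }
  for (v in names(X)[const]) {
    row <- data.frame(variable = v, set = unname(sets[v]), r2 = 0, p = 1,
                      stringsAsFactors = FALSE)
    row[ax_names] <- as.list(rep(NA_real_, ncol(scores)))
    rows[[v]] <- row
  }
  out <- do.call(rbind, rows[names(X)])
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  class(out) <- c("envfit_table", "data.frame")
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower triangles, with a one-sided p-value
#' from simultaneous row/column permutations of one matrix (site
#' relabelling), via \code{vegan::mantel}.
#'
#' @param d1,d2 \code{dist} objects or symmetric matrices over the same
#'   sites.
#' @param n_perm number of permutations (default 999).
#' @param seed permutation seed.
#' @return List of class \code{mantel_test}: \code{r}, \code{p},
#'   \code{n_perm}.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as_dist_matrix(d1, "first distance matrix")
  d2 <- as_dist_matrix(d2, "second distance matrix")
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices differ in size")
  if (attr(d1, "Size") < 4) stop("need at least 4 sites")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices have different site labels")
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
    stop("zero variance in a distance matrix: Mantel r undefined")
  mt <- with_seed(seed, vegan::mantel(d1, d2, method = "pearson",
                                      permutations = n_perm))
  structure(list(r = unname(mt$statistic), p = mt$signif, n_perm = n_perm),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, one-sided p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Great-circle distance matrix between sites
#'
#' Haversine distances in km from longitude/latitude coordinates.
#'
#' @param coords data frame with columns \code{lon}, \code{lat} (and
#'   optionally \code{site} for labels).
#' @return A \code{dist} object in km.
#' @export
great_circle_dist <- function(coords) {
  stopifnot(all(c("lon", "lat") %in% names(coords)))
  m <- geosphere::distm(as.matrix(coords[, c("lon", "lat")])) / 1000
  labs <- if ("site" %in% names(coords)) as.character(coords$site) else NULL
  dimnames(m) <- list(labs, labs)
  stats::as.dist(m)
}

#' Environmental distance of one predictor set
#'
#' Variables of the set are standardized, a principal component analysis is
#' computed, and the Euclidean distance over all components is returned
#' (identical to the Euclidean distance on the standardized variables, since
#' the rotation is orthogonal).  Constant variables are dropped with a
#' warning before the PCA.
#'
#' @param env a \code{predictor_table}.
#' @param set one of \code{"climatic"}, \code{"soil"}, \code{"historical"}.
#' @return A \code{dist} object labelled by site.
#' @export
predictor_distance <- function(env, set) {
  X <- set_matrix(env, set)
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant variable(s) before PCA: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2)
    stop("predictor set '", set, "' needs at least 2 non-constant variables")
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  d <- stats::dist(pc$x)
  attr(d, "Labels") <- rownames(env)
  d
}

# Adjusted R^2 of a least-squares regression of y on X (columns), with
# n = length(y) and p = ncol(X).
lm_r2adj <- function(y, X) {
  fit <- stats::.lm.fit(cbind(1, X), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  adjusted_r2(r2, length(y), ncol(X))
}

#' Distance-based variation partitioning of community dissimilarity
#'
#' Unfolds the strictly-lower triangles of the response and predictor-set
#' distance matrices (the latter from \code{\link{predictor_distance}}),
#' regresses response distances on each of the seven combinations of the
#' three predictor distances, and partitions the full-model adjusted
#' R-squared by inclusion-exclusion.  Here n in the adjustment is the number
#' of site pairs and p the number of distance predictors.  Fraction p-values
#' come from simultaneous row/column permutations of the response matrix
#' (one-sided, with the 95%-quantile significance rule).
#'
#' @param response_d community dissimilarity (\code{dist} or symmetric
#'   matrix), e.g. from \code{\link{jaccard_dist}}.
#' @param env a \code{predictor_table} over the same sites.
#' @param n_perm number of permutations (default 999; 0 disables the test).
#' @param seed permutation seed.
#' @param response name tag recorded in the result (e.g. \code{"jaccard"}).
#' @return Object of class \code{db_varpart} with the same fraction/total
#'   structure as \code{\link{en_varpart}}.
#' @export
db_varpart <- function(response_d, env, n_perm = 999, seed = NULL,
                       response = "dissimilarity") {
  response_d <- as_dist_matrix(response_d, "response distance matrix")
  n <- attr(response_d, "Size")
  if (n != nrow(env))
    stop("response distance matrix and predictor table differ in site count")
  labs <- attr(response_d, "Labels")
  if (!is.null(labs) && !identical(as.character(labs), rownames(env)))
    stop("site labels of the response distances do not match the predictor table")

  pd <- lapply(stats::setNames(PREDICTOR_SETS, c("C", "S", "H")),
               function(s) as.vector(predictor_distance(env, s)))
  Xcombo <- lapply(COMBOS, function(ss) {
    do.call(cbind, pd[match(ss, PREDICTOR_SETS)])
  })
  ymat <- as.matrix(response_d)
  ytri <- as.vector(response_d)
  if (stats::sd(ytri) == 0) stop("response distances have zero variance")

  R_obs <- vapply(Xcombo, function(X) lm_r2adj(ytri, X), numeric(1))
  fractions <- partition_fractions(R_obs)
  totals <- stats::setNames(R_obs[TOTALS], names(TOTALS))

  pvalues <- significant <- null_quantile <- NULL
  if (n_perm > 0) {
    wanted <- c(FRACTIONS, names(TOTALS))
    obs_vals <- vapply(wanted, eval_fraction, numeric(1), R = R_obs)
    null_mat <- matrix(NA_real_, n_perm, length(wanted),
                       dimnames = list(NULL, wanted))
    null_mat[] <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(b) {
        prm <- sample(n)
        yb <- as.vector(stats::as.dist(ymat[prm, prm]))
        Rb <- vapply(Xcombo, function(X) lm_r2adj(yb, X), numeric(1))
        vapply(wanted, eval_fraction, numeric(1), R = Rb)
      }, numeric(length(wanted))))
    })
    null_quantile <- apply(null_mat, 2, stats::quantile, probs = 0.95,
                           names = FALSE)
    pvalues <- vapply(wanted, function(w) {
      (1 + sum(null_mat[, w] >= obs_vals[w])) / (1 + n_perm)
    }, numeric(1))
    significant <- obs_vals > null_quantile
  }

  structure(list(fractions = fractions, totals = totals,
                 combo_r2adj = R_obs, pvalues = pvalues,
                 significant = significant, null_quantile = null_quantile,
                 n_perm = n_perm, n_pairs = length(ytri), n = n,
                 response = response, seed = seed, call = match.call()),
            class = "db_varpart")
}

#' @export
print.db_varpart <- function(x, digits = 4, ...) {
  cat(sprintf("Distance-based variation partitioning of %s (%d sites, %d pairs)\n",
              x$response, x$n, x$n_pairs))
  cat(sprintf("Full-model adjusted R2: %.*f\n", digits, x$combo_r2adj[["CSH"]]))
  print(format_partition(x, digits), row.names = FALSE)
  if (x$n_perm > 0)
    cat(sprintf("Permutation test: %d row/column permutations of the response matrix\n",
                x$n_perm))
  invisible(x)
}
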