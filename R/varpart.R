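# Adjusted-R^2 variation partitioning of a diversity response across the
# climatic, soil and historical predictor sets, with permutation inference.

COMBOS <- list(C = "climatic", S = "soil", H = "historical",
               CS = c("climatic", "soil"), CH = c("climatic", "historical"),
               SH = c("soil", "historical"),
               CSH = c("climatic", "soil", "historical"))

FRACTIONS <- c("pure_climatic", "pure_soil", "pure_historical",
               "shared_climatic_soil", "shared_climatic_historical",
               "shared_soil_historical", "shared_all")
TOTALS <- c(total_climatic = "C", total_soil = "S", total_historical = "H")

#' Inclusion-exclusion partition of combination-wise adjusted R-squared
#'
#' Given the adjusted R-squared of the seven predictor-set combinations
#' (named \code{C, S, H, CS, CH, SH, CSH}), decomposes the full-model value
#' into three pure, three pairwise-shared and one triple-shared fraction.
#' Negative fractions are retained as-is.  The seven fractions always sum to
#' the full-model value \code{R[CSH]} exactly (arithmetic identity).
#'
#' @param R named numeric vector with elements \code{C, S, H, CS, CH, SH,
#'   CSH}.
#' @return Named numeric vector over the seven fractions.
#' @export
partition_fractions <- function(R) {
  stopifnot(all(names(COMBOS) %in% names(R)))
  c(pure_climatic = unname(R["CSH"] - R["SH"]),
    pure_soil = unname(R["CSH"] - R["CH"]),
    pure_historical = unname(R["CSH"] - R["CS"]),
    shared_climatic_soil = unname(R["CH"] + R["SH"] - R["CSH"] - R["H"]),
    shared_climatic_historical = unname(R["CS"] + R["SH"] - R["CSH"] - R["S"]),
    shared_soil_historical = unname(R["CS"] + R["CH"] - R["CSH"] - R["C"]),
    shared_all = unname(R["C"] + R["S"] + R["H"] -
                          R["CS"] - R["CH"] - R["SH"] + R["CSH"]))
}

# Combinations needed to evaluate one fraction's or total's null value.
combos_for <- function(what) {
  switch(what,
         total_climatic = "C", total_soil = "S", total_historical = "H",
         pure_climatic = c("CSH", "SH"), pure_soil = c("CSH", "CH"),
         pure_historical = c("CSH", "CS"),
         shared_climatic_soil = c("CH", "SH", "CSH", "H"),
         shared_climatic_historical = c("CS", "SH", "CSH", "S"),
         shared_soil_historical = c("CS", "CH", "CSH", "C"),
         shared_all = names(COMBOS),
         stop("unknown fraction: ", what))
}

# Evaluate one fraction/total from a (possibly partial) named R vector.
eval_fraction <- function(what, R) {
  if (what %in% names(TOTALS)) return(unname(R[TOTALS[[what]]]))
  full <- c(C = NA_real_, S = NA_real_, H = NA_real_, CS = NA_real_,
            CH = NA_real_, SH = NA_real_, CSH = NA_real_)
  full[names(R)] <- R
  unname(partition_fractions(full)[what])
}

# Mean adjusted R^2 for each requested combination; one fold shuffle per
# repeat, shared across combinations.
combo_r2adj <- function(y, Xstd_list, repeats, folds, alpha_grid, nlambda,
                        seed, combos = names(COMBOS)) {
  n <- length(y)
  acc <- stats::setNames(numeric(length(combos)), combos)
  for (r in seq_len(repeats)) {
    foldid <- make_foldid(n, folds, substream(seed, r))
    for (cb in combos) {
      X <- Xstd_list[[cb]]
      core <- en_cv_core(y, X, foldid, alpha_grid, nlambda)
      acc[cb] <- acc[cb] + adjusted_r2(core$r2, n, ncol(X))
    }
  }
  acc / repeats
}

#' Variation partitioning of diversity by elastic-net regression
#'
#' Fits cross-validation-tuned elastic nets of the response on all seven
#' combinations of the climatic, soil and historical predictor sets, averages
#' the adjusted R-squared of each combination over repeated CV runs, and
#' decomposes the full-model value into pure and shared fractions by
#' inclusion-exclusion.  With \code{n_perm > 0}, a permutation null for each
#' fraction (and each set total) is built by re-partitioning randomly
#' reordered responses; a fraction is flagged significant when its observed
#' value exceeds the 95% quantile of its null, and a one-sided p-value
#' \code{(1 + #\{null >= obs\}) / (1 + n_perm)} is reported.
#'
#' @param y numeric response (e.g. genus richness or Shannon's diversity).
#' @param env a \code{predictor_table} containing all three sets.
#' @param repeats CV repeats averaged for the observed partition (default
#'   100).
#' @param n_perm number of response permutations (0 = no test; >= 99
#'   recommended for a usable 95% quantile).
#' @param repeats_null CV repeats per permutation (default 10; the null
#'   refits are the cost bottleneck).
#' @param retune if \code{TRUE} (default) each permutation re-tunes
#'   \code{(alpha, lambda)}; if \code{FALSE} the observed tuning is reused,
#'   which is faster but less conservative.
#' @param perm_fractions fractions/totals to test (default: all seven
#'   fractions plus the three set totals).  Restricting this prunes the
#'   per-permutation refits to the combinations those fractions need.
#' @param folds,alpha_grid,nlambda CV settings, as in \code{\link{en_fit}}.
#' @param seed master seed (fold shuffles and permutations draw from named
#'   substreams).
#' @return Object of class \code{en_varpart}: fractions, set totals,
#'   combination-wise adjusted R-squared, p-values and significance flags,
#'   and the full-model \code{en_fit} (for residual diagnostics).
#' @seealso \code{\link{morans_i}} for the residual spatial-autocorrelation
#'   check, \code{\link{db_varpart}} for the distance-based analogue.
#' @export
en_varpart <- function(y, env, repeats = 100, n_perm = 0, repeats_null = 10,
                       retune = TRUE, perm_fractions = NULL, folds = 5,
                       alpha_grid = seq(0.05, 1, by = 0.05), nlambda = 50,
                       seed = 1) {
  sets <- predictor_sets(env)
  missing_sets <- setdiff(PREDICTOR_SETS, unique(sets))
  if (length(missing_sets))
    stop("predictor table lacks set(s): ", paste(missing_sets, collapse = ", "))
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(env)) stop("response and predictor table differ in length")
  if (stats::sd(y) == 0) stop("constant response: nothing to partition")
  p_full <- ncol(env)
  if (n - p_full - 1 <= 0)
    stop("n - p - 1 <= 0 for the full model; use fewer variables or more sites")
  if (n_perm > 0 && n_perm < 99)
    stop("n_perm < 99 makes the 95% null quantile unreliable; use >= 99 or 0")

  std <- standardize_design(env)
  Xstd <- lapply(COMBOS, function(ss) {
    std$X[, names(sets)[sets %in% ss], drop = FALSE]
  })

  R_obs <- combo_r2adj(y, Xstd, repeats, folds, alpha_grid, nlambda,
                       substream(seed, "observed"))
  fractions <- partition_fractions(R_obs)
  totals <- stats::setNames(R_obs[TOTALS], names(TOTALS))

  pvalues <- significant <- NULL
  null_quantile <- NULL
  if (n_perm > 0) {
    wanted <- perm_fractions %||% c(FRACTIONS, names(TOTALS))
    bad <- setdiff(wanted, c(FRACTIONS, names(TOTALS)))
    if (length(bad)) stop("unknown fraction(s): ", paste(bad, collapse = ", "))
    need <- unique(unlist(lapply(wanted, combos_for)))
    obs_vals <- vapply(wanted, eval_fraction, numeric(1), R = R_obs)
    tuned <- NULL
    if (!retune) {
      tuned <- lapply(need, function(cb) {
        foldid <- make_foldid(n, folds, substream(seed, "tune"))
        core <- en_cv_core(y, Xstd[[cb]], foldid, alpha_grid, nlambda)
        list(alpha = core$alpha, lambda = core$lambda)
      })
      names(tuned) <- need
    }
    null_mat <- matrix(NA_real_, n_perm, length(wanted),
                       dimnames = list(NULL, wanted))
    for (b in seq_len(n_perm)) {
      yb <- y[with_seed(substream(seed, 1e6 + b), sample(n))]
      if (retune) {
        Rb <- combo_r2adj(yb, Xstd, repeats_null, folds, alpha_grid, nlambda,
                          substream(seed, 2e6 + b), combos = need)
      } else {
        Rb <- vapply(need, function(cb) {
          tu <- tuned[[cb]]
          X <- Xstd[[cb]]
          if (tu$lambda == 0) {
            pr <- as.vector(cbind(1, X) %*% ols_coef(yb, X))
          } else {
            fit <- glmnet::glmnet(X, yb, alpha = tu$alpha,
                                  lambda = tu$lambda * c(8, 4, 2, 1),
                                  standardize = FALSE)
            pr <- as.vector(stats::predict(fit, X, s = tu$lambda))
          }
          adjusted_r2(1 - sum((yb - pr)^2) / sum((yb - mean(yb))^2),
                      n, ncol(X))
        }, numeric(1))
      }
      null_mat[b, ] <- vapply(wanted, eval_fraction, numeric(1), R = Rb)
    }
    null_quantile <- apply(null_mat, 2, stats::quantile, probs = 0.95,
                           names = FALSE)
    pvalues <- vapply(wanted, function(w) {
      (1 + sum(null_mat[, w] >= obs_vals[w])) / (1 + n_perm)
    }, numeric(1))
    significant <- obs_vals > null_quantile
  }

  full_fit <- en_fit(y, as.data.frame(env), folds = folds,
                     alpha_grid = alpha_grid, nlambda = nlambda,
                     seed = substream(seed, "full"))

  structure(list(fractions = fractions, totals = totals,
                 combo_r2adj = R_obs, pvalues = pvalues,
                 significant = significant, null_quantile = null_quantile,
                 n_perm = n_perm, repeats = repeats,
                 repeats_null = repeats_null, retune = retune,
                 folds = folds, alpha_grid = alpha_grid, seed = seed,
                 n = n, p_full = p_full, full_fit = full_fit,
                 call = match.call()),
            class = "en_varpart")
}

format_partition <- function(x, digits) {
  vals <- c(x$fractions, x$totals)
  out <- data.frame(fraction = names(vals), r2adj = round(unname(vals), digits),
                    stringsAsFactors = FALSE)
  if (!is.null(x$pvalues)) {
    out$p <- NA_real_
    out$significant <- NA
    m <- match(names(x$pvalues), out$fraction)
    out$p[m] <- round(unname(x$pvalues), 4)
    out$significant[m] <- unname(x$significant)
  }
  out
}

#' @export
print.en_varpart <- function(x, digits = 4, ...) {
  cat(sprintf("Elastic-net variation partitioning (n = %d, %d predictors, %d CV repeats)\n",
              x$n, x$p_full, x$repeats))
  cat(sprintf("Full-model mean adjusted R2: %.*f\n", digits,
              x$combo_r2adj[["CSH"]]))
  print(format_partition(x, digits), row.names = FALSE)
  if (x$n_perm > 0)
    cat(sprintf("Permutation test: %d permutations, %s re-tuning, %d null CV repeats\n",
                x$n_perm, if (x$retune) "with" else "without", x$repeats_null))
  invisible(x)
}

#' @export
summary.en_varpart <- function(object, digits = 4, ...) {
  print(object, digits = digits)
  cat("\nCombination-wise mean adjusted R2:\n")
  print(round(object$combo_r2adj, digits))
  cat("\nFull-model fit:\n")
  print(object$full_fit, digits = digits)
  invisible(object)
}

#' @export
residuals.en_varpart <- function(object, ...) residuals(object$full_fit)

#' @export
fitted.en_varpart <- function(object, ...) fitted(object$full_fit)

#' @export
coef.en_varpart <- function(object, ...) coef(object$full_fit)

#' @export
plot.en_varpart <- function(x, ...) {
  vals <- x$fractions
  bp <- graphics::barplot(vals, names.arg = c("C", "S", "H", "C:S", "C:H",
                                              "S:H", "C:S:H"),
                          ylab = "adjusted R-squared",
                          main = "Variation partitioning", ...)
  if (!is.null(x$significant)) {
    sig <- x$significant[names(vals)]
    graphics::mtext(ifelse(is.na(sig), "", ifelse(sig, "*", "")), at = bp,
                    side = 3, line = -1)
  }
  invisible(x)
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' \code{I = (n / S0) * (z' W z) / (z' z)} with centred values \code{z} and
#' spatial weights \code{W} (zero diagonal).  The default weighting is
#' inverse great-circle distance, row-standardized.  The p-value comes from
#' randomly permuting the values across locations (two-sided: departure from
#' the permutation mean at least as large as observed).
#'
#' @param x numeric vector (typically model residuals).
#' @param coords data frame with columns \code{lon}, \code{lat} (ignored when
#'   \code{W} is supplied).
#' @param W optional precomputed weight matrix (used as given).
#' @param row_standardize row-standardize the inverse-distance weights
#'   (default \code{TRUE}).
#' @param n_perm number of permutations (>= 99).
#' @param seed permutation seed.
#' @return List of class \code{morans_i}: \code{I}, \code{expected}
#'   (\code{-1/(n-1)}), \code{p}, \code{n_perm}.
#' @export
morans_i <- function(x, coords = NULL, W = NULL, row_standardize = TRUE,
                     n_perm = 999, seed = NULL) {
  z <- x - mean(x)
  n <- length(z)
  if (n < 4) stop("need at least 4 locations")
  if (sum(z^2) == 0) stop("zero residual variance")
  if (is.null(W)) {
    if (is.null(coords)) stop("supply either 'coords' or 'W'")
    dm <- great_circle_dist(coords)
    dm <- as.matrix(dm)
    if (any(dm[upper.tri(dm)] == 0))
      stop("coincident sites give infinite inverse-distance weights")
    W <- 1 / dm
    diag(W) <- 0
    if (row_standardize) W <- W / rowSums(W)
  } else {
    W <- as.matrix(W)
    diag(W) <- 0
  }
  s0 <- sum(W)
  istat <- function(zz) (n / s0) * as.numeric(t(zz) %*% W %*% zz) / sum(zz^2)
  obs <- istat(z)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) istat(z[sample(n)]), numeric(1))
  })
  m0 <- mean(null)
  p <- (1 + sum(abs(null - m0) >= abs(obs - m0))) / (1 + n_perm)
  structure(list(I = obs, expected = -1 / (n - 1), p = p, n_perm = n_perm,
                 null_mean = m0, null_sd = stats::sd(null)),
            class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (null expectation %.4f), permutation p = %.4g (%d permutations)\n",
              x$I, x$expected, x$p, x$n_perm))
  invisible(x)
}
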