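# Core data containers: the site-by-genus community matrix and the
# site-by-variable predictor table with its three-set grouping.

PREDICTOR_SETS <- c("climatic", "soil", "historical")

#' Construct a validated site-by-genus community matrix
#'
#' Rows are sites, columns genera.  Entries are non-negative abundances;
#' fractional values are allowed because plot-level counts are averaged to
#' the site level.
#'
#' @param x numeric matrix or data frame (rows = sites, columns = genera).
#' @param sites,genera optional label vectors overriding the dimnames.
#' @return A numeric matrix of class \code{community_matrix}.
#' @examples
#' m <- community_matrix(rbind(a = c(4, 0, 6), b = c(2, 2, 6)))
#' richness(m)
#' @export
community_matrix <- function(x, sites = rownames(x), genera = colnames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(sites)) sites <- paste0("site", seq_len(nrow(x)))
  if (is.null(genera)) genera <- paste0("g", seq_len(ncol(x)))
  if (anyDuplicated(sites)) stop("duplicate site labels: ",
                                 paste(unique(sites[duplicated(sites)]), collapse = ", "))
  if (anyDuplicated(genera)) stop("duplicate genus labels: ",
                                  paste(unique(genera[duplicated(genera)]), collapse = ", "))
  if (anyNA(x)) stop("community matrix contains missing values")
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at site '%s', genus '%s'",
                 sites[idx[1]], genera[idx[2]]))
  }
  empty <- rowSums(x) <= 0
  if (any(empty)) stop("site(s) with no individuals: ",
                       paste(sites[empty], collapse = ", "))
  dimnames(x) <- list(sites, genera)
  class(x) <- c("community_matrix", class(x))
  x
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix: %d sites x %d genera (total abundance %.1f)\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(8, ncol(x))), drop = FALSE])
  invisible(x)
}

as_community <- function(x) {
  if (inherits(x, "community_matrix")) x else community_matrix(x)
}

#' Construct a predictor table grouped into climatic, soil and historical sets
#'
#' A numeric site-by-variable table in which every variable belongs to exactly
#' one of the three predictor sets used throughout the package.
#'
#' @param x data frame or matrix of numeric predictors (rows = sites).
#' @param sets character vector, one of \code{"climatic"}, \code{"soil"},
#'   \code{"historical"} per column of \code{x} (recycled names are not
#'   allowed; names, if present, must match the columns of \code{x}).
#' @param sites optional site labels.
#' @return A data frame of class \code{predictor_table} with a \code{"sets"}
#'   attribute naming each variable's set.
#' @examples
#' pt <- predictor_table(data.frame(MAT = 1:4, pH = 4:1, TA = c(2, 3, 1, 4)),
#'                       sets = c("climatic", "soil", "historical"))
#' predictor_sets(pt)
#' @export
predictor_table <- function(x, sets, sites = rownames(x)) {
  x <- as.data.frame(x)
  if (length(sets) != ncol(x))
    stop("'sets' must give one set label per variable")
  if (!is.null(names(sets))) {
    if (!setequal(names(sets), names(x)))
      stop("names of 'sets' do not match the variables")
    sets <- sets[names(x)]
  }
  sets <- as.character(sets)
  bad <- setdiff(unique(sets), PREDICTOR_SETS)
  if (length(bad))
    stop("unknown predictor set label(s): ", paste(bad, collapse = ", "),
         " (expected climatic, soil or historical)")
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all predictor variables must be numeric")
  if (anyNA(x)) {
    idx <- which(is.na(as.matrix(x)), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, variable '%s'",
                 idx[1], names(x)[idx[2]]))
  }
  if (is.null(sites)) sites <- paste0("site", seq_len(nrow(x)))
  if (anyDuplicated(sites)) stop("duplicate site labels")
  rownames(x) <- sites
  names(sets) <- names(x)
  attr(x, "sets") <- sets
  class(x) <- c("predictor_table", "data.frame")
  x
}

#' Set labels of a predictor table
#' @param env a \code{predictor_table}.
#' @return Named character vector mapping variable name to set label.
#' @export
predictor_sets <- function(env) {
  sets <- attr(env, "sets")
  if (is.null(sets)) stop("not a predictor_table: no set labels attached")
  sets
}

#' Extract the variables of one predictor set as a numeric matrix
#' @param env a \code{predictor_table}.
#' @param set one of \code{"climatic"}, \code{"soil"}, \code{"historical"}.
#' @export
set_matrix <- function(env, set) {
  set <- match.arg(set, PREDICTOR_SETS)
  sets <- predictor_sets(env)
  vars <- names(sets)[sets == set]
  if (!length(vars)) stop("predictor table has no '", set, "' variables")
  as.matrix(as.data.frame(env)[vars])
}

#' @export
print.predictor_table <- function(x, ...) {
  sets <- attr(x, "sets")
  cat(sprintf("Predictor table: %d sites x %d variables (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", PREDICTOR_SETS,
                            vapply(PREDICTOR_SETS, function(s) sum(sets == s), 0L)),
                    collapse = ", ")))
  print(as.data.frame(x))
  invisible(x)
}

# Validated symmetric distance input -> 'dist' object with labels.
as_dist_matrix <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) return(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop(what, " must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop(what, " must have a zero diagonal")
  stats::as.dist(d)
}
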