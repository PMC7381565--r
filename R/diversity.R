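# Site-level diversity responses and pairwise community dissimilarity.

#' Genus richness per site
#'
#' Number of genera with abundance strictly greater than zero (site-level
#' abundances can be fractional after plot averaging).
#'
#' @param comm community matrix (sites x genera).
#' @return Named integer vector.
#' @export
richness <- function(comm) {
  m <- unclass(as_community(comm))
  out <- as.integer(rowSums(m > 0))
  names(out) <- rownames(m)
  out
}

#' Shannon's diversity per site
#'
#' \code{-sum(p_i * log(p_i))} over genus proportions, natural log;
#' zero-abundance genera contribute nothing.
#'
#' @param comm community matrix (sites x genera).
#' @return Named numeric vector.
#' @export
shannon <- function(comm) {
  m <- unclass(as_community(comm))
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("zero total abundance at site(s): ",
         paste(rownames(m)[tot <= 0], collapse = ", "))
  out <- vegan::diversity(m, index = "shannon")
  names(out) <- rownames(m)
  out
}

#' Jaccard dissimilarity matrix
#'
#' Incidence-based pairwise dissimilarity \code{(b + c) / (a + b + c)}, where
#' \code{a} counts genera shared by both sites and \code{b}, \code{c} those
#' unique to each; presence is abundance > 0.
#'
#' @param comm community matrix (sites x genera).
#' @return A \code{dist} object labelled by site.
#' @export
jaccard_dist <- function(comm) {
  m <- unclass(as_community(comm))
  vegan::vegdist(m, method = "jaccard", binary = TRUE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Abundance-based pairwise dissimilarity
#' \code{sum(|x_ij - x_ik|) / (sum(x_ij) + sum(x_ik))}.  Against an all-empty
#' site the index equals 1 (the limit of the formula); between two all-empty
#' sites it is undefined and an error is raised.  The validated
#' \code{community_matrix} constructor rejects empty sites, so these cases
#' can only arise from raw matrices.
#'
#' @param comm community matrix or raw non-negative matrix (sites x genera).
#' @return A \code{dist} object labelled by site.
#' @export
braycurtis_dist <- function(comm) {
  m <- if (inherits(comm, "community_matrix")) unclass(comm) else as.matrix(comm)
  if (any(m < 0)) stop("negative abundances")
  tot <- rowSums(m)
  if (sum(tot == 0) >= 2)
    stop("Bray-Curtis is undefined between two all-zero sites: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  if (any(tot == 0))
    warning("all-zero site present; Bray-Curtis against it set to 1 ",
            "(limit convention)")
  suppressWarnings(vegan::vegdist(m, method = "bray"))
}

#' Per-site diversity summary table
#'
#' @param comm community matrix.
#' @return Data frame with columns \code{site}, \code{richness},
#'   \code{shannon}.
#' @export
diversity_table <- function(comm) {
  comm <- as_community(comm)
  data.frame(site = rownames(comm), richness = richness(comm),
             shannon = shannon(comm), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bivariate correlation screen of a response against every predictor
#'
#' Convenience report: Pearson r and its p-value for the response against
#' each predictor variable, grouped by set.
#'
#' @param y numeric response (e.g. richness or Shannon's diversity).
#' @param env a \code{predictor_table}.
#' @return Data frame with columns \code{variable}, \code{set}, \code{r},
#'   \code{p}.
#' @export
cor_report <- function(y, env) {
  sets <- predictor_sets(env)
  res <- lapply(names(sets), function(v) {
    ct <- stats::cor.test(y, env[[v]])
    data.frame(variable = v, set = unname(sets[v]),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
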