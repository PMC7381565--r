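# Shared fixtures and independent brute-force oracles.

toy_comm <- function() {
  community_matrix(rbind(s1 = c(4, 0, 6), s2 = c(2, 2, 6), s3 = c(0, 5, 1)),
                   genera = c("gA", "gB", "gC"))
}

# Brute-force pairwise dissimilarities straight from the defining formulas.
loop_jaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  inc <- m > 0
  for (j in seq_len(n)) for (k in seq_len(n)) {
    a <- sum(inc[j, ] & inc[k, ])
    b <- sum(inc[j, ] & !inc[k, ])
    cc <- sum(!inc[j, ] & inc[k, ])
    d[j, k] <- (b + cc) / (a + b + cc)
  }
  d
}

loop_braycurtis <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    d[j, k] <- sum(abs(m[j, ] - m[k, ])) / (sum(m[j, ]) + sum(m[k, ]))
  }
  d
}

# A small three-set predictor table with independent random columns.
random_env <- function(n, seed = 1) {
  vals <- with_seed_test(seed, {
    as.data.frame(matrix(rnorm(n * 11), n, 11))
  })
  names(vals) <- c("MAT", "MAP", "TS", "PS", "SOC", "TN", "pH",
                   "TA", "PA", "TCV", "PCV")
  predictor_table(vals, sets = c(rep("climatic", 4), rep("soil", 3),
                                 rep("historical", 4)))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Fast small settings for partition fits in tests.
quick_args <- list(repeats = 1, alpha_grid = 0.5, nlambda = 30)
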