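# Table I/O and the one-command end-to-end driver.

sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a site-by-genus community table
#'
#' TSV/CSV with site identifiers in the first column and one column per
#' genus.  Negative entries and duplicate labels are rejected with the
#' offending cell named.
#'
#' @param path input file.
#' @return A \code{community_matrix}.
#' @export
read_community <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("community table needs a site column plus genera")
  genera <- names(df)[-1]
  if (anyDuplicated(genera))
    stop("duplicate genus column(s) in header: ",
         paste(unique(genera[duplicated(genera)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  community_matrix(m, sites = as.character(df[[1]]), genera = genera)
}

#' Write a community matrix as TSV
#' @param comm a \code{community_matrix}.
#' @param path output file.
#' @export
write_community <- function(comm, path) {
  comm <- as_community(comm)
  df <- data.frame(site = rownames(comm), unclass(comm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a predictor table with set labels
#'
#' Expects two header rows: the first names the site column and the
#' variables, the second carries each variable's set label (climatic, soil
#' or historical).
#'
#' @param path input file.
#' @return A \code{predictor_table}.
#' @export
read_env <- function(path) {
  sep <- sep_for(path)
  hdr <- strsplit(readLines(path, n = 2), sep, fixed = TRUE)
  vars <- hdr[[1]][-1]
  sets <- hdr[[2]][-1]
  if (length(sets) != length(vars))
    stop("set-label header row does not match the variable header")
  df <- utils::read.table(path, header = FALSE, sep = sep, skip = 2,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) != length(vars) + 1)
    stop("data rows do not match the header width")
  vals <- df[, -1, drop = FALSE]
  names(vals) <- vars
  if (anyNA(vals)) {
    idx <- which(is.na(as.matrix(vals)), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at data row %d, variable '%s'",
                 idx[1], vars[idx[2]]))
  }
  predictor_table(vals, sets = sets, sites = as.character(df[[1]]))
}

#' Write a predictor table with its set-label header row
#' @param env a \code{predictor_table}.
#' @param path output file.
#' @export
write_env <- function(env, path) {
  sep <- sep_for(path)
  sets <- predictor_sets(env)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("site", names(sets)), collapse = sep),
               paste(c("set", unname(sets)), collapse = sep)), con)
  df <- data.frame(site = rownames(env), as.data.frame(env),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read site coordinates
#'
#' CSV/TSV with columns \code{site}, \code{lon}, \code{lat}.
#' @param path input file.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          stringsAsFactors = FALSE)
  if (!all(c("site", "lon", "lat") %in% names(df)))
    stop("site table needs columns: site, lon, lat")
  df$site <- as.character(df$site)
  df
}

#' Write site coordinates
#' @param sites data frame with \code{site}, \code{lon}, \code{lat}.
#' @param path output file.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, c("site", "lon", "lat")], path,
                     sep = sep_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits the community table, the labelled environment table and the site
#' coordinates in the formats the readers expect.
#'
#' @param dataset a \code{synthetic_dataset} from \code{\link{sim_dataset}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_community(dataset$community, file.path(dir, "community.tsv"))
  write_env(dataset$env, file.path(dir, "env.tsv"))
  write_sites(dataset$sites, file.path(dir, "sites.csv"))
  invisible(dir)
}

#' Configuration for the end-to-end analysis driver
#'
#' Validates that the referenced input files exist and collects the analysis
#' switches.  All randomness downstream flows from \code{seed} via named
#' substreams.
#'
#' @param community path to the community table.
#' @param env path to the predictor table (two header rows).
#' @param sites optional path to site coordinates (enables the Mantel test
#'   against spatial distance).
#' @param out_dir output directory.
#' @param responses diversity responses to partition.
#' @param indices dissimilarity indices to analyse.
#' @param repeats,n_perm,repeats_null,folds,alpha_grid,nlambda analysis
#'   settings, as in \code{\link{en_varpart}}.
#' @param nmds_k,nmds_starts NMDS settings.
#' @param seed master seed.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(community, env, sites = NULL, out_dir = tempfile("run"),
                       responses = c("richness", "shannon"),
                       indices = c("jaccard", "braycurtis"),
                       repeats = 100, n_perm = 999, repeats_null = 10,
                       folds = 5, alpha_grid = seq(0.05, 1, by = 0.05),
                       nlambda = 50, nmds_k = 2, nmds_starts = 50, seed = 1) {
  for (p in c(community, env, sites)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  responses <- match.arg(responses, c("richness", "shannon"), several.ok = TRUE)
  indices <- match.arg(indices, c("jaccard", "braycurtis"), several.ok = TRUE)
  if (seed != round(seed)) stop("seed must be an integer")
  structure(list(community = community, env = env, sites = sites,
                 out_dir = out_dir, responses = responses, indices = indices,
                 repeats = repeats, n_perm = n_perm,
                 repeats_null = repeats_null, folds = folds,
                 alpha_grid = alpha_grid, nlambda = nlambda, nmds_k = nmds_k,
                 nmds_starts = nmds_starts, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

partition_to_df <- function(x) {
  format_partition(x, digits = 10)
}

#' Run the full analysis pipeline
#'
#' Executes diversity computation, elastic-net variation partitioning of each
#' requested response, and for each dissimilarity index the NMDS ordination,
#' environmental vector fit, Mantel test against spatial distance (when site
#' coordinates are given) and distance-based variation partitioning.  All
#' outputs are written under \code{cfg$out_dir} together with a JSON run
#' record (config echo, per-stage seeds, package versions, wall time,
#' warnings); two runs with the same record are numerically identical.
#'
#' @param cfg a \code{run_config}.
#' @return The run record, invisibly (class \code{run_record}).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  warnings_seen <- character()
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = note),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  comm <- stage("read_community", read_community(cfg$community))
  env <- stage("read_env", read_env(cfg$env))
  if (!identical(rownames(comm), rownames(env)))
    stop("stage 'validate': community and environment site lists differ")
  sites <- if (!is.null(cfg$sites)) stage("read_sites", read_sites(cfg$sites))

  seeds <- list()
  div <- stage("diversity", diversity_table(comm))
  write_tsv(div, file.path(cfg$out_dir, "diversity.tsv"))

  for (resp in cfg$responses) {
    seeds[[paste0("varpart_", resp)]] <- substream(cfg$seed, paste0("varpart_", resp))
    vp <- stage(paste0("varpart_", resp), {
      en_varpart(div[[resp]], env, repeats = cfg$repeats, n_perm = cfg$n_perm,
                 repeats_null = cfg$repeats_null, folds = cfg$folds,
                 alpha_grid = cfg$alpha_grid, nlambda = cfg$nlambda,
                 seed = seeds[[paste0("varpart_", resp)]])
    })
    write_tsv(partition_to_df(vp),
              file.path(cfg$out_dir, sprintf("varpart_%s.tsv", resp)))
    if (!is.null(sites)) {
      mi <- stage(paste0("morans_i_", resp), {
        morans_i(residuals(vp), coords = sites,
                 seed = substream(cfg$seed, paste0("moran_", resp)))
      })
      write_tsv(data.frame(response = resp, I = mi$I, expected = mi$expected,
                           p = mi$p),
                file.path(cfg$out_dir, sprintf("morans_i_%s.tsv", resp)))
    }
  }

  mantel_out <- list()
  for (idx in cfg$indices) {
    d <- stage(paste0("dissimilarity_", idx),
               if (idx == "jaccard") jaccard_dist(comm) else braycurtis_dist(comm))
    seeds[[paste0("nmds_", idx)]] <- substream(cfg$seed, paste0("nmds_", idx))
    ord <- stage(paste0("nmds_", idx), {
      nmds_ord(d, k = cfg$nmds_k, n_starts = cfg$nmds_starts,
               seed = seeds[[paste0("nmds_", idx)]])
    })
    sc <- data.frame(site = rownames(comm), ord$scores, check.names = FALSE)
    write_tsv(sc, file.path(cfg$out_dir, sprintf("nmds_%s_scores.tsv", idx)))
    ef <- stage(paste0("envfit_", idx), {
      env_vector_fit(ord, env, n_perm = cfg$n_perm,
                     seed = substream(cfg$seed, paste0("envfit_", idx)))
    })
    write_tsv(as.data.frame(ef), file.path(cfg$out_dir,
                                           sprintf("envfit_%s.tsv", idx)))
    if (!is.null(sites)) {
      mt <- stage(paste0("mantel_", idx), {
        mantel_test(d, great_circle_dist(sites), n_perm = cfg$n_perm,
                    seed = substream(cfg$seed, paste0("mantel_", idx)))
      })
      mantel_out[[idx]] <- list(r = mt$r, p = mt$p, n_perm = mt$n_perm,
                                stress = ord$stress)
    }
    seeds[[paste0("dbvarpart_", idx)]] <- substream(cfg$seed, paste0("db_", idx))
    dbv <- stage(paste0("dbvarpart_", idx), {
      db_varpart(d, env, n_perm = cfg$n_perm,
                 seed = seeds[[paste0("dbvarpart_", idx)]], response = idx)
    })
    write_tsv(partition_to_df(dbv),
              file.path(cfg$out_dir, sprintf("dbvarpart_%s.tsv", idx)))
  }
  if (length(mantel_out))
    jsonlite::write_json(mantel_out, file.path(cfg$out_dir, "mantel.json"),
                         auto_unbox = TRUE, digits = NA)

  cfg_echo <- unclass(cfg)
  record <- structure(list(
    config = cfg_echo,
    config_hash = text_hash(cfg_echo[setdiff(names(cfg_echo), "out_dir")]),
    stage_seeds = seeds,
    versions = list(R = R.version.string,
                    nemapart = as.character(utils::packageVersion("nemapart")),
                    glmnet = as.character(utils::packageVersion("glmnet")),
                    vegan = as.character(utils::packageVersion("vegan"))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_seen), class = "run_record")
  jsonlite::write_json(record, file.path(cfg$out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(record)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("Pipeline run: seed %d, config hash %s, %.1f s, %d warning(s)\n",
              x$config$seed, x$config_hash, x$wall_time_s,
              length(x$warnings)))
  invisible(x)
}
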