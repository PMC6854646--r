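# Synthetic miRNA-target interaction databases with known null or planted
# enrichment structure, plus Monte-Carlo calibration of the Fisher test.

#' Configuration for a synthetic interaction database
#'
#' Describes a simulated world: a gene universe of size `N`, a designated
#' query set of size `K` (the first `K` universe genes), `M` miRNAs each
#' drawing a target set without replacement from the universe, and an
#' optional planted enrichment in which query genes carry relative sampling
#' weight `odds_ratio` for the planted miRNAs (sequential weighted sampling
#' without replacement, a Wallenius-type noncentral scheme whose
#' `odds_ratio = 1` case is exactly the uniform null of the Fisher test).
#'
#' @param universe_size Universe size N.
#' @param query_size Query size K (K <= N).
#' @param n_mirnas Number of miRNAs M.
#' @param target_size Per-miRNA target-set size: a single count or a
#'   `c(low, high)` range sampled uniformly per miRNA.
#' @param planted Integer indices (in `1:M`) of planted miRNAs.
#' @param odds_ratio Relative weight rho >= 1 of query genes for planted
#'   miRNAs; 1 is effectively unplanted.
#' @param n_sources Number of synthetic resource labels to emulate
#'   multi-resource input.
#' @param seed Integer root seed; all randomness flows through it.
#' @return A `sim_config` object.
#' @examples
#' sim_config(100, 20, 10, 10, seed = 1)
#' @export
sim_config <- function(universe_size, query_size, n_mirnas, target_size,
                       planted = integer(0), odds_ratio = 1,
                       n_sources = 1, seed = 1) {
  stopifnot(universe_size >= 1, query_size >= 0,
            query_size <= universe_size, n_mirnas >= 1,
            length(target_size) %in% c(1, 2), all(target_size >= 1),
            odds_ratio >= 1, n_sources >= 1)
  if (max(target_size) > universe_size) {
    stopf("target size (%d) exceeds universe size (%d)",
          max(target_size), universe_size)
  }
  planted <- as.integer(planted)
  if (length(planted) && (min(planted) < 1 || max(planted) > n_mirnas)) {
    stopf("planted indices must lie in 1..n_mirnas")
  }
  structure(list(universe_size = as.integer(universe_size),
                 query_size = as.integer(query_size),
                 n_mirnas = as.integer(n_mirnas),
                 target_size = as.integer(target_size),
                 planted = planted,
                 odds_ratio = odds_ratio,
                 n_sources = as.integer(n_sources),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-replicate child seed, kept inside 32-bit integer range.
child_seed <- function(root, i) {
  as.integer((as.double(root) + as.double(i) * 1000003) %% 2147483647)
}

sim_gene_names <- function(N) sprintf("G%04d", seq_len(N))
sim_mirna_names <- function(M) sprintf("sim-miR-%03d", seq_len(M))

#' Query gene set designated by a simulation configuration
#'
#' @param config A `sim_config`.
#' @return The first `query_size` universe gene names.
#' @export
query_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim_gene_names(config$universe_size)[seq_len(config$query_size)]
}

#' Generate a synthetic miRNA-target interaction database
#'
#' For each unplanted miRNA the target set is a uniform sample without
#' replacement from the universe; for planted miRNAs genes are drawn
#' sequentially without replacement with query genes carrying relative
#' weight `odds_ratio`. Each interaction receives one of `n_sources`
#' synthetic source labels. Deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `sim_db` list: `interactions` (interaction-dialect data frame),
#'   `truth` (`mirna`, `planted`, `odds_ratio`), `query`, `universe`, and
#'   the `config`.
#' @export
generate_target_db <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$universe_size
  genes <- sim_gene_names(N)
  mirnas <- sim_mirna_names(config$n_mirnas)
  query_idx <- seq_len(config$query_size)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  weights <- rep(1, N)
  rows <- vector("list", config$n_mirnas)
  for (i in seq_len(config$n_mirnas)) {
    n_i <- if (length(config$target_size) == 2) {
      sample(config$target_size[1]:config$target_size[2], 1)
    } else config$target_size
    planted_i <- i %in% config$planted
    idx <- if (planted_i && config$odds_ratio > 1) {
      w <- weights
      w[query_idx] <- config$odds_ratio
      sample.int(N, n_i, replace = FALSE, prob = w)
    } else {
      sample.int(N, n_i, replace = FALSE)
    }
    tg <- sort(genes[idx])
    rows[[i]] <- data.frame(mirna = mirnas[i], gene = tg,
                            source = paste0("sim_source_",
                                            sample.int(config$n_sources,
                                                       n_i, replace = TRUE)),
                            score = NA_real_, stringsAsFactors = FALSE)
  }
  interactions <- do.call(rbind, rows)
  rownames(interactions) <- NULL
  truth <- data.frame(mirna = mirnas,
                      planted = seq_len(config$n_mirnas) %in% config$planted,
                      odds_ratio = ifelse(seq_len(config$n_mirnas) %in%
                                            config$planted,
                                          config$odds_ratio, 1),
                      stringsAsFactors = FALSE)
  structure(list(interactions = interactions, truth = truth,
                 query = genes[query_idx], universe = genes,
                 config = config),
            class = "sim_db")
}

#' Write a synthetic database to disk
#'
#' Emits the interaction TSV dialect plus a ground-truth sidecar TSV
#' (`mirna  planted  odds_ratio`).
#'
#' @param db A `sim_db` from [generate_target_db()].
#' @param dir Output directory (created if needed).
#' @return Named paths of the two files, invisibly.
#' @export
write_sim_db <- function(db, dir) {
  stopifnot(inherits(db, "sim_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ip <- file.path(dir, "interactions.tsv")
  tp <- file.path(dir, "truth.tsv")
  write_tsv_plain(db$interactions, ip)
  write_tsv_plain(db$truth, tp)
  invisible(c(interactions = ip, truth = tp))
}

# Per-miRNA raw Fisher p-values of a sim_db against its own query/universe.
sim_pvalues <- function(db, alternative = "greater") {
  map <- merge_sources(db$interactions, min_sources = 1,
                       universe = db$universe)
  res <- run_enrichment(map, db$query, alternative = alternative)
  stats::setNames(res$p_value[match(names(map$targets), res$mirna)],
                  names(map$targets))
}

#' Empirical type-I error of the per-miRNA Fisher test
#'
#' Simulates `reps` independent null databases (`odds_ratio = 1`) and
#' reports the fraction of per-miRNA raw p-values at or below `alpha`
#' (discrete exact tests reject when `p <= alpha`), with the binomial
#' standard error of that fraction. Per-replicate seeds are derived from
#' the configuration's root seed, so replicates are reproducible and
#' independent.
#'
#' @param config A null `sim_config` (`odds_ratio = 1` or no planted
#'   miRNAs).
#' @param alpha Nominal level.
#' @param reps Number of replicate databases.
#' @return List with `rate`, `se`, `n_tests`.
#' @export
estimate_type1_error <- function(config, alpha = 0.05, reps = 200) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  if (length(config$planted) && config$odds_ratio != 1) {
    stopf("type-I calibration requires the null: odds_ratio = 1")
  }
  hits <- 0L
  total <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, r)
    p <- sim_pvalues(generate_target_db(cfg))
    hits <- hits + sum(p <= alpha)
    total <- total + length(p)
  }
  rate <- hits / total
  list(rate = rate, se = sqrt(rate * (1 - rate) / total), n_tests = total)
}

#' Empirical power against planted enrichment
#'
#' Simulates `reps` databases with planted miRNAs and reports the fraction
#' of planted-miRNA tests rejected at `alpha` -- on raw p-values by default,
#' or after Benjamini-Hochberg across all M per-database tests with
#' `adjust = "BH"`.
#'
#' @param config A `sim_config` with nonempty `planted`.
#' @param alpha Nominal level.
#' @param reps Number of replicate databases.
#' @param adjust `"none"` (raw p) or `"BH"`.
#' @return List with `rate`, `se`, `n_tests`.
#' @export
estimate_power <- function(config, alpha = 0.05, reps = 200,
                           adjust = c("none", "BH")) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  adjust <- match.arg(adjust)
  if (!length(config$planted)) stopf("config has no planted miRNAs")
  planted_names <- sim_mirna_names(config$n_mirnas)[config$planted]
  hits <- 0L
  total <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, r)
    db <- generate_target_db(cfg)
    p <- sim_pvalues(db)
    stat <- if (adjust == "BH") stats::setNames(bh_adjust(p), names(p)) else p
    hits <- hits + sum(stat[planted_names] <= alpha)
    total <- total + length(planted_names)
  }
  rate <- hits / total
  list(rate = rate, se = sqrt(rate * (1 - rate) / total), n_tests = total)
}
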