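# Configured, logged end-to-end pipeline: CSP -> CHESCA -> dynamics ->
# biochemical fits -> activity correlations, with all stage tables written
# as CSV/TSV and a consolidated run log.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the inference chain, with the
#' working defaults used throughout the package: MAD modified-Z gate 0.25;
#' combined-shift range gate 0.13 ppm; eta-shift correlation gate 0.7;
#' WT-vs-mutant eta-difference gate 8 1/s; covariance-cluster cut height
#' 1.5 (minimum cluster size 3); activity-correlation gate 0.65; tumbling
#' time 30 ns; build-up scaling constant C = 0.75.
#'
#' @param z_threshold MAD modified-Z significance gate.
#' @param range_threshold Combined-shift range gate, ppm.
#' @param r_threshold Gate on `|R_P|` for eta vs shift.
#' @param delta_eta_threshold Gate on `|eta_WT - mean(eta_mutants)|`, 1/s.
#' @param cluster_cutoff Dendrogram cut height.
#' @param min_cluster_size Minimum reported cluster size.
#' @param mean_rp_threshold Gate on `|mean_RP|` vs activities.
#' @param tau_c Overall tumbling time, seconds.
#' @param C Build-up scaling constant.
#' @param weights Combined-shift weight table.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(z_threshold = 0.25, range_threshold = 0.13,
                            r_threshold = 0.7, delta_eta_threshold = 8,
                            cluster_cutoff = 1.5, min_cluster_size = 3,
                            mean_rp_threshold = 0.65, tau_c = 30e-9,
                            C = 0.75, weights = methyl_weights(), seed = 1) {
  cfg <- list(z_threshold = z_threshold, range_threshold = range_threshold,
              r_threshold = r_threshold,
              delta_eta_threshold = delta_eta_threshold,
              cluster_cutoff = cluster_cutoff,
              min_cluster_size = min_cluster_size,
              mean_rp_threshold = mean_rp_threshold, tau_c = tau_c, C = C,
              weights = weights, seed = seed)
  thresholds <- unlist(cfg[c("z_threshold", "range_threshold", "r_threshold",
                             "delta_eta_threshold", "cluster_cutoff",
                             "min_cluster_size", "mean_rp_threshold",
                             "tau_c", "C")])
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[sort(names(config))], file = f)
  unname(tools::md5sum(f))
}

.write_stage <- function(df, dir, name, hash, sep = ",") {
  path <- file.path(dir, name)
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  close(con)
  path
}

#' Run the full inference pipeline
#'
#' Executes the stages the supplied inputs allow: combined-shift table and
#' MAD significance filter (always), covariance clustering of the
#' significant set, shift-dynamics classification (if build-up data is
#' given), biochemical fits (if titration / competition / kinetics /
#' chromatogram inputs are given) and activity correlations (if an activity
#' profile is given or assembled). Each stage table is written under
#' `out_dir` with the config hash in a header comment; a run log records
#' package version, seed, thresholds and skipped stages. A failing stage
#' aborts with the stage named; tables already written are retained.
#' Identical inputs + config reproduce byte-identical outputs.
#'
#' @param inputs List with element `panel` (a `variant_panel`; required) and
#'   optional elements `buildup` (long build-up table), `activities`
#'   (variant-level activity profile), `titration`, `competition` (list with
#'   the fixed probe parameters), `kinetics`, `chromatogram` (list with
#'   `data`, `monomer_window`, `dimer_window`).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_result` with the stage tables
#'   (`shift_table`, `csp`, `clusters`, `dynamics`, `biochem`,
#'   `correlations`, `cluster_summary`), the `skipped` stage names, the
#'   config and its hash.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = tempfile("allonmr_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs$panel) || !inherits(inputs$panel, "variant_panel"))
    stop("inputs$panel must be a variant_panel")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  log_lines <- c(paste0("allonmr ", as.character(utils::packageVersion("allonmr")),
                        " run log"),
                 paste0("config_hash: ", hash),
                 paste0("seed: ", config$seed),
                 paste0("thresholds: z>", config$z_threshold,
                        ", range>", config$range_threshold,
                        " ppm, |R_P|>", config$r_threshold,
                        ", |d_eta|>", config$delta_eta_threshold,
                        " 1/s, cut ", config$cluster_cutoff,
                        ", min size ", config$min_cluster_size,
                        ", |mean R_P|>", config$mean_rp_threshold))
  skipped <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  st <- stage("csp", shift_table(inputs$panel, weights = config$weights))
  csp <- stage("csp", mad_zscores(st, threshold = config$z_threshold))
  .write_stage(cbind(as.data.frame(st)), out_dir, "shift_table.csv", hash)
  .write_stage(csp, out_dir, "csp.csv", hash)

  sig <- csp$methyl[csp$significant]
  clusters <- NULL
  if (length(sig) >= 2) {
    d <- stage("chesca", shift_distance_matrix(st, sig))
    clusters <- stage("chesca", chesca_cluster(d, cutoff = config$cluster_cutoff,
                                               min_size = config$min_cluster_size))
    .write_stage(data.frame(methyl = rownames(d), round(d, 6)), out_dir,
                 "distance_matrix.csv", hash)
    .write_stage(clusters$assignment, out_dir, "clusters.csv", hash)
    .write_stage(dendrogram_export(clusters), out_dir, "merge_tree.tsv", hash,
                 sep = "\t")
  } else skipped <- c(skipped, "chesca")

  dynamics <- NULL
  if (!is.null(inputs$buildup)) {
    eta_tab <- stage("relaxation_tq", fit_buildup_table(inputs$buildup,
                                                        C = config$C))
    eta_tab$s2_axis <- eta_to_s2(eta_tab$eta, config$tau_c)
    dynamics <- stage("relaxation_tq",
                      classify_dynamics(eta_tab, st,
                                        range_threshold = config$range_threshold,
                                        r_threshold = config$r_threshold,
                                        delta_eta_threshold = config$delta_eta_threshold))
    .write_stage(eta_tab, out_dir, "eta_fits.csv", hash)
    .write_stage(dynamics, out_dir, "dynamics.csv", hash)
  } else skipped <- c(skipped, "relaxation_tq")

  biochem <- list()
  if (!is.null(inputs$titration)) {
    biochem$binding <- stage("biochem",
      quadratic_binding_fit(inputs$titration$conc, inputs$titration$signal,
                            probe_conc = inputs$titration$probe_conc[1]))
  }
  if (!is.null(inputs$competition)) {
    cmp <- inputs$competition
    biochem$competition <- stage("biochem",
      competition_fit(cmp$data$conc, cmp$data$signal, cmp$probe_K_D,
                      cmp$probe_conc, cmp$protein_conc, cmp$F0, cmp$F_max))
  }
  if (!is.null(inputs$kinetics)) {
    kin <- inputs$kinetics
    biochem$kinetics <- stage("biochem",
      mm_hill_fit(kin$data$atp_conc, kin$data$v0,
                  enzyme_conc_uM = kin$enzyme_conc_uM))
  }
  if (!is.null(inputs$chromatogram)) {
    ch <- inputs$chromatogram
    biochem$dimer <- stage("biochem",
      dimer_fraction(ch$data$volume, ch$data$absorbance,
                     ch$monomer_window, ch$dimer_window))
  }
  if (length(biochem)) {
    flat <- unlist(lapply(biochem, function(x) unclass(x)[vapply(x, is.numeric,
                                                                 logical(1))]))
    .write_stage(data.frame(parameter = names(flat), value = unname(flat)),
                 out_dir, "biochem_fits.csv", hash)
  } else skipped <- c(skipped, "biochem")

  correlations <- NULL
  summary_tab <- NULL
  if (!is.null(inputs$activities)) {
    correlations <- stage("activity_corr",
      activity_correlations(st, inputs$activities, clusters = clusters,
                            threshold = config$mean_rp_threshold))
    summary_tab <- stage("activity_corr", cluster_sign_summary(correlations))
    .write_stage(correlations, out_dir, "correlations.csv", hash)
    .write_stage(summary_tab, out_dir, "cluster_summary.csv", hash)
    .write_stage(residue_annotation(correlations, st), out_dir,
                 "residue_annotation.csv", hash)
  } else skipped <- c(skipped, "activity_corr")

  log_lines <- c(log_lines,
                 paste0("significant methyls: ", length(sig), " / ", nrow(csp)),
                 if (!is.null(clusters))
                   paste0("clusters: ",
                          length(unique(na.omit(clusters$assignment$cluster)))),
                 if (length(skipped))
                   paste0("skipped stages: ", paste(skipped, collapse = ", "))
                 else "skipped stages: none")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  structure(list(shift_table = st, csp = csp, clusters = clusters,
                 dynamics = dynamics, biochem = biochem,
                 correlations = correlations, cluster_summary = summary_tab,
                 skipped = skipped, config = config, config_hash = hash,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("allonmr pipeline result (", x$out_dir, ")\n", sep = "")
  cat("  significant methyls:", sum(x$csp$significant), "/", nrow(x$csp), "\n")
  if (!is.null(x$clusters)) print(x$clusters)
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions (up to relabeling), 0 the chance level.
#' Used to score recovery of planted response groups.
#'
#' @param a,b Equal-length label vectors (any type; `NA` allowed and treated
#'   as its own label).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- addNA(factor(a), ifany = TRUE)
  b <- addNA(factor(b), ifany = TRUE)
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
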