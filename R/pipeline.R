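# End-to-end pipelines: call -> filter -> (optional GP prefilter) ->
# impute -> score-filter, and the grid driver crossing pipelines, variant-
# calling methods and coverages.

#' Run one imputation pipeline cell
#'
#' Chains genotype calling, the deamination filter (masked to no-calls for
#' Method 3, dropped otherwise), target-site construction, the optional
#' two-step GP prefilter, the haplotype-copying HMM, and the imputation-
#' score filter.
#'
#' @param panel A `haplotype_panel`.
#' @param target An `ancient_target` with pileups at the desired coverage.
#' @param pipeline `"one-step"` (impute the called genotypes directly) or
#'   `"two-step"` (drop calls whose first-pass GP < `gp_threshold` first).
#' @param method Target-site construction (1 variant-only, 2 all confident,
#'   3 panel sites with missing no-calls).
#' @param map,ne,theta HMM parameters (see [impute_ls()]).
#' @param base_error Error rate for genotype likelihoods.
#' @param emit_quality,filter_quality Calling thresholds.
#' @param gp_threshold Two-step GP cutoff.
#' @param score_mode,score_threshold Post-imputation score filter.
#' @return List: `imputed` (score-filtered `imputation_result`),
#'   `imputed_all` (unfiltered), `calls`, `tsites`, `audit` (stage/site-count
#'   table).
#' @export
run_pipeline <- function(panel, target, pipeline = c("one-step", "two-step"),
                         method = 2, map = NULL, ne = 20000, theta = 1e-3,
                         base_error = 1e-3, emit_quality = 25,
                         filter_quality = 30, gp_threshold = 0.99,
                         score_mode = "certainty", score_threshold = 1) {
  pipeline <- match.arg(pipeline)
  if (!method %in% 1:3) stop("method must be 1, 2 or 3")
  calls <- call_genotypes(call_target(target, base_error),
                          emit_quality, filter_quality)
  n_called <- sum(!is.na(calls$gt))
  deam <- deamination_filter(calls, mode = if (method == 3) "mask" else "drop")
  calls <- deam$calls
  tsites <- build_target_sites(method, calls, panel)
  n_obs <- sum(!is.na(tsites$gt))
  if (n_obs == 0L) stop("empty target site set: nothing to impute from")

  n_prefiltered <- NA_integer_
  if (pipeline == "two-step") {
    pre <- two_step_prefilter(tsites, panel, map = map, ne = ne,
                              theta = theta, gp_threshold = gp_threshold)
    tsites <- pre$tsites
    n_prefiltered <- length(pre$removed)
  }
  gl <- target_gl_matrix(tsites, nrow(panel$sites), hard = TRUE)
  res <- impute_ls(gl, panel, map = map, ne = ne, theta = theta)
  filtered <- suppressWarnings(
    score_filter(res, mode = score_mode, threshold = score_threshold))
  # damage-explicable genotypes are excluded from all further analyses, so
  # the imputed output is held to the same rule as the gold standard
  filtered <- result_deamination_filter(filtered)
  audit <- data.frame(
    stage = c("panel_sites", "called", "post_deamination", "target_sites",
              "gp_prefiltered_out", "imputed", "score_filtered"),
    n = c(nrow(panel$sites), n_called, sum(!is.na(calls$gt)), n_obs,
          n_prefiltered, nrow(res), nrow(filtered)))
  list(imputed = filtered, imputed_all = res, calls = calls,
       tsites = tsites, audit = audit,
       settings = list(pipeline = pipeline, method = method, ne = ne,
                       theta = theta, gp_threshold = gp_threshold,
                       score_threshold = score_threshold))
}

#' Assemble an experiment configuration
#'
#' Defaults describe the framework's motivating scenario: the
#' 51-donor European-skewed panel, a ~46/54 European/Near-Eastern admixed
#' target, deamination damage, and the 0.5-2x coverage grid crossed with
#' both pipelines and all three calling methods.
#'
#' @param group_sizes,n_sites,fst Panel parameters ([simulate_panel()]).
#' @param ancestry_props,switch_rate_per_cm Target admixture
#'   ([simulate_admixed_target()]).
#' @param base_error,deam_rate Read-simulation noise ([simulate_reads()]).
#' @param coverages Coverage grid (x).
#' @param pipelines,methods Pipeline/method grid.
#' @param ne,theta,gp_threshold,score_threshold Imputation parameters.
#' @param seed Master seed; all cell seeds derive from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(group_sizes = c(EUW = 19, EUD = 25, BLW = 4,
                                              NEW = 3),
                              n_sites = 5000, fst = 0.15,
                              ancestry_props = NULL,
                              switch_rate_per_cm = 0.01,
                              base_error = 1e-3, deam_rate = 0.1,
                              coverages = c(0.5, 1, 1.5, 2),
                              pipelines = c("one-step", "two-step"),
                              methods = 1:3,
                              ne = 20000, theta = 1e-3, gp_threshold = 0.99,
                              score_threshold = 1, seed = 1L) {
  if (is.null(ancestry_props)) {
    # default target admixture: the ~46/54 European/Near-Eastern mixture when
    # those groups exist, otherwise an even split of the first two groups
    ancestry_props <- if (all(c("EUW", "NEW") %in% names(group_sizes))) {
      c(EUW = 0.46, NEW = 0.54)
    } else {
      g <- names(group_sizes)[seq_len(min(2, length(group_sizes)))]
      stats::setNames(rep(1 / length(g), length(g)), g)
    }
  }
  cfg <- list(group_sizes = group_sizes, n_sites = n_sites, fst = fst,
              ancestry_props = ancestry_props,
              switch_rate_per_cm = switch_rate_per_cm,
              base_error = base_error, deam_rate = deam_rate,
              coverages = coverages, pipelines = pipelines,
              methods = methods, ne = ne, theta = theta,
              gp_threshold = gp_threshold,
              score_threshold = score_threshold, seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  cfg
}

#' Run the full evaluation grid
#'
#' Simulates one panel/target pair, sequences it at the maximum grid
#' coverage, then for every coverage x pipeline x method cell downsamples,
#' imputes and evaluates (concordance vs the deamination-filtered gold
#' standard). Cells that fail are recorded and skipped. Deterministic for a
#' fixed config: all seeds derive from `config$seed`.
#'
#' @param config An `experiment_config`.
#' @param out_dir Optional directory; if given, writes `report.tsv`,
#'   `audit.tsv` and an archived `config.R` next to the outputs.
#' @return List: `report` (one row per cell), `cells` (full per-cell
#'   results), `panel`, `target`, `truth`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  panel <- simulate_panel(config$group_sizes, config$n_sites, config$fst,
                          seed = seed)
  target <- simulate_admixed_target(panel, config$ancestry_props,
                                    config$switch_rate_per_cm,
                                    seed = seed + 1L)
  target <- simulate_reads(target, coverage = max(config$coverages),
                           base_error = config$base_error,
                           deam_rate = config$deam_rate, seed = seed + 2L)
  truth <- truth_calls(target)

  grid <- expand.grid(coverage = config$coverages,
                      pipeline = config$pipelines,
                      method = config$methods,
                      stringsAsFactors = FALSE)
  cells <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cov <- grid$coverage[i]
    dst <- if (cov >= max(config$coverages)) {
      target # top of the grid is the full sequencing run
    } else {
      downsample_pileups(target, target_coverage = cov,
                         seed = seed + 10L + match(cov, config$coverages))
    }
    cell <- tryCatch(
      run_pipeline(panel, dst, pipeline = grid$pipeline[i],
                   method = grid$method[i], ne = config$ne,
                   theta = config$theta, base_error = config$base_error,
                   gp_threshold = config$gp_threshold,
                   score_threshold = config$score_threshold),
      error = function(e) e)
    if (inherits(cell, "error")) {
      rows[[i]] <- data.frame(
        pipeline = grid$pipeline[i], method = grid$method[i],
        coverage = cov, status = "failed", n_imputed = NA_integer_,
        n_correct = NA_integer_, n_incorrect_genotype = NA_integer_,
        n_incorrect_position = NA_integer_, concordance = NA_real_,
        information_content = NA_real_, stringsAsFactors = FALSE)
      cells[[i]] <- list(error = conditionMessage(cell))
      next
    }
    rep <- concordance(cell$imputed, truth)
    rows[[i]] <- data.frame(
      pipeline = grid$pipeline[i], method = grid$method[i],
      coverage = cov, status = "ok", n_imputed = rep$n_imputed,
      n_correct = rep$n_correct,
      n_incorrect_genotype = rep$n_incorrect_genotype,
      n_incorrect_position = rep$n_incorrect_position,
      concordance = rep$concordance,
      information_content = rep$information_content,
      stringsAsFactors = FALSE)
    cells[[i]] <- c(cell, list(concordance = rep))
  }
  report <- do.call(rbind, rows)
  out <- list(report = report, cells = cells, panel = panel,
              target = target, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    audits <- do.call(rbind, lapply(seq_along(cells), function(i) {
      if (is.null(cells[[i]]$audit)) return(NULL)
      cbind(grid[i, , drop = FALSE], cells[[i]]$audit, row.names = NULL)
    }))
    utils::write.table(audits, file.path(out_dir, "audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dput(unclass(config), file.path(out_dir, "config.R"))
  }
  out
}
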