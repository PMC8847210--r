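#' Configuration of the end-to-end discovery pipeline
#'
#' Collects every tunable of the stage chain with its default:
#' parallel-analysis replicates (1000) and percentile (95), the
#' Weiss-Indurkhya screen cutoff (|t| >= 2.0), sequential-forward-selection
#' iterations (1000; 100 is a documented fast mode), per-run feature cap
#' (10), consensus size (10), CV folds (10), the confirmatory significance
#' level (0.001) and the association rules (|rho| >= 0.5 at 0.05,
#' candidate |t| >= 2.0). One master seed fans out to stage-specific child
#' seeds so each stage is independently reproducible.
#'
#' @param pa_replicates,pa_percentile parallel-analysis Monte-Carlo size
#'   and percentile.
#' @param wi_threshold Welch screen cutoff on `|t|`.
#' @param sfs_iterations,sfs_max_features,sfs_top,sfs_folds consensus
#'   selection controls.
#' @param alpha_main confirmatory significance level for main features.
#' @param assoc_alpha_corr,assoc_t_threshold associated-feature rules.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pa_replicates = 1000L, pa_percentile = 95,
                            wi_threshold = 2.0,
                            sfs_iterations = 1000L, sfs_max_features = 10L,
                            sfs_top = 10L, sfs_folds = 10L,
                            alpha_main = 0.001,
                            assoc_alpha_corr = 0.05,
                            assoc_t_threshold = 2.0,
                            seed = 1L) {
  structure(list(pa_replicates = as.integer(pa_replicates),
                 pa_percentile = pa_percentile,
                 wi_threshold = wi_threshold,
                 sfs_iterations = as.integer(sfs_iterations),
                 sfs_max_features = as.integer(sfs_max_features),
                 sfs_top = as.integer(sfs_top),
                 sfs_folds = as.integer(sfs_folds),
                 alpha_main = alpha_main,
                 assoc_alpha_corr = assoc_alpha_corr,
                 assoc_t_threshold = assoc_t_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full waveform feature-discovery pipeline
#'
#' Per-variable trial-weighted correlation PCA, Horn's parallel analysis
#' (one threshold table shared by all variables of equal dimension), the
#' Weiss-Indurkhya Welch screen, consensus sequential forward selection,
#' confirmatory statistics with Hedges' g, associated-feature discovery
#' and per-feature interpretation artifacts. If a stage retains nothing,
#' the report stops early at that stage with the counts accumulated so far.
#'
#' @param cohort a [waveform_cohort()].
#' @param config a [pipeline_config()].
#' @return Object of class `pipeline_report`: list with `stage_counts`
#'   (total components, PA-retained, screen-retained, main features),
#'   `retention` (per variable/PC explained-variance table with retention
#'   markers), `pa`, `screen` (the [wi_filter()] comparisons), `selection`
#'   (the [select_main_features()] result), `main_tests`, `associations`,
#'   `interpretations`, `config`, `seeds`, `stopped_at` (`NA` for a
#'   complete run).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "waveform_cohort"),
            inherits(config, "pipeline_config"))
  set.seed(config$seed)
  child <- sample.int(2147483646L, 2L)
  seeds <- list(master = config$seed, pa = child[1L], sfs = child[2L])

  pcas <- lapply(names(cohort$variables), function(v) {
    fit_pca(cohort$variables[[v]], cohort$weights, variable = v)
  })
  names(pcas) <- names(cohort$variables)

  thr <- pa_thresholds(cohort$n, cohort$p, n_rep = config$pa_replicates,
                       percentile = config$pa_percentile, seed = seeds$pa)
  pa_results <- lapply(names(pcas), function(v) {
    retain_components(pcas[[v]]$eigenvalues, thr, variable = v)
  })
  names(pa_results) <- names(pcas)

  retention <- do.call(rbind, lapply(names(pcas), function(v) {
    k <- max(pa_results[[v]]$retained_k, 1L)
    data.frame(variable = v, pc = seq_len(k),
               explained_pct = 100 * pcas[[v]]$explained_fraction[seq_len(k)],
               pa_retained = seq_len(k) <= pa_results[[v]]$retained_k,
               wi_retained = FALSE, main = FALSE,
               stringsAsFactors = FALSE)
  }))

  total_components <- length(pcas) * cohort$p
  pa_count <- sum(vapply(pa_results, `[[`, integer(1), "retained_k"))
  counts <- c(total_components = total_components, pa_retained = pa_count,
              wi_retained = NA_integer_, main_features = NA_integer_)
  report <- structure(list(stage_counts = counts, retention = retention,
                           pcas = pcas, pa = pa_results, thresholds = thr,
                           screen = NULL, selection = NULL,
                           main_tests = NULL, associations = NULL,
                           interpretations = NULL,
                           config = config, seeds = seeds,
                           stopped_at = NA_character_),
                      class = "pipeline_report")
  if (pa_count == 0L) {
    report$stopped_at <- "parallel_analysis"
    return(report)
  }

  table <- assemble_feature_table(cohort, pcas, pa_results)
  screen <- wi_filter(table, threshold = config$wi_threshold)
  report$screen <- screen
  report$stage_counts["wi_retained"] <- screen$n_retained
  kept <- screen$comparisons$feature_id[screen$comparisons$retained]
  report$retention$wi_retained <-
    paste0(report$retention$variable, ".PC", report$retention$pc) %in% kept
  if (screen$n_retained == 0L) {
    report$stopped_at <- "wi_filter"
    return(report)
  }

  selection <- select_main_features(screen$table,
                                    iterations = config$sfs_iterations,
                                    max_features = config$sfs_max_features,
                                    top = config$sfs_top,
                                    folds = config$sfs_folds,
                                    seed = seeds$sfs)
  report$selection <- selection
  main <- selection$main_features
  report$stage_counts["main_features"] <- length(main)
  report$retention$main <-
    paste0(report$retention$variable, ".PC", report$retention$pc) %in% main
  if (length(main) == 0L) {
    report$stopped_at <- "sfs"
    return(report)
  }

  report$main_tests <- main_feature_tests(screen$table, main,
                                          alpha = config$alpha_main)
  report$associations <- associated_features(
    table, main,
    alpha_corr = config$assoc_alpha_corr,
    t_threshold = config$assoc_t_threshold,
    alpha_strict = config$alpha_main)
  report$interpretations <- lapply(main, function(id) {
    row <- table$map[match(id, table$map$feature_id), ]
    interpret_feature(cohort$variables[[row$variable]], pcas[[row$variable]],
                      row$pc, cohort$trial_meta$group)
  })
  names(report$interpretations) <- main
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("feature-discovery pipeline\n  stage chain:",
      sc["total_components"], "components ->", sc["pa_retained"],
      "after parallel analysis ->",
      if (is.na(sc["wi_retained"])) "-" else sc["wi_retained"],
      "after |t| screen ->",
      if (is.na(sc["main_features"])) "-" else sc["main_features"],
      "main features\n")
  if (!is.na(x$stopped_at)) {
    cat("  stopped early at stage:", x$stopped_at, "\n")
  } else if (!is.null(x$main_tests)) {
    cat(" ", attr(x$main_tests, "n_significant"), "of",
        nrow(x$main_tests), "main features significant at alpha =",
        attr(x$main_tests, "alpha"), "\n")
  }
  invisible(x)
}

#' Write the pipeline report as a directory of CSV tables
#'
#' Emits `stage_counts.csv`, the per-variable retention table
#' (`retention.csv`), the full screening table (`screen.csv`), the
#' main-feature statistics (`main_features.csv`), the association table
#' (`associations.csv`, header only when empty), the consensus frequency
#' table (`sfs_frequency.csv`), and one `interpretation_<feature>.csv`
#' bundle per main feature (phase, quartile mean/SD curves, coefficient
#' curve, explained-variance curve). With `figures = TRUE` a PNG per main
#' feature is rendered alongside.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @param figures also render per-feature PNG figures.
#' @return Invisibly, the written file paths.
#' @export
render_report <- function(report, out_dir, figures = FALSE) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory '", out_dir, "'")
  }
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  sc <- report$stage_counts
  put(data.frame(stage = names(sc), count = unname(sc)), "stage_counts.csv")
  put(report$retention, "retention.csv")
  if (!is.null(report$screen)) put(report$screen$comparisons, "screen.csv")
  if (!is.null(report$selection)) {
    put(data.frame(feature_id = names(report$selection$frequency),
                   frequency = unname(report$selection$frequency)),
        "sfs_frequency.csv")
  }
  if (!is.null(report$main_tests)) put(report$main_tests, "main_features.csv")
  if (!is.null(report$associations)) {
    put(report$associations, "associations.csv")
  }
  for (id in names(report$interpretations)) {
    it <- report$interpretations[[id]]
    p <- length(it$upper_mean)
    safe <- gsub("[^A-Za-z0-9_.-]", "_", id)
    put(data.frame(phase_pct = seq(0, 100, length.out = p),
                   upper_mean = it$upper_mean, upper_sd = it$upper_sd,
                   lower_mean = it$lower_mean, lower_sd = it$lower_sd,
                   coefficient = it$coefficient_curve,
                   explained = it$explained_curve),
        paste0("interpretation_", safe, ".csv"))
    if (figures) {
      path <- file.path(out_dir, paste0("figure_", safe, ".png"))
      grDevices::png(path, width = 800, height = 900)
      plot(it)
      grDevices::dev.off()
      files <- c(files, path)
    }
  }
  invisible(files)
}
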