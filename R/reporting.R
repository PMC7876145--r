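#' Welch's unpaired two-sample t-test
#'
#' Two-tailed unpaired t-test with Welch's correction for unequal
#' variances: \eqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' with Welch-Satterthwaite (fractional) degrees of freedom. Degenerate
#' zero-variance inputs are handled explicitly: equal means give t = 0,
#' p = 1; unequal means give p = 0 with a degeneracy flag.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2
#' @param labels character(2) group labels
#' @return object of class `comparison_result` with fields `group_labels`,
#'   `n_per_group`, `means`, `sds`, `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `degenerate`
#' @export
welch_ttest <- function(sample_a, sample_b, labels = c("A", "B")) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 observations")
  na <- length(sample_a); nb <- length(sample_b)
  ma <- mean(sample_a); mb <- mean(sample_b)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      tstat <- 0; df <- na + nb - 2; p <- 1
    } else {
      tstat <- sign(ma - mb) * Inf; df <- NA_real_; p <- 0
      degenerate <- TRUE
    }
  } else {
    sea <- va / na; seb <- vb / nb
    tstat <- (ma - mb) / sqrt(sea + seb)
    df <- (sea + seb)^2 / (sea^2 / (na - 1) + seb^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(group_labels = labels, n_per_group = c(na, nb),
                 means = c(ma, mb), sds = c(sqrt(va), sqrt(vb)),
                 t_statistic = tstat, degrees_of_freedom = df,
                 p_value = p, degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Welch's t-test, %s (n=%d) vs %s (n=%d):\n",
              x$group_labels[1], x$n_per_group[1],
              x$group_labels[2], x$n_per_group[2]))
  cat(sprintf("  means %.4g vs %.4g; t = %.4g, df = %.3g, p = %.3g%s\n",
              x$means[1], x$means[2], x$t_statistic, x$degrees_of_freedom,
              signif(x$p_value, 3),
              if (x$degenerate) " (degenerate: both variances zero)" else ""))
  invisible(x)
}

#' Mean and standard deviation over replicate measurements
#'
#' Sample SD uses the n - 1 denominator, matching the convention for
#' triplicate experimental error bars.
#'
#' @param values per-replicate scalars, length >= 2
#' @return named numeric vector `c(mean =, sd =)`
#' @export
aggregate_replicates <- function(values) {
  if (length(values) < 2) stop("need at least 2 replicates")
  c(mean = mean(values), sd = stats::sd(values))
}

.config_digest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the simulate -> analyse -> report pipeline
#'
#' Executes, for each condition in the configuration, replicate track-set
#' simulations followed by docked-vesicle counting and residence-time
#' estimation; aggregates replicates; and performs the requested Welch
#' comparisons. Deterministic given the seeds in the configuration.
#'
#' Configuration (R list or YAML file path):
#' \describe{
#'   \item{seed}{base integer seed}
#'   \item{conditions}{list of named entries, each with `arrival_rate`,
#'     `mean_residence` (ms) and optionally `frame_count` (default 2000),
#'     `frame_period` (ms, default 40), `dropout_prob` (default 0.1),
#'     `max_gap` (default 1), `n_replicates` (default 3),
#'     `window_frames` (default `min(3500, frame_count)`)}
#'   \item{comparisons}{list of `list(a =, b =, metric =)` with metric
#'     `"residence"` or `"mean_docked"`; default: none}
#' }
#'
#' @param config list or path to a YAML file
#' @return object of class `pipeline_report`: per-condition replicate
#'   metrics, aggregates, comparison table, provenance (config digest,
#'   seeds)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$conditions))
  base_seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cond_names <- names(config$conditions)
  if (is.null(cond_names) || any(cond_names == ""))
    stop("conditions must be a named list")
  set.seed(base_seed)
  conditions <- list()
  for (ci in seq_along(config$conditions)) {
    cn <- cond_names[ci]
    cc <- config$conditions[[ci]]
    n_rep <- if (is.null(cc$n_replicates)) 3L else cc$n_replicates
    frame_count <- if (is.null(cc$frame_count)) 2000L else cc$frame_count
    frame_period <- if (is.null(cc$frame_period)) 40 else cc$frame_period
    dropout <- if (is.null(cc$dropout_prob)) 0.1 else cc$dropout_prob
    max_gap <- if (is.null(cc$max_gap)) 1L else cc$max_gap
    wf <- if (is.null(cc$window_frames)) min(3500L, frame_count) else cc$window_frames
    seeds <- (base_seed * 1000L + ci * 100L + seq_len(n_rep)) %% .Machine$integer.max
    reps <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      sim <- simulate_track_set(frame_count, cc$arrival_rate,
                                cc$mean_residence,
                                frame_period = frame_period,
                                dropout_prob = dropout, max_gap = max_gap,
                                seed = seeds[r])
      win <- last_frames_window(frame_count, wf)
      counts <- count_docked(sim$tracks, win)
      fit <- fit_residence(compute_acf(sim$tracks, window = win))
      reps[[r]] <- list(seed = seeds[r], mean_docked = counts$mean,
                        sd_docked = counts$sd, residence_ms = fit$t2,
                        residence_se = fit$t2_se,
                        degenerate = fit$degenerate)
    }
    md <- vapply(reps, `[[`, 0, "mean_docked")
    rt <- vapply(reps, `[[`, 0, "residence_ms")
    conditions[[cn]] <- list(
      parameters = list(arrival_rate = cc$arrival_rate,
                        mean_residence = cc$mean_residence,
                        frame_count = frame_count,
                        frame_period = frame_period,
                        dropout_prob = dropout, max_gap = max_gap,
                        window_frames = wf),
      replicates = reps,
      mean_docked = as.list(aggregate_replicates(md)),
      residence_ms = as.list(aggregate_replicates(rt)))
  }
  comparisons <- list()
  for (cmp in config$comparisons) {
    metric <- if (is.null(cmp$metric)) "residence" else cmp$metric
    get_vals <- function(cn) {
      reps <- conditions[[cn]]$replicates
      vapply(reps, `[[`, 0,
             if (metric == "residence") "residence_ms" else "mean_docked")
    }
    ct <- welch_ttest(get_vals(cmp$a), get_vals(cmp$b),
                      labels = c(cmp$a, cmp$b))
    comparisons[[length(comparisons) + 1L]] <- list(
      a = cmp$a, b = cmp$b, metric = metric,
      t = ct$t_statistic, df = ct$degrees_of_freedom,
      p_value = signif(ct$p_value, 3), degenerate = ct$degenerate)
  }
  structure(list(conditions = conditions, comparisons = comparisons,
                 provenance = list(seed = base_seed,
                                   config_md5 = .config_digest(config),
                                   package_version = as.character(utils::packageVersion("synaptodock")))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n===============\n")
  for (cn in names(x$conditions)) {
    co <- x$conditions[[cn]]
    cat(sprintf("%s: %.1f +/- %.1f docked/frame; residence %.0f +/- %.0f ms (n=%d)\n",
                cn, co$mean_docked$mean, co$mean_docked$sd,
                co$residence_ms$mean, co$residence_ms$sd,
                length(co$replicates)))
  }
  for (cm in x$comparisons)
    cat(sprintf("%s vs %s (%s): p = %.3g\n", cm$a, cm$b, cm$metric,
                cm$p_value))
  cat(sprintf("seed %d, config md5 %s\n", x$provenance$seed,
              x$provenance$config_md5))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report a `pipeline_report`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
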