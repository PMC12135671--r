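#' Run the full two-step MR mediation pipeline
#'
#' Orchestrates, for one exposure, one outcome and any number of candidate
#' mediators: instrument selection, harmonization, the univariable suite
#' for the total effect (`beta0`) with a reverse-causation check, and per
#' mediator the step-1 univariable analysis (exposure to mediator,
#' `beta1`), the mediator's own reverse check, the univariable and
#' MVMR-adjusted mediator-to-outcome analyses (`beta2` from MVMR), the
#' three-criterion mediator screen, and — for mediators passing all three
#' criteria — the mediation proportion with its delta-method interval.
#' Step-1/step-2 significance uses the Bonferroni-adjusted threshold
#' `alpha / (n_mediators * n_outcomes)`; reverse-causation tests use plain
#' 0.05. A failure in one mediator's analyses is recorded for that mediator
#' and the pipeline continues with the rest. Results are deterministic in
#' the configured seed.
#'
#' @param config Either a named list or a path to a YAML/JSON file with
#'   entries:
#' \describe{
#'   \item{exposure, outcome}{lists with `name` and either `file` (a
#'     summary-statistics path read via [read_sumstats()]) or `data` (an
#'     in-memory canonical data frame).}
#'   \item{mediators}{named list of such entries (possibly empty).}
#'   \item{ld}{optional [ld_matrix()], or a path readable by
#'     [read_ld_matrix()].}
#'   \item{p_threshold, r2_threshold, window_kb, f_threshold}{instrument
#'     selection (defaults 5e-8, 0.001, 10000, 10).}
#'   \item{palindrome_policy, eaf_window}{harmonization (defaults
#'     "drop-all", 0.08).}
#'   \item{q_alpha, n_boot, n_sim, outlier_alpha, run_presso}{estimator
#'     settings as in [uvmr_suite()].}
#'   \item{alpha, include_var0}{screen/mediation settings (defaults 0.05,
#'     TRUE).}
#'   \item{outcome_binary, mediator_binary}{report odds-ratio scales
#'     (defaults FALSE, TRUE).}
#'   \item{seed}{base integer seed (default 1).}
#' }
#' @return Object of class `mediation_report`.
#' @seealso [report_table()], [write_report()]
#' @export
run_pipeline <- function(config) {
  cfg <- .pipeline_config(config)
  exposure <- .load_trait(cfg$exposure, "exposure")
  outcome <- .load_trait(cfg$outcome, "outcome")
  mediators <- lapply(cfg$mediators, .load_trait, what = "mediator")
  ld <- .load_ld(cfg$ld)

  sel_args <- list(ld = ld, p_threshold = cfg$p_threshold,
                   r2_threshold = cfg$r2_threshold, window_kb = cfg$window_kb,
                   f_threshold = cfg$f_threshold)
  harm <- function(sets) {
    harmonize(sets, palindrome_policy = cfg$palindrome_policy,
              eaf_window = cfg$eaf_window)
  }
  suite_cfg <- function(seed, exponentiate = FALSE) {
    list(q_alpha = cfg$q_alpha, n_boot = cfg$n_boot, n_sim = cfg$n_sim,
         outlier_alpha = cfg$outlier_alpha, seed = seed,
         exponentiate = exponentiate, run_presso = cfg$run_presso)
  }

  # Total effect and outcome-level reverse check.
  sel_exp <- do.call(select_instruments, c(list(exposure$data), sel_args))
  h0 <- harm(stats::setNames(list(sel_exp$data, outcome$data),
                             c(exposure$name, outcome$name)))
  total <- uvmr_suite(h0, suite_cfg(cfg$seed, cfg$outcome_binary))
  rev_outcome <- do.call(reverse_mr,
                         c(list(outcome$data, exposure$data, ld,
                                config = suite_cfg(cfg$seed + 1L),
                                palindrome_policy = cfg$palindrome_policy,
                                eaf_window = cfg$eaf_window),
                           sel_args[-1]))
  beta0 <- total$primary_estimate

  n_med <- length(mediators)
  alpha_step <- if (n_med) bonferroni_threshold(n_med, 1L, cfg$alpha) else cfg$alpha

  med_results <- stats::setNames(vector("list", n_med), names(mediators))
  for (i in seq_len(n_med)) {
    med <- mediators[[i]]
    seed_i <- cfg$seed + 10L * i
    med_results[[i]] <- tryCatch({
      # Step 1: exposure -> mediator on the exposure's instruments.
      h1 <- harm(stats::setNames(list(sel_exp$data, med$data),
                                 c(exposure$name, med$name)))
      step1 <- uvmr_suite(h1, suite_cfg(seed_i, cfg$mediator_binary))
      beta1 <- step1$primary_estimate

      rev_med <- do.call(reverse_mr,
                         c(list(med$data, exposure$data, ld,
                                config = suite_cfg(seed_i + 1L),
                                palindrome_policy = cfg$palindrome_policy,
                                eaf_window = cfg$eaf_window),
                           sel_args[-1]))

      # Step 2: mediator -> outcome, unadjusted and exposure-adjusted.
      uvmr_my <- tryCatch({
        sel_med <- do.call(select_instruments, c(list(med$data), sel_args))
        h_my <- harm(stats::setNames(list(sel_med$data, outcome$data),
                                     c(med$name, outcome$name)))
        uvmr_suite(h_my, suite_cfg(seed_i + 2L))
      }, mr_error = function(e) NULL)

      joint <- do.call(select_mvmr_instruments,
                       c(list(stats::setNames(list(exposure$data, med$data),
                                              c(exposure$name, med$name))),
                         sel_args, list(outcome_stats = outcome$data)))
      h2 <- harm(stats::setNames(
        list(exposure$data[exposure$data$snp_id %in% joint$snps, , drop = FALSE],
             med$data, outcome$data),
        c(exposure$name, med$name, outcome$name)))
      mv <- mvmr_ivw(h2)
      beta2 <- mv$betas[[med$name]]
      se2 <- mv$ses[[med$name]]

      screen <- screen_mediator(
        reverse_outcome = rev_outcome, reverse_mediator = rev_med,
        uvmr_my_p = if (is.null(uvmr_my)) NA_real_ else
          uvmr_my$primary_estimate$pvalue,
        mvmr_my_p = mv$pvalues[[med$name]],
        beta0 = beta0$beta, beta1 = beta1$beta, beta2 = beta2,
        alpha_step = alpha_step, alpha_reverse = 0.05)

      mediation <- NULL
      if (screen$all_pass) {
        mediation <- mediation_proportion(
          beta1 = beta1$beta, var1 = beta1$se^2,
          beta2 = beta2, var2 = se2^2,
          beta0 = beta0$beta, var0 = beta0$se^2,
          include_var0 = cfg$include_var0)
      }
      list(step1 = step1, reverse = rev_med, uvmr_my = uvmr_my, mvmr = mv,
           screen = screen, mediation = mediation, error = NULL)
    }, mr_error = function(e) {
      list(step1 = NULL, reverse = NULL, uvmr_my = NULL, mvmr = NULL,
           screen = NULL, mediation = NULL, error = conditionMessage(e))
    })
  }

  structure(list(exposure = exposure$name, outcome = outcome$name,
                 total = total, reverse_outcome = rev_outcome,
                 instruments = sel_exp, alpha_step = alpha_step,
                 mediators = med_results, config = cfg),
            class = "mediation_report")
}

# Fill pipeline defaults; read a YAML/JSON config file when given a path.
.pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      mr_abort(sprintf("config file not found: %s", config), "mr_config_error")
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) mr_abort("config must be a list or a file path", "mr_config_error")
  defaults <- list(p_threshold = 5e-8, r2_threshold = 0.001, window_kb = 10000,
                   f_threshold = 10, palindrome_policy = "drop-all",
                   eaf_window = 0.08, q_alpha = 0.05, n_boot = 1000,
                   n_sim = 1000, outlier_alpha = 0.05, run_presso = TRUE,
                   alpha = 0.05, include_var0 = TRUE, outcome_binary = FALSE,
                   mediator_binary = TRUE, seed = 1L, mediators = list(),
                   ld = NULL)
  cfg <- utils::modifyList(defaults, config)
  for (req in c("exposure", "outcome")) {
    if (is.null(cfg[[req]])) {
      mr_abort(sprintf("config must name an %s", req), "mr_config_error")
    }
  }
  if (length(cfg$mediators) && is.null(names(cfg$mediators))) {
    names(cfg$mediators) <- vapply(cfg$mediators, function(m) {
      m$name %||% mr_abort("each mediator needs a name", "mr_config_error")
    }, character(1))
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.load_trait <- function(entry, what) {
  if (is.data.frame(entry)) entry <- list(data = entry)
  if (!is.list(entry)) {
    mr_abort(sprintf("%s entry must be a list with name and file/data", what),
             "mr_config_error")
  }
  data <- if (!is.null(entry$data)) {
    validate_sumstats_strict(entry$data, sprintf("%s data", what))
  } else if (!is.null(entry$file)) {
    read_sumstats(entry$file, dialect = do.call(sumstats_dialect,
                                                as.list(entry$dialect %||% list())))
  } else {
    mr_abort(sprintf("%s entry needs either `data` or `file`", what),
             "mr_config_error")
  }
  list(name = entry$name %||% what, data = data)
}

.load_ld <- function(ld) {
  if (is.null(ld) || inherits(ld, "ld_matrix")) return(ld)
  if (is.character(ld)) return(read_ld_matrix(ld))
  mr_abort("ld must be NULL, an ld_matrix, or a file path", "mr_config_error")
}

#' Tabulate a mediation report
#'
#' One row per candidate mediator with the three effects, the screen
#' verdicts and (for passing mediators) the mediation proportion.
#'
#' @param report A [run_pipeline()] result.
#' @return A data frame.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "mediation_report"))
  b0 <- report$total$primary_estimate
  rows <- lapply(names(report$mediators), function(nm) {
    m <- report$mediators[[nm]]
    if (!is.null(m$error)) {
      return(data.frame(mediator = nm, beta0 = b0$beta, beta1 = NA_real_,
                        beta2 = NA_real_, unidirectional = NA, robust = NA,
                        sign_consistent = NA, passes = FALSE,
                        proportion = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, error = m$error,
                        stringsAsFactors = FALSE))
    }
    med <- m$mediation
    data.frame(mediator = nm, beta0 = b0$beta,
               beta1 = m$step1$primary_estimate$beta,
               beta2 = unname(m$mvmr$betas[nm]),
               unidirectional = m$screen$unidirectional$pass,
               robust = m$screen$robust_to_adjustment$pass,
               sign_consistent = m$screen$sign_consistent$pass,
               passes = m$screen$all_pass,
               proportion = if (is.null(med)) NA_real_ else med$proportion,
               ci_low = if (is.null(med)) NA_real_ else med$ci_low,
               ci_high = if (is.null(med)) NA_real_ else med$ci_high,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mediator = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a mediation report to disk
#'
#' Emits the per-method UVMR table for the total effect, the per-mediator
#' summary table, and a JSON digest of effects, diagnostics and screen
#' verdicts.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param format Any of `"tsv"`, `"json"` (default both).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir, format = c("tsv", "json")) {
  stopifnot(inherits(report, "mediation_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("tsv" %in% format) {
    utils::write.table(report$total$table, file.path(dir, "total_effect.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report_table(report), file.path(dir, "mediators.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("json" %in% format) {
    digest <- list(
      exposure = report$exposure, outcome = report$outcome,
      beta0 = report$total$primary_estimate$beta,
      primary_method = report$total$primary,
      heterogeneity = unclass(report$total$heterogeneity),
      presso_global_p = report$total$presso$global_p,
      presso_outliers = report$total$presso$outliers,
      alpha_step = report$alpha_step,
      mediators = stats::setNames(lapply(names(report$mediators), function(nm) {
        m <- report$mediators[[nm]]
        if (!is.null(m$error)) return(list(error = m$error))
        list(beta1 = m$step1$primary_estimate$beta,
             beta2 = unname(m$mvmr$betas[nm]),
             screen = lapply(unclass(m$screen)[1:3], function(s) s$pass),
             proportion = if (is.null(m$mediation)) NULL else m$mediation$proportion,
             ci = if (is.null(m$mediation)) NULL else
               c(m$mediation$ci_low, m$mediation$ci_high))
      }), names(report$mediators)))
    jsonlite::write_json(digest, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("Two-step MR mediation: %s -> %s\n", x$exposure, x$outcome))
  cat(sprintf("Total effect (%s): beta0 = %.4f, p = %.3g, %d instruments\n",
              x$total$primary, x$total$primary_estimate$beta,
              x$total$primary_estimate$pvalue, x$total$n_snps))
  if (length(x$mediators)) {
    print(report_table(x)[, c("mediator", "beta1", "beta2", "passes",
                              "proportion", "ci_low", "ci_high")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}
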