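#' Experimental force ratios from the sideways experiment
#'
#' Forms the directional force ratios that the model predicts from the bin
#' summaries of the sideways experiment: `fap_fas` = median(+90)/median(0),
#' `fan_fas` = median(-90)/median(0), `fap_fan` = median(+90)/median(-90).
#' The default estimator is these plain ratios of bin medians;
#' `method = "bootstrap"` instead resamples each bin jointly, forms the
#' ratios per replicate, and reports the median replicate ratio (the two
#' differ slightly because the ratio of medians is not the median ratio).
#'
#' @param summaries Per-bin summary table from [summarize_forces()], or a raw
#'   force table (columns `experiment`, `angle_bin`, `force_mN`) when
#'   `method = "bootstrap"`.
#' @param method `"median"` (ratio of bin medians) or `"bootstrap"`.
#' @param B,seed Bootstrap replicates and seed (bootstrap method only).
#' @return A one-row tibble: `fap_fas`, `fan_fas`, `fap_fan`, `method`.
#' @examples
#' experimental_ratios(summarize_forces(sample_forces(seed = 1)))
#' @export
experimental_ratios <- function(summaries, method = c("median", "bootstrap"),
                                B = 1000, seed = 0) {
  method <- match.arg(method)
  if (method == "median") {
    side <- summaries[summaries$experiment == "sideways", ]
    med <- function(bin) {
      m <- side$median_mN[side$angle_bin == bin]
      if (length(m) != 1 || !is.finite(m)) {
        abort(sprintf("Missing sideways bin '%s'.", bin),
              class = "abscissr_missing_bin")
      }
      m
    }
    tibble(fap_fas = med("+90") / med("0"),
           fan_fas = med("-90") / med("0"),
           fap_fan = med("+90") / med("-90"),
           method = method)
  } else {
    check_force_table(summaries)
    side <- summaries[summaries$experiment == "sideways", ]
    grab <- function(bin) {
      f <- side$force_mN[side$angle_bin == bin]
      if (length(f) < 2) {
        abort(sprintf("Missing or degenerate sideways bin '%s'.", bin),
              class = "abscissr_missing_bin")
      }
      f
    }
    fs <- grab("0"); fn <- grab("-90"); fp <- grab("+90")
    reps <- withr::with_seed(seed, {
      purrr::map_dfr(seq_len(B), function(i) {
        ms <- median(sample(fs, replace = TRUE))
        mn <- median(sample(fn, replace = TRUE))
        mp <- median(sample(fp, replace = TRUE))
        tibble(fap_fas = mp / ms, fan_fas = mn / ms, fap_fan = mp / mn)
      })
    })
    tibble(fap_fas = median(reps$fap_fas), fan_fas = median(reps$fan_fas),
           fap_fan = median(reps$fap_fan), method = method)
  }
}

#' Wind-speed factor implied by a force asymmetry
#'
#' Wind loads the seed through aerodynamic drag on the pappus, which scales
#' with the square of wind speed (`F ~ U^2`). A seed pushed in the negative
#' direction therefore needs a wind faster by `sqrt(Fan/Fap) = sqrt(1/fap_fan)`
#' than one pushed positively before it abscises.
#'
#' @param fap_fan Positive-to-negative abscission force ratio (> 0).
#' @return The dimensionless wind-speed factor.
#' @examples
#' wind_speed_factor(0.26 / 1.3)
#' @export
wind_speed_factor <- function(fap_fan) {
  if (any(!is.finite(fap_fan)) || any(fap_fan <= 0)) {
    abort("`fap_fan` must be positive.")
  }
  sqrt(1 / fap_fan)
}

#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis in one list: the
#' synthetic-generator bins, the morphology, the pull angles, the beta search
#' bounds, the sensitivity-sweep grids and the estimator choices. Can be
#' loaded from a YAML or JSON file via [read_pipeline_config()].
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param bins Bin specification table (see [force_bin_specs()]).
#' @param params A [morph_params()] object.
#' @param theta1,theta_pos,theta_neg Pull-scenario angles, degrees.
#' @param beta_bounds Search interval for [fit_beta()].
#' @param c_grid,r_grid Sweep grids, um.
#' @param ratio_method `"median"` or `"bootstrap"` (see
#'   [experimental_ratios()]).
#' @param eq_halfangle Use the half-angle variant of the full stress balance
#'   in reporting (see [force_ratio_full()]).
#' @param B Bootstrap replicates.
#' @param n_error_draws Morphology draws for error propagation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 0, bins = force_bin_specs(),
                            params = morph_params(),
                            theta1 = 90, theta_pos = 15, theta_neg = 35,
                            beta_bounds = c(1, 1000),
                            c_grid = seq(10, 40, by = 2),
                            r_grid = seq(10, 80, by = 5),
                            ratio_method = c("median", "bootstrap"),
                            eq_halfangle = FALSE, B = 1000,
                            n_error_draws = 200) {
  structure(
    list(seed = seed, bins = bins, params = params, theta1 = theta1,
         theta_pos = theta_pos, theta_neg = theta_neg,
         beta_bounds = beta_bounds, c_grid = c_grid, r_grid = r_grid,
         ratio_method = match.arg(ratio_method),
         eq_halfangle = isTRUE(eq_halfangle), B = B,
         n_error_draws = n_error_draws),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised top-level keys: `seed`, `morph` (flat mapping, see
#' [as_morph_params()]), `angles` (`theta1`, `theta_pos`, `theta_neg`),
#' `beta_bounds`, `ratio_method`, `eq32_halfangle`, `bins` (list of records
#' with `experiment`, `angle_bin`, `median_mN`, `q1_mN`, `q3_mN`, `n`).
#' Missing keys fall back to the defaults of [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$seed)) args$seed <- as.integer(raw$seed)
  if (!is.null(raw$morph)) args$params <- as_morph_params(raw$morph)
  if (!is.null(raw$angles)) {
    if (!is.null(raw$angles$theta1)) args$theta1 <- raw$angles$theta1
    if (!is.null(raw$angles$theta_pos)) args$theta_pos <- raw$angles$theta_pos
    if (!is.null(raw$angles$theta_neg)) args$theta_neg <- raw$angles$theta_neg
  }
  if (!is.null(raw$beta_bounds)) args$beta_bounds <- as.numeric(raw$beta_bounds)
  if (!is.null(raw$ratio_method)) args$ratio_method <- raw$ratio_method
  if (!is.null(raw$eq32_halfangle)) args$eq_halfangle <- raw$eq32_halfangle
  if (!is.null(raw$bins)) args$bins <- as_tibble(as.data.frame(raw$bins))
  do.call(pipeline_config, args)
}

pipeline_stage <- function(report, stage, quiet, expr) {
  if (!quiet) message(sprintf("[%s] running", stage))
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "abscissr_stage_error")
  })
}

#' Run the full abscission analysis
#'
#' Orchestrates the end-to-end analysis: simulate (or load) force
#' measurements; summarise each angle bin (median, IQR, bootstrap CI); run all
#' pairwise Wilcoxon comparisons; form the experimental force ratios from the
#' sideways medians; fit the stiffness ratio beta; sweep the geometry
#' parameters `c` and `r`; and derive the negative-to-positive force factor
#' and the implied wind-speed factor. Deterministic for a fixed
#' `config$seed`.
#'
#' If the input lacks the three sideways bins, the ratio, fit and derived
#' stages are skipped with an explicit notice recorded in the report.
#'
#' @param config A [pipeline_config()].
#' @param input `NULL` (simulate from `config$bins`), a path to a force CSV
#'   (see [read_forces_csv()]), or a force data frame.
#' @param out_dir Optional directory; when given, writes `summary.tsv`,
#'   `tests.tsv`, `sweep_c.tsv`, `sweep_r.tsv` and `report.json` there.
#' @param quiet Suppress stage messages.
#' @return A list of class `abscission_report`: `samples`, `summaries`,
#'   `tests`, `experimental`, `fit` (a `beta_fit` or `NULL`), `full_check`
#'   (full stress-balance ratios at the fitted beta, using the configured
#'   cosine variant), `errors`
#'   (propagated prediction half-widths), `sweeps` (list with `c` and `r`),
#'   `derived` (one-row tibble with `neg_pos_force_factor`,
#'   `wind_speed_factor`), `notes` (character), `config`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 1, B = 200, n_error_draws = 50))
#' rep$derived
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character()

  samples <- pipeline_stage(NULL, "simulate", quiet, {
    if (is.null(input)) {
      sample_forces(config$bins, seed = config$seed)
    } else if (is.character(input)) {
      read_forces_csv(input)
    } else {
      check_force_table(as_tibble(input))
    }
  })

  summaries <- pipeline_stage(NULL, "summarize", quiet,
    summarize_forces(samples, B = config$B, seed = config$seed)
  )

  tests <- pipeline_stage(NULL, "test", quiet,
    pairwise_direction_tests(samples)
  )

  side_bins <- c("0", "-90", "+90")
  have_sideways <- all(side_bins %in%
                         summaries$angle_bin[summaries$experiment == "sideways"])

  experimental <- NULL
  fit <- NULL
  full_check <- NULL
  errors <- NULL
  derived <- NULL
  if (have_sideways) {
    experimental <- pipeline_stage(NULL, "ratios", quiet, {
      if (config$ratio_method == "bootstrap") {
        experimental_ratios(samples, method = "bootstrap",
                            B = config$B, seed = config$seed)
      } else {
        experimental_ratios(summaries, method = "median")
      }
    })
    fit <- pipeline_stage(NULL, "fit", quiet,
      fit_beta(experimental, params = config$params,
               bounds = config$beta_bounds, theta1 = config$theta1,
               theta_pos = config$theta_pos, theta_neg = config$theta_neg)
    )
    full_check <- pipeline_stage(NULL, "model-check", quiet, {
      dplyr::bind_rows(
        force_ratio_full(config$params,
                         pull_scenario("positive", config$theta1,
                                       config$theta_pos),
                         beta = fit$beta_star,
                         halfangle = config$eq_halfangle),
        force_ratio_full(config$params,
                         pull_scenario("negative", config$theta1,
                                       config$theta_neg),
                         beta = fit$beta_star,
                         halfangle = config$eq_halfangle)
      )
    })
    errors <- pipeline_stage(NULL, "errors", quiet, {
      draws <- sample_morphology(config$n_error_draws, spread = "se",
                                 ell = config$params$ell,
                                 seed = config$seed + 1L)
      propagate_errors(draws, beta = fit$beta_star, theta1 = config$theta1,
                       theta_pos = config$theta_pos,
                       theta_neg = config$theta_neg)
    })
    derived <- pipeline_stage(NULL, "derived", quiet, {
      fap_fan <- experimental$fap_fan
      tibble(neg_pos_force_factor = 1 / fap_fan,
             wind_speed_factor = wind_speed_factor(fap_fan))
    })
  } else {
    notes <- c(notes,
               "sideways bins incomplete: ratio, fit and derived stages skipped")
    if (!quiet) message("[ratios/fit/derived] skipped: sideways bins incomplete")
  }

  sweeps <- pipeline_stage(NULL, "sweep", quiet, {
    beta_sweep <- if (!is.null(fit)) fit$beta_star else config$params$beta
    if (is.null(beta_sweep)) {
      notes <<- c(notes, "no beta available: sweeps skipped")
      NULL
    } else {
      list(
        c = sweep_parameter(config$params, "c", config$c_grid,
                            beta = beta_sweep, theta1 = config$theta1,
                            theta_pos = config$theta_pos,
                            theta_neg = config$theta_neg),
        r = sweep_parameter(config$params, "r", config$r_grid,
                            beta = beta_sweep, theta1 = config$theta1,
                            theta_pos = config$theta_pos,
                            theta_neg = config$theta_neg)
      )
    }
  })

  report <- structure(
    list(samples = samples, summaries = summaries, tests = tests,
         experimental = experimental, fit = fit, full_check = full_check,
         errors = errors, sweeps = sweeps, derived = derived, notes = notes,
         config = config),
    class = "abscission_report"
  )
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    if (!quiet) message(sprintf("[report] written to %s", out_dir))
  }
  report
}

#' @export
print.abscission_report <- function(x, ...) {
  cat("<abscission_report>\n")
  cat(sprintf("  %d measurements in %d bins\n",
              nrow(x$samples), nrow(x$summaries)))
  if (!is.null(x$fit)) {
    cat(sprintf("  beta* = %.4g; Fap/Fan (experimental) = %.3g\n",
                x$fit$beta_star, x$experimental$fap_fan))
  }
  if (!is.null(x$derived)) {
    cat(sprintf("  negative/positive force factor = %.3g; wind-speed factor = %.3g\n",
                x$derived$neg_pos_force_factor, x$derived$wind_speed_factor))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

report_json <- function(report) {
  fit <- report$fit
  list(
    summaries = report$summaries,
    tests = report$tests,
    experimental_ratios = report$experimental,
    fit = if (!is.null(fit)) {
      list(beta_star = fit$beta_star, objective = fit$objective,
           boundary = fit$boundary,
           predicted = list(ratio = fit$predicted[
             , c("fap_fas", "fan_fas", "fap_fan")]),
           full_stress_balance = report$full_check[
             , c("direction", "ratio", "y_max_um", "I_um4", "p_um", "valid")],
           errors = report$errors)
    },
    derived = report$derived,
    notes = report$notes,
    seed = report$config$seed
  )
}

#' Write pipeline artifacts to disk
#'
#' Writes the per-bin summary and pairwise-test tables as TSV, each sweep as
#' TSV (columns `param_value_um`, `fap_fan`, `valid`, plus the component
#' ratios), and the full report as JSON.
#'
#' @param report An `abscission_report` from [run_pipeline()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$summaries, file.path(out_dir, "summary.tsv"))
  readr::write_tsv(report$tests, file.path(out_dir, "tests.tsv"))
  if (!is.null(report$sweeps)) {
    readr::write_tsv(report$sweeps$c, file.path(out_dir, "sweep_c.tsv"))
    readr::write_tsv(report$sweeps$r, file.path(out_dir, "sweep_r.tsv"))
  }
  jsonlite::write_json(report_json(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(out_dir)
}
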