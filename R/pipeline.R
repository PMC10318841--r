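# One-call orchestration of the full analysis ---------------------------------

run_stage <- function(report, name, expr, strict) {
  res <- tryCatch(list(status = "ok", value = expr),
                  error = function(e) list(status = "failed",
                                           value = conditionMessage(e)))
  if (res$status == "failed" && strict) {
    abort(sprintf("stage `%s` failed: %s", name, res$value))
  }
  report$stages[[name]] <- res
  report
}

stage_value <- function(report, name) {
  s <- report$stages[[name]]
  if (is.null(s) || s$status != "ok") NULL else s$value
}

#' Run the full sampling-inequality and quality analysis
#'
#' Executes, in order: publication-trend statistics (yearly counts,
#' Mann-Kendall, exponential growth fit); sampling inequality (per-country
#' aggregation, Lorenz curve, Gini with Dagum decomposition over economic
#' blocs, Theil index, permutation test); methodological contrasts with
#' precision-weighted accuracies (LOOCV vs k-fold, independent vs internal
#' validation, cross- vs within-country validation); case-control skewness
#' prevalence and its correlation with accuracy; quality scoring with
#' quality-year and quality-accuracy correlations; and, when a covariate
#' table is supplied, GDP associations (GDP vs sampled population, GDP vs
#' within-unit inequality). Failed stages are recorded and skipped unless
#' `strict = TRUE`.
#'
#' @param evidence An evidence table, or a path passed to
#'   [read_evidence_table()].
#' @param units Optional grouped-sample tibble of per-unit totals; computed
#'   from the evidence table when `NULL`.
#' @param covariates Optional tibble with columns `unit` and `gdp` (and
#'   optionally `gini` for per-unit inequality).
#' @param seed Integer seed governing every stochastic stage.
#' @param B_perm Permutation replicates (default 10000).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param skew_threshold Case-control ratio above which a study counts as
#'   skewed (default 1.5).
#' @param rubric Quality rubric (default [default_rubric()]).
#' @param small_sample_n Threshold used for the small-sample share
#'   (default 200).
#' @param strict Abort on the first stage failure (default `FALSE`).
#' @return An object of class `run_report`: `config` (echo of arguments),
#'   `stages` (named list, each with `status` and `value`), and `warnings`.
#' @export
run_full_analysis <- function(evidence, units = NULL, covariates = NULL,
                              seed = 1, B_perm = 10000, n_boot = 1000,
                              skew_threshold = 1.5, rubric = default_rubric(),
                              small_sample_n = 200, strict = FALSE) {
  seed <- check_seed(seed)
  if (is.character(evidence)) evidence <- read_evidence_table(evidence)
  ev <- as_tibble(evidence)

  report <- structure(list(
    config = list(seed = seed, B_perm = B_perm, n_boot = n_boot,
                  skew_threshold = skew_threshold,
                  small_sample_n = small_sample_n,
                  n_studies = nrow(ev),
                  package_version = as.character(utils::packageVersion("metasample"))),
    stages = list(),
    warnings = character()
  ), class = "run_report")

  report <- run_stage(report, "trends", {
    counts <- ev |>
      dplyr::filter(!is.na(.data$year)) |>
      dplyr::count(.data$year, name = "k") |>
      tidyr::complete(year = tidyr::full_seq(.data$year, 1L),
                      fill = list(k = 0L))
    list(counts = counts,
         mann_kendall = mann_kendall(counts$k),
         growth = exp_growth_fit(counts$year, counts$k))
  }, strict)

  report <- run_stage(report, "inequality", {
    grouped <- if (!is.null(units)) as_tibble(units) else {
      aggregate_sample_by_unit(
        ev, unit_field = "sample_country",
        module_map = if ("economic_bloc" %in% names(ev)) "economic_bloc")
    }
    dec <- if (length(unique(grouped$module)) >= 2L) {
      dagum_decomposition(grouped)
    } else NULL
    per_module <- grouped |>
      dplyr::group_by(.data$module) |>
      dplyr::filter(dplyr::n() >= 2L) |>
      dplyr::summarise(n_units = dplyr::n(), gini = gini(.data$value),
                       .groups = "drop")
    list(grouped = grouped,
         gini = gini(grouped$value),
         theil = theil_index(grouped$value),
         lorenz = lorenz_curve(grouped$value),
         dagum = dec,
         per_module_gini = per_module,
         permutation = gini_permutation_test(grouped, B = B_perm, seed = seed))
  }, strict)

  contrast_spec <- list(
    loocv_vs_kfold = function(d) list(
      A = d[!is.na(d$cv_scheme) & d$cv_scheme == "LOOCV", ],
      B = d[!is.na(d$cv_scheme) & d$cv_scheme %in% c("kfold", "nested_kfold"), ]),
    independent_vs_internal = function(d) list(
      A = d[!is.na(d$external_validation) & d$external_validation != "none", ],
      B = d[!is.na(d$external_validation) & d$external_validation == "none", ]),
    cross_vs_within_country = function(d) list(
      A = d[!is.na(d$external_validation) & d$external_validation == "cross_country", ],
      B = d[!is.na(d$external_validation) & d$external_validation == "within_country", ])
  )
  report <- run_stage(report, "contrasts", {
    purrr::imap(contrast_spec, function(split_fn, nm) {
      g <- split_fn(ev)
      if (!nrow(g$A) || !nrow(g$B)) return(NULL)
      compare_groups(g$A, g$B, metric = "accuracy", seed = seed)
    })
  }, strict)

  report <- run_stage(report, "skewness", {
    ok <- !is.na(ev$n_patients) & !is.na(ev$n_controls) &
      ev$n_patients > 0 & ev$n_controls > 0
    ratio <- case_control_skewness(ev$n_patients[ok], ev$n_controls[ok])
    acc <- ev$accuracy[ok]
    corr <- if (sum(!is.na(acc)) >= 4 && sd(ratio[!is.na(acc)]) > 0) {
      spearman_bootstrap(ratio[!is.na(acc)], acc[!is.na(acc)],
                         n_boot = n_boot, seed = seed)
    } else NULL
    list(ratios = ratio,
         prevalence = mean(ratio > skew_threshold),
         n = sum(ok),
         n_skewed = sum(ratio > skew_threshold),
         skew_accuracy_correlation = corr)
  }, strict)

  report <- run_stage(report, "sample_size", {
    ok <- !is.na(ev$n_total)
    list(share_small = mean(ev$n_total[ok] < small_sample_n),
         n = sum(ok),
         year_correlation = if ("year" %in% names(ev)) {
           med <- ev |>
             dplyr::filter(!is.na(.data$year), !is.na(.data$n_total)) |>
             dplyr::group_by(.data$year) |>
             dplyr::summarise(n_med = median(.data$n_total), .groups = "drop")
           if (nrow(med) >= 4) {
             spearman_bootstrap(med$year, med$n_med, n_boot = n_boot, seed = seed)
           }
         })
  }, strict)

  report <- run_stage(report, "quality", {
    qs <- score_table(ev, rubric)
    year_corr <- if (!is.null(qs$by_year) && nrow(qs$by_year) >= 4) {
      spearman_bootstrap(qs$by_year$year, qs$by_year$mean_total,
                         n_boot = n_boot, seed = seed)
    }
    acc_ok <- !is.na(ev$accuracy)
    acc_corr <- if (sum(acc_ok) >= 4 && sd(qs$scores$total[acc_ok]) > 0) {
      spearman_bootstrap(qs$scores$total[acc_ok], ev$accuracy[acc_ok],
                         n_boot = n_boot, seed = seed)
    }
    list(summary = qs, quality_year_correlation = year_corr,
         quality_accuracy_correlation = acc_corr)
  }, strict)

  if (!is.null(covariates)) {
    report <- run_stage(report, "covariates", {
      cov <- as_tibble(covariates)
      stopifnot(all(c("unit", "gdp") %in% names(cov)))
      grouped <- stage_value(report, "inequality")$grouped
      joined <- dplyr::inner_join(grouped, cov, by = "unit")
      gdp_n <- if (nrow(joined) >= 4) {
        spearman_bootstrap(joined$gdp, joined$value, n_boot = n_boot, seed = seed)
      }
      gdp_gini <- if ("gini" %in% names(cov) && sum(!is.na(cov$gini)) >= 8) {
        dat <- cov[!is.na(cov$gini), ]
        spline_gam_fit(log(dat$gdp), dat$gini)
      }
      list(gdp_sample_correlation = gdp_n, gdp_gini_spline = gdp_gini)
    }, strict)
  } else {
    report$stages[["covariates"]] <- list(status = "skipped",
                                          value = "no covariates supplied")
  }

  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Analysis run over %d studies (seed %d)\n",
              x$config$n_studies, x$config$seed))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  }
  ineq <- stage_value(x, "inequality")
  if (!is.null(ineq)) {
    cat(sprintf("  sampling Gini = %.3f (permutation p = %.3g), Theil = %.3f\n",
                ineq$gini, ineq$permutation$p_value, ineq$theil))
  }
  invisible(x)
}

#' Write a run report to machine-readable files
#'
#' Writes `report.json` (every scalar result, seeds and replicate counts
#' echoed; percentages also rendered to two decimals) plus per-stage CSVs
#' (unit aggregation, Lorenz points, per-study quality scores).
#'
#' @param report A `run_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- report_json(report)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  ineq <- stage_value(report, "inequality")
  if (!is.null(ineq)) {
    readr::write_csv(ineq$grouped, file.path(dir, "unit_samples.csv"))
    readr::write_csv(as_tibble(ineq$lorenz), file.path(dir, "lorenz.csv"))
  }
  q <- stage_value(report, "quality")
  if (!is.null(q)) {
    readr::write_csv(q$summary$scores, file.path(dir, "quality_scores.csv"))
  }
  invisible(dir)
}

report_json <- function(report) {
  num <- function(x) if (is.null(x)) NULL else unname(x)
  corr_json <- function(cr) {
    if (is.null(cr)) return(NULL)
    list(rho = cr$rho, p_value = cr$p_value, ci95 = cr$ci95, n = cr$n,
         n_boot = cr$n_boot, seed = cr$seed, bf10 = num(cr$bf10))
  }
  comp_json <- function(cp) {
    if (is.null(cp)) return(NULL)
    list(W = cp$stat_W, p_value = cp$p_value, cohens_d = cp$cohens_d,
         weighted_mean_A = unname(cp$means["A"]),
         weighted_mean_B = unname(cp$means["B"]),
         weighted_mean_A_pct = round(100 * unname(cp$means["A"]), 2),
         weighted_mean_B_pct = round(100 * unname(cp$means["B"]), 2),
         bf10 = num(cp$bf10), n_A = unname(cp$n["A"]), n_B = unname(cp$n["B"]))
  }
  out <- list(schema_version = "1.0", config = report$config)

  tr <- stage_value(report, "trends")
  if (!is.null(tr)) {
    out$trends <- list(
      mann_kendall = list(S = tr$mann_kendall$S, Z = tr$mann_kendall$Z,
                          p_value = tr$mann_kendall$p_value,
                          trend = tr$mann_kendall$trend),
      growth = list(b = tr$growth$b, b_ci95 = tr$growth$b_ci95,
                    r2 = tr$growth$r2))
  }
  ineq <- stage_value(report, "inequality")
  if (!is.null(ineq)) {
    out$inequality <- list(
      gini = ineq$gini, theil = ineq$theil,
      permutation = list(p_value = ineq$permutation$p_value,
                         B = ineq$permutation$null_samples,
                         seed = ineq$permutation$seed,
                         null_model = ineq$permutation$null_model),
      dagum = if (!is.null(ineq$dagum)) {
        g <- ineq$dagum
        list(G_total = g$G_total, G_within = g$G_within,
             G_between_net = g$G_between_net,
             G_transvariation = g$G_transvariation)
      },
      per_module = if (nrow(ineq$per_module_gini)) {
        setNames(as.list(ineq$per_module_gini$gini),
                 ineq$per_module_gini$module)
      })
  }
  ct <- stage_value(report, "contrasts")
  if (!is.null(ct)) out$contrasts <- lapply(ct, comp_json)
  sk <- stage_value(report, "skewness")
  if (!is.null(sk)) {
    out$skewness <- list(prevalence = sk$prevalence,
                         prevalence_pct = round(100 * sk$prevalence, 2),
                         n = sk$n, n_skewed = sk$n_skewed,
                         accuracy_correlation = corr_json(sk$skew_accuracy_correlation))
  }
  ss <- stage_value(report, "sample_size")
  if (!is.null(ss)) {
    out$sample_size <- list(share_small = ss$share_small,
                            share_small_pct = round(100 * ss$share_small, 2),
                            year_correlation = corr_json(ss$year_correlation))
  }
  q <- stage_value(report, "quality")
  if (!is.null(q)) {
    out$quality <- list(
      mean_total = q$summary$mean_total, mean_stars = q$summary$mean_stars,
      low_quality_share = q$summary$low_quality_share,
      low_quality_share_pct = round(100 * q$summary$low_quality_share, 2),
      year_correlation = corr_json(q$quality_year_correlation),
      accuracy_correlation = corr_json(q$quality_accuracy_correlation))
  }
  cv <- stage_value(report, "covariates")
  if (!is.null(cv)) {
    out$covariates <- list(
      gdp_sample_correlation = corr_json(cv$gdp_sample_correlation),
      gdp_gini_spline = if (!is.null(cv$gdp_gini_spline)) {
        s <- cv$gdp_gini_spline
        list(beta = s$linear_beta, se = s$linear_se, t = s$t_value,
             r2_adj = s$r2_adj, edf = s$smooth_edf)
      })
  }
  out$stage_status <- lapply(report$stages, `[[`, "status")
  out
}
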