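# Synthetic evidence corpora with known effect structure ----------------------

#' Default synthetic country table
#'
#' A deterministic table of 40 synthetic countries whose GDPs follow a
#' log-normal quantile grid (heavy right tail, as national GDPs do) and whose
#' top economies form the MEDC bloc, the rest the LEDC bloc. Used as the
#' default unit universe of [corpus_config()]. All identifiers are synthetic.
#'
#' @param n_countries Number of countries (default 40).
#' @param medc Number of countries in the MEDC bloc (default: the top 37.5%
#'   of economies, i.e. 15 of 40).
#' @param meanlog,sdlog Log-normal GDP parameters (billion USD scale;
#'   defaults 6 and 1.5).
#' @return A tibble with columns `unit_id`, `gdp`, `bloc`.
#' @export
synthetic_country_units <- function(n_countries = 40,
                                    medc = ceiling(0.375 * n_countries),
                                    meanlog = 6, sdlog = 1.5) {
  gdp <- stats::qlnorm(stats::ppoints(n_countries), meanlog, sdlog)
  ord <- order(gdp, decreasing = TRUE)
  tibble(
    unit_id = sprintf("SC%02d", seq_len(n_countries)),
    gdp = gdp[ord],
    bloc = c(rep("MEDC", medc), rep("LEDC", n_countries - medc))
  )
}

#' Configuration of a synthetic evidence corpus
#'
#' Bundles and validates the parameters of [generate_corpus()]. The defaults
#' emulate the published landscape of neuroimaging-based psychiatric
#' classifiers: 476 studies over 1990-2021 with an exponential publication
#' ramp, country allocation concentrated on high-GDP countries (allocation
#' Gini around 0.8), about 40% LOOCV studies, about 16% external validation,
#' a quarter of studies case-control skewed, and additive accuracy inflation
#' for LOOCV (+0.04), missing external validation (+0.05) and within- versus
#' cross-country validation (+0.10) over a cross-country baseline of 0.73.
#'
#' @param n_studies Number of studies (default 476).
#' @param year_range Two-element integer vector (default `c(1990, 2021)`).
#' @param units Country table as from [synthetic_country_units()].
#' @param allocation_concentration Total Dirichlet concentration of the
#'   country-share draw; small values concentrate sampling on few countries
#'   (default 6).
#' @param gdp_gini_slope Exponent linking GDP to allocation weight
#'   (`weight = gdp^slope`); positive values direct sampling toward rich
#'   countries (default 1).
#' @param base_accuracy Accuracy of a cross-country-validated, non-LOOCV
#'   study before noise (default 0.73).
#' @param effect_loocv Additive accuracy inflation for LOOCV (default 0.04).
#' @param effect_no_external Inflation when no external validation is
#'   performed (default 0.05).
#' @param effect_within_vs_cross Inflation for within-country relative to
#'   cross-country external validation (default 0.10).
#' @param skew_prob Probability that a study is case-control imbalanced
#'   beyond `skew_threshold` (default 0.25).
#' @param skew_threshold Imbalance ratio above which a study counts as
#'   skewed (default 1.5).
#' @param noise_sd SD of the additive Gaussian accuracy noise (default 0.07).
#' @param year_ramp Exponential rate of the publication-year ramp
#'   (default 0.18 per year).
#' @param n_regions Admin-1 regions generated per country (default 8).
#' @param region_concentration Dirichlet concentration of the within-country
#'   sub-allocation (default 2).
#' @param seed Integer seed; every draw comes from this one generator.
#' @return A validated list of class `corpus_config`.
#' @export
corpus_config <- function(n_studies = 476,
                          year_range = c(1990L, 2021L),
                          units = synthetic_country_units(),
                          allocation_concentration = 6,
                          gdp_gini_slope = 1,
                          base_accuracy = 0.73,
                          effect_loocv = 0.04,
                          effect_no_external = 0.05,
                          effect_within_vs_cross = 0.10,
                          skew_prob = 0.25,
                          skew_threshold = 1.5,
                          noise_sd = 0.07,
                          year_ramp = 0.18,
                          n_regions = 8,
                          region_concentration = 2,
                          seed = 1) {
  cfg <- list(n_studies = as.integer(n_studies), year_range = as.integer(year_range),
              units = as_tibble(units),
              allocation_concentration = allocation_concentration,
              gdp_gini_slope = gdp_gini_slope, base_accuracy = base_accuracy,
              effect_loocv = effect_loocv, effect_no_external = effect_no_external,
              effect_within_vs_cross = effect_within_vs_cross,
              skew_prob = skew_prob, skew_threshold = skew_threshold,
              noise_sd = noise_sd, year_ramp = year_ramp,
              n_regions = as.integer(n_regions),
              region_concentration = region_concentration,
              seed = check_seed(seed))
  if (cfg$n_studies < 1L) abort("`n_studies` must be positive.")
  if (!all(c("unit_id", "gdp", "bloc") %in% names(cfg$units))) {
    abort("`units` must have columns unit_id, gdp, bloc.")
  }
  if (any(cfg$units$gdp <= 0)) abort("GDP values must be positive.")
  if (cfg$allocation_concentration <= 0) {
    abort("`allocation_concentration` must be positive.")
  }
  if (cfg$base_accuracy <= 0 || cfg$base_accuracy >= 1) {
    abort("`base_accuracy` must be in (0, 1).")
  }
  max_acc <- cfg$base_accuracy +
    max(0, cfg$effect_loocv) +
    max(0, cfg$effect_no_external, cfg$effect_within_vs_cross)
  if (max_acc >= 1) {
    abort("configured effects push accuracy out of (0, 1); lower the effects or base.")
  }
  if (cfg$skew_prob < 0 || cfg$skew_prob > 1) abort("`skew_prob` must be in [0, 1].")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  structure(cfg, class = "corpus_config")
}

#' Allocate a total sample across units with tunable concentration
#'
#' Draws unit shares from a Dirichlet distribution with parameter vector
#' `concentration * normalized(weights)` and scales them by `total_n`. Small
#' concentrations give highly concentrated (high-Gini) allocations;
#' `concentration = Inf` returns the deterministic weight-proportional
#' allocation.
#'
#' @param units Character vector of unit ids, or a units tibble with
#'   `unit_id` (and optionally `bloc` used as the module label).
#' @param total_n Total sample size to allocate.
#' @param concentration Positive total Dirichlet concentration (or `Inf`).
#' @param weights Optional positive per-unit weights (default equal).
#' @param seed Optional integer seed.
#' @return A grouped-sample tibble (`unit`, `value`, `module`).
#' @export
allocate_samples <- function(units, total_n, concentration, weights = NULL,
                             seed = NULL) {
  if (is.data.frame(units)) {
    ids <- units$unit_id %||% units$unit
    module <- units$bloc %||% units$module %||% rep("all", length(ids))
  } else {
    ids <- as.character(units)
    module <- rep("all", length(ids))
  }
  k <- length(ids)
  if (!k) abort("no units supplied.")
  if (concentration <= 0) abort("`concentration` must be positive.")
  weights <- weights %||% rep(1, k)
  if (length(weights) != k || any(weights <= 0)) {
    abort("`weights` must be positive, one per unit.")
  }
  w <- weights / sum(weights)
  draw <- function() {
    if (is.infinite(concentration)) return(w)
    g <- rgamma(k, shape = concentration * w)
    if (sum(g) == 0) g <- w # guard against underflow at tiny alpha
    g / sum(g)
  }
  shares <- if (is.null(seed)) draw() else with_seed(check_seed(seed), draw())
  tibble(unit = ids, value = shares * total_n, module = module)
}

# draws one categorical column from named probabilities
draw_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic evidence corpus
#'
#' Produces an evidence table (plus per-country and per-region sample tables)
#' with the statistical structure the downstream analyses assume, so that
#' parameter recovery can be verified end to end: country assignment follows
#' a GDP-weighted Dirichlet allocation, case-control skew occurs with a
#' configured prevalence, and accuracy is the configured base plus additive
#' effects of the CV scheme and validation design plus truncated Gaussian
#' noise. All draws come from one seeded generator in a fixed order.
#'
#' @param config A [corpus_config()].
#' @return A list of class `synthetic_corpus`: `evidence` (validated
#'   evidence table), `units` (achieved per-country totals with bloc labels),
#'   `regions` (per admin-1 totals within each country), `shares` (the drawn
#'   country share vector), `config`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

# All draws below consume one RNG stream in a fixed, documented order:
# country shares, region shares, then the per-study fields column by column.
generate_corpus_impl <- function(cfg) {
  n <- cfg$n_studies
  units <- cfg$units
  k <- nrow(units)

  # 1. country shares (GDP-weighted Dirichlet), then per-study assignment
  w <- units$gdp^cfg$gdp_gini_slope
  shares_tbl <- allocate_samples(units, 1, cfg$allocation_concentration,
                                 weights = w)
  shares <- shares_tbl$value
  country_idx <- sample.int(k, n, replace = TRUE, prob = shares)

  # 2. within-country region shares (two-level geography)
  region_shares <- matrix(rgamma(k * cfg$n_regions,
                                 shape = cfg$region_concentration / cfg$n_regions),
                          nrow = k)
  region_shares <- region_shares / rowSums(region_shares)
  region_idx <- vapply(country_idx, function(ci) {
    sample.int(cfg$n_regions, 1L, prob = region_shares[ci, ])
  }, 1L)

  # 3. study-level design fields
  years <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE,
                  prob = exp(cfg$year_ramp *
                               (seq(cfg$year_range[1], cfg$year_range[2]) -
                                  cfg$year_range[1])))
  disorder <- draw_cat(n, c(SZ = 0.246, ASD = 0.208, ADHD = 0.178, MDD = 0.12,
                            BP = 0.06, PTSD = 0.05, OCD = 0.05, other = 0.088))
  field <- draw_cat(n, c(computer_data_science = 0.464, neuroscience = 0.2,
                         psychiatry = 0.15, psychology = 0.12, other = 0.066))
  modality <- draw_cat(n, c(MRI_fMRI = 0.70, EEG_ERP = 0.21, fNIRS = 0.027,
                            MEG = 0.02, PET = 0.003, multimodal = 0.04))
  model_family <- draw_cat(n, c(shallow = 0.85, deep = 0.15))
  feat <- draw_cat(n, c(pre_engineered = 0.55, algorithmic = 0.31, none = 0.14))
  data_source <- draw_cat(n, c(self_collected = 0.66, open_dataset = 0.34))
  cv <- draw_cat(n, c(none = 0.12, LOOCV = 0.40, kfold = 0.38,
                      nested_kfold = 0.05, other = 0.05))
  external <- draw_cat(n, c(none = 0.8424, within_country = 0.10,
                            cross_country = 0.0576))

  # 4. sample sizes: log-normal, ~73% below 200 participants
  n_total <- pmax(20L, as.integer(round(stats::rlnorm(n, 4.75, 1.05))))

  # 5. case-control split with configured skew prevalence
  tau <- cfg$skew_threshold
  skewed <- runif(n) < cfg$skew_prob
  ratio <- ifelse(skewed,
                  tau * 1.1 + rexp(n, rate = 1.2),
                  1 + (tau * 0.93 - 1) * stats::rbeta(n, 2, 2))
  side <- sample(c(TRUE, FALSE), n, replace = TRUE)
  small <- pmax(5L, as.integer(round(n_total / (1 + ratio))))
  big <- n_total - small
  n_patients <- ifelse(side, big, small)
  n_controls <- n_total - n_patients

  # 6. accuracy: base + additive design effects + truncated Gaussian noise
  acc_mean <- cfg$base_accuracy +
    cfg$effect_loocv * (cv == "LOOCV") +
    cfg$effect_no_external * (external == "none") +
    cfg$effect_within_vs_cross * (external == "within_country")
  accuracy <- pmin(0.995, pmax(0.2, acc_mean + rnorm(n, 0, cfg$noise_sd)))

  # 7. reporting and availability flags
  rep_flags <- matrix(runif(4 * n) < 0.7, nrow = n)
  metric_names <- c("sensitivity", "specificity", "balanced_accuracy", "auc")
  reported_metrics <- apply(rep_flags, 1, function(z) {
    paste(metric_names[z], collapse = ";")
  })
  metric_value <- function(j) {
    ifelse(rep_flags[, j],
           pmin(0.995, pmax(0.2, accuracy + rnorm(n, 0, 0.03))), NA_real_)
  }
  sens <- metric_value(1); spec <- metric_value(2)
  bacc <- metric_value(3); auc <- metric_value(4)

  n_sites <- ifelse(runif(n) < 0.8, 1L, 1L + stats::rpois(n, 3))
  data_claimed <- runif(n) < 0.1912
  data_verified <- data_claimed & (runif(n) < 0.154)
  model_claimed <- runif(n) < 0.1225
  model_verified <- model_claimed & (runif(n) < 0.328)
  has_test <- external != "none" | runif(n) < 0.3
  n_test <- ifelse(has_test, pmax(5L, as.integer(round(0.2 * n_total))), NA_integer_)

  evidence <- tibble(
    study_id = sprintf("S%04d", seq_len(n)),
    year = years,
    disorder = disorder,
    first_author_field = field,
    sample_country = units$unit_id[country_idx],
    sample_region = sprintf("%s-R%d", units$unit_id[country_idx], region_idx),
    economic_bloc = units$bloc[country_idx],
    data_source = data_source,
    modality = modality,
    model_family = model_family,
    feature_selection = feat,
    cv_scheme = cv,
    external_validation = external,
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_total = as.integer(n_total),
    n_test = n_test,
    accuracy = accuracy,
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = bacc,
    auc = auc,
    reported_metrics = reported_metrics,
    n_sites = n_sites,
    data_claimed = data_claimed,
    data_verified = data_verified,
    model_claimed = model_claimed,
    model_verified = model_verified
  )
  evidence <- validate_evidence(evidence, strict = TRUE)

  unit_table <- aggregate_sample_by_unit(evidence, unit_field = "sample_country",
                                         module_map = "economic_bloc")
  region_table <- aggregate_sample_by_unit(evidence, unit_field = "sample_region")
  region_table$module <- sub("-R\\d+$", "", region_table$unit)

  structure(list(evidence = evidence, units = unit_table,
                 regions = region_table,
                 shares = tibble(unit = units$unit_id, share = shares,
                                 module = units$bloc),
                 config = cfg),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "Synthetic corpus: %d studies, %d sampled countries (seed %d)\n",
    nrow(x$evidence), nrow(x$units), x$config$seed))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Writes `evidence.csv`, `units.csv` and `regions.csv` in the dialect
#' [read_evidence_table()] accepts.
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_evidence_table(corpus$evidence, file.path(dir, "evidence.csv"))
  readr::write_csv(corpus$units, file.path(dir, "units.csv"))
  readr::write_csv(corpus$regions, file.path(dir, "regions.csv"))
  invisible(dir)
}
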