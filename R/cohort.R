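# Synthetic milk-intake cohort generator. Stands in for the confidential
# industrial intake data: it reproduces the statistical structure the
# downstream pipeline assumes (class-conditional shifts on the eight
# informative indicators, the Fat/TS correlation induced by the compositional
# identity TS = Fat + SNF + noise, uninformative nuisance indicators, three
# prevalence regimes, and raw-export messiness).

#' Indicator columns of a milk-intake record
#'
#' The fifteen routine physicochemical indicators, in their native intake
#' ordering, plus the leading binary ethanol-stability label `ES`
#' (1 = ethanol-unstable / positive, 0 = stable / negative).
#'
#' @return Character vector of the fifteen indicator names.
#' @export
milk_indicators <- function() {
  c("TVC", "Protein", "TS", "SNF", "Fat", "Acidity", "FP", "SCC", "Psychro",
    "Lactose", "RD", "MTemp", "Color", "AD1", "AD2")
}

#' @rdname milk_indicators
#' @export
milk_columns <- function() c("ES", milk_indicators())

#' The eight indicators used by the soft-sensing model
#'
#' Protein, total solids, solids-not-fat, fat, titratable acidity, lactose,
#' relative density and milk temperature: the indicators that carry signal
#' about ethanol stability. The remaining seven (microbial/cell counts,
#' freezing point, colour and the two contaminant flags) are generated as
#' class-independent noise.
#'
#' @return Character vector of length 8.
#' @export
informative_indicators <- function() {
  c("Protein", "TS", "SNF", "Fat", "Acidity", "Lactose", "RD", "MTemp")
}

#' Reference prevalence regimes
#'
#' Positive-class prevalences of the three evaluation regimes: the curated
#' base set (1 positive : 4 total), the cleaned intake cohort
#' (842 positives among 54,326 valid records) and full production intake
#' (842 positives among 907,595 records, about 0.09%).
#'
#' @return Named numeric vector with entries `curated`, `cleaned`,
#'   `production`.
#' @export
prevalence_regimes <- function() {
  c(curated = 842 / (842 + 3368),
    cleaned = 842 / 54326,
    production = 842 / 907595)
}

#' Describe one indicator for the synthetic generator
#'
#' @param name Indicator name (one of [milk_indicators()]).
#' @param mean_neg,mean_pos Class-conditional means in native units (for
#'   `dist = "lognormal"` these are log-scale location parameters; for
#'   `kind = "binary"` they are Bernoulli probabilities).
#' @param sd Standard deviation (log-scale for lognormal); must be positive
#'   for continuous indicators.
#' @param informative Logical; uninformative indicators must have
#'   `mean_neg == mean_pos`.
#' @param kind `"continuous"` or `"binary"`.
#' @param dist Sampling family for continuous indicators: `"normal"` or
#'   `"lognormal"` (right-skewed counts such as SCC/TVC).
#' @return A `feature_profile` list.
#' @export
feature_profile <- function(name, mean_neg, mean_pos = mean_neg, sd = 0,
                            informative = FALSE,
                            kind = c("continuous", "binary"),
                            dist = c("normal", "lognormal")) {
  kind <- match.arg(kind)
  dist <- match.arg(dist)
  if (kind == "continuous" && sd <= 0) {
    stopf("invalid profile for '%s': sd must be > 0", name)
  }
  if (kind == "binary" && (mean_neg < 0 || mean_neg > 1 || mean_pos < 0 || mean_pos > 1)) {
    stopf("invalid profile for '%s': binary probabilities must lie in [0, 1]", name)
  }
  if (!informative && !isTRUE(all.equal(mean_neg, mean_pos))) {
    stopf("invalid profile for '%s': uninformative features need mean_neg == mean_pos", name)
  }
  structure(list(name = name, mean_neg = mean_neg, mean_pos = mean_pos,
                 sd = sd, informative = informative, kind = kind, dist = dist),
            class = "feature_profile")
}

#' Default calibrated indicator profiles
#'
#' Plausible dairy ranges (g/100 g for composition, degrees Thorner for
#' acidity, degrees Celsius for temperatures) with the ethanol-unstable class
#' shifted on the eight informative indicators by `effect_size` standard
#' deviations. Shift directions follow dairy practice: unstable milk is
#' generated with lower protein, fat, solids, lactose and density and with
#' higher acidity and intake temperature. TS has no profile of its own: it is
#' produced structurally as `Fat + SNF + noise` (see [generate_cohort()]),
#' which is what gives the cohort its strong Fat/TS correlation.
#'
#' @param effect_size Planted standardized mean difference on the informative
#'   indicators (default 1.5 sd, giving clearly separable classes).
#' @return Named list of [feature_profile()] objects, one per indicator
#'   except TS.
#' @export
default_profiles <- function(effect_size = 1.5) {
  sh <- function(mu, sd, dir) feature_profile(NA_character_, mu, mu + dir * effect_size * sd, sd,
                                              informative = TRUE)
  p <- list(
    TVC = feature_profile("TVC", log(30), sd = 0.6, dist = "lognormal"),
    Protein = sh(3.25, 0.15, -1),
    SNF = sh(8.70, 0.18, -1),
    Fat = sh(3.90, 0.45, -1),
    Acidity = sh(13.5, 0.8, +1),
    FP = feature_profile("FP", -0.525, sd = 0.006),
    SCC = feature_profile("SCC", log(200), sd = 0.5, dist = "lognormal"),
    Psychro = feature_profile("Psychro", log(15), sd = 0.7, dist = "lognormal"),
    Lactose = sh(4.70, 0.15, -1),
    RD = sh(1.0300, 0.0015, -1),
    MTemp = sh(6.0, 1.5, +1),
    Color = feature_profile("Color", 80, sd = 5),
    AD1 = feature_profile("AD1", 0.02, kind = "binary"),
    AD2 = feature_profile("AD2", 0.02, kind = "binary")
  )
  for (nm in names(p)) p[[nm]]$name <- nm
  p
}

#' Specify a synthetic cohort
#'
#' @param n_records Number of records to generate.
#' @param prevalence Positive (ethanol-unstable) fraction in (0, 1); the
#'   positive count is exact by construction, `round(n_records * prevalence)`.
#' @param profiles Indicator profiles, as from [default_profiles()].
#' @param fat_ts_target_r Target Pearson correlation between Fat and TS
#'   (default 0.92). When `mass_balance_sd` is `NULL` the residual standard
#'   deviation of `TS - (Fat + SNF)` is solved analytically so the population
#'   correlation equals this target.
#' @param mass_balance_sd Standard deviation of the mass-balance residual, or
#'   `NULL` to derive it from `fat_ts_target_r`.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_records = 5000,
                        prevalence = prevalence_regimes()[["cleaned"]],
                        profiles = default_profiles(),
                        fat_ts_target_r = 0.92,
                        mass_balance_sd = NULL,
                        seed = 1L) {
  if (!is_count(n_records)) stopf("invalid cohort spec: n_records must be a positive integer")
  if (!is.numeric(prevalence) || length(prevalence) != 1L || prevalence <= 0 || prevalence >= 1) {
    stopf("invalid cohort spec: prevalence must lie in (0, 1)")
  }
  if (round(n_records * prevalence) < 1) {
    stopf("invalid cohort spec: prevalence too small, round(n_records * prevalence) must be >= 1")
  }
  if (!is.numeric(fat_ts_target_r) || abs(fat_ts_target_r) >= 1) {
    stopf("invalid cohort spec: fat_ts_target_r must lie in (-1, 1)")
  }
  need <- setdiff(milk_indicators(), c("TS", names(profiles)))
  if (length(need)) stopf("invalid cohort spec: profiles missing for %s", paste(need, collapse = ", "))
  if (is.null(mass_balance_sd)) {
    v <- (profiles$Fat$sd / fat_ts_target_r)^2 - profiles$Fat$sd^2 - profiles$SNF$sd^2
    if (v <= 0) {
      stopf("invalid cohort spec: fat_ts_target_r = %.3f is unattainable with sd(Fat) = %.3f, sd(SNF) = %.3f",
            fat_ts_target_r, profiles$Fat$sd, profiles$SNF$sd)
    }
    mass_balance_sd <- sqrt(v)
  }
  if (mass_balance_sd < 0) stopf("invalid cohort spec: mass_balance_sd must be >= 0")
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 profiles = profiles, fat_ts_target_r = fat_ts_target_r,
                 mass_balance_sd = mass_balance_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic milk-intake cohort
#'
#' Draws `spec$n_records` records with exactly
#' `round(n_records * prevalence)` positives. Continuous indicators come from
#' class-conditional Gaussians (lognormals for the skewed microbial counts),
#' the contaminant flags from Bernoulli draws, and total solids from the
#' structural equation `TS = Fat + SNF + Normal(0, mass_balance_sd)`, so the
#' compositional identity holds in expectation and the Fat/TS correlation
#' emerges from one mechanism. Output is a clean numeric table with the label
#' first; byte-identical across calls with the same spec.
#'
#' @param spec A [cohort_spec()].
#' @return A `clean_table` data frame (`ES` first, then the indicators).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_records
  n_pos <- round(n * spec$prevalence)
  with_seed(spec$seed, {
    label <- integer(n)
    label[sample.int(n, n_pos)] <- 1L
    out <- list(ES = label)
    for (nm in setdiff(milk_indicators(), "TS")) {
      pr <- spec$profiles[[nm]]
      mu <- ifelse(label == 1L, pr$mean_pos, pr$mean_neg)
      out[[nm]] <- switch(paste(pr$kind, pr$dist, sep = "."),
        continuous.normal = stats::rnorm(n, mu, pr$sd),
        continuous.lognormal = stats::rlnorm(n, mu, pr$sd),
        binary.normal = ,
        binary.lognormal = as.numeric(stats::rbinom(n, 1L, mu))
      )
    }
    out$TS <- out$Fat + out$SNF + stats::rnorm(n, 0, spec$mass_balance_sd)
    df <- as.data.frame(out)[, milk_columns()]
    class(df) <- c("clean_table", "data.frame")
    df
  })
}

#' Specify raw-export messiness
#'
#' @param null_rate Fraction of indicator cells set missing.
#' @param junk_rate Fraction of the remaining numeric cells replaced by
#'   non-numeric strings (instrument error codes and the like).
#' @param label_as_text Encode the label (and the contaminant flags) as
#'   `"positive"`/`"negative"` strings, as raw intake exports do.
#' @return A `messiness_spec` list.
#' @export
messiness_spec <- function(null_rate = 0, junk_rate = 0, label_as_text = FALSE) {
  assert_prob(null_rate, "null_rate")
  assert_prob(junk_rate, "junk_rate")
  if (!is_flag(label_as_text)) stopf("`label_as_text` must be TRUE or FALSE")
  structure(list(null_rate = null_rate, junk_rate = junk_rate,
                 label_as_text = label_as_text), class = "messiness_spec")
}

junk_tokens <- c("n/a", "err", "<LOD", "--", "pending", "not tested")

#' Degrade a clean cohort into a raw intake export
#'
#' Randomly blanks indicator cells, replaces others with non-numeric junk
#' strings, and optionally re-encodes the binary columns as
#' `"positive"`/`"negative"` text, producing the kind of raw file
#' [clean_table()] is designed to repair. With all rates zero and
#' `label_as_text = FALSE` the input is returned unchanged.
#'
#' @param table A clean numeric table (label first).
#' @param mess A [messiness_spec()].
#' @param seed Integer seed.
#' @return A data frame, with character columns wherever text was injected.
#' @export
inject_messiness <- function(table, mess = messiness_spec(), seed = 1L) {
  if (!inherits(mess, "messiness_spec")) mess <- do.call(messiness_spec, mess)
  if (mess$null_rate == 0 && mess$junk_rate == 0 && !mess$label_as_text) {
    return(table)
  }
  df <- as.data.frame(table)
  ind_cols <- setdiff(names(df), "ES")
  with_seed(seed, {
    for (cl in ind_cols) {
      v <- df[[cl]]
      nul <- stats::runif(length(v)) < mess$null_rate
      jnk <- !nul & stats::runif(length(v)) < mess$junk_rate
      if (any(jnk)) {
        v <- as.character(v)
        v[jnk] <- sample(junk_tokens, sum(jnk), replace = TRUE)
      }
      v[nul] <- NA
      df[[cl]] <- v
    }
    if (mess$label_as_text) {
      for (cl in intersect(c("ES", "AD1", "AD2"), names(df))) {
        if (is.numeric(df[[cl]])) {
          df[[cl]] <- ifelse(df[[cl]] == 1, "positive", "negative")
        } else {
          v <- df[[cl]]
          v[v == "1"] <- "positive"
          v[v == "0"] <- "negative"
          df[[cl]] <- v
        }
      }
    }
  })
  class(df) <- "data.frame"
  df
}
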