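# ---- default generating configuration -------------------------------------

#' Default study-scale twin cohort configuration
#'
#' A five-phenotype generating model at the scale of a large community twin
#' register: a parent-rated autistic-trait scale (`CAST`, count-like and
#' positively skewed, selected on its high tail) and four receptive language
#' test scores (`FL`, `Pragmatics`, `Syntax`, `Vocabulary`, roughly normal,
#' selected on their low tails, with partial missingness). Group sizes are
#' 1113 / 1102 / 1293 / 1188 same-sex pairs (MZM / DZM / MZF / DZF).
#' Standardized ACE proportions differ quantitatively by sex (trait scale:
#' males a2 = 0.73, c2 = 0.04; females 0.52 / 0.25; language measures a2
#' 0.18-0.39, c2 0.12-0.21) and the additive genetic correlation between the
#' trait scale and the language measures is mildly negative (-0.13), the
#' shared-environmental correlation more strongly so, while language
#' measures correlate positively with each other.
#'
#' @param seed master seed
#' @param n_pairs per-cell pair counts (named, default study scale)
#' @param missing_language per-score missingness probability of the language
#'   tests (default 0.27)
#' @return a [twin_sim_config()] object
#' @export
teds_like_config <- function(seed = 1L,
                             n_pairs = c(MZM = 1113, DZM = 1102,
                                         MZF = 1293, DZF = 1188),
                             missing_language = 0.27) {
  phen <- c("CAST", "FL", "Pragmatics", "Syntax", "Vocabulary")
  # cross-trait correlation structure shared by both sexes
  blk <- function(cast_lang, lang_lang) {
    m <- matrix(lang_lang, 5, 5)
    m[1, ] <- m[, 1] <- cast_lang
    diag(m) <- 1
    m
  }
  rA <- blk(-0.13, 0.55)
  rC <- blk(-0.60, 0.55)
  rE <- blk(-0.05, 0.15)
  mk <- function(a2, c2) {
    e2 <- 1 - a2 - c2
    paths_from_components(a2 = a2, c2 = c2, e2 = e2, rA = rA, rC = rC, rE = rE)
  }
  paths <- list(
    male = mk(a2 = c(0.73, 0.39, 0.18, 0.25, 0.27),
              c2 = c(0.04, 0.12, 0.15, 0.18, 0.19)),
    female = mk(a2 = c(0.52, 0.39, 0.25, 0.22, 0.33),
                c2 = c(0.25, 0.12, 0.12, 0.21, 0.12))
  )
  twin_sim_config(
    n_pairs = n_pairs, paths = paths, phenotypes = phen,
    skew = list(CAST = list(type = "exp", scale = 0.6)),
    missing_rate = stats::setNames(rep(missing_language, 4), phen[-1]),
    age_range = c(11.5, 12.5),
    age_effects = c(FL = 0.10, Pragmatics = 0.10, Syntax = 0.10,
                    Vocabulary = 0.10),
    sex_effects = c(CAST = 0.15, FL = -0.05, Vocabulary = -0.05),
    seed = seed
  )
}

#' Default phenotype preparation specs for [teds_like_config()] data
#' @return named list of [phenotype_spec()] objects
#' @export
teds_like_specs <- function() {
  list(
    phenotype_spec("CAST", log_transform = TRUE, log_offset = 1,
                   extreme_tail = "high"),
    phenotype_spec("FL", extreme_tail = "low"),
    phenotype_spec("Pragmatics", extreme_tail = "low"),
    phenotype_spec("Syntax", extreme_tail = "low"),
    phenotype_spec("Vocabulary", extreme_tail = "low")
  )
}

# ---- descriptive summary ---------------------------------------------------

#' Descriptive statistics table
#'
#' Per phenotype: n (non-missing individual scores), mean, SD and skew of
#' the raw scale; skew after preparation; and mean/SD of the extreme-scoring
#' group at each proportion (taken in the phenotype's declared tail of the
#' raw distribution).
#'
#' @param raw_records raw twin-pair data frame
#' @param prepared_records the same records after [preprocess_twins()]
#' @param specs list of [phenotype_spec()] objects
#' @param proportions extreme-group proportions
#' @return a data frame, one row per phenotype
#' @export
summarize_descriptives <- function(raw_records, prepared_records, specs,
                                   proportions = c(0.05, 0.025)) {
  long_raw <- stack_twins(raw_records)
  long_prep <- stack_twins(prepared_records)
  rows <- lapply(specs, function(sp) {
    x <- long_raw[[sp$name]]
    xp <- long_prep[[sp$name]]
    x <- x[!is.na(x)]
    row <- data.frame(phenotype = sp$name, n = length(x), mean = mean(x),
                      sd = stats::sd(x), skew_raw = sample_skew(x),
                      skew_prepared = sample_skew(xp))
    for (p in proportions) {
      q <- if (sp$extreme_tail == "high") x[x >= stats::quantile(x, 1 - p)]
           else x[x <= stats::quantile(x, p)]
      row[[sprintf("mean_extreme_%g", 100 * p)]] <- mean(q)
      row[[sprintf("sd_extreme_%g", 100 * p)]] <- stats::sd(q)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Run the full twin-analysis pipeline
#'
#' Simulates (or loads) a twin cohort, prepares the phenotypes, computes the
#' descriptive and twin-correlation tables, fits the requested Cholesky
#' models with saturated comparisons and standardized solutions, and runs
#' the DF extremes analyses, writing every table as CSV plus a run log.
#'
#' @param config list with elements:
#'   `input` (a twin-pair data frame, a CSV path, or a [twin_sim_config()]),
#'   `specs` (list of [phenotype_spec()]; default [teds_like_specs()]),
#'   `models` (character vector of component sets, default
#'   `c("ACE", "AE", "CE", "E")`),
#'   `sex_limitation` (settings to fit, default both),
#'   `extremes_proportions` (default `c(0.05, 0.025)`),
#'   `extremes_pairs` (list of `c(x, y)` phenotype pairs; default the trait
#'   scale against every language measure),
#'   `phenotypes` (subset to model; default all prepared),
#'   `n_restarts` (optimizer starts per model, default 3),
#'   `seed` (master seed, default 1)
#' @param output_dir directory for the output tables
#' @return invisibly, a list with every table and fit
#' @export
run_twin_pipeline <- function(config = list(), output_dir = tempfile("twinrun")) {
  seed <- if (is.null(config$seed)) 1L else config$seed
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(output_dir, "run_log.txt")
  logger <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  cat("twinpath pipeline run\n", file = logf)
  logger("R version: %s", R.version.string)
  logger("master seed: %d", seed)

  input <- config$input
  if (is.null(input)) input <- teds_like_config(seed = substream_seed(seed, "simulate"))
  if (inherits(input, "twin_sim_config")) {
    logger("stage simulate: %s pairs", paste(input$n_pairs, collapse = "/"))
    records <- simulate_twins(input)
  } else if (is.character(input)) {
    logger("stage load: %s", input)
    records <- read_twin_data(input)
  } else records <- input
  write_twin_data(records, file.path(output_dir, "raw_data.csv"))

  specs <- if (is.null(config$specs)) teds_like_specs() else config$specs
  names(specs) <- vapply(specs, `[[`, "", "name")
  prepared <- preprocess_twins(records, specs)
  writeLines(attr(prepared, "transform_log"),
             file.path(output_dir, "transforms_log.txt"))
  logger("stage preprocess: %d pairs, transforms logged", nrow(prepared))

  props <- if (is.null(config$extremes_proportions)) c(0.05, 0.025)
           else config$extremes_proportions
  desc <- summarize_descriptives(records, prepared, specs, props)
  utils::write.csv(desc, file.path(output_dir, "descriptives.csv"),
                   row.names = FALSE)

  phen <- if (is.null(config$phenotypes)) names(specs) else config$phenotypes
  cors <- twin_correlation_table(prepared, phen)
  utils::write.csv(cors, file.path(output_dir, "twin_correlations.csv"),
                   row.names = FALSE)
  logger("stage descriptives: %d correlation cells", nrow(cors))

  models <- if (is.null(config$models)) c("ACE", "AE", "CE", "E") else config$models
  sexlims <- if (is.null(config$sex_limitation)) c("equated", "quantitative")
             else config$sex_limitation
  n_restarts <- if (is.null(config$n_restarts)) 3 else config$n_restarts
  fit_rows <- list(); fits <- list()
  for (sl in sexlims) {
    sat <- fit_saturated(prepared, phen,
                         sex_limitation = if (sl == "equated") "equated" else "quantitative")
    fits[[paste0("saturated_", sl)]] <- sat
    fit_rows[[length(fit_rows) + 1L]] <- data.frame(
      sex_limitation = sl, model = "saturated", minus2LL = sat$minus2LL,
      df = sat$df, parameters = sat$n_parameters, delta_chi2 = NA, delta_df = NA,
      p_value = NA, AIC = NA)
    for (m in models) {
      comp <- strsplit(m, "")[[1]]
      fit <- twin_cholesky(prepared, phen, components = comp,
                           sex_limitation = sl, n_restarts = n_restarts,
                           seed = substream_seed(seed, paste0("fit", m, sl)))
      fits[[paste0(m, "_", sl)]] <- fit
      cmp <- likelihood_ratio_test(fit, sat)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        sex_limitation = sl, model = m, minus2LL = fit$minus2LL, df = fit$df,
        parameters = fit$n_parameters, delta_chi2 = cmp$delta_chi2,
        delta_df = cmp$delta_df, p_value = cmp$p_value, AIC = cmp$AIC)
      logger("stage fit: %s (%s) -2LL=%.2f", m, sl, fit$minus2LL)
    }
  }
  fit_table <- do.call(rbind, fit_rows)
  utils::write.csv(fit_table, file.path(output_dir, "fit_table.csv"),
                   row.names = FALSE)

  # standardized solution of the best-AIC full model
  full_rows <- fit_table[!is.na(fit_table$AIC) & fit_table$model %in%
                           c("ACE", "ADE"), , drop = FALSE]
  sol_table <- NULL; best <- NULL
  if (nrow(full_rows)) {
    b <- full_rows[which.min(full_rows$AIC), ]
    best <- fits[[paste0(b$model, "_", b$sex_limitation)]]
    sol <- correlated_factors(best)
    sexes <- if (best$spec$sex_limitation == "quantitative") c("male", "female")
             else "male"
    sol_rows <- list()
    for (s in sexes) {
      pr <- sol[[s]]$proportions
      for (ph in rownames(pr))
        sol_rows[[length(sol_rows) + 1L]] <- data.frame(
          sex = s, phenotype = ph, t(pr[ph, , drop = TRUE]))
    }
    sol_table <- do.call(rbind, sol_rows)
    utils::write.csv(sol_table, file.path(output_dir, "solution_table.csv"),
                     row.names = FALSE)
    logger("stage standardize: best full model %s (%s)", b$model,
           b$sex_limitation)
  }

  pairs <- config$extremes_pairs
  if (is.null(pairs)) {
    tails <- vapply(specs, `[[`, "", "extreme_tail")
    hi <- names(tails)[tails == "high"]
    lo <- names(tails)[tails == "low"]
    if (length(hi) && length(lo))
      pairs <- lapply(lo[lo %in% phen], function(y) c(hi[1], y))
  }
  df_rows <- list(); df_fits <- list()
  for (p in props) for (pr in pairs) {
    res <- df_extremes(prepared, specs[[pr[1]]], specs[[pr[2]]], proportion = p)
    df_fits[[sprintf("%s_%s_%g", pr[1], pr[2], p)]] <- res
    df_rows[[length(df_rows) + 1L]] <- data.frame(
      proportion = p, x = pr[1], y = pr[2],
      h2g_x = res$uni_x$capped_estimate, h2g_y = res$uni_y$capped_estimate,
      h2xy = res$biv_xy$capped_estimate, h2yx = res$biv_yx$capped_estimate,
      mu_MZ_x = res$uni_x$cotwin_means[["mu_MZ"]],
      mu_DZ_x = res$uni_x$cotwin_means[["mu_DZ"]],
      group_cor_xy = res$group_cor_xy, group_cor_yx = res$group_cor_yx,
      ratio_xy = res$biv_xy$capped_estimate / res$group_cor_xy,
      extremes_rg = res$r_g$r_g)
    logger("stage extremes: %s-%s at %g%%, rg=%.3f", pr[1], pr[2], 100 * p,
           res$r_g$r_g)
  }
  df_table <- if (length(df_rows)) do.call(rbind, df_rows) else NULL
  if (!is.null(df_table))
    utils::write.csv(df_table, file.path(output_dir, "df_extremes.csv"),
                     row.names = FALSE)
  logger("pipeline complete")
  invisible(list(records = records, prepared = prepared, descriptives = desc,
                 correlations = cors, fit_table = fit_table, fits = fits,
                 solution_table = sol_table, best_full = best,
                 df_table = df_table, df_fits = df_fits,
                 output_dir = output_dir))
}
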