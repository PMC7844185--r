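# Orchestration: simulate -> score -> search -> transfer -> fit, with a
# hashed run manifest and a plain-text report renderer.

#' Pipeline configuration
#'
#' @param countries named list: country -> [generator_config()] (to simulate)
#'   or a path to a cohort CSV (to load).
#' @param cv a [cv_config()].
#' @param out_dir output directory for all artifacts.
#' @param top_k rows of the ranked model table to report.
#' @param moderator,focal_terms moderation analysis settings.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(countries, cv = cv_config(), out_dir,
                            top_k = 3L, moderator = "resilience",
                            focal_terms = c("life_stress", "work_stress")) {
  for (cc in names(countries)) {
    x <- countries[[cc]]
    if (is.character(x) && !file.exists(x))
      stop_invalid("cohort path does not exist: ", x)
    if (!is.character(x) && !inherits(x, "generator_config"))
      stop_invalid("country entry must be a generator_config or a CSV path: ",
                   cc)
  }
  structure(list(countries = countries, cv = cv, out_dir = out_dir,
                 top_k = as.integer(top_k), moderator = moderator,
                 focal_terms = focal_terms),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, per country: cohort simulation (or load), inclusion filter,
#' scoring, the exhaustive cross-validated model search, then cross-country
#' transfer validation of the winning models, robust standardized refits
#' with the zero-filled coefficient export, the descriptive country
#' comparison, and the moderation analysis. Every artifact is written under
#' `out_dir` and md5-hashed into a JSON run manifest; an identical
#' configuration reproduces identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param catalog a [factor_catalog()] (defaults to the full 15-factor
#'   catalog).
#' @return the manifest (invisibly), a list with per-stage artifact paths and
#'   hashes.
#' @export
run_pipeline <- function(config, catalog = factor_catalog()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  stage <- "simulate"
  res <- tryCatch({
    cohorts <- list()
    for (cc in names(config$countries)) {
      x <- config$countries[[cc]]
      cohort <- if (is.character(x)) read_cohort(x) else generate_cohort(x)
      cohort <- apply_inclusion_filter(cohort)
      p <- file.path(config$out_dir, sprintf("cohort_%s.csv", cc))
      write_cohort(cohort, p); artifacts <- c(artifacts, p)
      cohorts[[cc]] <- cohort
    }

    stage <- "score"
    scored <- lapply(cohorts, score_cohort)
    for (cc in names(scored)) {
      p <- file.path(config$out_dir, sprintf("scores_%s.csv", cc))
      write.csv(scored[[cc]][, c("respondent_id", names(scale_catalog()))],
                p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }

    stage <- "search"
    searches <- list(); best <- list()
    for (cc in names(scored)) {
      sr <- run_search(scored[[cc]], catalog, config$cv)
      searches[[cc]] <- sr
      best[[cc]] <- best_model(sr)
      d <- file.path(config$out_dir, sprintf("search_%s", cc))
      artifacts <- c(artifacts, write_search_result(sr, d))
      p <- file.path(config$out_dir, sprintf("top_models_%s.csv", cc))
      write.csv(top_models_table(sr, config$top_k), p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }

    stage <- "transfer"
    tr <- cross_fit(best, scored, catalog, config$cv)
    p <- file.path(config$out_dir, "transfer_long.csv")
    write.csv(as.data.frame(tr), p, row.names = FALSE)
    artifacts <- c(artifacts, p)
    ts <- summarize_transfer(tr)
    p <- file.path(config$out_dir, "transfer_summary.csv")
    write.csv(ts$summary, p, row.names = FALSE)
    artifacts <- c(artifacts, p)

    stage <- "fit"
    coefs <- list()
    for (cc in names(scored)) {
      fit <- fit_winning_model(scored[[cc]], catalog, best[[cc]])
      tab <- as.data.frame(fit)
      tab$adj_r_squared <- attr(fit, "adj_r_squared")
      p <- file.path(config$out_dir, sprintf("fit_%s.csv", cc))
      write.csv(tab, p, row.names = FALSE)
      artifacts <- c(artifacts, p)
      coefs[[cc]] <- coefficient_export(fit, catalog, cc)
      mod_f <- intersect(config$focal_terms, best[[cc]])
      if (config$moderator %in% best[[cc]] && length(mod_f)) {
        mod <- moderation_analysis(scored[[cc]], catalog, best[[cc]],
                                   config$moderator, mod_f)
        p <- file.path(config$out_dir, sprintf("moderation_%s.csv", cc))
        write.csv(mod$simple_slopes, p, row.names = FALSE)
        artifacts <- c(artifacts, p)
      }
    }
    p <- file.path(config$out_dir, "coefficients_long.csv")
    write.csv(do.call(rbind, c(coefs, list(make.row.names = FALSE))), p,
              row.names = FALSE)
    artifacts <- c(artifacts, p)

    stage <- "descriptives"
    p <- file.path(config$out_dir, "descriptives.csv")
    write.csv(group_comparison_table(scored), p, row.names = FALSE)
    artifacts <- c(artifacts, p)
    list(best = best)
  }, error = function(e) {
    stop_invalid(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)))
  })

  manifest <- list(
    schema_version = "1.0",
    created = "run",
    cv = unclass(config$cv),
    countries = lapply(config$countries, function(x)
      if (is.character(x)) list(path = x) else
        list(label = x$country_label, n = x$n, seed = x$seed)),
    best_models = res$best,
    artifacts = lapply(setNames(nm = artifacts), function(p)
      unname(tools::md5sum(p)))
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Render a plain-text report from pipeline artifacts
#'
#' Assembles the descriptives table, per-country top models, the transfer
#' RMSE summary and the coefficient display into one markdown document.
#' Missing artifacts are listed as absent; the report renders regardless.
#'
#' @param dir pipeline output directory.
#' @param path report destination (default `report.md` in `dir`).
#' @return list with `path`, `sections` (present) and `missing` (absent
#'   section names), and `status` (0 if any section rendered, 1 otherwise).
#' @export
render_report <- function(dir, path = file.path(dir, "report.md")) {
  sections <- list(
    descriptives = "descriptives.csv",
    top_models = "top_models_.*\\.csv",
    transfer = "transfer_summary.csv",
    coefficients = "coefficients_long.csv"
  )
  lines <- c("# Cross-validated maternal mental health model selection", "")
  present <- character(); missing <- character()
  fmt <- function(df) c(paste(names(df), collapse = " | "),
                        apply(df, 1, function(r) paste(r, collapse = " | ")))
  for (s in names(sections)) {
    files <- list.files(dir, pattern = paste0("^", sections[[s]], "$"),
                        full.names = TRUE)
    lines <- c(lines, paste("##", gsub("_", " ", s)), "")
    if (!length(files)) {
      lines <- c(lines, "*absent*", "")
      missing <- c(missing, s)
      next
    }
    present <- c(present, s)
    for (f in files) {
      df <- read.csv(f, check.names = FALSE)
      lines <- c(lines, paste0("### ", basename(f)), "",
                 fmt(utils::head(df, 20L)), "")
    }
  }
  writeLines(lines, path)
  list(path = path, sections = present, missing = missing,
       status = as.integer(length(present) == 0L))
}
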