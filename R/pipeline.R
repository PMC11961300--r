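## Pipeline orchestration: landmark -> traits -> descriptives -> reliability
## -> twin models, driven by a config list or YAML file. Every output table
## is CSV with a JSON metadata sidecar; all randomness flows from one seed.

#' Validate pipeline input files
#'
#' Schema checks for the landmark and twin trait CSVs: required columns,
#' controlled vocabularies (stage, arch, landmark names), duplicate rows and
#' MZ sex concordance. Messages carry data row numbers (excluding the
#' header).
#'
#' @param paths Named list with optional elements `landmark_csv` and
#'   `twin_csv`.
#' @return Character vector of issues (empty when everything checks out).
#' @export
validate_inputs <- function(paths) {
  issues <- character(0)
  add <- function(...) issues <<- c(issues, sprintf(...))
  if (!is.null(paths$landmark_csv)) {
    p <- paths$landmark_csv
    if (!file.exists(p)) {
      add("landmark_csv: file not found: %s", p)
    } else {
      df <- read.csv(p, stringsAsFactors = FALSE)
      need <- c("subject_id", "stage", "arch", "landmark", "x", "y", "z")
      miss <- setdiff(need, names(df))
      if (length(miss)) {
        add("landmark_csv: missing column(s): %s", paste(miss, collapse = ", "))
      } else {
        bad <- which(!df$stage %in% .STAGES)
        for (i in bad) add("landmark_csv row %d: unknown stage '%s'", i, df$stage[i])
        bad <- which(!df$arch %in% .ARCHES)
        for (i in bad) add("landmark_csv row %d: unknown arch '%s'", i, df$arch[i])
        bad <- which(!df$landmark %in% landmark_vocabulary())
        for (i in bad) add("landmark_csv row %d: unknown landmark '%s'", i, df$landmark[i])
        bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
        for (i in bad) add("landmark_csv row %d: non-finite coordinate", i)
        key <- paste(df$subject_id, df$stage, df$arch, df$landmark)
        dup <- which(duplicated(key))
        for (i in dup) add("landmark_csv row %d: duplicate landmark row (%s)", i, key[i])
      }
    }
  }
  if (!is.null(paths$twin_csv)) {
    p <- paths$twin_csv
    if (!file.exists(p)) {
      add("twin_csv: file not found: %s", p)
    } else {
      df <- .fix_sex_col(read.csv(p, comment.char = "#", stringsAsFactors = FALSE))
      need <- c("family_id", "twin", "zygosity", "sex", "stage", "trait", "value")
      miss <- setdiff(need, names(df))
      if (length(miss)) {
        add("twin_csv: missing column(s): %s", paste(miss, collapse = ", "))
      } else {
        bad <- which(!df$zygosity %in% c("MZ", "DZ"))
        for (i in bad) add("twin_csv row %d: zygosity must be MZ or DZ", i)
        bad <- which(!df$sex %in% c("F", "M") & !is.na(df$sex))
        for (i in bad) add("twin_csv row %d: sex must be F or M", i)
        key <- paste(df$family_id, df$twin, df$stage, df$trait)
        dup <- which(duplicated(key))
        for (i in dup) add("twin_csv row %d: duplicate twin row (%s)", i, key[i])
        mz <- df[df$zygosity == "MZ", ]
        if (nrow(mz)) {
          sp <- split(mz, paste(mz$family_id, mz$stage, mz$trait))
          for (d in sp) {
            if (length(unique(d$sex)) > 1L) {
              add("twin_csv family %s (%s, %s): MZ pair with discordant sexes",
                  d$family_id[1], d$stage[1], d$trait[1])
            }
          }
        }
      }
    }
  }
  issues
}

.write_table <- function(df, out_dir, name, meta) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (twin-pair
#' generation), `traits` (landmark CSV to trait table), `describe`
#' (group summaries and Bonferroni-corrected comparisons), `reliability`
#' (ICC and Dahlberg per trait) and `twin` (twin ICCs with bootstrap, model
#' selection, variance-component table with profile CIs). Each stage writes
#' a CSV plus a JSON metadata sidecar recording the seed; outputs are a pure
#' function of (inputs, config, seed).
#'
#' @param config Named list, or path to a YAML file with the same structure.
#'   Recognized fields: `out_dir` (required), `stages` (default: all stages
#'   with available inputs), `seed` (default 1), `landmark_csv`, `twin_csv`,
#'   `simulate` (argument list for [twin_sim_config()]), `bootstrap_reps`
#'   (default 1000), `starts` (default 5), `alpha` (default 0.05),
#'   `bonferroni_m` (default 20), `error_sd` (reliability replicate noise,
#'   default from the simulator config).
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  issues <- validate_inputs(config[c("landmark_csv", "twin_csv")])
  if (length(issues)) stop("invalid inputs:\n", paste(issues, collapse = "\n"))
  stages <- config$stages %||% c(
    if (!is.null(config$simulate) || is.null(config$twin_csv)) "simulate",
    if (!is.null(config$landmark_csv)) "traits",
    "describe",
    if (!is.null(config$simulate) || is.null(config$twin_csv)) "reliability",
    "twin"
  )
  boot <- as.integer(config$bootstrap_reps %||% 1000L)
  starts <- as.integer(config$starts %||% 5L)
  alpha <- config$alpha %||% 0.05
  m <- config$bonferroni_m %||% 20
  results <- list(seed = seed, stages = stages)
  log_lines <- c(sprintf("twinarch %s", as.character(utils::packageVersion("twinarch"))),
                 sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %d", seed),
                 sprintf("stages: %s", paste(stages, collapse = ", ")))
  meta <- list(seed = seed)

  pairs <- NULL
  sim_cfg <- NULL
  if ("simulate" %in% stages) {
    sim_cfg <- do.call(twin_sim_config,
                       modifyList(config$simulate %||% list(), list(seed = seed)))
    pairs <- simulate_twin_pairs(sim_cfg)
    write_twin_pairs(pairs, file.path(out_dir, "twin_pairs.csv"), seed = seed)
    results$pairs <- pairs
    log_lines <- c(log_lines, sprintf("simulate: %d pairs", nrow(pairs)))
  } else if (!is.null(config$twin_csv)) {
    pairs <- read_twin_pairs(config$twin_csv)
    results$pairs <- pairs
  }

  if ("traits" %in% stages) {
    lms <- read_landmarks(config$landmark_csv)
    traits <- landmarks_to_traits(lms)
    .write_table(traits, out_dir, "arch_traits", meta)
    results$traits <- traits
    log_lines <- c(log_lines, sprintf("traits: %d subject-stage records", nrow(traits)))
  }

  if ("describe" %in% stages) {
    if (is.null(pairs)) stop("describe stage needs twin data (simulate or twin_csv)")
    desc <- describe_traits(pairs, alpha = alpha, m = m)
    .write_table(desc, out_dir, "descriptives",
                 c(meta, list(alpha = alpha, bonferroni_m = m,
                              threshold = bonferroni_threshold(alpha, m))))
    results$descriptives <- desc
    log_lines <- c(log_lines, sprintf("describe: %d trait-stage rows", nrow(desc)))
  }

  if ("reliability" %in% stages) {
    if (!is.null(config$replicate_csv)) {
      reps <- read.csv(config$replicate_csv, stringsAsFactors = FALSE)
    } else {
      if (is.null(pairs)) stop("reliability stage needs twin data or replicate_csv")
      err <- config$error_sd %||% (if (!is.null(sim_cfg)) sim_cfg$error_sd else 0.2)
      sp <- split(pairs, paste(pairs$trait, pairs$stage))
      reps <- do.call(rbind, lapply(sp, function(d) {
        r <- simulate_repeated_measures(c(d$value1, d$value2), err, seed = seed + 1L)
        r$trait <- d$trait[1]
        r
      }))
    }
    rel <- reliability_table(reps)
    .write_table(rel, out_dir, "reliability", meta)
    results$reliability <- rel
    log_lines <- c(log_lines, sprintf("reliability: %d traits", nrow(rel)))
  }

  if ("twin" %in% stages) {
    if (is.null(pairs)) stop("twin stage needs twin data (simulate or twin_csv)")
    cells <- split(pairs, paste(pairs$trait, pairs$stage))
    icc_rows <- list()
    boot_rows <- list()
    fit_rows <- list()
    traces <- list()
    for (d in cells) {
      gd <- grouped_twin_data(d)
      key <- paste(gd$trait, gd$stage, sep = "/")
      for (zy in c("MZ", "DZ")) {
        ti <- twin_icc(gd, zy, nboot = boot, seed = seed + 2L)
        icc_rows[[paste(key, zy)]] <- data.frame(
          trait = gd$trait, stage = gd$stage, zygosity = zy,
          icc = ti$estimate, n_pairs = ti$n_pairs,
          boot_lo = if (length(ti$boot)) quantile(ti$boot, 0.025) else NA_real_,
          boot_hi = if (length(ti$boot)) quantile(ti$boot, 0.975) else NA_real_,
          stringsAsFactors = FALSE)
        if (length(ti$boot)) {
          boot_rows[[paste(key, zy)]] <- data.frame(
            trait = gd$trait, stage = gd$stage, zygosity = zy,
            replicate = seq_along(ti$boot), icc = ti$boot,
            stringsAsFactors = FALSE)
        }
      }
      sel <- select_model(gd, starts = starts, seed = seed + 3L, alpha = alpha)
      tab <- twin_fit_table(sel)
      tab <- cbind(trait = gd$trait, stage = gd$stage, tab)
      fit_rows[[key]] <- tab
      traces[[key]] <- list(best = model_label(sel$best$spec),
                            sex_structure = sel$best$spec$sex,
                            fits = sel$fits, tests = sel$tests,
                            candidates = sel$candidates)
    }
    .write_table(do.call(rbind, icc_rows), out_dir, "twin_icc",
                 c(meta, list(bootstrap_reps = boot)))
    if (length(boot_rows)) {
      .write_table(do.call(rbind, boot_rows), out_dir, "twin_icc_bootstrap",
                   c(meta, list(bootstrap_reps = boot)))
    }
    .write_table(do.call(rbind, fit_rows), out_dir, "twin_models",
                 c(meta, list(starts = starts, alpha = alpha)))
    jsonlite::write_json(traces, file.path(out_dir, "selection_trace.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    results$twin_icc <- do.call(rbind, icc_rows)
    results$twin_models <- do.call(rbind, fit_rows)
    results$traces <- traces
    log_lines <- c(log_lines,
                   sprintf("twin: %d trait-stage cells modelled", length(cells)))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  message(paste(log_lines, collapse = "\n"))
  invisible(results)
}
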