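# Polynomial rolling hash (Horner, mod 2^31 - 1) over the serialized config,
# used to stamp outputs so a result bundle can be traced to the exact
# configuration that produced it.
config_hash <- function(config) {
  s <- yaml::as.yaml(config)
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a pipeline run configuration
#'
#' YAML with blocks `input` (paths: `flora_csv`, `trait_csv`, `genus_tree`,
#' optional `family_tree`), `analysis` (optional: `offset_propensity`,
#' `offset_ratio`, `models`, `fdr_q`, `levels`, `metrics`), `output`
#' (`dir`), and `seed`.
#'
#' @param path YAML file.
#' @return Config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  fill_config_defaults(config)
}

fill_config_defaults <- function(config) {
  a <- config$analysis
  if (is.null(a)) a <- list()
  defaults <- list(offset_propensity = 1, offset_ratio = 1,
                   models = c("BM", "OU", "EB"), fdr_q = 0.05,
                   levels = c("genus", "family"),
                   metrics = c("log_propensity", "log_ratio"))
  for (nm in names(defaults)) {
    if (is.null(a[[nm]])) a[[nm]] <- defaults[[nm]]
  }
  config$analysis <- a
  if (is.null(config$seed)) stop("config must set an explicit seed")
  if (a$fdr_q <= 0 || a$fdr_q >= 1) stop("fdr_q must lie in (0, 1)")
  config
}

#' Validate pipeline inputs before any computation
#'
#' Cross-checks paths, the (genus, flora) uniqueness contract, and taxon-label
#' agreement between the count table, the trait table and the trees. Returns a
#' report rather than failing, so all problems surface at once; `strict = TRUE`
#' escalates a non-empty problem list to an error.
#'
#' @param config Config list (see [read_run_config()]).
#' @param strict Escalate problems to errors.
#' @return List: `problems` (character), `info` (per-trait observation counts
#'   and prune candidates).
#' @export
validate_inputs <- function(config, strict = FALSE) {
  problems <- character(0)
  info <- list()
  paths <- config$input
  for (nm in c("flora_csv", "trait_csv", "genus_tree")) {
    if (is.null(paths[[nm]])) {
      problems <- c(problems, paste0("missing required input path: ", nm))
    } else if (!file.exists(paths[[nm]])) {
      problems <- c(problems, paste0("input file not found: ", paths[[nm]]))
    }
  }
  if (length(problems) == 0) {
    records <- tryCatch(read_flora_records(paths$flora_csv),
                        error = function(e) {
                          problems <<- c(problems, conditionMessage(e))
                          NULL
                        })
    tree <- tryCatch(read_newick(paths$genus_tree), error = function(e) {
      problems <<- c(problems, conditionMessage(e))
      NULL
    })
    traits <- tryCatch(read_trait_records(paths$trait_csv),
                       error = function(e) {
                         problems <<- c(problems, conditionMessage(e))
                         NULL
                       })
    if (!is.null(records) && !is.null(tree)) {
      info$genera_not_in_tree <- setdiff(unique(records$genus), tree$tip.label)
      info$tips_without_counts <- setdiff(tree$tip.label,
                                          unique(records$genus))
    }
    if (!is.null(traits)) {
      info$n_observed_per_trait <-
        vapply(split(traits$species, traits$trait),
               function(x) length(unique(x)), integer(1))
    }
  }
  if (strict && length(problems) > 0) {
    stop("input validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  list(problems = problems, info = info)
}

write_output_csv <- function(df, path, meta) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# hybcorr config_hash=", meta$hash, " seed=", meta$seed),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table
#'
#' Reads the CSVs written by [run_full_pipeline()], skipping the metadata
#' comment line.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

# Signal table (taxon level, per-variable n, lambda, chi-square, df, p).
signal_table <- function(vars, tree) {
  rows <- lapply(names(vars), function(nm) {
    y <- vars[[nm]]
    y <- y[!is.na(y)]
    taxa <- intersect(names(y), tree$tip.label)
    if (length(taxa) < 4) {
      return(data.frame(variable = nm, n = length(taxa), lambda = NA_real_,
                        chi_square = NA_real_, df = 1L, p_value = NA_real_))
    }
    fit <- fit_lambda_ml(y[taxa], prune_to_taxa(tree, taxa))
    data.frame(variable = nm, n = fit$n, lambda = fit$lambda,
               chi_square = fit$LRT, df = fit$df, p_value = fit$p_value)
  })
  do.call(rbind, rows)
}

# PGLS per trait x metric with model comparison, BH within the metric's
# family of tests on the representative model's p-values.
pgls_tables <- function(metrics, traits, tree, models, fdr_q) {
  pgls_rows <- list()
  cmp_rows <- list()
  for (metric in names(metrics)) {
    y <- metrics[[metric]]
    for (trait in names(traits)) {
      x <- traits[[trait]]
      taxa <- intersect(intersect(names(y)[!is.na(y)], names(x)[!is.na(x)]),
                        tree$tip.label)
      if (length(taxa) < 5) next
      sub <- prune_to_taxa(tree, taxa)
      fits <- lapply(models, function(m) {
        fit_pgls_model(y[taxa], x[taxa], sub, model = m)
      })
      sel <- if (length(fits) > 1) compare_models(fits) else
        list(table = NULL, all_within_2_AIC = NA, representative = models[1])
      rep_fit <- fits[[match(sel$representative,
                             vapply(fits, `[[`, character(1), "model"))]]
      pgls_rows[[length(pgls_rows) + 1]] <- data.frame(
        metric = metric, trait = trait, model = rep_fit$model, n = rep_fit$n,
        estimate = rep_fit$estimate, se = rep_fit$se,
        p_value = rep_fit$p_value, adjusted_R2 = rep_fit$adjusted_R2,
        logL = rep_fit$logL, AIC = rep_fit$AIC, BIC = rep_fit$BIC,
        all_within_2_AIC = sel$all_within_2_AIC,
        stringsAsFactors = FALSE)
      if (!is.null(sel$table)) {
        ct <- sel$table
        ct$metric <- metric
        ct$trait <- trait
        cmp_rows[[length(cmp_rows) + 1]] <- ct
      }
    }
  }
  pgls <- do.call(rbind, pgls_rows)
  if (!is.null(pgls)) {
    pgls$bh_significant <- NA
    for (metric in unique(pgls$metric)) {
      idx <- pgls$metric == metric
      pgls$bh_significant[idx] <- benjamini_hochberg(pgls$p_value[idx],
                                                     q = fdr_q)
    }
  }
  list(pgls = pgls, comparison = do.call(rbind, cmp_rows))
}

raw_correlation_table <- function(metrics, traits) {
  rows <- list()
  for (metric in names(metrics)) {
    for (trait in names(traits)) {
      x <- traits[[trait]]; y <- metrics[[metric]]
      shared <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
      if (length(shared) < 3) next
      pc <- pearson_with_p(x[shared], y[shared])
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, trait = trait, r = pc$r, p_value = pc$p_value,
        n = pc$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full hybridization-correlates pipeline
#'
#' Executes metrics -> trait means -> per-analysis pruning -> phylogenetic
#' signal -> PGLS per evolutionary model with AIC/BIC comparison ->
#' Benjamini-Hochberg flags -> raw correlations -> phylogenetic path analysis,
#' per taxonomic level, and writes each table as CSV into the output
#' directory. Every CSV carries the configuration hash and seed on its first
#' line; a `manifest.yaml` records per-analysis sample sizes after pruning.
#'
#' @param config Config list (see [read_run_config()]); validated with
#'   [validate_inputs()] in strict mode before any computation.
#' @return Invisible list of the result tables, by level.
#' @export
run_full_pipeline <- function(config) {
  config <- fill_config_defaults(config)
  validate_inputs(config, strict = TRUE)
  a <- config$analysis
  out_dir <- config$output$dir
  if (is.null(out_dir)) stop("config must set output$dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(hash = config_hash(config), seed = config$seed)

  records <- read_flora_records(config$input$flora_csv)
  trait_records <- read_trait_records(config$input$trait_csv)
  genus_tree <- read_newick(config$input$genus_tree)
  family_tree <- if (!is.null(config$input$family_tree)) {
    read_newick(config$input$family_tree)
  } else NULL

  genus_sum <- aggregate_genus(records)
  genus_sum <- apply_exclusions(genus_sum, records,
                                drop_taxa = setdiff(genus_sum$taxon,
                                                    genus_tree$tip.label))
  genus_sum <- log_transform_metrics(genus_sum, a$offset_propensity,
                                     a$offset_ratio)

  results <- list()
  manifest <- list(config_hash = meta$hash, seed = config$seed, levels = list())

  for (level in a$levels) {
    if (level == "genus") {
      summaries <- genus_sum
      tree <- genus_tree
    } else {
      if (is.null(family_tree)) next
      fam <- aggregate_family(genus_sum)
      fam <- fam[fam$taxon %in% family_tree$tip.label, , drop = FALSE]
      summaries <- log_transform_metrics(fam, a$offset_propensity,
                                         a$offset_ratio)
      tree <- family_tree
    }
    trait_means <- taxon_trait_means(trait_records, level = level)
    trait_means <- trait_means[trait_means$taxon %in% summaries$taxon, ,
                               drop = FALSE]

    metric_vars <- lapply(a$metrics, function(m) {
      stats::setNames(summaries[[m]], summaries$taxon)
    })
    names(metric_vars) <- a$metrics
    trait_cols <- setdiff(colnames(trait_means),
                          c("taxon", "level",
                            grep("^n_species_", colnames(trait_means),
                                 value = TRUE)))
    trait_vars <- lapply(trait_cols, function(tr) {
      stats::setNames(trait_means[[tr]], trait_means$taxon)
    })
    names(trait_vars) <- trait_cols

    sig <- signal_table(c(metric_vars, trait_vars), tree)
    pg <- pgls_tables(metric_vars, trait_vars, tree, a$models, a$fdr_q)
    rc <- raw_correlation_table(metric_vars, trait_vars)

    path_res <- list()
    if (all(c("woodiness", "perenniality") %in% names(trait_vars))) {
      for (metric in a$metrics) {
        vars <- data.frame(woodiness = trait_vars$woodiness,
                           perenniality = trait_vars$perenniality,
                           hybridization = metric_vars[[metric]],
                           row.names = trait_means$taxon)
        pr <- try(rank_and_select(default_candidate_set(), vars, tree),
                  silent = TRUE)
        if (!inherits(pr, "try-error")) path_res[[metric]] <- pr
      }
    }

    lv <- list(summaries = summaries, traits = trait_means, signal = sig,
               pgls = pg$pgls, model_comparison = pg$comparison,
               raw_correlations = rc, path = path_res)
    results[[level]] <- lv

    write_output_csv(summaries, file.path(out_dir,
                                          paste0("summaries_", level, ".csv")),
                     meta)
    write_output_csv(trait_means,
                     file.path(out_dir, paste0("traits_", level, ".csv")),
                     meta)
    write_output_csv(sig, file.path(out_dir, paste0("signal_", level, ".csv")),
                     meta)
    if (!is.null(pg$pgls)) {
      write_output_csv(pg$pgls,
                       file.path(out_dir, paste0("pgls_", level, ".csv")),
                       meta)
    }
    if (!is.null(pg$comparison)) {
      write_output_csv(pg$comparison,
                       file.path(out_dir,
                                 paste0("model_comparison_", level, ".csv")),
                       meta)
    }
    if (!is.null(rc)) {
      write_output_csv(rc,
                       file.path(out_dir,
                                 paste0("raw_correlations_", level, ".csv")),
                       meta)
    }
    for (metric in names(path_res)) {
      pr <- path_res[[metric]]
      write_output_csv(pr$table,
                       file.path(out_dir, paste0("path_models_", metric, "_",
                                                 level, ".csv")), meta)
      write_output_csv(pr$best$coefficients,
                       file.path(out_dir,
                                 paste0("path_coefficients_", metric, "_",
                                        level, ".csv")), meta)
    }
    manifest$levels[[level]] <- list(
      n_taxa = nrow(summaries),
      n_per_analysis = stats::setNames(as.list(sig$n), sig$variable))
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
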