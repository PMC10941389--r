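#' Default pipeline configuration
#'
#' Returns the full nested configuration of [run_pipeline()] with every
#' stage enabled and stage parameters at their standard values (moving
#' median window 5, period 99-140, at least 10 observed days, gaps of at
#' most 3 days, depth 700, prevalence 0.05, 1000 permutations, percentile
#' classes 5/95/47.5-52.5, MCMC 70000/10000/50, 4-fold cross-validation
#' with 50 repeats, 50/50 split).
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    stages = list(simulate = TRUE, feedclean = TRUE, phenotype = TRUE,
                  microbiome = TRUE, associate = TRUE,
                  microbiability = TRUE, plsda = TRUE),
    simulate = list(),
    feedclean = list(start_day = 99, end_day = 140, min_days = 10,
                     max_gap = 3, max_per_visit = 5, max_per_day = 10),
    phenotype = list(window = 5),
    microbiome = list(min_depth = 700, min_prev = 0.05),
    associate = list(indicator = "lnvar", n_perm = 1000),
    microbiability = list(indicator = "lnvar", iters = 70000,
                          burnin = 10000, thin = 50),
    plsda = list(indicator = "lnvar", folds = 4, repeats = 50,
                 elim_repeats = 10, max_comp = 5, split_fraction = 0.5))
}

merge_config <- function(user, defaults, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown %s key(s): %s", path,
                  paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && nm != "simulate") {
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]],
                                     paste0(path, "$", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

write_stage_tsv <- function(x, out_dir, name, files) {
  path <- file.path(out_dir, name)
  readr::write_tsv(x, path, progress = FALSE)
  c(files, path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate, feedclean,
#' phenotype, microbiome, associate, microbiability, plsda — writing each
#' stage's tables to `out_dir` together with a manifest (file MD5 hashes,
#' seed, completed stages) and a consolidated JSON + markdown report.
#' Per-stage seeds are derived from the global seed by fixed offsets, so
#' disabling a stage does not shift the draws of the others. If a stage
#' fails, the pipeline halts and the manifest records the stages that
#' completed.
#'
#' @param config Partial configuration list (merged over
#'   [default_run_config()]; unknown keys are rejected) or the path to a
#'   YAML file holding one.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(config, default_run_config())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  completed <- character(0)
  results <- list()
  seed <- cfg$seed

  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest <- function() {
    hashes <- tools::md5sum(sort(files))
    manifest <- list(seed = seed, stages = completed,
                     files = as.list(setNames(unname(hashes),
                                              basename(names(hashes)))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    manifest
  }

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      write_manifest()
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    results[[name]] <<- res
    completed <<- c(completed, name)
    invisible(res)
  }

  run_stage("simulate", function() {
    sim_cfg <- do.call(sim_config, cfg$simulate)
    meta <- simulate_cohort(sim_cfg, seed = derive_seed(seed, 1))
    feed <- simulate_feed_intake(sim_cfg, meta, seed = derive_seed(seed, 2))
    files <<- write_stage_tsv(meta, out_dir, "metadata.tsv", files)
    files <<- write_stage_tsv(feed$visits, out_dir, "visits.tsv", files)
    list(sim_cfg = sim_cfg, metadata = meta, feed = feed)
  })

  run_stage("feedclean", function() {
    fc <- cfg$feedclean
    visits <- clean_visits(results$simulate$feed$visits,
                           max_per_visit = fc$max_per_visit,
                           max_per_day = fc$max_per_day)
    daily <- aggregate_visits_to_daily(visits)
    daily <- restrict_period(daily, fc$start_day, fc$end_day)
    daily <- filter_animals(daily, fc$min_days, fc$max_gap)
    files <<- write_stage_tsv(
      daily[, c("animal_id", "age_days", "fcd_kg", "missing")],
      out_dir, "daily.tsv", files)
    daily
  })

  run_stage("phenotype", function() {
    ind <- resilience_indicators(results$feedclean,
                                 window = cfg$phenotype$window)
    classes <- assign_classes(ind)
    files <<- write_stage_tsv(ind, out_dir, "indicators.tsv", files)
    files <<- write_stage_tsv(classes, out_dir, "classes.tsv", files)
    list(indicators = ind, classes = classes)
  })

  run_stage("microbiome", function() {
    mc <- cfg$microbiome
    ind <- results$phenotype$indicators
    meta <- results$simulate$metadata
    meta <- meta[meta$animal_id %in% ind$animal_id, , drop = FALSE]
    ind_vec <- ind[[cfg$associate$indicator]][
      match(meta$animal_id, ind$animal_id)]
    sim <- simulate_microbiome(results$simulate$sim_cfg, meta,
                               seed = derive_seed(seed, 3),
                               indicator_values = ind_vec)
    counts <- sim$counts
    div <- alpha_diversity(counts)
    filt <- filter_samples_by_depth(counts, mc$min_depth)
    filt <- filter_asvs_by_prevalence(filt, mc$min_prev)
    clr <- clr_transform(filt)
    dist <- aitchison_distance(clr)
    kernel <- build_kernel(clr)
    files <<- write_stage_tsv(div, out_dir, "diversity.tsv", files)
    list(counts = counts, clr = clr, dist = dist, kernel = kernel,
         diversity = div, truth = sim$truth)
  })

  run_stage("associate", function() {
    ac <- cfg$associate
    mb <- results$microbiome
    ind <- results$phenotype$indicators
    ids <- rownames(mb$clr)
    meta <- dplyr::inner_join(
      tibble::tibble(animal_id = ids),
      ind[, c("animal_id", "breed", "room_id", ac$indicator)],
      by = "animal_id")
    names(meta)[names(meta) == ac$indicator] <- "indicator"
    pm <- permanova(mb$dist, meta, n_perm = ac$n_perm,
                    seed = derive_seed(seed, 4))
    div <- remove_diversity_outliers(mb$diversity, "shannon")
    div_dat <- dplyr::inner_join(
      div, dplyr::rename(ind, sample_id = "animal_id"), by = "sample_id")
    reg <- diversity_regression(div_dat, "shannon", ac$indicator,
                                covariates = c("room_id", "breed"))
    cls <- results$phenotype$classes
    cls_i <- cls[cls$indicator == ac$indicator &
                   cls$class != "unassigned", , drop = FALSE]
    ks_dat <- dplyr::inner_join(
      mb$diversity, dplyr::rename(cls_i, sample_id = "animal_id"),
      by = "sample_id")
    ks <- suppressWarnings(ks_class_test(ks_dat, "shannon"))
    files <<- write_stage_tsv(pm, out_dir, "permanova.tsv", files)
    files <<- write_stage_tsv(reg, out_dir, "diversity_regression.tsv",
                              files)
    if (!is.null(ks) && nrow(ks) > 0) {
      files <<- write_stage_tsv(ks, out_dir, "ks_tests.tsv", files)
    }
    list(permanova = pm, regression = reg, ks = ks)
  })

  run_stage("microbiability", function() {
    mb <- cfg$microbiability
    ind <- results$phenotype$indicators
    kernel <- results$microbiome$kernel
    dat <- ind[match(rownames(kernel), ind$animal_id), , drop = FALSE]
    dat$sire_breed <- interaction(dat$breed, dat$sire_id, drop = TRUE)
    fit <- fit_microbiability(dat, mb$indicator, kernel,
                              pen = "pen_id", sire = "sire_breed",
                              iters = mb$iters, burnin = mb$burnin,
                              thin = mb$thin, seed = derive_seed(seed, 5))
    summ <- summarize_m2(fit, min_draws = min(200, nrow(fit$draws)))
    files <<- write_stage_tsv(fit$draws, out_dir,
                              "microbiability_draws.tsv", files)
    json_path <- file.path(out_dir, "microbiability_summary.json")
    jsonlite::write_json(
      list(m2_median = summ$m2_median,
           hpd95 = as.list(summ$hpd95),
           fractions = summ$fractions, geweke = summ$geweke),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, json_path)
    list(fit = fit, summary = summ)
  })

  run_stage("plsda", function() {
    pc <- cfg$plsda
    cls <- results$phenotype$classes
    cls_i <- cls[cls$indicator == pc$indicator &
                   cls$class != "unassigned", , drop = FALSE]
    cls_i$class <- droplevels(cls_i$class)
    clr <- results$microbiome$clr
    cls_i <- cls_i[cls_i$animal_id %in% rownames(clr), , drop = FALSE]
    split <- stratified_split(cls_i, seed = derive_seed(seed, 6),
                              fraction = pc$split_fraction)
    tr <- split[split$split == "train", ]
    te <- split[split$split == "test", ]
    x_tr <- clr[tr$animal_id, , drop = FALSE]
    x_te <- clr[te$animal_id, , drop = FALSE]
    sel <- select_components(x_tr, tr$class, max_comp = pc$max_comp,
                             folds = pc$folds, repeats = pc$repeats,
                             seed = derive_seed(seed, 7))
    elim <- recursive_vip_elimination(x_tr, tr$class, ncomp = sel$best,
                                      folds = pc$folds,
                                      repeats = pc$elim_repeats,
                                      seed = derive_seed(seed, 8))
    ev <- suppressWarnings(
      evaluate_plsda(elim$model, x_te[, elim$features, drop = FALSE],
                     te$class))
    files <<- write_stage_tsv(ev$per_class, out_dir,
                              "plsda_evaluation.tsv", files)
    files <<- write_stage_tsv(tibble::as_tibble(as.data.frame(ev$confusion)),
                              out_dir, "plsda_confusion.tsv", files)
    files <<- write_stage_tsv(ev$roc, out_dir, "plsda_roc.tsv", files)
    files <<- write_stage_tsv(elim$trajectory, out_dir,
                              "plsda_trajectory.tsv", files)
    list(selection = sel, elimination = elim, evaluation = ev)
  })

  report <- build_report(results, cfg)
  report_path <- file.path(out_dir, "report.md")
  writeLines(report$markdown, report_path)
  json_report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report$json, json_report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, report_path, json_report_path)
  manifest <- write_manifest()
  invisible(c(results, list(manifest = manifest, config = cfg)))
}

build_report <- function(results, cfg) {
  md <- c("# resilink pipeline report", "",
          sprintf("Seed: %d", cfg$seed), "")
  json <- list(seed = cfg$seed)
  if (!is.null(results$phenotype)) {
    ind <- results$phenotype$indicators
    md <- c(md, "## Resilience indicators", "",
            sprintf("Animals: %d", nrow(ind)), "")
    json$n_animals <- nrow(ind)
  }
  if (!is.null(results$associate)) {
    pm <- results$associate$permanova
    md <- c(md, "## PERMANOVA (distance ~ room + breed + indicator)", "",
            "| Term | SumSq | F | Pr(>F) | VarExp |",
            "|---|---|---|---|---|",
            sprintf("| %s | %.3f | %s | %s | %.3f |", pm$term, pm$sum_sq,
                    ifelse(is.na(pm$pseudo_f), "",
                           sprintf("%.3f", pm$pseudo_f)),
                    ifelse(is.na(pm$p_value), "",
                           sprintf("%.3f", pm$p_value)), pm$var_exp), "")
    json$permanova <- pm
  }
  if (!is.null(results$microbiability)) {
    s <- results$microbiability$summary
    md <- c(md, "## Microbiability", "",
            sprintf("Posterior median m2 = %.3f, HPD95 [%.3f, %.3f]",
                    s$m2_median, s$hpd95[["lower"]], s$hpd95[["upper"]]),
            "")
    json$m2_median <- s$m2_median
    json$m2_hpd95 <- as.list(s$hpd95)
  }
  if (!is.null(results$plsda)) {
    ev <- results$plsda$evaluation
    md <- c(md, "## PLS-DA classification", "",
            "| Class | AUC | Incidence | P-value |",
            "|---|---|---|---|",
            sprintf("| %s | %.3f | %.3f | %.3f |", ev$per_class$class,
                    ev$per_class$auc, ev$per_class$incidence,
                    ev$per_class$p_value),
            "",
            sprintf("Overall (macro) AUC: %.3f", ev$overall_auc), "")
    json$plsda <- ev$per_class
    json$overall_auc <- ev$overall_auc
  }
  list(markdown = md, json = json)
}
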