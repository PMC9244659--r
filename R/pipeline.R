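# Stage orchestration: reproducible pipeline runs with per-stage artifact
# manifests (content hashes + seeds), so two runs with the same config are
# byte-comparable.

#' Pipeline configuration
#'
#' @param out_dir root directory for all artifacts.
#' @param cohort a [cohort_config()].
#' @param model an [mt_config()].
#' @param baseline a [baseline_config()].
#' @param eval_B bootstrap resamples for evaluation.
#' @param target_sensitivity operating-point convention.
#' @param split named proportions for train/val/test.
#' @param seed global seed (propagated to stages that draw).
#' @return class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(n_patients = 2000),
                            model = mt_config(),
                            baseline = baseline_config(),
                            eval_B = 1000L, target_sensitivity = 0.65,
                            split = c(train = 0.6, val = 0.2, test = 0.2),
                            seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-9)
  structure(list(out_dir = out_dir, cohort = cohort, model = model,
                 baseline = baseline, eval_B = as.integer(eval_B),
                 target_sensitivity = target_sensitivity, split = split,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_deps <- list(
  simulate = character(0),
  preprocess = "simulate",
  label = "preprocess",
  train = c("preprocess", "label"),
  baseline = c("preprocess", "label"),
  evaluate = c("train", "baseline"),
  interpret = "train",
  cluster = c("train", "label"),
  benefit = "label")

.manifest_write <- function(config, stage, inputs, outputs) {
  man <- list(stage = stage,
              seed = config$seed,
              package_version = as.character(utils::packageVersion("ardswatch")),
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(outputs)))
  names(man$inputs) <- basename(inputs)
  names(man$outputs) <- basename(outputs)
  path <- file.path(config$out_dir, "manifests", paste0(stage, ".json"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.require_artifacts <- function(paths, needed_stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing artifacts (", paste(basename(missing), collapse = ", "),
         "): run stage '", needed_stage, "' first")
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order, writing every
#' artifact under `config$out_dir` together with a per-stage JSON manifest
#' of input/output content hashes and seeds. Re-running an unchanged stage
#' reproduces byte-identical artifacts and manifests.
#'
#' Stages: `simulate` (cohort CSV trio), `preprocess` (split + input
#' matrices + algotime sidecar), `label` (labels CSV), `train` (multitask
#' network), `baseline` (one-vs-all boosters), `evaluate` (reports),
#' `interpret` (attention exports), `cluster` (phenotype exports),
#' `benefit` (mortality benefit report).
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of stage names (default: all, in order).
#' @return named list of manifest paths, invisibly.
#' @export
run_pipeline <- function(config, stages = names(.stage_deps)) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, names(.stage_deps), several.ok = TRUE)
  stages <- names(.stage_deps)[names(.stage_deps) %in% stages]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out, ...)
  manifests <- list()

  for (stage in stages) {
    for (dep in .stage_deps[[stage]]) {
      if (!file.exists(p("manifests", paste0(dep, ".json"))) &&
          !dep %in% stages)
        stop("stage '", stage, "' requires stage '", dep, "': run it first")
    }
  }

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(config$cohort)
    write_cohort_csv(cohort, p("cohort"))
    outs <- p("cohort", c("patients.csv", "observations.csv", "diagnoses.csv"))
    manifests$simulate <- .manifest_write(config, "simulate", character(0), outs)
  }

  if ("preprocess" %in% stages) {
    ins <- p("cohort", c("patients.csv", "observations.csv", "diagnoses.csv"))
    .require_artifacts(ins, "simulate")
    cohort <- read_cohort_csv(p("cohort"))
    set.seed(config$seed)
    n <- length(cohort)
    idx <- sample.int(n)
    n_tr <- floor(config$split[["train"]] * n)
    n_va <- floor(config$split[["val"]] * n)
    splits <- list(train = idx[seq_len(n_tr)],
                   val = idx[n_tr + seq_len(n_va)],
                   test = idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    sets <- list(train = build_tensor_set(cohort[splits$train], "train_val"),
                 val = build_tensor_set(cohort[splits$val], "train_val"),
                 test = build_tensor_set(cohort[splits$test], "test"))
    saveRDS(sets, p("tensors.rds"), version = 3)
    sidecar <- lapply(names(sets), function(sp) {
      s <- sets[[sp]]
      list(split = sp,
           patients = lapply(s$tensors, function(tn) {
             list(patient_id = tn$patient_id,
                  algotime = .iso8601(tn$algotime), source = tn$source)
           }),
           excluded = s$excluded)
    })
    jsonlite::write_json(sidecar, p("algotimes.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifests$preprocess <- .manifest_write(config, "preprocess", ins,
                                            p(c("tensors.rds", "algotimes.json")))
  }

  if ("label" %in% stages) {
    ins <- p(c("tensors.rds", "algotimes.json"))
    .require_artifacts(ins, "preprocess")
    cohort <- read_cohort_csv(p("cohort"))
    sets <- readRDS(p("tensors.rds"))
    algotimes <- do.call(c, unname(lapply(sets, function(s) s$algotimes)))
    labels <- cohort_labels(cohort, algotimes)
    split_of <- do.call(rbind, lapply(names(sets), function(sp) {
      ids <- names(sets[[sp]]$tensors)
      if (length(ids)) data.frame(patient_id = ids, split = sp) else NULL
    }))
    labels$split <- split_of$split[match(labels$patient_id,
                                         split_of$patient_id)]
    utils::write.csv(labels, p("labels.csv"), row.names = FALSE)
    manifests$label <- .manifest_write(config, "label", ins, p("labels.csv"))
  }

  .load_xy <- function(sets, labels, sp) {
    ids <- names(sets[[sp]]$tensors)
    y <- labels[match(ids, labels$patient_id), label_names()]
    list(x = tensor_stack(sets[[sp]]$tensors), y = as.matrix(y))
  }

  if ("train" %in% stages) {
    ins <- p(c("tensors.rds", "labels.csv"))
    .require_artifacts(ins, "label")
    sets <- readRDS(p("tensors.rds"))
    labels <- utils::read.csv(p("labels.csv"))
    tr <- .load_xy(sets, labels, "train"); va <- .load_xy(sets, labels, "val")
    model <- mt_train(tr$x, tr$y, va$x, va$y, config$model)
    save_mt_model(model, p("model.json"))
    manifests$train <- .manifest_write(config, "train", ins, p("model.json"))
  }

  if ("baseline" %in% stages) {
    ins <- p(c("tensors.rds", "labels.csv"))
    .require_artifacts(ins, "label")
    sets <- readRDS(p("tensors.rds"))
    labels <- utils::read.csv(p("labels.csv"))
    tr <- .load_xy(sets, labels, "train"); va <- .load_xy(sets, labels, "val")
    bl <- train_one_vs_all(flatten_tensors(tr$x), tr$y,
                           flatten_tensors(va$x), va$y, config$baseline)
    saveRDS(bl, p("baseline.rds"), version = 3)
    jsonlite::write_json(lapply(bl$chosen, function(g)
      if (all(is.na(g))) NA else as.list(g)),
      p("baseline_grid.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifests$baseline <- .manifest_write(
      config, "baseline", ins, p(c("baseline.rds", "baseline_grid.json")))
  }

  if ("evaluate" %in% stages) {
    ins <- p(c("tensors.rds", "labels.csv", "model.json", "baseline.rds"))
    .require_artifacts(ins, "train/baseline")
    sets <- readRDS(p("tensors.rds"))
    labels <- utils::read.csv(p("labels.csv"))
    te <- .load_xy(sets, labels, "test")
    model <- load_mt_model(p("model.json"))
    bl <- readRDS(p("baseline.rds"))
    np <- mt_forward(te$x, model)$probabilities
    colnames(np) <- model$config$target_subset
    bp <- predict_one_vs_all(bl, flatten_tensors(te$x))
    rep_n <- eval_report(np, te$y, "rnn", B = config$eval_B,
                         target_sensitivity = config$target_sensitivity,
                         seed = config$seed)
    rep_b <- eval_report(bp[, colnames(np), drop = FALSE], te$y, "xgb",
                         B = config$eval_B,
                         target_sensitivity = config$target_sensitivity,
                         seed = config$seed)
    both <- rbind(rep_n, rep_b)
    utils::write.table(both, p("eval_report.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(both, p("eval_report.json"), dataframe = "rows",
                         digits = NA, pretty = TRUE)
    manifests$evaluate <- .manifest_write(
      config, "evaluate", ins, p(c("eval_report.tsv", "eval_report.json")))
  }

  if ("interpret" %in% stages) {
    ins <- p(c("tensors.rds", "model.json"))
    .require_artifacts(ins, "train")
    sets <- readRDS(p("tensors.rds"))
    model <- load_mt_model(p("model.json"))
    tensors <- sets$test$tensors
    n_s <- min(50L, length(tensors))
    export_interpretability(model, tensors, p("interpret"), n_sample = n_s,
                            seed = config$seed)
    manifests$interpret <- .manifest_write(
      config, "interpret", ins,
      p("interpret", c("attention_weights.tsv", "max_attention_feature_z.tsv")))
  }

  if ("cluster" %in% stages) {
    ins <- p(c("tensors.rds", "labels.csv", "model.json"))
    .require_artifacts(ins, "train")
    sets <- readRDS(p("tensors.rds"))
    labels <- utils::read.csv(p("labels.csv"))
    model <- load_mt_model(p("model.json"))
    all_tensors <- c(sets$train$tensors, sets$val$tensors, sets$test$tensors)
    ards_ids <- labels$patient_id[labels$ards_5 == 1]
    tensors <- all_tensors[names(all_tensors) %in% ards_ids]
    if (length(tensors) < 3) stop("too few ARDS patients to cluster")
    emb <- extract_embeddings(model, tensors)
    mort <- labels$death_12[match(rownames(emb), labels$patient_id)]
    cl <- cluster_embeddings(emb, mortality = mort, seed = config$seed)
    rep <- incidence_table(cl, labels)
    coords <- project_2d(emb)
    export_clustering(cl, rep, coords, p("cluster"))
    manifests$cluster <- .manifest_write(
      config, "cluster", ins,
      p("cluster", c("cluster_assignments.csv", "cluster_incidence.tsv",
                     "embedding_coords.csv")))
  }

  if ("benefit" %in% stages) {
    ins <- p("labels.csv")
    .require_artifacts(ins, "label")
    labels <- utils::read.csv(p("labels.csv"))
    rep <- benefit_report(labels)
    jsonlite::write_json(
      list(table = as.list(stats::setNames(as.vector(t(rep$table)),
                                           c("early_died", "early_survived",
                                             "late_died", "late_survived"))),
           early_mortality = rep$early_mortality,
           late_mortality = rep$late_mortality,
           ards_baseline_mortality = rep$ards_baseline_mortality,
           non_ards_baseline_mortality = rep$non_ards_baseline_mortality,
           fisher_p = rep$fisher_p),
      p("benefit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- utils::capture.output(print(rep))
    writeLines(txt, p("benefit.txt"))
    manifests$benefit <- .manifest_write(config, "benefit", ins,
                                         p(c("benefit.json", "benefit.txt")))
  }

  invisible(manifests)
}

#' Read all stage manifests of a pipeline run
#' @param out_dir pipeline output directory.
#' @return named list of manifest objects.
#' @export
read_manifests <- function(out_dir) {
  files <- list.files(file.path(out_dir, "manifests"), full.names = TRUE)
  out <- lapply(files, jsonlite::read_json)
  names(out) <- sub("\\.json$", "", basename(files))
  out
}
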