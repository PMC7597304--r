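#' Configure a full antifragility experiment
#'
#' An experiment runs the whole pipeline for a set of networks: sample
#' mutant cohorts, classify every mutant by exhaustive attractor comparison,
#' compute paired fragility curves and 30-point difference curves, assemble
#' the labelled feature dataset and (optionally) select and evaluate a CNN
#' by nested cross-validation. All artifacts are plain TSV/JSON under
#' `out_dir`, listed with content hashes in `manifest.tsv`.
#'
#' @param networks either a character vector of network file paths (read
#'   with [read_network()]) or a list `list(n=, N=, K=, bias=)` describing a
#'   random-network cohort.
#' @param n_mutants mutants per network (`>= 1`).
#' @param perturbation a [perturbation_config()]; its seed is re-derived per
#'   network from the experiment seed so that original and mutants of one
#'   network share initial states and perturbation draws.
#' @param grid CNN hyperparameter grid, see [hyperparameter_grid()].
#' @param out_dir output directory (created if needed).
#' @param seed global experiment seed; every random draw descends from it
#'   through named substreams.
#' @param train run the cross-validation/training stage.
#' @param cap exhaustive attractor-enumeration cap.
#' @param min_class_count classes rarer than this in the assembled feature
#'   dataset are dropped before the training stage (small smoke cohorts
#'   routinely produce a handful of robust-and-evolvable mutants, too few
#'   for neighbour-based oversampling and stratified folds).
#' @param cv_args extra arguments passed to [nested_cross_validation()].
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(networks, n_mutants,
                              perturbation = perturbation_config(),
                              grid = hyperparameter_grid(), out_dir,
                              seed = 1L, train = TRUE, cap = 26L,
                              min_class_count = 8L,
                              cv_args = list(allow_missing_classes = TRUE)) {
  if (is.character(networks)) {
    missing_f <- networks[!file.exists(networks)]
    if (length(missing_f) > 0L)
      stop("network file not found: ", missing_f[1])
  } else if (!is.list(networks) ||
             !all(c("n", "N", "K") %in% names(networks))) {
    stop("networks must be file paths or list(n=, N=, K=)")
  }
  if (n_mutants < 1L) stop("n_mutants must be >= 1")
  structure(list(networks = networks, n_mutants = as.integer(n_mutants),
                 perturbation = perturbation, grid = grid, out_dir = out_dir,
                 seed = as.integer(seed), train = isTRUE(train),
                 cap = as.integer(cap),
                 min_class_count = as.integer(min_class_count),
                 cv_args = cv_args),
            class = "experiment_config")
}

#' Run a full experiment and write its artifact manifest
#'
#' Stages: load/generate networks; sample mutant cohorts; classify mutants
#' (labels.tsv); compute paired fragility curves (curves/*.tsv) and
#' 30-point difference features (features.tsv); optionally run nested
#' cross-validation and write the evaluation report (report.json). Every
#' file is listed with its MD5 in manifest.tsv; identical config + seed
#' reproduce identical hashes.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest data frame (`file`, `md5`), invisibly.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(file.path(out, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "mutants"), showWarnings = FALSE)
  dir.create(file.path(out, "curves"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # stage 1: networks
  if (is.character(config$networks)) {
    nets <- lapply(config$networks, read_network)
    net_names <- tools::file_path_sans_ext(basename(config$networks))
  } else {
    spec <- config$networks
    bias <- if (is.null(spec$bias)) 0.5 else spec$bias
    nets <- lapply(seq_len(spec$n), function(i)
      generate_rbn(spec$N, spec$K, seed = derive_seed(config$seed, "rbn", i),
                   bias = bias))
    net_names <- sprintf("rbn%02d", seq_len(spec$n))
  }
  names(nets) <- net_names
  for (nm in net_names)
    write_network(nets[[nm]], file.path(out, "networks", paste0(nm, ".txt")),
                  format = "table")
  say("loaded %d networks", length(nets))

  # stages 2-4 per network
  labels <- list(); curves_all <- list(); feats <- list()
  for (nm in net_names) {
    net <- nets[[nm]]
    cohort <- sample_mutants(net, config$n_mutants,
                             seed = derive_seed(config$seed, "mutants", nm))
    man <- data.frame(
      mutant = sprintf("%s_m%04d", nm, seq_along(cohort)),
      kind = vapply(cohort, function(e) e$mutation$kind, character(1)),
      target = vapply(cohort, function(e) e$mutation$target, integer(1)))
    mdir <- file.path(out, "mutants", nm)
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(cohort))
      write_network(cohort[[i]]$network,
                    file.path(mdir, paste0(man$mutant[i], ".txt")),
                    format = "table")
    utils::write.table(man, file.path(mdir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

    A <- find_attractors(net, cap = config$cap)
    cls <- vapply(cohort, function(e)
      classify_change(A, find_attractors(e$network, cap = config$cap)),
      character(1))
    labels[[nm]] <- data.frame(network = nm, mutant = man$mutant,
                               kind = man$kind, class = cls)

    pcfg <- config$perturbation
    pcfg$seed <- derive_seed(config$seed, "perturb", nm)
    orig_curve <- fragility_curve(net, pcfg)
    mut_curves <- lapply(cohort, function(e)
      fragility_curve(e$network, pcfg))
    curve_tab <- rbind(cbind(mutant = "original",
                             as.data.frame(orig_curve)),
                       do.call(rbind, lapply(seq_along(mut_curves), function(i)
                         cbind(mutant = man$mutant[i],
                               as.data.frame(mut_curves[[i]])))))
    curves_all[[nm]] <- curve_tab
    utils::write.table(curve_tab, file.path(out, "curves",
                                            paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    dcs <- lapply(mut_curves, function(mc) difference_curve(orig_curve, mc))
    feats[[nm]] <- list(curves = dcs, labels = cls,
                        groups = rep(nm, length(dcs)))
    say("network %s: %d mutants classified, curves done", nm, length(cohort))
  }

  labels_tab <- do.call(rbind, labels)
  utils::write.table(labels_tab, file.path(out, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  dataset <- build_dataset(unlist(lapply(feats, `[[`, "curves"),
                                  recursive = FALSE),
                           unlist(lapply(feats, `[[`, "labels")),
                           unlist(lapply(feats, `[[`, "groups")))
  feat_tab <- cbind(labels_tab[, c("network", "mutant", "kind", "class")],
                    as.data.frame(dataset$features))
  utils::write.table(feat_tab, file.path(out, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # stage 5: model selection and evaluation
  if (config$train) {
    counts <- table(dataset$labels)
    keep_cls <- names(counts)[counts >= config$min_class_count]
    if (length(keep_cls) < 2L)
      stop("training stage needs at least two classes with >= ",
           config$min_class_count, " mutants each")
    if (length(keep_cls) < length(counts[counts > 0]))
      say("dropping rare class(es) from training: %s",
          paste(setdiff(names(counts)[counts > 0], keep_cls),
                collapse = ", "))
    train_data <- fd_subset(dataset, which(as.character(dataset$labels)
                                           %in% keep_cls))
    cv <- do.call(nested_cross_validation,
                  c(list(data = train_data, grid = config$grid,
                         seed = derive_seed(config$seed, "cv")),
                    config$cv_args))
    aps <- vapply(cv$fold_reports[[1]]$per_class, function(p)
      if (is.null(p)) NA_real_ else p$ap, numeric(1))
    report <- list(best = as.list(cv$best),
                   selection_auc = as.list(cv$auc_table),
                   mean_test_accuracy = cv$mean_accuracy,
                   fold_accuracy = vapply(cv$fold_reports, `[[`, numeric(1),
                                          "accuracy"),
                   micro_ap = mean(vapply(cv$fold_reports, function(r)
                     r$micro$ap, numeric(1))),
                   per_class_ap_fold1 = as.list(aps),
                   random_baseline_ap = as.list(
                     random_baseline_ap(table(droplevels(train_data$labels)))))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("cross-validation done: best %s, mean accuracy %.3f",
        cv$best$set, cv$mean_accuracy)
  }

  files <- list.files(out, recursive = TRUE)
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))))
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Summarize the artifacts of a finished experiment
#'
#' Reads the artifacts under an experiment output directory and computes the
#' per-network class distribution, the mutation-kind-by-class contingency
#' table with Cramer's V, and (when present) the evaluation metrics.
#'
#' @param out_dir the experiment output directory (containing
#'   `manifest.tsv`).
#' @return a list with `class_distribution` (networks x classes,
#'   percentages), `contingency` (kind x class counts), `cramers_v`, and
#'   `evaluation` (parsed report.json, or `NULL`).
#' @export
summarize_experiment <- function(out_dir) {
  need <- file.path(out_dir, c("manifest.tsv", "labels.tsv"))
  absent <- need[!file.exists(need)]
  if (length(absent) > 0L)
    stop("missing experiment artifacts: ", paste(absent, collapse = ", "))
  labels <- utils::read.delim(file.path(out_dir, "labels.tsv"))
  cls <- factor(labels$class, levels = robustness_classes())
  dist <- 100 * prop.table(table(labels$network, cls), margin = 1L)
  cont <- table(factor(labels$kind,
                       levels = c("add", "delete", "change", "flip")), cls)
  v <- tryCatch(cramers_v(unclass(cont)), error = function(e) NA_real_)
  rep_path <- file.path(out_dir, "report.json")
  evaluation <- if (file.exists(rep_path))
    jsonlite::read_json(rep_path, simplifyVector = TRUE) else NULL
  list(class_distribution = dist, contingency = cont, cramers_v = v,
       evaluation = evaluation)
}
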