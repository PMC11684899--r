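#' Load an expression matrix and outcome table from delimited files
#'
#' The matrix file has one row per sample: first column sample ids, then
#' one numeric column per feature (header row = feature names). The
#' outcome file is keyed by sample id and carries `class` and/or
#' `time` + `event` columns. Samples present in only one file are dropped
#' with a warning naming them; non-numeric matrix cells and duplicated
#' feature names are errors.
#'
#' @param matrix_path Path to the TSV/CSV expression matrix.
#' @param outcome_path Path to the TSV/CSV outcome table.
#' @return An [mo_dataset()].
#' @export
load_dataset <- function(matrix_path, outcome_path) {
  mat <- read_delim_auto(matrix_path)
  out <- read_delim_auto(outcome_path)
  ids <- as.character(mat[[1]])
  feat_names <- names(mat)[-1]
  dup <- unique(feat_names[duplicated(feat_names)])
  if (length(dup) > 0) {
    stop("duplicated feature names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(x) || anyNA(x)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(x), nrow(x)))),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-numeric matrix cell at sample '", ids[bad[1]], "', feature '",
         feat_names[bad[2]], "'", call. = FALSE)
  }
  rownames(x) <- ids
  out_ids <- as.character(out[[1]])
  common <- intersect(ids, out_ids)
  if (length(common) == 0) {
    stop("no overlapping sample ids between matrix and outcome table",
         call. = FALSE)
  }
  dropped <- setdiff(union(ids, out_ids), common)
  if (length(dropped) > 0) {
    warning("dropped unmatched sample ids: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  x <- x[common, , drop = FALSE]
  out <- out[match(common, out_ids), , drop = FALSE]
  mo_dataset(
    x,
    class = if ("class" %in% names(out)) out$class,
    time = if ("time" %in% names(out)) out$time,
    event = if ("event" %in% names(out)) out$event
  )
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, name_repair = "minimal")
}

#' Write a dataset in the layout [load_dataset()] reads
#'
#' @param data An [mo_dataset()].
#' @param matrix_path,outcome_path Output TSV/CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, matrix_path, outcome_path) {
  mat <- tibble::as_tibble(data$x)
  mat <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(data$x)), mat)
  out <- tibble::tibble(sample_id = rownames(data$x))
  if (!is.null(data$class)) out$class <- as.character(data$class)
  if (!is.null(data$time)) {
    out$time <- data$time
    out$event <- data$event
  }
  write_delim_auto(mat, matrix_path)
  write_delim_auto(out, outcome_path)
  invisible(c(matrix_path, outcome_path))
}

write_delim_auto <- function(df, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
}

#' Serialize a solution set to JSON and CSV
#'
#' One record per solution, ordered by descending fitness in the first
#' objective (ties by fewer features, then feature indices): the selected
#' feature indices and names, and for each objective the expected
#' (adjusted) fitness, its SD, and the held-out fitness when available.
#'
#' @param ss An `mo_solution_set`.
#' @param path Output path; `.json` and `.csv` twins are written with this
#'   stem.
#' @param holdout Optional matrix from [evaluate_on_holdout()] to embed as
#'   the held-out fitness.
#' @return Invisibly, the JSON path.
#' @export
write_solution_set <- function(ss, path, holdout = NULL) {
  stem <- sub("\\.(json|csv)$", "", path)
  tb <- tidy_solutions(ss, holdout)
  ord <- order(-tb$wide[[paste0("fitness_", ss$objectives[[1]]$name)]],
               tb$wide$n_feat,
               tb$wide$features)
  wide <- tb$wide[ord, , drop = FALSE]
  recs <- tb$records[ord]
  jsonlite::write_json(recs, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_csv(wide, paste0(stem, ".csv"))
  invisible(paste0(stem, ".json"))
}

tidy_solutions <- function(ss, holdout = NULL) {
  obj_names <- purrr::map_chr(ss$objectives, "name")
  feat_names <- ss$meta$feature_names
  Xt <- if (!is.null(holdout)) holdout else test_fitness_matrix(ss)
  records <- purrr::imap(ss$solutions, function(sol, i) {
    list(
      feature_indices = sol$features,
      feature_names = if (!is.null(feat_names)) feat_names[sol$features],
      n_features = length(sol$features),
      objectives = purrr::map(seq_along(obj_names), function(j) {
        rec <- list(name = obj_names[j], fitness = sol$fitness[j],
                    sd = sol$sd[j])
        if (!is.na(Xt[i, j])) rec$holdout_fitness <- Xt[i, j]
        rec
      })
    )
  })
  wide <- tibble::tibble(
    n_feat = purrr::map_int(ss$solutions, ~ length(.x$features)),
    features = purrr::map_chr(ss$solutions, ~ paste(.x$features, collapse = ";"))
  )
  for (j in seq_along(obj_names)) {
    wide[[paste0("fitness_", obj_names[j])]] <-
      purrr::map_dbl(ss$solutions, ~ .x$fitness[j])
    wide[[paste0("sd_", obj_names[j])]] <-
      purrr::map_dbl(ss$solutions, ~ .x$sd[j])
    wide[[paste0("holdout_", obj_names[j])]] <- Xt[, j]
  }
  list(records = records, wide = wide)
}

#' Read back a serialized solution set
#'
#' @param path The `.json` file written by [write_solution_set()].
#' @return A tibble with one row per solution and objective.
#' @export
read_solution_set <- function(path) {
  recs <- jsonlite::read_json(path)
  purrr::map_dfr(seq_along(recs), function(i) {
    r <- recs[[i]]
    purrr::map_dfr(r$objectives, function(o) {
      tibble::tibble(
        solution = i,
        n_feat = r$n_features,
        features = paste(unlist(r$feature_indices), collapse = ";"),
        objective = o$name,
        fitness = o$fitness,
        sd = o$sd,
        holdout_fitness = if (!is.null(o$holdout_fitness)) o$holdout_fitness
                          else NA_real_
      )
    })
  })
}

#' Set-level estimation metrics for one train/test fitness pair
#'
#' @param X Expected (train-side) fitness matrix of a solution set.
#' @param X_test Matching held-out fitness matrix.
#' @return Tibble with one row per metric: `mope`, `pareto_delta`, `chv`,
#'   `hv_train`, `hv_test`.
#' @export
set_metrics <- function(X, X_test) {
  tibble::tibble(
    metric = c("mope", "pareto_delta", "chv", "hv_train", "hv_test"),
    value = c(mope(X, X_test), pareto_delta(X, X_test),
              cross_hypervolume(X, X_test), hypervolume(X),
              hypervolume(X_test))
  )
}

#' Run a full comparison experiment
#'
#' Compares adjuster kinds under the evaluation scheme of the config:
#' in `cv` mode the data is split into evaluation folds and, per fold and
#' adjuster, the dual-stage optimizer runs on the training part and its
#' front is measured on the left-out part; in `external` mode the
#' optimizer runs on the full training data and is measured on a holdout
#' dataset. Reported per fold: MOPE, Pareto delta, CHV, and the train/test
#' hypervolumes. The unadjusted baseline `"zero"` is run as the bare
#' genetic algorithm, which is exactly equivalent to the dual stage with a
#' zero adjuster under a shared seed.
#'
#' @param config A named list (or path to a YAML/JSON file) with entries
#'   `dataset` (paths `matrix`, `outcome` — or an [mo_dataset()] under
#'   `data`), optional `holdout` (same form), `objectives` (list of
#'   `list(kind, learner, k_inner, B, cap)`), `optimizer` (arguments of
#'   [optimizer_config()]), `dosa` (`k_outer`, optional `tuning` list),
#'   `adjusters` (character vector of [adjuster_kinds()]),
#'   `evaluation` (`mode` = "cv"/"external", `k`), optional `output_dir`,
#'   and `seed`.
#' @return List with `metrics` (tibble adjuster x fold x metric),
#'   `summary` (mean and SD between folds), and `solution_sets` (nested
#'   list of `mo_solution_set` objects). Files are written when
#'   `output_dir` is set.
#' @export
run_experiment <- function(config) {
  cfg <- resolve_config(config)
  log_event("experiment: resolved config hash %s", rlang::hash(cfg_hashable(cfg)))
  data <- cfg$data
  objectives <- cfg$objective_list
  rows <- list()
  sets <- list()

  eval_one <- function(kind, fold_id, train_data, test_data, run_seed) {
    ss <- if (kind == "zero") {
      cfgm <- cfg$main
      cfgm$seed <- run_seed
      ga_optimize(objectives, train_data, cfgm)
    } else {
      cfgm <- cfg$main
      cfgm$seed <- run_seed
      dcfg <- dosa_config(main = cfgm, tuning = cfg$tuning,
                          k_outer = cfg$k_outer, adjuster_kind = kind,
                          seed = run_seed)
      dosa_optimize(objectives, train_data, dcfg)
    }
    Xt <- evaluate_on_holdout(ss, train_data, test_data, objectives)
    mets <- set_metrics(fitness_matrix(ss), Xt)
    mets$adjuster <- kind
    mets$fold <- fold_id
    list(metrics = mets, ss = ss, holdout = Xt)
  }

  if (cfg$mode == "cv") {
    folds <- create_folds(data, cfg$k_eval, seed = (cfg$seed + 500L) %% 2147480017)
    log_event("experiment: %d evaluation folds, adjusters: %s",
              cfg$k_eval, paste(cfg$adjusters, collapse = ", "))
    for (kind in cfg$adjusters) {
      sets[[kind]] <- list()
      for (f in seq_len(cfg$k_eval)) {
        tr <- dataset_subset(data, fold_train_idx(folds, f))
        te <- dataset_subset(data, fold_test_idx(folds, f))
        res <- eval_one(kind, f, tr, te,
                        run_seed = (cfg$seed + 1000L * f) %% 2147480017)
        rows[[length(rows) + 1]] <- res$metrics
        sets[[kind]][[f]] <- res$ss
        attr(sets[[kind]][[f]], "holdout") <- res$holdout
      }
    }
  } else {
    stopifnot(!is.null(cfg$holdout))
    for (kind in cfg$adjusters) {
      res <- eval_one(kind, 1L, data, cfg$holdout, run_seed = cfg$seed)
      rows[[length(rows) + 1]] <- res$metrics
      sets[[kind]] <- list(res$ss)
      attr(sets[[kind]][[1]], "holdout") <- res$holdout
    }
  }

  metrics <- dplyr::bind_rows(rows)[, c("adjuster", "fold", "metric", "value")]
  summary <- metrics |>
    dplyr::group_by(.data$adjuster, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
                     .groups = "drop")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(cfg$output_dir, "metrics.csv"))
    readr::write_csv(summary, file.path(cfg$output_dir, "summary.csv"))
    for (kind in names(sets)) {
      for (f in seq_along(sets[[kind]])) {
        write_solution_set(
          sets[[kind]][[f]],
          file.path(cfg$output_dir, sprintf("solutions_%s_fold%d.json", kind, f)),
          holdout = attr(sets[[kind]][[f]], "holdout")
        )
        samp <- sets[[kind]][[f]]$meta$adjuster_samples
        if (!is.null(samp)) {
          export_adjuster_samples(
            samp,
            file.path(cfg$output_dir,
                      sprintf("adjuster_samples_%s_fold%d.csv", kind, f)))
        }
      }
    }
    writeLines(mo_log(), file.path(cfg$output_dir, "log.txt"))
    yaml::write_yaml(cfg_hashable(cfg), file.path(cfg$output_dir,
                                                  "config_resolved.yaml"))
  }
  list(metrics = metrics, summary = summary, solution_sets = sets)
}

# turn a raw config (list or file path) into resolved objects
resolve_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  data <- if (!is.null(config$dataset$data)) {
    config$dataset$data
  } else {
    load_dataset(config$dataset$matrix, config$dataset$outcome)
  }
  holdout <- NULL
  mode <- config$evaluation$mode %||% "cv"
  if (mode == "external") {
    if (is.null(config$holdout)) {
      stop("external evaluation requires a holdout dataset", call. = FALSE)
    }
    holdout <- if (!is.null(config$holdout$data)) {
      config$holdout$data
    } else {
      load_dataset(config$holdout$matrix, config$holdout$outcome)
    }
  }
  objective_list <- purrr::map(config$objectives, resolve_objective)
  main <- do.call(optimizer_config,
                  c(config$optimizer %||% list(), list(seed = seed)))
  tuning <- if (!is.null(config$dosa$tuning)) {
    do.call(optimizer_config, c(config$dosa$tuning, list(seed = seed)))
  }
  list(
    data = data, holdout = holdout, objective_list = objective_list,
    main = main, tuning = tuning,
    k_outer = as.integer(config$dosa$k_outer %||% 3L),
    adjusters = config$adjusters %||% c("zero", "dummy"),
    mode = mode,
    k_eval = as.integer(config$evaluation$k %||% 5L),
    output_dir = config$output_dir,
    seed = seed,
    raw = config
  )
}

resolve_objective <- function(o) {
  kind <- o$kind %||% "classification"
  if (kind == "parsimony") {
    return(objective_parsimony(cap = o$cap %||% 100))
  }
  k_inner <- o$k_inner %||% 5
  B <- o$B %||% 100
  if (kind == "classification") {
    learner <- switch(o$learner %||% "nb",
                      nb = learner_nb(),
                      svm = learner_svm_linear(),
                      stop("unknown classifier: ", o$learner, call. = FALSE))
    objective_classification(learner, k_inner = k_inner, B = B)
  } else if (kind == "survival") {
    objective_survival(learner_cox(), k_inner = k_inner, B = B)
  } else {
    stop("unknown objective kind: ", kind, call. = FALSE)
  }
}

# config view that is stable to hash/serialize (drops in-memory objects)
cfg_hashable <- function(cfg) {
  raw <- cfg$raw
  if (!is.null(raw$dataset$data)) raw$dataset <- "<in-memory dataset>"
  if (!is.null(raw$holdout$data)) raw$holdout <- "<in-memory dataset>"
  raw$seed <- cfg$seed
  raw
}
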