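#' Experiment configuration
#'
#' Describes a full experiment: activity classes x model roster x random
#' splits x training-set modifications. Every model inside one
#' class/split cell sees the identical split, so methods are compared on
#' the same data; modifications are applied to the training portion only.
#'
#' @param classes Named list of class sources: `activity_class` objects,
#'   [synthetic_class_config()] objects (generated at run time), or CSV
#'   paths readable by [read_activity_class()].
#' @param models Model roster: a character vector of known names
#'   (`"knn_ensemble"`, `"dt_ensemble"`, `"single_knn"`, `"single_dt"`,
#'   `"ffnn_small_d10"`/`"_d20"`/`"_d50"`, `"ffnn_large_d*"`,
#'   `"mve_small"`, `"mve_large"`) and/or a named list of explicit specs
#'   `list(kind = , config = )`.
#' @param n_splits Number of random splits per class (default 10).
#' @param train_fraction Training fraction per split (default 0.7).
#' @param modifications Character subset of
#'   `c("original", "balanced", "reduced")`.
#' @param scheme A [bin_scheme()] for the bin-wise confidence analysis.
#' @param x Standard-deviation multiple for coverage (default 1.0).
#' @param n_levels Calibration-curve grid size (default 99).
#' @param seed Master seed; all cell-level randomness derives from it.
#' @param profile `"desk"` (small nets, few epochs; minutes on one CPU) or
#'   `"paper"` (full published architectures and epoch counts). The
#'   profile is stamped into every report row.
#' @param optimize Run 5-fold CV hyperparameter optimization per split for
#'   ensemble/kNN models (default `FALSE`: fixed default configurations).
#' @param grids Optional named list of hyperparameter grids per roster
#'   name, used when `optimize = TRUE`.
#' @param out_dir Optional directory for per-cell result files; completed
#'   cells found there are skipped on restart (resumable runs).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(classes, models, n_splits = 10L,
                              train_fraction = 0.7,
                              modifications = "original",
                              scheme = bin_scheme(), x = 1.0,
                              n_levels = 99L, seed = 1L,
                              profile = c("desk", "paper"),
                              optimize = FALSE, grids = NULL,
                              out_dir = NULL) {
  profile <- match.arg(profile)
  if (!length(models)) stop("model roster is empty")
  if (n_splits < 1L) stop("n_splits must be at least 1")
  modifications <- match.arg(modifications,
                             c("original", "balanced", "reduced"),
                             several.ok = TRUE)
  if (is.null(names(classes)) || any(names(classes) == "")) {
    names(classes) <- paste0("class_", seq_along(classes))
  }
  structure(list(classes = classes, models = models,
                 n_splits = as.integer(n_splits),
                 train_fraction = train_fraction,
                 modifications = modifications, scheme = scheme, x = x,
                 n_levels = as.integer(n_levels), seed = as.integer(seed),
                 profile = profile, optimize = isTRUE(optimize),
                 grids = grids, out_dir = out_dir),
            class = "experiment_config")
}

resolve_class <- function(src, name) {
  if (inherits(src, "activity_class")) return(src)
  if (inherits(src, "synthetic_class_config")) {
    return(generate_activity_class(src, class_id = name))
  }
  if (is.character(src)) return(read_activity_class(src, class_id = name))
  stop("unrecognised class source for ", name)
}

resolve_roster <- function(models, profile) {
  specs <- list()
  add <- function(name, kind, config = NULL) {
    specs[[name]] <<- list(name = name, kind = kind, config = config)
  }
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (is.list(m)) {
      nm <- if (!is.null(names(models)) && names(models)[i] != "") {
        names(models)[i]
      } else paste0("model_", i)
      add(nm, m$kind, m$config)
      next
    }
    if (m %in% c("knn_ensemble", "dt_ensemble")) {
      add(m, "ensemble",
          ensemble_config(if (m == "knn_ensemble") "knn" else "dt"))
    } else if (m %in% c("single_knn", "single_dt")) {
      add(m, m)
    } else if (grepl("^ffnn_(small|large)_d(10|20|50)$", m)) {
      parts <- strsplit(m, "_")[[1L]]
      rate <- as.numeric(sub("d", "", parts[3L])) / 100
      add(m, "ffnn", network_config("ffnn", size = parts[2L],
                                    dropout_rate = rate, profile = profile))
    } else if (m %in% c("mve_small", "mve_large")) {
      add(m, "mve", network_config("mve", size = sub("mve_", "", m),
                                   profile = profile))
    } else {
      stop("unknown model roster entry: ", m)
    }
  }
  specs
}

fit_and_predict <- function(spec, train, test, cell_seed, cfg) {
  switch(spec$kind,
    ensemble = {
      config <- spec$config
      if (cfg$optimize) {
        fam <- paste0(config$base_learner, "_ensemble")
        grid <- cfg$grids[[spec$name]]
        config <- optimize_hyperparameters(fam, train, grid = grid,
                                           seed = cell_seed)
        attr(config, "cv_mse") <- NULL
      }
      h <- fit_ensemble(config, train, seed = cell_seed)
      predict_with_uncertainty(h, test)
    },
    single_knn = {
      k <- optimize_hyperparameters("knn", train, seed = cell_seed)
      h <- fit_single_model("knn", train, k_neighbors = as.integer(k))
      predict_with_uncertainty(h, test)
    },
    single_dt = {
      h <- fit_single_model("dt", train, seed = cell_seed)
      predict_with_uncertainty(h, test)
    },
    ffnn = {
      h <- fit_ffnn_dropout(spec$config, train, seed = cell_seed)
      mc_dropout_predict(h, test, seed = cell_seed)
    },
    mve = {
      h <- fit_mve(spec$config, train, seed = cell_seed)
      mve_predict(h, test)
    },
    stop("unknown model kind: ", spec$kind))
}

#' Run a full experiment
#'
#' For every activity class, training-set modification, split and roster
#' model: split the class, modify the training portion, fit, predict the
#' (unmodified) test portion, and record the full metric report plus the
#' bin-wise confidence table. Per-cell failures are caught and recorded in
#' the report without aborting the run. Deterministic given the master
#' seed. With `out_dir` set, completed cells are written to disk and
#' skipped when the run is restarted.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print per-cell progress to stderr (default `FALSE`).
#' @return An `experiment_report`: list with data frames `metrics`
#'   (one row per class/modification/model/split), `bins` (bin-wise
#'   coverage rows) and `failures`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  roster <- resolve_roster(cfg$models, cfg$profile)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  metrics <- list(); bins <- list(); failures <- list()
  for (ci in seq_along(cfg$classes)) {
    cname <- names(cfg$classes)[ci]
    cls <- resolve_class(cfg$classes[[ci]], cname)
    splits <- lapply(seq_len(cfg$n_splits), function(si) {
      split_data(cls, derive_seed(cfg$seed, ci * 1000L + si),
                 cfg$train_fraction)
    })
    for (mod in cfg$modifications) {
      for (si in seq_len(cfg$n_splits)) {
        train <- apply_modification(
          training_portion(cls, splits[[si]]),
          modification_scheme(mod, seed = derive_seed(cfg$seed, si)))
        test <- test_portion(cls, splits[[si]])
        for (mi in seq_along(roster)) {
          spec <- roster[[mi]]
          tag <- paste(cname, mod, spec$name, si, sep = "_")
          cell_file <- if (!is.null(cfg$out_dir)) {
            file.path(cfg$out_dir, paste0("metrics_", tag, ".csv"))
          }
          if (!is.null(cell_file) && file.exists(cell_file)) {
            metrics[[tag]] <- read.csv(cell_file, stringsAsFactors = FALSE,
                                       colClasses = c(split = "character"))
            bf <- file.path(cfg$out_dir, paste0("bins_", tag, ".csv"))
            if (file.exists(bf)) {
              bins[[tag]] <- read.csv(bf, stringsAsFactors = FALSE)
            }
            next
          }
          cell_seed <- derive_seed(cfg$seed,
                                   ((ci * 7L + mi) * 13L + si) * 17L +
                                     match(mod, cfg$modifications))
          t0 <- proc.time()[["elapsed"]]
          res <- tryCatch({
            ps <- fit_and_predict(spec, train, test, cell_seed, cfg)
            row <- uq_report(ps, class_id = cname, model = spec$name,
                             split = as.character(si),
                             n_levels = cfg$n_levels)
            row$modification <- mod
            row$profile <- cfg$profile
            bc <- if (has_uncertainty(ps)) {
              b <- as.data.frame(binwise_coverage(ps, cfg$scheme, cfg$x))
              attr(b, "x") <- NULL
              b$class <- cname; b$model <- spec$name
              b$split <- as.character(si); b$modification <- mod
              b
            }
            list(row = row, bc = bc)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failures[[tag]] <- data.frame(
              class = cname, modification = mod, model = spec$name,
              split = as.character(si),
              message = conditionMessage(res), stringsAsFactors = FALSE)
            if (verbose) {
              message(sprintf("[%s] FAILED: %s", tag, conditionMessage(res)))
            }
            next
          }
          metrics[[tag]] <- res$row
          if (!is.null(res$bc)) bins[[tag]] <- res$bc
          if (!is.null(cell_file)) {
            write.csv(res$row, cell_file, row.names = FALSE)
            if (!is.null(res$bc)) {
              write.csv(res$bc,
                        file.path(cfg$out_dir, paste0("bins_", tag, ".csv")),
                        row.names = FALSE)
            }
          }
          if (verbose) {
            message(sprintf("[%s] done in %.1fs", tag,
                            proc.time()[["elapsed"]] - t0))
          }
        }
      }
    }
  }
  rbind_all <- function(lst) {
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, c(lst, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
  }
  structure(list(metrics = rbind_all(metrics), bins = rbind_all(bins),
                 failures = rbind_all(failures), config = cfg),
            class = "experiment_report")
}

#' Aggregate an experiment report
#'
#' Median and quartiles of every metric per model (pooled over classes and
#' splits by default, or stratified by class), in a long boxplot-ready
#' table.
#'
#' @param report An `experiment_report`, or its `metrics` data frame.
#' @param by Grouping columns (default `c("model", "modification")`; add
#'   `"class"` for per-class aggregates).
#' @return Data frame with columns `by`..., `metric`, `median`, `q1`, `q3`,
#'   `n`.
#' @export
summarize_experiment <- function(report,
                                 by = c("model", "modification")) {
  df <- if (inherits(report, "experiment_report")) report$metrics else report
  if (is.null(df) || !nrow(df)) stop("empty report")
  by <- intersect(by, names(df))
  metric_cols <- intersect(c("mse", "r2", "nll", "A", "A_abs", "rho"),
                           names(df))
  groups <- split(df, df[by], drop = TRUE)
  rows <- lapply(groups, function(g) {
    do.call(rbind, lapply(metric_cols, function(mc) {
      v <- g[[mc]][!is.na(g[[mc]])]
      cbind(g[1L, by, drop = FALSE],
            data.frame(metric = mc,
                       median = if (length(v)) median(v) else NA_real_,
                       q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
                       q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
                       n = length(v), stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write / read an experiment report
#'
#' Serialises the report tables (`metrics.csv`, `bins.csv`,
#' `failures.csv`) to a directory; reading the directory back restores the
#' tables.
#'
#' @param report An `experiment_report`.
#' @param dir Directory path.
#' @return `dir` invisibly (writer); an `experiment_report` without the
#'   config echo (reader).
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("metrics", "bins", "failures")) {
    if (!is.null(report[[tab]]) && nrow(report[[tab]])) {
      write.csv(report[[tab]], file.path(dir, paste0(tab, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_experiment_report
#' @export
read_experiment_report <- function(dir) {
  get_tab <- function(tab) {
    f <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(f)) return(NULL)
    read.csv(f, stringsAsFactors = FALSE,
             colClasses = c(split = "character"))
  }
  structure(list(metrics = get_tab("metrics"), bins = get_tab("bins"),
                 failures = get_tab("failures"), config = NULL),
            class = "experiment_report")
}
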