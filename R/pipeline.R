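#' GCV-driven scan of the moving-average order Q
#'
#' Fits the forecaster for every candidate Q on the earlier part of the
#' training rows and scores each on a chronological holdout (the last
#' `1 - inner_fraction` of the training rows — the test set is never
#' touched). The score is the holdout RMSE inflated by the GCV penalty
#' on the fitted parameter count K + Q, \eqn{RMSE/(1 - (K+Q)/N_h)^2};
#' penalising only the (constant) regressor width K would reduce the
#' scan to plain holdout RMSE. Ties are broken toward the smaller Q.
#'
#' @param train a `regressor_set` of training rows.
#' @param Q_range candidate orders (default 1:18).
#' @param fitter function `(train, q) -> list(predict = function(test)
#'   numeric)`; defaults to the linear + MA(q) errors model.
#' @param inner_fraction fraction of training rows used for the inner
#'   fits (default 0.85).
#' @return list with `Q` (chosen order) and `table` (data.frame of `Q`,
#'   `rmse`, `gcv`; failed fits carry `NA`).
#' @export
gcv_scan <- function(train, Q_range = 1:18, fitter = NULL,
                     inner_fraction = 0.85) {
  stopifnot(inherits(train, "regressor_set"))
  if (length(Q_range) == 0L) stop("empty Q range", call. = FALSE)
  Q_range <- sort(unique(as.integer(Q_range)))
  if (is.null(fitter)) {
    fitter <- function(tr, q) {
      fit <- fit_linear_ma(tr, Q = q)
      list(predict = function(te) forecast_one_step(fit, te)$predicted)
    }
  }
  parts <- split_train_test(train, inner_fraction)
  inner <- parts$train
  hold <- parts$test
  Nh <- length(hold$y)
  K <- train$K
  rmse <- gcv <- rep(NA_real_, length(Q_range))
  errs <- character(0)
  for (i in seq_along(Q_range)) {
    q <- Q_range[i]
    res <- tryCatch({
      f <- fitter(inner, q)
      pred <- f$predict(hold)
      sqrt(mean((hold$y - pred)^2))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("Q=%d: %s", q, conditionMessage(res)))
    } else {
      rmse[i] <- res
      pen <- 1 - (K + q) / Nh
      gcv[i] <- if (pen > 0) res / pen^2 else NA_real_
    }
  }
  if (all(is.na(gcv))) {
    stop("all GCV-scan fits failed:\n", paste(errs, collapse = "\n"),
         call. = FALSE)
  }
  best <- Q_range[which.min(gcv)]   # ascending order: first min = smallest Q
  list(Q = best, table = data.frame(Q = Q_range, rmse = rmse, gcv = gcv))
}

#' Experiment configuration
#'
#' Collects every tunable of the two-stage pipeline. Exactly one of
#' `series` (numeric vector), `input` (CSV path) or `synthetic` (list of
#' [generate_accident_series()] arguments; an empty list uses its
#' defaults) supplies the data.
#'
#' @param series numeric series, or `NULL`.
#' @param input CSV path (see [read_series()]), or `NULL`.
#' @param synthetic list of generator arguments, or `NULL`.
#' @param smoothing subset of `c("ma3", "hsvd")`.
#' @param models subset of `c("arima", "ann-pso", "ann-rprop")`.
#' @param P lag order (regressor lags per component).
#' @param D differencing order applied to the (scaled) series before
#'   smoothing; 0 or 1 supported by the pipeline.
#' @param M number of HSVD components.
#' @param Q named vector of MA-error orders per smoothing for the linear
#'   model (default `c(ma3 = 10, hsvd = 11)`).
#' @param hidden named vector of hidden-node counts per smoothing for
#'   the networks (default `c(ma3 = 10, hsvd = 11)`).
#' @param q_scan candidate Q range for [gcv_scan()], or `NULL` to use
#'   the fixed `Q`.
#' @param runs stochastic-trainer repetitions; the run with the best
#'   training fitness is kept (default 30).
#' @param seed_base integer seed; run r of a stochastic trainer uses
#'   seed `seed_base + offset + r` (all below 2^31).
#' @param train_fraction chronological split fraction (default 0.85).
#' @param scaling `"minmax"` (training-portion extremes, default) or
#'   `"none"`.
#' @param hsvd_lag_mode `"both"` (K = 2P) or `"shared"` (K = P).
#' @param pso,rprop trainer configurations (seeds are overridden per
#'   run).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(series = NULL, input = NULL, synthetic = NULL,
                              smoothing = c("ma3", "hsvd"),
                              models = c("arima", "ann-pso", "ann-rprop"),
                              P = 9, D = 0, M = 2,
                              Q = c(ma3 = 10, hsvd = 11),
                              hidden = c(ma3 = 10, hsvd = 11),
                              q_scan = NULL, runs = 30, seed_base = 1,
                              train_fraction = 0.85,
                              scaling = c("minmax", "none"),
                              hsvd_lag_mode = c("both", "shared"),
                              pso = pso_config(), rprop = rprop_config(),
                              out_dir = NULL) {
  scaling <- match.arg(scaling)
  hsvd_lag_mode <- match.arg(hsvd_lag_mode)
  bad <- setdiff(smoothing, c("ma3", "hsvd"))
  if (length(bad)) stop("unknown smoothing id: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(models, c("arima", "ann-pso", "ann-rprop"))
  if (length(bad)) stop("unknown model id: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(models) == 0L || length(smoothing) == 0L) {
    stop("need at least one smoothing and one model", call. = FALSE)
  }
  if (sum(!vapply(list(series, input, synthetic), is.null, logical(1))) != 1L) {
    stop("supply exactly one of series, input, synthetic", call. = FALSE)
  }
  if (!is.null(q_scan) && (min(q_scan) < 1 || max(q_scan) > 30)) {
    stop("q_scan must lie within [1, 30]", call. = FALSE)
  }
  structure(
    list(series = series, input = input, synthetic = synthetic,
         smoothing = smoothing, models = models,
         P = validate_count(P, 1L), D = validate_count(D, 0L),
         M = validate_count(M, 2L), Q = Q, hidden = hidden,
         q_scan = q_scan, runs = validate_count(runs, 1L),
         seed_base = validate_count(seed_base, 0L),
         train_fraction = train_fraction, scaling = scaling,
         hsvd_lag_mode = hsvd_lag_mode, pso = pso, rprop = rprop,
         out_dir = out_dir),
    class = "experiment_config"
  )
}

smoothing_label <- function(s) c(ma3 = "MA", hsvd = "HSVD")[[s]]

model_label <- function(smoothing, model, P, D, Q, hidden) {
  sl <- smoothing_label(smoothing)
  switch(model,
         "arima" = sprintf("%s-ARIMA(%d,%d,%d)", sl, P, D, Q),
         "ann-pso" = sprintf("%s-ANN-PSO(%d,%d,1)", sl, P, hidden),
         "ann-rprop" = sprintf("%s-ANN-RPROP(%d,%d,1)", sl, P, hidden))
}

# best-of-`runs` stochastic training, seeded seed_base + offset + run
best_of_runs <- function(trainer, train, K, Q, base_cfg, runs, seed_base,
                         offset) {
  best <- NULL
  fitness <- numeric(runs)
  for (r in seq_len(runs)) {
    cfg_r <- base_cfg
    cfg_r$seed <- derive_seed(seed_base, offset + r)
    out <- trainer(train, K, Q, cfg_r)
    fitness[r] <- out$rmse
    if (is.null(best) || out$rmse < best$rmse) {
      best <- out
      best$run <- r
    }
  }
  best$run_fitness <- fitness
  best
}

#' Run the full smoothing-by-forecaster experiment
#'
#' For every (smoothing, model) combination: scale the series with
#' training-portion extremes, difference if requested, smooth or
#' decompose, build lagged regressors, split chronologically, optionally
#' choose the MA order by [gcv_scan()], fit (stochastic trainers: best
#' training fitness over `runs` seeded repetitions), forecast the test
#' rows one step ahead with teacher forcing, and evaluate (metrics,
#' relative-error bands, residual ACF). All fitted models are then
#' compared pairwise with [pitman_test()]. Fully reproducible from
#' (config, seed_base); when `out_dir` is set, `metrics.csv`,
#' `pitman.csv`, `report.json`, `runs/*.csv` and `predictions/*.csv`
#' are written there.
#'
#' @param cfg an `experiment_config`.
#' @return list of class `experiment_report` with `models` (per-model
#'   list: label, metrics, chosen_q, acf, forecast, trace, run
#'   fitnesses), `pitman` (matrix of correlations, antisymmetric),
#'   `pitman_threshold`, `config`, `version`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  x <- if (!is.null(cfg$series)) {
    validate_series(cfg$series, min_len = 10L, arg = "series")
  } else if (!is.null(cfg$input)) {
    read_series(cfg$input)
  } else {
    args <- cfg$synthetic
    if (is.null(args$seed)) args$seed <- derive_seed(cfg$seed_base, 777L)
    do.call(generate_accident_series, args)
  }
  x <- as.numeric(x)
  n <- length(x)

  scale_params <- NULL
  xs <- x
  if (cfg$scaling == "minmax") {
    n_train_raw <- floor(cfg$train_fraction * n)
    scale_params <- list(min = min(x[seq_len(n_train_raw)]),
                         max = max(x[seq_len(n_train_raw)]))
    xs <- scale_minmax(x, scale_params)$values
  }
  if (cfg$D > 0L) {
    if (cfg$D > 1L) stop("the pipeline supports D in {0, 1}", call. = FALSE)
    xs <- difference(xs, cfg$D)
  }

  results <- list()
  for (sm in cfg$smoothing) {
    if (sm == "ma3") {
      smoothed <- moving_average_3(xs)
      rs <- build_regressors_ma(smoothed, xs, cfg$P)
      decomposition <- NULL
    } else {
      decomposition <- hsvd_decompose(xs, cfg$M)
      rs <- build_regressors_hsvd(decomposition$low, decomposition$high, xs,
                                  cfg$P, mode = cfg$hsvd_lag_mode)
    }
    parts <- split_train_test(rs, cfg$train_fraction)
    for (mod in cfg$models) {
      chosen_q <- NA_integer_
      trace <- NULL
      run_fitness <- NULL
      best_run <- NA_integer_
      if (mod == "arima") {
        chosen_q <- if (!is.null(cfg$q_scan)) {
          gcv_scan(parts$train, cfg$q_scan)$Q
        } else {
          as.integer(cfg$Q[[sm]])
        }
        fit <- fit_linear_ma(parts$train, Q = chosen_q)
        fc <- forecast_one_step(fit, parts$test)
        label <- model_label(sm, mod, cfg$P, cfg$D, chosen_q, NA)
      } else {
        nh <- as.integer(cfg$hidden[[sm]])
        trainer <- if (mod == "ann-pso") train_pso else train_rprop
        base_cfg <- if (mod == "ann-pso") cfg$pso else cfg$rprop
        offset <- if (mod == "ann-pso") 10000L else 20000L
        offset <- offset + 1000L * match(sm, c("ma3", "hsvd"))
        best <- best_of_runs(trainer, parts$train, rs$K, nh, base_cfg,
                             cfg$runs, cfg$seed_base, offset)
        pred <- ann_forward(best$weights, parts$test$X)
        fc <- list(predicted = pred, observed = parts$test$y,
                   errors = parts$test$y - pred, Nv = length(pred), K = rs$K)
        trace <- best$trace
        run_fitness <- best$run_fitness
        best_run <- best$run
        label <- model_label(sm, mod, cfg$P, cfg$D, NA, nh)
      }
      metrics <- forecast_metrics(fc$observed, fc$predicted, rs$K)
      acf_rep <- acf_with_bounds(fc$errors,
                                 max_lag = min(20L, fc$Nv - 1L))
      results[[label]] <- list(
        label = label, smoothing = sm, model = mod, K = rs$K,
        chosen_q = chosen_q, metrics = metrics, acf = acf_rep,
        forecast = fc, trace = trace, run_fitness = run_fitness,
        best_run = best_run,
        t_index = parts$test$t_index
      )
    }
  }

  labels <- names(results)
  nm <- length(labels)
  pit <- matrix(NA_real_, nm, nm, dimnames = list(labels, labels))
  thr <- NA_real_
  for (i in seq_len(nm)) {
    for (j in seq_len(nm)) {
      if (i == j) next
      pt <- pitman_test(results[[i]]$forecast$errors,
                        results[[j]]$forecast$errors)
      pit[i, j] <- pt$corr
      thr <- pt$threshold
    }
  }

  report <- structure(
    list(models = results, pitman = pit, pitman_threshold = thr,
         scale_params = scale_params,
         config = cfg,
         version = as.character(utils::packageVersion("hankelcast"))),
    class = "experiment_report"
  )
  if (!is.null(cfg$out_dir)) write_experiment_report(report, cfg$out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment:", length(x$models), "fitted models\n")
  for (m in x$models) {
    cat(sprintf("  %-24s RMSE %.5g  GCV %.5g  MAPE %.4g%%  %s\n",
                m$label, m$metrics$rmse, m$metrics$gcv,
                m$metrics$mape_percent,
                if (m$acf$white) "residuals white" else "serial correlation"))
  }
  invisible(x)
}

metrics_table <- function(report) {
  do.call(rbind, lapply(report$models, function(m) {
    data.frame(model = m$label, rmse = m$metrics$rmse, gcv = m$metrics$gcv,
               mape = m$metrics$mape_percent, re_sum = m$metrics$re_sum,
               K = m$K, Nv = m$metrics$Nv, residuals_white = m$acf$white,
               stringsAsFactors = FALSE)
  }))
}

# serialisable (plain-list) view of the report, used for report.json and
# for determinism comparisons
report_to_list <- function(report) {
  list(
    version = report$version,
    config = list(
      smoothing = report$config$smoothing, models = report$config$models,
      P = report$config$P, D = report$config$D, M = report$config$M,
      Q = as.list(report$config$Q), hidden = as.list(report$config$hidden),
      runs = report$config$runs, seed_base = report$config$seed_base,
      train_fraction = report$config$train_fraction,
      scaling = report$config$scaling,
      hsvd_lag_mode = report$config$hsvd_lag_mode
    ),
    pitman_threshold = report$pitman_threshold,
    pitman = as.data.frame(report$pitman),
    models = lapply(report$models, function(m) {
      list(label = m$label, smoothing = m$smoothing, model = m$model,
           K = m$K, chosen_q = m$chosen_q, best_run = m$best_run,
           rmse = m$metrics$rmse, gcv = m$metrics$gcv,
           mape_percent = m$metrics$mape_percent,
           re_sum = m$metrics$re_sum, Nv = m$metrics$Nv,
           residuals_white = m$acf$white,
           acf = m$acf$coefficients, acf_limit = m$acf$conf_limit)
    })
  )
}

write_experiment_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "runs"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "predictions"), showWarnings = FALSE)
  # model labels contain commas: keep default quoting
  utils::write.csv(metrics_table(report), file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  pit <- as.data.frame(report$pitman)
  pit <- cbind(model = rownames(report$pitman), pit)
  utils::write.csv(pit, file.path(out_dir, "pitman.csv"), row.names = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in report$models) {
    safe <- gsub("[^A-Za-z0-9_-]+", "_", m$label)
    utils::write.csv(
      data.frame(period = m$t_index, observed = m$forecast$observed,
                 predicted = m$forecast$predicted, error = m$forecast$errors),
      file.path(out_dir, "predictions", paste0(safe, ".csv")),
      row.names = FALSE, quote = FALSE)
    if (!is.null(m$trace)) {
      utils::write.csv(
        data.frame(iteration = seq_along(m$trace) - 1L, fitness = m$trace),
        file.path(out_dir, "runs", paste0(safe, ".csv")),
        row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out_dir)
}
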