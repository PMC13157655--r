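# ---------------------------------------------------------------------------
# Experiment orchestration: cohort training, evaluation criteria, bundles.
# ---------------------------------------------------------------------------

#' Completion and accuracy criteria from a trial log
#'
#' Completion is the fraction of trials finished without a fixation break
#' and with a response inside the window; accuracy is the fraction of
#' completed trials on which the chosen slot had the maximum expected
#' offer value.
#'
#' @param trials Trial-log data.frame.
#' @return List with \code{completion}, \code{accuracy}, \code{n_trials}.
#' @export
evaluate_criteria <- function(trials) {
  list(completion = mean(trials$completed),
       accuracy = mean(trials$correct[trials$completed]),
       n_trials = nrow(trials))
}

#' Construct an experiment manifest
#'
#' @param name Experiment label.
#' @param tasks Character vector of task names (trained concurrently).
#' @param seeds Integer seeds, one network per seed (must be unique).
#' @param rho Intrinsic values for goods A-E.
#' @param n Network size.
#' @param total_steps Training budget per network (environment steps).
#' @param eval_trials Held-out trials for the criteria check.
#' @param constrained Constrained (orthogonal) offer sampling for risky.
#' @param analyses Character subset of \code{c("behavior", "dimensionality")}.
#' @param out_dir Output directory (created on demand); \code{NULL}
#'   disables writing.
#' @return List of class \code{experiment_manifest}.
#' @export
experiment_manifest <- function(name, tasks, seeds, rho = goods_default(),
                                n = 60, total_steps = 2e6,
                                eval_trials = 1000, constrained = FALSE,
                                analyses = character(),
                                out_dir = NULL) {
  stopifnot(!anyDuplicated(seeds), all(tasks %in% TASK_NAMES))
  structure(list(name = name, tasks = tasks, seeds = as.integer(seeds),
                 rho = rho, n = n, total_steps = total_steps,
                 eval_trials = eval_trials, constrained = constrained,
                 analyses = analyses, out_dir = out_dir),
            class = "experiment_manifest")
}

manifest_hash <- function(manifest) {
  m <- manifest; m$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(m), f)
  unname(tools::md5sum(f))
}

#' Run an experiment manifest
#'
#' Trains one network per seed on the manifest's tasks, evaluates the
#' performance criteria, runs the requested analyses, and returns (and
#' optionally writes) the results bundle. When an output directory
#' already contains a bundle with the same manifest hash, it is loaded
#' instead of recomputed (idempotence).
#'
#' @param manifest An \code{experiment_manifest}.
#' @param verbose Print progress.
#' @return List of class \code{results_bundle}: per-network entries
#'   (net, evaluation, fits) plus the manifest and its hash.
#' @export
run_experiment <- function(manifest, verbose = FALSE) {
  hash <- manifest_hash(manifest)
  if (!is.null(manifest$out_dir)) {
    cache <- file.path(manifest$out_dir, paste0(manifest$name, "_bundle.rds"))
    if (file.exists(cache)) {
      bundle <- readRDS(cache)
      if (identical(bundle$hash, hash)) return(bundle)
    }
  }
  specs <- lapply(manifest$tasks, function(tn)
    task_spec(tn, rho = manifest$rho,
              constrained = manifest$constrained && tn == "risky"))
  networks <- list()
  for (seed in manifest$seeds) {
    set.seed(seed)
    net <- init_network(network_config(n = manifest$n))
    res <- try(train_network(net, specs, total_steps = manifest$total_steps,
                             eval_trials = manifest$eval_trials,
                             verbose = verbose), silent = TRUE)
    if (inherits(res, "try-error")) {
      networks[[as.character(seed)]] <- list(seed = seed, error = res)
      next
    }
    entry <- list(seed = seed, net = res$net, history = res$history,
                  criteria_met = res$criteria_met, steps = res$steps)
    set.seed(seed + 10000L)
    ev <- evaluate_network(res$net, specs,
                           n_trials = manifest$eval_trials, log = TRUE)
    entry$evaluation <- ev[c("completion", "accuracy", "per_task")]
    if ("behavior" %in% manifest$analyses) {
      entry$fits <- lapply(manifest$tasks, function(tn) {
        d <- ev$trials[ev$trials$task == tn, , drop = FALSE]
        try(fit_behavior(d, tn), silent = TRUE)
      })
      names(entry$fits) <- manifest$tasks
    }
    if ("dimensionality" %in% manifest$analyses) {
      entry$pr <- vapply(specs, function(sp) {
        rec <- collect_rates(res$net, sp, n_trials = 300)
        participation_ratio(offer_window(rec))
      }, numeric(1))
      names(entry$pr) <- manifest$tasks
    }
    networks[[as.character(seed)]] <- entry
  }
  bundle <- structure(list(manifest = manifest, hash = hash,
                           networks = networks),
                      class = "results_bundle")
  if (!is.null(manifest$out_dir)) {
    dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(bundle, file.path(manifest$out_dir,
                              paste0(manifest$name, "_bundle.rds")))
  }
  bundle
}

#' Write a trial log as CSV
#' @param trials Trial-log data.frame.
#' @param path Output path.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial log CSV
#' @param path CSV written by \code{write_trial_log}.
#' @return data.frame.
#' @export
read_trial_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a behavioral fit as JSON
#' @param fit \code{behavior_fit}.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
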