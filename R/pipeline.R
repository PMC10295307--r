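#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end channel-optimization pipeline
#' with sensible defaults at a desk scale. The full configuration (including
#' defaults) is serialized into the run manifest of [run_pipeline()].
#'
#' @param n_participants,n_trials,n_channels,n_samples,informative_channels,effect_size,per_participant_jitter,noise_correlation,n_periods
#'   Synthetic-data settings, see [generate_participant_group()]. Ignored
#'   when `data_dir` is given.
#' @param data_dir Optional directory of [write_trialset()] outputs to
#'   analyse instead of simulating; all `*_meta.json` stems found are read
#'   and grouped by participant.
#' @param participants Optional participant ids that must be present in
#'   `data_dir` (a missing one aborts with its name).
#' @param n_repeats_store Random splits per period used to build weight
#'   stores.
#' @param n_repeats_eval Random splits used by the decoding-queue
#'   evaluation.
#' @param train_fraction Training fraction of each split.
#' @param intervals Counting-interval fractions to rank with.
#' @param rank_interval Interval fraction whose group ranking is evaluated
#'   in the decoding queue.
#' @param k_max Longest decoding queue evaluated.
#' @param prune_threshold,max_iter,tol Classifier settings, see
#'   [fit_slr_var()].
#' @param seed Master seed for every random stage.
#' @param figures Also write topographic maps (SVG; requires cairo support).
#' @return A named list of class `slrco_config`.
#' @export
slrco_config <- function(n_participants = 2, n_trials = 40, n_channels = 8,
                         n_samples = 16, informative_channels = c(2, 5),
                         effect_size = 2, per_participant_jitter = 0.2,
                         noise_correlation = 0.3, n_periods = 1,
                         data_dir = NULL, participants = NULL,
                         n_repeats_store = 3, n_repeats_eval = 3,
                         train_fraction = 0.8,
                         intervals = c(1, 0.5, 0.25), rank_interval = 0.25,
                         k_max = NULL, prune_threshold = 1e8,
                         max_iter = 500, tol = 1e-6, seed = 1,
                         figures = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "slrco_config"
  cfg
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the channel-optimization pipeline end to end
#'
#' Executes simulate (or load) -> fit weight stores -> rank channels
#' (individual and group, all configured counting intervals) -> correlation
#' baseline -> decoding-queue evaluation of the group and baseline rankings
#' -> reports. Every artifact is written to `out_dir` as TSV/JSON together
#' with a manifest carrying the full configuration, its hash, package
#' version and stage timings; two runs with the same configuration produce
#' byte-identical TSVs.
#'
#' @param config An [slrco_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results: `stores`,
#'   `rankings` (individual), `group_rankings`, `ccs_ranking`, `curves`,
#'   `optimal`, `common`, `manifest`.
#' @export
run_pipeline <- function(config = slrco_config(), out_dir) {
  stopifnot(inherits(config, "slrco_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- pipeline_stage(stage, expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  fit_args <- list(
    prune_threshold = config$prune_threshold,
    max_iter = config$max_iter, tol = config$tol
  )

  group <- tick("simulate", {
    if (!is.null(config$data_dir)) {
      load_participant_dir(config$data_dir, config$participants)
    } else {
      generate_participant_group(
        n_participants = config$n_participants, n_trials = config$n_trials,
        n_channels = config$n_channels, n_samples = config$n_samples,
        shared_informative_channels = config$informative_channels,
        effect_size = config$effect_size,
        per_participant_jitter = config$per_participant_jitter,
        noise_correlation = config$noise_correlation,
        n_periods = config$n_periods, seed = config$seed
      )
    }
  })
  pids <- vapply(group, function(g) g$trialsets[[1]]$participant_id, character(1))

  stores <- tick("fit", {
    purrr::map(group, function(g) {
      fit_weight_store(g$trialsets,
        n_repeats = config$n_repeats_store,
        train_fraction = config$train_fraction,
        seed = config$seed, fit_args = fit_args
      )$store
    })
  })

  interval_names <- vapply(
    config$intervals,
    function(f) interval_name_of(f), character(1)
  )
  rankings <- tick("rank", {
    res <- purrr::map(seq_along(stores), function(i) {
      rks <- purrr::map(config$intervals, function(f) rank_store(stores[[i]], f))
      names(rks) <- interval_names
      purrr::iwalk(rks, function(rk, nm) {
        write_ranking(rk, file.path(out_dir, sprintf(
          "ranking_individual_%s_%s.tsv", pids[i], nm
        )))
      })
      rks
    })
    names(res) <- pids
    res
  })

  group_store <- pool_group(stores)
  group_rankings <- tick("rank-group", {
    rks <- purrr::map(config$intervals, function(f) rank_store(group_store, f))
    names(rks) <- interval_names
    purrr::iwalk(rks, function(rk, nm) {
      write_ranking(rk, file.path(out_dir, sprintf("ranking_group_%s.tsv", nm)))
    })
    rks
  })

  ccs_ranking <- tick("ccs", {
    profiles <- purrr::map(group, function(g) pairwise_pearson(g$trialsets))
    rk <- ccs_rank(profiles)
    write_ranking(rk, file.path(out_dir, "ranking_ccs.tsv"))
    rk
  })

  eval_interval <- interval_name_of(config$rank_interval)
  datasets <- purrr::map(group, "trialsets")
  curves <- tick("evaluate", {
    cv <- list(
      slrco = evaluate_ranking(group_rankings[[eval_interval]], datasets,
        n_repeats = config$n_repeats_eval,
        train_fraction = config$train_fraction,
        k_max = config$k_max, seed = config$seed, fit_args = fit_args
      ),
      ccs = evaluate_ranking(ccs_ranking, datasets,
        n_repeats = config$n_repeats_eval,
        train_fraction = config$train_fraction,
        k_max = config$k_max, seed = config$seed, fit_args = fit_args
      )
    )
    purrr::iwalk(cv, function(curve, nm) {
      write_curve(curve, file.path(out_dir, sprintf("curve_%s.tsv", nm)))
    })
    cv
  })
  optimal <- purrr::map(curves, optimal_queue)

  common <- tick("report", {
    cc <- common_channels(
      purrr::map(rankings, eval_interval),
      m = optimal$slrco$k_star
    )
    write.table(as.data.frame(cc), file.path(out_dir, "common_channels.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    if (isTRUE(config$figures) && capabilities("cairo")) {
      counts <- count_per_channel(
        group_store,
        interval_bound(group_store, config$rank_interval)
      )
      fig <- plot_topomap(counts, highlight = cc$channel_name)
      grDevices::svg(file.path(out_dir, "topomap_group.svg"), width = 6, height = 6)
      print(fig)
      grDevices::dev.off()
    }
    cc
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("slrco")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    participants = pids,
    optimal = list(
      slrco = optimal$slrco[c("k_star", "mean_acc", "sd_acc")],
      ccs = optimal$ccs[c("k_star", "mean_acc", "sd_acc")]
    ),
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )

  invisible(list(
    stores = stores, rankings = rankings, group_rankings = group_rankings,
    ccs_ranking = ccs_ranking, curves = curves, optimal = optimal,
    common = common, manifest = manifest
  ))
}

interval_name_of <- function(fraction) {
  switch(as.character(fraction),
    "1" = "full", "0.5" = "top50", "0.25" = "top25",
    sprintf("top%g", 100 * fraction)
  )
}

load_participant_dir <- function(data_dir, participants = NULL) {
  metas <- list.files(data_dir, pattern = "_meta\\.json$", full.names = TRUE)
  if (!length(metas)) abort(sprintf("no trial sets found in '%s'.", data_dir))
  stems <- sub("_meta\\.json$", "", metas)
  tsets <- purrr::map(stems, read_trialset)
  pids <- vapply(tsets, function(t) t$participant_id, character(1))
  if (!is.null(participants)) {
    missing <- setdiff(participants, unique(pids))
    if (length(missing)) {
      abort(sprintf(
        "data for participant(s) %s missing from '%s'.",
        paste(missing, collapse = ", "), data_dir
      ))
    }
  }
  purrr::map(split(tsets, pids), function(ts) {
    ord <- order(vapply(ts, function(t) t$period_id, integer(1)))
    list(trialsets = ts[ord], truth = NULL)
  })
}
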