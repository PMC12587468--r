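#' Load and validate a pipeline configuration
#'
#' YAML configuration covering every stage of the workflow. Unspecified
#' fields fall back to the package defaults (2 s windows, 20 MAD outlier
#' threshold, 30 Hz high-pass, 512-sample Welch segments, 54.7 Hz cap,
#' mu grid 1e-1/1e-2/1e-3, k = 10 smoothing, display alpha 0.01).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    out_dir = "electosleep-run",
    seed = 1L,
    cohort = list(),
    features = list(window_s = 2, segment_samples = 512L, f_max = 54.7,
                    mad_multiplier = 20, highpass_hz = 30),
    labels = list(method = "truth", reference_region = "CxPrL"),
    sae = list(mu = 1e-2, epochs = 200L, batch_size = 256L,
               learning_rate = 1e-3, n_latent = 32L),
    smoothing = list(k = 10L, smoothing_constant = 1),
    comparison = list(alpha_display = 0.01, groups = NULL)
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (!config$labels$method %in% c("truth", "statemap")) {
    stop("labels.method must be 'truth' or 'statemap'", call. = FALSE)
  }
  class(config) <- c("pipeline_config", "list")
  config
}

stage_order <- function() {
  c("simulate", "features", "label", "train", "predict", "smooth",
    "architecture", "compare")
}

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  unname(tools::md5sum(paths))
}

#' Run the full synthetic-cohort workflow
#'
#' Executes the requested stages in dependency order: simulate a cohort,
#' extract feature tensors, produce labels (ground truth or the EMG
#' state-map labeler), train the supervised autoencoder, predict
#' hypnograms, smooth them with top-k Viterbi, compute architecture
#' statistics, and (when a grouping is configured) compare conditions.
#' Every stage writes its outputs under `out_dir` and records input/output
#' hashes in `manifest.json`; a stage whose recorded input hashes are
#' unchanged and whose outputs exist is skipped as up-to-date.
#'
#' @param config A [pipeline_config()] (or path / list accepted by it).
#' @param stages Subset of stages to run (default: all applicable).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = stage_order()) {
  cfg <- pipeline_config(config)
  stages <- match.arg(stages, stage_order(), several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else list(package = "electosleep", stages = list())
  cfg_plain <- rapply(unclass(cfg), unclass, how = "replace")
  cfg_hash <- digest_string(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE,
                                             digits = NA, force = TRUE,
                                             null = "null"))
  manifest$config_hash <- cfg_hash
  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  n_mice <- spec$n_mice
  mouse_ids <- sprintf("mouse%02d", seq_len(n_mice))

  paths <- list(
    rec = file.path(out, mouse_ids),
    truth = file.path(out, paste0(mouse_ids, "_hypnogram.csv")),
    feats = file.path(out, paste0(mouse_ids, "_features.rds")),
    labels = file.path(out, paste0(mouse_ids, "_labels.csv")),
    model = file.path(out, "model.json"),
    pred = file.path(out, paste0(mouse_ids, "_predicted.csv")),
    trans = file.path(out, "transitions.json"),
    smoothed = file.path(out, paste0(mouse_ids, "_smoothed.csv")),
    arch = file.path(out, "architecture.json"),
    cmp = file.path(out, "comparison.json"))

  run_stage <- function(name, inputs, outputs, fun) {
    if (!name %in% stages) return(invisible(FALSE))
    in_hash <- hash_files(inputs)
    rec <- manifest$stages[[name]]
    up_to_date <- !is.null(rec) &&
      identical(as.character(unlist(rec$input_md5)), in_hash) &&
      identical(rec$config_hash, cfg_hash) &&
      all(file.exists(outputs))
    if (up_to_date) {
      message("[", name, "] up to date, skipped")
      return(invisible(FALSE))
    }
    message("[", name, "] running")
    fun()
    manifest$stages[[name]] <<- list(
      input_md5 = in_hash, output_md5 = hash_files(outputs),
      config_hash = cfg_hash, timestamp = format(Sys.time(), tz = "UTC"))
    invisible(TRUE)
  }

  run_stage("simulate", character(0),
            c(paste0(paths$rec, ".bin"), paths$truth), function() {
    write_fixture_cohort(spec, out)
  })

  run_stage("features", paste0(paths$rec, ".bin"), paths$feats, function() {
    for (m in seq_len(n_mice)) {
      rec <- read_recording(paths$rec[m])
      mask <- detect_outliers(rec, highpass_hz = cfg$features$highpass_hz,
                              mad_multiplier = cfg$features$mad_multiplier,
                              window_s = cfg$features$window_s)
      reg <- average_regions(rec)
      tens <- welch_feature_tensor(
        reg, mask, window_s = cfg$features$window_s,
        segment_samples = cfg$features$segment_samples,
        f_max = cfg$features$f_max)
      tens <- median_normalize(tens)
      saveRDS(tens, paths$feats[m])
      message("  ", mouse_ids[m], ": ", sum(tens$valid_mask), "/",
              length(tens$valid_mask), " valid windows")
    }
  })

  run_stage("label", c(paste0(paths$rec, ".bin"), paths$truth),
            paths$labels, function() {
    for (m in seq_len(n_mice)) {
      hyp <- if (cfg$labels$method == "truth") {
        read_hypnogram(paths$truth[m])
      } else {
        rec <- read_recording(paths$rec[m])
        pts <- statemap_features(rec, cfg$labels$reference_region,
                                 window_s = cfg$features$window_s)
        polys <- auto_polygons(pts, seed = derive_seed(cfg$seed, "polygons"))
        assign_by_polygons(pts, polys)
      }
      write_hypnogram(hyp, paths$labels[m])
    }
  })

  run_stage("train", c(paths$feats, paths$labels), paths$model, function() {
    xs <- lapply(paths$feats, readRDS)
    ys <- lapply(paths$labels, read_hypnogram)
    X <- do.call(rbind, lapply(xs, flatten_features))
    attr(X, "regions") <- xs[[1L]]$regions
    attr(X, "freqs") <- xs[[1L]]$freqs
    attr(X, "valid_mask") <- unlist(lapply(xs, `[[`, "valid_mask"))
    yl <- unlist(lapply(ys, `[[`, "label"))
    cfg_sae <- sae_config(epochs = cfg$sae$epochs,
                          batch_size = cfg$sae$batch_size,
                          learning_rate = cfg$sae$learning_rate,
                          seed = derive_seed(cfg$seed, "train"))
    model <- electome_sae(X, yl, mu = cfg$sae$mu,
                          n_latent = cfg$sae$n_latent, config = cfg_sae)
    write_sae(model, paths$model)
  })

  run_stage("predict", c(paths$model, paths$feats), paths$pred, function() {
    model <- read_sae(paths$model)
    for (m in seq_len(n_mice)) {
      tens <- readRDS(paths$feats[m])
      write_hypnogram(predict(model, tens), paths$pred[m])
    }
  })

  run_stage("smooth", c(paths$pred, paths$labels),
            c(paths$trans, paths$smoothed), function() {
    labs <- lapply(paths$labels, function(p) read_hypnogram(p)$label)
    trans <- estimate_transitions(labs,
                                  smoothing = cfg$smoothing$smoothing_constant)
    write_transitions(trans, paths$trans)
    for (m in seq_len(n_mice)) {
      hyp <- read_hypnogram(paths$pred[m])
      write_hypnogram(smooth_hypnogram(hyp, trans, k = cfg$smoothing$k),
                      paths$smoothed[m])
    }
  })

  run_stage("architecture", paths$smoothed, paths$arch, function() {
    stats_by_mouse <- lapply(seq_len(n_mice), function(m) {
      st <- architecture_stats(read_hypnogram(paths$smoothed[m]))
      st$per_state$subject_id <- mouse_ids[m]
      st$per_state
    })
    jsonlite::write_json(do.call(rbind, stats_by_mouse), paths$arch,
                         digits = NA, dataframe = "rows")
  })

  if (!is.null(cfg$comparison$groups)) {
    run_stage("compare", c(paths$feats, paths$smoothed), paths$cmp,
              function() {
      grp <- cfg$comparison$groups   # named list: condition -> subject ids
      sums <- lapply(seq_len(n_mice), function(m) {
        state_mean_features(readRDS(paths$feats[m]),
                            read_hypnogram(paths$smoothed[m]))
      })
      names(sums) <- mouse_ids
      conds <- names(grp)
      cmpres <- compare_conditions(sums[unlist(grp[[conds[1L]]])],
                                   sums[unlist(grp[[conds[2L]]])],
                                   alpha_display = cfg$comparison$alpha_display)
      headline <- lapply(intersect(sleep_states(), names(cmpres)),
                         function(st) list(state = st,
                                           headline_p = cmpres[[st]]$headline_p,
                                           hmp = cmpres[[st]]$hmp))
      jsonlite::write_json(headline, paths$cmp, auto_unbox = TRUE,
                           digits = NA)
    })
  }

  manifest$seed <- cfg$seed
  manifest$version <- as.character(utils::packageVersion("electosleep"))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Validate pipeline input files
#'
#' Per-recording format checks: the .bin/.json pair parses, the channel map
#' covers the expected regions, the sampling rate matches, and each channel
#' passes the saturation screen.
#'
#' @param stems Character vector of recording stems (paths without
#'   extension).
#' @param regions Regions the channel map must cover (default the 8-region
#'   montage).
#' @param fs Expected sampling rate (default 1000 Hz).
#' @return Data frame report with columns `stem`, `check`, `ok`, `message`;
#'   failures are listed, never raised.
#' @export
validate_inputs <- function(stems, regions = default_regions(), fs = 1000) {
  rows <- list()
  add <- function(stem, check, ok, msg = "") {
    rows[[length(rows) + 1L]] <<- data.frame(stem = stem, check = check,
                                             ok = ok, message = msg)
  }
  for (stem in stems) {
    rec <- tryCatch(read_recording(stem), error = function(e) e)
    if (inherits(rec, "error")) {
      add(stem, "readable", FALSE, conditionMessage(rec))
      next
    }
    add(stem, "readable", TRUE)
    missing <- setdiff(regions, rec$channel_regions)
    add(stem, "region_coverage", length(missing) == 0L,
        if (length(missing)) paste("missing region(s):",
                                   paste(missing, collapse = ", ")) else "")
    add(stem, "sampling_rate", isTRUE(all.equal(rec$fs, fs)),
        if (!isTRUE(all.equal(rec$fs, fs)))
          sprintf("fs = %g, expected %g", rec$fs, fs) else "")
    for (ch in seq_len(nrow(rec$signals))) {
      scr <- saturation_screen(rec$signals[ch, ], rec$fs)
      add(stem, paste0("saturation:", rec$channel_regions[ch]),
          !scr$saturated,
          if (scr$saturated)
            sprintf("plateau fraction %.3f exceeds threshold",
                    scr$plateau_fraction) else "")
    }
  }
  do.call(rbind, rows)
}
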