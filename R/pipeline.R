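#' Pipeline configuration
#'
#' Bundles every knob of the synthetic end-to-end pipeline: assay geometry,
#' detection parameters, imaging defaults, the true transfer frequency of
#' each mating role, replicate count, seed and verbosity. Unspecified fields
#' fall back to the standard assay constants (270 mm^2 filter, 7 x 7 fields
#' of 980 x 732 um, 30,000 cells/mm^2, recipient fraction 0.5, 4 um^2 area
#' cutoff). Configurations round-trip losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @param geometry an [experiment_geometry()] or a named list of overrides.
#' @param detection a [detection_params()] or a named list of overrides.
#' @param imaging an [imaging_defaults()] list or overrides.
#' @param matings named list of true transfer frequencies (T/R) per mating
#'   role; roles among `conj_comm`, `conj_intra`, `retro_comm`,
#'   `retro_intra`, `direct_comm`.
#' @param n_replicates replicate filters per mating.
#' @param seed integer master seed.
#' @param verbosity 0 (quiet), 1 (stage messages), 2 (per-field detail).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = list(),
                            detection = list(),
                            imaging = list(),
                            matings = list(conj_comm = 1.16e-4,
                                           conj_intra = 1.76e-3,
                                           retro_comm = 1.16e-5,
                                           retro_intra = 8.34e-4,
                                           direct_comm = 3.14e-3),
                            n_replicates = 3,
                            seed = 1L,
                            verbosity = 1) {
  fill <- function(user, builder) {
    if (inherits(user, c("experiment_geometry", "detection_params")))
      return(user)
    if (!is.list(user)) stop("config section must be a named list")
    unknown <- setdiff(names(user), names(formals(builder)))
    if (length(unknown))
      stop("unknown config field: ", paste(unknown, collapse = ", "))
    do.call(builder, user)
  }
  geometry <- fill(geometry, experiment_geometry)
  detection <- fill(detection, detection_params)
  if (!is.list(imaging)) stop("imaging section must be a named list")
  imaging <- utils::modifyList(imaging_defaults(), imaging)
  bad <- which(!names(matings) %in%
                 c("conj_comm", "conj_intra", "retro_comm", "retro_intra",
                   "direct_comm"))
  if (length(bad))
    stop("unknown mating role in config: matings$", names(matings)[bad[1]])
  structure(list(geometry = geometry, detection = detection,
                 imaging = imaging, matings = matings,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), verbosity = verbosity),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(geometry = unclass(config$geometry),
                detection = unclass(config$detection),
                imaging = config$imaging,
                matings = config$matings,
                n_replicates = config$n_replicates,
                seed = config$seed,
                verbosity = config$verbosity)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  pipeline_config(geometry = raw$geometry %||% list(),
                  detection = raw$detection %||% list(),
                  imaging = raw$imaging %||% list(),
                  matings = raw$matings,
                  n_replicates = raw$n_replicates %||% 3,
                  seed = raw$seed %||% 1L,
                  verbosity = raw$verbosity %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

say <- function(config, level, ...) {
  if (config$verbosity >= level) message(...)
  invisible(NULL)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order, wiring each stage's artifacts to
#' the next, and writes a run manifest (config copy and hash, seed, package
#' version, per-stage file list) sufficient to reproduce the run.
#'
#' Stages:
#' * `simulate-images`: one synthetic filter experiment (TIFFs + ground
#'   truth) per mating role and replicate.
#' * `quantify`: microcolony detection on every field; per-field counts and
#'   object tables.
#' * `frequencies`: scanned-zone counts scaled to whole-filter transfer
#'   frequencies, aggregated over replicates.
#' * `framework`: the mobilization report from the aggregated frequencies.
#' * `simulate-mating`: contact-level mating simulation and parameter
#'   recovery (independent of the image stages).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param stages character vector of stages to run, in order.
#' @return Invisibly, a list with the stage artifacts (`report` holds the
#'   `mobilization_report` when the framework stage ran) and the manifest
#'   path.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate-images", "quantify",
                                    "frequencies", "framework")) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate-images", "quantify", "frequencies", "framework",
             "simulate-mating")
  if (!all(stages %in% known))
    stop("unknown stage: ", paste(setdiff(stages, known), collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  manifest_files <- list()
  roles <- names(config$matings)
  reps <- seq_len(config$n_replicates)
  set.seed(config$seed)
  exp_seeds <- matrix(sample.int(2147483647L, length(roles) * length(reps)),
                      nrow = length(roles),
                      dimnames = list(roles, NULL))

  if ("simulate-images" %in% stages) {
    say(config, 1, "stage simulate-images")
    for (role in roles) for (r in reps) {
      ex <- generate_filter_experiment(config$matings[[role]],
                                       config$geometry, config$imaging,
                                       seed = exp_seeds[role, r])
      dir <- file.path(outdir, "images", role, sprintf("rep%d", r))
      written <- write_filter_experiment(ex, dir)
      manifest_files[[paste("simulate-images", role, r)]] <-
        c(written$tiffs, written$truth, written$counts)
    }
  }

  if ("quantify" %in% stages) {
    img_root <- file.path(outdir, "images")
    if (!dir.exists(img_root))
      stop("stage 'quantify' is missing its upstream artifact: ", img_root,
           " (run 'simulate-images' first)")
    say(config, 1, "stage quantify")
    counts_rows <- list()
    objects_rows <- list()
    for (role in roles) for (r in reps) {
      dir <- file.path(img_root, role, sprintf("rep%d", r))
      tiffs <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
      if (!length(tiffs))
        stop("stage 'quantify': no TIFF images under ", dir)
      fields <- lapply(tiffs, read_field_tiff,
                       pixel_scale_um = config$imaging$pixel_scale_um)
      q <- quantify_fields(fields, config$detection)
      say(config, 2, sprintf("  %s rep%d: %d green objects", role, r,
                             sum(q$counts$green_count)))
      counts_rows[[paste(role, r)]] <-
        cbind(mating_id = role, replicate = r, q$counts)
      if (nrow(q$objects))
        objects_rows[[paste(role, r)]] <-
          cbind(mating_id = role, replicate = r, q$objects)
    }
    counts <- do.call(rbind, counts_rows); rownames(counts) <- NULL
    utils::write.csv(counts, file.path(outdir, "counts.csv"),
                     row.names = FALSE)
    objects <- do.call(rbind, objects_rows)
    if (!is.null(objects)) {
      rownames(objects) <- NULL
      utils::write.table(objects, file.path(outdir, "objects.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    artifacts$counts <- counts
    manifest_files[["quantify"]] <-
      file.path(outdir, c("counts.csv", "objects.tsv"))
  }

  if ("frequencies" %in% stages) {
    counts_path <- file.path(outdir, "counts.csv")
    if (is.null(artifacts$counts)) {
      if (!file.exists(counts_path))
        stop("stage 'frequencies' is missing its upstream artifact: ",
             counts_path, " (run 'quantify' first)")
      artifacts$counts <- utils::read.csv(counts_path)
    }
    say(config, 1, "stage frequencies")
    counts <- artifacts$counts
    per_rep <- do.call(rbind, lapply(split(
      counts, list(counts$mating_id, counts$replicate), drop = TRUE),
      function(d) {
        scanned <- sum(d$green_count)
        data.frame(mating_id = d$mating_id[1], replicate = d$replicate[1],
                   scanned_count = scanned,
                   total_count = scale_to_filter(scanned, config$geometry),
                   recipients = recipients_on_filter(config$geometry),
                   frequency = transfer_frequency(scanned, config$geometry))
      }))
    rownames(per_rep) <- NULL
    per_rep <- per_rep[order(per_rep$mating_id, per_rep$replicate), ]
    agg <- do.call(rbind, lapply(split(per_rep, per_rep$mating_id),
      function(d) {
        est <- aggregate_replicates(d$frequency)
        data.frame(mating_id = d$mating_id[1], mean = est$mean,
                   sem = est$sem, n = est$n_replicates)
      }))
    rownames(agg) <- NULL
    utils::write.csv(per_rep, file.path(outdir, "frequencies.csv"),
                     row.names = FALSE)
    utils::write.csv(agg, file.path(outdir, "frequencies_aggregate.csv"),
                     row.names = FALSE)
    artifacts$frequencies <- per_rep
    artifacts$aggregate <- agg
    manifest_files[["frequencies"]] <-
      file.path(outdir, c("frequencies.csv", "frequencies_aggregate.csv"))
  }

  if ("framework" %in% stages) {
    agg_path <- file.path(outdir, "frequencies_aggregate.csv")
    if (is.null(artifacts$aggregate)) {
      if (!file.exists(agg_path))
        stop("stage 'framework' is missing its upstream artifact: ",
             agg_path, " (run 'frequencies' first)")
      artifacts$aggregate <- utils::read.csv(agg_path)
    }
    say(config, 1, "stage framework")
    agg <- artifacts$aggregate
    per_rep <- artifacts$frequencies
    rec <- function(role) {
      i <- match(role, agg$mating_id)
      if (is.na(i)) return(NA)
      list(mean = agg$mean[i], sem = agg$sem[i],
           per_replicate = if (!is.null(per_rep))
             per_rep$frequency[per_rep$mating_id == role] else NULL)
    }
    freqs <- mating_frequency_set(conj_comm = rec("conj_comm"),
                                  conj_intra = rec("conj_intra"),
                                  retro_comm = rec("retro_comm"),
                                  retro_intra = rec("retro_intra"),
                                  direct_comm = rec("direct_comm"))
    report <- build_report(freqs)
    utils::write.csv(as.data.frame(report),
                     file.path(outdir, "mobilization_report.csv"),
                     row.names = FALSE)
    txt <- file.path(outdir, "mobilization_report.txt")
    sink(txt); print(report); sink()
    artifacts$report <- report
    manifest_files[["framework"]] <-
      file.path(outdir, c("mobilization_report.csv",
                          "mobilization_report.txt"))
  }

  if ("simulate-mating" %in% stages) {
    say(config, 1, "stage simulate-mating")
    rec <- recover_parameters(n_recipients = 1e6,
                              permissive_fraction = 0.066,
                              mobilizer_fraction = 0.05,
                              p_conj = 1.76e-3,
                              p_mob_given_conj = 0.474,
                              seed = config$seed)
    path <- file.path(outdir, "mating_simulation.csv")
    if (!rec$skipped)
      utils::write.csv(as.data.frame(rec$report), path, row.names = FALSE)
    artifacts$mating_recovery <- rec
    manifest_files[["simulate-mating"]] <- path
  }

  config_path <- file.path(outdir, "config.yaml")
  write_config(config, config_path)
  manifest <- list(
    package = "mobipot",
    version = as.character(utils::packageVersion("mobipot")),
    seed = config$seed,
    config_file = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    stages = stages,
    files = manifest_files)
  manifest_path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  artifacts$manifest <- manifest_path
  invisible(artifacts)
}
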