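#' End-to-end pipeline
#'
#' Orchestrates the stages — simulate (or load), static gradients, arousal
#' indices, dynamic gradients, variance partition, receptor screen — from a
#' single configuration, with one global seed fanned out deterministically
#' to per-stage seeds. Results are returned as a list and, when `outdir` is
#' set, written as TSV/JSON with a manifest.
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   `seed`, `outdir`, `stages` (character subset of simulate, gradients,
#'   arousal, dynamics, glm, receptors), `cohort_dir` (load a written cohort
#'   instead of simulating), `simulate` (arguments for [make_cohort()]),
#'   `params` (density, n_components, n_bins, n_shuffles, m_surrogates,
#'   ridge).
#' @return list of stage results, invisibly when writing to disk.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- modifyList(list(density = 0.10, n_components = 4, n_bins = 10,
                            n_shuffles = 1000, m_surrogates = 1000,
                            ridge = 1e-6),
                       config$params %||% list())
  stages <- config$stages %||%
    c("simulate", "gradients", "arousal", "dynamics", "glm", "receptors")
  seed <- config$seed %||% 1L
  res <- list(config = config, params = params)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$cohort_dir)) {
    res$cohort <- read_cohort(config$cohort_dir)
  } else if ("simulate" %in% stages) {
    res$cohort <- do.call(make_cohort,
                          modifyList(list(seed = child_seed(seed, "simulate")),
                                     config$simulate %||% list()))
  } else {
    stop("validation error: no cohort_dir given and simulate stage disabled")
  }
  ch <- res$cohort
  coords <- ch$truth$coords %||% ch$coords
  D <- coord_dist(coords)
  sc <- tracing_similarity(ch$tracing)
  ns <- expression_similarity(ch$expression)

  # --- static gradients ---------------------------------------------------
  if ("gradients" %in% stages) {
    fc_scans <- lapply(ch$scans, compute_fc)
    fc_mean <- Reduce(`+`, fc_scans) / length(fc_scans)
    ref <- connectivity_gradients(fc_mean, params$n_components,
                                  params$density)
    res$gradients <- list(fc_mean = fc_mean, fc_scans = fc_scans,
                          reference = ref,
                          sc_gradients = connectivity_gradients(
                            sc, params$n_components, params$density,
                            reference = ref))
  }

  # --- arousal ------------------------------------------------------------
  if ("arousal" %in% stages) {
    beh <- lapply(ch$pupil, behavioral_index, fps = ch$fps, tr = ch$tr)
    template <- arousal_template(ch$scans, beh, tr = ch$tr)
    fmri_idx <- lapply(ch$scans, fmri_arousal_index, template = template)
    res$arousal <- list(behavioral = beh, template = template,
                        fmri = fmri_idx)
  }

  # --- dynamics -----------------------------------------------------------
  if ("dynamics" %in% stages) {
    fits <- lapply(ch$scans, dcc_fit)
    idx <- unlist(lapply(res$arousal$fmri, `[[`, "index"))
    dfc <- do.call(abind3, lapply(fits, `[[`, "dfc"))
    assignment <- bin_by_arousal(idx, params$n_bins)
    bins <- binned_mean_dfc(dfc, assignment)
    dyn <- dynamic_gradients(bins, res$gradients$reference,
                             params$n_components, params$density)
    ev <- t(vapply(dyn, `[[`, numeric(params$n_components),
                   "explained_variance"))
    trend <- quadratic_trend(seq_len(params$n_bins) / params$n_bins, ev[, 1])
    res$dynamics <- list(dcc = fits, assignment = assignment, bins = bins,
                         gradients = dyn, explained_variance = ev,
                         g1_trend = trend)
  }

  # --- variance partition -------------------------------------------------
  if ("glm" %in% stages) {
    fc_vecs <- lapply(res$gradients$fc_scans, vectorize_pairs)
    res$glm <- partition_variance(fc_vecs, list(SC = sc, NS = ns),
                                  n_shuffles = params$n_shuffles,
                                  seed = child_seed(seed, "glm"),
                                  ridge = params$ridge)
  }

  # --- receptor screen ----------------------------------------------------
  if ("receptors" %in% stages) {
    res$receptors <- receptor_screen(res$dynamics$bins, ch$expression, sc, D,
                                     n_shuffles = params$m_surrogates,
                                     seed = child_seed(seed, "receptors"),
                                     reference = res$gradients$reference,
                                     ridge = params$ridge)
  }

  if (!is.null(config$outdir)) {
    write_pipeline(res, config$outdir)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `manifest.yaml`.
#' @return list compatible with the pipeline's cohort field (no ground
#'   truth).
#' @export
read_cohort <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  for (f in c(man$scans, man$pupil, man$tracing, man$expression,
              man$coords)) {
    if (!file.exists(file.path(dir, f))) {
      stop("validation error: missing input file ", f)
    }
  }
  scans <- lapply(man$scans, function(f) {
    as.matrix(read_tsv(file.path(dir, f)))
  })
  pupil <- lapply(man$pupil, function(f) read_tsv(file.path(dir, f))$pupil)
  tracing <- as.matrix(read_tsv(file.path(dir, man$tracing),
                                row_names = TRUE))
  expression <- as.matrix(read_tsv(file.path(dir, man$expression),
                                   row_names = TRUE))
  coords <- as.matrix(read_tsv(file.path(dir, man$coords), row_names = TRUE))
  list(scans = scans, pupil = pupil, tracing = tracing,
       expression = expression, coords = coords, tr = man$tr, fps = man$fps)
}

write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$gradients)) {
    write_tsv(as.data.frame(res$gradients$reference$components),
              file.path(outdir, "gradients.tsv"), row_names = TRUE)
    jsonlite::write_json(
      list(explained_variance = res$gradients$reference$explained_variance,
           eigenvalues = res$gradients$reference$eigenvalues),
      file.path(outdir, "gradients.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$arousal)) {
    write_tsv(data.frame(template = res$arousal$template),
              file.path(outdir, "arousal_template.tsv"), row_names = TRUE)
  }
  if (!is.null(res$dynamics)) {
    write_tsv(as.data.frame(res$dynamics$explained_variance),
              file.path(outdir, "binned_explained_variance.tsv"))
  }
  if (!is.null(res$glm)) {
    jsonlite::write_json(
      list(cv_r2_full = res$glm$full$mean,
           cv_r2_single = lapply(res$glm$single, `[[`, "mean"),
           delta_r2 = lapply(res$glm$delta, `[[`, "delta_r2")),
      file.path(outdir, "variance_partition.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$receptors)) {
    write_tsv(res$receptors, file.path(outdir, "receptor_screen.tsv"))
  }
  jsonlite::write_json(list(package = "gradflow",
                            version = "0.1.0",
                            seed = res$config$seed %||% 1L,
                            params = res$params,
                            stages = names(res)),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
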