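#' Default pipeline configuration
#'
#' A nested list of every pipeline parameter with its default value:
#' simulation (the synthetic population), registration (kernel,
#' regularization, tolerance, point counts), shape model, and deviation
#' settings.  No stage relies on silent defaults — the effective
#' configuration is echoed into the run manifest.
#'
#' @param seed master seed for the run.
#' @return a nested named list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    output_dir = "ssmreg_out",
    simulate = list(
      n_subjects = 20L,
      axes = c(25, 18, 14),
      protrusion_amplitude = 8,
      resolution = 4L,
      scale_sd = 0.05,
      mode_amplitudes = c(1.0),
      noise_sd = 0.05,
      rot_sd_deg = 5,
      trans_sd_mm = 2,
      mirror_fraction = 0.5),
    register = list(
      reference = "",          # path to reference STL; "" = first target
      targets = "",            # glob of target STLs; "" = simulated ones
      sigma = 1.0,             # isotropic kernel variance (mm^2)
      knn = 6L,
      normalization = "standard",
      lambda = 1e-11,
      tolerance = 0.4,
      ref_points = 1360L,
      target_points = 2000L,
      max_outer_iter = 10L),
    build_ssm = list(cohort_label = "cohort"),
    synthesize = list(mode = 1L, sigma_level = 3),
    deviate = list(threshold = 1.0, match_volume = NA_real_),
    sections = list(axes = c("x", "y", "z"))),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults, so a
#' config file only needs to state what it overrides.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_into <- function(base, upd, where) {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown config key '", k, "' in ", where)
      if (is.list(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(where, k, "."))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  cfg2 <- merge_into(unclass(cfg), raw, "")
  if (!is.null(seed)) cfg2$seed <- as.integer(seed)
  structure(cfg2, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

reg_config_from_pipeline <- function(config) {
  r <- config$register
  registration_config(
    kernel = kernel_config(sigma = r$sigma * diag(3), knn = r$knn,
                           normalization = r$normalization),
    lambda = r$lambda, tolerance = r$tolerance,
    ref_points = r$ref_points, target_points = r$target_points,
    max_outer_iter = r$max_outer_iter, seed = config$seed)
}

pop_spec_from_pipeline <- function(config) {
  s <- config$simulate
  population_spec(
    n_subjects = s$n_subjects,
    base = list(axes = s$axes, protrusion_amplitude = s$protrusion_amplitude,
                resolution = s$resolution),
    scale_sd = s$scale_sd, mode_amplitudes = s$mode_amplitudes,
    noise_sd = s$noise_sd, rot_sd_deg = s$rot_sd_deg,
    trans_sd_mm = s$trans_sd_mm, mirror_fraction = s$mirror_fraction,
    seed = config$seed)
}

#' Run the shape-modelling pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate` (generate a synthetic STL population with ground truth),
#' `register` (groupwise registration of all targets to the reference),
#' `build-ssm` (PCA shape model over the registered correspondences),
#' `synthesize` (a mode shape at a chosen sigma level),
#' `deviate` (deviation report of the synthesized mode shape against the
#' mean shape), and `sections` (plane-section circumference comparison of
#' the same pair).  Every output file is listed, with its MD5 hash, in
#' `manifest.json` in the output directory, together with the effective
#' configuration and seed.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param stages character vector of stage names; default all.
#' @param verbose print per-stage progress.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("simulate", "register", "build-ssm",
                                    "synthesize", "deviate", "sections"),
                         verbose = FALSE) {
  known <- c("simulate", "register", "build-ssm", "synthesize", "deviate",
             "sections")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  stages <- known[known %in% stages]
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (verbose) message(sprintf(...))

  state <- new.env()

  if ("simulate" %in% stages) {
    note("simulate: %d subjects", config$simulate$n_subjects)
    pop <- generate_population(pop_spec_from_pipeline(config))
    state$pop <- pop
    write_stl(pop$base_mesh, file.path(out, "base_shape.stl"))
    for (i in seq_along(pop$meshes))
      write_stl(pop$meshes[[i]],
                file.path(out, sprintf("subject_%02d.stl", i)))
    gt <- data.frame(subject = sprintf("subject_%02d", seq_along(pop$meshes)),
                     scale = pop$truth$scale,
                     mirrored = pop$truth$mirrored)
    sc <- pop$truth$scores
    if (ncol(sc) > 0) {
      colnames(sc) <- sprintf("mode%d_score", seq_len(ncol(sc)))
      gt <- cbind(gt, sc)
    }
    write.csv(gt, file.path(out, "ground_truth.csv"), row.names = FALSE)
  }

  if (any(c("register", "build-ssm", "synthesize", "deviate", "sections")
          %in% stages)) {
    # resolve inputs: explicit paths win, otherwise the simulate outputs
    tpaths <- config$register$targets
    if (!nzchar(tpaths[1])) {
      tpaths <- sort(Sys.glob(file.path(out, "subject_*.stl")))
      if (!length(tpaths)) stop("no target meshes: run 'simulate' or set ",
                                "register$targets")
    } else tpaths <- sort(Sys.glob(tpaths))
    missing <- tpaths[!file.exists(tpaths)]
    if (length(missing)) stop("missing target file(s): ",
                              paste(missing, collapse = ", "))
    targets <- lapply(tpaths, read_stl)
    gt_path <- file.path(out, "ground_truth.csv")
    if (file.exists(gt_path)) {
      gt <- read.csv(gt_path)
      for (i in seq_along(targets))
        if (isTRUE(gt$mirrored[i]))
          targets[[i]] <- mirror_mesh(targets[[i]], "x")
    }
    ref_path <- config$register$reference
    reference <- if (nzchar(ref_path)) read_stl(ref_path) else targets[[1]]
    state$targets <- targets
    state$reference_mesh <- reference
  }

  if ("register" %in% stages) {
    note("register: %d targets", length(state$targets))
    rcfg <- reg_config_from_pipeline(config)
    rs <- groupwise_register(state$reference_mesh, state$targets, rcfg,
                             verbose = verbose)
    state$registered <- rs
    write.csv(data.frame(subject = rs$labels, error_mm = rs$errors,
                         iterations = rs$iterations,
                         converged = rs$converged),
              file.path(out, "registration_errors.csv"), row.names = FALSE)
    utils::write.table(rs$reference$points,
                       file.path(out, "reference_cloud.txt"),
                       row.names = FALSE, col.names = FALSE)
    for (i in seq_along(rs$transforms))
      write_tps(rs$transforms[[i]],
                file.path(out, sprintf("theta_%02d.tps", i)))
  }

  if ("build-ssm" %in% stages) {
    if (is.null(state$registered)) stop("'build-ssm' needs the register stage")
    note("build-ssm")
    model <- build_shape_model(state$registered,
                               cohort_label = config$build_ssm$cohort_label)
    state$model <- model
    write.csv(data.frame(mode = seq_along(model$eigenvalues),
                         eigenvalue = model$eigenvalues,
                         variance_fraction = model$variance_fraction),
              file.path(out, "ssm_modes.csv"), row.names = FALSE)
    sc <- as.data.frame(model$scores)
    names(sc) <- sprintf("pc%d", seq_len(ncol(sc)))
    write.csv(cbind(subject = state$registered$labels, sc),
              file.path(out, "ssm_scores.csv"), row.names = FALSE)
    mean_mesh <- warp_mesh(state$reference_mesh,
                           state$registered$reference,
                           point_cloud(model$mean_shape))
    state$mean_mesh <- mean_mesh
    write_stl(mean_mesh, file.path(out, "mean_shape.stl"))
  }

  if ("synthesize" %in% stages) {
    if (is.null(state$model)) stop("'synthesize' needs the build-ssm stage")
    k <- config$synthesize$mode
    s <- config$synthesize$sigma_level
    note("synthesize: mode %d at %+g sigma", k, s)
    scores <- rep(0, k); scores[k] <- s
    cl <- synthesize_shape(state$model, scores)
    mode_mesh <- warp_mesh(state$reference_mesh,
                           state$registered$reference, cl)
    state$mode_mesh <- mode_mesh
    write_stl(mode_mesh,
              file.path(out, sprintf("mode%d_%+gsigma.stl", k, s)))
  }

  if ("deviate" %in% stages) {
    if (is.null(state$mode_mesh)) stop("'deviate' needs the synthesize stage")
    note("deviate")
    mv <- config$deviate$match_volume
    rep_ <- if (is.finite(mv))
      compare_volume_matched(state$mean_mesh, state$mode_mesh, mv,
                             threshold = config$deviate$threshold)
    else
      deviation_report(mesh_to_cloud(state$mode_mesh), state$mean_mesh,
                       threshold = config$deviate$threshold)
    write.csv(data.frame(
      mean_signed = rep_$mean_signed, mean_abs = rep_$mean_abs,
      max_positive = rep_$max_positive, max_negative = rep_$max_negative,
      fraction_over = rep_$fraction_over, threshold = rep_$threshold),
      file.path(out, "deviation_report.csv"), row.names = FALSE)
    utils::write.table(rep_$distances,
                       file.path(out, "deviation_distances.txt"),
                       row.names = FALSE, col.names = FALSE)
  }

  if ("sections" %in% stages) {
    if (is.null(state$mode_mesh)) stop("'sections' needs the synthesize stage")
    note("sections")
    res <- lapply(config$sections$axes, function(ax)
      section_difference(state$mean_mesh, state$mode_mesh, ax))
    write.csv(data.frame(
      axis = unlist(config$sections$axes),
      circumference_mean = vapply(res, `[[`, numeric(1), "circumference_a"),
      circumference_mode = vapply(res, `[[`, numeric(1), "circumference_b"),
      difference_mm = vapply(res, `[[`, numeric(1), "difference"),
      empty = vapply(res, `[[`, logical(1), "empty")),
      file.path(out, "section_differences.csv"), row.names = FALSE)
  }

  files <- sort(list.files(out, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "ssmreg",
    version = as.character(utils::packageVersion("ssmreg")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
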