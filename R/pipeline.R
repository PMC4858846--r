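# Pipeline plumbing: a declarative configuration (YAML-compatible list)
# naming every stage parameter, and a runner chaining parenchyma -> ACM ->
# vessels -> refinement with per-stage outputs and metrics.

config_defaults <- function() {
  list(
    input = NULL,            # path to a volume, or NULL when phantom is set
    phantom = NULL,          # list of phantom_spec() arguments
    init = NULL,             # list(seed=, radius_mm=) or path to a mask
    output_dir = NULL,
    seed = 1L,
    verbose = FALSE,
    stages = list(parenchyma = FALSE, acm = TRUE, vessels = FALSE,
                  refine = FALSE),
    acm = list(),            # acm_params() overrides
    vessels = list(),        # vessel_params() overrides + seeds
    refine = list(dilation = 1L, k_clusters = 3L, si_scale = 1.5)
  )
}

check_keys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Pipeline configuration
#'
#' Builds and validates the full pipeline configuration from a named
#' list or a YAML file. Every stage parameter is named here; unknown
#' keys are rejected; overrides are validated against the documented
#' ranges when the stage objects are constructed.
#'
#' @param x named list of settings, or a path to a YAML file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
  if (!is.list(x)) stop("configuration must be a list or a YAML path")
  def <- config_defaults()
  check_keys(x, names(def), "top level")
  cfg <- utils::modifyList(def, x)
  check_keys(cfg$stages, c("parenchyma", "acm", "vessels", "refine"),
             "stages")
  check_keys(cfg$acm, names(formals(acm_params)), "acm")
  check_keys(cfg$vessels, names(formals(vessel_params)), "vessels")
  check_keys(cfg$refine, c("dilation", "k_clusters", "si_scale"), "refine")
  if (is.null(cfg$input) && is.null(cfg$phantom))
    stop("configuration needs either `input` or `phantom`")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Run the full segmentation pipeline
#'
#' Executes the enabled stages in order: parenchyma pre-segmentation,
#' integrated ACM nodule segmentation (`S_c2`), flow-direction vessel
#' growing (`S_c1`), and K-means refinement of the attachment collar
#' `S_r`. With refinement disabled the final mask is `S_c2`. Given a
#' fixed configuration and seed the outputs are bitwise identical across
#' runs.
#'
#' @param config a [pipeline_config] (or a list/YAML path coerced to one).
#' @return A `segmentation_report`: list with `volume`, per-stage masks
#'   (`parenchyma`, `s_c1`, `s_c2`, `s_r`, `final`), `acm_fit`,
#'   `metrics` (when phantom truth is available), `voxel_counts`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  truth <- NULL
  if (!is.null(cfg$phantom)) {
    ph_args <- cfg$phantom
    ph_args$seed <- ph_args$seed %||% cfg$seed
    ph <- make_phantom(do.call(phantom_spec, ph_args))
    volume <- ph$volume
    truth <- ph$truth
    pipe_log(cfg, "phantom '", ph$spec$kind, "' generated: ",
             paste(dim(volume$data), collapse = "x"))
  } else {
    volume <- read_volume(cfg$input)
    pipe_log(cfg, "volume read: ", paste(dim(volume$data), collapse = "x"))
  }
  d <- dim(volume$data)
  counts <- list()
  masks <- list()

  if (isTRUE(cfg$stages$parenchyma)) {
    masks$parenchyma <- withCallingHandlers(
      parenchyma_mask(volume),
      error = function(e) stop("stage parenchyma failed: ",
                               conditionMessage(e), call. = FALSE))
    counts$parenchyma <- sum(masks$parenchyma$data)
    pipe_log(cfg, "parenchyma: ", counts$parenchyma, " voxels")
  }

  acm_fit <- NULL
  if (isTRUE(cfg$stages$acm)) {
    init <- cfg$init
    if (is.character(init)) init <- read_mask(init)
    if (is.null(init) && !is.null(truth)) {
      tm <- truth$sphere %||% truth$object
      ctr <- round(colMeans(arrayInd(which(tm$data), d)))
      init <- list(seed = ctr, radius_mm = 3)
    }
    if (is.null(init)) stop("stage acm failed: no initialization given")
    pars <- do.call(acm_params, utils::modifyList(
      list(seed = cfg$seed), cfg$acm))
    acm_fit <- tryCatch(
      segment_nodule(volume, init, pars),
      error = function(e) stop("stage acm failed: ",
                               conditionMessage(e), call. = FALSE))
    masks$s_c2 <- acm_fit$mask
    counts$s_c2 <- sum(masks$s_c2$data)
    pipe_log(cfg, "ACM nodule candidates: ", counts$s_c2, " voxels")
  }

  if (isTRUE(cfg$stages$vessels)) {
    vres <- tryCatch({
      field <- structure_tensor(volume,
                                sigma_grad = cfg$vessels$sigma_grad %||% 1,
                                sigma_window = cfg$vessels$sigma_window %||% 2)
      vp_over <- cfg$vessels
      if (is.null(vp_over$intensity_range)) {
        rng <- range(volume$data)
        vp_over$intensity_range <- c(rng[1] + 0.3 * diff(rng), rng[2])
      }
      if (is.null(vp_over$seeds) || length(vp_over$seeds) == 0)
        vp_over$seeds <- derive_vessel_seeds(volume, field,
                                             vp_over$intensity_range)
      vp <- do.call(vessel_params, vp_over)
      fdf_region_grow(volume, field, vp)
    }, error = function(e) stop("stage vessels failed: ",
                                conditionMessage(e), call. = FALSE))
    masks$s_c1 <- vres
    counts$s_c1 <- sum(masks$s_c1$data)
    pipe_log(cfg, "vessel candidates: ", counts$s_c1, " voxels")
  }

  final <- masks$s_c2
  if (isTRUE(cfg$stages$refine)) {
    if (is.null(masks$s_c1) || is.null(masks$s_c2))
      stop("stage refine failed: needs both vessel and ACM stages")
    masks$s_r <- refinement_region(masks$s_c1, masks$s_c2,
                                   dilation = cfg$refine$dilation %||% 1L)
    counts$s_r <- sum(masks$s_r$data)
    final <- tryCatch(
      cluster_refine(masks$s_r, masks$s_c2, volume,
                     k_clusters = cfg$refine$k_clusters %||% 3L,
                     si_scale = cfg$refine$si_scale %||% 1.5,
                     seed = cfg$seed),
      error = function(e) stop("stage refine failed: ",
                               conditionMessage(e), call. = FALSE))
    pipe_log(cfg, "refinement region: ", counts$s_r, " voxels")
  }
  masks$final <- final
  counts$final <- if (!is.null(final)) sum(final$data) else 0L

  metrics <- NULL
  if (!is.null(truth) && !is.null(final)) {
    ref <- truth$sphere %||% truth$object
    metrics <- list(jaccard_error = jaccard_error(final, ref),
                    dice = dice_coefficient(final, ref))
    if (!is.null(masks$s_c2))
      metrics$jaccard_error_unrefined <- jaccard_error(masks$s_c2, ref)
    pipe_log(cfg, "Jaccard error vs truth: ",
             signif(metrics$jaccard_error, 4))
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (length(d) == 3) ".nii.gz" else ".png"
    for (nm in names(masks)) {
      if (is.null(masks[[nm]])) next
      write_mask(masks[[nm]], file.path(cfg$output_dir,
                                        paste0(nm, ext)))
    }
  }

  structure(list(volume = volume, masks = masks, truth = truth,
                 acm_fit = acm_fit, metrics = metrics,
                 voxel_counts = counts, config = cfg),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat("<segmentation_report>\n  stages:",
      paste(names(x$voxel_counts), unlist(x$voxel_counts),
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$metrics))
    cat("  Jaccard error:", signif(x$metrics$jaccard_error, 4), "\n")
  invisible(x)
}
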