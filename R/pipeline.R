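#' Configuration of an end-to-end run
#'
#' Bundles every tunable of the pipeline into one JSON-serialisable document:
#' the master seed, the cohort parameters, the phantom-experiment parameters
#' and the CALS and CI settings. The config is copied verbatim into the run's
#' output directory.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_patients,prevalence,sensitivity,specificity cohort parameters
#'   (defaults mirror the validation study: 53 patients, 37 IPH-positive,
#'   a software call operating around 0.9 sensitivity / 0.3 specificity).
#' @param exact_margins fix the IPH-positive count at
#'   `round(n_patients * prevalence)`.
#' @param n_phantom_pairs paired CTA/NCCT phantoms in the blooming
#'   experiment.
#' @param blooming_width_mm blooming kernel width (mm).
#' @param cals_threshold,cals_min_area,slice_thickness CALS protocol
#'   constants (130 HU, 1 mm^2, 0.625 mm).
#' @param ci_method `"clopper_pearson"` or `"wilson"`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_patients = 53L, prevalence = 37 / 53,
                       sensitivity = 0.9, specificity = 0.3,
                       exact_margins = TRUE, n_phantom_pairs = 20L,
                       blooming_width_mm = 0.5, cals_threshold = 130,
                       cals_min_area = 1, slice_thickness = 0.625,
                       ci_method = c("clopper_pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 prevalence = prevalence, sensitivity = sensitivity,
                 specificity = specificity, exact_margins = exact_margins,
                 n_phantom_pairs = as.integer(n_phantom_pairs),
                 blooming_width_mm = blooming_width_mm,
                 cals_threshold = cals_threshold,
                 cals_min_area = cals_min_area,
                 slice_thickness = slice_thickness, ci_method = ci_method),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline end to end
#'
#' Executes, under one seed: cohort generation, the paired CTA/NCCT phantom
#' scoring experiment, a demonstration phantom's component analysis and
#' vulnerability call, and the statistics battery (diagnostic metrics with
#' CIs, Mann-Whitney grade comparisons by IPH stratum, Spearman and
#' Bland-Altman agreement of CTA vs NCCT CALS, Cohen's kappa). All outputs
#' are written under `out_dir` (`config.json`, `cohort.csv`, `phantoms/`,
#' `lesions/`, `metrics.json`, `report/`) and listed, with MD5 checksums, in
#' `manifest.json`. The same config and seed reproduce identical checksums.
#' A failing stage is recorded in the manifest before the error is re-raised.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly: a list with `config`, `status`, `files`
#'   (data frame of path + md5) and `failed_stage` (NA on success).
#' @export
run_end_to_end <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "phantoms"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "lesions"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "report"), showWarnings = FALSE)
  failed <- NA_character_
  current <- "config"

  res <- tryCatch({
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)

    current <- "cohort"
    cs <- cohort_spec(config$n_patients, config$prevalence,
                      config$sensitivity, config$specificity,
                      exact_margins = config$exact_margins,
                      seed = config$seed)
    cohort <- generate_cohort(cs)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    stage_log("cohort", "n=%d, %d IPH-positive", nrow(cohort), sum(cohort$iph))

    current <- "phantoms"
    exp <- paired_cals_experiment(config$n_phantom_pairs,
                                  seed = config$seed + 1000L,
                                  kernel_width_mm = config$blooming_width_mm)
    utils::write.csv(exp, file.path(out_dir, "lesions", "paired_cals.csv"),
                     row.names = FALSE)
    demo <- demo_component_phantom(config$seed + 2000L)
    write_phantom(demo$phantom, file.path(out_dir, "phantoms", "demo"))
    stage_log("phantoms", "%d CTA/NCCT pairs scored; demo phantom written",
              nrow(exp))

    current <- "components"
    labels <- classify_voxels(demo$phantom$volume, demo$phantom$truth$roi)
    profile <- quantify_components(labels)
    call <- call_vulnerability(profile, ulcerated = demo$phantom$truth$ulcerated)
    prof_out <- profile
    prof_out$verdict <- call$verdict
    utils::write.csv(prof_out, file.path(out_dir, "report", "profile.csv"),
                     row.names = FALSE)
    stage_log("components", "dominant %s -> %s", call$dominant, call$verdict)

    current <- "validation"
    metrics <- cohort_statistics(cohort, exp, ci_method = config$ci_method)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    render_bland_altman(exp, file.path(out_dir, "report", "bland_altman.svg"))
    stage_log("validation", "sensitivity %.3f, specificity %.3f",
              metrics$diagnostic$estimate[1], metrics$diagnostic$estimate[2])
    TRUE
  }, error = function(e) {
    failed <<- current
    e
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    config = unclass(config),
    status = if (is.na(failed)) "ok" else "failed",
    failed_stage = failed,
    files = data.frame(path = sub(paste0("^", out_dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (inherits(res, "error"))
    stop(sprintf("stage '%s' failed: %s", failed, conditionMessage(res)),
         call. = FALSE)
  invisible(manifest)
}

# small five-component phantom used for the component-analysis stage
demo_component_phantom <- function(seed) {
  comps <- list(
    list(name = "lipid",          mean = 30,  sd = 3, center = c(12, 12), radius_mm = 1.6, slices = 1:4),
    list(name = "fibrolipid",     mean = 50,  sd = 3, center = c(12, 30), radius_mm = 1.4, slices = 1:4),
    list(name = "fibrotic",       mean = 70,  sd = 3, center = c(30, 12), radius_mm = 1.8, slices = 1:4),
    list(name = "fibrocalcified", mean = 160, sd = 15, center = c(30, 30), radius_mm = 1.2, slices = 1:4),
    list(name = "calcification",  mean = 320, sd = 20, center = c(21, 21), radius_mm = 0.9, slices = 1:4)
  )
  sp <- phantom_spec(shape = c(42, 42, 4), components = comps, seed = seed)
  list(phantom = generate_plaque_volume(sp), spec = sp)
}

#' Full statistics battery on a cohort table
#'
#' Computes every validation statistic the pipeline reports: the confusion
#' table and diagnostic metrics of the software call against the IPH gold
#' standard, Mann-Whitney comparisons of micro-/macrocalcification grades and
#' CTA CALS between IPH strata, Spearman correlation and Bland-Altman
#' agreement (with drift) of CTA vs NCCT CALS, and Cohen's kappa of the call
#' against the gold standard.
#'
#' @param cohort a cohort data frame ([generate_cohort()] / [read_cohort()]).
#' @param paired optional paired phantom experiment table
#'   ([paired_cals_experiment()]); when given, its CTA/NCCT scores are used
#'   for the agreement analyses instead of the cohort columns.
#' @param ci_method CI method for [diagnostic_metrics()].
#' @return a list of results, JSON-serialisable.
#' @export
cohort_statistics <- function(cohort, paired = NULL,
                              ci_method = c("clopper_pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  ct <- confusion(cohort$software_call, cohort$iph)
  dm <- diagnostic_metrics(ct, ci_method = ci_method)
  pos <- cohort$iph == 1
  mw <- function(v) {
    r <- mann_whitney(v[!pos], v[pos])
    list(mean_rank_non_iph = r$mean_rank_a, mean_rank_iph = r$mean_rank_b,
         u = r$u_a, p = r$p)
  }
  cta <- if (is.null(paired)) cohort$cals_cta else paired$cals_cta
  ncct <- if (is.null(paired)) cohort$cals_ncct else paired$cals_ncct
  sp <- spearman_rank(cta, ncct)
  ba <- bland_altman(ncct, cta)
  kp <- cohen_kappa(cohort$software_call, cohort$iph)
  list(
    n = nrow(cohort),
    iph_prevalence_pct = as_pct(mean(cohort$iph), 2),
    confusion = unclass(ct),
    diagnostic = dm,
    mann_whitney = list(micro = mw(cohort$micro_grade),
                        macro = mw(cohort$macro_grade),
                        cals_cta = mw(cohort$cals_cta)),
    spearman_cta_ncct = sp[c("rho", "p", "n")],
    bland_altman = ba[c("mean_diff", "sd_diff", "loa_lower", "loa_upper",
                        "drift_rho", "drift_p", "n")],
    kappa_call_vs_iph = kp[c("po", "pe", "kappa", "band")]
  )
}

#' Render a Bland-Altman plot
#'
#' Difference (NCCT - CTA) against pair mean, with the bias line and 95%
#' limits of agreement.
#'
#' @param paired table with `cals_ncct` and `cals_cta` columns.
#' @param path output SVG path.
#' @return `path`, invisibly.
#' @export
render_bland_altman <- function(paired, path) {
  ba <- bland_altman(paired$cals_ncct, paired$cals_cta)
  grDevices::svg(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  plot(ba$means, ba$differences, pch = 19,
       xlab = "Mean CALS of the two methods",
       ylab = "NCCT - CTA CALS difference",
       main = "Agreement of CTA and NCCT calcification scores")
  graphics::abline(h = ba$mean_diff, col = "red", lwd = 2)
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), lty = 2)
  invisible(path)
}
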