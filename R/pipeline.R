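# End-to-end batch orchestration: generate -> segment -> measure ->
# compare, with per-image child seeds fanned out from one master seed,
# a JSON run manifest, and a long-format results CSV.

# Stable per-image child seed: a fixed LCG-style mix of (master, index),
# kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 97651 * 20011 + as.numeric(index) * 7919 + 13) %%
               2147483629)
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible(NULL)
}

#' Run the full in-silico comparison pipeline
#'
#' For `n_images` seeded synthetic samples: generates a vascular
#' network, renders image + truth mask (optionally with artifacts),
#' segments the image, measures morphometry on both the truth mask
#' (method `"reference"`) and the segmented mask (method
#' `"tubularity"`), runs the manual-protocol emulation on the truth
#' mask (method `"manual"`: branch points and sampled thickness), and
#' the positive pixel count on the image (method `"ppc"`: positive area
#' and strong-positive percentage). Per-image failures are logged and
#' skipped; the run aborts if more than 10% of images fail.
#'
#' Everything is deterministic given `seed`: per-image seeds are a
#' stable hash of (seed, image index), so two runs with the same master
#' seed produce byte-identical results CSVs.
#'
#' @param out_dir output directory (created if missing).
#' @param n_images number of synthetic samples.
#' @param seed master seed.
#' @param params [generator_params()] template; its `seed` field is
#'   replaced per image.
#' @param seg_config [segmentation_config()] for the tubularity arm.
#' @param ppc_conf [ppc_config()] for the positive-pixel-count arm.
#' @param artifacts `NULL` for artifact-free rendering, or an
#'   [artifact_params()] object to corrupt the images.
#' @param manual_n vessels sampled by the manual-protocol emulation.
#' @param write_images write per-sample `img_####.png`,
#'   `mask_####.png` (truth), `seg_####.png` and `truth_####.json`
#'   files. Disable to save time when only the tables matter.
#' @return The run manifest (list, also written to `manifest.json`),
#'   invisibly. Side effects in `out_dir`: `results.csv` (long format:
#'   `image_id, method, metric, value`), `agreement.csv`, `run.log`,
#'   `manifest.json`, and per-sample files if requested.
#' @export
run_pipeline <- function(out_dir, n_images = 30L, seed = 1L,
                         params = generator_params(),
                         seg_config = segmentation_config(),
                         ppc_conf = ppc_config(),
                         artifacts = NULL,
                         manual_n = 20L,
                         write_images = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  t0 <- Sys.time()
  log_line(logf, "pipeline start: n_images=", n_images, " seed=", seed,
           " image=", params$image_height_px, "x", params$image_width_px,
           " artifacts=", !is.null(artifacts))
  rows <- list()
  files <- list()
  failed <- character(0)
  for (i in seq_len(n_images)) {
    id <- sprintf("img_%04d", i)
    res <- tryCatch({
      p_i <- params
      p_i$seed <- child_seed(seed, i)
      net <- generate_network(p_i)
      smp <- render_network(net, p_i)
      if (!is.null(artifacts)) {
        a_i <- artifacts
        a_i$seed <- child_seed(seed, i) + 1L
        smp <- add_artifacts(smp, a_i)
      }
      seg <- segment_vessels(smp$image, seg_config)
      rep_ref <- morphometry_report(smp$truth_mask)
      rep_seg <- morphometry_report(seg)
      sk_ref <- skeletonize_mask(smp$truth_mask)
      man <- sample_thickness(sk_ref, n = manual_n,
                              seed = child_seed(seed, i) + 2L)
      ppc <- classify_pixels(smp$image, ppc_conf)
      if (write_images) {
        files[[id]] <- c(
          image = write_image(smp$image, file.path(out_dir, paste0(id, ".png"))),
          truth_mask = write_mask(smp$truth_mask,
                                  file.path(out_dir, paste0("mask_", id, ".png"))),
          seg_mask = write_mask(seg,
                                file.path(out_dir, paste0("seg_", id, ".png"))),
          truth = write_report_json(smp$truth,
                                    file.path(out_dir, paste0("truth_", id, ".json"))))
      }
      long_rows(id, rep_ref, rep_seg, man, ppc, smp)
    }, error = function(e) {
      log_line(logf, "FAILED ", id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, id) else rows[[id]] <- res
    if (i %% 10 == 0) log_line(logf, "processed ", i, "/", n_images)
  }
  if (n_images > 0 && length(failed) > n_images * 0.10) {
    log_line(logf, "aborting: ", length(failed), "/", n_images, " images failed")
    stop(length(failed), " of ", n_images, " images failed", call. = FALSE)
  }
  results <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(image_id = character(), method = character(),
                   metric = character(), value = numeric())
  readr::write_csv(results, file.path(out_dir, "results.csv"))
  agreement <- NULL
  if (length(rows) >= 2) {
    agreement <- suppressWarnings(compare_methods(results))
    readr::write_csv(agreement, file.path(out_dir, "agreement.csv"))
    log_line(logf, "agreement table: ", nrow(agreement), " method-pair x metric rows")
  } else {
    log_line(logf, "fewer than 2 images succeeded; no comparison attempted")
  }
  manifest <- list(
    run_id = sprintf("camquant-%s-seed%d", format(t0, "%Y%m%d%H%M%S"), seed),
    package_version = as.character(utils::packageVersion("camquant")),
    seed = as.integer(seed),
    n_images = as.integer(n_images),
    failed = failed,
    config = list(generator = unclass(params),
                  segmentation = unclass(seg_config),
                  ppc = unclass(ppc_conf),
                  artifacts = if (!is.null(artifacts)) unclass(artifacts),
                  manual_n = manual_n),
    files = files,
    outputs = list(results = file.path(out_dir, "results.csv"),
                   agreement = if (!is.null(agreement))
                     file.path(out_dir, "agreement.csv")),
    started = format(t0, "%Y-%m-%d %H:%M:%OS3"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_line(logf, "pipeline done: ", length(rows), " images in ",
           sprintf("%.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(manifest)
}

# Assemble the long-format rows for one image.
long_rows <- function(id, rep_ref, rep_seg, man, ppc, smp) {
  metric_cols <- c("total_area_px2", "total_length_px", "n_branch_points",
                   "mean_thickness_px", "n_vessels", "vessel_density",
                   "lacunarity")
  per_method <- function(method, rep) {
    tibble::tibble(image_id = id, method = method, metric = metric_cols,
                   value = as.numeric(unlist(rep[1, metric_cols])))
  }
  dplyr::bind_rows(
    per_method("reference", rep_ref),
    per_method("tubularity", rep_seg),
    tibble::tibble(image_id = id, method = "manual",
                   metric = c("n_branch_points", "mean_thickness_px"),
                   value = c(man$n_branch_points, man$sampled_thickness_px)),
    tibble::tibble(image_id = id, method = "ppc",
                   metric = c("positive_area_px2", "strong_positive_pct"),
                   value = c(ppc$n_strong + ppc$n_medium + ppc$n_weak,
                             ppc$strong_positive_pct)),
    tibble::tibble(image_id = id, method = "truth",
                   metric = c("n_branch_points", "total_length_px",
                              "mean_thickness_px", "total_area_px2"),
                   value = c(smp$truth$n_branch_points,
                             smp$truth$total_length_px,
                             2 * smp$truth$mean_radius_px - 1,
                             smp$truth$mask_area_px2)))
}
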