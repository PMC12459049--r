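# End-to-end orchestration: bin matrix in, SEG files, plot-data tables,
# optional figures, aberration matrices and a run log out.

#' Assemble a pipeline run configuration
#'
#' @param input Path to a bin-matrix TSV ([write_bin_matrix] format), or a
#'   [bin_matrix] object.
#' @param out_dir Output directory (created if missing).
#' @param mode `"cs"`, `"sw"` or `"both"` (default).
#' @param gamma Combined-fit breakpoint penalty.
#' @param theta Aberration-calling threshold.
#' @param weighted Use inverse-variance weights in the sample-wise mode.
#' @param arm_level Also emit arm-level aberration matrices (requires
#'   `arms`).
#' @param arms Optional [arm_table] or BED4 path.
#' @param seed Top-level seed (jitter, CBS permutations).
#' @param return_matrix Also write the segment x sample intensity matrix.
#' @param render Render figures (PDF) next to the plot-data tables.
#' @param alpha,n_perm Sample-wise CBS significance settings.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, mode = c("both", "cs", "sw"),
                       gamma = 1, theta = 0.2, weighted = FALSE,
                       arm_level = FALSE, arms = NULL, seed = 1L,
                       return_matrix = TRUE, render = FALSE,
                       alpha = 0.01, n_perm = 1000) {
  structure(
    list(
      input = input, out_dir = out_dir, mode = match.arg(mode),
      gamma = gamma, theta = theta, weighted = weighted,
      arm_level = arm_level, arms = arms, seed = as.integer(seed),
      return_matrix = return_matrix, render = render,
      alpha = alpha, n_perm = n_perm
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_segment_matrix <- function(segmentation, bm, path) {
  if (inherits(segmentation, "shared_segmentation")) {
    seg <- segmentation$segments
    out <- data.frame(
      region = sprintf(
        "%s:%d-%d", seg$chrom,
        bm$bin_map$start[seg$start_bin], bm$bin_map$end[seg$end_bin]
      ),
      segmentation$means,
      check.names = FALSE
    )
    colnames(out)[-1] <- segmentation$samples
  } else {
    d <- disjoint_intervals(segmentation)
    out <- data.frame(
      region = sprintf(
        "%s:%d-%d", d$atoms$chrom,
        bm$bin_map$start[d$atoms$start_bin], bm$bin_map$end[d$atoms$end_bin]
      ),
      d$means,
      check.names = FALSE
    )
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full cumulative-CNV workflow
#'
#' Reads the bin-level input, runs the requested segmentation mode(s), calls
#' aberrations, and writes SEG files, plot-data TSVs (optionally rendered
#' figures), aberration matrices, the optional segment x sample intensity
#' matrix, and a run log capturing configuration and versions. Reruns with
#' the same configuration and seed produce identical TSV artifacts.
#'
#' @param config A [run_config] or path to its YAML form.
#' @return Invisibly, a named list of the written artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  bm <- if (inherits(config$input, "bin_matrix")) {
    config$input
  } else {
    read_bin_matrix(config$input)
  }
  arms <- config$arms
  if (is.character(arms)) arms <- load_arm_table(arms)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, sprintf(...))
  artifacts <- list()
  emit <- function(name, path) artifacts[[name]] <<- path

  do_plot <- function(pd, stem) {
    emit(paste0(stem, "_data"), write_plot_data(pd, out("%s", stem)))
    if (isTRUE(config$render)) {
      emit(paste0(stem, "_figure"), render_cnv_plot(pd, out("%s.pdf", stem)))
    }
  }

  if (config$mode %in% c("cs", "both")) {
    cs <- segment_genome_cs(bm, pcf_config(gamma = config$gamma))
    calls <- call_aberrations(
      cs, bm, calling_config(theta = config$theta, noise_adjust = FALSE)
    )
    emit("cs_seg", write_seg(cs, bm, out("cs_segments.seg")))
    emit("cs_bkpt", write_breakpoint_bed(cs, bm, out("cs_breakpoints.bed")))
    emit("cs_calls", write_aberration_matrix(calls, out("cs_aberrations.tsv")))
    do_plot(cs_intensity_data(bm, cs, jitter_seed = config$seed), "cs_intensity")
    do_plot(cs_frequency_data(calls, bm), "cs_frequency")
    if (config$return_matrix) {
      emit("cs_matrix", write_segment_matrix(cs, bm, out("cs_segment_matrix.tsv")))
    }
    if (config$arm_level && !is.null(arms)) {
      am <- classify_arms(
        arm_weighted_mean(cs, arms, bm),
        calling_config(theta = config$theta, noise_adjust = FALSE)
      )
      emit("cs_arms", write_aberration_matrix(am, out("cs_arm_aberrations.tsv")))
    }
  }

  if (config$mode %in% c("sw", "both")) {
    sw <- segment_cohort_sw(bm, cbs_config(
      alpha = config$alpha, n_perm = config$n_perm,
      weighted = config$weighted, seed = config$seed
    ))
    calls <- call_aberrations(
      sw, bm, calling_config(theta = config$theta, noise_adjust = TRUE)
    )
    emit("sw_seg", write_seg(sw, bm, out("sw_segments.seg")))
    emit("sw_calls", write_aberration_matrix(calls, out("sw_aberrations.tsv")))
    do_plot(sw_intensity_data(sw, bm), "sw_intensity")
    do_plot(sw_frequency_data(calls, bm), "sw_frequency")
    if (config$return_matrix) {
      emit("sw_matrix", write_segment_matrix(sw, bm, out("sw_segment_matrix.tsv")))
    }
    if (!is.null(arms)) {
      am <- classify_arms(
        arm_weighted_mean(sw, arms, bm),
        calling_config(theta = config$theta, noise_adjust = FALSE)
      )
      emit("sw_arms", write_aberration_matrix(am, out("sw_arm_aberrations.tsv")))
    }
  }

  log_lines <- c(
    sprintf("cumcnv %s | R %s", utils::packageVersion("cumcnv"), getRversion()),
    sprintf("mode=%s gamma=%g theta=%g weighted=%s arm_level=%s seed=%d",
      config$mode, config$gamma, config$theta, config$weighted,
      config$arm_level, config$seed
    ),
    sprintf("bins=%d samples=%d", nrow(bm$values), ncol(bm$values))
  )
  writeLines(log_lines, out("run_log.txt"))
  emit("log", out("run_log.txt"))
  invisible(artifacts)
}
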