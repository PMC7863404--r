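# Pipeline orchestration: run the standard stages from one config with
# deterministic CSV outputs and a reproducibility manifest.

# CSVs are written with fixed column order and 6-significant-digit floats
# so identical runs are byte-identical (hash-stable).
write_csv_stable <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  readr::write_csv(df, path, progress = FALSE)
  path
}

default_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "segment", "classify", "morphometry",
               "cochleogram", "stats"),
    simulate = list(genotypes = c("WT", "KO"), n_cells_per_row = 12,
                    noise_sd = 5),
    cochleogram = list(bin_width = 100),
    transduction = list(control = NULL),
    place_map = list(intercept = 156.5, slope = 82.5, length_mm = 5.13)
  )
}

#' Run the quantification pipeline from a config
#'
#' Stages run in dependency order
#' (`simulate -> segment -> classify -> morphometry -> cochleogram ->
#' transduction -> stats`); each stage echoes its parameters (no silent
#' defaults), writes its outputs as CSV into `output_dir`, and is recorded
#' in a JSON manifest with parameters, output file hashes, seed, and
#' package version. Re-running with the same config and seed reproduces
#' byte-identical CSVs.
#'
#' @param config A YAML file path or a named list. Recognised fields:
#'   `seed`, `stages`, `output_dir`, per-stage parameter lists
#'   (`simulate`, `cochleogram`, `transduction`, `place_map`). The
#'   `transduction` stage requires `transduction$control` (either
#'   `"simulate"` to generate a control specimen or a stack TIFF path).
#' @param output_dir Output directory (overrides the config field).
#' @return The manifest (a list), invisibly; outputs on disk.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  out_dir <- output_dir %||% cfg$output_dir %||% abort("no output_dir set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_log <- list()
  outputs <- character(0)
  say <- function(stage, params) {
    message(sprintf("[%s] %s", stage,
                    paste(names(params), vapply(params, function(x)
                      paste(format(x), collapse = ","), character(1)),
                      sep = "=", collapse = " ")))
    stage_log[[stage]] <<- params
  }
  need <- function(x, stage, what) {
    if (is.null(x)) {
      abort(sprintf("stage `%s` failed: missing %s", stage, what))
    }
    x
  }

  sims <- NULL
  detections_all <- NULL

  for (stage in cfg$stages) {
    if (stage == "simulate") {
      sp <- cfg$simulate
      genotypes <- sp$genotypes %||% "WT"
      say("simulate", c(sp, seed = cfg$seed))
      sims <- lapply(seq_along(genotypes), function(i) {
        pars <- sp[setdiff(names(sp), "genotypes")]
        pars$genotype <- genotypes[i]
        pars$seed <- cfg$seed + i
        sim <- do.call(cochlea_sim_params, pars) |> sim_cochlea_stack()
        f <- file.path(out_dir, paste0("truth_", genotypes[i], ".csv"))
        outputs <<- c(outputs, write_csv_stable(sim$truth, f))
        sim
      })
      names(sims) <- genotypes
    } else if (stage == "segment") {
      need(sims, "segment", "simulated stacks (run `simulate` first)")
      say("segment", list(channel = "DAPI"))
      for (g in names(sims)) {
        sims[[g]]$segments <- segment_nuclei(sims[[g]]$stack)
        f <- file.path(out_dir, paste0("segments_", g, ".csv"))
        outputs <- c(outputs, write_csv_stable(sims[[g]]$segments, f))
      }
    } else if (stage == "classify") {
      say("classify", list(myo_channel = "MYO7A", axis = "pillar polyline"))
      for (g in names(sims)) {
        need(sims[[g]]$segments, "classify", "segments")
        sims[[g]]$detections <- classify_cells(sims[[g]]$segments,
                                               sims[[g]]$stack,
                                               axis = sims[[g]]$polyline)
      }
      detections_all <- dplyr::bind_rows(
        lapply(names(sims), function(g) {
          dplyr::mutate(as_tibble(sims[[g]]$detections), genotype = g)
        }))
      outputs <- c(outputs, write_csv_stable(
        detections_all, file.path(out_dir, "detections.csv")))
    } else if (stage == "morphometry") {
      need(detections_all, "morphometry", "detections")
      say("morphometry", list(voxel_size = "um (landmarks already in um)"))
      morpho <- detections_all |>
        dplyr::group_by(.data$genotype) |>
        dplyr::group_modify(~ measure_nuclei(.x)) |>
        dplyr::ungroup()
      outputs <- c(outputs, write_csv_stable(
        morpho, file.path(out_dir, "morphometry.csv")))
      detections_all <- morpho
    } else if (stage == "cochleogram") {
      bw <- cfg$cochleogram$bin_width %||% 100
      say("cochleogram", list(bin_width = bw))
      for (g in names(sims)) {
        need(sims[[g]]$detections, "cochleogram", "detections")
        bins <- bin_cochleogram(sims[[g]]$detections, sims[[g]]$polyline,
                                bin_width = bw)
        f <- file.path(out_dir, paste0("cochleogram_", g, ".csv"))
        outputs <- c(outputs, write_csv_stable(bins, f))
      }
    } else if (stage == "transduction") {
      ctl <- need(cfg$transduction$control, "transduction",
                  "control-specimen path (`transduction$control`)")
      say("transduction", list(control = ctl))
      control_sim <- if (identical(ctl, "simulate")) {
        pars <- cfg$simulate[setdiff(names(cfg$simulate), "genotypes")]
        pars$genotype <- "WT"
        pars$transduced_fraction <- 0
        pars$seed <- cfg$seed + 1000
        do.call(cochlea_sim_params, pars) |> sim_cochlea_stack()
      } else {
        list(stack = read_stack_tiff(ctl))
      }
      cdet <- classify_cells(segment_nuclei(control_sim$stack),
                             control_sim$stack)
      ctl_stats <- control_stats(cdet, control_sim$stack)
      for (g in names(sims)) {
        need(sims[[g]]$detections, "transduction", "detections")
        q <- gfp_quantify(sims[[g]]$detections, sims[[g]]$stack, ctl_stats)
        outputs <- c(outputs, write_csv_stable(
          transduction_rate(q),
          file.path(out_dir, paste0("transduction_", g, ".csv"))))
      }
    } else if (stage == "stats") {
      need(detections_all, "stats", "morphometry table")
      if (!"distance_um" %in% names(detections_all)) {
        abort("stage `stats` failed: run `morphometry` first")
      }
      say("stats", list(model = "distance ~ type * genotype (balanced subsample)"))
      d <- detections_all |>
        dplyr::group_by(.data$genotype, .data$type) |>
        dplyr::slice_head(n = min(table(detections_all$genotype,
                                        detections_all$type))) |>
        dplyr::ungroup()
      fit <- anova_two_way(d, .data$distance_um, .data$type, .data$genotype)
      outputs <- c(outputs, write_csv_stable(
        tidy(fit), file.path(out_dir, "anova_distance.csv")))
    } else {
      abort(sprintf("unknown stage `%s`", stage))
    }
  }

  manifest <- list(
    package = "otoquant",
    version = as.character(utils::packageVersion("otoquant")),
    seed = cfg$seed,
    stages = stage_log,
    outputs = lapply(setNames(nm = basename(outputs)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
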