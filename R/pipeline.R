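#' Run the full hole-hopping analysis pipeline
#'
#' Wires the stages end to end: obtain a system (generate a synthetic one,
#' or read topology/trajectory/series files), then geometry and conformer
#' analysis, partitioned surface potentials, ET detection and outcome
#' classification, proximal solvation, and the theory block. Every stage
#' writes its artifact under `out_dir` (when given) and contributes to the
#' returned summary; the seed and every numeric default are echoed into
#' the summary for provenance.
#'
#' @param config A named list (or path to a YAML file) with exactly one of:
#'   \describe{
#'     \item{synthetic}{List of [synthetic_config()] arguments.}
#'     \item{input}{List with paths `pdb`, `fragment_config`, `xyz`,
#'       `series`.}
#'   }
#'   plus optional elements `out_dir`, `seed` (overrides the synthetic
#'   seed), and `thresholds` (any of `conformer_threshold`,
#'   `conformer_hysteresis`, `f_hi`, `hole_floor`, `min_cs2_dwell`,
#'   `surface_scale`, `points_per_atom`, `potential_stride`, `gr_bin_width`,
#'   `gr_r_max`, `gr_bulk_density`, `gr_mc_samples`, `lag_max`, `r_cut`)
#'   and `theory` (arguments to [et_parameters()]).
#' @return A `pipeline_summary` list: `system` (the in-memory objects),
#'   `geometry`, `conformers`, `potentials`, `outcome`, `solvation`,
#'   `theory`, `settings`, and `summary` (the JSON-ready digest).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp) {
    stop("config must supply exactly one of `synthetic` or `input`",
         call. = FALSE)
  }
  th <- utils::modifyList(list(
    conformer_threshold = 5.0, conformer_hysteresis = 0.3,
    f_hi = 0.8, hole_floor = 0.5, min_cs2_dwell = 200,
    surface_scale = 2.0, points_per_atom = 64, potential_stride = 10,
    gr_bin_width = 0.25, gr_r_max = 6, gr_bulk_density = 0.0334,
    gr_mc_samples = 1e4, gr_frame_stride = 100,
    lag_max = 50, r_cut = 3.5
  ), config$thresholds %||% list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sys <- stage("generate", {
    if (has_syn) {
      args <- config$synthetic
      if (!is.null(config$seed)) args$seed <- config$seed
      generate_system(do.call(synthetic_config, args))
    } else {
      inp <- config$input
      for (p in c("pdb", "fragment_config", "xyz", "series")) {
        if (is.null(inp[[p]]) || !file.exists(inp[[p]])) {
          stop("missing input file for `", p, "`: ",
               inp[[p]] %||% "<unset>", call. = FALSE)
        }
      }
      topo <- read_topology(inp$pdb, inp$fragment_config)
      list(topology = topo,
           trajectory = read_xyz_trajectory(inp$xyz, topo),
           series = read_fragment_series(inp$series),
           truth = NULL)
    }
  })
  seed <- config$seed %||% (if (has_syn) (config$synthetic$seed %||% 1) else 1)

  geom <- stage("geometry", {
    geometry_series(sys$trajectory, sys$topology)
  })
  conf <- stage("geometry", {
    d <- geom[geom$pair == "dmp-W124", ]
    classify_conformers(d$d_min, th$conformer_threshold,
                        th$conformer_hysteresis)
  })

  pot_frames <- seq(1, n_frames(sys$trajectory), by = th$potential_stride)
  pot <- stage("potential", {
    partition_trace(sys$trajectory, sys$topology,
                    scale = th$surface_scale,
                    points_per_atom = th$points_per_atom,
                    seed = seed, frames = pot_frames)
  })

  outcome <- stage("detect", {
    classify_outcome(sys$series, min_cs2_dwell = th$min_cs2_dwell,
                     f_hi = th$f_hi, hole_floor = th$hole_floor)
  })

  gr_frames <- seq(1, n_frames(sys$trajectory), by = th$gr_frame_stride)
  solv <- stage("solvation", {
    residues <- c("W124", "W122")
    gr <- purrr::map(residues, function(res) {
      proximal_gr(sys$trajectory, sys$topology, res, residues = residues,
                  bin_width = th$gr_bin_width, r_max = th$gr_r_max,
                  bulk_density = th$gr_bulk_density,
                  mc_samples = th$gr_mc_samples, seed = seed,
                  frames = gr_frames)
    })
    names(gr) <- residues
    cn <- purrr::map_dbl(residues, function(res) {
      coordination_number(sys$trajectory, sys$topology, res,
                          residues = residues, r_cut = th$r_cut,
                          frames = gr_frames)
    })
    names(cn) <- residues
    list(gr = gr, cn = cn)
  })

  theory <- stage("theory", {
    do.call(et_parameters, config$theory %||%
              list(lambda = 800, delta_g = 11, h_ab = 40, h_ab_min = 10))
  })

  summary <- list(
    seed = seed,
    settings = th,
    conformer_occupancy = as.list(conf$occupancy),
    verdict = outcome$verdict,
    events = outcome$events,
    deloc_fraction = outcome$deloc_fraction,
    dphi_range_v = range(pot$dphi),
    coordination_numbers = as.list(solv$cn),
    theory = as.data.frame(tidy(theory))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(geom, file.path(config$out_dir, "geometry.csv"))
    readr::write_csv(pot, file.path(config$out_dir, "potentials.csv"))
    readr::write_csv(outcome$labels,
                     file.path(config$out_dir, "state_labels.csv"))
    readr::write_csv(dplyr::bind_rows(purrr::imap(
      solv$gr, ~dplyr::mutate(tibble::as_tibble(.x), residue = .y))),
      file.path(config$out_dir, "solvation.csv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  structure(
    list(system = sys, geometry = geom, conformers = conf, potentials = pot,
         outcome = outcome, solvation = solv, theory = theory,
         settings = th, summary = summary),
    class = "pipeline_summary"
  )
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("<pipeline_summary>\n")
  cat(sprintf("  verdict: %s; occupancy(in) = %.2f\n",
              x$outcome$verdict, x$conformers$occupancy[["in"]]))
  cat(sprintf("  frames: %d; dphi range %.2f..%.2f V\n",
              n_frames(x$system$trajectory),
              min(x$potentials$dphi), max(x$potentials$dphi)))
  invisible(x)
}
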