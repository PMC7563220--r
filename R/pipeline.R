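#' Experiment configuration for a segmentation-sensitivity study
#'
#' Describes the full study grid: phantoms x tumor sites x GTV sizes x
#' segmentation schemes. The `"detailed"` scheme is always included — it is
#' the benchmark that drives are optimized on.
#'
#' @param phantom a [phantom_params()] record or a list of them.
#' @param sites tumor sites to study.
#' @param sizes GTV sizes, subset of small/medium/large.
#' @param schemes segmentation scheme names.
#' @param solver a [solver_settings()].
#' @param applicator an [applicator_model()].
#' @param swarm a [swarm_config()] (used when `drive = "pso"`).
#' @param seed global integer seed; phantom and swarm seeds are derived from
#'   it as named sub-seeds.
#' @param drive `"pso"` (swarm-optimized on the detailed benchmark) or
#'   `"focus"` (deterministic conjugate-phase focusing on the HTV centroid).
#' @param output_dir optional directory for [write_study_report()].
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_params(),
                              sites = "cervix",
                              sizes = c("small", "medium", "large"),
                              schemes = .scheme_names,
                              solver = solver_settings(),
                              applicator = applicator_model(),
                              swarm = swarm_config(),
                              seed = 1L, drive = c("pso", "focus"),
                              output_dir = NULL) {
  drive <- match.arg(drive)
  if (inherits(phantom, "phantom_params")) phantom <- list(phantom)
  if (!all(sizes %in% c("small", "medium", "large"))) {
    stop("sizes must be a subset of small/medium/large")
  }
  schemes <- union("detailed", schemes)
  bad <- setdiff(schemes, .scheme_names)
  if (length(bad) > 0) stop("unknown scheme(s): ", paste(bad, collapse = ", "))
  structure(list(phantom = phantom, sites = sites, sizes = sizes,
                 schemes = schemes, solver = solver, applicator = applicator,
                 swarm = swarm, seed = as.integer(seed), drive = drive,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run the full segmentation-sensitivity study
#'
#' For each phantom and tumor site: (1) generate the detailed phantom at each
#' GTV size (the sizes share one anatomy seed, so the GTVs nest); (2) solve
#' per-channel fields for the detailed materials and re-solve for every
#' reduced scheme on the same grid and applicator (materials change the
#' electromagnetic solution; only the drive is frozen); (3) optimize the
#' drive on the detailed benchmark; (4) apply the frozen drive to every
#' scheme; (5) compute THQ, |dTHQ| and per-tissue |dRD| against the detailed
#' benchmark, with tissue masks always taken from the detailed labels;
#' (6) aggregate per scheme the maximum |dTHQ| across sizes (with the SD
#' across sizes reported alongside) and boxplot summaries of per-tissue
#' max-over-sizes |dRD|.
#'
#' A failure in one (phantom, site, size) cell is logged and tabulated; the
#' study continues.
#'
#' @param config an [experiment_config()].
#' @param progress emit per-stage messages.
#' @return object of class `study_report`: list with `cells` (per
#'   phantom/site/size/scheme THQ and |dTHQ|), `aggregate` (max and SD of
#'   |dTHQ| across sizes plus acceptability flag), `drd` (per-tissue rows),
#'   `boxplots` (per site/scheme summaries of max-over-sizes |dRD|),
#'   `failures`, `config`, `config_hash`, `seed`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (progress) message(sprintf(...))
  table <- default_tissue_table()
  cells <- list(); drd_rows <- list(); failures <- list()

  for (pi in seq_along(config$phantom)) {
    for (site in config$sites) {
      ph_seed <- sub_seed(config$seed, sprintf("phantom_%d_%s", pi, site))
      for (size in config$sizes) {
        res <- tryCatch(
          run_cell(config, pi, site, size, ph_seed, table, say),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          say("cell (%d, %s, %s) FAILED: %s", pi, site, size,
              conditionMessage(res))
          failures[[length(failures) + 1]] <- data.frame(
            phantom = pi, site = site, size = size,
            error = conditionMessage(res))
          next
        }
        cells[[length(cells) + 1]] <- res$cells
        drd_rows[[length(drd_rows) + 1]] <- res$drd
      }
    }
  }

  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(phantom = integer(), site = character(), size = character(),
               scheme = character(), thq = numeric(), dthq_pct = numeric())
  drd <- if (length(drd_rows)) do.call(rbind, drd_rows) else NULL
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(phantom = integer(), site = character(), size = character(),
               error = character())

  aggregate <- aggregate_cells(cells)
  boxplots <- aggregate_drd(drd)

  structure(list(
    cells = cells, aggregate = aggregate, drd = drd, boxplots = boxplots,
    failures = failures, config = config, config_hash = object_hash(config),
    seed = config$seed
  ), class = "study_report")
}

# One (phantom index, site, size) cell: solve every scheme, optimize on the
# detailed benchmark, apply the frozen drive everywhere.
run_cell <- function(config, pi, site, size, ph_seed, table, say) {
  pp <- config$phantom[[pi]]
  pp$tumor_site <- site
  pp$gtv_size <- size
  pp$sex <- switch(site, cervix = "female", prostate = "male", pp$sex)
  phantom3d <- generate_phantom(pp, seed = ph_seed)
  phantom <- if (config$solver$mode == "2d") phantom_slice(phantom3d) else
    phantom3d
  masks <- tissue_masks(phantom)

  t0 <- Sys.time()
  fieldsets <- list()
  for (sc_name in config$schemes) {
    sc <- build_scheme(sc_name, phantom_label_set())
    mats <- assign_material_grids(phantom, sc, table, config$applicator,
                                  config$solver)
    fieldsets[[sc_name]] <- solve_all_channels(mats)
  }
  say("cell (%d, %s, %s): %d scheme solves in %.1fs", pi, site, size,
      length(config$schemes), as.numeric(Sys.time() - t0, units = "secs"))

  det_scheme <- build_scheme("detailed", phantom_label_set())
  drive <- if (config$drive == "pso") {
    sw <- config$swarm
    sw$seed <- sub_seed(config$seed, sprintf("swarm_%d_%s_%s", pi, site, size))
    optimize_drive(fieldsets[["detailed"]], phantom, det_scheme, sw,
                   table)$drive
  } else {
    focus_drive(fieldsets[["detailed"]], phantom$htv_mask)
  }

  sar_of <- function(sc_name) {
    sc <- build_scheme(sc_name, phantom_label_set())
    sr <- phantom_sigma_rho(phantom, sc, table)
    total <- combine_fields(fieldsets[[sc_name]], drive)
    compute_sar(total, sr$sigma, sr$rho, phantom)
  }
  sar_det <- sar_of("detailed")
  thq_det <- compute_thq(sar_det)

  cell_rows <- list(); drd_list <- list()
  for (sc_name in config$schemes) {
    sar_n <- if (sc_name == "detailed") sar_det else sar_of(sc_name)
    thq_n <- if (sc_name == "detailed") thq_det else compute_thq(sar_n)
    cell_rows[[sc_name]] <- data.frame(
      phantom = pi, site = site, size = size, scheme = sc_name,
      thq = thq_n, dthq_pct = compute_dthq(thq_n, thq_det),
      drive = config$drive, stringsAsFactors = FALSE)
    dd <- suppressWarnings(compute_drd(sar_n, sar_det, masks))
    dd <- data.frame(phantom = pi, site = site, size = size,
                     scheme = sc_name, dd, stringsAsFactors = FALSE)
    drd_list[[sc_name]] <- dd
  }
  list(cells = do.call(rbind, cell_rows), drd = do.call(rbind, drd_list))
}

# Max |dTHQ| across the GTV sizes, with the SD across sizes alongside.
aggregate_cells <- function(cells) {
  if (nrow(cells) == 0) return(cells)
  sp <- split(cells, cells[c("phantom", "site", "scheme")], drop = TRUE)
  rows <- lapply(sp, function(g) {
    data.frame(phantom = g$phantom[1], site = g$site[1], scheme = g$scheme[1],
               max_dthq_pct = max(g$dthq_pct),
               sd_dthq_pct = if (nrow(g) > 1) stats::sd(g$dthq_pct) else NA_real_,
               n_sizes = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$phantom, out$site, out$scheme), ]
  rownames(out) <- NULL
  out$dthq_acceptable <- out$max_dthq_pct <= 5
  out
}

# Boxplot summaries over tissues of the max-over-sizes per-tissue |dRD|.
aggregate_drd <- function(drd) {
  if (is.null(drd) || nrow(drd) == 0) return(NULL)
  sp <- split(drd, drd[c("phantom", "site", "scheme")], drop = TRUE)
  out <- lapply(sp, function(g) {
    per_tissue <- vapply(split(g, g$tissue), function(t) {
      if (all(is.na(t$drd_pct))) NA_real_ else max(t$drd_pct, na.rm = TRUE)
    }, numeric(1))
    summ <- suppressWarnings(summarize_boxplot(per_tissue))
    list(phantom = g$phantom[1], site = g$site[1], scheme = g$scheme[1],
         max_drd_per_tissue = as.list(per_tissue),
         summary = as.list(summ))
  })
  unname(out)
}

#' Classify clinical relevance of study cells
#'
#' Flags each aggregated (phantom, site, scheme) cell as acceptable when its
#' maximum |dTHQ| across GTV sizes is at or below the 5 percent
#' clinical-relevance threshold.
#'
#' @param report a `study_report`.
#' @return the aggregate data.frame with the `dthq_acceptable` flag.
#' @export
classify_relevance <- function(report) {
  stopifnot(inherits(report, "study_report"))
  agg <- report$aggregate
  agg$dthq_acceptable <- agg$max_dthq_pct <= 5
  agg
}

#' Write a study report to disk
#'
#' Emits `cells.csv`, `aggregate.csv`, `drd.csv`, `failures.csv`,
#' `boxplots.json` and `study_meta.json` (config hash, seed). Two runs with
#' the same configuration and seed produce byte-identical files.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wcsv(report$cells, "cells.csv")
  wcsv(report$aggregate, "aggregate.csv")
  if (!is.null(report$drd)) wcsv(report$drd, "drd.csv")
  wcsv(report$failures, "failures.csv")
  jsonlite::write_json(report$boxplots, file.path(dir, "boxplots.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(list(config_hash = report$config_hash,
                            seed = report$seed),
                       file.path(dir, "study_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$cells), " cells, ",
      nrow(x$failures), " failures\n", sep = "")
  if (nrow(x$aggregate) > 0) {
    cat("max |dTHQ| across sizes, by scheme:\n")
    print(x$aggregate[c("phantom", "site", "scheme", "max_dthq_pct",
                        "sd_dthq_pct", "dthq_acceptable")], row.names = FALSE)
  }
  invisible(x)
}
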