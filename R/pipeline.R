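#' Configuration for a synthetic encroachment/water-condition study
#'
#' Describes a factorial design of treatment groups (e.g. low water stress,
#' moderate water stress, field capacity) with per-group soil saturation and
#' stem embolism rate, replicated `n_replicates` times. Every replicate gets
#' its own deterministic seed derived from `seed`.
#'
#' @param groups named list; each element a list with `saturation` (soil
#'   water fraction) and `embolism_rate` (stem).
#' @param n_replicates replicates per group.
#' @param soil named list of overrides for [soil_phantom_spec()]
#'   (e.g. `grid_shape`, `n_tubes`).
#' @param stem named list of overrides for [stem_phantom_spec()].
#' @param seed base integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(groups = list(
                           LWS = list(saturation = 0.15, embolism_rate = 0.24),
                           MWS = list(saturation = 0.40, embolism_rate = 0.56),
                           FCS = list(saturation = 0.70, embolism_rate = 0.34)),
                         n_replicates = 3,
                         soil = list(grid_shape = c(96, 96, 96),
                                     n_tubes = 15, n_spheres = 30,
                                     n_blobs = 40),
                         stem = list(grid_shape = c(48, 120, 120),
                                     n_vessels = 40),
                         seed = 1L) {
  structure(list(groups = groups, n_replicates = n_replicates,
                 soil = soil, stem = stem, seed = as.integer(seed)),
            class = "study_config")
}

cell_seed <- function(base, g, r, offset = 0L) {
  (as.integer(base) + 7919L * as.integer(g) + 104729L * as.integer(r) +
     as.integer(offset)) %% 2147483647L
}

run_soil_cell <- function(cfg, gname, gi, ri) {
  gr <- cfg$groups[[gname]]
  args <- cfg$soil
  args$saturation <- gr$saturation
  args$seed <- cell_seed(cfg$seed, gi, ri)
  spec <- do.call(soil_phantom_spec, args)
  ph <- make_soil_phantom(spec)
  seg <- segment_soil(ph$volume)
  regions <- label_components(seg$pore, water = seg$water)
  roi_m3 <- prod(dim(ph$volume$data)) * (spec$voxel_size * 1e-6)^3
  sk <- suppressWarnings(skeletonize(seg$pore))
  ns <- network_summary(regions, sk, roi_m3, mask = seg$pore)
  pw_num <- pwp(regions, by = "number", group_by = "size_class")
  pw_vol <- pwp(regions, by = "volume", group_by = "size_class")
  list(group = gname, replicate = ri,
       thresholds = seg$thresholds,
       seed = args$seed,
       vars = c(porosity = ns$porosity,
                ND_per_m3 = ns$ND_per_m3, BD_per_m3 = ns$BD_per_m3,
                SD_m2_per_m3 = ns$SD_m2_per_m3, NoD_per_m3 = ns$NoD_per_m3,
                MA_deg = ns$MA_deg, CN = ns$CN, HR_mm = ns$HR_mm,
                tortuosity = ns$tortuosity,
                pwp_num_micro = pw_num$pwp_percent[pw_num$group == "micro"],
                pwp_num_meso = pw_num$pwp_percent[pw_num$group == "meso"],
                pwp_num_macro = pw_num$pwp_percent[pw_num$group == "macro"],
                pwp_vol_total = 100 * sum(regions$water_volume_um3) /
                  sum(regions$volume_um3),
                n_water_filled_pores = sum(regions$water_filled)))
}

run_stem_cell <- function(cfg, gname, gi, ri) {
  gr <- cfg$groups[[gname]]
  args <- cfg$stem
  args$embolism_rate <- gr$embolism_rate
  args$seed <- cell_seed(cfg$seed, gi, ri, offset = 499L)
  spec <- do.call(stem_phantom_spec, args)
  ph <- make_stem_phantom(spec)
  # emulate the natural / fully-dried scan pair from the single stem volume:
  # inside the stem, lumina are darker than the wall; embolized lumina carry
  # the air intensity, water-filled ones the water intensity
  roi <- cylindrical_roi(ph$volume, margin = 0.12 *
                           min(dim(ph$volume$data)[2:3]) / 2 *
                           ph$volume$voxel_size)
  h <- graphics::hist(ph$volume$data[roi$data], breaks = 256, plot = FALSE)
  lev <- spec$phase_levels
  thr_lumen <- parabola_threshold(h, c(lev$water[1] + 10, lev$solid[1] - 10))
  thr_air <- (lev$air[1] + lev$water[1]) / 2
  dried <- phase_mask(ph$volume$data < thr_lumen & roi$data,
                      phase = "vessel-lumen", voxel_size = spec$voxel_size)
  natural <- phase_mask(ph$volume$data < thr_air & roi$data,
                        phase = "embolized-vessel",
                        voxel_size = spec$voxel_size)
  water_filled <- extract_water_filled_vessels(natural, dried)
  pop <- vessel_table_from_mask(dried, embolized = natural,
                                stem_area_um2 = ph$stem_area_um2)
  vs <- vessel_summary(pop)
  list(group = gname, replicate = ri, seed = args$seed,
       thresholds = c(lumen = thr_lumen, air = thr_air),
       vars = c(n_vessels = vs$n, Dh_um = vs$Dh_um, D95_um = vs$D95_um,
                mean_area_um2 = vs$mean_area_um2,
                vessel_density_per_mm2 = vs$vessel_density_per_mm2,
                lumen_fraction = vs$lumen_fraction,
                Km = vs$Km, Ks = vs$Ks, Kn = vs$Kn,
                embolism_rate_percent = vs$embolism_rate_percent,
                n_water_filled_vessels = sum(pop$status == "water-filled")))
}

#' Run the full synthetic study pipeline
#'
#' For every group x replicate cell: generate the soil and stem phantoms,
#' segment them, run the pore-network morphometry and the vessel hydraulics,
#' then assemble the statistical layer — per-variable one-way ANOVA with
#' protected-LSD letters across groups, the Pearson correlation matrix of
#' soil against vessel variables, and the univariate regression of
#' water-filled vessel count on water-filled pore count. A failing cell is
#' recorded and skipped, not fatal. All seeds and thresholds are logged.
#' Rerunning with the same config gives byte-identical tables.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, CSV tables and a JSON run
#'   log are written there.
#' @return A report bundle: `soil_cells`, `stem_cells` (per-cell variable
#'   data frames), `anova_tables` (group means, sd, letters per variable),
#'   `correlations`, `regression`, `failed_cells`, `log`.
#' @export
run_study_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  gnames <- names(config$groups)
  soil_rows <- list(); stem_rows <- list()
  failed <- list(); log <- list()
  for (gi in seq_along(gnames)) for (ri in seq_len(config$n_replicates)) {
    gname <- gnames[gi]
    id <- sprintf("%s_rep%d", gname, ri)
    sc <- tryCatch(run_soil_cell(config, gname, gi, ri), error = function(e)
      structure(list(msg = conditionMessage(e)), class = "cell_error"))
    if (inherits(sc, "cell_error")) {
      failed[[paste0("soil_", id)]] <- sc$msg
    } else {
      soil_rows[[id]] <- data.frame(group = gname, replicate = ri,
                                    t(sc$vars))
      log[[paste0("soil_", id)]] <- list(seed = sc$seed,
                                         thresholds = as.list(sc$thresholds))
    }
    st <- tryCatch(run_stem_cell(config, gname, gi, ri), error = function(e)
      structure(list(msg = conditionMessage(e)), class = "cell_error"))
    if (inherits(st, "cell_error")) {
      failed[[paste0("stem_", id)]] <- st$msg
    } else {
      stem_rows[[id]] <- data.frame(group = gname, replicate = ri,
                                    t(st$vars))
      log[[paste0("stem_", id)]] <- list(seed = st$seed,
                                         thresholds = as.list(st$thresholds))
    }
  }
  soil_df <- if (length(soil_rows)) do.call(rbind, soil_rows) else NULL
  stem_df <- if (length(stem_rows)) do.call(rbind, stem_rows) else NULL
  anova_one <- function(df, var) {
    ok <- is.finite(df[[var]])
    if (sum(ok) < 4 || length(unique(df$group[ok])) < 2) return(NULL)
    res <- tryCatch(anova_lsd(df[[var]][ok], df$group[ok]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(variable = var, res$table,
          F = res$F, p = res$p, row.names = NULL)
  }
  anova_tables <- list()
  if (!is.null(soil_df))
    anova_tables$soil <- do.call(rbind, Filter(Negate(is.null),
      lapply(setdiff(names(soil_df), c("group", "replicate")),
             function(v) anova_one(soil_df, v))))
  if (!is.null(stem_df))
    anova_tables$stem <- do.call(rbind, Filter(Negate(is.null),
      lapply(setdiff(names(stem_df), c("group", "replicate")),
             function(v) anova_one(stem_df, v))))
  correlations <- NULL; regression <- NULL
  if (!is.null(soil_df) && !is.null(stem_df) &&
      nrow(soil_df) == nrow(stem_df)) {
    both <- cbind(soil_df[c("porosity", "pwp_vol_total",
                            "n_water_filled_pores", "HR_mm")],
                  stem_df[c("Dh_um", "D95_um", "Kn",
                            "embolism_rate_percent",
                            "n_water_filled_vessels")])
    correlations <- pearson_matrix(both)
    if (sd(soil_df$n_water_filled_pores) > 0)
      regression <- univariate_regression(soil_df$n_water_filled_pores,
                                          stem_df$n_water_filled_vessels)
  }
  bundle <- list(soil_cells = soil_df, stem_cells = stem_df,
                 anova_tables = anova_tables, correlations = correlations,
                 regression = regression, failed_cells = failed, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, nm) if (!is.null(df))
      write.csv(format(df, digits = 10), file.path(out_dir, nm),
                row.names = FALSE)
    wr(soil_df, "soil_cells.csv")
    wr(stem_df, "stem_cells.csv")
    wr(anova_tables$soil, "soil_anova.csv")
    wr(anova_tables$stem, "stem_anova.csv")
    if (!is.null(correlations))
      wr(as.data.frame(round(correlations$r, 10)), "correlations.csv")
    if (!is.null(regression))
      wr(data.frame(slope = regression$slope,
                    intercept = regression$intercept,
                    r_squared = regression$r_squared, p = regression$p),
         "regression.csv")
    jsonlite::write_json(list(failed_cells = failed, log = log),
                         file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}
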