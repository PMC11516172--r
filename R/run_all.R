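#' Configuration for a full synthetic-study run
#'
#' Collects every tunable the pipeline uses, pre-filled with the
#' study-design defaults: 300 m fire-point thinning (the detection
#' resolution) and 1000 m species-point thinning; correlation cutoffs 0.75
#' (fire covariates) and 0.85 (species covariates); AUC gate 0.8 for the
#' presence-only members; 2 pseudo-absences per presence; 70/30
#' train/test split; the `"fire6"` and `"sdm8"` learner registries.
#'
#' @param landscape A [landscape_spec()] (or a list of arguments for one).
#' @param seasons Seasons to model (subset of spring/summer/autumn).
#' @param n_fire,n_species Presence points sampled per season from the true
#'   risk / suitability surfaces.
#' @param thin_fire,thin_species Thinning distances in meters.
#' @param cor_fire,cor_species Absolute-correlation screening cutoffs.
#' @param auc_gate Presence-only ensemble AUC gate.
#' @param pa_multiplier Pseudo-absences per fire presence.
#' @param background_multiplier Background points per species presence
#'   (uniform random background stands in for unobserved species absences).
#' @param train_fraction Training share of each labeled table.
#' @param registry_fire,registry_sdm Learner registry ids.
#' @param species Name tag for the synthetic focal species.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param yaml Optional path to a YAML file whose top-level keys override
#'   the arguments above (its `landscape` key is passed to
#'   [landscape_spec()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(landscape = landscape_spec(),
                       seasons = c("spring", "summer", "autumn"),
                       n_fire = 300L,
                       n_species = 300L,
                       thin_fire = 300,
                       thin_species = 1000,
                       cor_fire = 0.75,
                       cor_species = 0.85,
                       auc_gate = 0.8,
                       pa_multiplier = 2,
                       background_multiplier = 2,
                       train_fraction = 0.7,
                       registry_fire = "fire6",
                       registry_sdm = "sdm8",
                       species = "synthetic_focal",
                       seed = 1L,
                       yaml = NULL) {
  cfg <- list(
    landscape = landscape, seasons = seasons, n_fire = n_fire,
    n_species = n_species, thin_fire = thin_fire, thin_species = thin_species,
    cor_fire = cor_fire, cor_species = cor_species, auc_gate = auc_gate,
    pa_multiplier = pa_multiplier, background_multiplier = background_multiplier,
    train_fraction = train_fraction, registry_fire = registry_fire,
    registry_sdm = registry_sdm, species = species, seed = as.integer(seed)
  )
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) abort(sprintf("Config file '%s' does not exist.", yaml))
    over <- yaml::read_yaml(yaml)
    for (nm in names(over)) {
      if (nm == "landscape") {
        cfg$landscape <- do.call(landscape_spec, over$landscape)
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
  }
  if (is.list(cfg$landscape) && !inherits(cfg$landscape, "landscape_spec")) {
    cfg$landscape <- do.call(landscape_spec, cfg$landscape)
  }
  bad <- setdiff(cfg$seasons, modeled_seasons)
  if (length(bad) > 0L) {
    abort(sprintf("Unsupported season(s) in config: %s.", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

# stage seeds derive from the master seed; k indexes the stage so every
# stochastic step gets its own reproducible stream (kept well under 2^31)
stage_seed <- function(base, k) as.integer(base * 1000L + k)

#' Run the full synthetic study end to end
#'
#' Generates the landscape, then per season: samples and thins fire
#' presences, cross-tabulates them against land use, screens covariates for
#' collinearity, performs two-step pseudo-absence selection, fits the
#' AUC-weighted fire ensemble, thresholds the probability map by maximum
#' TSS, and ranks variable importance; in parallel fits the species ensemble
#' from suitability-sampled presences plus uniform background, thresholds
#' it, and overlays the binary habitat and fire maps (GAP analysis).
#' Between-season change surfaces are computed for consecutive season pairs.
#' All artifacts are written to `out_dir` as plain-text rasters and CSVs,
#' with a JSON manifest of seeds, parameters and per-stage record counts;
#' rerunning with the same config reproduces every file bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage progress messages.
#' @return A list of class `firescape_run` with the landscape, per-season
#'   results, validation/importance/overlap tables, change maps, and the
#'   manifest, invisibly. Artifact paths are in `$paths`.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("firescape_run_"),
                    quiet = FALSE) {
  if (!inherits(config, "run_config")) abort("`config` must come from run_config().")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  base <- config$seed
  paths <- character(0)
  add_path <- function(p) {
    paths <<- c(paths, p)
    p
  }
  counts <- list()

  say("[landscape] generating synthetic landscape (seed %d)", base)
  land <- make_landscape(config$landscape)
  write_raster(land$landuse, add_path(file.path(out_dir, "landuse.asc")))

  season_results <- list()
  fire_validation <- list()
  sdm_validation <- list()
  importance <- list()
  overlaps <- list()
  fire_probs <- list()

  for (i in seq_along(config$seasons)) {
    s <- config$seasons[i]
    stack <- land$stacks[[s]]
    k0 <- i * 100L

    # --- fire side -------------------------------------------------------
    fire_raw <- sample_presences(land$truth, config$n_fire, s,
                                 seed = stage_seed(base, k0 + 1L))
    fire_pts <- thin_points(fire_raw, config$thin_fire)
    say("[%s] fire presences: %d sampled, %d after %gm thinning",
        s, nrow(fire_raw), nrow(fire_pts), config$thin_fire)
    write_occurrences(fire_pts, add_path(file.path(out_dir, sprintf("fire_points_%s.csv", s))))

    ct <- crosstab_landuse(fire_pts, land$landuse)
    write.csv(ct, add_path(file.path(out_dir, sprintf("fire_crosstab_%s.csv", s))),
              row.names = FALSE)

    fire_feats <- extract_at_points(stack, fire_pts, quiet = TRUE)
    screen <- correlation_screen(fire_feats[names(stack$layers)], config$cor_fire)
    write.csv(
      tibble(kept = paste(screen$kept, collapse = ";"),
             dropped = paste(screen$dropped$layer, collapse = ";"),
             threshold = screen$threshold),
      add_path(file.path(out_dir, sprintf("fire_screening_%s.csv", s))),
      row.names = FALSE
    )
    fire_stack <- raster_stack(stack$layers[screen$kept])

    pa_sel <- select_pseudo_absences(
      fire_stack, fire_pts, seed = stage_seed(base, k0 + 10L),
      gate = config$auc_gate, multiplier = config$pa_multiplier,
      train_fraction = config$train_fraction
    )
    write.csv(pa_sel$ensemble$members,
              add_path(file.path(out_dir, sprintf("fire_presence_only_auc_%s.csv", s))),
              row.names = FALSE)

    merged <- dplyr::bind_rows(
      pa_sel$presences[c("x", "y", "season", "label", "source", screen$kept)],
      extract_at_points(fire_stack, pa_sel$pseudo_absences, quiet = TRUE)
    )
    write.csv(merged, add_path(file.path(out_dir, sprintf("fire_training_%s.csv", s))),
              row.names = FALSE)
    table_fire <- split_table(
      merged, merged$label,
      train_fraction = config$train_fraction, seed = stage_seed(base, k0 + 20L)
    )
    fit_fire <- fit_suite(table_fire, config$registry_fire,
                          seed = stage_seed(base, k0 + 30L))
    write.csv(tidy(fit_fire),
              add_path(file.path(out_dir, sprintf("fire_member_auc_%s.csv", s))),
              row.names = FALSE)

    prob_fire <- predict_ensemble(fit_fire, fire_stack)
    rep_fire <- tss_threshold(fit_fire$test_scores, fit_fire$test_labels, tag = s)
    bin_fire <- binarize(prob_fire, rep_fire$threshold)
    write_raster(prob_fire, add_path(file.path(out_dir, sprintf("fire_prob_%s.asc", s))))
    write_raster(bin_fire, add_path(file.path(out_dir, sprintf("fire_binary_%s.asc", s))))
    say("[%s] fire ensemble AUC %.3f, TSS %.3f at threshold %.3f",
        s, rep_fire$auc, rep_fire$tss, rep_fire$threshold)

    imp <- variable_importance(table_fire, seed = stage_seed(base, k0 + 40L), tag = s)
    write.csv(imp, add_path(file.path(out_dir, sprintf("fire_importance_%s.csv", s))),
              row.names = FALSE)

    # --- species side ----------------------------------------------------
    sp_raw <- sample_presences(land$truth, config$n_species, s,
                               seed = stage_seed(base, k0 + 50L),
                               surface = "suitability")
    sp_pts <- thin_points(sp_raw, config$thin_species)
    say("[%s] species presences: %d sampled, %d after %gm thinning",
        s, nrow(sp_raw), nrow(sp_pts), config$thin_species)
    write_occurrences(sp_pts, add_path(file.path(out_dir, sprintf("species_points_%s.csv", s))))

    sp_feats <- extract_at_points(stack, sp_pts, quiet = TRUE)
    screen_sp <- correlation_screen(sp_feats[names(stack$layers)], config$cor_species)
    sdm_stack <- raster_stack(stack$layers[screen_sp$kept])
    sp_feats <- sp_feats[c("x", "y", "season", "label", "source", screen_sp$kept)]

    cells <- as_tibble(sdm_stack, drop_na = TRUE)
    n_bg <- min(nrow(cells), config$background_multiplier * nrow(sp_feats))
    bg_idx <- with_seed(stage_seed(base, k0 + 60L), sample.int(nrow(cells), n_bg))
    background <- cells[bg_idx, ]
    ctr <- background[c("x", "y")]
    bg <- occurrence_set(ctr$x, ctr$y, season = s,
                         label = "pseudo_absence", source = "uniform_background")
    bg <- dplyr::bind_cols(bg, background[screen_sp$kept])
    merged_sp <- dplyr::bind_rows(sp_feats, bg)
    table_sdm <- split_table(
      merged_sp, merged_sp$label,
      train_fraction = config$train_fraction, seed = stage_seed(base, k0 + 70L)
    )
    fit_sdm <- fit_suite(table_sdm, config$registry_sdm,
                         seed = stage_seed(base, k0 + 80L))
    prob_sdm <- predict_ensemble(fit_sdm, sdm_stack)
    rep_sdm <- tss_threshold(fit_sdm$test_scores, fit_sdm$test_labels,
                             tag = paste(config$species, s, sep = "/"))
    bin_sdm <- binarize(prob_sdm, rep_sdm$threshold)
    write_raster(prob_sdm, add_path(file.path(out_dir, sprintf("sdm_prob_%s.asc", s))))
    write_raster(bin_sdm, add_path(file.path(out_dir, sprintf("sdm_binary_%s.asc", s))))
    say("[%s] SDM ensemble AUC %.3f, TSS %.3f", s, rep_sdm$auc, rep_sdm$tss)

    gap <- gap_overlap(bin_sdm, bin_fire, species = config$species, season = s)
    write_raster(gap$class_map, add_path(file.path(out_dir, sprintf("gap_classes_%s.asc", s))))

    fire_validation[[s]] <- rep_fire
    sdm_validation[[s]] <- rep_sdm
    importance[[s]] <- imp
    overlaps[[s]] <- gap
    fire_probs[[s]] <- prob_fire
    counts[[s]] <- list(
      fire_sampled = nrow(fire_raw), fire_thinned = nrow(fire_pts),
      fire_layers_dropped = nrow(screen$dropped),
      presence_only_passing = sum(pa_sel$ensemble$members$passed),
      pseudo_absences = nrow(pa_sel$pseudo_absences),
      fire_learners_dropped = length(fit_fire$dropped),
      species_sampled = nrow(sp_raw), species_thinned = nrow(sp_pts),
      species_layers_dropped = nrow(screen_sp$dropped),
      background_points = n_bg,
      sdm_learners_dropped = length(fit_sdm$dropped)
    )
    season_results[[s]] <- list(
      fire_points = fire_pts, crosstab = ct, screening = screen,
      pseudo_absence = pa_sel, fire_fit = fit_fire, fire_prob = prob_fire,
      fire_binary = bin_fire, fire_report = rep_fire, importance = imp,
      species_points = sp_pts, sdm_fit = fit_sdm, sdm_prob = prob_sdm,
      sdm_binary = bin_sdm, sdm_report = rep_sdm, gap = gap
    )
  }

  # --- between-season change surfaces -----------------------------------
  change_maps <- list()
  if (length(config$seasons) >= 2L) {
    for (i in seq_len(length(config$seasons) - 1L)) {
      a <- config$seasons[i]
      b <- config$seasons[i + 1L]
      tag <- paste(a, b, sep = "-")
      cm <- change_index(fire_probs[[a]], fire_probs[[b]], season_pair = tag)
      write_raster(cm$index, add_path(file.path(out_dir, sprintf("change_%s_%s.asc", a, b))))
      change_maps[[tag]] <- cm
    }
  }

  fire_val <- dplyr::bind_rows(fire_validation)
  sdm_val <- dplyr::bind_rows(sdm_validation)
  overlap_all <- dplyr::bind_rows(lapply(overlaps, function(g) g$summary))
  write.csv(fire_val, add_path(file.path(out_dir, "fire_validation.csv")), row.names = FALSE)
  write.csv(sdm_val, add_path(file.path(out_dir, "sdm_validation.csv")), row.names = FALSE)
  write.csv(overlap_all, add_path(file.path(out_dir, "overlap_summary.csv")), row.names = FALSE)

  manifest <- list(
    package = "firescape",
    version = as.character(utils::packageVersion("firescape")),
    seed = base,
    parameters = unclass(config)[setdiff(names(config), "landscape")],
    landscape = unclass(config$landscape)[setdiff(names(config$landscape), "layer_names")],
    stage_counts = counts,
    files = sort(basename(paths))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    list(
      landscape = land, seasons = season_results, change = change_maps,
      fire_validation = fire_val, sdm_validation = sdm_val,
      importance = dplyr::bind_rows(importance), overlap = overlap_all,
      manifest = manifest, out_dir = out_dir,
      paths = c(paths, manifest_path)
    ),
    class = "firescape_run"
  ))
}

#' @export
print.firescape_run <- function(x, ...) {
  cat(sprintf("<firescape_run> %d season(s) in %s\n",
              length(x$seasons), x$out_dir))
  cat("fire validation:\n")
  print(as.data.frame(x$fire_validation), digits = 3)
  cat("habitat/fire overlap (km^2):\n")
  print(as.data.frame(x$overlap), digits = 5)
  invisible(x)
}
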