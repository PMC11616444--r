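# End-to-end pipeline: preprocess -> segment -> metrics -> null simulation
# -> hierarchical fits -> overlap. One call reproduces the whole analysis
# on a set of bat-night tracks.

#' Run the full colony-foraging analysis
#'
#' Cleans and regularizes every track, fits one pooled movement HMM per
#' colony x season, decodes states, extracts commutes, foraging locations
#' and on/off-island time, simulates landscape-constrained null cohorts
#' from the pooled kernels, fits the hierarchical distance/bearing model
#' per colony x season x provenance, and computes pairwise colony overlap
#' of the 95% foraging-density contours.
#'
#' @param tracks list of `bat_track` objects.
#' @param ls a [landscape()].
#' @param target_interval downsampling interval (s).
#' @param n_states HMM states.
#' @param hmm_restarts random restarts per HMM fit.
#' @param null_reps null tracks per observed night (0 skips the null step).
#' @param draws,warmup,chains MCMC settings per hierarchical fit.
#' @param cell_size overlap raster cell (m).
#' @param do_overlap compute pairwise colony overlaps (dry season,
#'   observed fits)?
#' @param hier_on_nonconverged convergence handling for the per-group
#'   hierarchical fits; the default `"warn"` tolerates the weakly
#'   identified mean direction of near-uniform null-cohort bearings.
#' @param seed master seed.
#' @return list with `nights` (per-night summary), `hmm` (per-group fits),
#'   `commutes`, `locations` (observed + simulated), `proportions`,
#'   `hier` (per-group `bat_hier` fits), `overlap` (matrix of directed
#'   percentages), `rasters`.
#' @export
run_colony_pipeline <- function(tracks, ls, target_interval = 120,
                                n_states = 2, hmm_restarts = 2,
                                null_reps = 3, draws = 800, warmup = 800,
                                chains = 2, cell_size = 1000,
                                do_overlap = TRUE,
                                hier_on_nonconverged = "warn", seed = 1) {
  # --- preprocessing ---------------------------------------------------
  clean <- lapply(tracks, function(tr) {
    tr <- remove_outliers(tr, ls)
    downsample(tr, target_interval)
  })
  series <- lapply(clean, regularize)
  nights <- do.call(rbind, lapply(seq_along(clean), function(i) {
    tr <- clean[[i]]
    roost <- ls$roosts[[tr$colony_id]]
    data.frame(idx = i, individual_id = tr$individual_id,
               colony_id = tr$colony_id, season = tr$season,
               period = tr$period, night_date = format(tr$night_date),
               n_fixes = nrow(tr$fixes),
               status = classify_night(tr, roost))
  }))
  grp <- paste(nights$colony_id, nights$season, sep = ".")

  # --- pooled HMM per colony x season ----------------------------------
  hmm_fits <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    hmm_fits[[g]] <- fit_hmm(series[idx], n_states = n_states,
                             n_restarts = hmm_restarts,
                             seed = .substream(seed, 3L, match(g, unique(grp))))
  }
  decoded <- lapply(seq_along(series), function(i)
    decode_states(hmm_fits[[grp[i]]], series[[i]]))

  # --- metrics ---------------------------------------------------------
  commutes <- list(); locs <- list()
  for (i in seq_along(series)) {
    tr <- clean[[i]]
    roost <- ls$roosts[[tr$colony_id]]
    cm <- extract_commutes(series[[i]], decoded[[i]], roost)
    if (nrow(cm)) {
      cm$individual_id <- tr$individual_id; cm$colony_id <- tr$colony_id
      cm$season <- tr$season; cm$night <- i
      commutes[[length(commutes) + 1L]] <- cm
    }
    fl <- extract_foraging_locations(
      series[[i]], decoded[[i]], roost, ls,
      meta = list(individual_id = tr$individual_id, colony_id = tr$colony_id,
                  season = tr$season, provenance = "observed"))
    if (nrow(fl)) locs[[length(locs) + 1L]] <- fl
  }
  commutes <- if (length(commutes)) do.call(rbind, commutes) else NULL
  locations <- if (length(locs)) do.call(rbind, locs) else
    stop("no foraging locations extracted", call. = FALSE)
  complete <- which(nights$status == "complete")
  proportions <- foraging_time_proportions(
    series[complete], decoded[complete], ls,
    meta_list = lapply(complete, function(i)
      nights[i, c("individual_id", "colony_id", "season", "period")]))

  # --- null cohorts ----------------------------------------------------
  if (null_reps > 0) {
    for (g in unique(grp)) {
      idx <- which(grp == g)
      tpl <- data.frame(colony_id = nights$colony_id[idx],
                        season = nights$season[idx],
                        individual_id = nights$individual_id[idx],
                        n_slots = vapply(series[idx], nrow, 1L),
                        interval = target_interval)
      nc <- simulate_null_cohort(tpl, hmm_fits[[g]], ls,
                                 n_per_template = null_reps,
                                 seed = .substream(seed, 5L, match(g, unique(grp))))
      if (nrow(nc)) {
        nc$template <- NULL; nc$replicate <- NULL
        locations <- rbind(locations, nc)
      }
    }
  }

  # --- hierarchical fits per colony x season x provenance --------------
  hier_fits <- list()
  off <- locations[!locations$on_home_island, , drop = FALSE]
  key <- paste(off$colony_id, off$season, off$provenance, sep = ".")
  for (g in unique(key)) {
    sub <- off[key == g, , drop = FALSE]
    if (nrow(sub) < 3 || length(unique(sub$individual_id)) < 2) next
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    hier_fits[[g]] <- fit_hier(
      sub, draws = draws, warmup = warmup, chains = chains,
      on_nonconverged = hier_on_nonconverged,
      seed = .substream(seed, 7L, match(g, unique(key))),
      group = list(colony = parts[1], season = parts[2],
                   provenance = parts[3]))
  }

  # --- colony overlap (dry season, observed) ---------------------------
  overlap <- NULL; rasters <- list()
  if (do_overlap) {
    obs_dry <- names(hier_fits)[grepl("\\.dry\\.observed$", names(hier_fits))]
    if (length(obs_dry) >= 2) {
      masks <- list()
      for (g in obs_dry) {
        colony <- strsplit(g, ".", fixed = TRUE)[[1]][1]
        r <- pdf_map(hier_fits[[g]], ls$roosts[[colony]], ls,
                     cell_size = cell_size,
                     seed = .substream(seed, 9L, match(g, obs_dry)))
        rasters[[g]] <- r
        masks[[g]] <- contour_mask(r, 0.95)
      }
      cn <- vapply(strsplit(obs_dry, ".", fixed = TRUE), `[`, "", 1)
      overlap <- matrix(NA_real_, length(obs_dry), length(obs_dry),
                        dimnames = list(cn, cn))
      for (a in seq_along(obs_dry)) for (b in seq_along(obs_dry)) {
        if (a == b) { overlap[a, b] <- 100; next }
        ov <- overlap_percentage(masks[[obs_dry[a]]], masks[[obs_dry[b]]],
                                 rasters[[obs_dry[a]]], ls)
        overlap[a, b] <- ov[["a_in_b"]]
      }
    }
  }

  list(nights = nights, hmm = hmm_fits, commutes = commutes,
       locations = locations, proportions = proportions,
       hier = hier_fits, overlap = overlap, rasters = rasters)
}
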