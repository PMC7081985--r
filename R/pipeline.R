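# End-to-end orchestration: synthetic session -> call processing -> LFP
# conditioning -> effect maps -> coherence -> spike-phase locking ->
# decoding, with per-stage artifacts, derived sub-seeds and a provenance
# manifest. The "desk" profile scales the randomization counts down from
# the full-scale settings (n_rand 10,000, k 100, 0.5-ms step) to sizes
# suited to interactive runs; every knob can be overridden.

#' Pipeline run configuration
#'
#' @param output_dir directory for stage artifacts.
#' @param session a [session_config()] describing the synthetic session
#'   (its `rng_seed` is overridden by a sub-seed of `rng_seed`).
#' @param rng_seed master seed; every stochastic stage consumes its own
#'   derived sub-seed.
#' @param profile `"desk"` (n_rand 500, k 50, 10-ms spectrogram step) or
#'   `"full"` (n_rand 10,000, k 100, 1-ms step).
#' @param n_rand,k_avg,step_s randomization/spectrogram overrides.
#' @param decode_band band used by the decoder stage.
#' @param n_shuffle label permutations averaged for the shuffled control
#'   (per-permutation accuracies are strongly bimodal; see the methods
#'   vignette).
#' @param n_boot,m_boot spike-phase bootstrap parameters.
#' @param analysis_channels channel indices analyzed in the spectral /
#'   spike-phase stages (default: deepest FAF channel and first CN
#'   channel).
#' @param stages character vector of stage names to run.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("vocolock_run_"),
                       session = session_config(make_audio = FALSE),
                       rng_seed = 1, profile = c("desk", "full"),
                       n_rand = NULL, k_avg = NULL, step_s = NULL,
                       decode_band = "high_gamma", n_shuffle = 11,
                       n_boot = NULL, m_boot = 100, analysis_channels = NULL,
                       stages = c("simulate", "calls", "condition",
                                  "spectral", "coherence", "spikephase",
                                  "decode")) {
  profile <- match.arg(profile)
  full <- profile == "full"
  structure(list(
    output_dir = output_dir, session = session,
    rng_seed = as.integer(rng_seed), profile = profile,
    n_rand = n_rand %||% (if (full) 10000 else 500),
    k_avg = k_avg %||% (if (full) 100 else 50),
    step_s = step_s %||% (if (full) 0.001 else 0.01),
    decode_band = decode_band, n_shuffle = n_shuffle,
    n_boot = n_boot %||% (if (full) 10000 else 1000),
    m_boot = m_boot,
    analysis_channels = analysis_channels,
    stages = stages), class = "run_config")
}

#' Run the full vocalization-locked analysis pipeline
#'
#' Executes the configured stages on a synthetic session, writing per-stage
#' artifacts and a provenance manifest under `config$output_dir`. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return invisible list (the report bundle): `events`, `epochs`,
#'   `effect_maps`, `coherence`, `spike_phase`, `decoding`,
#'   `ground_truth`, `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$rng_seed, 10L)
  bundle <- list(output_dir = config$output_dir)
  manifest <- list(package_version = as.character(utils::packageVersion("vocolock")),
                   rng_seed = config$rng_seed, profile = config$profile,
                   stage_seeds = as.list(stats::setNames(seeds, paste0("s", 1:10))),
                   params = config[c("n_rand", "k_avg", "step_s",
                                     "decode_band", "n_shuffle", "n_boot",
                                     "m_boot")])
  stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(NULL)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  session <- stage("simulate", {
    sc <- config$session
    sc$rng_seed <- seeds[1]
    s <- generate_session(sc)
    write_events(s$events, file.path(config$output_dir, "events.csv"))
    jsonlite::write_json(
      list(burst_table = s$ground_truth$burst_table,
           coherence_table = s$ground_truth$coherence_table,
           spike_coupling = s$ground_truth$spike_coupling,
           alpha = s$ground_truth$alpha, rng_seed = s$ground_truth$rng_seed,
           duration_s = s$ground_truth$duration_s),
      file.path(config$output_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
    s
  })
  if (is.null(session)) stop("pipeline requires the 'simulate' stage")
  bundle$ground_truth <- session$ground_truth

  # -- calls ---------------------------------------------------------------
  events <- stage("calls", {
    if (!is.null(session$audio)) {
      ev <- annotate_calls(session$audio$x, session$audio$fs)
      ev[!is.na(ev$class), , drop = FALSE]
    } else {
      select_isolated(session$events,
                      recording_bounds = c(0, session$ground_truth$duration_s))
    }
  }) %||% session$events
  bundle$events <- events

  # -- condition -----------------------------------------------------------
  epochs <- stage("condition", {
    rec <- bandpass_lfp(session$recording)
    rec <- downsample_recording(rec, 1000)
    rec <- zscore_recording(rec, "auto")
    keep <- events$isolated
    if ("is_distractor" %in% names(events)) keep <- keep & !events$is_distractor
    ep <- extract_epochs(rec, events[keep, , drop = FALSE])
    saveRDS(ep, file.path(config$output_dir, "epochs.rds"))
    ep
  })
  bundle$epochs <- epochs
  if (is.null(epochs)) {
    stop("pipeline stages beyond 'condition' need conditioned epochs")
  }
  meta <- epochs$channel_meta
  faf_idx <- which(meta$structure == "FAF")
  cn_idx <- which(meta$structure == "CN")
  ana_ch <- config$analysis_channels %||%
    c(faf_idx[which.max(meta$depth_um[faf_idx])], cn_idx[1])

  # -- spectral ------------------------------------------------------------
  bundle$effect_maps <- stage("spectral", {
    rs_e <- build_randomization_trials(epochs, "echolocation",
                                       config$n_rand, config$k_avg,
                                       rng_seed = seeds[2],
                                       channels = ana_ch)
    rs_c <- build_randomization_trials(epochs, "communication",
                                       config$n_rand, config$k_avg,
                                       rng_seed = seeds[3],
                                       channels = ana_ch)
    maps <- lapply(seq_along(ana_ch), function(ci) {
      effect_size_map(rs_e, rs_c, channel = ci, step_s = config$step_s)
    })
    names(maps) <- paste0(meta$structure[ana_ch], "_", meta$depth_um[ana_ch])
    saveRDS(maps, file.path(config$output_dir, "effect_maps.rds"))
    maps
  })

  # -- coherence -----------------------------------------------------------
  bundle$coherence <- stage("coherence", {
    out <- list()
    for (cond in c("echolocation", "communication")) {
      tr <- which(epochs$labels$class == cond)
      if (length(tr) < 2) next
      faf_deep <- ana_ch[meta$structure[ana_ch] == "FAF"][1]
      per_cn <- lapply(cn_idx, function(cc) {
        coherogram(epochs$data[tr, faf_deep, ], epochs$data[tr, cc, ],
                   fs = epochs$fs, step_s = config$step_s,
                   t0 = epochs$window[1])
      })
      avg <- average_over_cn(per_cn)
      msk <- suppressWarnings(significance_mask(avg))
      out[[cond]] <- list(map = avg, mask = msk,
                          theta_profile = band_coherence_profile(
                            list(avg), "theta",
                            meta$depth_um[faf_deep]))
    }
    saveRDS(out, file.path(config$output_dir, "coherence.rds"))
    out
  })

  # -- spikephase ----------------------------------------------------------
  bundle$spike_phase <- stage("spikephase", {
    if (is.null(session$spikes)) return(NULL)
    cn_rec_ch <- which(session$recording$channel_meta$structure == "CN")[1]
    spk <- session$spikes[[cn_rec_ch]]
    tab <- phase_locking_analysis(epochs, cn_idx[1], spk,
                                  n_boot = config$n_boot, m = config$m_boot,
                                  rng_seed = seeds[4])
    utils::write.csv(tab, file.path(config$output_dir, "phase_locking.csv"),
                     row.names = FALSE)
    tab
  })

  # -- decode --------------------------------------------------------------
  bundle$decoding <- stage("decode", {
    ch <- 1L # first analysis channel (deep FAF)
    mk <- function(cond, seed) {
      build_randomization_trials(epochs, cond, config$n_rand, config$k_avg,
                                 rng_seed = seed, channels = ana_ch)
    }
    feats <- function(rs) {
      band_power_features(rs, config$decode_band, "pre", channel = ch,
                          step_s = config$step_s)
    }
    train <- combine_features(feats(mk("echolocation", seeds[5])),
                              feats(mk("communication", seeds[6])))
    test <- combine_features(feats(mk("echolocation", seeds[7])),
                             feats(mk("communication", seeds[8])))
    model <- train_decoder(train)
    rep <- data.frame(
      band = if (is.character(config$decode_band)) config$decode_band else
        paste(config$decode_band, collapse = "-"),
      window = "pre",
      accuracy_pct = evaluate_decoder(model, test),
      cv_error = crossvalidate_decoder(train, rng_seed = seeds[9]),
      shuffled_accuracy_pct = mean(vapply(seq_len(config$n_shuffle),
        function(i) shuffled_label_control(train, test,
                                           rng_seed = seeds[10] + i - 1L),
        numeric(1))))
    utils::write.csv(rep, file.path(config$output_dir, "decoding.csv"),
                     row.names = FALSE)
    rep
  })

  # -- manifest ------------------------------------------------------------
  files <- list.files(config$output_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$artifacts <- as.list(tools::md5sum(files))
  names(manifest$artifacts) <- basename(files)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Reload a pipeline report bundle from its output directory
#'
#' Reconstructs the pieces of a [run_pipeline()] bundle that
#' [validate_report()] needs from the artifacts written on disk.
#'
#' @param output_dir a [run_pipeline()] output directory.
#' @return list with the available bundle elements.
#' @export
load_bundle <- function(output_dir) {
  pick <- function(f, reader) {
    path <- file.path(output_dir, f)
    if (file.exists(path)) reader(path) else NULL
  }
  gt <- pick("ground_truth.json", function(p) {
    g <- jsonlite::read_json(p, simplifyVector = TRUE)
    g$burst_table <- as.data.frame(g$burst_table)
    g$coherence_table <- as.data.frame(g$coherence_table)
    g
  })
  list(output_dir = output_dir,
       ground_truth = gt,
       events = pick("events.csv", read_events),
       epochs = pick("epochs.rds", readRDS),
       effect_maps = pick("effect_maps.rds", readRDS),
       coherence = pick("coherence.rds", readRDS),
       spike_phase = pick("phase_locking.csv", function(p) {
         utils::read.csv(p, stringsAsFactors = FALSE)
       }),
       decoding = pick("decoding.csv", function(p) {
         utils::read.csv(p, stringsAsFactors = FALSE)
       }),
       manifest = pick("manifest.json", jsonlite::read_json))
}

#' Recovery checks of a synthetic-run report bundle
#'
#' Compares the bundle's measured quantities with the session's ground
#' truth: injected bursts must surface as medium-or-larger effect sizes in
#' their band/window, non-injected high frequencies must stay below the
#' small-effect border, coherence timing must match the injected lag
#' structure, spike-phase locking must be significant exactly when the
#' generator coupled spikes to the LFP, and decoding must beat chance when
#' a class-dependent injection exists (shuffled labels staying near 50%).
#'
#' @param bundle a [run_pipeline()] result.
#' @param ground_truth the session's ground-truth record (defaults to the
#'   bundle's own).
#' @return data.frame with `check`, `measured`, `criterion`, `pass`.
#' @export
validate_report <- function(bundle, ground_truth = bundle$ground_truth) {
  if (is.null(ground_truth)) stop("ground truth missing")
  rows <- list()
  add <- function(check, measured, criterion, pass) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, measured = measured, criterion = criterion,
      pass = pass, stringsAsFactors = FALSE)
  }
  bt <- ground_truth$burst_table
  maps <- bundle$effect_maps
  if (!is.null(maps) && !is.null(bt) && nrow(bt) > 0) {
    map_meta <- do.call(rbind, strsplit(names(maps), "_"))
    for (b in seq_len(nrow(bt))) {
      mi <- which(map_meta[, 1] == bt$region[b] &
                    as.numeric(map_meta[, 2]) >= bt$depth_min_um[b] &
                    as.numeric(map_meta[, 2]) <= bt$depth_max_um[b])
      if (length(mi) == 0L) next
      m <- maps[[mi[1]]]
      sgn <- if (bt$class[b] == "echolocation") 1 else -1
      sel_t <- m$time >= bt$t_start_ms[b] / 1000 &
        m$time <= bt$t_end_ms[b] / 1000
      sel_f <- m$freq >= bt$f_lo[b] & m$freq <= bt$f_hi[b]
      dmax <- max(sgn * m$values[sel_t, sel_f])
      add(sprintf("burst recovery %s %s %g-%g Hz", bt$class[b],
                  bt$region[b], bt$f_lo[b], bt$f_hi[b]),
          dmax, "> 0.33 (injected gain > 0) / < 0.15 (gain 0)",
          if (bt$gain[b] > 0) dmax > 0.33 else abs(dmax) < 0.15)
    }
  }
  coh <- bundle$coherence
  ct <- ground_truth$coherence_table
  if (!is.null(coh) && !is.null(ct) && nrow(ct) > 0) {
    for (b in seq_len(nrow(ct))) {
      cond <- ct$class[b]
      if (is.null(coh[[cond]])) next
      prof <- coh[[cond]]$theta_profile
      t_at_max <- prof$time[which.max(prof$profile[1, ])]
      tc <- (ct$t_start_ms[b] + ct$t_end_ms[b]) / 2000
      add(sprintf("coherence timing %s", cond), t_at_max,
          sprintf("max theta coherence near %.2f s", tc),
          abs(t_at_max - tc) < 0.2)
    }
  }
  sp <- bundle$spike_phase
  if (!is.null(sp)) {
    kappa <- ground_truth$spike_coupling$kappa
    cb <- c(ground_truth$spike_coupling$f_lo, ground_truth$spike_coupling$f_hi)
    bands <- lfp_bands()
    bname <- bands$name[bands$low_hz == cb[1] & bands$high_hz == cb[2]]
    if (length(bname) == 1 && bname %in% sp$band) {
      p <- sp$p_corrected[sp$band == bname]
      add(sprintf("spike-phase locking in %s (kappa = %g)", bname, kappa),
          p, if (kappa > 0) "p < 0.001" else "p >= 0.001",
          if (kappa > 0) isTRUE(p < 0.001) else isTRUE(p >= 0.001))
    }
  }
  dec <- bundle$decoding
  if (!is.null(dec)) {
    any_gain <- !is.null(bt) && nrow(bt) > 0 && any(bt$gain > 0)
    if (any_gain) {
      add("decoding beats chance", dec$accuracy_pct, "> 55%",
          dec$accuracy_pct > 55)
    }
    add("shuffled-label control at chance", dec$shuffled_accuracy_pct,
        "within [35, 65]%",
        dec$shuffled_accuracy_pct >= 35 && dec$shuffled_accuracy_pct <= 65)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
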