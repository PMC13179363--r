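# Configuration and the two end-to-end workflows.

#' Analysis configuration
#'
#' Collects the tunable parameters of the estimation pipeline with the
#' package defaults; serializable to JSON and back without loss.
#'
#' @param segment_len_s,overlap_frac,taper Welch parameters.
#' @param half_bw_at_3hz peripheral half bandwidth at 3 Hz; other centers use
#'   the proportional value `center / 3 * half_bw_at_3hz`.
#' @param n_restarts,tol,max_iter,gamma optimizer parameters.
#' @param n_perm,epoch_len_s permutation parameters.
#' @param seed master seed.
#' @param out_dir output directory for [run_study()].
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(segment_len_s = 1, overlap_frac = 0.5,
                            taper = "hann", half_bw_at_3hz = 1,
                            n_restarts = 10, tol = 1e-8, max_iter = 200,
                            gamma = 1e-4, n_perm = 199, epoch_len_s = 1,
                            seed = 1, out_dir = NULL) {
  stopifnot(segment_len_s > 0, overlap_frac >= 0, overlap_frac < 1,
            half_bw_at_3hz > 0, n_restarts >= 1, tol > 0, max_iter >= 1,
            gamma >= 0, gamma < 1, n_perm >= 0, epoch_len_s > 0)
  structure(
    list(segment_len_s = segment_len_s, overlap_frac = overlap_frac,
         taper = taper, half_bw_at_3hz = half_bw_at_3hz,
         n_restarts = n_restarts, tol = tol, max_iter = max_iter,
         gamma = gamma, n_perm = n_perm, epoch_len_s = epoch_len_s,
         seed = seed, out_dir = out_dir),
    class = "analysis_config"
  )
}

#' @rdname analysis_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname analysis_config
#' @param config an `analysis_config` (for `write_config`).
#' @export
read_config <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, v[!vapply(v, is.null, logical(1))])
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small portable rolling hash; enough to detect config drift in manifests
  h <- 0
  for (b in as.integer(charToRaw(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Table-6/7/8 comparison columns.
pair_table_columns <- function() {
  list(
    "3:3 vs 6:6" = c("3:3", "6:6"), "3:3 vs 3:6" = c("3:3", "3:6"),
    "6:6 vs 3:6" = c("6:6", "3:6"), "3:3 vs 9:9" = c("3:3", "9:9"),
    "3:3 vs 3:9" = c("3:3", "3:9"), "9:9 vs 3:9" = c("9:9", "3:9")
  )
}

interaction_freq <- function(label) {
  as.numeric(strsplit(label, ":", fixed = TRUE)[[1]][2]) # analysis frequency f_r
}

run_real_style_one <- function(eeg, acc, config, seed, log_stage) {
  if (n_channels(acc) == 3) acc <- acc_first_pc(acc)
  assert_univariate(acc, "peripheral")
  hb <- function(f) config$half_bw_at_3hz * f / 3
  labels <- c("3:3", "6:6", "9:9", "3:6", "3:9")
  specs <- list(coupling_spec(3, 1), coupling_spec(6, 1), coupling_spec(9, 1),
                coupling_spec(3, 2), coupling_spec(3, 3))
  names(specs) <- labels

  log_stage("coupling estimation + permutation tests")
  fits <- list(); perms <- list()
  for (i in seq_along(labels)) {
    pn <- coupling_significance(
      eeg, acc, specs[[i]], n_perm = config$n_perm,
      seed = child_seed(seed, i), epoch_len_s = config$epoch_len_s,
      half_bw_hz = hb(3), segment_len_s = config$segment_len_s,
      overlap_frac = config$overlap_frac, taper = config$taper,
      gamma = config$gamma, n_restarts = config$n_restarts,
      tol = config$tol, max_iter = config$max_iter
    )
    perms[[labels[i]]] <- pn
    fits[[labels[i]]] <- pn$solution
  }

  log_stage("peripheral self-coupling")
  acc_sync <- list(
    "3:6" = cross_freq_sync(acc, acc, coupling_spec(3, 2), half_bw_hz = hb(3)),
    "3:9" = cross_freq_sync(acc, acc, coupling_spec(3, 3), half_bw_hz = hb(3))
  )

  log_stage("pattern similarity and projected-source synchronization")
  cols <- pair_table_columns()
  k_sim <- vapply(cols, function(pr) {
    pattern_similarity(fits[[pr[1]]]$pattern_a, fits[[pr[2]]]$pattern_a)
  }, numeric(1))
  projections <- lapply(labels, function(lab) {
    f <- interaction_freq(lab)
    project(eeg, fits[[lab]]$alpha, f, hb(f))
  })
  names(projections) <- labels
  k_sync <- vapply(cols, function(pr) {
    f1 <- interaction_freq(pr[1]); f2 <- interaction_freq(pr[2])
    sl <- if (f1 <= f2) c(pr[1], pr[2]) else c(pr[2], pr[1])
    fq <- min(f1, f2); fr <- max(f1, f2)
    cross_freq_sync(projections[[sl[1]]], projections[[sl[2]]],
                    coupling_spec(fq, round(fr / fq)), half_bw_hz = hb(fq))$k_sync
  }, numeric(1))

  list(
    coupling = data.frame(
      interaction = labels,
      coherence = vapply(labels, function(l) perms[[l]]$observed, numeric(1)),
      null95 = vapply(labels, function(l) perms[[l]]$percentile_95, numeric(1)),
      p_value = vapply(labels, function(l) perms[[l]]$p_value, numeric(1)),
      significant = vapply(labels, function(l) perms[[l]]$significant, logical(1)),
      row.names = NULL
    ),
    acc_sync = data.frame(
      interaction = names(acc_sync),
      k_sync = vapply(acc_sync, function(s) s$k_sync, numeric(1)),
      row.names = NULL
    ),
    k_sim = k_sim, k_sync = k_sync,
    fits = fits, perm = perms
  )
}

#' Run a complete analysis workflow
#'
#' Two modes mirroring the package's two use cases:
#'
#' * `"real-style"`: for each dataset (a list with elements `eeg` and `acc`),
#'   computes within-frequency coupling at 3:3, 6:6 and 9:9 Hz, XF coupling
#'   at 3:6 and 3:9 Hz, peripheral self-coupling (3:6, 3:9 on the
#'   accelerometer component), permutation significance for every coupling,
#'   pattern similarities for the six canonical comparison pairs, and
#'   projected-source synchronization for the same pairs. With three or more
#'   datasets the similarity/synchrony correlation table (Holm-adjusted) is
#'   added.
#' * `"simulate-sweep"`: runs [snr_sweep()] and polarity-aligned pattern
#'   averaging per interaction.
#'
#' When `config$out_dir` is set, results are written there as TSV/JSON
#' together with a manifest (config hash, seed, package version).
#'
#' @param config an [analysis_config()].
#' @param mode `"real-style"` or `"simulate-sweep"`.
#' @param datasets for `"real-style"`: list of datasets, each a list with
#'   `eeg` (multichannel [ts_set()]) and `acc` (3-channel or univariate
#'   `ts_set`).
#' @param ... for `"simulate-sweep"`: arguments passed to [snr_sweep()].
#' @param quiet suppress stage logging.
#' @return a list of result tables (see Details), invisibly written to
#'   `config$out_dir` when set.
#' @export
run_study <- function(config, mode = c("real-style", "simulate-sweep"),
                      datasets = NULL, ..., quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  log_stage <- function(msg) {
    if (!quiet) message(sprintf("[%6.1fs] %s",
                                as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }

  if (mode == "real-style") {
    if (is.null(datasets)) stop("real-style mode needs datasets")
    if (!is.null(datasets$eeg)) datasets <- list(datasets)
    per_subject <- lapply(seq_along(datasets), function(i) {
      log_stage(sprintf("dataset %d/%d", i, length(datasets)))
      run_real_style_one(datasets[[i]]$eeg, datasets[[i]]$acc, config,
                         seed = child_seed(config$seed, i), log_stage)
    })
    out <- list(per_subject = per_subject)
    cols <- names(pair_table_columns())
    out$k_sim_table <- do.call(rbind, lapply(per_subject, function(s) s$k_sim))
    out$k_sync_table <- do.call(rbind, lapply(per_subject, function(s) s$k_sync))
    colnames(out$k_sim_table) <- colnames(out$k_sync_table) <- cols
    if (length(per_subject) >= 3) {
      log_stage("similarity/synchrony correlations (Holm-adjusted)")
      out$sim_sync <- sim_sync_correlation(
        lapply(cols, function(cn) out$k_sim_table[, cn]),
        lapply(cols, function(cn) out$k_sync_table[, cn])
      )
      rownames(out$sim_sync) <- cols
    }
  } else {
    log_stage("SNR sweep")
    sweep_tab <- snr_sweep(..., seed = config$seed)
    out <- list(sweep = sweep_tab, failure_rates = attr(sweep_tab, "failure_rates"))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    log_stage(paste("writing results to", config$out_dir))
    manifest <- list(
      config_hash = config_hash(config), seed = config$seed,
      package_version = as.character(utils::packageVersion("xfcacoh")),
      mode = mode, created = format(Sys.time(), tz = "UTC"),
      stages_completed = character(0)
    )
    if (mode == "real-style") {
      for (i in seq_along(out$per_subject)) {
        s <- out$per_subject[[i]]
        utils::write.table(s$coupling,
                           file.path(config$out_dir, sprintf("coupling_%02d.tsv", i)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        for (lab in names(s$fits)) {
          write_pattern_tsv(names(s$fits[[lab]]$pattern_a),
                            s$fits[[lab]]$alpha, s$fits[[lab]]$pattern_a,
                            file.path(config$out_dir,
                                      sprintf("pattern_%02d_%s.tsv", i, gsub(":", "-", lab))))
        }
        manifest$stages_completed <- c(manifest$stages_completed, sprintf("dataset_%02d", i))
      }
      utils::write.table(cbind(dataset = seq_len(nrow(out$k_sim_table)), out$k_sim_table),
                         file.path(config$out_dir, "k_sim.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(cbind(dataset = seq_len(nrow(out$k_sync_table)), out$k_sync_table),
                         file.path(config$out_dir, "k_sync.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else {
      utils::write.table(out$sweep, file.path(config$out_dir, "sweep.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(out$failure_rates,
                         file.path(config$out_dir, "failure_rates.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      manifest$stages_completed <- "sweep"
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  log_stage("done")
  out
}
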