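# Plain-text serialization of synthetic sessions: one directory holding
# CSV tables per component plus a YAML metadata file. Sparse-noise frames
# are stored as (row, col, frame, value) triplets of the non-gray squares.

#' Write a synthetic session to a directory of CSV/YAML files
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if missing).
#'
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- session$behavior
  write.csv(data.frame(time = b$times, running_speed = b$running_speed,
                       pupil_area = b$pupil_area, blink = b$blink_mask),
            file.path(dir, "behavior.csv"), row.names = FALSE)
  g <- session$gratings
  write.csv(data.frame(onset = g$trial_onsets, duration = g$trial_duration,
                       direction = g$directions, laser_on = g$laser_on),
            file.path(dir, "gratings.csv"), row.names = FALSE)
  for (nm in c("raw_F", "raw_N", "raw_red")) {
    m <- session[[nm]]
    colnames(m) <- paste0("unit", seq_len(ncol(m)))
    write.csv(as.data.frame(m), file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  gt <- do.call(rbind, lapply(seq_along(session$ground_truth), function(i) {
    u <- session$ground_truth[[i]]
    data.frame(unit = i, theta_p = u$theta_p, sigma = u$sigma, ds = u$ds,
               p_small = u$p_small, p_large = u$p_large,
               offset_small = u$offset_small, offset_large = u$offset_large,
               suppressed = u$suppressed, run_coupling = u$run_coupling,
               alpha_true = u$alpha_true, kernel_tau = u$kernel_tau)
  }))
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  if (!is.null(session$noise)) {
    fr <- session$noise$frames
    nz <- which(fr != 0, arr.ind = TRUE)
    write.csv(data.frame(row = nz[, 1], col = nz[, 2], frame = nz[, 3],
                         value = fr[nz]),
              file.path(dir, "noise_frames.csv"), row.names = FALSE)
  }
  if (length(session$spikes)) {
    sp <- do.call(rbind, lapply(seq_along(session$spikes), function(i) {
      data.frame(axon = i, time = session$spikes[[i]]$spike_times,
                 amplitude = session$spikes[[i]]$amplitudes)
    }))
    write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  }
  meta <- list(seed = session$seed, dt = b$dt,
               trial_duration = g$trial_duration,
               n_units = length(session$ground_truth))
  if (!is.null(session$noise))
    meta$noise <- list(dims = dim(session$noise$frames),
                       update_rate = session$noise$update_rate,
                       square_edge = session$noise$square_edge)
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory produced by [write_session()].
#'
#' @return A `synthetic_session` (ground-truth units as plain rows of the
#'   ground-truth table; RF fields are not serialized).
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  b <- read.csv(file.path(dir, "behavior.csv"))
  behavior <- structure(list(times = b$time, running_speed = b$running_speed,
                             pupil_area = b$pupil_area, blink_mask = b$blink,
                             dt = meta$dt, seed = meta$seed),
                        class = "behavior_traces")
  g <- read.csv(file.path(dir, "gratings.csv"))
  gratings <- structure(list(trial_onsets = g$onset,
                             trial_duration = meta$trial_duration,
                             directions = g$direction, laser_on = g$laser_on,
                             seed = meta$seed),
                        class = "grating_schedule")
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  units <- lapply(seq_len(nrow(gt)), function(i) {
    r <- gt[i, ]
    ground_truth_unit(r$theta_p, r$sigma, r$ds, r$p_small, r$p_large,
                      r$offset_small, r$offset_large, r$suppressed,
                      r$run_coupling, r$alpha_true, r$kernel_tau)
  })
  noise <- NULL
  nf_path <- file.path(dir, "noise_frames.csv")
  if (file.exists(nf_path) && !is.null(meta$noise)) {
    nz <- read.csv(nf_path)
    fr <- array(0, dim = unlist(meta$noise$dims))
    fr[cbind(nz$row, nz$col, nz$frame)] <- nz$value
    noise <- structure(list(
      frame_times = (seq_len(dim(fr)[3]) - 1L) / meta$noise$update_rate,
      frames = fr, square_edge = meta$noise$square_edge,
      update_rate = meta$noise$update_rate, seed = meta$seed),
      class = "noise_movie")
  }
  spikes <- list()
  sp_path <- file.path(dir, "spikes.csv")
  if (file.exists(sp_path)) {
    sp <- read.csv(sp_path)
    spikes <- lapply(unique(sp$axon), function(a) {
      s <- sp[sp$axon == a, ]
      list(spike_times = s$time, amplitudes = s$amplitude)
    })
  }
  structure(list(behavior = behavior, gratings = gratings, noise = noise,
                 raw_F = as.matrix(read.csv(file.path(dir, "raw_F.csv"))),
                 raw_N = as.matrix(read.csv(file.path(dir, "raw_N.csv"))),
                 raw_red = as.matrix(read.csv(file.path(dir, "raw_red.csv"))),
                 spikes = spikes, ground_truth = units, seed = meta$seed),
            class = "synthetic_session")
}
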