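# Shared fixture builders; everything is generated in code at test time.

# small noiseless configuration: exact rendering, no photophysics
noiseless_config <- function(k_on = 0.7e8, c = 5e-9, k_off = 0.7,
                             n_frames = 2000, seed = 1) {
  trace_sim_config(k_on = k_on, c = c, k_off = k_off,
                   n_frames = n_frames, noise_sd = 0, background_mean = 0,
                   p_acceptor_dark = 0, seed = seed)
}

# independent segmentation oracle: run-length encode the frame-discretized
# ground-truth path at the same intensity threshold the analysis used
oracle_segments <- function(path, config, threshold, min_frames = 4) {
  occ <- aptakinetics:::frame_occupancy(path, config$frame_interval,
                                        config$n_frames)
  high <- occ * config$total_intensity > threshold
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_frames
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             n_frames = r$lengths[keep])
}

# deterministic two-level square-wave trace (blocks of low/high summed
# intensity, split equally between channels)
square_trace <- function(low, high, block = 25, n_blocks = 40) {
  s <- rep(rep(c(low, high), length.out = n_blocks), each = block)
  structure(list(molecule_id = "sq", frame_interval = 0.1,
                 donor = s / 2, acceptor = s / 2),
            class = "fluor_trace")
}
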