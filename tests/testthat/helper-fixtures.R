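# shared fixtures, all generated in code

sine_recording <- function(freq_hz, fs = 44100, duration_s = 1, amp = 1,
                           song_type = "calling", id = "tone") {
  tt <- seq_len(round(fs * duration_s)) / fs
  song_recording(amp * sin(2 * pi * freq_hz * tt), fs,
                 song_type = song_type, individual_id = id)
}

square_config <- function(id = "sq") {
  # unit square corners padded to 14 landmarks with a fixed outline
  base <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  extra <- cbind(seq(2, 3.8, length.out = 10), seq(0, 2, length.out = 10))
  landmark_configuration(rbind(base, extra), individual_id = id)
}

rotate_points <- function(points, degrees) {
  th <- degrees * pi / 180
  points %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# best label agreement over all permutations of 3 cluster indices
perm_agreement <- function(labels, truth) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  truth <- as.integer(factor(truth))
  max(vapply(perms, function(p) mean(p[labels] == truth), numeric(1)))
}

tiny_tps <- function(path, scale = NULL, n = 14, id = "w1") {
  coords <- cbind(seq_len(n), seq_len(n) * 2)
  lines <- c(paste0("LM=", n), sprintf("%d %d", coords[, 1], coords[, 2]))
  if (!is.null(scale)) lines <- c(lines, paste0("SCALE=", scale))
  lines <- c(lines, paste0("ID=", id))
  writeLines(lines, path)
  coords
}
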