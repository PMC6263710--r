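# Build small AU streams in code. `intensities` may be a scalar, a length-14
# vector (per-AU constants), a length-n vector (same series for every AU), or
# an n x 14 matrix.
make_stream <- function(n, fps = 25, intensities = 0.5, valid = TRUE,
                        pitch = 0, yaw = 0, roll = 0) {
  aus <- au_columns()
  if (is.matrix(intensities)) {
    m <- intensities
  } else if (length(intensities) == 1) {
    m <- matrix(intensities, n, 14)
  } else if (length(intensities) == 14 && n != 14) {
    m <- matrix(intensities, n, 14, byrow = TRUE)
  } else {
    m <- matrix(intensities, n, 14)
  }
  colnames(m) <- aus
  df <- tibble::tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1) / fps,
    pitch = rep_len(pitch, n), yaw = rep_len(yaw, n), roll = rep_len(roll, n),
    valid = rep_len(valid, n)
  )
  df <- dplyr::bind_cols(df, tibble::as_tibble(m))
  as_au_stream(df, fps = fps)
}

# Write a tracker-style CSV in the default OpenFace-like dialect.
write_dialect_csv <- function(path, n = 3, fps = 25, success = 1,
                              pose_rad = 0, au_value = 0.5,
                              drop_au = NULL, shuffle = FALSE) {
  d <- au_dialect()
  df <- data.frame(
    frame = seq_len(n) - 1L,
    timestamp = (seq_len(n) - 1) / fps,
    success = rep_len(success, n)
  )
  df[d$pose] <- rep_len(pose_rad, n)
  for (col in unname(d$au)) df[[col]] <- rep_len(au_value, n)
  if (!is.null(drop_au)) df[[paste0(drop_au, "_r")]] <- NULL
  if (shuffle) df <- df[, sample(ncol(df))]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

random_symmetric_p <- function() {
  p <- matrix(runif(14 * 14), 14, 14)
  p <- (p + t(p)) / 2
  diag(p) <- 0
  dimnames(p) <- list(au_columns(), au_columns())
  facexpr:::new_cooccurrence(p)
}
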