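# trajectory with a constant boundary, for degenerate-input checks
make_const_traj <- function(L_B = 22, times = 0:100) {
  series <- data.frame(time_min = times, L_B_um = L_B, n_B = 0L,
                       cell_length_um = 2 * L_B)
  structure(list(series = series, params = mt_params(),
                 final = list(lengths = numeric(0), boundary = L_B,
                              t = max(times))),
            class = "mt_trajectory")
}

# circle mask for Feret checks
make_disc_mask <- function(size, radius, centre = (size + 1) / 2) {
  m <- matrix(FALSE, size, size)
  m[(row(m) - centre)^2 + (col(m) - centre)^2 <= radius^2] <- TRUE
  m
}
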