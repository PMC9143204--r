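# shared fixtures, built in code

# flat-tissue phantom: no streaks, no texture -> breast region is constant
flat_phantom <- function(h = 480, w = 520, level = 120, seed = 2) {
  generate_phantom(phantom_spec(h, w, seed = seed, n_streaks = 0,
                                background_level = level,
                                texture_sd = 0, noise_sd = 0))
}

# a defect core covering columns [left, right) on every row where the
# breast run fully contains the band
band_core_in_mask <- function(mask, left, right) {
  runs <- deband:::mask_runs(mask)
  rows <- which(!is.na(runs$first) & runs$first <= left - 1L &
                runs$last >= right)
  defect_core(data.frame(row = rows, left = left, right = right),
              connected = TRUE, dim = dim(mask))
}

# deterministic integer test pattern shared with the external metric oracle
oracle_pair <- function(n = 96) {
  r <- matrix(0:(n - 1), n, n)
  cc <- t(r)
  ref <- (7 * r + 13 * cc) %% 251
  test <- pmax(pmin(ref + ((3 * r + 5 * cc) %% 17) - 8, 255), 0)
  list(ref = gray_image(ref), test = gray_image(test))
}

# local rounding/clipping helper mirroring the package's 8-bit convention
clip8i <- function(x) {
  x <- floor(x + 0.5)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}
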