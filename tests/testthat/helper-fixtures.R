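# shared fixtures built in code

# the six-reading layout of one procedure
example_readings <- function(in_lv = 0.10, in_lh = 0.08, in_rv = 0.09,
                             in_rh = 0.12, out_l = 0.20, out_r = 0.18) {
  data.frame(
    placement = c("inside", "inside", "inside", "inside",
                  "outside", "outside"),
    side = c("left", "left", "right", "right", "left", "right"),
    orientation = c("vertical", "horizontal", "vertical", "horizontal",
                    "none", "none"),
    air_kerma_mGy = c(in_lv, in_lh, in_rv, in_rh, out_l, out_r))
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# per-procedure hp3 data.frame built directly (bypassing readings)
hp3_frame <- function(outside, inside, practice = "assisted_ventilation",
                      extension_tube = TRUE, dlp = 1e4) {
  n <- length(outside)
  data.frame(procedure_id = sprintf("X%03d", seq_len(n)),
             practice = practice, extension_tube = extension_tube,
             dlp_mgycm = dlp, hp3_outside = outside, hp3_inside = inside)
}
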