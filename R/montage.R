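#' Electrode montage for the oddball recordings
#'
#' Scalp channels follow the extended 10-20 layout of a 31-channel active
#' electrode cap referenced at the nose tip, with M1/M2 over the mastoids.
#' Three EOG channels capture horizontal (left/right outer canthus) and
#' vertical (below the left eye) eye movements. Approximate 2-D positions
#' (unit head circle, nasion up) are used only to spread component
#' topographies smoothly across neighbouring sites in the synthetic
#' generator.
#'
#' @return A data frame with columns `channel`, `x`, `y`, `type`
#'   (`"eeg"` or `"eog"`).
#' @export
default_montage <- function() {
  pos <- c(
    Fp1 = "-0.31,0.95", Fp2 = "0.31,0.95",
    F7 = "-0.81,0.59", F3 = "-0.40,0.55", Fz = "0.00,0.52",
    F4 = "0.40,0.55", F8 = "0.81,0.59",
    FC5 = "-0.62,0.28", FC1 = "-0.20,0.26", FCz = "0.00,0.26",
    FC2 = "0.20,0.26", FC6 = "0.62,0.28",
    T7 = "-1.00,0.00", C3 = "-0.40,0.00", Cz = "0.00,0.00",
    C4 = "0.40,0.00", T8 = "1.00,0.00",
    CP5 = "-0.62,-0.28", CP1 = "-0.20,-0.26", CP2 = "0.20,-0.26",
    CP6 = "0.62,-0.28",
    P7 = "-0.81,-0.59", P3 = "-0.40,-0.55", Pz = "0.00,-0.52",
    P4 = "0.40,-0.55", P8 = "0.81,-0.59",
    O1 = "-0.31,-0.95", Oz = "0.00,-0.95", O2 = "0.31,-0.95",
    M1 = "-1.05,-0.40", M2 = "1.05,-0.40"
  )
  xy <- do.call(rbind, lapply(strsplit(unname(pos), ","), as.numeric))
  eeg <- data.frame(channel = names(pos), x = xy[, 1], y = xy[, 2],
                    type = "eeg", stringsAsFactors = FALSE)
  eog <- data.frame(channel = c("HEOG_L", "HEOG_R", "VEOG"),
                    x = c(-0.60, 0.60, -0.31), y = c(1.10, 1.10, 1.15),
                    type = "eog", stringsAsFactors = FALSE)
  rbind(eeg, eog)
}

eeg_channels <- function(montage = default_montage()) {
  montage$channel[montage$type == "eeg"]
}

eog_channels <- function(montage = default_montage()) {
  montage$channel[montage$type == "eog"]
}

# Smooth scalp weighting centred on an electrode: Gaussian falloff in the
# 2-D montage plane, weight 1 at the centre site.
topography_weights <- function(center, spread = 0.55,
                               montage = default_montage()) {
  m <- montage[montage$type == "eeg", ]
  i <- match(center, m$channel)
  if (is.na(i)) stopf("unknown electrode '%s'", center)
  d2 <- (m$x - m$x[i])^2 + (m$y - m$y[i])^2
  w <- exp(-d2 / (2 * spread^2))
  names(w) <- m$channel
  w
}
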