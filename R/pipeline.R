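#' Fit and detect in one pass
#'
#' The end-to-end unsupervised mode: build the cluster model from the
#' recording itself, then score the same recording against it.
#'
#' @param rec An `eeg_recording`.
#' @param config An [rp_config()].
#' @return List with `model` (`rp_model`) and `detection` (`rp_detection`).
#' @export
rp_pipeline <- function(rec, config = rp_config()) {
  model <- rp_fit(rec, config)
  detection <- rp_detect(rec, model, config)
  list(model = model, detection = detection)
}
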