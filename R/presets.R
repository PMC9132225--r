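#' Condition presets calibrated to the reported group outcomes
#'
#' Returns the generative parameters for one experimental condition of the
#' observational-fear MEA study design: `"naive"` (no stress exposure),
#' `"observer"` (psychological stress: watched a conspecific being
#' shocked) or `"demonstrator"` (physiological stress: received the foot
#' shocks). The per-layer LTP/LTD plateaus, recruited-channel amplitudes,
#' and expected recruited/silenced channel counts per slice are the
#' reported group means of the study this pipeline models, so that a
#' simulated cohort run through the full pipeline recovers them;
#' demonstrator presets yield no recruited and no silenced channels.
#'
#' @param condition `"naive"`, `"observer"` or `"demonstrator"`.
#' @param peakAmpUv baseline fEPSP amplitude at the stimulation site (uV).
#' @param activeMinUv minimum baseline amplitude of an activated channel
#'   (uV); the distance-decayed amplitude field is truncated to 0 below
#'   this, so activation truth is unambiguous at the 10 uV criterion.
#' @param tauPlasticityMin plasticity approach time constant (min).
#' @param channelSd between-channel SD of the plateau (multiplier scale).
#' @return A [ConditionPreset-class].
#' @examples
#' conditionPreset("observer")
#' @export
conditionPreset <- function(condition = c("naive", "observer", "demonstrator"),
                            peakAmpUv = 500, activeMinUv = 90,
                            tauPlasticityMin = 5, channelSd = 0.05) {
  condition <- match.arg(condition)
  lay <- function(s, d) c(superficial = s, deep = d)
  ltp <- switch(condition,
    naive        = lay(154.145, 148.872),
    observer     = lay(128.799, 132.249),
    demonstrator = lay(107.795, 107.558))
  ltd <- switch(condition,
    naive        = lay(67.375, 69.583),
    observer     = lay(84.644, 78.943),
    demonstrator = lay(83.772, 80.480))
  nRec <- switch(condition,
    naive        = lay(1.333, 3.667),
    observer     = lay(1.800, 1.800),
    demonstrator = lay(0, 0))
  recAmp <- switch(condition,
    naive        = lay(11.506, 13.937),
    observer     = lay(18.504, 13.411),
    demonstrator = lay(0, 0))
  nSil <- switch(condition,
    naive        = lay(1.400, 1.200),
    observer     = lay(2.333, 1.667),
    demonstrator = lay(0, 0))
  ppr <- c("25" = 1.40, "50" = 1.20, "75" = 1.10, "100" = 1.05)
  new("ConditionPreset", condition = condition,
      ltpPlateauPct = ltp, ltdPlateauPct = ltd, pprCurve = ppr,
      nRecruited = nRec, nSilenced = nSil, recruitedAmpUv = recAmp,
      peakAmpUv = peakAmpUv, activeMinUv = activeMinUv,
      tauPlasticityMin = tauPlasticityMin, channelSd = channelSd)
}
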