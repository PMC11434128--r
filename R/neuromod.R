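#' Map neuromodulator levels to effective parameters
#'
#' The neuromodulators act through three linear gains, all identity at the
#' wake reference levels (`ach = ha = gaba = 1`):
#' \itemize{
#'   \item potassium leak: `g_KL_eff = g_KL * (1 + kappa_ach*(1 - ach) +
#'     kappa_ha*(1 - ha))`, clamped at zero. Histamine gains are zero for the
#'     cortical types (histamine acts on thalamic leak).
#'   \item cortical AMPA weights: `w * (1 + lambda_ampa*(1 - ach))` — lower
#'     acetylcholine strengthens recurrent excitation.
#'   \item GABA-A weights: `w * gaba`.
#' }
#'
#' @param cfg A config object (supplies base parameters and gains).
#' @param levels A list or one-row data.frame with `ach`, `ha`, `gaba`.
#' @return A list with `g_kl` (named per population, mS/cm^2), `ampa_scale`
#'   and `gaba_scale` (dimensionless weight multipliers).
#' @examples
#' cfg <- default_config()
#' effective_params(cfg, list(ach = 1, ha = 1, gaba = 1)) # identity
#' @export
effective_params <- function(cfg, levels) {
  gkl <- vapply(pop_names, function(p) {
    base <- if (p %in% c("py", "inh")) cfg$cells[[p]]$dend$g_kl
            else cfg$cells[[p]]$g_kl
    modulated_gkl(base, levels, cfg$modulation[[p]]$kappa_ach,
                  cfg$modulation[[p]]$kappa_ha)
  }, 0)
  list(g_kl = gkl,
       ampa_scale = max(0, 1 + cfg$modulation$lambda_ampa *
                             (1 - levels$ach)),
       gaba_scale = levels$gaba)
}

#' Modulated potassium leak conductance
#'
#' @param g_kl_base Baseline (wake) leak density (mS/cm^2).
#' @param levels List with `ach` and `ha`.
#' @param kappa_ach,kappa_ha Non-negative gains.
#' @return Effective leak density, clamped at zero.
#' @export
modulated_gkl <- function(g_kl_base, levels, kappa_ach, kappa_ha = 0) {
  pmax(0, g_kl_base * (1 + kappa_ach * (1 - levels$ach) +
                         kappa_ha * (1 - levels$ha)))
}
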