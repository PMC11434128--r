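#' Channel kinetic constant table
#'
#' Machine-readable tabulation of every fixed kinetic constant used by the
#' compiled channel models: half-activation voltages, slopes, rate
#' constants, temperature factors and the calcium/messenger rates of the
#' regulated h-current. Functional forms are fixed in the integrator; the
#' constants that practitioners tune (maximal conductances, reversals,
#' calcium pool, modulation gains) live in the config instead. A copy of
#' this table ships as `inst/extdata/channel_params.tsv`.
#'
#' @return A data.frame with columns `channel`, `parameter`, `value`,
#'   `unit`, `description`.
#' @export
channel_param_table <- function() {
  row <- function(channel, parameter, value, unit, description)
    data.frame(channel = channel, parameter = parameter, value = value,
               unit = unit, description = description)
  rbind(
    row("it_tc", "m_vhalf", -59, "mV", "activation half-voltage"),
    row("it_tc", "m_slope", 6.2, "mV", "activation slope"),
    row("it_tc", "h_vhalf", -83, "mV", "inactivation half-voltage"),
    row("it_tc", "h_slope", -4.0, "mV", "inactivation slope"),
    row("it_tc", "phi_m", 6.96, "1", "activation temperature factor"),
    row("it_tc", "phi_h", 3.74, "1", "inactivation temperature factor"),
    row("it_re", "m_vhalf", -52, "mV", "activation half-voltage"),
    row("it_re", "m_slope", 7.4, "mV", "activation slope"),
    row("it_re", "h_vhalf", -80, "mV", "inactivation half-voltage"),
    row("it_re", "h_slope", -5.0, "mV", "inactivation slope"),
    row("ih", "s_vhalf", -75, "mV", "voltage gate half-activation"),
    row("ih", "s_slope", -5.5, "mV", "voltage gate slope"),
    row("ih", "k1", 2.5e7, "mM^-4 ms^-1", "Ca binding rate (on Ca^4)"),
    row("ih", "k2", 4e-4, "ms^-1", "Ca unbinding rate"),
    row("ih", "k3", 0.1, "ms^-1", "open-state locking rate (times P1)"),
    row("ih", "k4", 1e-3, "ms^-1", "unlocking rate"),
    row("ih", "g_inc", 2, "1", "locked-open conductance gain"),
    row("na_k", "vtraub", -63, "mV", "rate-function voltage shift"),
    row("km", "q", 2.95, "1", "rate temperature factor"),
    row("km", "vhalf", -30, "mV", "rate singular point (limit value)"),
    row("kca", "k_f", 5, "mM^-1 ms^-1", "Ca-dependent forward rate"),
    row("kca", "beta", 0.01, "ms^-1", "backward rate"),
    row("nap", "m_vhalf", -42, "mV", "activation half-voltage"),
    row("nap", "m_slope", 5, "mV", "activation slope"),
    row("hva", "q", 2.95, "1", "rate temperature factor"),
    row("ampa", "alpha", 1.1, "mM^-1 ms^-1", "binding rate"),
    row("ampa", "beta", 0.19, "ms^-1", "unbinding rate"),
    row("nmda", "alpha", 0.072, "mM^-1 ms^-1", "binding rate"),
    row("nmda", "beta", 0.0066, "ms^-1", "unbinding rate"),
    row("nmda", "mg_mm", 1, "mM", "extracellular magnesium"),
    row("gabaa", "alpha", 5, "mM^-1 ms^-1", "binding rate"),
    row("gabaa", "beta", 0.18, "ms^-1", "unbinding rate"),
    row("gabab", "K1", 0.52, "mM^-1 ms^-1", "receptor activation"),
    row("gabab", "K2", 0.0013, "ms^-1", "receptor deactivation"),
    row("gabab", "K3", 0.098, "ms^-1", "G-protein production"),
    row("gabab", "K4", 0.033, "ms^-1", "G-protein decay"),
    row("gabab", "Kd", 100, "1", "half-activation of G^4"),
    row("pulse", "amplitude", 0.5, "mM", "transmitter pulse amplitude"),
    row("pulse", "duration", 0.3, "ms", "transmitter pulse duration"))
}
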