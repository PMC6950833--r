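# Packaged Cav1.3 variant parameter sets. Boltzmann/reversal values are the
# published construct parameters (junction-corrected voltage scale);
# kinetic, CDI and tail parameters were calibrated with scripts/calibrate.R
# so that the simulated recordings, analyzed through this package's
# pipeline, reproduce the published activation/inactivation parameters and
# 5-s inactivation time courses. Regenerated by scripts/calibrate.R.

.cav13_presets <- list(
  WT_L = list(variant = "WT_L",
    v_half_act = -0.4180263905, slope_act =  9.52177334, g_max =         8.6, v_rev =        71.1,
    tau_act_min = 0.1559892444, tau_act_max = 1.2, tau_act_v = -0.4180263905, tau_act_k = 9.355332973,
    frac_fast = 0.1666494924, frac_slow = 0.6053503206, frac_persistent = 0.2280001871,
    tau_fast_0 =  158.486876, tau_slow_0 = 1782.655901, tau_v_dep = 153.7591782,
    v_half_inact = -25.70938975, slope_inact = 5.831494972,
    cdi_coupling = 1.683848263e-05, tau_cdi_recovery = 1767.987681,
    tail_slow_frac = 0.2696629213, tau_tail_slow =        1.12,
    q_on_total =       158.9, tau_q = 0.4,
    ic50 =        60.3, rundown_rate = 3),
  S652L_L = list(variant = "S652L_L",
    v_half_act = -16.48088203, slope_act = 8.201880439, g_max =         5.5, v_rev =        59.9,
    tau_act_min = 0.1703395683, tau_act_max = 1.2, tau_act_v = -16.48088203, tau_act_k =  9.94678024,
    frac_fast = 0.4873398874, frac_slow = 0.4031202715, frac_persistent = 0.1095398411,
    tau_fast_0 = 230.4588899, tau_slow_0 =  3022.59766, tau_v_dep = 58.24410545,
    v_half_inact = -43.94895182, slope_inact = 4.776734725,
    cdi_coupling = 5.244861197e-05, tau_cdi_recovery = 3228.810449,
    tail_slow_frac = 0.6506024096, tau_tail_slow =        1.95,
    q_on_total =       140.3, tau_q = 0.4,
    ic50 =        18.1, rundown_rate = 3),
  WT_S = list(variant = "WT_S",
    v_half_act = -10.73234661, slope_act = 7.562216202, g_max =           8, v_rev =        64.7,
    tau_act_min = 0.1583322844, tau_act_max = 1.2, tau_act_v = -10.73234661, tau_act_k = 6.793844956,
    frac_fast = 0.5665327117, frac_slow = 0.4074779386, frac_persistent = 0.02598934967,
    tau_fast_0 = 9910.003916, tau_slow_0 = 764.3262598, tau_v_dep = 29.29313947,
    v_half_inact = -35.39409371, slope_inact = 2.390000359,
    cdi_coupling = 0.0001268960865, tau_cdi_recovery = 489.5339408,
    tail_slow_frac =        0.27, tau_tail_slow =        1.12,
    q_on_total =          30, tau_q = 0.4,
    ic50 =        60.3, rundown_rate = 3),
  S652L_S = list(variant = "S652L_S",
    v_half_act = -23.3528521, slope_act = 7.463516585, g_max =           6, v_rev =        58.4,
    tau_act_min = 0.189985151, tau_act_max = 1.2, tau_act_v = -23.3528521, tau_act_k = 6.659561938,
    frac_fast = 0.6042158968, frac_slow = 0.3472909121, frac_persistent = 0.04849319113,
    tau_fast_0 =  322.116413, tau_slow_0 = 6747.273019, tau_v_dep = 33.58117575,
    v_half_inact = -48.71753314, slope_inact = 2.722351702,
    cdi_coupling = 0.0001572704921, tau_cdi_recovery = 944.7482433,
    tail_slow_frac =        0.65, tau_tail_slow =        1.95,
    q_on_total =          30, tau_q = 0.4,
    ic50 =        18.1, rundown_rate = 3),
  S652W_L = list(variant = "S652W_L",
    v_half_act =        4.23, slope_act =        8.73, g_max =         8.6, v_rev =        64.6,
    tau_act_min = 0.1547747066, tau_act_max = 1.2, tau_act_v =        4.23, tau_act_k = 10.47794673,
    frac_fast = 0.273590091, frac_slow = 0.6970698935, frac_persistent = 0.02934001552,
    tau_fast_0 =  388.241384, tau_slow_0 = 8024.026587, tau_v_dep = 28.93060822,
    v_half_inact = -18.0943699, slope_inact = 2.869814997,
    cdi_coupling = 2.627099416e-05, tau_cdi_recovery = 2617.707367,
    tail_slow_frac =        0.27, tau_tail_slow =        1.12,
    q_on_total =         150, tau_q = 0.4,
    ic50 =        60.3, rundown_rate = 3)
)
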