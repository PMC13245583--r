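#' Acquisition configuration
#'
#' Timing and labeling parameters of the three simulated sequences: the
#' multi-echo SSFP FID/ECHO acquisition (paired FID and ECHO readouts per TR),
#' velocity-selective venous spin labeling (VS-VSL), and pseudo-continuous ASL
#' (pCASL). All times are in seconds internally; the defaults correspond to a
#' 3 T protocol with 17 echoes at 1.5 ms spacing and TR 30 ms, VS-VSL with
#' TI 1.14 s, and pCASL with a 2 s post-labeling delay and 6 control/tag
#' pairs.
#'
#' @param ausfide_first_te_fid First FID echo time, s.
#' @param ausfide_first_te_echo First ECHO echo time, s.
#' @param ausfide_echo_spacing Echo spacing, s.
#' @param ausfide_n_echoes Number of echoes per component (>= 2).
#' @param ausfide_tr SSFP repetition time, s.
#' @param vsvl_tr,vsvl_ts,vsvl_ti VS-VSL repetition, saturation, inversion
#'   times, s.
#' @param pcasl_pld Post-labeling delay, s.
#' @param pcasl_label_duration Label duration tau, s.
#' @param pcasl_n_pairs Number of control/label pairs.
#' @param blood_t1 Longitudinal relaxation time of arterial blood, s.
#' @param labeling_efficiency pCASL labeling efficiency alpha.
#' @param partition_coefficient Blood-brain partition coefficient lambda,
#'   mL/g.
#'
#' @return An `acquisition_config` list with derived echo-time vectors
#'   `te_fid` and `te_echo`.
#' @examples
#' acq <- acquisition_config()
#' acq$te_fid
#' @export
acquisition_config <- function(ausfide_first_te_fid = 1.6e-3,
                               ausfide_first_te_echo = 2.2e-3,
                               ausfide_echo_spacing = 1.5e-3,
                               ausfide_n_echoes = 17L,
                               ausfide_tr = 30e-3,
                               vsvl_tr = 3.0,
                               vsvl_ts = 1.65,
                               vsvl_ti = 1.14,
                               pcasl_pld = 2.0,
                               pcasl_label_duration = 1.8,
                               pcasl_n_pairs = 6L,
                               blood_t1 = 1.65,
                               labeling_efficiency = 0.85,
                               partition_coefficient = 0.9) {
  times <- c(ausfide_first_te_fid, ausfide_first_te_echo,
             ausfide_echo_spacing, ausfide_tr, vsvl_tr, vsvl_ts, vsvl_ti,
             pcasl_pld, pcasl_label_duration, blood_t1)
  if (any(times <= 0)) abort("All acquisition times must be positive.")
  ausfide_n_echoes <- as.integer(ausfide_n_echoes)
  if (ausfide_n_echoes < 2L) abort("`ausfide_n_echoes` must be >= 2.")
  if (pcasl_n_pairs < 1L) abort("`pcasl_n_pairs` must be >= 1.")
  te_fid <- ausfide_first_te_fid +
    ausfide_echo_spacing * (seq_len(ausfide_n_echoes) - 1L)
  te_echo <- ausfide_first_te_echo +
    ausfide_echo_spacing * (seq_len(ausfide_n_echoes) - 1L)
  if (max(te_fid) >= ausfide_tr) {
    abort("Last FID echo time must be earlier than the repetition time.")
  }
  if (max(te_echo) >= ausfide_tr) {
    abort("Last ECHO echo time must be earlier than the repetition time.")
  }
  structure(
    list(ausfide_first_te_fid = ausfide_first_te_fid,
         ausfide_first_te_echo = ausfide_first_te_echo,
         ausfide_echo_spacing = ausfide_echo_spacing,
         ausfide_n_echoes = ausfide_n_echoes,
         ausfide_tr = ausfide_tr,
         vsvl_tr = vsvl_tr, vsvl_ts = vsvl_ts, vsvl_ti = vsvl_ti,
         pcasl_pld = pcasl_pld,
         pcasl_label_duration = pcasl_label_duration,
         pcasl_n_pairs = as.integer(pcasl_n_pairs),
         blood_t1 = blood_t1,
         labeling_efficiency = labeling_efficiency,
         partition_coefficient = partition_coefficient,
         te_fid = te_fid, te_echo = te_echo),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("<acquisition_config>\n")
  cat(sprintf("  FID/ECHO: %d echoes, first TE %.2f/%.2f ms, spacing %.2f ms, TR %.1f ms\n",
              x$ausfide_n_echoes, 1e3 * x$ausfide_first_te_fid,
              1e3 * x$ausfide_first_te_echo, 1e3 * x$ausfide_echo_spacing,
              1e3 * x$ausfide_tr))
  cat(sprintf("  VS-VSL:   TR %.2f s, TS %.2f s, TI %.2f s\n",
              x$vsvl_tr, x$vsvl_ts, x$vsvl_ti))
  cat(sprintf("  pCASL:    PLD %.2f s, tau %.2f s, %d pairs, alpha %.2f, lambda %.2f, T1b %.2f s\n",
              x$pcasl_pld, x$pcasl_label_duration, x$pcasl_n_pairs,
              x$labeling_efficiency, x$partition_coefficient, x$blood_t1))
  invisible(x)
}
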