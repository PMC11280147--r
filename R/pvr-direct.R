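#' Directly computed per-lung pulmonary vascular resistance
#'
#' The non-iterative baseline estimate: per lung, the transpulmonary pressure
#' gradient from catheterization divided by the CMR branch flow,
#' `R_L = (P_SVC - P_LA) / Q_LPA` and `R_R = (P_SVC - P_LA) / Q_RPA`
#' (all BSA-indexed, so the result is in WU.m^2). The total PVR of the two
#' parallel lungs is also reported.
#'
#' @param records Patient table (see [load_patient_table()]).
#' @return A tibble with one row per patient: `pid`, `pvr_lpa`, `pvr_rpa`,
#'   `pvr_total`, and the catheterization total PVR `pvr_cath` for reference.
#' @details A zero branch flow is a domain error naming the branch. A negative
#'   pressure gradient is physiologically suspect but allowed with a warning.
#' @export
#' @examples
#' computed_pvr(load_patient_table("bundled"))
computed_pvr <- function(records) {
  zero_l <- records$q_lpa <= 0
  zero_r <- records$q_rpa <= 0
  if (any(zero_l) || any(zero_r)) {
    branch <- if (any(zero_l)) "q_lpa" else "q_rpa"
    pid <- records$pid[if (any(zero_l)) zero_l else zero_r][1L]
    stop(sprintf("zero branch flow (%s) for patient %s: computed PVR undefined",
                 branch, pid), call. = FALSE)
  }
  dp <- records$p_svc - records$p_la
  if (any(dp < 0)) {
    warning("negative SVC-to-LA pressure gradient for patient(s) ",
            paste(records$pid[dp < 0], collapse = ", "),
            "; computed PVR will be negative", call. = FALSE)
  }
  r_l <- dp / records$q_lpa
  r_r <- dp / records$q_rpa
  tibble::tibble(
    pid = records$pid,
    pvr_lpa = r_l,
    pvr_rpa = r_r,
    pvr_total = ifelse(r_l > 0 & r_r > 0, r_l * r_r / (r_l + r_r), NA_real_),
    pvr_cath = records$pvr_cath
  )
}

#' Total PVR of two lungs in parallel
#'
#' Both lungs see the same driving gradient (SVC to left atrium), so their
#' resistances combine in parallel: `r_l * r_r / (r_l + r_r)`. Algebraically
#' identical to gradient over summed flow, `(P_SVC - P_LA)/(Q_LPA + Q_RPA)`,
#' when both per-lung values share the gradient.
#'
#' @param r_l,r_r Per-lung PVR, WU.m^2 (> 0). Vectorized.
#' @return Total PVR, WU.m^2.
#' @export
#' @examples
#' total_pvr(6, 6)
total_pvr <- function(r_l, r_r) {
  if (any(!is.finite(r_l) | r_l <= 0) || any(!is.finite(r_r) | r_r <= 0)) {
    stop("per-lung PVR values must be finite and > 0", call. = FALSE)
  }
  r_l * r_r / (r_l + r_r)
}
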