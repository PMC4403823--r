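#' Oxygen carrying capacity from paired respirometry traces
#'
#' Measures the injection step of a haemolymph trace and a seawater control
#' trace, removes the linear background oxygen flux fitted on the
#' pre-injection segment of each trace, and converts the dissolved-O2
#' corrected step to a carrying capacity per litre of sample:
#' `capacity = (step_sample - step_control) * chamber_vol / sample_vol`.
#'
#' Step sizes are differences of plateau medians (robust to spikes); the
#' background line is fitted on the pre-injection segment only, so the
#' estimate is invariant to any common linear drift in both traces.
#'
#' @param sample_trace,control_trace Data frames (`time_s`, `o2_umol_l`),
#'   e.g. from [simulate_respirometry()]. Each needs pre- and post-injection
#'   plateaus.
#' @param sample_vol Injected volume, microlitres.
#' @param chamber_vol Chamber volume, millilitres.
#' @param injection_time Injection time, s; defaults to the trace attribute.
#' @param settle Seconds after injection excluded from the post plateau.
#' @return Carrying capacity, mmol O2 per litre of sample.
#' @export
carrying_capacity_from_respirometry <- function(sample_trace, control_trace,
                                                sample_vol = 10,
                                                chamber_vol = 2,
                                                injection_time = NULL,
                                                settle = 30) {
  stop_if_not_scalar(sample_vol, "sample_vol", positive = TRUE)
  stop_if_not_scalar(chamber_vol, "chamber_vol", positive = TRUE)
  step_of <- function(trace) {
    t0 <- injection_time
    if (is.null(t0)) t0 <- attr(trace, "injection_time")
    if (is.null(t0)) stop("injection_time not given and not a trace attribute")
    pre <- trace[trace$time_s < t0, , drop = FALSE]
    post <- trace[trace$time_s > t0 + settle, , drop = FALSE]
    if (nrow(pre) < 3 || nrow(post) < 3) {
      stop("trace lacks pre- or post-injection plateau")
    }
    bg <- lm(o2_umol_l ~ time_s, data = pre)
    pre_resid <- resid(bg)
    post_detr <- post$o2_umol_l - predict(bg, newdata = post)
    list(step = median(post_detr) - median(pre_resid),
         noise_sd = sd(pre_resid))
  }
  s <- step_of(sample_trace)
  ctl <- step_of(control_trace)
  if (s$step < 3 * s$noise_sd) {
    stop("no detectable injection step in the sample trace ",
         "(below 3x the baseline noise sd)")
  }
  (s$step - ctl$step) * (chamber_vol * 1000 / sample_vol) / 1000
}
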