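#' Plot the tick-level trajectory of a session log
#'
#' Video score, difficulty level and neurofeedback score against session
#' time, with EMG-gated ticks marked.
#'
#' @param log a `session_log`.
#' @return a ggplot object.
#' @export
plot_session_log <- function(log) {
  t <- log$ticks
  df <- rbind(
    data.frame(time_s = t$time_s, value = t$video_score,
               what = "video score"),
    data.frame(time_s = t$time_s, value = t$level, what = "difficulty"),
    data.frame(time_s = t$time_s, value = t$nfb_score, what = "NFB score"))
  ggplot2::ggplot(df, ggplot2::aes(.data[["time_s"]], .data[["value"]])) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data[["what"]]),
                        scales = "free_y") +
    ggplot2::geom_point(
      data = data.frame(time_s = t$time_s[t$emg_flag],
                        value = t$nfb_score[t$emg_flag],
                        what = "NFB score"),
      color = "red", size = 0.6) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Session trajectory (red: EMG-gated ticks)")
}

#' Plot a group x session ERD/S summary
#'
#' @param summary output of [summarize_group_session()].
#' @return a ggplot object.
#' @export
plot_erds_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data[["session"]], .data[["mean_log2_erds"]],
                               color = .data[["group"]])) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[["mean_log2_erds"]] - .data[["sd_log2_erds"]],
                   ymax = .data[["mean_log2_erds"]] + .data[["sd_log2_erds"]]),
      width = 0.1, position = ggplot2::position_dodge(0.2)) +
    ggplot2::facet_grid(ggplot2::vars(.data[["task"]]),
                        ggplot2::vars(.data[["hemisphere"]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "session", y = "mean log2 ERD/S")
}
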