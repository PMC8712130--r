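#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom utils head packageVersion
#' @export
generics::tidy

#' @export
generics::glance

#' Plot behavioural scores by load and modality
#'
#' Mean accuracy, correct RT and IES per n-back level and modality with
#' subject-level points.
#'
#' @param behavior Behaviour tibble from [run_pipeline()] / [score_session()].
#' @return A ggplot object.
#' @export
plot_behavior <- function(behavior) {
  long <- behavior |>
    select("subject", "modality", "level", ACC = "acc",
           RT = "mean_rt_correct_ms", IES = "ies_ms") |>
    tidyr::pivot_longer(c("ACC", "RT", "IES"), names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$level), y = .data$value,
                                     colour = .data$modality)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        alpha = 0.4, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          ggplot2::aes(group = .data$modality),
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2.5,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "n-back level", y = NULL, colour = "modality")
}

#' Plot normalized cluster band power by condition
#'
#' @param cluster_power Cluster power tibble from [run_pipeline()].
#' @param bands Bands to show.
#' @return A ggplot object.
#' @export
plot_cluster_power <- function(cluster_power, bands = c("theta", "gamma")) {
  df <- filter(cluster_power, .data$band %in% bands)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$level), y = .data$power,
                                   colour = .data$modality)) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          ggplot2::aes(group = .data$modality)) +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::facet_grid(band ~ cluster, scales = "free_y") +
    ggplot2::labs(x = "n-back level", y = "power / baseline",
                  colour = "modality")
}

#' Plot the channel-averaged Welch spectrum of a recording
#'
#' @param rec An `eeg_recording`.
#' @param channels Channels to average (default all).
#' @param fmax Upper frequency limit shown.
#' @return A ggplot object.
#' @export
plot_psd <- function(rec, channels = rec$channels, fmax = 45) {
  channels <- resolve_channels(channels, rec$channels)
  sp <- welch_psd(rec$data[, channels, drop = FALSE], rec$fs, window_s = 2,
                  overlap_s = 1)
  df <- tibble(freq = sp$freq, psd = rowMeans(sp$psd)) |>
    filter(.data$freq > 0, .data$freq <= fmax)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (uV²/Hz)")
}

#' @export
autoplot.vwm_report <- function(object, ...) {
  plot_cluster_power(object$cluster_power)
}
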