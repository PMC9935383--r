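#' Annotated sense/antisense coverage plot for a group profile
#'
#' Normalised mean counts per position with the across-sample min-max band,
#' sense and antisense as separate series. Antisense is drawn below a zero
#' baseline so the two orientations never overplot. Construct features are
#' rendered as labelled boxes beneath the axis.
#'
#' @param profile A `group_profile`.
#' @param features Optional `feature_table` on the profile's construct.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, features = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  len <- length(profile$mean_sense)
  if (len == 0L) stop("empty profile", call. = FALSE)
  pos <- seq_len(len) - 1L
  df <- rbind(
    data.frame(position = pos, strand = "sense",
               mean = profile$mean_sense, lo = profile$min_sense,
               hi = profile$max_sense),
    data.frame(position = pos, strand = "antisense",
               mean = -profile$mean_antisense, lo = -profile$max_antisense,
               hi = -profile$min_antisense)
  )
  ymax <- max(df$hi, 1e-9)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, fill = .data$strand),
      alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean, colour = .data$strand)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(sense = "#1b6ca8", antisense = "#c0392b"),
      aesthetics = c("colour", "fill")) +
    ggplot2::labs(
      title = paste0(profile$group_id, " / ", profile$construct_id),
      x = "nucleotide position",
      y = "normalised counts (antisense below axis)") +
    ggplot2::theme_minimal()
  if (!is.null(features) && nrow(features) > 0L) {
    feats <- features[features$construct_id == profile$construct_id, ,
                      drop = FALSE]
    if (any(feats$end > len)) {
      stop("feature '", feats$name[which(feats$end > len)[1L]],
           "' outside construct bounds", call. = FALSE)
    }
    band <- 0.06 * ymax
    feats$ymin <- -max(-df$lo, 0) - 2 * band
    feats$ymax <- feats$ymin + band
    p <- p +
      ggplot2::geom_rect(
        data = feats,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = .data$ymin, ymax = .data$ymax),
        inherit.aes = FALSE, fill = "grey70", colour = "grey30",
        linewidth = 0.2) +
      ggplot2::geom_text(
        data = feats,
        ggplot2::aes(x = (.data$start + .data$end) / 2,
                     y = .data$ymin - band / 2, label = .data$name),
        inherit.aes = FALSE, size = 2.4, angle = 45, hjust = 1)
  }
  p
}
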