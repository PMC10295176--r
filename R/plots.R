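# Envelope plots in the style of the protocol figures: observed summary
# function as a solid line, null-model envelopes as shaded bands.

#' Plot a summary function with its reference envelope
#'
#' @param env an [EnvelopeResult-class], or a named list of them (one band
#'   per null model)
#' @return a ggplot object
#' @export
plotEnvelope <- function(env) {
  envs <- if (is(env, "EnvelopeResult")) list(model = env) else env
  bands <- do.call(rbind, lapply(names(envs), function(nm) {
    cbind(as.data.frame(envs[[nm]]), model = nm)
  }))
  first <- envs[[1]]
  ggplot2::ggplot(bands, ggplot2::aes(x = r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi, fill = model),
                         alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = mean, colour = model),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = data), colour = "black") +
    ggplot2::labs(x = "r [um]", y = first@statistic) +
    ggplot2::theme_minimal()
}
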