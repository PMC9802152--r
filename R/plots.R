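#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs facet_wrap scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Concentration of every species against time.
#'
#' @param object an `eff_trajectory` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eff_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"time", names_to = "species",
                              values_to = "concentration")
  ggplot(long, aes(x = .data$time, y = .data$concentration,
                   colour = .data$species)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "time", y = "concentration")
}

#' Plot diffusion-map nonharmonic residuals
#'
#' Residual of each candidate eigenvector under the parsimonious
#' local-linear-regression test; retained eigenvectors (new intrinsic
#' directions) stand out near 1.
#'
#' @param object a `dmaps` object.
#' @param selection a [parsimonious_select()] result (computed if missing).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dmaps <- function(object, selection = NULL, ...) {
  if (is.null(selection)) selection <- parsimonious_select(object)
  d <- tidy(object, selection = selection)
  d <- d[!is.na(d$residual) & d$index > 0, ]
  ggplot(d, aes(x = factor(.data$index), y = .data$residual,
                fill = .data$retained)) +
    geom_col() +
    geom_hline(yintercept = selection$threshold, linetype = 2) +
    labs(x = "eigenvector index", y = "nonharmonic residual")
}

#' Plot JSF scores against the joint-smoothness ceiling
#'
#' @param object a `jsf_basis` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.jsf_basis <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$index, y = .data$score,
                colour = .data$jointly_smooth)) +
    geom_point() +
    geom_hline(yintercept = sqrt(2), linetype = 2) +
    labs(x = "function index", y = "joint-smoothness score")
}

#' Plot conformal-autoencoder training losses
#'
#' @param object a `cae_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cae_model <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$value,
                           colour = .data$loss)) +
    geom_line() + scale_y_log10() +
    labs(x = "epoch", y = "loss component")
}
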