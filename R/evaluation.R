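#' Model-vs-observation summary statistics
#'
#' The statistics reported throughout model validation: means and standard
#' deviations (n - 1 denominator) of both series, the root mean square error
#' expressed as a percentage of the observed mean
#' (`100 / mean_obs * sqrt(sum((obs - sim)^2) / n)`), and the Pearson
#' sample correlation coefficient.
#'
#' @param obs,sim paired numeric vectors of equal length (n >= 2), no NA
#' @return named list: mean_obs, sd_obs, mean_sim, sd_sim, rmse_pct, r
#' @export
summary_stats <- function(obs, sim) {
  if (length(obs) != length(sim)) stop("obs and sim must have equal length")
  if (anyNA(obs) || anyNA(sim)) stop("missing values in paired series")
  n <- length(obs)
  if (n < 2) stop("need at least two pairs")
  m_obs <- mean(obs)
  if (m_obs == 0) stop("RMSE%% undefined: observed mean is zero")
  rmse <- sqrt(sum((obs - sim)^2) / n)
  list(mean_obs = m_obs, sd_obs = stats::sd(obs),
       mean_sim = mean(sim), sd_sim = stats::sd(sim),
       rmse_pct = 100 * rmse / m_obs,
       r = stats::cor(obs, sim))
}
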